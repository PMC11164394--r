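test_that("per-cycle FN probability composes baseline, cycle, history and drug effects", {
  p <- base_params
  expect_equal(fn_probability(1, FALSE, 1, p), 0.364)
  expect_equal(fn_probability(2, TRUE, 1, p), 0.364 * 0.46 * 2.4)
  expect_equal(fn_probability(3, FALSE, 0.334, p), 0.364 * 0.46 * 0.334)
  expect_equal(fn_probability(4, FALSE, 0, p), 0)
  # cap at 1 under extreme multipliers (set_fn_param skips range checks)
  p_hot <- set_fn_param(set_fn_param(p, "p_fn_cycle1", 0.9),
                        "rr_history", 2.6)
  expect_equal(fn_probability(1, TRUE, 1, p_hot), 1)
  expect_error(fn_probability(1, FALSE, -1, p), "non-negative")
})

test_that("drug RR follows the prophylaxis mode and cycle tier", {
  p <- base_params
  pp_fil <- fn_strategy("primary", "filgrastim")
  sp_len <- fn_strategy("secondary", "lenograstim")
  expect_equal(drug_rr_for(pp_fil, 2, FALSE, p), 0.640)
  expect_equal(drug_rr_for(pp_fil, 3, FALSE, p), 0.575)
  expect_equal(drug_rr_for(sp_len, 1, FALSE, p), 1)
  expect_equal(drug_rr_for(sp_len, 4, TRUE, p), 0.609)
  expect_equal(drug_rr_for(sp_len, 2, TRUE, p), 0.452)
  expect_equal(drug_rr_for(fn_strategy("none"), 5, TRUE, p), 1)
  # pegfilgrastim: one RR in all cycles
  pp_peg <- fn_strategy("primary", "pegfilgrastim")
  expect_equal(drug_rr_for(pp_peg, 1, FALSE, p),
               drug_rr_for(pp_peg, 6, TRUE, p))
})

test_that("expectation engine equals exhaustive path enumeration for every strategy", {
  for (s in c(all_strategies, scenario2_strategies())) {
    got <- run_chemo_phase(s, base_params)
    want <- oracle_chemo(s, base_params)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = paste(s$label, f))
    }
  }
})

test_that("cohort mass is conserved each cycle", {
  for (s in all_strategies) {
    out <- run_chemo_phase(s, base_params)
    total <- out$survivors_without_history + out$survivors_with_history +
      out$expected_fn_deaths
    expect_equal(total, 1, tolerance = 1e-12)
    expect_true(all(out$trace$alive_start <= 1 + 1e-12))
    expect_true(all(diff(out$trace$alive_start) <= 1e-12))
  }
})

test_that("degenerate inputs behave: zero baseline risk, perfect prophylaxis", {
  p0 <- fn_params(p_fn_cycle1 = 0, ranges = {
    r <- fncea:::default_ranges(); r$p_fn_cycle1 <- c(0, 0.436); r
  })
  out <- run_chemo_phase(fn_strategy("none"), p0)
  expect_equal(out$expected_fn_events, 0)
  expect_equal(out$cost_total, 0)
  expect_equal(out$survivors_without_history, 1)
})

test_that("expected FN events are monotone in drug RR and baseline risk", {
  events_at_rr <- function(rr) {
    d <- default_drug_table()
    d[d$drug == "pegfilgrastim", c("rr_cycles_1_2", "rr_cycles_3plus")] <- rr
    d[d$drug == "pegfilgrastim_biosimilar",
      c("rr_cycles_1_2", "rr_cycles_3plus")] <- rr
    p <- fn_params(drugs = d, ranges = {
      r <- fncea:::default_ranges(); r$rr_pegfilgrastim <- c(0, 1.1); r
    })
    run_chemo_phase(fn_strategy("primary", "pegfilgrastim"),
                    p)$expected_fn_events
  }
  ev <- vapply(seq(0.05, 1.05, by = 0.2), events_at_rr, 0)
  expect_true(all(diff(ev) > 0))

  events_at_p1 <- function(p1) {
    p <- fn_params(p_fn_cycle1 = p1, ranges = {
      r <- fncea:::default_ranges(); r$p_fn_cycle1 <- c(0, 1); r
    })
    run_chemo_phase(fn_strategy("none"), p)$expected_fn_events
  }
  ev <- vapply(seq(0.05, 0.95, by = 0.15), events_at_p1, 0)
  expect_true(all(diff(ev) > 0))
})

test_that("primary prophylaxis never uses less drug than secondary", {
  for (drug in c("filgrastim", "lenograstim", "pegfilgrastim")) {
    pp <- run_chemo_phase(fn_strategy("primary", drug), base_params)
    sp <- run_chemo_phase(fn_strategy("secondary", drug), base_params)
    expect_gt(pp$cost_drug, sp$cost_drug)
  }
})

test_that("cost difference across prices equals price gap times injections", {
  pp_peg <- run_chemo_phase(fn_strategy("primary", "pegfilgrastim"),
                            base_params)
  pp_bio <- run_chemo_phase(fn_strategy("primary", "pegfilgrastim_biosimilar"),
                            base_params)
  expect_equal(pp_peg$expected_injections, pp_bio$expected_injections)
  expect_equal(pp_peg$cost_total - pp_bio$cost_total,
               (16626 - 14457) * pp_peg$expected_injections)
})

test_that("RDI classification uses the converted odds ratio for FN history", {
  out <- run_chemo_phase(fn_strategy("none"), base_params)
  expect_equal(p_rdi_low(FALSE, base_params), 0.247)
  expect_equal(p_rdi_low(TRUE, base_params),
               0.247 * or_to_rr(1.58, 0.247))
  strata <- classify_rdi(out, base_params)
  expect_equal(sum(strata$mass),
               out$survivors_without_history + out$survivors_with_history)
  # null odds ratio: both strata at baseline
  p1 <- set_fn_param(base_params, "or_rdi_low", 1)
  expect_equal(p_rdi_low(TRUE, p1), p_rdi_low(FALSE, p1))
})
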