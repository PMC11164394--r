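pp_leno_vs_none <- list(fn_strategy("primary", "lenograstim"),
                        fn_strategy("none"))
pp_peg_vs_pp_leno <- list(fn_strategy("primary", "pegfilgrastim"),
                          fn_strategy("primary", "lenograstim"))

test_that("scenario 1 severs the RDI-mortality link and raises every QALY total", {
  sc1 <- run_scenario(1, base_params, base_life_table)
  base <- fn_cea(base_params, all_strategies, base_life_table)
  expect_true(all(sc1$results$qalys > base$results$qalys))
  expect_equal(sc1$results$cost, base$results$cost)  # costs unaffected
  # with a null hazard ratio scenario 1 is the base case
  p1 <- set_fn_param(base_params, "hr_rdi_low", 1)
  expect_equal(run_scenario(1, p1, base_life_table)$results,
               fn_cea(p1, default_strategies(), base_life_table)$results)
})

test_that("scenario 2 adds biosimilars which dominate their reference products", {
  sc2 <- run_scenario(2, base_params, base_life_table)
  expect_equal(nrow(sc2$results), 11)
  fr <- sc2$frontier
  status <- setNames(fr$status, fr$label)
  expect_equal(status[["PP with pegfilgrastim"]], "dominated")
  expect_equal(status[["SP with filgrastim"]], "dominated")
  qb <- fr$qalys[fr$label == "PP with pegfilgrastim biosimilar"]
  qr <- fr$qalys[fr$label == "PP with pegfilgrastim"]
  expect_equal(qb, qr)  # same molecule, same effectiveness
  cb <- fr$cost[fr$label == "PP with pegfilgrastim biosimilar"]
  expect_lt(cb, fr$cost[fr$label == "PP with pegfilgrastim"])
})

test_that("distribution fitting matches the moment targets", {
  specs <- psa_distributions(base_params)
  # beta: mean = base, sd = range width / 3.92
  s <- specs$p_fn_cycle1
  expect_equal(s$shape1 / (s$shape1 + s$shape2), 0.364)
  v <- with(s, shape1 * shape2 / ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_equal(sqrt(v), (0.436 - 0.293) / 3.92)
  # gamma: mean = base, sd = range width / 3.92
  g <- specs$cost_fn_event
  expect_equal(g$shape / g$rate, 8287)
  expect_equal(sqrt(g$shape) / g$rate, (9944 - 6630) / 3.92)
  # log-normal: median = base; 2.5/97.5 quantiles near the printed range
  ln <- specs$rr_history
  expect_equal(exp(ln$meanlog), 2.4)
  expect_equal(qlnorm(c(0.025, 0.975), ln$meanlog, ln$sdlog),
               c(2.2, 2.6), tolerance = 0.01)
  expect_equal(specs$price_pegfilgrastim$family, "fixed")
  # infeasible beta moments are reported by parameter name
  p_bad <- base_params
  p_bad$ranges$p_fn_death <- c(0, 0.8)
  p_bad$p_fn_death <- 0.036
  expect_error(psa_distributions(p_bad), "p_fn_death")
})

test_that("PSA draws are calibrated, fixed parameters never move", {
  set.seed(42)
  d <- sample_psa(base_params, 1e5)
  expect_equal(mean(d$p_fn_cycle1), 0.364, tolerance = 0.02)
  expect_equal(mean(d$cost_fn_event), 8287, tolerance = 0.02 * 8287 / 8287)
  expect_equal(median(d$rr_history), 2.4, tolerance = 0.02)
  expect_equal(unname(quantile(d$rr_history, c(0.025, 0.975))),
               c(2.2, 2.6), tolerance = 0.02)
  expect_true(all(d$price_pegfilgrastim == 16626))
  expect_true(all(d$discount_rate == 0.03))
  expect_true(all(d$p_fn_cycle1 > 0 & d$p_fn_cycle1 < 1))
  expect_true(all(d$cost_fn_event > 0))
})

test_that("one-way sensitivity recomputes ICERs at range endpoints", {
  row <- one_way("cost_fn_event", pp_leno_vs_none, base_params,
                 base_life_table)
  expect_equal(row$low, 6630)
  expect_equal(row$high, 9944)
  # FN cost affects the comparator more: analytic slope check
  a <- run_chemo_phase(fn_strategy("primary", "lenograstim"), base_params)
  b <- run_chemo_phase(fn_strategy("none"), base_params)
  dq <- evaluate_strategy(fn_strategy("primary", "lenograstim"), base_params,
                          base_life_table)$qalys -
    evaluate_strategy(fn_strategy("none"), base_params,
                      base_life_table)$qalys
  slope <- (a$expected_fn_events - b$expected_fn_events) / dq
  expect_equal((row$icer_at_high - row$icer_at_low) / (9944 - 6630), slope,
               tolerance = 1e-9)
  expect_equal(row$span, abs(row$icer_at_high - row$icer_at_low))
  # zero-width range
  p0 <- base_params
  p0$ranges$rr_history <- c(2.4, 2.4)
  expect_equal(one_way("rr_history", pp_leno_vs_none, p0,
                       base_life_table)$span, 0)
  expect_error(one_way("nonexistent", pp_leno_vs_none, base_params,
                       base_life_table), "range")
})

test_that("tornado ranks pegfilgrastim's RR first for the long- vs short-acting comparison", {
  tor <- owsa(pp_peg_vs_pp_leno, base_params, base_life_table)
  expect_equal(tor$parameter[1], "rr_pegfilgrastim")
  expect_true(all(diff(tor$span) <= 0))
})

test_that("discount rate is among the four most influential parameters for PP lenograstim vs none", {
  tor <- owsa(pp_leno_vs_none, base_params, base_life_table)
  expect_true("discount_rate" %in% tor$parameter[1:4])
  expect_true(any(grepl("rr_lenograstim", tor$parameter[1:4])))
})

test_that("threshold search matches the analytic crossing of an ICER linear in FN cost", {
  # drug costs and FN event counts do not depend on cost_fn_event, so the
  # ICER of PP lenograstim vs none is exactly linear in it; solve for the
  # crossing in closed form and require bisection to agree
  a_ch <- run_chemo_phase(fn_strategy("primary", "lenograstim"), base_params)
  b_ch <- run_chemo_phase(fn_strategy("none"), base_params)
  a <- evaluate_strategy(fn_strategy("primary", "lenograstim"), base_params,
                         base_life_table)
  b <- evaluate_strategy(fn_strategy("none"), base_params, base_life_table)
  dq <- a$qalys - b$qalys
  d_drug <- a_ch$cost_drug - b_ch$cost_drug
  d_fn <- a_ch$expected_fn_events - b_ch$expected_fn_events
  icer_at <- function(cost) (d_drug + d_fn * cost) / dq
  target <- (icer_at(6630) + icer_at(9944)) / 2   # inside the bracket's span
  analytic <- (target * dq - d_drug) / d_fn
  got <- threshold_search("cost_fn_event", pp_leno_vs_none, target,
                          base_params, base_life_table,
                          bracket = c(6630, 9944), tol = 1e-8)
  expect_equal(got, analytic, tolerance = 1e-6)
})

test_that("threshold search degenerate and failure modes", {
  base_icer <- fncea:::icer_between(pp_leno_vs_none[[1]], pp_leno_vs_none[[2]],
                                    base_params, base_life_table)
  got <- threshold_search("cost_fn_event", pp_leno_vs_none, base_icer,
                          base_params, base_life_table, tol = 1e-6)
  expect_equal(got, 8287, tolerance = 1e-4)
  expect_error(
    threshold_search("cost_fn_event", pp_leno_vs_none, 1e7,
                     base_params, base_life_table),
    "cross")
})

test_that("pegfilgrastim's FN relative risk has a WTP crossing inside its range", {
  rr_star <- threshold_search("rr_pegfilgrastim", pp_peg_vs_pp_leno,
                              base_params$wtp, base_params, base_life_table)
  expect_gt(rr_star, 0.2097)
  expect_lt(rr_star, 0.5319)
  p_star <- set_fn_param(base_params, "rr_pegfilgrastim", rr_star)
  icer <- fncea:::icer_between(pp_peg_vs_pp_leno[[1]], pp_peg_vs_pp_leno[[2]],
                               p_star, base_life_table)
  expect_equal(icer, base_params$wtp, tolerance = 1 / base_params$wtp)
})

test_that("PSA with every distribution fixed reproduces the base case each iteration", {
  p_fix <- base_params
  p_fix$dist_family[] <- "fixed"
  ceac <- run_psa(p_fix, all_strategies, base_life_table, n_iter = 10,
                  seed = 1)
  base <- fn_cea(base_params, all_strategies, base_life_table)
  for (it in 1:10) {
    expect_equal(unname(ceac$cost[it, ]), base$results$cost)
    expect_equal(unname(ceac$qalys[it, ]), base$results$qalys)
  }
  expect_true(all(ceac$prob %in% c(0, 1)))
})

test_that("PSA is deterministic given a seed and probabilities sum to one", {
  a <- run_psa(base_params, all_strategies, base_life_table, n_iter = 40,
               seed = 9, wtp_grid = c(0, 5e5, 976914))
  b <- run_psa(base_params, all_strategies, base_life_table, n_iter = 40,
               seed = 9, wtp_grid = c(0, 5e5, 976914))
  expect_identical(a$cost, b$cost)
  expect_identical(a$prob, b$prob)
  expect_equal(unname(rowSums(a$prob)), rep(1, length(a$wtp)))
  expect_true(all(a$prob >= 0 & a$prob <= 1))
})
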