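#' Per-cycle febrile neutropenia probability
#'
#' Composes the FN risk for one chemotherapy cycle multiplicatively from the
#' cycle-1 baseline risk, the cycles-2+ relative risk, the FN-history
#' relative risk, and the prophylaxis drug's relative risk, capped at 1:
#' `min(1, p_fn_cycle1 * rr_cycle2plus^[cycle >= 2] * rr_history^[history] *
#' drug_rr)`. Vectorised over its first three arguments.
#'
#' @param cycle Chemotherapy cycle number (1-based).
#' @param has_history Logical; FN event in any prior cycle?
#' @param drug_rr Relative risk of the prophylaxis received this cycle (1 for
#'   no prophylaxis).
#' @param params An [fn_params()] object.
#' @return FN probability for the cycle.
#' @examples
#' p <- fn_params()
#' fn_probability(1, FALSE, 1, p)     # 0.364
#' fn_probability(2, TRUE, 1, p)      # 0.364 * 0.46 * 2.4
#' @export
fn_probability <- function(cycle, has_history, drug_rr, params) {
  if (any(drug_rr < 0)) stop("drug_rr must be non-negative", call. = FALSE)
  pmin(1, params$p_fn_cycle1 *
         ifelse(cycle >= 2, params$rr_cycle2plus, 1) *
         ifelse(has_history, params$rr_history, 1) *
         drug_rr)
}

#' Drug relative risk applying to a cycle under a strategy
#'
#' Returns 1 for no prophylaxis, the drug's cycle-tier RR (cycles 1-2 vs
#' cycles 3+) for primary prophylaxis, and for secondary prophylaxis the same
#' tier RR once an FN history exists (1 before the trigger). Once triggered,
#' secondary prophylaxis continues in all remaining cycles.
#'
#' @param strategy An [fn_strategy()].
#' @param cycle Cycle number.
#' @param has_history Logical; FN event in any prior cycle?
#' @param params An [fn_params()] object.
#' @return Relative risk (1 when untreated this cycle).
#' @export
drug_rr_for <- function(strategy, cycle, has_history, params) {
  exposed <- strategy_exposed(strategy, has_history)
  if (!any(exposed)) {
    return(rep(1, max(length(exposed), length(cycle))))
  }
  row <- params$drugs[params$drugs$drug == strategy$drug, ]
  if (nrow(row) != 1) {
    stop("unknown drug '", strategy$drug, "'", call. = FALSE)
  }
  tier <- ifelse(cycle <= 2, row$rr_cycles_1_2, row$rr_cycles_3plus)
  ifelse(exposed, tier, 1)
}

strategy_exposed <- function(strategy, has_history) {
  switch(strategy$mode,
         none = rep(FALSE, length(has_history)),
         primary = rep(TRUE, length(has_history)),
         secondary = as.logical(has_history))
}

#' Evaluate the chemotherapy phase of one strategy
#'
#' Exact expected-value run of the six-cycle event tree: each alive patient
#' may have at most one FN event per cycle (probability from
#' [fn_probability()]); each event is fatal with probability `p_fn_death`;
#' FN survivors carry FN history thereafter; the dead state absorbs. Events
#' resolve at cycle end: a patient dying in cycle k still accrues that
#' cycle's drug injections, the FN event cost and the cycle's QALY (minus the
#' FN decrement), and nothing afterwards. Costs cover drug acquisition
#' (injections per cycle x unit price, for every alive-at-cycle-start patient
#' receiving drug under the strategy) and FN events (fatal ones included).
#' Cycle QALYs are `u_chemo * cycle_days / year_days` minus
#' `u_fn_decrement * los_fn / year_days` per FN event, undiscounted by
#' default (the phase ends within the first year).
#'
#' @param strategy An [fn_strategy()].
#' @param params An [fn_params()] object.
#' @return An object of class `chemo_outcome`: expected FN events and deaths,
#'   expected injections, drug / FN / total cost (NTD), chemotherapy-phase
#'   QALYs, the end-of-chemotherapy cohort split
#'   (`survivors_without_history`, `survivors_with_history`), and a per-cycle
#'   `trace` data frame.
#' @examples
#' run_chemo_phase(fn_strategy("none"), fn_params())
#' @export
run_chemo_phase <- function(strategy, params) {
  stopifnot(inherits(strategy, "fn_strategy"), inherits(params, "fn_params"))
  drow <- if (strategy$mode == "none") NULL else {
    params$drugs[params$drugs$drug == strategy$drug, ]
  }
  if (!is.null(drow) && nrow(drow) != 1) {
    stop("unknown drug '", strategy$drug, "'", call. = FALSE)
  }
  m_nh <- 1    # alive, no FN history
  m_h <- 0     # alive, FN history
  fn_events <- 0
  fn_deaths <- 0
  injections <- 0
  qaly <- 0
  q_cycle <- params$u_chemo * params$cycle_days / params$year_days
  q_fn <- params$u_fn_decrement * params$los_fn / params$year_days
  trace <- vector("list", params$n_cycles)

  for (cyc in seq_len(params$n_cycles)) {
    mass <- c(nh = m_nh, h = m_h)
    hist <- c(nh = FALSE, h = TRUE)
    exposed <- strategy_exposed(strategy, hist)
    drr <- drug_rr_for(strategy, rep(cyc, 2), hist, params)
    p_fn <- fn_probability(rep(cyc, 2), hist, drr, params)
    ev <- sum(mass * p_fn)
    de <- sum(mass * p_fn) * params$p_fn_death
    inj <- if (is.null(drow)) 0 else {
      sum(mass[exposed]) * drow$injections_per_cycle
    }
    fn_events <- fn_events + ev
    fn_deaths <- fn_deaths + de
    injections <- injections + inj
    disc <- if (params$discount_chemo_qalys) {
      (1 + params$discount_rate)^(-(cyc * params$cycle_days /
                                      params$year_days))
    } else 1
    qaly <- qaly + disc * (sum(mass) * q_cycle - ev * q_fn)

    new_nh <- m_nh * (1 - p_fn[[1]])
    new_h <- m_h * (1 - p_fn[[2]] * params$p_fn_death) +
      m_nh * p_fn[[1]] * (1 - params$p_fn_death)
    trace[[cyc]] <- data.frame(
      cycle = cyc, alive_start = m_nh + m_h, fn_events = ev, fn_deaths = de,
      injections = inj
    )
    m_nh <- new_nh
    m_h <- new_h
  }

  price <- if (is.null(drow)) 0 else drow$price
  out <- list(
    strategy = strategy,
    expected_fn_events = fn_events,
    expected_fn_deaths = fn_deaths,
    expected_injections = injections,
    cost_drug = injections * price,
    cost_fn = fn_events * params$cost_fn_event,
    cost_total = injections * price + fn_events * params$cost_fn_event,
    qaly_chemo = qaly,
    survivors_without_history = m_nh,
    survivors_with_history = m_h,
    trace = do.call(rbind, trace)
  )
  class(out) <- "chemo_outcome"
  out
}

#' @export
print.chemo_outcome <- function(x, ...) {
  cat("<chemo_outcome> ", x$strategy$label, "\n", sep = "")
  cat(sprintf("  expected FN events %.4f (deaths %.4f), injections %.3f\n",
              x$expected_fn_events, x$expected_fn_deaths,
              x$expected_injections))
  cat(sprintf("  cost: drug NT$%s + FN NT$%s = NT$%s\n",
              format(round(x$cost_drug), big.mark = ","),
              format(round(x$cost_fn), big.mark = ","),
              format(round(x$cost_total), big.mark = ",")))
  cat(sprintf("  chemo-phase QALYs %.4f; survivors: %.4f no history, %.4f with history\n",
              x$qaly_chemo, x$survivors_without_history,
              x$survivors_with_history))
  invisible(x)
}

#' Probability of reduced relative dose intensity
#'
#' Probability of RDI < 85% for a chemotherapy survivor: the age-<65
#' no-history baseline, or — with an FN history — the baseline multiplied by
#' the risk ratio obtained from the history odds ratio via [or_to_rr()],
#' capped at 1.
#'
#' @param has_history Logical (vectorised).
#' @param params An [fn_params()] object.
#' @return Probability of RDI < 85%.
#' @export
p_rdi_low <- function(has_history, params) {
  p0 <- params$p_rdi_low_base
  rr <- or_to_rr(params$or_rdi_low, p0)
  ifelse(has_history, pmin(1, p0 * rr), p0)
}

#' Split chemotherapy survivors into RDI strata
#'
#' Partitions the end-of-chemotherapy cohort of a [run_chemo_phase()] outcome
#' into the four (FN history x RDI) strata that enter the post-chemotherapy
#' survival phase.
#'
#' @param outcome A `chemo_outcome`.
#' @param params An [fn_params()] object.
#' @return Data frame with columns `has_history`, `rdi_low`, `mass`; masses
#'   sum to the surviving cohort fraction.
#' @export
classify_rdi <- function(outcome, params) {
  p_low <- p_rdi_low(c(FALSE, TRUE), params)
  data.frame(
    has_history = c(FALSE, FALSE, TRUE, TRUE),
    rdi_low = c(FALSE, TRUE, FALSE, TRUE),
    mass = c(outcome$survivors_without_history * (1 - p_low[1]),
             outcome$survivors_without_history * p_low[1],
             outcome$survivors_with_history * (1 - p_low[2]),
             outcome$survivors_with_history * p_low[2])
  )
}
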