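# Independent oracles used across the suite. These deliberately share no
# code with the package engines: the chemo oracle enumerates every event
# path of the cycle tree; the frontier oracle brute-forces net monetary
# benefit maximisers.

# Exhaustive enumeration of the chemotherapy-phase event tree: per cycle an
# alive patient branches into {no FN, FN survived, FN died}. Returns the
# same expectations as run_chemo_phase().
oracle_chemo <- function(strategy, params) {
  drow <- if (strategy$mode == "none") NULL else
    params$drugs[params$drugs$drug == strategy$drug, ]
  q_cycle <- params$u_chemo * params$cycle_days / params$year_days
  q_fn <- params$u_fn_decrement * params$los_fn / params$year_days
  acc <- list(fn = 0, deaths = 0, inj = 0, qaly = 0, s_nh = 0, s_h = 0)

  recurse <- function(cycle, prob, history) {
    if (cycle > params$n_cycles) {
      if (history) acc$s_h <<- acc$s_h + prob else
        acc$s_nh <<- acc$s_nh + prob
      return(invisible())
    }
    exposed <- switch(strategy$mode, none = FALSE, primary = TRUE,
                      secondary = history)
    drr <- if (exposed) {
      if (cycle <= 2) drow$rr_cycles_1_2 else drow$rr_cycles_3plus
    } else 1
    p <- min(1, params$p_fn_cycle1 *
               (if (cycle >= 2) params$rr_cycle2plus else 1) *
               (if (history) params$rr_history else 1) * drr)
    if (exposed) acc$inj <<- acc$inj + prob * drow$injections_per_cycle
    acc$qaly <<- acc$qaly + prob * q_cycle
    # no FN
    recurse(cycle + 1, prob * (1 - p), history)
    # FN, survived
    acc$fn <<- acc$fn + prob * p
    acc$qaly <<- acc$qaly - prob * p * q_fn
    recurse(cycle + 1, prob * p * (1 - params$p_fn_death), TRUE)
    # FN, died (absorb; costs/QALY of the fatal cycle already accrued)
    acc$deaths <<- acc$deaths + prob * p * params$p_fn_death
    invisible()
  }
  recurse(1, 1, FALSE)
  price <- if (is.null(drow)) 0 else drow$price
  list(
    expected_fn_events = acc$fn,
    expected_fn_deaths = acc$deaths,
    expected_injections = acc$inj,
    cost_drug = acc$inj * price,
    cost_fn = acc$fn * params$cost_fn_event,
    cost_total = acc$inj * price + acc$fn * params$cost_fn_event,
    qaly_chemo = acc$qaly,
    survivors_without_history = acc$s_nh,
    survivors_with_history = acc$s_h
  )
}

# Brute-force frontier oracle: the efficient frontier is the set of
# strategies that maximise net monetary benefit at some WTP >= 0. Candidate
# WTPs: 0, every pairwise slope (perturbed both sides), and a huge value.
oracle_frontier_labels <- function(results) {
  n <- nrow(results)
  slopes <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dq <- results$qalys[j] - results$qalys[i]
      if (dq > 0) slopes <- c(slopes, (results$cost[j] - results$cost[i]) / dq)
    }
  }
  slopes <- slopes[slopes >= 0]
  cand <- sort(unique(c(0, slopes - 1e-6, slopes + 1e-6, 1e12)))
  cand <- cand[cand >= 0]
  winners <- unique(unlist(lapply(cand, function(w) {
    b <- results$qalys * w - results$cost
    results$label[b >= max(b) - 1e-9]
  })))
  sort(winners)
}

base_params <- fn_params()
base_life_table <- make_life_table()
all_strategies <- default_strategies()
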