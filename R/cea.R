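#' Evaluate one strategy over both model phases
#'
#' Runs the chemotherapy phase, splits survivors into (FN history x RDI)
#' strata, and accrues each stratum's discounted post-chemotherapy QALYs.
#' Total cost is chemotherapy-phase cost only (G-CSF acquisition plus FN
#' events): no costs accrue after chemotherapy under the payer perspective
#' modelled here.
#'
#' @param strategy An [fn_strategy()].
#' @param params An [fn_params()] object.
#' @param life_table A `life_table`.
#' @param scenario1 Logical; sever the RDI-mortality link.
#' @return A one-row data frame: `label`, `mode`, `drug`, `cost`, `qalys`.
#' @export
evaluate_strategy <- function(strategy, params, life_table,
                              scenario1 = FALSE) {
  post <- list(
    hi = run_post_chemo(FALSE, life_table, params, scenario1),
    lo = run_post_chemo(TRUE, life_table, params, scenario1)
  )
  evaluate_strategy_(strategy, params, post)
}

# shared-post-chemo variant used by fn_cea / run_psa so the two survival
# evaluations are not repeated per strategy
evaluate_strategy_ <- function(strategy, params, post) {
  chemo <- run_chemo_phase(strategy, params)
  strata <- classify_rdi(chemo, params)
  q_post <- ifelse(strata$rdi_low, post$lo$discounted_qalys,
                   post$hi$discounted_qalys)
  data.frame(
    label = strategy$label,
    mode = strategy$mode,
    drug = if (is.null(strategy$drug)) NA_character_ else strategy$drug,
    cost = chemo$cost_total,
    qalys = chemo$qaly_chemo + sum(strata$mass * q_post),
    stringsAsFactors = FALSE
  )
}

#' Cost-effectiveness analysis of G-CSF prophylaxis strategies
#'
#' The package's main entry point: evaluates each strategy through the
#' two-phase Markov cohort model and assembles the cost-effectiveness
#' frontier with dominance labels and incremental cost-effectiveness ratios
#' (ICERs).
#'
#' @param params An [fn_params()] object.
#' @param strategies List of [fn_strategy()] objects.
#' @param life_table A `life_table`; defaults to the packaged synthetic
#'   table.
#' @param scenario1 Logical; assume G-CSF has no impact on long-term survival
#'   (the RDI-mortality link is severed).
#' @param wtp Willingness-to-pay threshold carried into summaries.
#' @return An object of class `fn_cea` with components `results` (per
#'   strategy cost and QALYs), `frontier` (see [build_frontier()]), `params`,
#'   `wtp` and `scenario1`.
#' @examples
#' cea <- fn_cea(life_table = make_life_table())
#' cea
#' @export
fn_cea <- function(params = fn_params(),
                   strategies = default_strategies(),
                   life_table = default_life_table(),
                   scenario1 = FALSE,
                   wtp = params$wtp) {
  stopifnot(length(strategies) >= 1)
  post <- list(
    hi = run_post_chemo(FALSE, life_table, params, scenario1),
    lo = run_post_chemo(TRUE, life_table, params, scenario1)
  )
  results <- do.call(rbind, lapply(strategies, evaluate_strategy_,
                                   params = params, post = post))
  rownames(results) <- NULL
  out <- list(
    results = results,
    frontier = build_frontier(results),
    params = params,
    strategies = strategies,
    wtp = wtp,
    scenario1 = scenario1
  )
  class(out) <- "fn_cea"
  out
}

#' Cost-effectiveness frontier with dominance labels
#'
#' Orders strategies by cost, marks strong dominance (weakly higher cost and
#' weakly fewer QALYs than some other strategy, at least one strict), then
#' iteratively removes extended dominance (strategies whose removal is
#' required for the incremental ICER sequence along the frontier to be
#' strictly increasing). ICERs are computed between successive frontier
#' members from unrounded costs and QALYs; rounding happens only in
#' presentation ([cea_table()]).
#'
#' Strategies tying on both cost and QALYs are both retained (neither
#' strictly dominates), ordered deterministically by input order.
#'
#' @param results Data frame with columns `label`, `cost`, `qalys` (e.g. the
#'   `results` component of [fn_cea()]).
#' @return A data frame of class `fn_frontier`, ordered by cost, with
#'   `status` (`"frontier"`, `"dominated"`, `"extended_dominated"`) and
#'   `icer` (NTD/QALY vs the previous frontier member; `NA` for the cheapest
#'   frontier member and for non-frontier rows).
#' @export
build_frontier <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("label", "cost", "qalys") %in% names(results)),
            nrow(results) >= 1)
  df <- results[order(results$cost, results$qalys,
                      seq_len(nrow(results))), , drop = FALSE]
  n <- nrow(df)
  status <- rep("frontier", n)

  for (i in seq_len(n)) {
    dominated <- any(df$cost <= df$cost[i] & df$qalys >= df$qalys[i] &
                       (df$cost < df$cost[i] | df$qalys > df$qalys[i]))
    if (dominated) status[i] <- "dominated"
  }

  repeat {
    keep <- which(status == "frontier")
    if (length(keep) < 3) break
    ic <- diff(df$cost[keep]) / diff(df$qalys[keep])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    # the interior member whose incremental ICER is not improved upon
    status[keep[bad[1] + 1]] <- "extended_dominated"
  }

  keep <- which(status == "frontier")
  icer <- rep(NA_real_, n)
  if (length(keep) > 1) {
    icer[keep[-1]] <- diff(df$cost[keep]) / diff(df$qalys[keep])
  }
  df$status <- status
  df$icer <- icer
  rownames(df) <- NULL
  class(df) <- c("fn_frontier", "data.frame")
  df
}

#' Net monetary benefit
#'
#' `NMB = QALYs * WTP - cost`; the strategy maximising NMB at a given
#' willingness-to-pay is the cost-effective choice at that threshold.
#'
#' @param result Data frame with columns `cost` and `qalys` (one or more
#'   rows), e.g. the `results` component of [fn_cea()].
#' @param wtp Willingness-to-pay (NTD per QALY), `>= 0`.
#' @return Numeric vector of NMB values (NTD), one per row.
#' @export
nmb <- function(result, wtp) {
  stopifnot(wtp >= 0)
  result$qalys * wtp - result$cost
}

#' @export
print.fn_cea <- function(x, digits = 2, ...) {
  cat("Cost-effectiveness analysis: G-CSF prophylaxis of febrile neutropenia\n")
  if (x$scenario1) {
    cat("  (scenario 1: no G-CSF impact on long-term survival)\n")
  }
  cat(sprintf("  %d strategies; WTP NT$%s/QALY\n\n", nrow(x$results),
              format(x$wtp, big.mark = ",")))
  print(cea_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fn_cea <- function(object, ...) {
  fr <- object$frontier
  optimal <- fr$label[fr$status == "frontier" &
                        (is.na(fr$icer) | fr$icer <= object$wtp)]
  structure(list(cea = object, table = cea_table(object),
                 optimal = optimal[length(optimal)]),
            class = "summary.fn_cea")
}

#' @export
print.summary.fn_cea <- function(x, ...) {
  print(x$cea)
  cat(sprintf("\nCost-effective strategy at WTP NT$%s/QALY: %s\n",
              format(x$cea$wtp, big.mark = ","), x$optimal))
  invisible(x)
}

#' @export
as.data.frame.fn_cea <- function(x, ...) {
  merge(x$results, x$frontier[, c("label", "status", "icer")], by = "label",
        sort = FALSE)
}

#' Cost-effectiveness plane
#'
#' Plots each strategy on the (QALY, cost) plane, connecting the efficient
#' frontier; dominated and extended-dominated strategies are shown hollow.
#'
#' @param x An `fn_cea` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fn_cea <- function(x, ...) {
  fr <- x$frontier
  on_fr <- fr$status == "frontier"
  graphics::plot(fr$qalys, fr$cost, pch = ifelse(on_fr, 19, 1),
                 xlab = "QALYs", ylab = "Cost (NTD)", ...)
  graphics::lines(fr$qalys[on_fr], fr$cost[on_fr], lty = 2)
  graphics::text(fr$qalys, fr$cost, fr$label, pos = 3, cex = 0.6)
  invisible(x)
}

#' Microsimulate patient cohorts under the fitted strategies
#'
#' `simulate()` draws individual-level chemotherapy-cycle records for each
#' strategy of a fitted [fn_cea()] object via [simulate_cohort()]; useful as
#' an independent Monte-Carlo check of the expectation engine.
#'
#' @param object An `fn_cea` object.
#' @param nsim Number of patients per strategy.
#' @param seed Random seed.
#' @param ... Unused.
#' @return Named list (by strategy label) of record data frames.
#' @export
simulate.fn_cea <- function(object, nsim = 1000, seed = NULL, ...) {
  lapply(object$strategies, function(s) {
    simulate_cohort(nsim, s, object$params, seed = seed)
  })
}
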