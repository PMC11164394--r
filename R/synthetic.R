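#' Simulate individual-level chemotherapy-cycle records
#'
#' Monte-Carlo microsimulation of the chemotherapy phase, emulating the kind
#' of per-cycle claims records from which the model's FN relative risks were
#' estimated: one record per patient per cycle with prophylaxis exposure, FN
#' event and FN death indicators. Exposure follows the assigned strategy
#' (secondary prophylaxis triggers the cycle after a first FN event); FN
#' events are Bernoulli with the model's true per-cycle probabilities; FN
#' deaths truncate a patient's records. An optional uniform record-drop
#' fraction emulates claims exclusion filters.
#'
#' @param n_patients Number of patients.
#' @param strategy A single [fn_strategy()] applied to all patients, or a
#'   list of strategies with `assignment` mapping each patient to one.
#' @param params An [fn_params()] object.
#' @param seed Random seed; given a seed, output is reproducible.
#' @param assignment Integer vector of length `n_patients` indexing into
#'   `strategy` when it is a list; defaults to a balanced round-robin.
#' @param drop_fraction Fraction of records dropped uniformly at random
#'   after simulation (default 0).
#' @return Data frame with one row per surviving patient-cycle: `patient`,
#'   `cycle`, `strategy`, `drug` (`NA` when unexposed), `exposed`,
#'   `fn_history` (FN event in a prior cycle), `fn_event`, `died_of_fn`.
#' @examples
#' rec <- simulate_cohort(500, fn_strategy("none"), fn_params(), seed = 1)
#' mean(rec$fn_event[rec$cycle == 1])
#' @export
simulate_cohort <- function(n_patients, strategy, params, seed = NULL,
                            assignment = NULL, drop_fraction = 0) {
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(strategy, "fn_strategy")) strategy <- list(strategy)
  if (is.null(assignment)) {
    assignment <- rep_len(seq_along(strategy), n_patients)
  }
  stopifnot(length(assignment) == n_patients,
            all(assignment %in% seq_along(strategy)))

  labels <- vapply(strategy, `[[`, "", "label")
  modes <- vapply(strategy, `[[`, "", "mode")
  drugs <- vapply(strategy, function(s) {
    if (is.null(s$drug)) NA_character_ else s$drug
  }, "")
  di <- match(drugs, params$drugs$drug)
  rr12 <- ifelse(is.na(di), 1, params$drugs$rr_cycles_1_2[di])
  rr3p <- ifelse(is.na(di), 1, params$drugs$rr_cycles_3plus[di])

  alive <- rep(TRUE, n_patients)
  history <- rep(FALSE, n_patients)
  recs <- vector("list", params$n_cycles)
  for (cyc in seq_len(params$n_cycles)) {
    idx <- which(alive)
    if (!length(idx)) break
    a <- assignment[idx]
    exposed <- modes[a] == "primary" |
      (modes[a] == "secondary" & history[idx])
    drr <- ifelse(exposed, if (cyc <= 2) rr12[a] else rr3p[a], 1)
    p <- fn_probability(cyc, history[idx], drr, params)
    fn <- stats::runif(length(idx)) < p
    died <- fn & stats::runif(length(idx)) < params$p_fn_death
    recs[[cyc]] <- data.frame(
      patient = idx,
      cycle = cyc,
      strategy = labels[a],
      drug = ifelse(exposed, drugs[a], NA_character_),
      exposed = exposed,
      fn_history = history[idx],
      fn_event = fn,
      died_of_fn = died,
      stringsAsFactors = FALSE
    )
    history[idx] <- history[idx] | fn
    alive[idx[died]] <- FALSE
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$patient, out$cycle), , drop = FALSE]
  if (drop_fraction > 0) {
    keep <- stats::runif(nrow(out)) >= drop_fraction
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Cycle-stratified relative risk of FN under prophylaxis
#'
#' Estimates the relative risk of an FN event in prophylaxis-exposed vs
#' unexposed cycles within a cycle tier (cycles 1-2 or cycles 3+), from
#' records such as those produced by [simulate_cohort()]. Because exposure
#' is entangled with FN history (secondary prophylaxis is triggered by it)
#' and FN risk varies by cycle, the crude ratio of incidence proportions is
#' confounded; the estimator is therefore the Mantel-Haenszel common risk
#' ratio stratified by (cycle x FN history). The Wald 95% confidence
#' interval on the log scale uses a cluster-robust variance with patients as
#' sampling units, since a patient's cycles are correlated (an early FN
#' event changes the history stratum of later cycles).
#'
#' @param records Record data frame from [simulate_cohort()] (columns
#'   `cycle`, `drug`, `exposed`, `fn_history`, `fn_event`).
#' @param drug Drug whose exposed cycles are analysed.
#' @param cycle_stratum `"1-2"`, `"3+"`, or `"all"` (for drugs with a single
#'   RR across cycles, e.g. pegfilgrastim).
#' @return List with `rr` (point estimate), `ci` (95% interval), `se_log`
#'   and the stratum event table `strata`.
#' @export
estimate_rr <- function(records, drug, cycle_stratum = c("1-2", "3+", "all")) {
  cycle_stratum <- match.arg(cycle_stratum)
  tier <- switch(cycle_stratum,
                 "1-2" = records$cycle <= 2,
                 "3+" = records$cycle >= 3,
                 all = rep(TRUE, nrow(records)))
  r <- records[tier, , drop = FALSE]
  exp_rows <- r$exposed & !is.na(r$drug) & r$drug == drug
  unexp_rows <- !r$exposed
  if (!any(exp_rows) || !any(unexp_rows)) {
    stop("both exposed ('", drug, "') and unexposed cycles are required ",
         "in the '", cycle_stratum, "' stratum", call. = FALSE)
  }
  r <- r[exp_rows | unexp_rows, , drop = FALSE]
  r$exp <- exp_rows[exp_rows | unexp_rows]
  g <- interaction(r$cycle, r$fn_history, drop = TRUE)
  tab <- do.call(rbind, lapply(split(r, g), function(s) {
    data.frame(
      a = as.numeric(sum(s$fn_event[s$exp])), n1 = as.numeric(sum(s$exp)),
      b = as.numeric(sum(s$fn_event[!s$exp])), n0 = as.numeric(sum(!s$exp))
    )
  }))
  if (sum(tab$b) == 0) {
    stop("no FN events among unexposed cycles; RR undefined", call. = FALSE)
  }
  use <- tab$n1 > 0 & tab$n0 > 0
  N <- tab$n1 + tab$n0
  num <- sum((tab$a * tab$n0 / N)[use])
  den <- sum((tab$b * tab$n1 / N)[use])
  rr <- num / den
  # cluster-robust variance of log(RR_MH): the numerator and denominator are
  # sums of per-record MH-weighted events; aggregate to patient level (the
  # independent sampling unit) and take the empirical variance of the sums
  w_num <- (tab$n0 / N)[match(g, rownames(tab))]
  w_den <- (tab$n1 / N)[match(g, rownames(tab))]
  ok <- use[match(g, rownames(tab))]
  u <- r$fn_event * ifelse(r$exp, w_num, w_den) * ok
  var_sum <- function(rows) {
    ui <- rowsum(u[rows], r$patient[rows])
    n <- length(ui)
    if (n < 2) return(NA_real_)
    n / (n - 1) * sum((ui - mean(ui))^2)
  }
  v <- var_sum(r$exp) / num^2 + var_sum(!r$exp) / den^2
  se <- sqrt(v)
  list(rr = rr, ci = rr * exp(c(-1.96, 1.96) * se), se_log = se,
       strata = tab[use, , drop = FALSE])
}
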