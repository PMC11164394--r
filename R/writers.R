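#' Presentation table of a cost-effectiveness analysis
#'
#' Formats an [fn_cea()] result in the conventional layout: strategies
#' ordered by cost with incremental costs/QALYs vs the previous row, and an
#' ICER column carrying the NTD/QALY value for frontier members (vs the
#' previous frontier member) or the dominance label. Rounding (integer NTD,
#' two-decimal QALYs) happens here only; all comparisons upstream use exact
#' values.
#'
#' @param x An `fn_cea` object.
#' @return Data frame with columns `strategy`, `cost`, `incr_cost`, `qalys`,
#'   `incr_qalys`, `icer`.
#' @export
cea_table <- function(x) {
  fr <- x$frontier
  icer_col <- ifelse(
    fr$status == "dominated", "Dominated",
    ifelse(fr$status == "extended_dominated", "Extended dominance",
           ifelse(is.na(fr$icer), "-",
                  format(round(fr$icer), big.mark = ",", trim = TRUE)))
  )
  data.frame(
    strategy = fr$label,
    cost = round(fr$cost),
    incr_cost = c(NA, round(diff(fr$cost))),
    qalys = round(fr$qalys, 2),
    incr_qalys = c(NA, round(diff(fr$qalys), 2)),
    icer = icer_col,
    stringsAsFactors = FALSE
  )
}

#' Write analysis outputs as CSV
#'
#' `write_cea_table()` writes the presentation table of [cea_table()];
#' `write_tornado_table()` the one-way sensitivity rows of [owsa()];
#' `write_ceac_table()` the acceptability curves of [run_psa()] in long
#' format (`wtp`, `strategy`, `probability`); `write_psa_draws()` the
#' iteration-level costs and QALYs.
#'
#' @param x The object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cea_table <- function(x, path) {
  utils::write.csv(cea_table(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cea_table
#' @export
write_tornado_table <- function(x, path) {
  df <- as.data.frame(x)
  df$icer_at_low <- round(df$icer_at_low)
  df$icer_at_high <- round(df$icer_at_high)
  df$span <- round(df$span)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cea_table
#' @export
write_ceac_table <- function(x, path) {
  long <- data.frame(
    wtp = rep(x$wtp, times = ncol(x$prob)),
    strategy = rep(colnames(x$prob), each = length(x$wtp)),
    probability = as.vector(x$prob)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cea_table
#' @export
write_psa_draws <- function(x, path) {
  df <- data.frame(iteration = seq_len(x$n_iter))
  for (s in colnames(x$cost)) {
    df[[paste0("cost.", s)]] <- x$cost[, s]
    df[[paste0("qalys.", s)]] <- x$qalys[, s]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
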