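#' Scenario analyses
#'
#' Scenario 1 re-runs the base-case strategies with the RDI-mortality link
#' severed (G-CSF assumed to have no impact on long-term survival: only FN
#' incidence and FN-related mortality are affected). Scenario 2 re-runs the
#' base case with the filgrastim and pegfilgrastim biosimilars added as
#' secondary- and primary-prophylaxis strategies at biosimilar prices.
#'
#' @param which Scenario number, 1 or 2.
#' @param params An [fn_params()] object.
#' @param life_table A `life_table`.
#' @return An [fn_cea()] object.
#' @export
run_scenario <- function(which, params = fn_params(),
                         life_table = default_life_table()) {
  if (!which %in% c(1, 2)) stop("scenario must be 1 or 2", call. = FALSE)
  if (which == 1) {
    fn_cea(params, default_strategies(), life_table, scenario1 = TRUE)
  } else {
    fn_cea(params, scenario2_strategies(), life_table)
  }
}

icer_between <- function(strategy_a, strategy_b, params, life_table,
                         scenario1 = FALSE) {
  a <- evaluate_strategy(strategy_a, params, life_table, scenario1)
  b <- evaluate_strategy(strategy_b, params, life_table, scenario1)
  (a$cost - b$cost) / (a$qalys - b$qalys)
}

#' One-way sensitivity analysis
#'
#' `one_way()` recomputes the ICER of strategy A vs strategy B at the low and
#' high end of one parameter's uncertainty range, all other parameters held
#' at base case. `owsa()` does so for a set of parameters and returns the
#' tornado table sorted by descending ICER span.
#'
#' @param parameter Parameter name (see [fn_param_names()]).
#' @param comparison List of two [fn_strategy()] objects, `list(A, B)`; the
#'   ICER is of A vs B.
#' @param params An [fn_params()] object.
#' @param life_table A `life_table`.
#' @param parameters Character vector of parameter names; defaults to every
#'   ranged parameter.
#' @return `one_way()`: a one-row data frame `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `span`; `owsa()`: an `fn_owsa` data frame
#'   of such rows plus the base-case ICER as attribute `icer_base`.
#' @examples
#' comp <- list(fn_strategy("primary", "lenograstim"), fn_strategy("none"))
#' one_way("discount_rate", comp, fn_params(), make_life_table())
#' @export
one_way <- function(parameter, comparison, params = fn_params(),
                    life_table = default_life_table()) {
  rng <- params$ranges[[parameter]]
  if (is.null(rng)) {
    stop("no range defined for parameter '", parameter, "'", call. = FALSE)
  }
  at <- function(v) {
    icer_between(comparison[[1]], comparison[[2]],
                 set_fn_param(params, parameter, v), life_table)
  }
  lo <- at(rng[1])
  hi <- at(rng[2])
  data.frame(parameter = parameter, low = rng[1], high = rng[2],
             icer_at_low = lo, icer_at_high = hi, span = abs(hi - lo),
             stringsAsFactors = FALSE)
}

#' @rdname one_way
#' @export
owsa <- function(comparison, params = fn_params(),
                 life_table = default_life_table(),
                 parameters = fn_param_names(params)) {
  rows <- do.call(rbind, lapply(parameters, one_way, comparison = comparison,
                                params = params, life_table = life_table))
  rows <- rows[order(-rows$span), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "icer_base") <- icer_between(comparison[[1]], comparison[[2]],
                                          params, life_table)
  attr(rows, "comparison") <- c(comparison[[1]]$label, comparison[[2]]$label)
  class(rows) <- c("fn_owsa", "data.frame")
  rows
}

#' Tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high ICER around the
#' base-case ICER, widest span on top.
#'
#' @param x An `fn_owsa` object.
#' @param n_top Number of parameters displayed.
#' @param ... Further arguments passed to [graphics::barplot()] (unused).
#' @return `x`, invisibly.
#' @export
plot.fn_owsa <- function(x, n_top = min(10, nrow(x)), ...) {
  d <- x[seq_len(n_top), ]
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "icer_base")
  graphics::plot(NULL, xlim = range(c(d$icer_at_low, d$icer_at_high, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER (NTD/QALY)", ylab = "",
                 main = paste(attr(x, "comparison"), collapse = " vs "))
  for (i in seq_len(nrow(d))) {
    graphics::rect(min(d$icer_at_low[i], d$icer_at_high[i]), i - 0.3,
                   max(d$icer_at_low[i], d$icer_at_high[i]), i + 0.3,
                   col = "grey80")
  }
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}

#' Threshold (break-even) search on one parameter
#'
#' Bisection for the parameter value at which the ICER of strategy A vs
#' strategy B crosses a target (typically the willingness-to-pay threshold).
#' The ICER must be monotone in the parameter over the bracket and the target
#' must be crossed inside it.
#'
#' @param parameter Parameter name.
#' @param comparison `list(A, B)` of [fn_strategy()] objects.
#' @param target_icer Target ICER (NTD/QALY).
#' @param params An [fn_params()] object.
#' @param life_table A `life_table`.
#' @param bracket `c(low, high)` search interval; defaults to the parameter's
#'   range.
#' @param tol Convergence tolerance on `|ICER - target|` (NTD/QALY).
#' @param maxit Maximum bisection steps.
#' @return The crossing parameter value.
#' @export
threshold_search <- function(parameter, comparison, target_icer,
                             params = fn_params(),
                             life_table = default_life_table(),
                             bracket = params$ranges[[parameter]],
                             tol = 1, maxit = 200) {
  if (is.null(bracket)) {
    stop("no bracket available for parameter '", parameter, "'",
         call. = FALSE)
  }
  g <- function(v) {
    icer_between(comparison[[1]], comparison[[2]],
                 set_fn_param(params, parameter, v), life_table) -
      target_icer
  }
  f_lo <- g(bracket[1])
  f_hi <- g(bracket[2])
  if (abs(f_lo) < tol) return(bracket[1])
  if (abs(f_hi) < tol) return(bracket[2])
  if (sign(f_lo) == sign(f_hi)) {
    stop("ICER does not cross ", target_icer, " inside the bracket [",
         bracket[1], ", ", bracket[2], "]", call. = FALSE)
  }
  lo <- bracket[1]
  hi <- bracket[2]
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    f_mid <- g(mid)
    if (abs(f_mid) < tol || (hi - lo) / 2 < 1e-12) return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid
      f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# ---- probabilistic sensitivity analysis ---------------------------------

#' Probabilistic distributions fitted to parameter ranges
#'
#' Fits each ranged parameter's PSA distribution from `(base, low, high)`:
#' beta and gamma by method of moments with mean = base and
#' `SE = (high - low) / 3.92` (the range read as a 95% interval); log-normal
#' with `meanlog = log(base)` and `sdlog = (log(high) - log(low)) / 3.92`;
#' `fixed` parameters (drug prices, structural constants) keep their base
#' value.
#'
#' @param params An [fn_params()] object.
#' @return Named list of distribution specifications (family plus fitted
#'   shape parameters).
#' @export
psa_distributions <- function(params) {
  out <- lapply(fn_param_names(params), function(nm) {
    base <- fn_param_value(params, nm)
    rng <- params$ranges[[nm]]
    fam <- params$dist_family[[nm]]
    se <- (rng[2] - rng[1]) / 3.92
    spec <- switch(
      fam,
      fixed = list(value = base),
      beta = {
        if (se^2 >= base * (1 - base)) {
          stop("beta fit infeasible for parameter '", nm,
               "': SE^2 >= p(1-p)", call. = FALSE)
        }
        nu <- base * (1 - base) / se^2 - 1
        list(shape1 = base * nu, shape2 = (1 - base) * nu)
      },
      gamma = list(shape = base^2 / se^2, rate = base / se^2),
      `log-normal` = list(meanlog = log(base),
                          sdlog = (log(rng[2]) - log(rng[1])) / 3.92)
    )
    c(list(parameter = nm, family = fam, base = base), spec)
  })
  stats::setNames(out, fn_param_names(params))
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Independent draws from the fitted distributions of [psa_distributions()];
#' fixed parameters are returned unchanged in every draw. Draws consume the
#' current RNG stream (set a seed for reproducibility).
#'
#' @param params An [fn_params()] object.
#' @param n Number of draws.
#' @return Data frame of `n` rows, one column per ranged parameter.
#' @examples
#' set.seed(1)
#' head(sample_psa(fn_params(), 3))
#' @export
sample_psa <- function(params, n = 1) {
  specs <- psa_distributions(params)
  cols <- lapply(specs, function(s) {
    switch(s$family,
           fixed = rep(s$value, n),
           beta = stats::rbeta(n, s$shape1, s$shape2),
           gamma = stats::rgamma(n, shape = s$shape, rate = s$rate),
           `log-normal` = stats::rlnorm(n, s$meanlog, s$sdlog))
  })
  as.data.frame(cols, optional = TRUE)
}

apply_psa_draw <- function(params, draw) {
  for (nm in names(draw)) {
    if (params$dist_family[[nm]] != "fixed") {
      params <- set_fn_param(params, nm, draw[[nm]])
    }
  }
  params
}

#' Probabilistic sensitivity analysis and acceptability curves
#'
#' Second-order Monte Carlo: each iteration draws one parameter set from
#' [sample_psa()], evaluates every strategy through both model phases, and
#' records which strategy maximises net monetary benefit at each
#' willingness-to-pay on the grid. The cost-effectiveness acceptability
#' curve (CEAC) is the frequency with which each strategy is optimal.
#'
#' @param params An [fn_params()] object.
#' @param strategies List of [fn_strategy()] objects.
#' @param life_table A `life_table`.
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Random seed (results are deterministic given the seed).
#' @param wtp_grid Willingness-to-pay grid (NTD/QALY); defaults to 0 to
#'   1.5x the threshold in steps of NT$10,000.
#' @param scenario1 Logical; sever the RDI-mortality link.
#' @return An object of class `fn_ceac`: `wtp` grid, `prob` matrix
#'   (wtp x strategy probabilities, rows summing to 1), per-iteration `cost`
#'   and `qalys` matrices, `n_iter` and `seed`.
#' @export
run_psa <- function(params = fn_params(),
                    strategies = default_strategies(),
                    life_table = default_life_table(),
                    n_iter = 10000, seed = NULL,
                    wtp_grid = seq(0, 15e4 * ceiling(params$wtp / 1e5),
                                   by = 1e4),
                    scenario1 = FALSE) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- sample_psa(params, n_iter)
  labels <- vapply(strategies, `[[`, "", "label")
  cost <- matrix(NA_real_, n_iter, length(strategies),
                 dimnames = list(NULL, labels))
  qalys <- cost
  for (it in seq_len(n_iter)) {
    p_it <- apply_psa_draw(params, draws[it, , drop = FALSE])
    post <- list(
      hi = run_post_chemo(FALSE, life_table, p_it, scenario1),
      lo = run_post_chemo(TRUE, life_table, p_it, scenario1)
    )
    for (j in seq_along(strategies)) {
      r <- evaluate_strategy_(strategies[[j]], p_it, post)
      cost[it, j] <- r$cost
      qalys[it, j] <- r$qalys
    }
  }
  prob <- matrix(NA_real_, length(wtp_grid), length(strategies),
                 dimnames = list(NULL, labels))
  for (k in seq_along(wtp_grid)) {
    win <- max.col(qalys * wtp_grid[k] - cost, ties.method = "first")
    prob[k, ] <- tabulate(win, nbins = length(strategies)) / n_iter
  }
  out <- list(wtp = wtp_grid, prob = prob, cost = cost, qalys = qalys,
              n_iter = n_iter, seed = seed)
  class(out) <- "fn_ceac"
  out
}

#' @export
print.fn_ceac <- function(x, ...) {
  cat(sprintf("<fn_ceac> %d PSA iterations, %d strategies, WTP grid %s-%s\n",
              x$n_iter, ncol(x$prob),
              format(min(x$wtp), big.mark = ","),
              format(max(x$wtp), big.mark = ",")))
  i <- which.min(abs(x$wtp - stats::median(x$wtp)))
  cat("  probabilities at WTP ", format(x$wtp[i], big.mark = ","), ":\n",
      sep = "")
  print(round(x$prob[i, ], 3))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' One curve per strategy: probability of being the net-monetary-benefit
#' optimum across the willingness-to-pay grid.
#'
#' @param x An `fn_ceac` object.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fn_ceac <- function(x, ...) {
  graphics::matplot(x$wtp, x$prob, type = "l", lty = 1,
                    col = seq_len(ncol(x$prob)), ylim = c(0, 1),
                    xlab = "Willingness-to-pay (NTD/QALY)",
                    ylab = "Probability cost-effective", ...)
  graphics::legend("right", legend = colnames(x$prob), lty = 1,
                   col = seq_len(ncol(x$prob)), cex = 0.6, bty = "n")
  invisible(x)
}
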