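#' Model parameter set
#'
#' Construct the full set of model inputs: clinical probabilities and relative
#' risks, health utilities, unit costs, structural constants, and — for the
#' sensitivity analyses — per-parameter uncertainty ranges and probabilistic
#' distribution families. Defaults are the base case of the analysis.
#'
#' Drug efficacy is a per-drug pair of FN relative risks (cycles 1-2 vs
#' cycles 3+) against no prophylaxis; pegfilgrastim has a single RR applied
#' to all cycles, stored in both tiers. Biosimilars are distinct drugs that
#' differ from their reference product only in price: their RR columns always
#' mirror the reference drug named in `efficacy_source`.
#'
#' @param p_fn_cycle1 FN baseline risk in chemotherapy cycle 1, no
#'   prophylaxis.
#' @param rr_cycle2plus RR of an FN event in cycles 2+ vs cycle 1.
#' @param rr_history RR of an FN event with vs without a prior FN event.
#' @param p_fn_death Case-fatality probability per FN event.
#' @param drugs Data frame of drugs: `drug`, `rr_cycles_1_2`,
#'   `rr_cycles_3plus`, `price` (NTD per injection), `injections_per_cycle`,
#'   `efficacy_source`.
#' @param p_rdi_low_base Probability of relative dose intensity (RDI) < 85%
#'   for patients under 65 without FN history.
#' @param or_rdi_low Odds ratio of RDI < 85% with vs without FN history.
#' @param hr_rdi_low Hazard ratio for long-term mortality, RDI < 85% vs
#'   >= 85%.
#' @param u_chemo Utility per year while receiving chemotherapy.
#' @param u_fn_decrement Utility decrement per year during FN
#'   hospitalization.
#' @param u_surv_1_5 Utility per year, survivor years 1-5 post chemotherapy.
#' @param u_surv_5plus Utility per year, survivor years 5+.
#' @param cost_fn_event Cost per FN event (NTD).
#' @param los_fn Length of stay per FN hospitalization (days).
#' @param annual_bc_mortality Annual breast-cancer mortality probability,
#'   post-chemotherapy years 1-10.
#' @param bc_mortality_years Number of post-chemotherapy years over which
#'   `annual_bc_mortality` applies before reverting to general-population
#'   mortality.
#' @param discount_rate Annual discount rate applied to health outcomes
#'   (costs all fall in year one and are not discounted).
#' @param wtp Willingness-to-pay threshold (NTD per QALY).
#' @param start_age Cohort age at chemotherapy start (years).
#' @param n_cycles Number of chemotherapy cycles.
#' @param cycle_days Chemotherapy cycle length (days).
#' @param age_cap Terminal age by which the whole cohort is absorbed into the
#'   dead state.
#' @param year_days Days per year used in day-to-year conversions.
#' @param discount_chemo_qalys Logical; discount chemotherapy-phase QALYs?
#'   The phase ends within the first year, so the default is `FALSE`.
#' @param ranges Named list of `c(low, high)` uncertainty ranges; see
#'   [fn_param_names()] for the recognised names.
#' @param dist_family Named character vector giving each ranged parameter's
#'   probabilistic distribution family: `"beta"`, `"gamma"`, `"log-normal"`
#'   or `"fixed"`. Drug prices and structural constants are `"fixed"`.
#'
#' @return An object of class `fn_params`.
#' @seealso [read_fn_params()], [or_to_rr()], [set_fn_param()]
#' @examples
#' p <- fn_params()
#' p$p_fn_cycle1
#' p$drugs
#' @export
fn_params <- function(p_fn_cycle1 = 0.364,
                      rr_cycle2plus = 0.46,
                      rr_history = 2.4,
                      p_fn_death = 0.036,
                      drugs = default_drug_table(),
                      p_rdi_low_base = 0.247,
                      or_rdi_low = 1.58,
                      hr_rdi_low = 1.73,
                      u_chemo = 0.78,
                      u_fn_decrement = 0.36,
                      u_surv_1_5 = 0.84,
                      u_surv_5plus = 0.91,
                      cost_fn_event = 8287,
                      los_fn = 10.53,
                      annual_bc_mortality = 0.0202,
                      bc_mortality_years = 10,
                      discount_rate = 0.03,
                      wtp = 976914,
                      start_age = 56,
                      n_cycles = 6,
                      cycle_days = 21,
                      age_cap = 110,
                      year_days = 365.25,
                      discount_chemo_qalys = FALSE,
                      ranges = default_ranges(),
                      dist_family = default_dist_family()) {
  p <- list(
    p_fn_cycle1 = p_fn_cycle1, rr_cycle2plus = rr_cycle2plus,
    rr_history = rr_history, p_fn_death = p_fn_death,
    drugs = drugs,
    p_rdi_low_base = p_rdi_low_base, or_rdi_low = or_rdi_low,
    hr_rdi_low = hr_rdi_low,
    u_chemo = u_chemo, u_fn_decrement = u_fn_decrement,
    u_surv_1_5 = u_surv_1_5, u_surv_5plus = u_surv_5plus,
    cost_fn_event = cost_fn_event, los_fn = los_fn,
    annual_bc_mortality = annual_bc_mortality,
    bc_mortality_years = bc_mortality_years,
    discount_rate = discount_rate, wtp = wtp,
    start_age = start_age, n_cycles = n_cycles, cycle_days = cycle_days,
    age_cap = age_cap, year_days = year_days,
    discount_chemo_qalys = discount_chemo_qalys,
    ranges = ranges, dist_family = dist_family
  )
  class(p) <- "fn_params"
  validate_fn_params(p)
}

#' @rdname fn_params
#' @export
default_drug_table <- function() {
  data.frame(
    drug = c("filgrastim", "lenograstim", "pegfilgrastim",
             "filgrastim_biosimilar", "pegfilgrastim_biosimilar"),
    rr_cycles_1_2 = c(0.640, 0.452, 0.334, 0.640, 0.334),
    rr_cycles_3plus = c(0.575, 0.609, 0.334, 0.575, 0.334),
    price = c(1673, 1674, 16626, 1559, 14457),
    injections_per_cycle = c(4, 4, 1, 4, 1),
    efficacy_source = c("filgrastim", "lenograstim", "pegfilgrastim",
                        "filgrastim", "pegfilgrastim"),
    stringsAsFactors = FALSE
  )
}

# (low, high) uncertainty ranges: 95% CIs or plausible bounds for clinical
# parameters and utilities; +/-20% for the FN event cost; [-20%, 0%] for drug
# prices (reimbursement prices only move downwards); 0-5% for the discount
# rate.
default_ranges <- function() {
  list(
    p_fn_cycle1 = c(0.293, 0.436),
    rr_cycle2plus = c(0.4203, 0.5034),
    rr_history = c(2.2, 2.6),
    p_fn_death = c(0.029, 0.043),
    rr_filgrastim_cycles_1_2 = c(0.5077, 0.8076),
    rr_filgrastim_cycles_3plus = c(0.4477, 0.7379),
    rr_lenograstim_cycles_1_2 = c(0.2767, 0.7393),
    rr_lenograstim_cycles_3plus = c(0.3944, 0.9398),
    rr_pegfilgrastim = c(0.2097, 0.5319),
    p_rdi_low_base = c(0.149, 0.345),
    or_rdi_low = c(1.20, 2.10),
    hr_rdi_low = c(1.17, 2.55),
    u_chemo = c(0.728, 0.832),
    u_fn_decrement = c(0.289, 0.431),
    u_surv_1_5 = c(0.791, 0.889),
    u_surv_5plus = c(0.893, 0.927),
    price_pegfilgrastim = c(13301, 16626),
    price_filgrastim = c(1338, 1673),
    price_lenograstim = c(1339, 1674),
    cost_fn_event = c(6630, 9944),
    los_fn = c(7.39, 13.67),
    discount_rate = c(0, 0.05)
  )
}

default_dist_family <- function() {
  c(
    p_fn_cycle1 = "beta",
    rr_cycle2plus = "log-normal",
    rr_history = "log-normal",
    p_fn_death = "beta",
    rr_filgrastim_cycles_1_2 = "log-normal",
    rr_filgrastim_cycles_3plus = "log-normal",
    rr_lenograstim_cycles_1_2 = "log-normal",
    rr_lenograstim_cycles_3plus = "log-normal",
    rr_pegfilgrastim = "log-normal",
    p_rdi_low_base = "beta",
    or_rdi_low = "log-normal",
    hr_rdi_low = "log-normal",
    u_chemo = "beta",
    u_fn_decrement = "beta",
    u_surv_1_5 = "beta",
    u_surv_5plus = "beta",
    price_pegfilgrastim = "fixed",
    price_filgrastim = "fixed",
    price_lenograstim = "fixed",
    cost_fn_event = "gamma",
    los_fn = "gamma",
    discount_rate = "fixed"
  )
}

#' Names of ranged model parameters
#'
#' Parameter names recognised by [set_fn_param()], [fn_param_value()],
#' [owsa()], [threshold_search()] and [sample_psa()]. Drug relative risks and
#' prices are addressed as e.g. `"rr_filgrastim_cycles_1_2"`,
#' `"rr_pegfilgrastim"` (single RR, both tiers) and `"price_lenograstim"`.
#'
#' @param params An `fn_params` object.
#' @return Character vector of parameter names.
#' @export
fn_param_names <- function(params) names(params$ranges)

validate_fn_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!isTRUE(all(cond))) {
      stop("invalid parameter '", field, "': ", msg, call. = FALSE)
    }
  }
  for (f in c("p_fn_cycle1", "p_fn_death", "p_rdi_low_base",
              "annual_bc_mortality", "u_chemo", "u_fn_decrement",
              "u_surv_1_5", "u_surv_5plus")) {
    v <- p[[f]]
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1, f,
        "must be a single value in [0, 1]")
  }
  for (f in c("rr_cycle2plus", "rr_history", "or_rdi_low", "hr_rdi_low",
              "cost_fn_event", "los_fn", "year_days")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] > 0, f,
        "must be a single positive value")
  }
  chk(p$discount_rate >= 0, "discount_rate", "must be non-negative")
  chk(p$wtp >= 0, "wtp", "must be non-negative")
  for (f in c("start_age", "n_cycles", "cycle_days", "age_cap",
              "bc_mortality_years")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] > 0 &&
          p[[f]] == round(p[[f]]), f, "must be a positive integer")
  }
  chk(p$age_cap > p$start_age, "age_cap", "must exceed start_age")

  d <- p$drugs
  need <- c("drug", "rr_cycles_1_2", "rr_cycles_3plus", "price",
            "injections_per_cycle", "efficacy_source")
  chk(is.data.frame(d) && all(need %in% names(d)), "drugs",
      paste("must be a data frame with columns",
            paste(need, collapse = ", ")))
  chk(!anyDuplicated(d$drug), "drugs", "drug names must be unique")
  chk(all(d$rr_cycles_1_2 > 0) && all(d$rr_cycles_3plus > 0), "drugs",
      "relative risks must be positive")
  chk(all(d$price > 0) && all(d$injections_per_cycle > 0), "drugs",
      "prices and injection counts must be positive")
  chk(all(d$efficacy_source %in% d$drug), "drugs",
      "efficacy_source must name a drug in the table")
  # biosimilar efficacy mirrors the reference product
  src <- match(d$efficacy_source, d$drug)
  chk(all(d$rr_cycles_1_2 == d$rr_cycles_1_2[src]) &&
        all(d$rr_cycles_3plus == d$rr_cycles_3plus[src]), "drugs",
      "RR columns must equal those of the efficacy_source drug")

  chk(is.list(p$ranges) && !is.null(names(p$ranges)), "ranges",
      "must be a named list of c(low, high)")
  for (nm in names(p$ranges)) {
    r <- p$ranges[[nm]]
    chk(is.numeric(r) && length(r) == 2 && r[1] <= r[2], nm,
        "range must be numeric c(low, high) with low <= high")
    b <- fn_param_value(p, nm)
    chk(r[1] <= b + 1e-9 && b <= r[2] + 1e-9, nm,
        sprintf("base value %g outside range [%g, %g]", b, r[1], r[2]))
  }
  fam <- p$dist_family
  chk(all(fam %in% c("beta", "gamma", "log-normal", "fixed")),
      "dist_family", "families must be beta, gamma, log-normal or fixed")
  chk(all(names(fam) %in% names(p$ranges)) &&
        all(names(p$ranges) %in% names(fam)),
      "dist_family", "must name exactly the ranged parameters")
  p
}

#' Read or write a parameter configuration file
#'
#' The configuration is a flat YAML key-value document with a nested drug
#' table, a `ranges` map and a `dist_family` map; [write_fn_params()]
#' produces the canonical form and a reference base-case file ships with the
#' package (`system.file("extdata", "params_basecase.yaml", package =
#' "fncea")`). All fields of [fn_params()] are mandatory; a missing or
#' invalid field raises an error naming it.
#'
#' @param path File path.
#' @param params An `fn_params` object.
#' @return `read_fn_params()` returns a validated `fn_params` object;
#'   `write_fn_params()` returns `path` invisibly.
#' @examples
#' cfg <- system.file("extdata", "params_basecase.yaml", package = "fncea")
#' p <- read_fn_params(cfg)
#' p$cost_fn_event
#' @export
read_fn_params <- function(path) {
  raw <- yaml::read_yaml(path)
  scalars <- setdiff(names(formals(fn_params)),
                     c("drugs", "ranges", "dist_family"))
  for (f in c(scalars, "drugs", "ranges", "dist_family")) {
    if (is.null(raw[[f]])) stop("missing field '", f, "' in ", path,
                                call. = FALSE)
  }
  drugs <- do.call(rbind, lapply(raw$drugs, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  args <- raw[scalars]
  args$drugs <- drugs
  args$ranges <- lapply(raw$ranges, as.numeric)
  args$dist_family <- unlist(raw$dist_family)
  do.call(fn_params, args)
}

#' @rdname read_fn_params
#' @export
write_fn_params <- function(params, path) {
  scalars <- setdiff(names(formals(fn_params)),
                     c("drugs", "ranges", "dist_family"))
  out <- params[scalars]
  out$drugs <- lapply(seq_len(nrow(params$drugs)), function(i) {
    as.list(params$drugs[i, , drop = FALSE])
  })
  out$ranges <- lapply(params$ranges, as.numeric)
  out$dist_family <- as.list(params$dist_family)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Convert an odds ratio to a risk ratio
#'
#' Zhang-Yu conversion `RR = OR / (1 - p0 + p0 * OR)` where `p0` is the
#' outcome risk in the unexposed (reference) group. Used to turn the odds
#' ratio for reduced relative dose intensity with an FN history into the risk
#' ratio applied to the baseline probability.
#'
#' @param or Odds ratio (> 0).
#' @param p0 Baseline (unexposed) outcome probability in `[0, 1)`.
#' @return Risk ratio.
#' @examples
#' or_to_rr(1.58, 0.247) # 1.382
#' @export
or_to_rr <- function(or, p0) {
  if (any(or <= 0)) stop("odds ratio must be positive", call. = FALSE)
  if (any(p0 < 0) || any(p0 >= 1)) {
    stop("baseline probability must lie in [0, 1)", call. = FALSE)
  }
  or / (1 - p0 + p0 * or)
}

#' Get or set a ranged parameter by name
#'
#' Accessor pair used by the one-way and probabilistic sensitivity analyses.
#' Drug-level names (`rr_<drug>_cycles_1_2`, `rr_<drug>_cycles_3plus`,
#' `rr_pegfilgrastim`, `price_<drug>`) address the drug table;
#' `rr_pegfilgrastim` sets both cycle tiers, and setting a reference drug's
#' RR propagates to its biosimilar.
#'
#' @param params An `fn_params` object.
#' @param name Parameter name; see [fn_param_names()].
#' @param value Replacement value.
#' @return `fn_param_value()` the current value; `set_fn_param()` a modified
#'   `fn_params` object.
#' @export
fn_param_value <- function(params, name) {
  d <- params$drugs
  if (name %in% names(params)) return(params[[name]])
  if (name == "rr_pegfilgrastim") {
    return(d$rr_cycles_1_2[d$drug == "pegfilgrastim"])
  }
  m <- regmatches(name, regexec("^rr_([a-z_]+)_cycles_(1_2|3plus)$", name))[[1]]
  if (length(m)) {
    col <- if (m[3] == "1_2") "rr_cycles_1_2" else "rr_cycles_3plus"
    if (!m[2] %in% d$drug) stop("unknown drug '", m[2], "'", call. = FALSE)
    return(d[[col]][d$drug == m[2]])
  }
  m <- regmatches(name, regexec("^price_([a-z_]+)$", name))[[1]]
  if (length(m)) {
    if (!m[2] %in% d$drug) stop("unknown drug '", m[2], "'", call. = FALSE)
    return(d$price[d$drug == m[2]])
  }
  stop("unknown parameter '", name, "'", call. = FALSE)
}

#' @rdname fn_param_value
#' @export
set_fn_param <- function(params, name, value) {
  d <- params$drugs
  if (name %in% names(params)) {
    params[[name]] <- value
  } else if (name == "rr_pegfilgrastim") {
    d$rr_cycles_1_2[d$efficacy_source == "pegfilgrastim"] <- value
    d$rr_cycles_3plus[d$efficacy_source == "pegfilgrastim"] <- value
    params$drugs <- d
  } else if (grepl("^rr_[a-z_]+_cycles_(1_2|3plus)$", name)) {
    m <- regmatches(name,
                    regexec("^rr_([a-z_]+)_cycles_(1_2|3plus)$", name))[[1]]
    col <- if (m[3] == "1_2") "rr_cycles_1_2" else "rr_cycles_3plus"
    if (!m[2] %in% d$drug) stop("unknown drug '", m[2], "'", call. = FALSE)
    d[[col]][d$efficacy_source == m[2]] <- value
    params$drugs <- d
  } else if (grepl("^price_", name)) {
    drug <- sub("^price_", "", name)
    if (!drug %in% d$drug) stop("unknown drug '", drug, "'", call. = FALSE)
    d$price[d$drug == drug] <- value
    params$drugs <- d
  } else {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  params
}

#' @export
print.fn_params <- function(x, ...) {
  cat("FN prophylaxis model parameters\n")
  cat(sprintf("  cohort: age %d, %d chemotherapy cycles of %d days\n",
              x$start_age, x$n_cycles, x$cycle_days))
  cat(sprintf("  FN risk: cycle-1 %.3f, cycles-2+ RR %.2f, history RR %.1f, case fatality %.3f\n",
              x$p_fn_cycle1, x$rr_cycle2plus, x$rr_history, x$p_fn_death))
  cat(sprintf("  FN event cost NT$%s; discount %.1f%%; WTP NT$%s/QALY\n",
              format(x$cost_fn_event, big.mark = ","),
              100 * x$discount_rate, format(x$wtp, big.mark = ",")))
  cat("  drugs:\n")
  print(x$drugs, row.names = FALSE)
  invisible(x)
}
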