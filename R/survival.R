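#' Annual mortality probability in the post-chemotherapy phase
#'
#' Baseline annual death probability is the excess breast-cancer rate
#' (`annual_bc_mortality`, default 2.02%) for post-chemotherapy years 1-10
#' and the general-population female life-table `qx` at the attained age
#' thereafter. For the reduced-RDI stratum the long-term mortality hazard
#' ratio is applied on the hazard scale, `q' = 1 - (1 - q)^hr`, which is the
#' correct transform for a hazard ratio and stays within `[0, 1]` for any
#' `hr > 0` (a naive `q * hr` can exceed 1 at sensitivity-analysis extremes).
#'
#' @param post_chemo_year Post-chemotherapy year (>= 1).
#' @param rdi_low Logical; RDI < 85% stratum?
#' @param age Attained age (years) during that year, used for the life-table
#'   lookup beyond year 10.
#' @param life_table A `life_table` (see [make_life_table()]).
#' @param params An [fn_params()] object.
#' @return Annual death probability.
#' @examples
#' lt <- make_life_table()
#' annual_mortality(3, FALSE, 59, lt, fn_params())  # 0.0202
#' @export
annual_mortality <- function(post_chemo_year, rdi_low, age, life_table,
                             params) {
  if (any(post_chemo_year < 1)) {
    stop("post_chemo_year must be >= 1", call. = FALSE)
  }
  i <- match(age, life_table$age)
  if (anyNA(i)) {
    stop("age ", paste(age[is.na(i)], collapse = ", "),
         " not covered by the life table", call. = FALSE)
  }
  q <- ifelse(post_chemo_year <= params$bc_mortality_years,
              params$annual_bc_mortality, life_table$qx[i])
  low <- rep_len(as.logical(rdi_low), length(q))
  q[low] <- 1 - (1 - q[low])^params$hr_rdi_low
  q
}

#' Post-chemotherapy survival and discounted QALY accrual
#'
#' Depletes the cohort in annual cycles from the end of chemotherapy to the
#' terminal age using [annual_mortality()]. Person-years per cycle use a
#' half-cycle correction (mean of start- and end-of-year survivors); utility
#' is `u_surv_1_5` in post-chemotherapy years 1-5 and `u_surv_5plus`
#' afterwards; health outcomes in year `t` are discounted by
#' `(1 + discount_rate)^-t` (the discount clock starts at the end of
#' chemotherapy; costs are not discounted as none accrue in this phase).
#' The attained age in year `t` is `start_age + t`. With `scenario1 = TRUE`
#' the RDI-mortality link is severed and both strata follow baseline
#' mortality.
#'
#' @param rdi_low Logical; evaluate the RDI < 85% stratum?
#' @param life_table A `life_table`.
#' @param params An [fn_params()] object.
#' @param scenario1 Logical; ignore the RDI stratum (G-CSF assumed to have no
#'   impact on long-term survival)?
#' @return An object of class `survival_outcome` with `discounted_qalys`,
#'   `discounted_life_years` and `survival_curve` (fraction alive at the end
#'   of each post-chemotherapy year; reaches 0 at the terminal age).
#' @export
run_post_chemo <- function(rdi_low, life_table, params, scenario1 = FALSE) {
  horizon <- params$age_cap - params$start_age
  years <- seq_len(horizon)
  ages <- params$start_age + years
  q <- annual_mortality(years, rdi_low && !scenario1, ages, life_table,
                        params)
  surv <- cumprod(1 - q)
  surv_start <- c(1, surv[-length(surv)])
  person_years <- (surv_start + surv) / 2
  u <- ifelse(years <= 5, params$u_surv_1_5, params$u_surv_5plus)
  disc <- (1 + params$discount_rate)^(-years)
  out <- list(
    rdi_low = rdi_low, scenario1 = scenario1,
    discounted_qalys = sum(person_years * u * disc),
    discounted_life_years = sum(person_years * disc),
    survival_curve = surv
  )
  class(out) <- "survival_outcome"
  out
}

#' @export
print.survival_outcome <- function(x, ...) {
  cat("<survival_outcome> RDI stratum: ",
      if (x$rdi_low) "< 85%" else ">= 85%",
      if (x$scenario1) " (scenario 1: RDI-mortality link severed)", "\n",
      sep = "")
  cat(sprintf("  discounted QALYs %.4f over %.4f discounted life years\n",
              x$discounted_qalys, x$discounted_life_years))
  invisible(x)
}
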