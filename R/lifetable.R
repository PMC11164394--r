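#' Build a calibrated synthetic female life table
#'
#' Generates an annual life table (age, `qx` = annual death probability) on a
#' Gompertz mortality schedule `qx(x) = min(1, a * exp(b * (x - start_age)))`
#' with fixed slope `b`, where the level `a` is calibrated by bisection so
#' that residual life expectancy at `start_age` equals `target_e0`. The
#' default target of 29 years approximates the remaining life expectancy of a
#' Taiwanese woman aged 56. `qx` at `age_cap` is forced to 1 so the whole
#' cohort is absorbed in finite time. The schedule is a deliberately simple
#' synthetic stand-in for an official female life table; a real table can be
#' supplied through [read_life_table()] wherever a life table is accepted.
#'
#' @param start_age First age of the table (years).
#' @param age_cap Terminal age; `qx(age_cap) = 1`.
#' @param target_e0 Residual life expectancy at `start_age` (years).
#' @param b Gompertz log-mortality slope per year of age.
#' @return A data frame of class `life_table` with columns `age` and `qx`.
#' @examples
#' lt <- make_life_table()
#' life_expectancy(lt)
#' @export
make_life_table <- function(start_age = 56, age_cap = 110, target_e0 = 29,
                            b = 0.095) {
  if (target_e0 <= 0 || target_e0 >= age_cap - start_age) {
    stop("target_e0 must lie in (0, age_cap - start_age)", call. = FALSE)
  }
  ages <- start_age:age_cap
  e0_of <- function(a) {
    qx <- pmin(1, a * exp(b * (ages - start_age)))
    qx[length(qx)] <- 1
    lx_expectancy(qx)
  }
  lo <- 1e-10
  hi <- 1
  if (e0_of(lo) < target_e0 || e0_of(hi) > target_e0) {
    stop("life-table calibration failed to bracket target_e0", call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (e0_of(mid) > target_e0) lo <- mid else hi <- mid
    if (hi - lo < 1e-14) break
  }
  a <- (lo + hi) / 2
  qx <- pmin(1, a * exp(b * (ages - start_age)))
  qx[length(qx)] <- 1
  new_life_table(data.frame(age = ages, qx = qx))
}

# half-year-convention residual expectancy at the table's first age
lx_expectancy <- function(qx) {
  s <- cumprod(1 - qx)
  s_start <- c(1, s[-length(s)])
  sum((s_start + s) / 2)
}

new_life_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("age", "qx") %in% names(df)))
  df <- df[order(df$age), c("age", "qx")]
  if (any(diff(df$age) != 1)) {
    stop("life-table ages must be contiguous", call. = FALSE)
  }
  if (any(df$qx < 0 | df$qx > 1)) {
    stop("life-table qx must lie in [0, 1]", call. = FALSE)
  }
  if (df$qx[nrow(df)] != 1) {
    stop("life-table qx at the terminal age must equal 1", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

#' Residual life expectancy from a life table
#'
#' Expectancy at `age` under the half-year convention (deaths in a year
#' contribute half that year).
#'
#' @param life_table A `life_table`.
#' @param age Age at which to evaluate; defaults to the table's first age.
#' @return Residual life expectancy in years.
#' @export
life_expectancy <- function(life_table, age = life_table$age[1]) {
  i <- match(age, life_table$age)
  if (is.na(i)) stop("age ", age, " not in life table", call. = FALSE)
  lx_expectancy(life_table$qx[i:nrow(life_table)])
}

#' Read or write a life table CSV
#'
#' Two-column CSV (`age`, `qx`); ages must be contiguous and `qx` at the
#' final age must be 1. A packaged synthetic table generated by
#' [make_life_table()] is available via [default_life_table()].
#'
#' @param path CSV file path.
#' @param life_table A `life_table`.
#' @return `read_life_table()` a validated `life_table`;
#'   `write_life_table()` `path`, invisibly.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  new_life_table(df)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_life_table
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_synthetic.csv",
                              package = "fncea", mustWork = TRUE))
}
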