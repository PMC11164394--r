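#' Prophylaxis strategies
#'
#' A strategy is a prophylaxis mode combined with a G-CSF drug. Under primary
#' prophylaxis (PP) the drug is given in every cycle from cycle 1; under
#' secondary prophylaxis (SP) it is given only in cycles after a first FN
#' event; under no prophylaxis there is no drug (and `drug` must be absent).
#'
#' @param mode One of `"none"`, `"primary"`, `"secondary"`.
#' @param drug Drug identifier matching a row of the parameter set's drug
#'   table, or `NULL` iff `mode = "none"`.
#' @param label Display label; a Table-style default ("PP with pegfilgrastim",
#'   ...) is derived when omitted.
#' @return An object of class `fn_strategy`.
#' @examples
#' fn_strategy("primary", "pegfilgrastim")
#' fn_strategy("none")
#' @export
fn_strategy <- function(mode = c("none", "primary", "secondary"),
                        drug = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (mode == "none" && !is.null(drug)) {
    stop("mode 'none' cannot carry a drug", call. = FALSE)
  }
  if (mode != "none" && is.null(drug)) {
    stop("mode '", mode, "' requires a drug", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (mode == "none") {
      "No G-CSF prophylaxis"
    } else {
      paste(if (mode == "primary") "PP" else "SP", "with",
            gsub("_", " ", drug))
    }
  }
  structure(list(mode = mode, drug = drug, label = label),
            class = "fn_strategy")
}

#' @export
print.fn_strategy <- function(x, ...) {
  cat("<fn_strategy> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Base-case and scenario strategy sets
#'
#' `default_strategies()` returns the seven base-case strategies (no
#' prophylaxis plus SP/PP with each reference drug);
#' `scenario2_strategies()` adds SP/PP with the filgrastim and pegfilgrastim
#' biosimilars (eleven strategies; no lenograstim biosimilar is marketed).
#'
#' @return A named list of `fn_strategy` objects.
#' @export
default_strategies <- function() {
  s <- list(
    fn_strategy("none"),
    fn_strategy("secondary", "filgrastim"),
    fn_strategy("secondary", "lenograstim"),
    fn_strategy("primary", "lenograstim"),
    fn_strategy("primary", "filgrastim"),
    fn_strategy("secondary", "pegfilgrastim"),
    fn_strategy("primary", "pegfilgrastim")
  )
  stats::setNames(s, vapply(s, `[[`, "", "label"))
}

#' @rdname default_strategies
#' @export
scenario2_strategies <- function() {
  s <- c(default_strategies(), {
    extra <- list(
      fn_strategy("secondary", "filgrastim_biosimilar"),
      fn_strategy("primary", "filgrastim_biosimilar"),
      fn_strategy("secondary", "pegfilgrastim_biosimilar"),
      fn_strategy("primary", "pegfilgrastim_biosimilar")
    )
    stats::setNames(extra, vapply(extra, `[[`, "", "label"))
  })
  s
}
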