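#' Tidy a classified element catalog
#'
#' @param x A `pre_classification` from [classify_pres()].
#' @param ... Unused.
#' @return A plain tibble, one row per element.
#' @export
tidy.pre_classification <- function(x, ...) {
  tibble::as_tibble(unclass(x)[!names(unclass(x)) %in% character(0)])
}

#' One-row summary of a classification
#'
#' @inheritParams tidy.pre_classification
#' @return Tibble with class counts and fractions, median RD, median
#'   mutant/control ratio, and the ChIP-vs-input Wilcoxon p-value when the
#'   input RD is available.
#' @export
glance.pre_classification <- function(x, ...) {
  out <- summarize_classes(x)
  out$median_rd <- median(x$rd)
  out$median_ratio <- median(x$ratio, na.rm = TRUE)
  if (!all(is.na(x$rd_input))) {
    w <- compare_distributions(x$rd, x$rd_input)
    out$median_rd_input <- w$median_y
    out$wilcoxon_p <- w$p_value
  }
  out
}

#' @export
tidy.fitted_curve <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.fitted_curve <- function(x, ...) {
  tibble(n = nrow(x), span = attr(x, "span"), degree = attr(x, "degree"))
}

#' @export
tidy.profile_matrix <- function(x, ...) as_tibble(x)
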