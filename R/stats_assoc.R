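#' Pearson chi-square test of association on a contingency table
#'
#' Classic r x c test for association between two categorical variables
#' (e.g. marker level versus tumour stage). By default no continuity
#' correction is applied, matching large clinical tables; set
#' `correct = TRUE` for the Yates-corrected 2x2 variant.
#'
#' @param counts Matrix (or data frame) of non-negative integer counts, at
#'   least 2x2.
#' @param correct Apply the Yates continuity correction for 2x2 tables
#'   (default `FALSE`).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value)
  )
}

#' Reconstruct integer counts from printed percentages
#'
#' Published tables often report a row total and per-category percentages;
#' this utility rebuilds integer counts: each cell is `round(n * p / 100)`
#' and any residual against `n` is assigned to the largest cell, so the
#' reconstructed row sums to `n` exactly.
#'
#' @param n Row total (positive integer).
#' @param percents Numeric vector of percentages summing to 100 within
#'   `tol`.
#' @param tol Allowed deviation of `sum(percents)` from 100 (default 0.5).
#' @return Integer vector of counts summing to `n`.
#' @export
counts_from_percentages <- function(n, percents, tol = 0.5) {
  stopifnot(length(n) == 1L, n > 0)
  if (abs(sum(percents) - 100) > tol) {
    stop("percentages sum to ", sum(percents), ", not 100 (+/- ", tol, ")",
         call. = FALSE)
  }
  counts <- round(n * percents / 100)
  resid <- n - sum(counts)
  if (resid != 0) {
    i <- which.max(counts)
    counts[i] <- counts[i] + resid
  }
  as.integer(counts)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()] so the package's significance tables share one entry
#' point.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input, capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
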