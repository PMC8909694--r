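#' Estimate regulator activities from target-gene expression
#'
#' A transcription factor's activity in a sample is estimated as the
#' edge-score-weighted mean of the z-scored expression of its target genes in
#' that sample: `act[t, k] = sum_i es_i * g[i, k] / sum_i es_i`, over the
#' regulator's targets present in the (preprocessed) expression matrix. The
#' modelling target gene itself is excluded from every activity sum so that
#' the response never leaks into the predictors. Targets missing a value in a
#' sample are dropped pairwise from numerator and denominator for that sample.
#'
#' @param x A preprocessed `expr_matrix` (see [preprocess_expression()]).
#' @param net A `reg_network`.
#' @param regulators Character vector of regulator ids to compute activities
#'   for.
#' @param exclude_gene Gene id excluded from all activity sums (the modelling
#'   target); may be `NULL`.
#' @return An `activity_matrix`: numeric matrix regulators x samples with
#'   attribute `undefined`, the ids of regulators with no scored target in
#'   `x` (their rows are all-`NA` and they are skipped downstream).
#' @export
compute_activity <- function(x, net, regulators, exclude_gene = NULL) {
  stopifnot(inherits(x, "expr_matrix"), inherits(net, "reg_network"))
  vals <- x$values
  act <- matrix(NA_real_, nrow = length(regulators), ncol = ncol(vals),
                dimnames = list(regulators, colnames(vals)))
  undefined <- character()
  es_tab <- net$es[net$es$es > 0, ]
  for (t in regulators) {
    sub <- es_tab[es_tab$regulator == t, ]
    if (!is.null(exclude_gene)) sub <- sub[!sub$target %in% exclude_gene, ]
    sub <- sub[sub$target %in% rownames(vals), ]
    if (nrow(sub) == 0L) {
      undefined <- c(undefined, t)
      next
    }
    g <- vals[sub$target, , drop = FALSE]
    obs <- !is.na(g)
    g[!obs] <- 0
    num <- colSums(sub$es * g)
    den <- colSums(sub$es * obs)
    a <- num / den
    a[den == 0] <- NA_real_
    act[t, ] <- a
  }
  if (length(undefined)) {
    message("activity undefined for ", length(undefined), " regulator(s): ",
            paste(utils::head(undefined, 5L), collapse = ", "),
            if (length(undefined) > 5L) ", ...")
  }
  structure(act, class = c("activity_matrix", "matrix", "array"),
            undefined = undefined)
}

#' Drop regulators whose activity is undefined or constant
#'
#' @param act An `activity_matrix`.
#' @return The matrix restricted to regulators with at least one finite,
#'   non-constant activity profile.
#' @keywords internal
drop_undefined <- function(act) {
  ok <- apply(act, 1L, function(a) {
    a <- a[is.finite(a)]
    length(a) >= 2L && stats::sd(a) > 0
  })
  act[ok, , drop = FALSE]
}

#' Write activities to TSV (regulators x samples)
#'
#' @param act An `activity_matrix`.
#' @param path Output path.
#' @export
write_activity <- function(act, path) {
  tab <- cbind(regulator = rownames(act), as.data.frame(unclass(act)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
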