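#' Read a gene-expression matrix from a tab-separated file
#'
#' The file must have gene identifiers in the first column and one column per
#' sample, with a header row of sample identifiers. Values are numeric on a
#' log-expression scale; missing entries carry `na_token`.
#'
#' @param path Path to a tab-separated text file.
#' @param na_token String marking a missing value (default `"NA"`).
#' @param condition Optional named character vector or two-column data frame
#'   (`sample_id`, `condition`) assigning each sample a condition label. When
#'   omitted, all samples are labelled `"all"`.
#' @return An `expr_matrix` object: a list with `values` (numeric matrix,
#'   genes x samples), `condition` (named character vector over samples) and
#'   `preprocessed` (logical).
#' @seealso [preprocess_expression()], [read_condition_labels()]
#' @export
read_expression <- function(path, na_token = "NA", condition = NULL) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression file must contain a header row and at least one gene row: ",
         path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) == 0L) {
    stop("malformed header: no sample columns in ", path, call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  n_s <- length(sample_ids)
  values <- matrix(NA_real_, nrow = length(gene_ids), ncol = n_s,
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_s + 1L) {
      stop("row for gene '", gene_ids[i], "' has ", length(row) - 1L,
           " values, expected ", n_s, call. = FALSE)
    }
    cells <- row[-1L]
    miss <- cells == na_token
    num <- suppressWarnings(as.numeric(cells))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      j <- which(bad)[1L]
      stop("non-numeric value '", cells[j], "' for gene '", gene_ids[i],
           "', sample '", sample_ids[j], "'", call. = FALSE)
    }
    num[miss] <- NA_real_
    values[i, ] <- num
  }
  new_expr_matrix(values, condition = condition)
}

#' Read sample condition labels
#'
#' @param path Two-column tab-separated file: sample id, condition label. A
#'   header row is detected (and skipped) when its first field matches
#'   `"sample"` case-insensitively.
#' @return Named character vector mapping sample id to condition label.
#' @export
read_condition_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("condition file needs two columns", call. = FALSE)
  if (grepl("^sample", tab[1L, 1L], ignore.case = TRUE)) tab <- tab[-1L, , drop = FALSE]
  stats::setNames(tab[[2L]], tab[[1L]])
}

new_expr_matrix <- function(values, condition = NULL, preprocessed = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  sample_ids <- colnames(values)
  if (is.null(condition)) {
    condition <- stats::setNames(rep("all", length(sample_ids)), sample_ids)
  } else {
    if (is.data.frame(condition)) {
      condition <- stats::setNames(as.character(condition[[2L]]),
                                   as.character(condition[[1L]]))
    }
    missing <- setdiff(sample_ids, names(condition))
    if (length(missing)) {
      stop("no condition label for sample(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    condition <- condition[sample_ids]
  }
  structure(
    list(values = values, condition = condition, preprocessed = preprocessed),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values), " samples",
      if (x$preprocessed) " (z-scored)", "\n", sep = "")
  tab <- table(x$condition)
  cat("  conditions: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `sample_id`, `condition`, `value`.
#' @importFrom tibble as_tibble
#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    condition = rep(unname(x$condition), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Filter and z-score an expression matrix for modelling
#'
#' Applies the preprocessing used before regulator-activity computation:
#' genes with more than `na_frac` missing values are removed, genes whose
#' standard deviation over non-missing entries is `<= sd_min` are removed
#' (low-varying genes carry no signal for activity estimation), remaining
#' genes are z-scored per gene across all samples of all conditions jointly,
#' and samples lacking a value for `target_gene` are dropped (the target must
#' be observed to be modelled). The target gene itself is exempt from the
#' NA/SD filters, as are any genes listed in `keep_genes`, whose unfiltered
#' values are retained and z-scored.
#'
#' @param x An `expr_matrix` from [read_expression()].
#' @param target_gene Gene id of the modelling target; must be present.
#' @param na_frac Maximum tolerated missing fraction per gene (default 0.25;
#'   the filter removes genes strictly above it).
#' @param sd_min Standard-deviation threshold (default 0.5; the filter removes
#'   genes at or below it, sample SD with n-1 denominator on non-missing
#'   entries, computed before z-scoring). Set to `NULL` to skip the SD filter.
#' @param keep_genes Character vector of gene ids exempted from both filters.
#' @return A preprocessed `expr_matrix` (per-gene mean 0, SD 1 over
#'   non-missing entries).
#' @export
preprocess_expression <- function(x, target_gene, na_frac = 0.25, sd_min = 0.5,
                                  keep_genes = character()) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- x$values
  if (!target_gene %in% rownames(vals)) {
    stop("target gene '", target_gene, "' not present in expression matrix",
         call. = FALSE)
  }
  exempt <- rownames(vals) %in% c(target_gene, keep_genes)

  miss_frac <- rowMeans(is.na(vals))
  keep <- exempt | miss_frac <= na_frac
  if (!is.null(sd_min)) {
    sds <- apply(vals, 1L, stats::sd, na.rm = TRUE)
    keep <- keep & (exempt | (!is.na(sds) & sds > sd_min))
  }
  vals <- vals[keep, , drop = FALSE]

  # drop samples where the target is unobserved, then z-score per gene
  ok_sample <- !is.na(vals[target_gene, ])
  if (!any(ok_sample)) {
    stop("all samples lack a value for target gene '", target_gene, "'",
         call. = FALSE)
  }
  vals <- vals[, ok_sample, drop = FALSE]
  mu <- rowMeans(vals, na.rm = TRUE)
  sd <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  sd[is.na(sd) | sd == 0] <- 1  # constant rows map to all-zero, flag below
  vals <- (vals - mu) / sd

  new_expr_matrix(vals, condition = x$condition[colnames(vals)],
                  preprocessed = TRUE)
}

#' Split an expression matrix by condition label
#'
#' @param x An `expr_matrix`.
#' @param label A condition label present in `x$condition`.
#' @return An `expr_matrix` restricted to samples with that label.
#' @export
subset_condition <- function(x, label) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- x$condition == label
  if (!any(keep)) stop("no samples with condition '", label, "'", call. = FALSE)
  new_expr_matrix(x$values[, keep, drop = FALSE],
                  condition = x$condition[keep], preprocessed = x$preprocessed)
}

#' Write an expression matrix to a tab-separated file
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @param na_token Token written for missing values.
#' @export
write_expression <- function(x, path, na_token = "NA") {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- cbind(gene_id = rownames(x$values), as.data.frame(x$values))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na_token)
  invisible(path)
}
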