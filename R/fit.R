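#' Best-subset regression of target expression on regulator activities
#'
#' Selects at most `size` regulators and fits
#' `g_hat[k] = beta0 + sum_t beta[t] * es[t] * act[t, k]`
#' minimising the sum of absolute residuals over samples. The cardinality-
#' constrained problem is solved exactly by branch and bound (see the package
#' vignette); among equally optimal subsets the alphabetically earliest,
#' smallest one is returned.
#'
#' @param act An `activity_matrix` (regulators x samples) covering the
#'   training samples.
#' @param target Numeric vector of the target gene's (z-scored) expression in
#'   the same samples, in column order of `act`.
#' @param es_target Named numeric vector: edge score of each candidate
#'   regulator onto the target gene. Candidates are the names with a positive
#'   score that have a defined, non-constant activity.
#' @param size Maximum number of regulators in the model (`>= 0`).
#' @param big_m Diagnostic bound on coefficient magnitude; a warning is
#'   issued when any fitted `|beta|` reaches it (default 100, ample for
#'   z-scored data).
#' @return A `regulator_model`: list with `selected` (regulator ids), `beta0`,
#'   `beta` (named, non-zero only on `selected`), `es_target`, `size_limit`,
#'   `train_error` (sum of absolute residuals) and `candidates`.
#' @export
fit_regulators <- function(act, target, es_target, size, big_m = 100) {
  X <- candidate_design(act, es_target)
  keep <- stats::complete.cases(cbind(target, t(X)))
  if (!all(keep)) {
    X <- X[, keep, drop = FALSE]
    target <- target[keep]
  }
  if (length(target) == 0L) stop("no complete training samples", call. = FALSE)
  sol <- best_subset_lad(t(X), target, sizes = size)[[1L]]
  model_from_solution(sol, rownames(X), es_target, size, big_m)
}

# design rows = candidates, cols = samples; entry es_t * act_tk
candidate_design <- function(act, es_target) {
  es_target <- es_target[es_target > 0]
  cand <- intersect(rownames(act), names(es_target))
  act <- drop_undefined(act[cand, , drop = FALSE])
  cand <- rownames(act)
  if (length(cand) == 0L) stop("no usable candidate regulators", call. = FALSE)
  unclass(act) * es_target[cand]
}

model_from_solution <- function(sol, cand, es_target, size, big_m) {
  selected <- sort(cand[sol$cols])
  beta <- stats::setNames(numeric(length(cand)), cand)
  if (length(sol$cols)) {
    # coef order follows sol$cols (sorted column indices)
    beta[cand[sol$cols]] <- sol$coef[-1L]
  }
  if (any(abs(beta) >= big_m)) {
    warning("coefficient magnitude reached big_m = ", big_m,
            " (bound active); consider rescaling", call. = FALSE)
  }
  structure(
    list(selected = selected, beta0 = unname(sol$coef[1L]),
         beta = beta[selected], es_target = es_target[selected],
         size_limit = size, train_error = sol$err, candidates = cand),
    class = "regulator_model"
  )
}

#' @export
print.regulator_model <- function(x, ...) {
  cat("<regulator_model> size limit ", x$size_limit, ", selected {",
      paste(x$selected, collapse = ", "), "}\n", sep = "")
  cat("  beta0 = ", format(x$beta0, digits = 4),
      ", train L1 error = ", format(x$train_error, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Predict target expression from a fitted regulator model
#'
#' @param object A `regulator_model`.
#' @param act An `activity_matrix` covering `object$selected` (any sample
#'   set).
#' @param ... Unused.
#' @return Named numeric vector of predictions over the samples of `act`.
#' @export
predict.regulator_model <- function(object, act, ...) {
  miss <- setdiff(object$selected, rownames(act))
  if (length(miss)) {
    stop("no activity for selected regulator(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pred <- rep(object$beta0, ncol(act))
  names(pred) <- colnames(act)
  for (t in object$selected) {
    pred <- pred + object$beta[t] * object$es_target[t] * unclass(act)[t, ]
  }
  pred
}

#' Pearson correlation between predicted and measured expression
#'
#' The model-performance statistic: Pearson correlation of predictions with
#' measurements on held-out samples. Returns `NA` (with a warning) when
#' either vector is constant, where the correlation is undefined.
#'
#' @param predicted,measured Equal-length numeric vectors (length `>= 3`);
#'   pairs with missing values are dropped.
#' @return A single correlation value in `[-1, 1]`, or `NA`.
#' @export
model_performance <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  ok <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[ok]; measured <- measured[ok]
  if (length(predicted) < 3L) stop("need at least 3 sample pairs", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    warning("constant vector: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(predicted, measured)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy regulator_model
#' @export
tidy.regulator_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$selected),
    estimate = c(x$beta0, unname(x$beta)),
    edge_score = c(NA_real_, unname(x$es_target))
  )
}

#' @method glance regulator_model
#' @export
glance.regulator_model <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    size_limit = x$size_limit,
    train_error = x$train_error,
    n_candidates = length(x$candidates)
  )
}
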