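#' Repeated cross-validated best-subset model ensembles
#'
#' Builds the ensemble of regulator models used for selection-frequency
#' analysis: the samples are repeatedly and randomly divided into `folds`
#' parts; for each repeat and fold, models of every size in `sizes` are
#' fitted on the remaining folds and evaluated by Pearson correlation on the
#' held-out fold. With the defaults (10 repeats, 3 folds, sizes 1..10) this
#' yields 300 models per condition.
#'
#' @param x A preprocessed `expr_matrix` (a single condition; use
#'   [subset_condition()] first for dual-condition analyses).
#' @param net A `reg_network`.
#' @param target_gene The modelled gene id (present in `x`).
#' @param candidates Character vector of candidate direct regulators; default
#'   all regulators with an edge onto `target_gene`.
#' @param sizes Integer vector of model-size caps (default `1:10`).
#' @param repeats Number of random fold divisions (default 10).
#' @param folds Number of folds (default 3); fold sizes differ by at most 1.
#' @param seed Integer seed controlling the fold divisions.
#' @param big_m Coefficient-bound diagnostic, see [fit_regulators()].
#' @return A `cv_result`: list with `models` (tibble: `repeat_id`, `fold`,
#'   `size`, `selected` list-column, `n_selected`, `train_error`,
#'   `performance`), `frequencies` (tibble: `regulator`, `count`, `freq`,
#'   sorted by count), `n_models`, `candidates`, and the CV parameters.
#' @export
cross_validate <- function(x, net, target_gene, candidates = NULL,
                           sizes = 1:10, repeats = 10, folds = 3, seed = 1,
                           big_m = 100) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(candidates)) candidates <- regulators_of(net, target_gene)$regulator
  es_target <- stats::setNames(
    edge_score(net, candidates, rep(target_gene, length(candidates))),
    candidates
  )
  es_target <- es_target[es_target > 0]
  if (length(es_target) == 0L) {
    stop("no candidate regulator has an edge onto '", target_gene, "'",
         call. = FALSE)
  }
  act <- compute_activity(x, net, names(es_target), exclude_gene = target_gene)
  y_all <- x$values[target_gene, ]
  cv_core(act, y_all, es_target, sizes = sizes, repeats = repeats,
          folds = folds, seed = seed, big_m = big_m)
}

# CV engine on a prepared activity matrix + target vector.
cv_core <- function(act, y_all, es_target, sizes, repeats, folds, seed, big_m) {
  n <- ncol(act)
  if (n < folds) stop("fewer samples (", n, ") than folds (", folds, ")",
                      call. = FALSE)
  sizes <- sort(unique(as.integer(sizes)))
  X_all <- candidate_design(act, es_target)
  cand <- rownames(X_all)
  rows <- list()
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
      for (f in seq_len(folds)) {
        train <- fold_id != f
        ok <- train & !is.na(y_all) & colSums(is.na(X_all)) == 0L
        sols <- best_subset_lad(t(X_all[, ok, drop = FALSE]), y_all[ok],
                                sizes = sizes)
        test <- which(!train & !is.na(y_all))
        for (sol in sols) {
          m <- model_from_solution(sol, cand, es_target, sol$size, big_m)
          perf <- NA_real_
          if (length(test) >= 3L) {
            pred <- predict(m, act[, test, drop = FALSE])
            perf <- suppressWarnings(model_performance(pred, y_all[test]))
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            repeat_id = r, fold = f, size = sol$size,
            selected = list(m$selected), n_selected = length(m$selected),
            train_error = m$train_error, performance = perf
          )
        }
      }
    }
  })
  models <- dplyr::bind_rows(rows)
  new_cv_result(models, cand,
                params = list(sizes = sizes, repeats = repeats, folds = folds,
                              seed = seed))
}

new_cv_result <- function(models, candidates, params) {
  counts <- table(factor(unlist(models$selected), levels = sort(candidates)))
  frequencies <- tibble::tibble(
    regulator = names(counts),
    count = as.integer(counts),
    freq = as.integer(counts) / nrow(models)
  ) |> dplyr::arrange(dplyr::desc(.data$count), .data$regulator)
  structure(
    list(models = models, frequencies = frequencies, n_models = nrow(models),
         candidates = sort(candidates), params = params),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$n_models, " models (",
      x$params$repeats, " repeats x ", x$params$folds, " folds x ",
      length(x$params$sizes), " sizes), ",
      length(x$candidates), " candidates\n", sep = "")
  print(utils::head(x$frequencies, 5L))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$frequencies

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_models = x$n_models,
    n_candidates = length(x$candidates),
    mean_performance = mean(x$models$performance, na.rm = TRUE),
    mean_train_error = mean(x$models$train_error)
  )
}

#' Compare regulator selection frequencies between two conditions
#'
#' For each candidate regulator, the number of cross-validation models that
#' selected it in condition A versus condition B is compared with a
#' two-sided Fisher exact test on the 2x2 table
#' `[count_A, n_A - count_A; count_B, n_B - count_B]`, and p-values are
#' Benjamini-Hochberg adjusted across all tested regulators.
#'
#' @param cv_a,cv_b `cv_result` objects for the two conditions, built on the
#'   same candidate set.
#' @return A tibble (`regulator`, `count_a`, `count_b`, `n_a`, `n_b`,
#'   `freq_a`, `freq_b`, `p_raw`, `p_adj`) sorted by `p_adj` then `p_raw`.
#' @export
compare_conditions <- function(cv_a, cv_b) {
  stopifnot(inherits(cv_a, "cv_result"), inherits(cv_b, "cv_result"))
  if (!identical(cv_a$candidates, cv_b$candidates)) {
    stop("the two cross-validations use different candidate sets", call. = FALSE)
  }
  if (cv_a$n_models == 0L || cv_b$n_models == 0L) {
    stop("a condition has zero models", call. = FALSE)
  }
  fa <- stats::setNames(cv_a$frequencies$count, cv_a$frequencies$regulator)
  fb <- stats::setNames(cv_b$frequencies$count, cv_b$frequencies$regulator)
  regs <- cv_a$candidates
  n_a <- cv_a$n_models; n_b <- cv_b$n_models
  p_raw <- vapply(regs, function(t) {
    tab <- matrix(c(fa[[t]], n_a - fa[[t]], fb[[t]], n_b - fb[[t]]), nrow = 2L)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  tibble::tibble(
    regulator = regs,
    count_a = unname(fa[regs]), count_b = unname(fb[regs]),
    n_a = n_a, n_b = n_b,
    freq_a = unname(fa[regs]) / n_a, freq_b = unname(fb[regs]) / n_b,
    p_raw = unname(p_raw),
    p_adj = benjamini_hochberg(unname(p_raw))
  ) |> dplyr::arrange(.data$p_adj, .data$p_raw, .data$regulator)
}
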