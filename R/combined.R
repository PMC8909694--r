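#' Pre-select indirect regulator candidates
#'
#' Indirect regulators act on the target through its direct regulators. For
#' each direct regulator whose coding gene has expression values, a
#' single-target cross-validation ([cross_validate()]) is run with that gene
#' as target; regulators selected in at least `threshold` of the models are
#' kept. The union over all direct regulators forms the indirect candidate
#' pool. Direct regulators lacking expression contribute no candidates (a
#' message is emitted).
#'
#' @param x A preprocessed `expr_matrix`.
#' @param net A `reg_network`.
#' @param direct_regulators Character vector of direct-regulator ids.
#' @param threshold Minimum selection fraction, inclusive (default 0.20).
#' @inheritParams cross_validate
#' @return A list: `per_direct` (tibble `direct`, `indirect`, `count`,
#'   `freq`), `pool` (character vector, union of kept indirect regulators),
#'   `overlap` (pool members that are themselves direct regulators),
#'   `skipped` (direct regulators without expression).
#' @export
preselect_indirect <- function(x, net, direct_regulators, threshold = 0.20,
                               sizes = 1:10, repeats = 10, folds = 3,
                               seed = 1, big_m = 100) {
  stopifnot(inherits(x, "expr_matrix"))
  per <- list()
  skipped <- character()
  for (d in direct_regulators) {
    if (!d %in% rownames(x$values)) {
      message("direct regulator '", d,
              "' has no expression values; no model possible, skipped")
      skipped <- c(skipped, d)
      next
    }
    cand <- setdiff(regulators_of(net, d)$regulator, d)
    if (length(cand) == 0L) next
    cv <- cross_validate(x, net, target_gene = d, candidates = cand,
                         sizes = sizes, repeats = repeats, folds = folds,
                         seed = seed, big_m = big_m)
    kept <- cv$frequencies[cv$frequencies$freq >= threshold, ]
    if (nrow(kept)) {
      per[[d]] <- tibble::tibble(direct = d, indirect = kept$regulator,
                                 count = kept$count, freq = kept$freq)
    }
  }
  per_direct <- if (length(per)) dplyr::bind_rows(per) else {
    tibble::tibble(direct = character(), indirect = character(),
                   count = integer(), freq = numeric())
  }
  pool <- sort(unique(per_direct$indirect))
  list(per_direct = per_direct, pool = pool,
       overlap = intersect(pool, direct_regulators), skipped = skipped)
}

#' Jointly select direct and indirect regulators
#'
#' Solves the combined problem: minimise the L1 regression error of the
#' target on the selected *direct* regulators' activities minus `lambda`
#' times the modularity score of *all* selected regulators, subject to a
#' total budget `limit` on the selected set. A candidate belonging to both
#' pools carries a single selection variable that feeds both objective
#' parts. Solved exactly by branch and bound; `lambda = 0` reduces to
#' [fit_regulators()] (zero-cost indirect nodes are not added, by the
#' smaller-set tie-break), large `lambda` reduces to [solve_module()].
#'
#' @param act An `activity_matrix` over the training samples, covering all
#'   candidates.
#' @param target Numeric target-expression vector over those samples.
#' @param es_target Named edge scores of direct candidates onto the target.
#' @param direct_candidates,indirect_candidates Candidate pools (ids).
#' @param module_graph A modularity-corrected `module_graph` spanning the
#'   union of the pools.
#' @param lambda Trade-off weight (`>= 0`).
#' @param limit Total selection budget (direct + indirect).
#' @param big_m Coefficient-bound diagnostic.
#' @param corrected Use corrected weights `w_mod` (default) or raw `w`.
#' @return A `combined_model`: list with `direct_selected`,
#'   `indirect_selected`, `model` (a `regulator_model` on the direct part),
#'   `fit_error`, `modularity_score`, `objective`
#'   (`fit_error - lambda * modularity_score`), `lambda`, `limit`.
#' @export
solve_combined <- function(act, target, es_target, direct_candidates,
                           indirect_candidates, module_graph, lambda, limit,
                           big_m = 100, corrected = TRUE) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (limit < 0) stop("limit must be >= 0", call. = FALSE)
  stopifnot(inherits(module_graph, "module_graph"))
  W <- if (corrected) {
    if (is.null(module_graph$w_mod)) {
      stop("module graph is not modularity-corrected", call. = FALSE)
    }
    module_graph$w_mod
  } else {
    module_graph$w
  }
  cands <- unique(c(direct_candidates, indirect_candidates))
  miss <- setdiff(cands, module_graph$nodes)
  if (length(miss)) {
    stop("module graph does not span candidate(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  W <- W[cands, cands, drop = FALSE]

  es_target <- es_target[names(es_target) %in% direct_candidates &
                           es_target > 0]
  X <- candidate_design(act, es_target)        # direct design, rows = direct
  keep <- stats::complete.cases(cbind(target, t(X)))
  Xs <- t(X[, keep, drop = FALSE])
  y <- target[keep]
  dir_ids <- rownames(X)

  sol <- combined_branch_bound(Xs, y, dir_ids, cands, W, lambda, limit)
  sel <- cands[sol$selected]
  dir_sel_idx <- match(intersect(sel, dir_ids), dir_ids)
  fit <- lad_fit(Xs, y, cols = sort(dir_sel_idx))
  reg <- model_from_solution(
    list(size = limit, cols = sort(dir_sel_idx), coef = fit$coef,
         err = fit$err),
    dir_ids, es_target, limit, big_m
  )
  mod_score <- module_score(W, sol$selected)
  structure(
    list(direct_selected = sort(intersect(sel, direct_candidates)),
         indirect_selected = sort(setdiff(sel, direct_candidates)),
         model = reg, fit_error = fit$err, modularity_score = mod_score,
         objective = fit$err - lambda * mod_score,
         lambda = lambda, limit = limit),
    class = "combined_model"
  )
}

# Exact branch and bound for: minimise lad(S n direct) - lambda *
# module_score(W, S) + tie_eps * sum(rank(S)), |S| <= limit, over subsets S
# of the candidate indices 1..n (order of `cands`). Bound combines the
# regression relaxation (all undecided direct columns free) with the
# optimistic modularity bound of max_weight_subset.
combined_branch_bound <- function(Xs, y, dir_ids, cands, W, lambda, limit,
                                  tie_eps = 1e-9) {
  n <- length(cands)
  limit <- min(limit, n)
  rank_pen <- tie_eps * rank(cands, ties.method = "first")
  dir_col <- match(cands, dir_ids)              # NA for indirect-only nodes
  Wpos <- pmax(W, 0); diag(Wpos) <- 0

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  lad_err <- function(cols) {                   # cols: sorted design columns
    key <- paste0("s", paste(cols, collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    v <- lad_fit(Xs, y, cols)$err
    cache[[key]] <- v
    v
  }

  # branch order: direct candidates by relaxed coefficient strength, then
  # indirect nodes by positive modularity strength
  full <- lad_fit(Xs, y, seq_along(dir_ids))
  strength <- numeric(n)
  has_col <- !is.na(dir_col)
  strength[has_col] <- abs(full$coef[-1L][dir_col[has_col]])
  ord <- order(has_col, strength + rowSums(Wpos)[seq_len(n)] * 1e-3,
               decreasing = TRUE)

  best <- list(obj = Inf, sel = integer())
  evaluate <- function(chosen, mscore) {
    cols <- sort(dir_col[chosen])
    cols <- cols[!is.na(cols)]
    obj <- lad_err(cols) - lambda * mscore + sum(rank_pen[chosen])
    if (obj < best$obj - 1e-15) best <<- list(obj = obj, sel = chosen)
    obj
  }
  evaluate(integer(), 0)

  recurse <- function(chosen, mscore, rem, r) {
    # regression relaxation: chosen direct + every undecided direct free
    relax_cols <- sort(c(dir_col[chosen], dir_col[rem]))
    relax_cols <- relax_cols[!is.na(relax_cols)]
    u <- vapply(rem, function(j) {
      sum(Wpos[j, chosen]) + sum(Wpos[j, rem]) / 2
    }, numeric(1))
    mod_ub <- mscore + if (r > 0L && length(u)) {
      sum(utils::head(sort(u, decreasing = TRUE), r))
    } else 0
    bound <- lad_err(relax_cols) - lambda * mod_ub + sum(rank_pen[chosen])
    if (bound >= best$obj - 1e-12) return(invisible())
    if (length(rem) == 0L || r == 0L) return(invisible())
    j <- rem[[1L]]
    rest <- rem[-1L]
    ms_j <- mscore + sum(W[j, chosen])
    evaluate(c(chosen, j), ms_j)
    recurse(c(chosen, j), ms_j, rest, r - 1L)
    recurse(chosen, mscore, rest, r)
  }
  recurse(integer(), 0, ord, limit)
  list(selected = sort(best$sel), objective = best$obj)
}

#' @export
print.combined_model <- function(x, ...) {
  cat("<combined_model> lambda = ", x$lambda, ", limit = ", x$limit, "\n",
      "  direct: {", paste(x$direct_selected, collapse = ", "), "}\n",
      "  indirect: {", paste(x$indirect_selected, collapse = ", "), "}\n",
      "  fit L1 error = ", format(x$fit_error, digits = 6),
      ", modularity = ", format(x$modularity_score, digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' @method glance combined_model
#' @export
glance.combined_model <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, limit = x$limit,
    n_direct = length(x$direct_selected),
    n_indirect = length(x$indirect_selected),
    fit_error = x$fit_error, modularity_score = x$modularity_score,
    objective = x$objective
  )
}

#' Cross-validated ensemble of combined models
#'
#' Runs the combined direct+indirect selection over repeated fold divisions
#' and all size budgets, mirroring [cross_validate()] for the joint model.
#'
#' @inheritParams solve_combined
#' @param sizes Integer vector of total budgets (default `2:20`).
#' @param repeats,folds,seed Cross-validation parameters.
#' @return Tibble with one row per (repeat, fold, size): `repeat_id`, `fold`,
#'   `size`, `direct` and `indirect` list-columns, counts, `fit_error`,
#'   `modularity_score` and held-out `performance`.
#' @export
cross_validate_combined <- function(act, target, es_target, direct_candidates,
                                    indirect_candidates, module_graph, lambda,
                                    sizes = 2:20, repeats = 10, folds = 3,
                                    seed = 1, big_m = 100, corrected = TRUE) {
  n <- ncol(act)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  sizes <- sort(unique(as.integer(sizes)))
  rows <- list()
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
      for (f in seq_len(folds)) {
        tr <- fold_id != f & !is.na(target)
        te <- which(fold_id == f & !is.na(target))
        for (s in sizes) {
          cm <- solve_combined(act[, tr, drop = FALSE], target[tr], es_target,
                               direct_candidates, indirect_candidates,
                               module_graph, lambda = lambda, limit = s,
                               big_m = big_m, corrected = corrected)
          perf <- NA_real_
          if (length(te) >= 3L && length(cm$model$selected)) {
            pred <- predict(cm$model, act[, te, drop = FALSE])
            perf <- suppressWarnings(model_performance(pred, target[te]))
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            repeat_id = r, fold = f, size = s,
            direct = list(cm$direct_selected),
            indirect = list(cm$indirect_selected),
            n_direct = length(cm$direct_selected),
            n_indirect = length(cm$indirect_selected),
            fit_error = cm$fit_error,
            modularity_score = cm$modularity_score,
            performance = perf
          )
        }
      }
    }
  })
  dplyr::bind_rows(rows)
}

#' Tune the regression/modularity trade-off weight
#'
#' For each `lambda` on the grid, a full combined cross-validation is run
#' and the total numbers of selected direct and indirect regulators over all
#' models are counted, together with mean held-out performance. The tuned
#' `lambda_star` is where the two count curves cross, interpolated linearly
#' in `log10(lambda)` between adjacent grid points where the sign of
#' (direct - indirect) flips; an exact tie at a grid point is returned as
#' is. If the curves never cross on the grid, `lambda_star` is the grid
#' value minimising `|direct - indirect|` and a warning is issued.
#'
#' @inheritParams cross_validate_combined
#' @param lambda_grid Candidate trade-off weights (default the logarithmic
#'   grid 0.001, 0.01, 0.1, 0.3, 1, 3, 10, 100, 1000).
#' @return A `lambda_sweep` object: list with `sweep` (tibble: `lambda`,
#'   `n_direct`, `n_indirect`, `mean_performance`), `lambda_star`,
#'   `crossed` (logical), `capacity` (total selection slots per lambda,
#'   `repeats * folds * sum(sizes)`), and the call parameters.
#' @export
sweep_lambda <- function(act, target, es_target, direct_candidates,
                         indirect_candidates, module_graph,
                         lambda_grid = c(0.001, 0.01, 0.1, 0.3, 1, 3, 10, 100,
                                         1000),
                         sizes = 2:20, repeats = 10, folds = 3, seed = 1,
                         big_m = 100, corrected = TRUE) {
  lambda_grid <- sort(lambda_grid)
  per <- purrr::map(lambda_grid, function(lam) {
    mods <- cross_validate_combined(
      act, target, es_target, direct_candidates, indirect_candidates,
      module_graph, lambda = lam, sizes = sizes, repeats = repeats,
      folds = folds, seed = seed, big_m = big_m, corrected = corrected
    )
    tibble::tibble(
      lambda = lam,
      n_direct = sum(mods$n_direct),
      n_indirect = sum(mods$n_indirect),
      mean_performance = mean(mods$performance, na.rm = TRUE)
    )
  })
  sweep <- dplyr::bind_rows(per)
  cross <- interpolate_crossing(lambda_grid, sweep$n_direct, sweep$n_indirect)
  structure(
    list(sweep = sweep, lambda_star = cross$lambda_star,
         crossed = cross$crossed,
         capacity = selection_capacity(sizes, repeats, folds),
         params = list(sizes = sizes, repeats = repeats, folds = folds,
                       seed = seed, lambda_grid = lambda_grid)),
    class = "lambda_sweep"
  )
}

#' Total selection slots of a cross-validated size sweep
#'
#' Each of the `repeats * folds` cross-validation models is built at every
#' size budget, so the total number of regulator slots available per lambda
#' is `repeats * folds * sum(sizes)` (6270 for the defaults: sizes 2..20,
#' 10 repeats, 3 folds).
#'
#' @param sizes Integer vector of size budgets.
#' @param repeats,folds Cross-validation parameters.
#' @return Integer slot count.
#' @export
selection_capacity <- function(sizes, repeats, folds) {
  as.integer(repeats) * as.integer(folds) * sum(as.integer(sizes))
}

# Crossing of the direct and indirect count curves against log10(lambda).
interpolate_crossing <- function(grid, n_direct, n_indirect) {
  diff <- n_direct - n_indirect
  exact <- which(diff == 0)
  if (length(exact)) {
    return(list(lambda_star = grid[exact[1L]], crossed = TRUE))
  }
  sign_flip <- which(diff[-length(diff)] * diff[-1L] < 0)
  if (length(sign_flip)) {
    i <- sign_flip[1L]
    frac <- diff[i] / (diff[i] - diff[i + 1L])
    lg <- log10(grid[i]) + frac * (log10(grid[i + 1L]) - log10(grid[i]))
    return(list(lambda_star = 10^lg, crossed = TRUE))
  }
  warning("direct and indirect count curves do not cross on the grid; ",
          "returning the closest-balance lambda", call. = FALSE)
  list(lambda_star = grid[which.min(abs(diff))], crossed = FALSE)
}

#' @export
print.lambda_sweep <- function(x, ...) {
  cat("<lambda_sweep> ", nrow(x$sweep), " grid points, capacity ",
      x$capacity, " slots per lambda\n", sep = "")
  cat("  lambda_star = ", format(x$lambda_star, digits = 6),
      if (!x$crossed) " (no crossing; closest balance)", "\n", sep = "")
  invisible(x)
}

#' @method tidy lambda_sweep
#' @export
tidy.lambda_sweep <- function(x, ...) x$sweep

#' @method glance lambda_sweep
#' @export
glance.lambda_sweep <- function(x, ...) {
  tibble::tibble(lambda_star = x$lambda_star, crossed = x$crossed,
                 capacity = x$capacity,
                 best_mean_performance = max(x$sweep$mean_performance,
                                             na.rm = TRUE))
}

#' Extract the consensus module from an ensemble of combined models
#'
#' Across all cross-validated combined models (typically at the tuned
#' `lambda_star`), the most frequent exact combination of direct regulators
#' is identified (ties broken by higher mean held-out performance, then
#' lexicographically); the module's indirect regulators are those selected
#' in more than half of the models carrying that winning combination.
#'
#' @param models Tibble from [cross_validate_combined()].
#' @return List with `direct` (winning combination), `indirect` (majority
#'   co-selected set), `support` (model count of the combination),
#'   `support_frac` (fraction of all models), `n_models`.
#' @export
extract_final_module <- function(models) {
  stopifnot(nrow(models) >= 1L)
  key <- vapply(models$direct, function(s) paste(sort(s), collapse = "|"),
                character(1))
  stat <- tibble::tibble(key = key, performance = models$performance) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_perf = mean(.data$performance, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), dplyr::desc(.data$mean_perf),
                   .data$key)
  win <- stat$key[1L]
  in_win <- key == win
  ind_counts <- table(unlist(models$indirect[in_win]))
  indirect <- sort(names(ind_counts)[ind_counts > sum(in_win) / 2])
  list(
    direct = if (nzchar(win)) strsplit(win, "|", fixed = TRUE)[[1L]] else character(),
    indirect = indirect,
    support = sum(in_win),
    support_frac = sum(in_win) / nrow(models),
    n_models = nrow(models)
  )
}
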