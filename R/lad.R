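# Least-absolute-deviations (L1) fitting utilities.
#
# The subset-selection solvers below repeatedly need the exact optimum of
#   minimize_b sum_k | y_k - b0 - X[k, S] %*% b_S |
# for a fixed column subset S. This is a linear program; it is solved with the
# Barrodale-Roberts simplex as implemented in quantreg (median regression,
# tau = 0.5). An intercept is always included.

# Fit LAD with an intercept on the given columns of X (may be empty).
# Returns list(coef = c(intercept, per-column), err = sum of |residuals|).
lad_fit <- function(X, y, cols = seq_len(ncol(X))) {
  if (length(cols) == 0L) {
    b0 <- stats::median(y)
    return(list(coef = b0, err = sum(abs(y - b0))))
  }
  Xs <- cbind(1, X[, cols, drop = FALSE])
  co <- rep(0, ncol(Xs))
  # rank-deficient designs (e.g. duplicated columns): fit on a maximal
  # independent column set, leave the dependent coefficients at zero
  qr_x <- qr(Xs)
  use <- qr_x$pivot[seq_len(qr_x$rank)]
  fit <- suppressWarnings(
    quantreg::rq.fit.br(Xs[, use, drop = FALSE], y, tau = 0.5)
  )
  co[use] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  err <- sum(abs(y - drop(Xs %*% co)))
  list(coef = co, err = err)
}

# Exact best-subset LAD regression by branch and bound.
#
# Finds, for every cardinality cap s in `sizes`, the subset S of columns of X
# with |S| <= s minimising sum |y - b0 - X_S b_S|, with a deterministic
# lexicographic tie-break: the objective is perturbed by
# tie_eps * sum of the selected columns' alphabetical ranks, so among
# equally fitting subsets the smaller / alphabetically earlier one wins.
#
# Validity of the bound: the optimal L1 error is non-increasing under adding
# columns, so the LAD fit on (chosen + all undecided) columns lower-bounds
# every completion of a node. Search is depth-first, include-branch first,
# with incumbents shared across all size caps.
#
# Returns a list with one element per size cap: list(size, cols, coef, err).
best_subset_lad <- function(X, y, sizes, tie_eps = 1e-9) {
  p <- ncol(X)
  stopifnot(p == 0L || !is.null(colnames(X)))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 0L)) stop("size must be >= 0", call. = FALSE)
  smax <- min(max(sizes), p)
  rank_pen <- tie_eps * rank(colnames(X), ties.method = "first")

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  fit_cached <- function(cols) {
    key <- paste0("s", paste(cols, collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    res <- lad_fit(X, y, cols)
    cache[[key]] <- res
    res
  }

  # incumbents: best[[k + 1]] = best solution with |S| <= k (perturbed obj)
  best_obj <- rep(Inf, smax + 1L)
  best_sol <- vector("list", smax + 1L)
  offer <- function(cols) {
    f <- fit_cached(cols)
    obj <- f$err + sum(rank_pen[cols])
    k <- length(cols)
    for (s in seq.int(k, smax)) {
      if (obj < best_obj[s + 1L]) {
        best_obj[s + 1L] <<- obj
        best_sol[[s + 1L]] <<- list(cols = cols, coef = f$coef, err = f$err)
      }
    }
    invisible(obj)
  }

  offer(integer())
  if (p > 0L && smax > 0L) {
    # greedy forward pass seeds the incumbents
    cur <- integer()
    for (k in seq_len(smax)) {
      rem <- setdiff(seq_len(p), cur)
      errs <- vapply(rem, function(j) fit_cached(sort(c(cur, j)))$err,
                     numeric(1))
      cur <- sort(c(cur, rem[which.min(errs)]))
      offer(cur)
    }

    # branch order: strongest coefficients in the full relaxation first
    full <- fit_cached(seq_len(p))
    ord <- order(abs(full$coef[-1L]), decreasing = TRUE)

    recurse <- function(chosen, undecided) {
      relax <- sort(c(chosen, undecided))
      bound <- fit_cached(relax)$err + sum(rank_pen[chosen])
      # reachable caps are |chosen|..smax; best_obj is non-increasing, so the
      # loosest incumbent among them is at |chosen|
      if (bound >= best_obj[length(chosen) + 1L] - 1e-12) return(invisible())
      if (length(undecided) == 0L) {
        offer(sort(chosen))
        return(invisible())
      }
      v <- undecided[1L]
      rest <- undecided[-1L]
      inc <- sort(c(chosen, v))
      offer(inc)
      if (length(inc) < smax && length(rest) > 0L) recurse(inc, rest)
      recurse(chosen, rest)
    }
    recurse(integer(), ord)
  }

  lapply(sizes, function(s) {
    sol <- best_sol[[min(s, smax) + 1L]]
    list(size = s, cols = sol$cols, coef = sol$coef, err = sol$err)
  })
}
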