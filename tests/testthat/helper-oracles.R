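# Independent oracles and small builders shared across tests.

# Exhaustive best-subset search: every subset of columns up to size smax is
# scored by its own least-absolute-deviations fit. Independent of the
# package's branch-and-bound search path.
brute_best_subset <- function(X, y, smax) {
  p <- ncol(X)
  best <- list(err = Inf, cols = integer())
  for (k in 0:min(smax, p)) {
    combs <- if (k == 0L) list(integer()) else asplit(utils::combn(p, k), 2L)
    for (S in combs) {
      e <- lad_oracle_err(X, y, as.integer(S))
      if (e < best$err - 1e-9) best <- list(err = e, cols = as.integer(S))
    }
  }
  best
}

# LAD error for a fixed subset via quantreg (plain median regression).
lad_oracle_err <- function(X, y, cols) {
  if (length(cols) == 0L) return(sum(abs(y - stats::median(y))))
  Xs <- cbind(1, X[, cols, drop = FALSE])
  co <- suppressWarnings(quantreg::rq.fit.br(Xs, y, tau = 0.5))$coefficients
  co[is.na(co)] <- 0
  sum(abs(y - drop(Xs %*% co)))
}

# Vertex-enumeration LAD oracle for tiny problems: an optimal L1 hyperplane
# interpolates p+1 data points, so minimising over all interpolating planes
# is exact. Independent of any simplex implementation.
lad_vertex_err <- function(X, y, cols) {
  Xs <- cbind(1, X[, cols, drop = FALSE])
  p <- ncol(Xs)
  n <- length(y)
  best <- Inf
  for (S in asplit(utils::combn(n, p), 2L)) {
    A <- Xs[S, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    b <- solve(A, y[S])
    e <- sum(abs(y - drop(Xs %*% b)))
    if (e < best) best <- e
  }
  best
}

# Exhaustive maximum-modularity subset search over all subsets of <= limit
# nodes; score(S) = sum of pair weights inside S.
brute_module <- function(W, limit) {
  p <- nrow(W)
  best <- list(score = 0, sel = integer())
  for (k in 2:min(limit, p)) {
    for (S in asplit(utils::combn(p, k), 2L)) {
      S <- as.integer(S)
      sc <- sum(W[S, S][upper.tri(matrix(0, k, k))])
      if (sc > best$score + 1e-12) best <- list(score = sc, sel = S)
    }
  }
  best
}

# Module graph from a symmetric weight matrix (diagonal zeroed).
make_module_graph <- function(W, correct = TRUE) {
  stopifnot(isSymmetric(unname(W)))
  diag(W) <- 0
  nodes <- rownames(W)
  g <- structure(list(nodes = nodes, w = W), class = "module_graph")
  if (correct) g <- modularity_correct(g)
  g
}

# Random symmetric weight matrix with named nodes.
random_weights <- function(p, seed) {
  withr::with_seed(seed, {
    W <- matrix(stats::rnorm(p * p), p)
    W <- (W + t(W)) / 2
  })
  diag(W) <- 0
  nd <- sprintf("N%02d", seq_len(p))
  dimnames(W) <- list(nd, nd)
  W
}

# Activity matrix wrapper for hand-built matrices.
as_activity <- function(m) {
  structure(m, class = c("activity_matrix", "matrix", "array"),
            undefined = character())
}

# Small expression file fixture written to a temp path.
write_expr_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
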