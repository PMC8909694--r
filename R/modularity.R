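#' Regulator-pair weights from activity correlations
#'
#' Builds the weighted regulator-regulator graph used by the modularity
#' stage. For a pair (t1, t2) the weight is the Pearson correlation of the
#' two activity profiles multiplied by the network edge score between them;
#' because the network is directed and the two directions need not carry the
#' same score, the mean of both directions is taken (a missing direction
#' contributes score 0):
#' `w(t1, t2) = mean(cor * es(t1 -> t2), cor * es(t2 -> t1))`.
#' A constant activity profile has undefined correlation; it is set to 0 and
#' flagged with a warning. Self-weights are fixed to 0.
#'
#' @param act An `activity_matrix` over a common sample set (`>= 3` samples).
#' @param net A `reg_network`.
#' @param nodes Regulator ids to include (default all rows of `act`).
#' @return A `module_graph`: list with `nodes`, `w` (symmetric matrix) and,
#'   after [modularity_correct()], `w_mod`, `d`, `m`.
#' @export
pairwise_weights <- function(act, net, nodes = rownames(act)) {
  stopifnot(inherits(net, "reg_network"))
  act <- unclass(act)[nodes, , drop = FALSE]
  if (ncol(act) < 3L) stop("need at least 3 common samples", call. = FALSE)
  n <- length(nodes)
  const <- apply(act, 1L, function(a) stats::sd(a, na.rm = TRUE) == 0 ||
                   sum(is.finite(a)) < 2L)
  if (any(const)) {
    warning("constant activity for: ", paste(nodes[const], collapse = ", "),
            "; correlations set to 0", call. = FALSE)
  }
  cors <- suppressWarnings(stats::cor(t(act), use = "pairwise.complete.obs"))
  cors[!is.finite(cors)] <- 0
  fwd <- matrix(edge_score(net,
                           rep(nodes, times = n), rep(nodes, each = n)),
                nrow = n, dimnames = list(nodes, nodes))
  w <- cors * (fwd + t(fwd)) / 2
  diag(w) <- 0
  structure(list(nodes = nodes, w = w), class = "module_graph")
}

#' Apply the Newman null-model correction to pair weights
#'
#' Subtracts from each pair weight the expectation under the configuration
#' null model: `w_mod(t1, t2) = w(t1, t2) - d(t1) * d(t2) / (2 m)` with node
#' degrees `d(t) = sum_t2 w(t, t2)` and total weight `m = sum(d) / 2`. Summed
#' over all ordered pairs (self-pairs included, with `w_mod(t, t) =
#' -d(t)^2 / (2 m)`), the corrected weights add to zero exactly.
#'
#' @param g A `module_graph` from [pairwise_weights()].
#' @return The graph with `w_mod`, `d` and `m` filled in.
#' @export
modularity_correct <- function(g) {
  stopifnot(inherits(g, "module_graph"))
  d <- rowSums(g$w)
  m <- sum(d) / 2
  if (m == 0) stop("degenerate graph: total weight m = 0", call. = FALSE)
  g$w_mod <- g$w - outer(d, d) / (2 * m)
  g$d <- d
  g$m <- m
  g
}

#' @export
print.module_graph <- function(x, ...) {
  cat("<module_graph> ", length(x$nodes), " nodes",
      if (!is.null(x$w_mod)) ", modularity-corrected", "\n", sep = "")
  invisible(x)
}

# Objective of a node subset: sum of pair weights over unordered pairs,
# self-pairs excluded (their stored value is the null-model term only).
module_score <- function(W, sel) {
  if (length(sel) < 2L) return(0)
  s <- sum(W[sel, sel])
  (s - sum(diag(W)[sel])) / 2
}

#' Find the best regulatory module of bounded size
#'
#' Maximises the sum of (by default modularity-corrected) pair weights over
#' all unordered pairs inside a selected node set of size at most `limit`.
#' Every pair inside the module counts, including negative ones, so the
#' optimum is a genuinely dense, internally consistent module. Solved
#' exactly by branch and bound with an admissible optimistic bound; ties are
#' broken towards the smaller, alphabetically earliest node set.
#'
#' @param g A `module_graph`; must be modularity-corrected when
#'   `corrected = TRUE` (the default).
#' @param limit Maximum module size (`>= 0`).
#' @param corrected Use `w_mod` (Newman-corrected) rather than raw `w`.
#' @param tie_eps Tie-break perturbation per node rank (default 1e-9).
#' @return List with `selected` (node ids), `edges` (tibble `t1`, `t2`,
#'   `weight` of all within-module pairs, the selected `y` variables) and
#'   `objective`.
#' @export
solve_module <- function(g, limit, corrected = TRUE, tie_eps = 1e-9) {
  stopifnot(inherits(g, "module_graph"))
  if (limit < 0) stop("limit must be >= 0", call. = FALSE)
  W <- if (corrected) {
    if (is.null(g$w_mod)) stop("call modularity_correct() first", call. = FALSE)
    g$w_mod
  } else {
    g$w
  }
  nodes <- g$nodes
  sel_idx <- max_weight_subset(W, limit, tie_eps = tie_eps,
                               rank_pen = tie_eps * rank(nodes, ties.method = "first"))
  selected <- sort(nodes[sel_idx$selected])
  edges <- if (length(sel_idx$selected) >= 2L) {
    pairs <- utils::combn(sort(sel_idx$selected), 2L)
    tibble::tibble(
      t1 = nodes[pairs[1L, ]], t2 = nodes[pairs[2L, ]],
      weight = W[cbind(pairs[1L, ], pairs[2L, ])]
    )
  } else {
    tibble::tibble(t1 = character(), t2 = character(), weight = numeric())
  }
  list(selected = selected, edges = edges, objective = sel_idx$objective)
}

# Exact maximisation of module_score(W, S) - sum(rank_pen[S]) over |S| <= limit.
# Depth-first branch and bound. The optimistic bound adds, for up to r more
# nodes, the largest per-node potentials u_j = (positive ties to chosen) +
# half the positive ties to other remaining nodes; each positive remaining
# pair is counted at most once across its two endpoints, so the bound is
# admissible.
max_weight_subset <- function(W, limit, tie_eps = 1e-9, rank_pen = NULL) {
  p <- nrow(W)
  if (is.null(rank_pen)) rank_pen <- rep(0, p)
  limit <- min(limit, p)
  best <- list(obj = 0, sel = integer())  # empty set scores 0
  Wpos <- pmax(W, 0); diag(Wpos) <- 0

  # branch order: nodes by decreasing positive strength
  ord <- order(rowSums(Wpos), decreasing = TRUE)

  recurse <- function(chosen, score, rem, r) {
    if (score - sum(rank_pen[chosen]) > best$obj + 1e-15) {
      best <<- list(obj = score - sum(rank_pen[chosen]), sel = chosen)
    }
    if (r == 0L || length(rem) == 0L) return(invisible())
    u <- vapply(rem, function(j) {
      sum(Wpos[j, chosen]) + sum(Wpos[j, rem]) / 2
    }, numeric(1))
    bound <- score + sum(utils::head(sort(u, decreasing = TRUE), r))
    if (bound <= best$obj + 1e-15) return(invisible())
    j <- rem[[1L]]
    rest <- rem[-1L]
    recurse(c(chosen, j), score + sum(W[j, chosen]), rest, r - 1L)
    recurse(chosen, score, rest, r)
  }
  recurse(integer(), 0, ord, limit)
  list(selected = sort(best$sel), objective = module_score(W, best$sel))
}

#' Export a module graph to GraphML or SIF
#'
#' Edges carry the raw weight `w` and, when available, the corrected
#' `w_mod` as attributes; edge width in downstream viewers can be mapped to
#' these weights.
#'
#' @param g A `module_graph`.
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @export
write_module_graph <- function(g, path, format = c("graphml", "sif")) {
  stopifnot(inherits(g, "module_graph"))
  format <- match.arg(format)
  n <- length(g$nodes)
  pairs <- which(upper.tri(g$w), arr.ind = TRUE)
  df <- data.frame(
    from = g$nodes[pairs[, 1L]], to = g$nodes[pairs[, 2L]],
    w = g$w[pairs]
  )
  if (!is.null(g$w_mod)) df$w_mod <- g$w_mod[pairs]
  df <- df[df$w != 0, , drop = FALSE]
  if (format == "sif") {
    writeLines(paste(df$from, "pair", df$to, sep = "\t"), path)
  } else {
    ig <- igraph::graph_from_data_frame(df, directed = FALSE,
                                        vertices = g$nodes)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
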