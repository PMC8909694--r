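#' Build a regulatory network from an edge table
#'
#' A regulatory network is a directed, weighted regulator-to-target edge list
#' distilled from promoter-binding resources (ChIP experiments, motif scans).
#' Each source resource contributes a non-negative weight per edge; evidence
#' for the same (regulator, target) pair from several sources is summed into
#' a single aggregated edge score `es`.
#'
#' @param edges Data frame with columns `regulator`, `target`, `source`,
#'   `weight` (non-negative).
#' @return A `reg_network` object: a list with `edges` (the source-level
#'   tibble) and `es` (tibble `regulator`, `target`, `es` of aggregated
#'   scores). Self-edges are retained but flagged with a warning.
#' @export
regulatory_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  need <- c("regulator", "target", "source", "weight")
  if (!all(need %in% names(edges))) {
    stop("edge table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  edges$weight <- as.numeric(edges$weight)
  if (any(is.na(edges$weight))) stop("non-numeric edge weight", call. = FALSE)
  if (any(edges$weight < 0)) stop("negative edge weight", call. = FALSE)
  if (any(edges$regulator == edges$target)) {
    warning("network contains self-edges (regulator == target)", call. = FALSE)
  }
  es <- edges |>
    dplyr::group_by(.data$regulator, .data$target) |>
    dplyr::summarise(es = sum(.data$weight), .groups = "drop")
  structure(list(edges = edges, es = es), class = "reg_network")
}

#' Read a regulatory network from a tab-separated file
#'
#' @param path TSV with header columns `regulator`, `target`, `source`,
#'   `weight`.
#' @return A `reg_network`; see [regulatory_network()].
#' @export
read_network <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(NA, NA, NA, "numeric"))
  names(tab) <- tolower(names(tab))
  regulatory_network(tab)
}

#' @export
print.reg_network <- function(x, ...) {
  cat("<reg_network> ", nrow(x$es), " regulator-target pairs (",
      length(unique(x$es$regulator)), " regulators, ",
      nrow(x$edges), " source-level edges)\n", sep = "")
  invisible(x)
}

#' Aggregated edge score of a regulator-target pair
#'
#' @param net A `reg_network`.
#' @param regulator,target Gene ids. Vectorised over pairs.
#' @return Numeric vector of aggregated scores; 0 for absent pairs.
#' @export
edge_score <- function(net, regulator, target) {
  stopifnot(inherits(net, "reg_network"))
  key <- paste(regulator, target, sep = "\r")
  lut <- stats::setNames(net$es$es, paste(net$es$regulator, net$es$target, sep = "\r"))
  out <- unname(lut[key])
  out[is.na(out)] <- 0
  out
}

#' Targets of a regulator with aggregated edge scores
#'
#' @param net A `reg_network`.
#' @param regulator Regulator id. Unknown regulators yield an empty result
#'   (with a message), not an error.
#' @param exclude Optional gene id removed from the result (e.g. the modelling
#'   target, which must not feed back into its regulators' activities).
#' @return Tibble with columns `target`, `es` (all `es > 0`).
#' @export
targets_of <- function(net, regulator, exclude = NULL) {
  stopifnot(inherits(net, "reg_network"))
  out <- net$es[net$es$regulator == regulator & net$es$es > 0, c("target", "es")]
  if (nrow(out) == 0L) {
    message("regulator '", regulator, "' has no targets in the network")
  }
  if (!is.null(exclude)) out <- out[!out$target %in% exclude, , drop = FALSE]
  out
}

#' Regulators with an edge onto a given gene
#'
#' @param net A `reg_network`.
#' @param gene Target gene id.
#' @return Tibble with columns `regulator`, `es`.
#' @export
regulators_of <- function(net, gene) {
  stopifnot(inherits(net, "reg_network"))
  out <- net$es[net$es$target == gene & net$es$es > 0, c("regulator", "es")]
  out[order(out$regulator), , drop = FALSE]
}

#' Export a network to SIF or GraphML
#'
#' SIF carries one `regulates` interaction per aggregated edge; GraphML (via
#' igraph) carries the aggregated score as edge attribute `es`.
#'
#' @param net A `reg_network`.
#' @param path Output file path.
#' @name network-export
NULL

#' @rdname network-export
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  writeLines(paste(net$es$regulator, "regulates", net$es$target, sep = "\t"),
             path)
  invisible(path)
}

#' @rdname network-export
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$es$regulator, to = net$es$target, es = net$es$es)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a source-level edge list to TSV
#'
#' @param net A `reg_network`.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  utils::write.table(as.data.frame(net$edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
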