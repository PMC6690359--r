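#' Build the candidate-induced interaction subnetwork
#'
#' Restricts the interaction network to the candidate genes: retained edges
#' are those connecting two candidates with confidence at least
#' \code{min_confidence}. Every candidate becomes a node even when it has no
#' retained edge — including candidates absent from the interaction
#' database altogether, mirroring recently described proteins for which
#' interaction databases carry no edges yet.
#'
#' @param network A \code{ppi_network}.
#' @param candidates A \code{candidate_set} (or plain character vector of
#'   gene symbols).
#' @param min_confidence Minimum edge confidence in [0, 1]; 0.7 is the
#'   conventional high-confidence STRING cutoff.
#' @return A \code{subnetwork}: list with \code{nodes}, \code{edges}
#'   (gene_a, gene_b, confidence), \code{core_genes}, \code{outer_genes}
#'   (empty here) and \code{min_confidence}.
#' @export
build_subnetwork <- function(network, candidates, min_confidence = 0.7) {
  stopifnot(inherits(network, "ppi_network"),
            min_confidence >= 0, min_confidence <= 1)
  core <- if (inherits(candidates, "candidate_set")) candidates$genes
          else as.character(candidates)
  core <- unique(core)
  e <- network$edges
  keep <- e$confidence >= min_confidence &
    e$gene_a %in% core & e$gene_b %in% core
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(core),
                 edges = edges,
                 core_genes = sort(core),
                 outer_genes = character(0),
                 min_confidence = min_confidence),
            class = "subnetwork")
}

#' One-layer outer-gene extension of a candidate subnetwork
#'
#' Adds "outer genes": non-candidate genes one interaction hop away from a
#' core gene through an edge of confidence at least the subnetwork's
#' \code{min_confidence}. Only core-outer edges are added; outer-outer
#' edges are excluded by default (the extension exists to add context around
#' core genes), but can be included with \code{include_outer_edges = TRUE}
#' for sensitivity checks.
#'
#' @param network The full \code{ppi_network} the subnetwork was built from.
#' @param sub A \code{subnetwork} from [build_subnetwork()].
#' @param include_outer_edges Also retain passing edges between two outer
#'   genes (default FALSE).
#' @return The extended \code{subnetwork}; \code{core_genes} unchanged,
#'   \code{outer_genes} populated.
#' @export
extend_outer <- function(network, sub, include_outer_edges = FALSE) {
  stopifnot(inherits(network, "ppi_network"), inherits(sub, "subnetwork"))
  core <- sub$core_genes
  e <- network$edges[network$edges$confidence >= sub$min_confidence, ,
                     drop = FALSE]
  a_core <- e$gene_a %in% core
  b_core <- e$gene_b %in% core
  cross <- xor(a_core, b_core)
  outer <- sort(unique(c(e$gene_b[cross & a_core], e$gene_a[cross & b_core])))
  edges <- rbind(sub$edges, e[cross, , drop = FALSE])
  if (include_outer_edges) {
    oo <- !a_core & !b_core & e$gene_a %in% outer & e$gene_b %in% outer
    edges <- rbind(edges, e[oo, , drop = FALSE])
  }
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(core, outer))),
                 edges = edges,
                 core_genes = core,
                 outer_genes = outer,
                 min_confidence = sub$min_confidence),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork: ", length(x$core_genes), " core + ",
      length(x$outer_genes), " outer genes, ", nrow(x$edges),
      " edges (confidence >= ", x$min_confidence, ")\n", sep = "")
  invisible(x)
}

#' Convert a subnetwork (or ppi_network) to an igraph graph
#'
#' Convenience bridge for layout and graph algorithms; edge confidences are
#' carried as the \code{weight} attribute.
#'
#' @param x A \code{subnetwork} or \code{ppi_network}.
#' @return An undirected \code{igraph} graph.
#' @export
as_igraph <- function(x) {
  nodes <- if (inherits(x, "subnetwork")) x$nodes else x$nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = x$edges$gene_a, to = x$edges$gene_b,
               weight = x$edges$confidence),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  g
}
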