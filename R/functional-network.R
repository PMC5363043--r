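# Undirected weighted gene graphs whose edge weights are interaction
# probabilities in [0, 1]. Stored as a canonical edge tibble (gene_a <
# gene_b), converted to igraph on demand.

#' Construct a tissue-specific functional network
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `weight`
#'   (probabilities in \[0, 1\]). Self-loops are forbidden; duplicate
#'   unordered pairs are rejected.
#' @param tissue tissue/context label.
#' @param nodes optional full node set (defaults to genes occurring in
#'   `edges`); lets isolated genes be carried along.
#' @return A `functional_network` object.
#' @export
functional_network <- function(edges, tissue = NA_character_, nodes = NULL) {
  edges <- as_tibble(edges)[, c("gene_a", "gene_b", "weight")]
  check_that(all(is.finite(edges$weight)) &&
               all(edges$weight >= 0 & edges$weight <= 1),
             "edge weights must lie in [0, 1]")
  check_that(!any(edges$gene_a == edges$gene_b), "self-loops are not allowed")
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  check_that(!anyDuplicated(paste(edges$gene_a, edges$gene_b)),
             "duplicate edges for the same gene pair")
  edges <- arrange(edges, .data$gene_a, .data$gene_b)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, nodes = sort(nodes), tissue = tissue),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %s: %d nodes, %d edges\n",
              x$tissue, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.functional_network <- function(x, ...) x$edges

#' @export
glance.functional_network <- function(x, ...) {
  tibble(tissue = x$tissue, n_nodes = length(x$nodes),
         n_edges = nrow(x$edges), mean_weight = mean(x$edges$weight))
}

#' Convert a functional network to an igraph graph
#'
#' @param x a `functional_network`.
#' @return A weighted undirected `igraph` graph including isolated nodes.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.functional_network <- function(x) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(x$edges), directed = FALSE,
    vertices = data.frame(name = x$nodes)
  )
  g
}

#' Read a functional network from an edge-list TSV
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `weight`.
#' @param tissue tissue label to attach.
#' @return A [functional_network()].
#' @export
read_functional_network <- function(path, tissue = NA_character_) {
  functional_network(read_edgelist_tsv(path), tissue = tissue)
}

#' Write a functional network as an edge-list TSV
#'
#' @param x a `functional_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_functional_network <- function(x, path) {
  write_edgelist_tsv(x$edges, path)
}
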