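# Differential network analysis between tissue networks against a global
# baseline: the differential adjacency is the focal network minus, edgewise,
# the maximum of the comparator and baseline weights, floored at zero —
# leaving only interactions that are strictly stronger in the focal tissue.
# Missing edges are read as weight 0. The single-comparator variant
# (baseline-only subtraction) is the same operation with comparator set to
# the baseline network.

#' Nodes common to two query results' largest components
#'
#' @param result_a,result_b `query_result` objects computed with identical
#'   query genes and prune threshold.
#' @return Character vector of shared component genes (errors when empty).
#' @export
common_nodes <- function(result_a, result_b) {
  check_that(identical(result_a$query_genes, result_b$query_genes) &&
               identical(result_a$prune_below, result_b$prune_below),
             "query results must share query genes and prune threshold")
  out <- intersect(result_a$component, result_b$component)
  check_that(length(out) > 0, "components share no nodes")
  sort(out)
}

# dense weight matrix of a functional network restricted to `nodes`,
# missing edges as 0
weight_matrix <- function(network, nodes) {
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ed <- network$edges
  ed <- ed[ed$gene_a %in% nodes & ed$gene_b %in% nodes, ]
  m[cbind(ed$gene_a, ed$gene_b)] <- ed$weight
  m[cbind(ed$gene_b, ed$gene_a)] <- ed$weight
  m
}

#' Differential adjacency between tissue networks
#'
#' Entrywise `max(focal - max(comparator, baseline), 0)` over the stated
#' node set; all three networks are restricted to those nodes with missing
#' edges read as 0.
#'
#' @param focal,comparator,baseline [functional_network()] objects.
#' @param nodes node set of the comparison (e.g. from [common_nodes()]).
#' @return A `differential_network`: positive-weight edge tibble, the node
#'   set, and provenance labels.
#' @export
differential_adjacency <- function(focal, comparator, baseline, nodes) {
  f <- weight_matrix(focal, nodes)
  cmp <- pmax(weight_matrix(comparator, nodes), weight_matrix(baseline, nodes))
  d <- pmax(f - cmp, 0)
  idx <- which(upper.tri(d) & d > 0, arr.ind = TRUE)
  edges <- tibble(gene_a = nodes[idx[, 1]], gene_b = nodes[idx[, 2]],
                  weight = d[idx]) %>%
    arrange(.data$gene_a, .data$gene_b)
  structure(
    list(edges = edges, nodes = nodes,
         provenance = c(focal = focal$tissue, comparator = comparator$tissue,
                        baseline = baseline$tissue)),
    class = "differential_network"
  )
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("<differential_network> %s vs (%s, %s): %d nodes, %d positive edges\n",
              x$provenance["focal"], x$provenance["comparator"],
              x$provenance["baseline"], length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.differential_network <- function(x, ...) x$edges

#' @export
glance.differential_network <- function(x, ...) {
  tibble(focal = unname(x$provenance["focal"]),
         comparator = unname(x$provenance["comparator"]),
         baseline = unname(x$provenance["baseline"]),
         n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         total_weight = sum(x$edges$weight))
}

#' @export
as_igraph.differential_network <- function(x) {
  igraph::graph_from_data_frame(as.data.frame(x$edges), directed = FALSE,
                                vertices = data.frame(name = x$nodes))
}

#' Spin-glass communities of a differential network
#'
#' Communities are found within the largest connected component of the
#' positive-edge differential graph, using the shared spin-glass engine.
#'
#' @param diff_network a `differential_network` with at least one positive
#'   edge (an all-zero network returns an empty result with a warning).
#' @param max_communities,restarts,seed as in [query_network()].
#' @return Tibble `gene_id`, `module` (labels `DM1`, `DM2`, ... by
#'   decreasing size) over the largest component.
#' @export
differential_communities <- function(diff_network, max_communities = 10,
                                     restarts = 5, seed = 1L) {
  if (nrow(diff_network$edges) == 0) {
    warn("differential network has no positive edges")
    return(tibble(gene_id = character(), module = character()))
  }
  g <- igraph::graph_from_data_frame(as.data.frame(diff_network$edges),
                                     directed = FALSE)
  comps <- igraph::components(g)
  best <- which.max(comps$csize)
  comp_nodes <- sort(igraph::V(g)$name[comps$membership == best])
  gc <- igraph::induced_subgraph(g, comp_nodes)
  memb <- spinglass_partition(gc, max_communities = max_communities,
                              restarts = restarts, seed = seed)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(sprintf("DM%d", seq_along(sizes)), names(sizes))
  tibble(gene_id = names(memb), module = unname(relabel[as.character(memb)])) %>%
    arrange(.data$gene_id)
}

#' Permutation test of within-community edge weight
#'
#' The observed total edge weight inside each community is compared with a
#' null obtained by permuting the node labels of the adjacency matrix
#' (simultaneous row/column permutation, preserving the weight multiset and
#' degree structure). A community is labeled `"more"` when its observed
#' weight exceeds the 97.5th null percentile, `"less"` below the 2.5th, else
#' `"none"`.
#'
#' @param network a `functional_network` or `differential_network`.
#' @param modules tibble `gene_id`, `module` partitioning the tested nodes.
#' @param n_permutations node-label permutations. Default 1000.
#' @param seed RNG seed.
#' @return Tibble `module`, `n_genes`, `observed_weight`, `null_lo`,
#'   `null_hi`, `label`.
#' @export
community_weight_permutation <- function(network, modules,
                                         n_permutations = 1000, seed = 1L) {
  nodes <- sort(modules$gene_id)
  check_that(!anyDuplicated(nodes), "modules must partition the nodes")
  w <- weight_matrix(network, nodes)
  lab <- setNames(modules$module, modules$gene_id)[nodes]
  mods <- sort(unique(lab))
  within_weight <- function(lab_vec) {
    vapply(mods, function(m) {
      idx <- which(lab_vec == m)
      sum(w[idx, idx]) / 2
    }, numeric(1))
  }
  observed <- within_weight(lab)
  null_w <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) within_weight(sample(lab)),
           numeric(length(mods)))
  })
  null_w <- matrix(null_w, nrow = length(mods))
  lo <- apply(null_w, 1, quantile, probs = 0.025)
  hi <- apply(null_w, 1, quantile, probs = 0.975)
  tibble(
    module = mods,
    n_genes = as.integer(table(lab)[mods]),
    observed_weight = unname(observed),
    null_lo = unname(lo), null_hi = unname(hi),
    label = unname(ifelse(observed > hi, "more",
                          ifelse(observed < lo, "less", "none")))
  )
}
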