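# Mutual-information consensus clustering: the module overlap network. Each
# cross-dataset module pair (C_i, C_j) over a shared universe of N genes gets
# the overlap score
#
#   W_ij = (|Ci n Cj| / N) * log2( N |Ci n Cj| / (|Ci| |Cj|) )
#
# which is positive/zero/negative when the modules overlap more/the same/less
# than expected at random, and whose sum over all module pairs equals the
# mutual information (in bits) of the two partitions. The N inside the
# logarithm is required for that sign semantics and the MI decomposition;
# log base 2 only rescales scores and changes no edge sign or ranking.

#' Information-theoretic module overlap score
#'
#' @param n_ij size of the intersection of the two modules (within the
#'   shared universe).
#' @param n_i,n_j module sizes within the shared universe (each >= 1).
#' @param N number of genes shared between the two datasets.
#' @return `(n_ij/N) * log2(N * n_ij / (n_i * n_j))`; 0 when `n_ij` is 0
#'   (the 0 * log 0 convention).
#' @export
#' @examples
#' overlap_score(10, 20, 20, 100) # 0.1 * log2(2.5)
overlap_score <- function(n_ij, n_i, n_j, N) {
  check_that(all(n_i >= 1) && all(n_j >= 1), "module sizes must be >= 1")
  check_that(all(n_ij >= 0) && all(n_ij <= pmin(n_i, n_j)) &&
               all(pmax(n_i, n_j) <= N),
             "need 0 <= n_ij <= min(n_i, n_j) <= N")
  out <- ifelse(n_ij == 0, 0, (n_ij / N) * log2(N * n_ij / (n_i * n_j)))
  unname(out)
}

#' Mutual information between two module partitions
#'
#' MI in bits of two gene-to-module labelings over a shared gene universe;
#' identically the sum of unthresholded [overlap_score()] values over all
#' label pairs.
#'
#' @param labels_a,labels_b named character vectors (names = gene IDs) or
#'   tibbles with `gene_id` and `module` columns.
#' @param shared_genes the gene universe over which to compute (defaults to
#'   the genes common to both labelings).
#' @return MI in bits (numeric scalar).
#' @export
partition_mutual_information <- function(labels_a, labels_b, shared_genes = NULL) {
  labels_a <- as_label_vector(labels_a)
  labels_b <- as_label_vector(labels_b)
  if (is.null(shared_genes)) {
    shared_genes <- intersect(names(labels_a), names(labels_b))
  }
  check_that(length(shared_genes) > 0 &&
               all(shared_genes %in% names(labels_a)) &&
               all(shared_genes %in% names(labels_b)),
             "empty or uncovered shared gene universe")
  a <- labels_a[shared_genes]
  b <- labels_b[shared_genes]
  tab <- table(a, b)
  N <- sum(tab)
  p <- tab / N
  pa <- rowSums(p); pb <- colSums(p)
  terms <- p * log2(p / outer(pa, pb))
  sum(terms[p > 0])
}

as_label_vector <- function(x) {
  if (is.data.frame(x)) {
    check_that(all(c("gene_id", "module") %in% names(x)),
               "partition tables need gene_id and module columns")
    return(setNames(as.character(x$module), x$gene_id))
  }
  if (inherits(x, "module_partition")) {
    return(setNames(x$assignments$module, x$assignments$gene_id))
  }
  check_that(!is.null(names(x)), "label vectors must be named by gene ID")
  setNames(as.character(x), names(x))
}

#' Build the multipartite module overlap network
#'
#' Nodes are (dataset, module) pairs; for every cross-dataset module pair the
#' overlap score is computed over that dataset pair's shared gene universe.
#' Genes labeled `"unassigned"` are excluded from modules but retained in the
#' shared universe N. Edges are retained when the score is positive and
#' (under the default policy) the one-sided hypergeometric overlap p-value
#' survives Bonferroni correction over all module pairs of that dataset pair.
#'
#' @param partitions list of `module_partition` objects (>= 2), or of
#'   tibbles with `gene_id`/`module` columns (then names of the list are the
#'   dataset IDs).
#' @param threshold_policy `"positive+hypergeometric"` (default) or
#'   `"positive_only"`.
#' @param alpha Bonferroni-corrected significance cutoff for the
#'   hypergeometric filter. Default 0.05.
#' @param include_unassigned_in_N keep unassigned genes in the shared
#'   universe count N (default TRUE).
#' @return An `overlap_network`: tibbles of `nodes` (`node`, `dataset_id`,
#'   `module`, `size`), `edges` (`node_a`, `node_b`, `weight`,
#'   `n_overlap`, `hyper_p`, `bonferroni_p`), and `pair_universes`
#'   (per dataset pair: shared N and the shared gene lists).
#' @export
build_overlap_network <- function(partitions,
                                  threshold_policy = c("positive+hypergeometric",
                                                       "positive_only"),
                                  alpha = 0.05,
                                  include_unassigned_in_N = TRUE) {
  threshold_policy <- match.arg(threshold_policy)
  check_that(length(partitions) >= 2, "need at least two partitions")
  labels <- lapply(partitions, as_label_vector)
  ids <- names(partitions)
  if (is.null(ids)) {
    ids <- vapply(partitions, function(p) {
      if (inherits(p, "module_partition")) p$dataset_id else NA_character_
    }, character(1))
  }
  check_that(!anyNA(ids) && !anyDuplicated(ids), "partitions need unique dataset ids")
  names(labels) <- ids

  node_rows <- lapply(ids, function(d) {
    lab <- labels[[d]]
    mods <- setdiff(unique(lab), "unassigned")
    tibble(node = paste(d, mods, sep = ":"), dataset_id = d, module = mods,
           size = as.integer(table(factor(lab, levels = mods))[mods]))
  })
  nodes <- bind_rows(node_rows)

  edge_rows <- list()
  pair_rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      da <- ids[i]; db <- ids[j]
      shared <- intersect(names(labels[[da]]), names(labels[[db]]))
      if (length(shared) == 0) {
        warn(sprintf("datasets %s and %s share no genes; pair skipped", da, db))
        next
      }
      la <- labels[[da]][shared]
      lb <- labels[[db]][shared]
      if (!include_unassigned_in_N) {
        keep <- la != "unassigned" & lb != "unassigned"
        la <- la[keep]; lb <- lb[keep]
      }
      N <- length(la)
      mods_a <- setdiff(unique(la), "unassigned")
      mods_b <- setdiff(unique(lb), "unassigned")
      if (!length(mods_a) || !length(mods_b)) next
      tab <- table(factor(la, levels = mods_a), factor(lb, levels = mods_b))
      na <- as.integer(table(factor(la, levels = mods_a)))
      nb <- as.integer(table(factor(lb, levels = mods_b)))
      grid <- expand.grid(ai = seq_along(mods_a), bi = seq_along(mods_b))
      n_ij <- tab[cbind(grid$ai, grid$bi)]
      n_i <- na[grid$ai]; n_j <- nb[grid$bi]
      w <- overlap_score(n_ij, n_i, n_j, N)
      hyper_p <- phyper(n_ij - 1, n_i, N - n_i, n_j, lower.tail = FALSE)
      bonf <- pmin(1, hyper_p * nrow(grid))
      keep <- w > 0
      if (threshold_policy == "positive+hypergeometric") keep <- keep & bonf <= alpha
      if (any(keep)) {
        edge_rows[[paste(da, db)]] <- tibble(
          node_a = paste(da, mods_a[grid$ai], sep = ":")[keep],
          node_b = paste(db, mods_b[grid$bi], sep = ":")[keep],
          weight = w[keep], n_overlap = as.integer(n_ij[keep]),
          hyper_p = hyper_p[keep], bonferroni_p = bonf[keep]
        )
      }
      pair_rows[[paste(da, db)]] <- tibble(
        dataset_a = da, dataset_b = db, N = N, shared_genes = list(shared)
      )
    }
  }
  edges <- bind_rows(edge_rows)
  if (nrow(edges) == 0) {
    warn("overlap network has no retained edges")
    edges <- tibble(node_a = character(), node_b = character(),
                    weight = numeric(), n_overlap = integer(),
                    hyper_p = numeric(), bonferroni_p = numeric())
  }
  structure(
    list(nodes = nodes, edges = edges, pair_universes = bind_rows(pair_rows),
         threshold_policy = threshold_policy, alpha = alpha,
         partitions = labels),
    class = "overlap_network"
  )
}

#' @export
print.overlap_network <- function(x, ...) {
  cat(sprintf("<overlap_network> %d modules from %d datasets, %d edges (%s)\n",
              nrow(x$nodes), length(unique(x$nodes$dataset_id)),
              nrow(x$edges), x$threshold_policy))
  invisible(x)
}

#' @export
tidy.overlap_network <- function(x, ...) x$edges

#' @export
glance.overlap_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_datasets = length(unique(x$nodes$dataset_id)),
         n_edges = nrow(x$edges),
         threshold_policy = x$threshold_policy)
}

#' @export
as_igraph.overlap_network <- function(x) {
  igraph::graph_from_data_frame(
    as.data.frame(x$edges[, c("node_a", "node_b", "weight")]),
    directed = FALSE, vertices = as.data.frame(x$nodes)
  )
}

#' Write an overlap network as adjacency-matrix and node-attribute TSVs
#'
#' The adjacency matrix holds the retained overlap scores (zero where no
#' edge was retained), rows and columns labeled by `dataset:module` node
#' names. The node table carries dataset of origin, module label and module
#' size, joined with any community labels and phenotype flags supplied.
#'
#' @param x an `overlap_network`.
#' @param adjacency_path,nodes_path output TSV paths.
#' @param assignment optional `community_assignment` whose labels are added
#'   to the node table.
#' @param node_attributes optional tibble with a `node` column (e.g.
#'   phenotype flags) joined into the node table.
#' @return The two paths, invisibly.
#' @export
write_overlap_network <- function(x, adjacency_path, nodes_path,
                                  assignment = NULL, node_attributes = NULL) {
  nodes <- x$nodes$node
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(x$edges$node_a, x$edges$node_b)] <- x$edges$weight
  adj[cbind(x$edges$node_b, x$edges$node_a)] <- x$edges$weight
  write.table(data.frame(node = nodes, adj, check.names = FALSE),
              adjacency_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- x$nodes
  if (!is.null(assignment)) {
    tab <- left_join(tab, assignment$assignment, by = "node")
  }
  if (!is.null(node_attributes)) {
    tab <- left_join(tab, as_tibble(node_attributes), by = "node")
  }
  write.table(as.data.frame(tab), nodes_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(adjacency = adjacency_path, nodes = nodes_path))
}

#' Permutation test for the mutual information of two partitions
#'
#' The null is built by permuting the gene labels of one partition over the
#' shared universe, which preserves both marginal module-size distributions.
#'
#' @param labels_a,labels_b partitions as in
#'   [partition_mutual_information()].
#' @param n_permutations number of permutations (>= 1).
#' @param seed RNG seed.
#' @param shared_genes optional explicit shared universe (>= 10 genes).
#' @return A list with `observed_mi`, `null_mis`, `p_raw` (fraction of null
#'   >= observed) and `p_add_one` (add-one-corrected p).
#' @export
mi_permutation_test <- function(labels_a, labels_b, n_permutations = 1000,
                                seed = 1L, shared_genes = NULL) {
  check_that(n_permutations >= 1, "n_permutations must be >= 1")
  labels_a <- as_label_vector(labels_a)
  labels_b <- as_label_vector(labels_b)
  if (is.null(shared_genes)) {
    shared_genes <- intersect(names(labels_a), names(labels_b))
  }
  check_that(length(shared_genes) >= 10, "shared universe must have >= 10 genes")
  a <- labels_a[shared_genes]
  b <- labels_b[shared_genes]
  observed <- partition_mutual_information(a, b, shared_genes)
  null_mis <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      bp <- setNames(sample(b), names(b))
      partition_mutual_information(a, bp, shared_genes)
    }, numeric(1))
  })
  list(observed_mi = observed, null_mis = null_mis,
       p_raw = mean(null_mis >= observed),
       p_add_one = (1 + sum(null_mis >= observed)) / (1 + n_permutations))
}
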