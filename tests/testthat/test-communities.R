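two_cliques_network <- function() {
  # two 4-cliques joined by a single edge, as an overlap-network stand-in
  nodes <- tibble::tibble(
    node = c(paste0("D1:M", 1:4), paste0("D2:M", 1:4)),
    dataset_id = rep(c("D1", "D2"), each = 4),
    module = rep(paste0("M", 1:4), 2), size = 10L)
  pairs <- function(v) t(combn(v, 2))
  e1 <- pairs(nodes$node[1:4]); e2 <- pairs(nodes$node[5:8])
  edges <- tibble::tibble(
    node_a = c(e1[, 1], e2[, 1], nodes$node[1]),
    node_b = c(e1[, 2], e2[, 2], nodes$node[5]),
    weight = 1, n_overlap = 5L, hyper_p = 0.001, bonferroni_p = 0.01)
  structure(list(nodes = nodes, edges = edges,
                 pair_universes = tibble::tibble(),
                 threshold_policy = "positive_only", alpha = 0.05,
                 partitions = NULL),
            class = "overlap_network")
}

test_that("greedy top-level detection finds the brute-force optimum on two cliques", {
  net <- two_cliques_network()
  top <- detect_top_level(net)
  asg <- top$assignment
  expect_length(unique(asg$top_label), 2)
  expect_length(unique(asg$top_label[1:4]), 1)
  expect_length(unique(asg$top_label[5:8]), 1)

  # brute force over all set partitions of the 8 nodes confirms the split
  g <- as_igraph(net)
  parts <- all_set_partitions(8)
  best_q <- -Inf; best_p <- NULL
  for (p in parts) {
    memb <- integer(8)
    for (k in seq_along(p)) memb[p[[k]]] <- k
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best_p <- memb }
  }
  expect_equal(adjusted_rand_index(best_p, asg$top_label), 1)
  expect_equal(top$modularity_top, best_q, tolerance = 1e-12)
  # and beats the all-singleton partition
  expect_gt(top$modularity_top,
            igraph::modularity(g, 1:8, weights = igraph::E(g)$weight))
})

test_that("a uniform complete graph is a single community", {
  nodes <- tibble::tibble(node = c(paste0("D1:M", 1:3), paste0("D2:M", 1:3)),
                          dataset_id = rep(c("D1", "D2"), each = 3),
                          module = rep(paste0("M", 1:3), 2), size = 5L)
  pr <- t(combn(nodes$node, 2))
  net <- structure(list(
    nodes = nodes,
    edges = tibble::tibble(node_a = pr[, 1], node_b = pr[, 2], weight = 1,
                           n_overlap = 3L, hyper_p = 0.01, bonferroni_p = 0.05),
    pair_universes = tibble::tibble(), threshold_policy = "positive_only",
    alpha = 0.05, partitions = NULL), class = "overlap_network")
  top <- detect_top_level(net)
  expect_length(unique(top$assignment$top_label), 1)
})

test_that("edgeless networks fall back to singleton communities with Q = 0", {
  net <- two_cliques_network()
  net$edges <- net$edges[0, ]
  expect_warning(top <- detect_top_level(net), "edgeless")
  expect_equal(top$modularity_top, 0)
  expect_equal(length(unique(top$assignment$top_label)), 8)
})

test_that("bottom-level spin-glass recovers planted sub-blocks and nests in top", {
  set.seed(2)
  # one top-level community made of two dense blocks, weakly joined
  nodes <- tibble::tibble(node = paste0("D", rep(1:2, 8), ":M", 1:16),
                          dataset_id = paste0("D", rep(1:2, 8)),
                          module = paste0("M", 1:16), size = 10L)
  blk1 <- nodes$node[1:8]; blk2 <- nodes$node[9:16]
  p1 <- t(combn(blk1, 2)); p2 <- t(combn(blk2, 2))
  cross <- cbind(blk1[1:2], blk2[1:2])
  edges <- tibble::tibble(
    node_a = c(p1[, 1], p2[, 1], cross[, 1]),
    node_b = c(p1[, 2], p2[, 2], cross[, 2]),
    weight = c(rep(1, nrow(p1) + nrow(p2)), rep(0.05, 2)),
    n_overlap = 5L, hyper_p = 0.001, bonferroni_p = 0.01)
  net <- structure(list(nodes = nodes, edges = edges,
                        pair_universes = tibble::tibble(),
                        threshold_policy = "positive_only", alpha = 0.05,
                        partitions = NULL), class = "overlap_network")
  top <- detect_top_level(net)
  for (s in 1:5) {
    asg <- detect_bottom_level(net, top, seed = s)$assignment
    truthlab <- rep(c("b1", "b2"), each = 8)
    expect_equal(adjusted_rand_index(asg$bottom_label, truthlab), 1)
    # hierarchy: bottom labels nest within top labels
    expect_true(all(tapply(asg$top_label, asg$bottom_label,
                           function(v) length(unique(v))) == 1))
    # letters by decreasing size: both blocks equal here, labels exist
    expect_true(all(grepl("^[0-9]+[A-Z]+$", asg$bottom_label)))
  }
  # determinism contract
  a1 <- detect_bottom_level(net, top, seed = 99)
  a2 <- detect_bottom_level(net, top, seed = 99)
  expect_identical(a1$assignment, a2$assignment)
})

test_that("a uniform clique stays one sub-community", {
  net <- two_cliques_network()
  top <- detect_top_level(net)
  asg <- detect_bottom_level(net, top, seed = 1)$assignment
  expect_equal(length(unique(asg$bottom_label[1:4])), 1)
})

test_that("modularity permutation test separates structure from noise", {
  # three 6-cliques weakly joined: random relabelings essentially never
  # reproduce the planted modularity
  blocks <- split(sprintf("D%d:M%d", rep(1:3, 6), 1:18), rep(1:3, each = 6))
  edges <- do.call(rbind, lapply(blocks, function(b) {
    p <- t(combn(b, 2))
    data.frame(node_a = p[, 1], node_b = p[, 2], weight = 1)
  }))
  cross <- data.frame(node_a = c(blocks[[1]][1], blocks[[2]][1]),
                      node_b = c(blocks[[2]][1], blocks[[3]][1]),
                      weight = 0.05)
  net <- structure(list(
    nodes = tibble::tibble(node = unlist(blocks),
                           dataset_id = sub(":.*", "", unlist(blocks)),
                           module = sub(".*:", "", unlist(blocks)), size = 5L),
    edges = tibble::as_tibble(cbind(rbind(edges, cross),
                                    n_overlap = 3L, hyper_p = 0.01,
                                    bonferroni_p = 0.05)),
    pair_universes = tibble::tibble(), threshold_policy = "positive_only",
    alpha = 0.05, partitions = NULL), class = "overlap_network")
  top <- detect_top_level(net)
  res <- modularity_permutation_test(net, top, n_permutations = 500, seed = 4)
  expect_equal(res$p_raw, 0)

  # single-community assignment: every permutation reproduces the observed Q
  one <- top
  one$assignment$top_label <- "1"
  res1 <- modularity_permutation_test(net, one, n_permutations = 100, seed = 4)
  expect_equal(res1$p_raw, 1)
  expect_true(all(res1$null_qs == res1$observed_q))
})

test_that("community phenotype enrichment matches the brute-force Fisher oracle", {
  # community of 10 nodes with 8 flagged; 90 outside with 10 flagged
  nodes <- sprintf("D1:M%03d", 1:100)
  asg <- structure(list(assignment = tibble::tibble(
    node = nodes, top_label = rep(c("1", "2"), c(10, 90)))),
    class = "community_assignment")
  attrs <- tibble::tibble(node = nodes,
                          pheno = c(rep(TRUE, 8), FALSE, FALSE,
                                    rep(TRUE, 10), rep(FALSE, 80)))
  res <- phenotype_enrichment(asg, attrs, min_nodes = 2)
  m <- matrix(c(8, 2, 10, 80), nrow = 2)
  expect_equal(res$raw_p[res$top_label == "1"], brute_fisher_two_sided(m),
               tolerance = 1e-12)
  expect_equal(res$raw_p[res$top_label == "1"],
               fisher.test(m)$p.value, tolerance = 1e-12)
  expect_equal(res$bonferroni_p, pmin(1, res$raw_p * 2))

  # a phenotype with no flagged modules reports p = 1
  attrs0 <- tibble::tibble(node = nodes, pheno = FALSE)
  res0 <- phenotype_enrichment(asg, attrs0)
  expect_true(all(res0$raw_p == 1))
})

test_that("edge gene sets are exact intersections over shared universes", {
  genes1 <- c("A", "B", "C", "D", "X1", "X2")
  genes2 <- c("C", "D", "E", "X1", "X3")
  p1 <- tibble::tibble(gene_id = genes1,
                       module = c("M1", "M1", "M1", "M1", "unassigned", "unassigned"))
  p2 <- tibble::tibble(gene_id = genes2,
                       module = c("M1", "M1", "M1", "unassigned", "unassigned"))
  net <- suppressWarnings(build_overlap_network(list(D1 = p1, D2 = p2),
                                                threshold_policy = "positive_only"))
  es <- edge_gene_sets(net)
  k <- which(es$node_a == "D1:M1" & es$node_b == "D2:M1")
  expect_equal(sort(es$genes[[k]]), c("C", "D"))

  # identical modules: the edge gene set is the module itself
  net2 <- build_overlap_network(list(D1 = p1, D2 = p1),
                                threshold_policy = "positive_only")
  es2 <- edge_gene_sets(net2)
  k2 <- which(es2$node_a == "D1:M1" & es2$node_b == "D2:M1")
  expect_equal(sort(es2$genes[[k2]]), c("A", "B", "C", "D"))
})

test_that("jaccard similarity obeys its bounds and arithmetic", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_similarity(letters[1:10], letters[6:20]), 5 / 20)
})

test_that("pathway annotation is invariant to pathway and edge order", {
  comp <- tiny_compendium(seed = 31)
  stack <- micc_stack(comp)
  es <- edge_gene_sets(stack$network)
  pw <- generate_genesets(comp$truth, decoys = 2, seed = 1)
  set.seed(44)
  ann1 <- suppressMessages(
    annotate_communities(es, stack$assignment, pw))
  ann2 <- suppressMessages(
    annotate_communities(es[sample(nrow(es)), ], stack$assignment, rev(pw)))
  ord <- function(x) x[order(x$community, x$pathway), ]
  expect_equal(ord(ann1), ord(ann2))
  expect_tibble_cols(ann1, c("community", "pathway", "within_median_j",
                             "outside_median_j", "raw_p", "bonferroni_p"))
})
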