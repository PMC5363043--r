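star_network <- function() {
  functional_network(data.frame(
    gene_a = rep("hub", 5),
    gene_b = paste0("leaf", 1:5),
    weight = c(0.9, 0.9, 0.9, 0.9, 0.4)), tissue = "t")
}

test_that("query pruning removes low-probability edges and stray leaves", {
  net <- star_network()
  res <- query_network(net, net$nodes, prune_below = 0.5, seed = 1)
  expect_false("leaf5" %in% res$component)
  expect_true(all(res$subnetwork$edges$weight >= 0.5))
  expect_setequal(res$component, c("hub", paste0("leaf", 1:4)))

  # prune at 0 with the full node set: subnetwork equals the network
  res0 <- query_network(net, net$nodes, prune_below = 0, seed = 1)
  expect_equal(res0$subnetwork$edges, net$edges)

  expect_error(query_network(net, c("nope1", "nope2")), "nope1")
})

test_that("pruning is monotone: higher thresholds never grow the component", {
  set.seed(6)
  net <- random_network(sprintf("g%02d", 1:20))
  prev <- Inf
  for (th in c(0, 0.3, 0.5, 0.7, 0.9)) {
    res <- query_network(net, net$nodes, prune_below = th, seed = 1)
    expect_lte(length(res$component), prev)
    prev <- length(res$component)
  }
})

test_that("component ties break toward the lexicographically smallest node", {
  net <- functional_network(data.frame(
    gene_a = c("b1", "a1"), gene_b = c("b2", "a2"), weight = 0.9))
  res <- query_network(net, net$nodes, prune_below = 0.5, seed = 1)
  expect_setequal(res$component, c("a1", "a2"))
})

test_that("planted functional modules are recovered from a tissue network", {
  tri <- suppressMessages(generate_network_triple(network_triple_spec(seed = 17)))
  tr <- tri$truth
  qgenes <- tr$gene_id[tr$kind %in% c("backbone", "tissue_a")]
  res <- query_network(tri$tissue_a, qgenes, seed = 2)
  m <- merge(res$modules, tr, by = "gene_id")
  expect_gte(adjusted_rand_index(m$module, m$community), 0.8)
})

test_that("hubs are the top within-module degree genes with documented ties", {
  # star module: the center is the unique hub
  net <- functional_network(data.frame(
    gene_a = rep("center", 6), gene_b = paste0("leaf", 1:6), weight = 0.9))
  res <- query_network(net, net$nodes, prune_below = 0.5, seed = 1)
  hubs <- find_hubs(res, top_fraction = 0.05)
  expect_equal(hubs$gene_id, "center")

  # uniform clique: ceil(fraction * n) lexicographically-first genes
  cl <- t(combn(sprintf("g%d", 1:6), 2))
  clique <- functional_network(data.frame(gene_a = cl[, 1], gene_b = cl[, 2],
                                          weight = 0.8))
  resc <- query_network(clique, clique$nodes, prune_below = 0.5, seed = 1)
  hubsc <- find_hubs(resc, top_fraction = 0.3)
  expect_equal(sort(hubsc$gene_id), c("g1", "g2"))
})

test_that("planted high-degree genes are always recovered as hubs", {
  for (s in 1:20) {
    set.seed(s)
    others <- sprintf("n%02d", 1:14)
    # planted hub connects to everyone; others connect sparsely
    pairs <- t(combn(others, 2))
    keep <- runif(nrow(pairs)) < 0.25
    edges <- rbind(
      data.frame(gene_a = "hub00", gene_b = others, weight = 0.95),
      data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                 weight = 0.6))
    net <- functional_network(edges)
    res <- query_network(net, net$nodes, prune_below = 0.5, seed = s)
    hubs <- find_hubs(res, top_fraction = 0.05)
    expect_true("hub00" %in% hubs$gene_id)
  }
})

test_that("participation coefficients and bridge calls follow the closed form", {
  # two triangles joined by one gene with equal weight to both sides
  t1 <- t(combn(c("a1", "a2", "a3"), 2))
  t2 <- t(combn(c("b1", "b2", "b3"), 2))
  edges <- rbind(
    data.frame(gene_a = t1[, 1], gene_b = t1[, 2], weight = 0.9),
    data.frame(gene_a = t2[, 1], gene_b = t2[, 2], weight = 0.9),
    data.frame(gene_a = "bridge", gene_b = c("a1", "a2", "a3", "b1", "b2", "b3"),
               weight = 0.9))
  net <- functional_network(edges)
  res <- query_network(net, net$nodes, prune_below = 0.5, seed = 3)
  # force the known module structure for the closed-form check
  res$modules$module <- ifelse(grepl("^a", res$modules$gene_id), "FM1",
                               ifelse(grepl("^b", res$modules$gene_id), "FM2",
                                      res$modules$module))
  res$modules$module[res$modules$gene_id == "bridge"] <- "FM1"
  br <- find_bridges(res, min_participation = 0.5)
  b <- br[br$gene_id == "bridge", ]
  expect_equal(b$participation, 0.5)  # equal weight to 2 modules
  expect_true(b$is_bridge)
  # genes with all edges in one module have P = 0
  expect_equal(br$participation[br$gene_id == "a2"], 0)
  expect_false(br$is_bridge[br$gene_id == "a2"])
  # bound: P <= 1 - 1/m for m modules
  m <- length(unique(res$modules$module))
  expect_true(all(br$participation <= 1 - 1 / m + 1e-12))
})

test_that("planted bridges between planted communities are always detected", {
  for (s in 1:20) {
    set.seed(s)
    c1 <- sprintf("a%02d", 1:8); c2 <- sprintf("b%02d", 1:8)
    p1 <- t(combn(c1, 2)); p2 <- t(combn(c2, 2))
    edges <- rbind(
      data.frame(gene_a = p1[, 1], gene_b = p1[, 2], weight = 0.9),
      data.frame(gene_a = p2[, 1], gene_b = p2[, 2], weight = 0.9),
      data.frame(gene_a = "bridge", gene_b = c(c1[1:4], c2[1:4]), weight = 0.9))
    net <- functional_network(edges)
    res <- query_network(net, net$nodes, prune_below = 0.5, seed = s)
    br <- find_bridges(res, min_participation = 0.5)
    expect_true(br$is_bridge[br$gene_id == "bridge"])
  }
})

test_that("module annotation matches the hypergeometric tail oracle", {
  universe <- sprintf("u%02d", 1:30)
  # component containing exactly one gene set
  setA <- universe[1:6]
  pr <- t(combn(setA, 2))
  net <- functional_network(data.frame(gene_a = pr[, 1], gene_b = pr[, 2],
                                       weight = 0.9))
  res <- query_network(net, setA, prune_below = 0.5, seed = 1)
  ann <- suppressMessages(
    annotate_modules(res, list(A = setA, B = universe[7:12]),
                     universe = universe))
  a <- ann[ann$gene_set == "A", ]
  expect_equal(a$p, brute_hyper_upper(6, 6, 30, 6), tolerance = 1e-12)
  # disjoint set is skipped only when absent from the universe
  ann2 <- suppressMessages(
    annotate_modules(res, list(A = setA, Z = c("zz1", "zz2")),
                     universe = universe))
  expect_false("Z" %in% ann2$gene_set)
  expect_true(all(ann$bh_q >= ann$p - 1e-15))
})
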