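test_that("tissue consensus follows the union-then-intersect set algebra", {
  p1 <- tibble::tibble(gene_id = c("A", "B", "C", "Z"),
                       module = c("M1", "M1", "M2", "unassigned"))
  p2 <- tibble::tibble(gene_id = c("B", "C", "D", "Z"),
                       module = c("M1", "M1", "M2", "unassigned"))
  tissue_map <- c(D1 = "lung", D2 = "lung")
  cons <- derive_tissue_consensus(list(D1 = p1, D2 = p2),
                                  c("D1:M1", "D1:M2", "D2:M1", "D2:M2"),
                                  tissue_map)
  # unions {A,B,C} and {B,C,D}; lung consensus is the intersection
  expect_equal(cons$tissue_sets$lung, c("B", "C"))
  expect_equal(cons$union_set, c("B", "C"))

  # identical datasets: consensus equals the shared union
  cons2 <- derive_tissue_consensus(list(D1 = p1, D2 = p1),
                                   c("D1:M1", "D2:M1"), tissue_map)
  expect_equal(cons2$tissue_sets$lung, c("A", "B"))

  # single-dataset tissue contributes its union directly
  cons3 <- derive_tissue_consensus(list(D1 = p1), "D1:M1", c(D1 = "skin"))
  expect_equal(cons3$tissue_sets$skin, c("A", "B"))

  # invariance to dataset order within a tissue
  cons4 <- derive_tissue_consensus(list(D2 = p2, D1 = p1),
                                   c("D2:M1", "D2:M2", "D1:M1", "D1:M2"),
                                   tissue_map)
  expect_equal(cons4$tissue_sets$lung, cons$tissue_sets$lung)

  # disjoint selected unions warn and give an empty set
  p3 <- tibble::tibble(gene_id = c("Q", "R"), module = c("M1", "M1"))
  expect_warning(
    cons5 <- derive_tissue_consensus(list(D1 = p1, D2 = p3),
                                     c("D1:M1", "D2:M1"), tissue_map),
    "share no selected genes")
  expect_length(cons5$tissue_sets$lung, 0)
})

test_that("random-fixture consensus matches an independent set-algebra oracle", {
  set.seed(21)
  for (k in 1:10) {
    genes <- sprintf("g%03d", 1:60)
    parts <- lapply(1:3, function(d) {
      tibble::tibble(gene_id = genes,
                     module = sample(c("M1", "M2", "M3", "unassigned"),
                                     60, replace = TRUE))
    })
    names(parts) <- paste0("D", 1:3)
    tissue_map <- c(D1 = "skin", D2 = "skin", D3 = "lung")
    sel <- c("D1:M1", "D2:M1", "D2:M2", "D3:M3")
    cons <- derive_tissue_consensus(parts, sel, tissue_map)
    u1 <- parts$D1$gene_id[parts$D1$module == "M1"]
    u2 <- parts$D2$gene_id[parts$D2$module %in% c("M1", "M2")]
    u3 <- parts$D3$gene_id[parts$D3$module == "M3"]
    expect_equal(cons$tissue_sets$skin, sort(intersect(u1, u2)))
    expect_equal(cons$tissue_sets$lung, sort(u3))
    expect_equal(cons$union_set, sort(union(intersect(u1, u2), u3)))
  }
})

test_that("community selection applies the alpha rule and its boundaries", {
  enr <- tibble::tibble(top_label = c("1", "2", "3"),
                        phenotype = "disease_status",
                        n_in_flagged = c(8L, 1L, 0L),
                        odds_ratio = c(30, 1, 0),
                        raw_p = c(1e-6, 0.8, 1),
                        bonferroni_p = c(3e-6, 1, 1))
  asg <- structure(list(assignment = tibble::tibble(
    node = sprintf("D1:M%d", 1:6),
    top_label = rep(c("1", "2", "3"), each = 2),
    bottom_label = c("1A", "1B", "2A", "2A", "3A", "3A"))),
    class = "community_assignment")
  attrs <- tibble::tibble(node = sprintf("D1:M%d", 1:6),
                          disease_status = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                          disease_status_up = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  sel <- select_disease_communities(enr, asg, attrs)
  expect_equal(sel$top, "1")
  # only bottom children containing phenotype-increased modules survive
  expect_equal(sel$bottom, "1A")
  expect_equal(sel$nodes, "D1:M1")

  expect_warning(sel0 <- select_disease_communities(enr, asg, attrs, alpha = 0),
                 "no disease-enriched")
  expect_length(sel0$nodes, 0)

  # manual override bypasses the rule
  selo <- select_disease_communities(enr, asg, attrs, override = c("3A"))
  expect_equal(selo$bottom, "3A")
  expect_equal(selo$nodes, c("D1:M5", "D1:M6"))
})

test_that("consensus genes sit closer to their module eigengenes", {
  # needs the 4-dataset reference scale so the enrichment-based community
  # selection has power
  comp <- generate_compendium(compendium_spec(seed = 41))
  stack <- micc_stack(comp, min_module_size = 20)
  flags <- node_phenotype_flags(stack$associations)
  enr <- phenotype_enrichment(stack$assignment, flags)
  sel <- select_disease_communities(enr, stack$assignment, flags)
  tissue_map <- vapply(comp$datasets, function(d) d$tissue, character(1))
  cons <- derive_tissue_consensus(stack$partitions, sel$nodes, tissue_map)
  res <- consensus_centrality_test(stack$partitions, comp$datasets, cons,
                                   sel$nodes)
  expect_gt(nrow(res), 0)
  expect_true(all(res$median_cor_consensus > res$median_cor_other))

  # all-consensus split is degenerate and skipped
  all_cons <- cons
  all_cons$union_set <- unique(comp$truth$assignments$gene_id)
  expect_message(
    res2 <- consensus_centrality_test(stack$partitions, comp$datasets,
                                      all_cons, sel$nodes),
    "degenerate")
  expect_equal(nrow(res2), 0)
})

test_that("DE enrichment of consensus genes behaves at the extremes", {
  genes <- sprintf("g%03d", 1:200)
  de <- structure(list(
    table = tibble::tibble(gene_id = genes,
                           d_statistic = c(rep(3, 40), rep(0, 160)),
                           q_value = c(rep(0.001, 40), rep(0.9, 160))),
    contrast = c("disease", "control"), n_permutations = 100,
    exhaustive = FALSE), class = "de_result")
  # consensus equal to the DE-up set: minimal achievable one-sided p
  cons <- structure(list(union_set = genes[1:40]), class = "consensus_geneset")
  res <- consensus_de_enrichment(cons, de)
  m <- matrix(c(40, 0, 0, 160), 2)
  expect_equal(res$p, fisher.test(m, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(res$p, brute_hyper_upper(40, 40, 200, 40), tolerance = 1e-12)

  cons_bad <- structure(list(union_set = c("x1", "x2")),
                        class = "consensus_geneset")
  expect_error(consensus_de_enrichment(cons_bad, de), "no genes")
})
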