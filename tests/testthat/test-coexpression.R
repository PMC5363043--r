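test_that("signed adjacency has the right closed form", {
  cm <- matrix(c(1, -1, 0, -1, 1, 0.5, 0, 0.5, 1), 3, 3)
  a <- miccnet:::signed_adjacency(cm, 12)
  expect_equal(a[1, 1], 1)
  expect_equal(a[1, 2], 0)
  expect_equal(a[1, 3], 0.5^12)
  expect_equal(a[2, 3], 0.75^12)
})

test_that("zero-noise planted partitions are recovered exactly", {
  comp <- generate_compendium(compendium_spec(
    n_datasets = 1, genes_master = 200, gene_overlap_fraction = 1,
    samples_per_dataset = 20, modules_per_dataset = 4,
    module_size_range = c(20, 25), n_shared_processes = 0,
    noise_sd = 0, seed = 6))
  # background genes stay noisy; planted blocks are exactly rank one
  part <- detect_modules(comp$datasets[[1]], min_module_size = 15)
  tr <- comp$truth$assignments
  planted <- tr$gene_id[tr$module != "unassigned"]
  m <- merge(tr[tr$gene_id %in% planted, ], part$assignments, by = "gene_id")
  expect_equal(adjusted_rand_index(m$module.x, m$module.y), 1)
})

test_that("anti-correlated gene blocks land in different signed modules", {
  set.seed(4)
  n <- 30
  latent <- rnorm(n)
  up <- t(replicate(20, latent * runif(1, 0.6, 1))) +
    matrix(rnorm(20 * n, sd = 0.05), 20)
  down <- t(replicate(20, -latent * runif(1, 0.6, 1))) +
    matrix(rnorm(20 * n, sd = 0.05), 20)
  mat <- rbind(up, down)
  dimnames(mat) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:n))
  part <- detect_modules(mat, min_module_size = 10)
  asg <- part$assignments
  mod_up <- unique(asg$module[asg$gene_id %in% sprintf("g%02d", 1:20)])
  mod_down <- unique(asg$module[asg$gene_id %in% sprintf("g%02d", 21:40)])
  expect_length(mod_up, 1)
  expect_length(mod_down, 1)
  expect_false(mod_up == mod_down)
})

test_that("detect_modules enforces its sample and size preconditions", {
  small <- matrix(rnorm(7 * 50), nrow = 50,
                  dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:7)))
  expect_error(detect_modules(small), "at least 8")
  few_genes <- matrix(rnorm(10 * 30), nrow = 30,
                      dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:10)))
  expect_error(detect_modules(few_genes, min_module_size = 20), "min_module_size")
})

test_that("eigengenes are unit-norm first PCs oriented to the mean profile", {
  set.seed(2)
  n <- 12
  base <- rnorm(n)
  mat <- t(replicate(6, base)) + matrix(rnorm(6 * n, sd = 1e-8), 6)
  dimnames(mat) <- list(sprintf("g%d", 1:6), sprintf("s%d", 1:n))
  eig <- module_eigengene(mat, rownames(mat))
  expect_equal(sum(eig^2), 1, tolerance = 1e-9)
  zrow <- (base - mean(base)) / sd(base)
  expect_equal(unname(eig), zrow / sqrt(sum(zrow^2)), tolerance = 1e-4)

  # flipping all module rows flips the eigengene
  eig_flipped <- module_eigengene(-mat, rownames(mat))
  expect_equal(unname(eig_flipped), -unname(eig), tolerance = 1e-6)

  # first-PC optimality: variance explained >= any single member projection
  set.seed(3)
  noisy <- t(replicate(8, rnorm(n))) + matrix(rnorm(8 * n), 8)
  dimnames(noisy) <- list(sprintf("g%d", 1:8), sprintf("s%d", 1:n))
  e <- module_eigengene(noisy, rownames(noisy))
  std <- t(scale(t(noisy)))
  proj_eig <- sum((std %*% e)^2)
  for (g in seq_len(nrow(std))) {
    row_dir <- std[g, ] / sqrt(sum(std[g, ]^2))
    expect_gte(proj_eig + 1e-9, sum((std %*% row_dir)^2))
  }

  expect_error(module_eigengene(mat * 0, rownames(mat), "M9"), "M9")
})

test_that("planted eigengenes are recovered at moderate noise", {
  comp <- generate_compendium(compendium_spec(
    n_datasets = 1, genes_master = 150, samples_per_dataset = 25,
    modules_per_dataset = 3, module_size_range = c(20, 25),
    n_shared_processes = 1, shared_process_sizes = 20,
    noise_sd = 0.3, seed = 12))
  d <- comp$datasets[[1]]
  tr <- comp$truth$assignments
  for (m in setdiff(unique(tr$module), "unassigned")) {
    genes <- intersect(tr$gene_id[tr$module == m], rownames(d$matrix))
    eig <- module_eigengene(d$matrix, genes)
    # the planted latent is proxied by the module mean profile
    latent <- colMeans(d$matrix[genes, ])
    expect_gte(abs(cor(eig, latent)), 0.95)
  }
})

test_that("phenotype association matches exact references and Bonferroni rule", {
  part <- structure(list(
    dataset_id = "D",
    assignments = tibble::tibble(gene_id = sprintf("g%d", 1:4),
                                 module = c("M1", "M1", "M2", "M2")),
    module_genes = list(M1 = c("g1", "g2"), M2 = c("g3", "g4")),
    eigengenes = matrix(c(1, 2, 3, 10, 11, 12,
                          5, 5, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
                        dimnames = list(c("M1", "M2"), sprintf("s%d", 1:6))),
    sample_ids = sprintf("s%d", 1:6)), class = "module_partition")
  pheno <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                          grp = rep(c("a", "b"), each = 3))
  res <- associate_phenotypes(part, pheno)
  m1 <- res[res$module == "M1", ]
  # exact two-sided Mann-Whitney for {1,2,3} vs {10,11,12}: 2/20
  expect_equal(m1$raw_p, 0.1)
  expect_equal(m1$direction, 1)
  expect_equal(m1$bonferroni_p, min(1, m1$raw_p * 2))
  # an eigengene identical in both groups is a complete tie: p = 1
  m2 <- res[res$module == "M2", ]
  expect_equal(m2$raw_p, 1)

  single <- tibble::tibble(sample_id = sprintf("s%d", 1:6), grp = "a")
  expect_warning(res2 <- associate_phenotypes(part, single), "single level")
  expect_equal(nrow(res2), 0)
})

test_that("planted disease modules reach Bonferroni significance with power", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    comp <- generate_compendium(compendium_spec(
      n_datasets = 1, genes_master = 150, samples_per_dataset = 40,
      modules_per_dataset = 3, module_size_range = c(20, 25),
      n_shared_processes = 1, shared_process_sizes = 20,
      effect_size = 2, seed = 3000 + s))
    d <- comp$datasets[[1]]
    part <- detect_modules(d, min_module_size = 15)
    res <- associate_phenotypes(part, d$phenotypes,
                                phenotype_cols = "disease_status")
    proc_genes <- comp$truth$processes[[1]]
    ov <- vapply(part$module_genes, function(g) length(intersect(g, proc_genes)),
                 numeric(1))
    planted_mod <- names(which.max(ov))
    p <- res$bonferroni_p[res$module == planted_mod]
    if (length(p) == 1 && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("the permutation d statistic matches its formula and degenerate cases", {
  set.seed(9)
  mat <- matrix(rnorm(20 * 12), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  mat["g01", ] <- rep(c(2, 2, 2, 2, 2, 2), 2)  # zero variance, equal means
  groups <- rep(c("x", "y"), each = 6)
  de <- suppressMessages(sam_like_de(mat, contrast = c("x", "y"),
                                     groups = groups, n_permutations = 50,
                                     seed = 2))
  tab <- tidy(de)
  expect_equal(tab$d_statistic[tab$gene_id == "g01"], 0)
  expect_true(all(tab$q_value >= 0 & tab$q_value <= 1))
  # q monotone non-increasing in |d|
  ord <- order(abs(tab$d_statistic))
  expect_true(all(diff(tab$q_value[ord]) <= 1e-12))

  # d matches a hand-computed pooled-SE formula
  g <- "g05"
  x1 <- mat[g, 1:6]; x2 <- mat[g, 7:12]
  s_g <- sqrt((1 / 6 + 1 / 6) *
                (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 10)
  all_s <- apply(mat, 1, function(v) {
    a <- v[1:6]; b <- v[7:12]
    sqrt((1 / 6 + 1 / 6) * (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 10)
  })
  d_manual <- (mean(x1) - mean(x2)) / (s_g + median(all_s))
  expect_equal(tab$d_statistic[tab$gene_id == g], unname(d_manual))
})

test_that("small designs fall back to exhaustive label enumeration", {
  set.seed(5)
  mat <- matrix(rnorm(10 * 6), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  expect_message(
    de <- sam_like_de(mat, contrast = c("x", "y"),
                      groups = rep(c("x", "y"), each = 3),
                      n_permutations = 1000, seed = 1),
    "enumerating")
  expect_equal(de$n_permutations, choose(6, 3))
  expect_true(de$exhaustive)
})

test_that("planted shifts are detected with high recall at q < 0.05", {
  set.seed(31)
  n1 <- 20; n2 <- 20
  mat <- matrix(rnorm(300 * (n1 + n2)), nrow = 300,
                dimnames = list(sprintf("g%03d", 1:300),
                                sprintf("s%02d", seq_len(n1 + n2))))
  shifted <- sprintf("g%03d", 1:30)
  mat[shifted, seq_len(n1)] <- mat[shifted, seq_len(n1)] + 3
  de <- sam_like_de(mat, contrast = c("case", "ctrl"),
                    groups = rep(c("case", "ctrl"), c(n1, n2)),
                    n_permutations = 200, seed = 7)
  tab <- tidy(de)
  recall <- mean(tab$q_value[tab$gene_id %in% shifted] < 0.05)
  expect_gte(recall, 0.9)
})
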