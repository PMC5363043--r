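# Signed weighted co-expression module detection. Pipeline: signed adjacency
# a_ij = ((1 + cor_ij)/2)^power -> topological overlap dissimilarity ->
# average-linkage hierarchical clustering -> fixed-height cut (0.99 quantile
# of merge heights) -> minimum module size -> merge modules whose eigengenes
# correlate above 1 - merge_height. The module eigengene is the first
# principal component of the standardized module submatrix.

new_module_partition <- function(dataset_id, assignments, module_genes,
                                 eigengenes, sample_ids) {
  structure(
    list(dataset_id = dataset_id, assignments = assignments,
         module_genes = module_genes, eigengenes = eigengenes,
         sample_ids = sample_ids),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  n_un <- sum(x$assignments$module == "unassigned")
  cat(sprintf("<module_partition> %s: %d genes in %d modules (%d unassigned)\n",
              x$dataset_id, nrow(x$assignments), length(x$module_genes), n_un))
  invisible(x)
}

#' @export
tidy.module_partition <- function(x, ...) x$assignments

#' @export
glance.module_partition <- function(x, ...) {
  sizes <- lengths(x$module_genes)
  tibble(dataset_id = x$dataset_id, n_genes = nrow(x$assignments),
         n_modules = length(x$module_genes),
         n_unassigned = sum(x$assignments$module == "unassigned"),
         median_module_size = if (length(sizes)) median(sizes) else NA_real_)
}

# signed adjacency from a gene-gene correlation matrix
signed_adjacency <- function(cor_mat, power = 12) {
  ((1 + cor_mat) / 2)^power
}

# topological overlap dissimilarity of a signed adjacency (diagonal ignored)
tom_dissimilarity <- function(adj) {
  diag(adj) <- 0
  k <- rowSums(adj)
  L <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (L + adj) / denom
  diag(tom) <- 1
  1 - tom
}

#' First-principal-component eigengene of a gene module
#'
#' Gene rows are standardized, the first right singular vector of the
#' submatrix is taken, and its sign is oriented so that it correlates
#' positively with the module's mean standardized expression profile.
#'
#' @param mat numeric genes x samples matrix (or an `expression_dataset`).
#' @param genes gene IDs of the module (at least 2 with positive variance).
#' @param module optional module name used in error messages.
#' @return Unit-norm numeric vector, one value per sample.
#' @export
module_eigengene <- function(mat, genes, module = "module") {
  if (inherits(mat, "expression_dataset")) mat <- mat$matrix
  check_that(all(genes %in% rownames(mat)),
             sprintf("%s: genes missing from matrix", module))
  sub <- mat[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd, na.rm = TRUE)
  ok <- is.finite(sds) & sds > 0
  if (sum(ok) < 2) abort(sprintf("degenerate module '%s': fewer than 2 genes with variance", module))
  sub <- (sub[ok, , drop = FALSE] - rowMeans(sub[ok, , drop = FALSE], na.rm = TRUE)) / sds[ok]
  sub[is.na(sub)] <- 0
  v1 <- svd(sub, nu = 0, nv = 1)$v[, 1]
  mp <- colMeans(sub)
  if (sum(v1 * mp) < 0) v1 <- -v1   # orient toward the mean profile
  setNames(v1, colnames(mat))
}

#' Detect signed co-expression modules in one dataset
#'
#' @param dataset an [expression_dataset()] (or plain genes x samples
#'   matrix). Needs at least 8 samples (correlations are unstable below
#'   that) and at least `2 * min_module_size` genes.
#' @param power soft-threshold exponent of the signed adjacency. Default 12.
#' @param min_module_size smallest surviving module. Default 20.
#' @param merge_height modules whose eigengenes correlate above
#'   `1 - merge_height` are merged. Default 0.15.
#' @param cut_height fixed dendrogram cut height. The default (`NULL`)
#'   places the cut at the midpoint of a large gap between consecutive merge
#'   heights, which separates the tight within-module merges from the loose
#'   background and between-module merges; among the three largest gaps the
#'   cut producing the most modules of at least `min_module_size` is used.
#' @return A `module_partition`: per-gene assignments (modules labeled
#'   `"M1"`, `"M2"`, ... by decreasing size, plus `"unassigned"`),
#'   per-module gene lists, and unit-norm eigengenes (modules x samples).
#' @export
detect_modules <- function(dataset, power = 12, min_module_size = 20,
                           merge_height = 0.15, cut_height = NULL) {
  if (inherits(dataset, "expression_dataset")) {
    mat <- dataset$matrix
    dataset_id <- dataset$dataset_id
  } else {
    mat <- dataset
    dataset_id <- "dataset"
  }
  if (ncol(mat) < 8) {
    abort(sprintf("%s: %d samples; at least 8 required for stable correlations",
                  dataset_id, ncol(mat)))
  }
  check_that(nrow(mat) >= 2 * min_module_size,
             sprintf("%s: need at least 2 * min_module_size genes", dataset_id))

  sds <- apply(mat, 1, sd, na.rm = TRUE)
  keep <- is.finite(sds) & sds > 0
  if (!all(keep)) {
    warn(sprintf("%s: dropping %d zero-variance gene(s) before clustering",
                 dataset_id, sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }
  genes <- rownames(mat)

  cmat <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  cmat[is.na(cmat)] <- 0
  adj <- signed_adjacency(cmat, power)
  diss <- tom_dissimilarity(adj)
  tree <- hclust(as.dist(diss), method = "average")
  cut_h <- if (is.null(cut_height)) {
    choose_cut_height(tree, min_module_size)
  } else cut_height
  raw <- cutree(tree, h = cut_h)

  sizes <- table(raw)
  keep_cl <- names(sizes)[sizes >= min_module_size]
  module_genes <- lapply(keep_cl, function(cl) genes[raw == cl])

  if (length(module_genes) > 1) {
    module_genes <- merge_by_eigengene(mat, module_genes, merge_height)
  }
  module_genes <- module_genes[order(-lengths(module_genes))]
  names(module_genes) <- sprintf("M%d", seq_along(module_genes))

  assignments <- tibble(gene_id = genes, module = "unassigned")
  for (m in names(module_genes)) {
    assignments$module[assignments$gene_id %in% module_genes[[m]]] <- m
  }
  eigs <- t(vapply(names(module_genes),
                   function(m) module_eigengene(mat, module_genes[[m]], m),
                   numeric(ncol(mat))))
  colnames(eigs) <- colnames(mat)
  new_module_partition(dataset_id, assignments, module_genes, eigs, colnames(mat))
}

# Fixed-height cut placed in a large gap of the merge-height distribution:
# within-module merges are tight and background/between-module merges are
# loose, so the gap between the regimes is the natural cut. Among the three
# largest gaps, the candidate cut yielding the most clusters of at least
# min_module_size wins (ties to the larger gap); this guards against a
# stray outlier merge capturing the single largest gap.
choose_cut_height <- function(tree, min_module_size) {
  h <- sort(tree$height)
  n <- length(h)
  if (n < 2) return(max(h) / 2)
  gaps <- diff(h)
  cand <- order(gaps, decreasing = TRUE)[seq_len(min(3, length(gaps)))]
  cand <- cand[gaps[cand] > 0]
  if (!length(cand)) return(mean(range(h)))
  best_cut <- NA_real_
  best_score <- -1
  for (k in cand) {
    cut_h <- (h[k] + h[k + 1L]) / 2
    sizes <- table(cutree(tree, h = cut_h))
    score <- sum(sizes >= min_module_size)
    if (score > best_score) {
      best_score <- score
      best_cut <- cut_h
    }
  }
  best_cut
}

# iteratively merge the most-correlated eigengene pair above 1 - merge_height
merge_by_eigengene <- function(mat, module_genes, merge_height) {
  repeat {
    if (length(module_genes) < 2) break
    eigs <- vapply(module_genes, function(g) module_eigengene(mat, g),
                   numeric(ncol(mat)))
    cc <- cor(eigs)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] <= 1 - merge_height) break
    i <- min(best); j <- max(best)
    module_genes[[i]] <- c(module_genes[[i]], module_genes[[j]])
    module_genes[[j]] <- NULL
  }
  module_genes
}

#' Test module eigengenes for phenotype association
#'
#' Two-class categorical phenotypes are tested by a two-sided Mann-Whitney U
#' test on the eigengene; continuous phenotypes by a Spearman correlation
#' test. P values are Bonferroni-corrected across modules within each
#' phenotype. Direction is the sign of the location shift (second factor
#' level minus first) or of the correlation.
#'
#' @param partition a `module_partition`.
#' @param phenotypes per-sample table with a `sample_id` column; every other
#'   column except `dataset_id`/`tissue` is treated as a phenotype.
#'   Categorical phenotypes need exactly 2 levels with at least 3 samples
#'   each; continuous ones at least 5 observations.
#' @param phenotype_cols optional explicit phenotype column names.
#' @return A tibble with columns `module`, `phenotype`, `type`, `statistic`,
#'   `raw_p`, `bonferroni_p`, `direction`.
#' @export
associate_phenotypes <- function(partition, phenotypes, phenotype_cols = NULL) {
  phenotypes <- as_tibble(phenotypes)
  check_that("sample_id" %in% names(phenotypes), "phenotypes need sample_id")
  check_that(all(partition$sample_ids %in% phenotypes$sample_id),
             "phenotype table does not cover the partition's samples")
  phenotypes <- phenotypes[match(partition$sample_ids, phenotypes$sample_id), ]
  if (is.null(phenotype_cols)) {
    phenotype_cols <- setdiff(names(phenotypes),
                              c("sample_id", "dataset_id", "tissue"))
  }
  eigs <- partition$eigengenes
  rows <- list()
  for (ph in phenotype_cols) {
    v <- phenotypes[[ph]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      lev <- sort(unique(as.character(v[!is.na(v)])))
      if (length(lev) < 2) {
        warn(sprintf("phenotype '%s' has a single level; skipped", ph))
        next
      }
      check_that(length(lev) == 2,
                 sprintf("phenotype '%s' must be two-class", ph))
      check_that(min(table(v)) >= 3,
                 sprintf("phenotype '%s' needs >= 3 samples per level", ph))
      res <- lapply(rownames(eigs), function(m) {
        e <- eigs[m, ]
        mw <- mw_test(e[v == lev[1]], e[v == lev[2]])
        tibble(module = m, phenotype = ph, type = "categorical",
               statistic = mw$statistic, raw_p = mw$p, direction = mw$direction)
      })
    } else {
      ok <- !is.na(v)
      check_that(sum(ok) >= 5,
                 sprintf("phenotype '%s' needs >= 5 observations", ph))
      res <- lapply(rownames(eigs), function(m) {
        ct <- suppressWarnings(
          cor.test(eigs[m, ok], v[ok], method = "spearman"))
        tibble(module = m, phenotype = ph, type = "continuous",
               statistic = unname(ct$estimate), raw_p = ct$p.value,
               direction = sign(unname(ct$estimate)))
      })
    }
    tab <- bind_rows(res)
    tab$bonferroni_p <- pmin(1, tab$raw_p * nrow(tab))
    rows[[ph]] <- tab
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(module = character(), phenotype = character(),
                  type = character(), statistic = numeric(),
                  raw_p = numeric(), bonferroni_p = numeric(),
                  direction = numeric())
  }
  out
}

#' Permutation-based moderated differential expression (SAM-style d statistic)
#'
#' For each gene, `d = (mean(group1) - mean(group2)) / (s + s0)` with pooled
#' standard error `s` and fudge factor `s0 = median(s)`. The null
#' distribution of `d` comes from label permutations; the per-gene q-value is
#' the median permutation count of |d| values exceeding the gene's |d|,
#' divided by the observed count, capped at 1 and made monotone in |d|.
#'
#' @param dataset an [expression_dataset()] or genes x samples matrix.
#' @param contrast character of length 2: the two group labels, in the order
#'   `(group1, group2)`; `d > 0` means higher in `group1`.
#' @param group_col phenotype column holding the group labels (used when
#'   `dataset` is an `expression_dataset`). Default `"disease_status"`.
#' @param groups explicit per-sample label vector (used for matrix input).
#' @param n_permutations label permutations for the null; if it exceeds the
#'   number of distinct arrangements, all arrangements are enumerated.
#' @param seed RNG seed for the permutations.
#' @return A `de_result`: tibble of `gene_id`, `d_statistic`, `q_value`, plus
#'   the contrast and permutation count as attributes; `tidy()` returns the
#'   table.
#' @export
sam_like_de <- function(dataset, contrast, group_col = "disease_status",
                        groups = NULL, n_permutations = 1000, seed = 1L) {
  if (inherits(dataset, "expression_dataset")) {
    mat <- dataset$matrix
    if (is.null(groups)) groups <- dataset$phenotypes[[group_col]]
  } else {
    mat <- dataset
  }
  check_that(!is.null(groups) && length(groups) == ncol(mat),
             "need one group label per sample")
  check_that(length(contrast) == 2 && all(contrast %in% groups),
             "contrast labels absent from groups")
  use <- groups %in% contrast
  mat <- mat[, use, drop = FALSE]
  groups <- groups[use]
  g1 <- groups == contrast[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  check_that(n1 >= 3 && n2 >= 3, "both groups need at least 3 samples")

  d_stat <- function(idx1) {
    x1 <- mat[, idx1, drop = FALSE]
    x2 <- mat[, !idx1, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
    list(s = s, num = m1 - m2)
  }
  obs <- d_stat(g1)
  s0 <- median(obs$s)
  d <- obs$num / (obs$s + s0)

  n <- n1 + n2
  n_arr <- choose(n, n1)
  exhaustive <- n_permutations >= n_arr
  perms <- with_seed(seed, {
    if (exhaustive) {
      inform(sprintf("enumerating all %d label arrangements", n_arr))
      cols <- utils::combn(n, n1)
      lapply(seq_len(ncol(cols)), function(j) {
        idx <- rep(FALSE, n); idx[cols[, j]] <- TRUE; idx
      })
    } else {
      lapply(seq_len(n_permutations), function(j) {
        idx <- rep(FALSE, n); idx[sample(n, n1)] <- TRUE; idx
      })
    }
  })
  abs_d <- abs(d)
  count_ge <- function(values_sorted, thresholds) {
    # number of values >= each threshold (findInterval with left.open
    # counts values strictly below the threshold)
    length(values_sorted) - findInterval(thresholds, values_sorted,
                                         left.open = TRUE)
  }
  null_counts <- vapply(perms, function(idx) {
    p <- d_stat(idx)
    count_ge(sort(abs(p$num / (p$s + s0))), abs_d)
  }, numeric(length(d)))
  med_fp <- apply(null_counts, 1, median)
  observed <- count_ge(sort(abs_d), abs_d)
  q <- pmin(1, med_fp / observed)
  ord <- order(abs_d)                 # ascending |d|
  q[ord] <- rev(cummax(rev(q[ord])))  # monotone non-increasing in |d|

  out <- tibble(gene_id = rownames(mat), d_statistic = unname(d),
                q_value = unname(q))
  structure(list(table = out, contrast = contrast,
                 n_permutations = length(perms), exhaustive = exhaustive),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s vs %s: %d genes, %d permutations, %d at q < 0.05\n",
              x$contrast[1], x$contrast[2], nrow(x$table), x$n_permutations,
              sum(x$table$q_value < 0.05)))
  invisible(x)
}

#' @export
tidy.de_result <- function(x, ...) x$table

#' @export
glance.de_result <- function(x, ...) {
  tibble(group1 = x$contrast[1], group2 = x$contrast[2],
         n_genes = nrow(x$table), n_permutations = x$n_permutations,
         n_significant = sum(x$table$q_value < 0.05))
}
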