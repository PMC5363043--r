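# Single-sample gene-set summaries: the average z-score of a set's measured
# genes per array summarizes the set's expression in that sample; group
# differences per set are assessed with two-sided Mann-Whitney tests.

#' Average z-score of gene sets per sample
#'
#' For every (sample, gene set) pair, the mean z-score over the set's
#' measured genes. Sets covering less than `min_coverage` of their genes in
#' the matrix are flagged and not scored; sets with zero measured genes are
#' excluded.
#'
#' @param z_matrix genes x samples z-score matrix (see [zscore_genes()]).
#' @param collection named list of gene-ID vectors (e.g. [read_gmt()]).
#' @param min_coverage minimum fraction of set genes measured. Default 0.5.
#' @return A `sample_score_table`: `scores` tibble (`sample_id`, `gene_set`,
#'   `score`) and `coverage` tibble (`gene_set`, `n_set`, `n_measured`,
#'   `coverage`, `scored`).
#' @export
score_genesets <- function(z_matrix, collection, min_coverage = 0.5) {
  check_that(is.matrix(z_matrix) && !is.null(rownames(z_matrix)),
             "z_matrix must be a matrix with gene rownames")
  check_that(length(collection) > 0 && !is.null(names(collection)),
             "collection must be a named list")
  cov_rows <- list()
  score_rows <- list()
  for (gs in names(collection)) {
    set <- unique(collection[[gs]])
    measured <- intersect(set, rownames(z_matrix))
    coverage <- length(measured) / length(set)
    scored <- length(measured) > 0 && coverage >= min_coverage
    cov_rows[[gs]] <- tibble(gene_set = gs, n_set = length(set),
                             n_measured = length(measured),
                             coverage = coverage, scored = scored)
    if (!scored) {
      inform(sprintf("gene set %s: coverage %.2f below %.2f; not scored",
                     gs, coverage, min_coverage))
      next
    }
    sc <- colMeans(z_matrix[measured, , drop = FALSE], na.rm = TRUE)
    score_rows[[gs]] <- tibble(sample_id = colnames(z_matrix), gene_set = gs,
                               score = unname(sc))
  }
  structure(
    list(scores = bind_rows(score_rows), coverage = bind_rows(cov_rows)),
    class = "sample_score_table"
  )
}

#' @export
print.sample_score_table <- function(x, ...) {
  cat(sprintf("<sample_score_table> %d gene sets scored over %d samples\n",
              length(unique(x$scores$gene_set)),
              length(unique(x$scores$sample_id))))
  invisible(x)
}

#' @export
tidy.sample_score_table <- function(x, ...) x$scores

#' @export
glance.sample_score_table <- function(x, ...) x$coverage

#' Compare gene-set scores between two sample groups
#'
#' Two-sided Mann-Whitney test per gene set (exact when both groups have at
#' most 10 tie-free observations). Raw p-values are reported by default; set
#' `adjust = "BH"` for Benjamini-Hochberg adjustment across sets.
#'
#' @param scores a `sample_score_table` (or its `scores` tibble).
#' @param grouping named vector (names = sample IDs) of group labels, or a
#'   data frame with `sample_id` and a grouping column.
#' @param contrast the two group labels compared, `(group1, group2)`;
#'   direction is positive when group2 scores higher. Defaults to the two
#'   observed labels sorted.
#' @param group_col grouping column name for data-frame input. Default
#'   `"disease_status"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble `gene_set`, `n1`, `n2`, `statistic`, `p`, `direction`
#'   (plus `adj_p` when adjusted).
#' @export
compare_groups <- function(scores, grouping, contrast = NULL,
                           group_col = "disease_status",
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(scores, "sample_score_table")) scores <- scores$scores
  if (is.data.frame(grouping)) {
    grouping <- setNames(grouping[[group_col]], grouping$sample_id)
  }
  scores <- scores[scores$sample_id %in% names(grouping), ]
  g <- grouping[scores$sample_id]
  if (is.null(contrast)) contrast <- sort(unique(g))
  check_that(length(contrast) == 2, "grouping must have exactly two levels")
  rows <- lapply(sort(unique(scores$gene_set)), function(gs) {
    sel <- scores$gene_set == gs
    x <- scores$score[sel & g == contrast[1]]
    y <- scores$score[sel & g == contrast[2]]
    check_that(length(x) >= 3 && length(y) >= 3,
               sprintf("gene set %s: both groups need >= 3 samples", gs))
    mw <- mw_test(x, y)
    tibble(gene_set = gs, n1 = length(x), n2 = length(y),
           statistic = mw$statistic, p = mw$p, direction = mw$direction)
  })
  out <- bind_rows(rows)
  if (adjust == "BH") out$adj_p <- p.adjust(out$p, method = "BH")
  out
}
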