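# Tissue consensus gene sets. Within each selected (disease-enriched)
# community, take the union of selected-module genes per dataset, then
# intersect those unions across the datasets of a tissue; the cross-tissue
# union of the tissue consensus sets is the disease-axis consensus used to
# query functional networks. Tissues with a single dataset contribute their
# union directly.

#' Select disease-enriched communities from an enrichment table
#'
#' Top-level communities whose Bonferroni-corrected Fisher p-value is at or
#' below `alpha` for at least one phenotype are selected; their bottom-level
#' children are restricted to those containing at least one
#' phenotype-increased module. A manual override replicates analyst-driven
#' choices.
#'
#' @param enrichment tibble from [phenotype_enrichment()].
#' @param assignment a `community_assignment` with bottom labels.
#' @param node_attributes tibble from [node_phenotype_flags()] (needs the
#'   `<phenotype>_up` columns).
#' @param alpha Bonferroni significance cutoff. Default 0.05.
#' @param override optional character vector of bottom-level labels to use
#'   verbatim instead of the alpha rule.
#' @return List with `top`, `bottom` (labels) and `nodes` (module nodes in
#'   the selected bottom communities). Empty selection warns.
#' @export
select_disease_communities <- function(enrichment, assignment, node_attributes,
                                       alpha = 0.05, override = NULL) {
  asg <- assignment$assignment
  check_that("bottom_label" %in% names(asg),
             "assignment needs bottom-level labels")
  if (!is.null(override)) {
    bottom <- intersect(override, asg$bottom_label)
    top <- unique(asg$top_label[asg$bottom_label %in% bottom])
  } else {
    hits <- enrichment %>%
      filter(.data$bonferroni_p <= alpha) %>%
      pull(.data$top_label) %>%
      unique()
    up_cols <- grep("_up$", names(node_attributes), value = TRUE)
    up_nodes <- node_attributes$node[
      rowSums(as.matrix(node_attributes[, up_cols, drop = FALSE])) > 0]
    cand <- asg[asg$top_label %in% hits, ]
    bottom <- sort(unique(cand$bottom_label[cand$node %in% up_nodes]))
    top <- sort(unique(hits))
  }
  nodes <- asg$node[asg$bottom_label %in% bottom]
  if (!length(nodes)) warn("no disease-enriched communities selected")
  list(top = top, bottom = bottom, nodes = nodes)
}

#' Derive tissue consensus gene sets from selected communities
#'
#' Per dataset, the union of the genes of its modules inside the selected
#' communities; per tissue, the intersection of those unions across the
#' tissue's datasets (a single-dataset tissue contributes its union); the
#' cross-tissue union is the axis consensus set.
#'
#' @param partitions named list (by dataset ID) of `module_partition` objects
#'   or gene/module tibbles.
#' @param selected_nodes character vector of selected module nodes
#'   (`"dataset:module"`), e.g. `select_disease_communities()$nodes`.
#' @param tissue_map named character vector mapping dataset ID to tissue.
#' @return A `consensus_geneset`: `tissue_sets` (named list of gene vectors),
#'   `union_set`, `dataset_unions`, `source_nodes`.
#' @export
derive_tissue_consensus <- function(partitions, selected_nodes, tissue_map) {
  labels <- lapply(partitions, as_label_vector)
  sel <- tibble(node = selected_nodes,
                dataset_id = sub(":.*$", "", selected_nodes),
                module = sub("^[^:]*:", "", selected_nodes))
  check_that(all(sel$dataset_id %in% names(labels)),
             "selected nodes reference unknown datasets")
  datasets_used <- unique(sel$dataset_id)
  check_that(all(datasets_used %in% names(tissue_map)),
             "tissue_map must cover every dataset with selected modules")

  dataset_unions <- lapply(datasets_used, function(d) {
    lab <- labels[[d]]
    mods <- sel$module[sel$dataset_id == d]
    sort(unique(names(lab)[lab %in% mods]))
  })
  names(dataset_unions) <- datasets_used

  tissues <- unique(unname(tissue_map[datasets_used]))
  tissue_sets <- lapply(tissues, function(tt) {
    ds <- datasets_used[tissue_map[datasets_used] == tt]
    cc <- Reduce(intersect, dataset_unions[ds])
    if (!length(cc)) warn(sprintf("tissue %s: datasets share no selected genes", tt))
    sort(cc)
  })
  names(tissue_sets) <- tissues
  structure(
    list(tissue_sets = tissue_sets,
         union_set = sort(unique(unlist(tissue_sets, use.names = FALSE))),
         dataset_unions = dataset_unions,
         source_nodes = selected_nodes),
    class = "consensus_geneset"
  )
}

#' @export
print.consensus_geneset <- function(x, ...) {
  cat(sprintf("<consensus_geneset> %d tissues, union of %d genes\n",
              length(x$tissue_sets), length(x$union_set)))
  for (tt in names(x$tissue_sets)) {
    cat(sprintf("  %s: %d genes\n", tt, length(x$tissue_sets[[tt]])))
  }
  invisible(x)
}

#' @export
tidy.consensus_geneset <- function(x, ...) {
  bind_rows(lapply(names(x$tissue_sets), function(tt) {
    tibble(gene_id = x$tissue_sets[[tt]], tissue = tt)
  })) %>%
    group_by(.data$gene_id) %>%
    summarise(tissues = paste(sort(.data$tissue), collapse = ";"),
              .groups = "drop") %>%
    mutate(in_union = .data$gene_id %in% x$union_set)
}

#' @export
glance.consensus_geneset <- function(x, ...) {
  tibble(tissue = c(names(x$tissue_sets), "union"),
         n_genes = c(lengths(x$tissue_sets), length(x$union_set)))
}

#' Eigengene-centrality validation of consensus genes
#'
#' Within the selected modules of each dataset, each gene's Pearson
#' correlation with its module eigengene is computed; consensus genes'
#' correlations are compared with non-consensus genes' by a two-sided
#' Mann-Whitney test. Consensus genes sitting closer to the module cores
#' yield higher correlations.
#'
#' @param partitions named list of `module_partition` objects (need
#'   eigengenes).
#' @param datasets named list of [expression_dataset()] objects.
#' @param consensus a `consensus_geneset`.
#' @param selected_nodes the selected module nodes (same as used to derive
#'   the consensus).
#' @return Tibble `dataset_id`, `n_consensus`, `n_other`,
#'   `median_cor_consensus`, `median_cor_other`, `statistic`, `p`. Datasets
#'   with a degenerate split are skipped with a message.
#' @export
consensus_centrality_test <- function(partitions, datasets, consensus,
                                      selected_nodes) {
  sel <- tibble(dataset_id = sub(":.*$", "", selected_nodes),
                module = sub("^[^:]*:", "", selected_nodes))
  rows <- list()
  for (d in unique(sel$dataset_id)) {
    part <- partitions[[d]]
    mat <- datasets[[d]]$matrix
    mods <- sel$module[sel$dataset_id == d]
    cors <- list()
    for (m in mods) {
      genes <- part$module_genes[[m]]
      if (is.null(genes) || length(genes) < 2) next
      eig <- part$eigengenes[m, ]
      cors[[m]] <- tibble(
        gene_id = genes,
        cor = suppressWarnings(as.vector(cor(t(mat[genes, , drop = FALSE]),
                                             eig, use = "pairwise.complete.obs")))
      )
    }
    tab <- bind_rows(cors)
    if (nrow(tab) == 0) next
    tab$consensus <- tab$gene_id %in% consensus$union_set
    if (sum(tab$consensus) < 2 || sum(!tab$consensus) < 2) {
      inform(sprintf("dataset %s: degenerate consensus split; skipped", d))
      next
    }
    mw <- mw_test(tab$cor[!tab$consensus], tab$cor[tab$consensus])
    rows[[d]] <- tibble(
      dataset_id = d,
      n_consensus = sum(tab$consensus), n_other = sum(!tab$consensus),
      median_cor_consensus = median(tab$cor[tab$consensus], na.rm = TRUE),
      median_cor_other = median(tab$cor[!tab$consensus], na.rm = TRUE),
      statistic = mw$statistic, p = mw$p
    )
  }
  bind_rows(rows)
}

#' Enrichment of consensus genes among upregulated DE genes
#'
#' One-sided Fisher exact test on the 2x2 table of consensus membership
#' against differential upregulation (q below `fdr` and d statistic positive
#' toward the first contrast group).
#'
#' @param consensus a `consensus_geneset`.
#' @param de a `de_result` from [sam_like_de()].
#' @param universe gene universe for the table (default: the DE result's
#'   genes). Must intersect the consensus universe.
#' @param fdr q-value cutoff defining DE genes. Default 0.05.
#' @return List with the 2x2 `table`, `odds_ratio` and one-sided `p`.
#' @export
consensus_de_enrichment <- function(consensus, de, universe = NULL, fdr = 0.05) {
  tab <- de$table
  if (is.null(universe)) universe <- tab$gene_id
  universe <- intersect(universe, tab$gene_id)
  check_that(length(intersect(universe, consensus$union_set)) > 0 ||
               length(universe) > 0, "empty universe")
  if (!length(intersect(universe, consensus$union_set))) {
    abort("consensus set shares no genes with the DE universe")
  }
  tab <- tab[tab$gene_id %in% universe, ]
  in_cons <- tab$gene_id %in% consensus$union_set
  de_up <- tab$q_value < fdr & tab$d_statistic > 0
  m <- matrix(c(sum(in_cons & de_up), sum(in_cons & !de_up),
                sum(!in_cons & de_up), sum(!in_cons & !de_up)), nrow = 2,
              dimnames = list(consensus = c("yes", "no"),
                              de_up = c("yes", "no")))
  ft <- fisher.test(t(m), alternative = "greater")
  list(table = m, odds_ratio = unname(ft$estimate), p = ft$p.value)
}
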