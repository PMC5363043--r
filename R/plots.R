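# ggplot2 visualizations for the main result types.

#' Heatmap of the module overlap network adjacency
#'
#' Modules are ordered by dataset (and by community when an assignment is
#' supplied), mirroring the sorted-adjacency view of the overlap graph.
#'
#' @param object an `overlap_network`.
#' @param assignment optional `community_assignment` used to sort nodes by
#'   top- then bottom-level community.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_network <- function(object, assignment = NULL, ...) {
  nodes <- object$nodes$node
  if (!is.null(assignment)) {
    asg <- assignment$assignment
    ord <- order(asg$top_label,
                 asg$bottom_label %||% asg$top_label, asg$node)
    nodes <- asg$node[ord]
  }
  ed <- object$edges
  both <- bind_rows(ed, rename(ed, node_a = "node_b", node_b = "node_a"))
  both$node_a <- factor(both$node_a, levels = nodes)
  both$node_b <- factor(both$node_b, levels = nodes)
  ggplot2::ggplot(both, ggplot2::aes(.data$node_a, .data$node_b,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "overlap\nscore") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Module overlap network adjacency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Eigengene-by-phenotype association overview
#'
#' @param object a tibble from [associate_phenotypes()].
#' @param alpha Bonferroni significance threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_associations <- function(object, alpha = 0.05) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$module, -log10(.data$bonferroni_p),
                               fill = factor(sign(.data$direction)))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(~phenotype) +
    ggplot2::scale_fill_manual(values = c(`-1` = "steelblue", `0` = "grey70",
                                          `1` = "firebrick"),
                               name = "direction") +
    ggplot2::labs(x = "module", y = expression(-log[10]~"Bonferroni p")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Gene-set score distributions by group
#'
#' @param object a `sample_score_table`.
#' @param grouping named vector or data frame as in [compare_groups()].
#' @param group_col grouping column for data-frame input.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sample_score_table <- function(object, grouping,
                                        group_col = "disease_status", ...) {
  if (is.data.frame(grouping)) {
    grouping <- setNames(grouping[[group_col]], grouping$sample_id)
  }
  df <- mutate(object$scores, group = unname(grouping[.data$sample_id]))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_set, .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "mean z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Differential-network edge weight map
#'
#' @param object a `differential_network`.
#' @param modules optional tibble `gene_id`, `module` used to order nodes.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.differential_network <- function(object, modules = NULL, ...) {
  nodes <- object$nodes
  if (!is.null(modules)) {
    nodes <- c(modules$gene_id[order(modules$module)],
               setdiff(nodes, modules$gene_id))
  }
  ed <- object$edges
  both <- bind_rows(ed, rename(ed, gene_a = "gene_b", gene_b = "gene_a"))
  both$gene_a <- factor(both$gene_a, levels = nodes)
  both$gene_b <- factor(both$gene_b, levels = nodes)
  ggplot2::ggplot(both, ggplot2::aes(.data$gene_a, .data$gene_b,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "differential\nweight") +
    ggplot2::labs(x = NULL, y = NULL, title = sprintf(
      "%s-specific interactions", object$provenance["focal"])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
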