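# Querying tissue-specific functional networks with a gene set: induced
# subgraph, probability pruning, largest connected component, spin-glass
# functional modules, hub/bridge identification and hypergeometric gene-set
# annotation.

#' Query a functional network with a gene set
#'
#' Takes the induced subgraph on the query genes, drops edges whose
#' interaction probability is below `prune_below`, keeps the largest
#' connected component (ties broken toward the component containing the
#' lexicographically smallest node ID), and partitions it into functional
#' modules with the spin-glass engine.
#'
#' @param network a [functional_network()].
#' @param query_genes character vector; at least 2 must be present in the
#'   network (otherwise an error lists the missing genes).
#' @param prune_below edges with weight strictly below this are removed.
#'   Default 0.5.
#' @param max_communities spin cap for the module search. Default 10.
#' @param restarts spin-glass restarts. Default 5.
#' @param seed RNG seed.
#' @return A `query_result`: the pruned `subnetwork`
#'   ([functional_network()] on the query genes), `component` (genes of the
#'   largest component), and `modules` (tibble `gene_id`, `module`,
#'   weighted `degree` within the component).
#' @export
query_network <- function(network, query_genes, prune_below = 0.5,
                          max_communities = 10, restarts = 5, seed = 1L) {
  present <- intersect(query_genes, network$nodes)
  if (length(present) < 2) {
    abort(paste0("fewer than 2 query genes present in network; missing: ",
                 paste(head(setdiff(query_genes, network$nodes), 10),
                       collapse = ", ")))
  }
  ed <- network$edges
  ed <- ed[ed$gene_a %in% present & ed$gene_b %in% present &
             ed$weight >= prune_below, , drop = FALSE]
  sub <- functional_network(ed, tissue = network$tissue, nodes = present)
  g <- as_igraph(sub)
  comps <- igraph::components(g)
  sizes <- comps$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie: pick the component holding the smallest node ID
    firsts <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comps$membership == ci])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  comp_nodes <- sort(igraph::V(g)$name[comps$membership == best])
  gc <- igraph::induced_subgraph(g, comp_nodes)
  memb <- spinglass_partition(gc, max_communities = max_communities,
                              restarts = restarts, seed = seed)
  # module labels FM1, FM2, ... by decreasing size
  sizes_m <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(sprintf("FM%d", seq_along(sizes_m)), names(sizes_m))
  strength <- igraph::strength(gc, weights = igraph::E(gc)$weight)
  modules <- tibble(gene_id = names(memb),
                    module = unname(relabel[as.character(memb)]),
                    degree = unname(strength[names(memb)])) %>%
    arrange(.data$gene_id)
  structure(
    list(subnetwork = sub, component = comp_nodes, modules = modules,
         prune_below = prune_below, tissue = network$tissue,
         query_genes = sort(unique(query_genes))),
    class = "query_result"
  )
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %s: %d query genes present, component of %d, %d functional modules\n",
              x$tissue, length(x$subnetwork$nodes), length(x$component),
              length(unique(x$modules$module))))
  invisible(x)
}

#' @export
tidy.query_result <- function(x, ...) x$modules

#' @export
glance.query_result <- function(x, ...) {
  tibble(tissue = x$tissue, n_query = length(x$query_genes),
         n_present = length(x$subnetwork$nodes),
         n_component = length(x$component),
         n_modules = length(unique(x$modules$module)),
         prune_below = x$prune_below)
}

# weighted degree of each component gene toward each functional module
module_degrees <- function(result) {
  ed <- result$subnetwork$edges
  comp <- result$component
  ed <- ed[ed$gene_a %in% comp & ed$gene_b %in% comp, ]
  mod <- setNames(result$modules$module, result$modules$gene_id)
  half <- bind_rows(
    tibble(gene = ed$gene_a, other = ed$gene_b, w = ed$weight),
    tibble(gene = ed$gene_b, other = ed$gene_a, w = ed$weight)
  )
  half$to_module <- mod[half$other]
  half %>%
    group_by(.data$gene, .data$to_module) %>%
    summarise(k = sum(.data$w), .groups = "drop")
}

#' Identify per-module hub genes
#'
#' Hubs are the genes with the highest weighted within-module degree: the top
#' `ceil(top_fraction * module size)` of each module (at least one), with
#' ties broken lexicographically by gene ID. Modules below `min_size` genes
#' are skipped.
#'
#' @param result a `query_result`.
#' @param top_fraction fraction of the module taken as hubs. Default 0.05.
#' @param min_size smallest module considered. Default 5.
#' @return Tibble `module`, `gene_id`, `within_degree`.
#' @export
find_hubs <- function(result, top_fraction = 0.05, min_size = 5) {
  deg <- module_degrees(result)
  mod <- result$modules
  within <- deg %>%
    left_join(select(mod, gene_id = "gene_id", module = "module"),
              by = c(gene = "gene_id")) %>%
    filter(.data$to_module == .data$module)
  rows <- list()
  for (m in sort(unique(mod$module))) {
    members <- mod$gene_id[mod$module == m]
    if (length(members) < min_size) next
    wd <- setNames(rep(0, length(members)), members)
    sub <- within[within$module == m, ]
    wd[sub$gene] <- sub$k
    n_hub <- max(1, ceiling(top_fraction * length(members)))
    ord <- order(-wd, names(wd))
    hubs <- names(wd)[ord][seq_len(n_hub)]
    rows[[m]] <- tibble(module = m, gene_id = hubs,
                        within_degree = unname(wd[hubs]))
  }
  bind_rows(rows)
}

#' Identify bridge genes between functional modules
#'
#' A gene's participation coefficient is `P = 1 - sum_s (k_s / k)^2` over its
#' weighted degree `k_s` toward each module `s` (`k` total); P is 0 when all
#' edges stay in one module and approaches `1 - 1/m` when spread over `m`
#' modules. Bridges are genes with `P >= min_participation` whose total
#' weighted degree is at least the component median.
#'
#' @param result a `query_result` with at least 2 functional modules.
#' @param min_participation participation threshold. Default 0.5.
#' @return Tibble `gene_id`, `participation`, `degree`, `is_bridge`.
#' @export
find_bridges <- function(result, min_participation = 0.5) {
  mod <- result$modules
  check_that(length(unique(mod$module)) >= 2,
             "need at least 2 functional modules")
  deg <- module_degrees(result)
  parts <- deg %>%
    group_by(.data$gene) %>%
    summarise(degree = sum(.data$k),
              participation = 1 - sum((.data$k / sum(.data$k))^2),
              .groups = "drop")
  all_genes <- tibble(gene = mod$gene_id)
  parts <- left_join(all_genes, parts, by = "gene") %>%
    mutate(degree = ifelse(is.na(.data$degree), 0, .data$degree),
           participation = ifelse(is.na(.data$participation), 0,
                                  .data$participation))
  med <- median(parts$degree)
  parts %>%
    mutate(is_bridge = .data$participation >= min_participation &
             .data$degree >= med) %>%
    rename(gene_id = "gene") %>%
    arrange(desc(.data$participation))
}

#' Hypergeometric gene-set annotation of functional modules
#'
#' One-sided hypergeometric enrichment of each module against each gene set
#' over a stated universe, Benjamini-Hochberg adjusted within module. Gene
#' sets with no genes in the universe are skipped.
#'
#' @param result a `query_result`.
#' @param genesets named list of gene-ID vectors.
#' @param universe gene universe; defaults to the query subnetwork's genes
#'   and must contain all module genes.
#' @return Tibble `module`, `gene_set`, `n_overlap`, `n_module`, `n_set`,
#'   `p`, `bh_q`.
#' @export
annotate_modules <- function(result, genesets, universe = NULL) {
  mod <- result$modules
  if (is.null(universe)) universe <- result$subnetwork$nodes
  check_that(all(mod$gene_id %in% universe),
             "universe must contain all module genes")
  N <- length(universe)
  rows <- list()
  for (m in sort(unique(mod$module))) {
    members <- intersect(mod$gene_id[mod$module == m], universe)
    tab <- lapply(names(genesets), function(gs) {
      set <- intersect(genesets[[gs]], universe)
      if (!length(set)) {
        inform(sprintf("gene set %s has no genes in the universe; skipped", gs))
        return(NULL)
      }
      ov <- length(intersect(members, set))
      p <- phyper(ov - 1, length(set), N - length(set), length(members),
                  lower.tail = FALSE)
      tibble(module = m, gene_set = gs, n_overlap = ov,
             n_module = length(members), n_set = length(set), p = p)
    })
    tab <- bind_rows(tab)
    if (nrow(tab)) {
      tab$bh_q <- p.adjust(tab$p, method = "BH")
      rows[[m]] <- tab
    }
  }
  bind_rows(rows)
}
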