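# Hierarchical community detection on the module overlap network: fast-greedy
# modularity maximization gives large "top-level" communities (numerals);
# spin-glass (Potts model) optimization within each top-level community gives
# "bottom-level" sub-communities (numeral + letter, letters by decreasing
# size). Communities are then tested for enrichment of phenotype-associated
# modules (Fisher) and annotated against pathways through edge gene sets
# (Jaccard similarity + Mann-Whitney).

# Shared spin-glass engine (also used by netquery and diffnet): runs
# igraph::cluster_spinglass per connected component with gamma = 1 and up to
# `max_communities` spins, taking the best modularity over `restarts`
# deterministic restarts. Components below 3 nodes become single communities.
spinglass_partition <- function(g, max_communities = 10, gamma = 1,
                                restarts = 5, seed = 1L) {
  comps <- igraph::components(g)
  vnames <- igraph::V(g)$name
  membership <- setNames(integer(length(vnames)), vnames)
  next_label <- 0L
  for (ci in seq_len(comps$no)) {
    vs <- vnames[comps$membership == ci]
    sub <- igraph::induced_subgraph(g, vs)
    if (length(vs) < 3 || igraph::ecount(sub) == 0) {
      membership[vs] <- next_label + 1L
      next_label <- next_label + 1L
      next
    }
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(restarts)) {
      cm <- with_seed(child_seed(seed, ci * 1000L + r), {
        igraph::cluster_spinglass(sub, spins = max_communities, gamma = gamma)
      })
      q <- igraph::modularity(sub, igraph::membership(cm),
                              weights = igraph::E(sub)$weight)
      if (q > best_q) {
        best_q <- q
        best <- igraph::membership(cm)
      }
    }
    membership[vs] <- next_label + as.integer(best[vs])
    next_label <- next_label + max(as.integer(best))
  }
  membership
}

#' Top-level communities by greedy modularity maximization
#'
#' Greedy agglomerative modularity maximization (fast-greedy) on the weighted
#' overlap network. Disconnected components are handled independently by the
#' algorithm. An edgeless network yields singleton communities with Q = 0 and
#' a warning.
#'
#' @param network an `overlap_network` (or any igraph-convertible object via
#'   [as_igraph()]).
#' @return A `community_assignment`: tibble `assignment` with `node` and
#'   `top_label` (numerals, by decreasing community size), plus
#'   `modularity_top`.
#' @export
detect_top_level <- function(network) {
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0) {
    warn("edgeless network: every node becomes its own community")
    memb <- seq_len(igraph::vcount(g))
    q <- 0
  } else {
    cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    memb <- as.integer(igraph::membership(cm))
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    # on flat landscapes the greedy cut can land below the trivial
    # one-community-per-component partition (Q = 0); never return that
    comp_memb <- as.integer(igraph::components(g)$membership)
    comp_q <- igraph::modularity(g, comp_memb, weights = igraph::E(g)$weight)
    if (q < comp_q) {
      memb <- comp_memb
      q <- comp_q
    }
  }
  # relabel communities 1, 2, ... by decreasing size
  sizes <- table(memb)
  relabel <- setNames(rank(-as.integer(sizes), ties.method = "first"),
                      names(sizes))
  top <- relabel[as.character(memb)]
  structure(
    list(assignment = tibble(node = igraph::V(g)$name,
                             top_label = as.character(top)),
         modularity_top = q, graph = g),
    class = "community_assignment"
  )
}

#' Bottom-level sub-communities by spin-glass optimization
#'
#' Within each top-level community, the induced subgraph is optimized with
#' the Potts-model spin-glass algorithm (gamma = 1, at most
#' `max_communities` spins, best of `restarts` seeded runs). Sub-communities
#' get letters by decreasing size, so a node's full label is e.g. `"4A"`.
#' Sub-networks below 3 nodes become a single sub-community without
#' annealing.
#'
#' @param network the `overlap_network` used for `top`.
#' @param top a `community_assignment` from [detect_top_level()].
#' @param max_communities spin count cap per top-level community. Default 10.
#' @param restarts annealing restarts, best modularity kept. Default 5.
#' @param seed RNG seed (results are reproducible run-to-run).
#' @return The `community_assignment` with a `bottom_label` column added and
#'   `modularity_bottom` (weighted mean of within-top-community
#'   modularities) recorded.
#' @export
detect_bottom_level <- function(network, top, max_communities = 10,
                                restarts = 5, seed = 1L) {
  check_that(inherits(top, "community_assignment"), "top must be a community_assignment")
  g <- if (is.null(top$graph)) as_igraph(network) else top$graph
  asg <- top$assignment
  asg$bottom_label <- NA_character_
  q_parts <- numeric(0)
  w_parts <- numeric(0)
  for (tl in unique(asg$top_label)) {
    vs <- asg$node[asg$top_label == tl]
    sub <- igraph::induced_subgraph(g, vs)
    memb <- spinglass_partition(sub, max_communities = max_communities,
                                restarts = restarts,
                                seed = child_seed(seed, as.integer(factor(tl, levels = unique(asg$top_label)))))
    sizes <- sort(table(memb), decreasing = TRUE)
    letter <- setNames(make_letters(length(sizes)), names(sizes))
    asg$bottom_label[match(names(memb), asg$node)] <-
      paste0(tl, letter[as.character(memb)])
    if (igraph::ecount(sub) > 0) {
      q_parts <- c(q_parts, igraph::modularity(sub, memb[igraph::V(sub)$name],
                                               weights = igraph::E(sub)$weight))
      w_parts <- c(w_parts, length(vs))
    }
  }
  top$assignment <- asg
  top$modularity_bottom <- if (length(q_parts)) {
    sum(q_parts * w_parts) / sum(w_parts)
  } else 0
  top
}

make_letters <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("<community_assignment> %d nodes, %d top-level communities (Q = %.3f)%s\n",
              nrow(x$assignment), length(unique(x$assignment$top_label)),
              x$modularity_top,
              if (!is.null(x$assignment$bottom_label))
                sprintf(", %d bottom-level", length(unique(x$assignment$bottom_label)))
              else ""))
  invisible(x)
}

#' @export
tidy.community_assignment <- function(x, ...) x$assignment

#' @export
glance.community_assignment <- function(x, ...) {
  tibble(n_nodes = nrow(x$assignment),
         n_top = length(unique(x$assignment$top_label)),
         n_bottom = if (is.null(x$assignment$bottom_label)) NA_integer_
                    else length(unique(x$assignment$bottom_label)),
         modularity_top = x$modularity_top,
         modularity_bottom = x$modularity_bottom %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test of community-structure modularity
#'
#' Null modularity distribution from random permutations of the node labels
#' (community sizes preserved).
#'
#' @param network the network the assignment was computed on.
#' @param assignment a `community_assignment` (top level is tested).
#' @param n_permutations number of label permutations. Default 1000.
#' @param seed RNG seed.
#' @return List with `observed_q`, `null_qs`, `p_raw`.
#' @export
modularity_permutation_test <- function(network, assignment,
                                        n_permutations = 1000, seed = 1L) {
  g <- as_igraph(network)
  asg <- assignment$assignment
  check_that(setequal(asg$node, igraph::V(g)$name),
             "assignment must cover the network")
  memb <- as.integer(factor(asg$top_label[match(igraph::V(g)$name, asg$node)]))
  w <- igraph::E(g)$weight
  observed <- igraph::modularity(g, memb, weights = w)
  null_qs <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      igraph::modularity(g, sample(memb), weights = w)
    }, numeric(1))
  })
  list(observed_q = observed, null_qs = null_qs,
       p_raw = mean(null_qs >= observed))
}

#' Phenotype enrichment of top-level communities
#'
#' For each (top-level community, phenotype) a 2x2 table of community
#' membership against the phenotype-association flag (modules associated in
#' either direction count) is tested with a two-sided Fisher exact test,
#' Bonferroni-corrected across communities within each phenotype.
#'
#' @param assignment a `community_assignment`.
#' @param node_attributes tibble with `node` plus one logical flag column per
#'   phenotype (e.g. from [node_phenotype_flags()]).
#' @param phenotypes which flag columns to test (default: all non-`node`
#'   logical columns).
#' @param min_nodes smallest community tested (and counted in the Bonferroni
#'   factor). Default 2: a single isolated module is not a community, and
#'   its "enrichment" is just the module's own flag.
#' @return Tibble `top_label`, `phenotype`, `n_in_flagged`, `odds_ratio`,
#'   `raw_p`, `bonferroni_p`. Phenotypes with zero associated modules report
#'   p = 1.
#' @export
phenotype_enrichment <- function(assignment, node_attributes, phenotypes = NULL,
                                 min_nodes = 2) {
  asg <- assignment$assignment
  attrs <- as_tibble(node_attributes)
  check_that("node" %in% names(attrs), "node_attributes need a node column")
  if (is.null(phenotypes)) {
    phenotypes <- names(attrs)[vapply(attrs, is.logical, logical(1))]
  }
  df <- left_join(asg, attrs, by = "node")
  rows <- list()
  for (ph in phenotypes) {
    flag <- df[[ph]]
    flag[is.na(flag)] <- FALSE
    comm_sizes <- table(df$top_label)
    tops <- sort(names(comm_sizes)[comm_sizes >= min_nodes])
    tab <- lapply(tops, function(tl) {
      inn <- df$top_label == tl
      if (!any(inn)) {
        warn(sprintf("community %s is empty; skipped", tl))
        return(NULL)
      }
      if (!any(flag)) {
        return(tibble(top_label = tl, phenotype = ph,
                      n_in_flagged = 0L, odds_ratio = NA_real_, raw_p = 1))
      }
      m <- matrix(c(sum(inn & flag), sum(inn & !flag),
                    sum(!inn & flag), sum(!inn & !flag)), nrow = 2)
      ft <- fisher.test(m, alternative = "two.sided")
      tibble(top_label = tl, phenotype = ph,
             n_in_flagged = sum(inn & flag),
             odds_ratio = unname(ft$estimate), raw_p = ft$p.value)
    })
    tab <- bind_rows(tab)
    tab$bonferroni_p <- pmin(1, tab$raw_p * nrow(tab))
    rows[[ph]] <- tab
  }
  bind_rows(rows)
}

#' Phenotype-association flags per overlap-network node
#'
#' Converts per-dataset association tables into one logical flag column per
#' phenotype (and a `<phenotype>_up` column for increased-in-phenotype
#' modules), keyed by node.
#'
#' @param association_tables named list (by dataset ID) of tibbles from
#'   [associate_phenotypes()].
#' @param alpha Bonferroni-corrected significance cutoff. Default 0.05.
#' @return Tibble with `node` and logical flag columns.
#' @export
node_phenotype_flags <- function(association_tables, alpha = 0.05) {
  long <- bind_rows(lapply(names(association_tables), function(d) {
    tab <- association_tables[[d]]
    if (nrow(tab) == 0) return(NULL)
    mutate(tab, node = paste(d, .data$module, sep = ":"))
  }))
  if (is.null(long) || nrow(long) == 0) return(tibble(node = character()))
  flags <- long %>%
    group_by(.data$node, .data$phenotype) %>%
    summarise(assoc = any(.data$bonferroni_p <= alpha),
              up = any(.data$bonferroni_p <= alpha & .data$direction > 0),
              .groups = "drop")
  wide_a <- tidyr::pivot_wider(select(flags, "node", "phenotype", "assoc"),
                               names_from = "phenotype", values_from = "assoc",
                               values_fill = FALSE)
  wide_u <- tidyr::pivot_wider(select(flags, "node", "phenotype", "up"),
                               names_from = "phenotype", values_from = "up",
                               names_glue = "{phenotype}_up", values_fill = FALSE)
  left_join(wide_a, wide_u, by = "node")
}

#' Edge gene sets of the overlap network
#'
#' Every retained edge joins two modules from different datasets; its edge
#' gene set is the intersection of the two module gene sets over that
#' dataset pair's shared universe. Empty intersections on retained edges are
#' flagged (they indicate an edge that should not have been retained).
#'
#' @param network an `overlap_network`.
#' @param partitions the same partitions used to build it (list of
#'   `module_partition` or gene/module tibbles, named by dataset ID).
#' @return Tibble `node_a`, `node_b`, `genes` (list-column), `n_genes`.
#' @export
edge_gene_sets <- function(network, partitions = NULL) {
  labels <- if (is.null(partitions)) network$partitions else lapply(partitions, as_label_vector)
  if (is.null(names(labels)) && !is.null(partitions)) {
    names(labels) <- vapply(partitions, function(p) p$dataset_id, character(1))
  }
  ed <- network$edges
  split_node <- function(x) sub(":.*$", "", x)
  module_of <- function(x) sub("^[^:]*:", "", x)
  genes <- vector("list", nrow(ed))
  for (k in seq_len(nrow(ed))) {
    da <- split_node(ed$node_a[k]); db <- split_node(ed$node_b[k])
    la <- labels[[da]]; lb <- labels[[db]]
    shared <- intersect(names(la), names(lb))
    ga <- names(la)[la == module_of(ed$node_a[k])]
    gb <- names(lb)[lb == module_of(ed$node_b[k])]
    genes[[k]] <- intersect(intersect(ga, gb), shared)
  }
  out <- tibble(node_a = ed$node_a, node_b = ed$node_b,
                genes = genes, n_genes = lengths(genes))
  if (any(out$n_genes == 0)) {
    warn(sprintf("%d retained edge(s) have empty gene sets", sum(out$n_genes == 0)))
  }
  out
}

#' Jaccard similarity of two gene sets
#'
#' @param a,b character vectors of gene IDs.
#' @return `|a n b| / |a u b|`; 0 when both are empty.
#' @export
jaccard_similarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pathway annotation of communities via edge gene sets
#'
#' For every pathway, the Jaccard similarity to each edge gene set is
#' computed; a community is annotated to a pathway when within-community
#' edges are more similar to it than outside edges (two-sided Mann-Whitney,
#' Bonferroni-corrected across pathways within each community). An edge is
#' inside a community when both endpoints carry that community label.
#'
#' @param edge_sets output of [edge_gene_sets()].
#' @param assignment a `community_assignment`.
#' @param pathways named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param level `"top"` or `"bottom"` community labels. Default `"top"`.
#' @return Tibble `community`, `pathway`, `within_median_j`,
#'   `outside_median_j`, `raw_p`, `bonferroni_p`, `direction`.
#' @export
annotate_communities <- function(edge_sets, assignment, pathways,
                                 level = c("top", "bottom")) {
  level <- match.arg(level)
  asg <- assignment$assignment
  lab_col <- if (level == "top") "top_label" else "bottom_label"
  check_that(lab_col %in% names(asg), sprintf("assignment lacks %s", lab_col))
  lab <- setNames(asg[[lab_col]], asg$node)
  comm_a <- lab[edge_sets$node_a]
  comm_b <- lab[edge_sets$node_b]
  edge_comm <- ifelse(!is.na(comm_a) & !is.na(comm_b) & comm_a == comm_b,
                      comm_a, NA_character_)
  universe <- unique(unlist(edge_sets$genes, use.names = FALSE))
  rows <- list()
  for (comm in sort(unique(edge_comm[!is.na(edge_comm)]))) {
    inside <- which(!is.na(edge_comm) & edge_comm == comm)
    outside <- setdiff(seq_len(nrow(edge_sets)), inside)
    if (!length(inside) || !length(outside)) next
    tab <- lapply(names(pathways), function(pw) {
      pset <- pathways[[pw]]
      if (!length(intersect(pset, universe))) {
        inform(sprintf("pathway %s has no genes in any edge set; skipped", pw))
        return(NULL)
      }
      js <- vapply(edge_sets$genes, jaccard_similarity, numeric(1), b = pset)
      mw <- mw_test(js[outside], js[inside])
      tibble(community = comm, pathway = pw,
             within_median_j = median(js[inside]),
             outside_median_j = median(js[outside]),
             raw_p = mw$p, direction = mw$direction)
    })
    tab <- bind_rows(tab)
    if (nrow(tab)) {
      tab$bonferroni_p <- pmin(1, tab$raw_p * nrow(tab))
      rows[[comm]] <- tab
    }
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    out <- select(out, "community", "pathway", "within_median_j",
                  "outside_median_j", "raw_p", "bonferroni_p", "direction")
  }
  out
}
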