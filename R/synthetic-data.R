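# Synthetic multi-dataset compendia and tissue-network triples with planted
# ground truth. The generator is the test surface for the whole pipeline:
# planted co-expression modules are rank-one (eigengene x loadings) blocks, a
# subset of modules ("shared processes") recurs across datasets with elevated
# expression in disease samples, and network triples share a community
# backbone plus tissue-specific communities.

#' Specification for a synthetic expression compendium
#'
#' Defaults define the package's reference simulation: four cohorts on
#' partially overlapping gene universes drawn from a 1200-gene master list,
#' eight planted modules each, three of which are shared disease processes
#' whose eigengene is shifted upward in disease samples.
#'
#' @param n_datasets number of cohorts.
#' @param genes_master size of the master gene list.
#' @param gene_overlap_fraction fraction of the master list measured by each
#'   dataset (universes sampled without replacement, so pairwise shared-gene
#'   counts vary).
#' @param samples_per_dataset arrays per cohort.
#' @param modules_per_dataset planted co-expression modules per cohort
#'   (includes the shared processes).
#' @param module_size_range integer `c(min, max)` genes per planted module;
#'   min must be at least 3.
#' @param n_shared_processes planted cross-dataset consensus gene sets; each
#'   becomes one module in every dataset.
#' @param shared_process_sizes sizes of the shared processes (recycled).
#' @param disease_fraction fraction of samples labeled `disease`.
#' @param effect_size standardized mean shift of shared-process eigengenes in
#'   disease samples.
#' @param process_private_fraction per dataset, each shared-process module is
#'   padded with this fraction of dataset-private genes riding the same
#'   eigengene at weaker loadings (uniform in \[0.3, 0.6\]) — the shared
#'   core is each dataset's module core, private members its periphery, as
#'   in real compendia where cohort modules overlap without coinciding.
#'   Default 0.2.
#' @param noise_sd residual standard deviation around the rank-one module
#'   signal.
#' @param seed integer; fully determines all outputs.
#' @return A `compendium_spec` list.
#' @export
compendium_spec <- function(n_datasets = 4,
                            genes_master = 1200,
                            gene_overlap_fraction = 0.8,
                            samples_per_dataset = 60,
                            modules_per_dataset = 8,
                            module_size_range = c(20, 40),
                            n_shared_processes = 3,
                            shared_process_sizes = 30,
                            disease_fraction = 0.5,
                            effect_size = 2,
                            process_private_fraction = 0.2,
                            noise_sd = 0.3,
                            seed = 1L) {
  spec <- list(
    n_datasets = as.integer(n_datasets),
    genes_master = as.integer(genes_master),
    gene_overlap_fraction = gene_overlap_fraction,
    samples_per_dataset = as.integer(samples_per_dataset),
    modules_per_dataset = as.integer(modules_per_dataset),
    module_size_range = as.integer(module_size_range),
    n_shared_processes = as.integer(n_shared_processes),
    shared_process_sizes = as.integer(shared_process_sizes),
    disease_fraction = disease_fraction,
    effect_size = effect_size,
    process_private_fraction = process_private_fraction,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  with(spec, {
    check_that(n_datasets >= 1 && genes_master >= 1 && samples_per_dataset >= 1 &&
                 modules_per_dataset >= 1, "counts must be positive")
    check_that(length(module_size_range) == 2 && module_size_range[1] >= 3 &&
                 module_size_range[1] <= module_size_range[2],
               "module_size_range must be c(min >= 3, max >= min)")
    check_that(gene_overlap_fraction > 0 && gene_overlap_fraction <= 1,
               "gene_overlap_fraction must be in (0, 1]")
    check_that(disease_fraction > 0 && disease_fraction <= 1,
               "disease_fraction must be in (0, 1]")
    check_that(n_shared_processes <= modules_per_dataset,
               "n_shared_processes cannot exceed modules_per_dataset")
    check_that(noise_sd >= 0 && effect_size >= 0, "effect/noise must be nonnegative")
    check_that(process_private_fraction >= 0 && process_private_fraction <= 1,
               "process_private_fraction must lie in [0, 1]")
  })
  structure(spec, class = "compendium_spec")
}

#' Generate a synthetic expression compendium with planted modules
#'
#' Each dataset measures a random subset of the master gene list (always
#' including the shared-process genes, so every shared process appears in all
#' universes). Planted modules are rank-one blocks: a per-sample eigengene
#' times per-gene loadings drawn uniform in \[0.5, 1\], plus Gaussian noise.
#' Shared-process eigengenes are shifted by `effect_size` in disease samples,
#' so the planted consensus signal is a coherent module-level shift.
#' Unassigned background genes are independent standard normal.
#'
#' @param spec a [compendium_spec()].
#' @return A list with `datasets` (list of [expression_dataset()]) and
#'   `truth` (a `partition_truth`: per-gene module assignments, the
#'   module-to-shared-process map, the planted process gene sets and the
#'   per-dataset universes).
#' @export
generate_compendium <- function(spec) {
  check_that(inherits(spec, "compendium_spec"), "spec must be a compendium_spec")
  with_seed(spec$seed, {
    master <- sprintf("G%05d", seq_len(spec$genes_master))
    proc_sizes <- rep_len(spec$shared_process_sizes, spec$n_shared_processes)
    check_that(sum(proc_sizes) <= spec$genes_master,
               "shared processes exceed master gene list")
    proc_pool <- sample(master, sum(proc_sizes))
    processes <- split(proc_pool, rep(seq_along(proc_sizes), proc_sizes))
    names(processes) <- sprintf("P%d", seq_along(processes))
    proc_genes <- unlist(processes, use.names = FALSE)

    universe_size <- round(spec$gene_overlap_fraction * spec$genes_master)
    check_that(universe_size >= length(proc_genes),
               "universes too small to hold the shared processes")

    datasets <- vector("list", spec$n_datasets)
    assign_rows <- vector("list", spec$n_datasets)
    map_rows <- vector("list", spec$n_datasets)
    universes <- vector("list", spec$n_datasets)
    # pairs of datasets share a tissue (as real compendia have 2-3 cohorts
    # per tissue), so the per-tissue intersection of Eq.-style consensus
    # algebra is non-trivial; an odd trailing dataset gets its own tissue
    tissue_pool <- c("skin", "lung", "eso", "pbmc")
    tissues <- rep(rep_len(tissue_pool, ceiling(spec$n_datasets / 2)),
                   each = 2)[seq_len(spec$n_datasets)]

    for (d in seq_len(spec$n_datasets)) {
      ds_id <- sprintf("DS%d", d)
      extra <- sample(setdiff(master, proc_genes), universe_size - length(proc_genes))
      universe <- sample(c(proc_genes, extra))   # shuffled measured universe
      universes[[d]] <- universe

      n_other <- spec$modules_per_dataset - spec$n_shared_processes
      size_choices <- seq(spec$module_size_range[1], spec$module_size_range[2])
      other_sizes <- if (n_other > 0) {
        size_choices[sample.int(length(size_choices), n_other, replace = TRUE)]
      } else integer(0)
      free <- setdiff(universe, proc_genes)
      priv_sizes <- round(spec$process_private_fraction * lengths(processes))
      if (sum(other_sizes) + sum(priv_sizes) > length(free)) {
        abort(sprintf("infeasible spec: module sizes exceed universe of %s", ds_id))
      }
      other_pool <- sample(free, sum(other_sizes))
      other_modules <- if (n_other > 0) {
        split(other_pool, rep(seq_len(n_other), other_sizes))
      } else list()
      # dataset-private peripheral members of each shared-process module
      priv_pool <- sample(setdiff(free, other_pool), sum(priv_sizes))
      priv_idx <- rep(seq_along(priv_sizes), priv_sizes)
      shared_modules <- lapply(seq_along(processes), function(m) {
        c(processes[[m]], priv_pool[priv_idx == m])
      })

      module_genes <- c(shared_modules, other_modules)
      names(module_genes) <- sprintf("T%d", seq_along(module_genes))
      is_shared <- seq_along(module_genes) <= spec$n_shared_processes
      n_core <- lengths(processes)

      n <- spec$samples_per_dataset
      sample_ids <- sprintf("%s_S%03d", ds_id, seq_len(n))
      n_disease <- max(1, round(spec$disease_fraction * n))
      status <- rep("control", n)
      status[sample(n, n_disease)] <- "disease"

      mat <- matrix(rnorm(length(universe) * n), nrow = length(universe),
                    dimnames = list(universe, sample_ids))
      shared_eigs <- matrix(0, nrow = spec$n_shared_processes, ncol = n)
      for (m in seq_along(module_genes)) {
        eig <- rnorm(n)
        if (is_shared[m]) {
          eig <- eig + spec$effect_size * (status == "disease")
          shared_eigs[m, ] <- eig
        }
        genes <- module_genes[[m]]
        loadings <- if (is_shared[m]) {
          # shared core genes load strongly, private periphery weakly
          c(runif(n_core[m], 0.5, 1),
            runif(length(genes) - n_core[m], 0.3, 0.6))
        } else {
          runif(length(genes), 0.5, 1)
        }
        mat[genes, ] <- loadings %*% t(eig) +
          matrix(rnorm(length(genes) * n, sd = spec$noise_sd), nrow = length(genes))
      }

      severity <- if (spec$n_shared_processes > 0) {
        colMeans(shared_eigs) + rnorm(n, sd = 0.5)
      } else rnorm(n)
      pheno <- tibble(
        sample_id = sample_ids, dataset_id = ds_id, tissue = tissues[d],
        disease_status = status, severity = severity
      )
      datasets[[d]] <- expression_dataset(mat, pheno, dataset_id = ds_id,
                                          tissue = tissues[d])

      module_of <- setNames(rep("unassigned", length(universe)), universe)
      for (m in seq_along(module_genes)) module_of[module_genes[[m]]] <- names(module_genes)[m]
      assign_rows[[d]] <- tibble(dataset_id = ds_id, gene_id = universe,
                                 module = unname(module_of))
      map_rows[[d]] <- tibble(dataset_id = ds_id,
                              module = names(module_genes),
                              process = c(names(processes),
                                          rep(NA_character_, n_other)))
    }
    names(datasets) <- vapply(datasets, function(x) x$dataset_id, character(1))
    names(universes) <- names(datasets)
    truth <- structure(
      list(assignments = bind_rows(assign_rows),
           process_map = bind_rows(map_rows),
           processes = processes,
           universes = universes),
      class = "partition_truth"
    )
    list(datasets = datasets, truth = truth)
  })
}

#' Specification for a synthetic tissue-network triple
#'
#' Two tissue networks plus a global baseline on a shared node set. All three
#' share a community backbone (dense blocks present everywhere); each tissue
#' network additionally elevates the internal edges of its own tissue-specific
#' communities, which are disjoint from the backbone and from each other.
#'
#' @param n_genes nodes per network.
#' @param backbone_communities dense communities present in all networks.
#' @param tissue_specific_communities_per_tissue per-tissue planted
#'   communities, elevated in exactly one tissue network.
#' @param within_weight_mean mean edge weight inside a (backbone or planted)
#'   community, in \[0, 1\].
#' @param between_weight_mean mean background edge weight, in \[0, 1\].
#' @param weight_noise_sd Gaussian noise added independently per network and
#'   edge; weights are clipped back to \[0, 1\] and the clipping fraction is
#'   reported.
#' @param linker_fraction fraction of between-community gene pairs carrying a
#'   strong (within-level) edge shared by all three networks. Linkers keep
#'   the pruned high-probability graph connected, as in real tissue
#'   networks, and cancel exactly in the differential adjacency. Default
#'   0.05.
#' @param seed integer; fully determines all outputs.
#' @return A `network_triple_spec` list.
#' @export
network_triple_spec <- function(n_genes = 150,
                                backbone_communities = 3,
                                tissue_specific_communities_per_tissue = 2,
                                within_weight_mean = 0.8,
                                between_weight_mean = 0.1,
                                weight_noise_sd = 0.05,
                                linker_fraction = 0.05,
                                seed = 1L) {
  spec <- list(
    n_genes = as.integer(n_genes),
    backbone_communities = as.integer(backbone_communities),
    tissue_specific_communities_per_tissue =
      as.integer(tissue_specific_communities_per_tissue),
    within_weight_mean = within_weight_mean,
    between_weight_mean = between_weight_mean,
    weight_noise_sd = weight_noise_sd,
    linker_fraction = linker_fraction,
    seed = as.integer(seed)
  )
  with(spec, {
    check_that(within_weight_mean >= 0 && within_weight_mean <= 1 &&
                 between_weight_mean >= 0 && between_weight_mean <= 1,
               "weight means must lie in [0, 1]")
    check_that(weight_noise_sd >= 0, "weight_noise_sd must be nonnegative")
    check_that(linker_fraction >= 0 && linker_fraction <= 1,
               "linker_fraction must lie in [0, 1]")
    check_that(n_genes >= 6, "n_genes too small")
  })
  structure(spec, class = "network_triple_spec")
}

#' Generate a tissue/tissue/global functional-network triple
#'
#' @param spec a [network_triple_spec()].
#' @return A list with `tissue_a`, `tissue_b`, `global`
#'   ([functional_network()] objects on the same node set) and `truth`, a
#'   tibble of planted community memberships (`gene_id`, `community`,
#'   `kind` in backbone/tissue_a/tissue_b).
#' @export
generate_network_triple <- function(spec) {
  check_that(inherits(spec, "network_triple_spec"), "spec must be a network_triple_spec")
  with_seed(spec$seed, {
    genes <- sprintf("N%04d", seq_len(spec$n_genes))
    n_comm <- spec$backbone_communities +
      2 * spec$tissue_specific_communities_per_tissue
    comm_size <- floor(spec$n_genes * 0.9 / max(1, n_comm))
    check_that(comm_size >= 3, "n_genes too small for the requested communities")
    pool <- sample(genes, comm_size * n_comm)
    comm_members <- split(pool, rep(seq_len(n_comm), each = comm_size))
    kind <- c(rep("backbone", spec$backbone_communities),
              rep("tissue_a", spec$tissue_specific_communities_per_tissue),
              rep("tissue_b", spec$tissue_specific_communities_per_tissue))
    truth <- bind_rows(lapply(seq_len(n_comm), function(k) {
      tibble(gene_id = comm_members[[k]],
             community = sprintf("C%d", k), kind = kind[k])
    }))

    idx <- utils::combn(length(genes), 2)
    a <- idx[1, ]; b <- idx[2, ]
    comm_of <- setNames(rep(NA_integer_, length(genes)), genes)
    for (k in seq_len(n_comm)) comm_of[comm_members[[k]]] <- k
    ca <- comm_of[genes[a]]; cb <- comm_of[genes[b]]
    same <- !is.na(ca) & !is.na(cb) & ca == cb

    base <- rep(spec$between_weight_mean, length(a))
    in_backbone <- same & kind[ca] == "backbone"
    base[in_backbone] <- spec$within_weight_mean
    # strong linker edges shared by all networks keep the pruned graph
    # connected; they subtract out of the differential exactly
    cross <- !is.na(ca) & !is.na(cb) & ca != cb
    linker <- cross & runif(length(a)) < spec$linker_fraction
    base[linker] <- spec$within_weight_mean
    w_a <- base; w_a[same & kind[ca] == "tissue_a"] <- spec$within_weight_mean
    w_b <- base; w_b[same & kind[ca] == "tissue_b"] <- spec$within_weight_mean

    noisy <- function(w) {
      w <- w + rnorm(length(w), sd = spec$weight_noise_sd)
      clipped <- mean(w < 0 | w > 1)
      if (clipped > 0) {
        inform(sprintf("clipped %.2f%% of edge weights to [0, 1]", 100 * clipped))
      }
      pmin(1, pmax(0, w))
    }
    edge_tbl <- function(w, tissue) {
      functional_network(
        tibble(gene_a = genes[a], gene_b = genes[b], weight = noisy(w)),
        tissue = tissue
      )
    }
    list(
      tissue_a = edge_tbl(w_a, "tissue_a"),
      tissue_b = edge_tbl(w_b, "tissue_b"),
      global = edge_tbl(base, "global"),
      truth = truth
    )
  })
}

#' Emit planted shared processes as a gene-set collection, plus decoys
#'
#' The planted shared-process gene sets become "pathways"; decoy sets of
#' matched sizes are sampled at random from the union of dataset universes.
#'
#' @param truth a `partition_truth` from [generate_compendium()].
#' @param decoys number of random decoy sets.
#' @param seed RNG seed for decoy sampling.
#' @return A named list of gene-ID vectors (GMT-compatible, see
#'   [write_gmt()]) with a `descriptions` attribute.
#' @export
generate_genesets <- function(truth, decoys = 0, seed = 1L) {
  check_that(inherits(truth, "partition_truth"), "truth must be a partition_truth")
  with_seed(seed, {
    universe <- unique(unlist(truth$universes, use.names = FALSE))
    sets <- truth$processes
    desc <- setNames(rep("planted shared process", length(sets)), names(sets))
    if (decoys > 0) {
      sizes <- rep_len(lengths(truth$processes), decoys)
      for (k in seq_len(decoys)) {
        nm <- sprintf("DECOY%d", k)
        sets[[nm]] <- sample(universe, sizes[k])
        desc[[nm]] <- "random decoy set"
      }
    }
    attr(sets, "descriptions") <- desc
    sets
  })
}
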