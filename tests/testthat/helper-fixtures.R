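# Shared fixtures: everything is generated in code at test time.

# small compendium used by most integration tests: 3 cohorts, 2 shared
# disease processes, moderate noise
tiny_compendium <- function(seed = 1, n_datasets = 3) {
  generate_compendium(compendium_spec(
    n_datasets = n_datasets, genes_master = 400, gene_overlap_fraction = 0.8,
    samples_per_dataset = 30, modules_per_dataset = 5,
    module_size_range = c(20, 30), n_shared_processes = 2,
    shared_process_sizes = 25, seed = seed
  ))
}

# partitions + association tables + overlap network for a compendium
micc_stack <- function(comp, seed = 5, min_module_size = 15) {
  partitions <- lapply(comp$datasets, detect_modules,
                       min_module_size = min_module_size)
  associations <- lapply(names(partitions), function(d) {
    associate_phenotypes(partitions[[d]], comp$datasets[[d]]$phenotypes)
  })
  names(associations) <- names(partitions)
  network <- build_overlap_network(partitions)
  assignment <- detect_bottom_level(network, detect_top_level(network),
                                    seed = seed)
  list(partitions = partitions, associations = associations,
       network = network, assignment = assignment)
}

# overlap-network node ("dataset:module") of the detected module carrying
# each planted shared process: per dataset, the detected module holding the
# majority of the process core
process_nodes <- function(partitions, truth, proc) {
  core <- truth$processes[[proc]]
  out <- character(0)
  for (d in names(partitions)) {
    lab <- partitions[[d]]$assignments
    cand <- lab$module[lab$gene_id %in% core & lab$module != "unassigned"]
    if (!length(cand)) next
    tab <- sort(table(cand), decreasing = TRUE)
    if (tab[1] >= length(core) * 0.5) {
      out <- c(out, paste(d, names(tab)[1], sep = ":"))
    }
  }
  out
}

# ARI between a partition and the planted truth of one dataset
truth_ari <- function(partition, truth, dataset) {
  tr <- truth$assignments[truth$assignments$dataset_id == dataset, ]
  m <- merge(tr, partition$assignments, by = "gene_id")
  adjusted_rand_index(m$module.x, m$module.y)
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
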