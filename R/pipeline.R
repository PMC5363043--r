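# Single-config orchestration of the full analysis: preprocess -> module
# detection -> phenotype association -> module overlap network -> hierarchical
# communities -> enrichment -> consensus gene sets, with optional functional
# network query, differential network and gene-set scoring stages when the
# config supplies networks / gene sets. One global seed fans out to
# deterministic per-stage child seeds, so reruns are checksum-identical.

pipeline_defaults <- list(
  power = 12, min_module_size = 20, merge_height = 0.15,
  prune_below = 0.5, n_permutations = 1000, alpha = 0.05,
  max_communities = 10, restarts = 5, fdr = 0.05,
  max_missing = 0.20, min_coverage = 0.5,
  threshold_policy = "positive+hypergeometric"
)

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills stage-parameter defaults,
#' checks ranges and referenced paths, and returns the normalized config.
#' Recognized top-level keys: `seed` (required), `output_dir` (required),
#' `datasets` (list of `dataset_id`/`dir`/`tissue` entries pointing at TSV
#' pairs written by [write_expression_dataset()]), `simulate` (a
#' [compendium_spec()] field list, used when `datasets` is absent),
#' `networks` (named paths `focal`/`comparator`/`baseline` of edge-list
#' TSVs), `genesets` (GMT path) and `parameters`.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return The normalized config (class `run_config`), with every stage
#'   parameter materialized.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_that(is.list(config), "config must parse to a list")
  known <- c("seed", "output_dir", "datasets", "simulate", "networks",
             "genesets", "parameters")
  unknown <- setdiff(names(config), known)
  check_that(!length(unknown),
             paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  check_that(!is.null(config$seed), "config must set a seed")
  check_that(is.numeric(config$seed) && config$seed == round(config$seed),
             "seed must be an integer")
  check_that(!is.null(config$output_dir), "config must set output_dir")

  pars <- utils::modifyList(pipeline_defaults, config$parameters %||% list())
  extra <- setdiff(names(pars), names(pipeline_defaults))
  check_that(!length(extra),
             paste0("unknown parameters: ", paste(extra, collapse = ", ")))
  check_that(pars$prune_below >= 0 && pars$prune_below <= 1,
             "prune_below must lie in [0, 1]")
  check_that(pars$alpha > 0 && pars$alpha <= 1, "alpha must lie in (0, 1]")
  check_that(pars$max_missing >= 0 && pars$max_missing <= 1,
             "max_missing must lie in [0, 1]")
  check_that(pars$n_permutations >= 1, "n_permutations must be positive")
  config$parameters <- pars

  if (!is.null(config$datasets)) {
    ids <- vapply(config$datasets, function(d) d$dataset_id, character(1))
    check_that(!anyDuplicated(ids), "duplicate dataset_id in manifest")
    for (d in config$datasets) {
      for (p in file.path(d$dir, paste0(d$dataset_id,
                                        c("_expression.tsv", "_phenotypes.tsv")))) {
        check_that(file.exists(p), sprintf("missing dataset file: %s", p))
      }
    }
  } else {
    sim <- config$simulate %||% list()
    sim$seed <- sim$seed %||% config$seed
    config$simulate <- sim
  }
  if (!is.null(config$networks)) {
    for (p in unlist(config$networks)) {
      check_that(file.exists(p), sprintf("missing network file: %s", p))
    }
  }
  if (!is.null(config$genesets)) {
    check_that(file.exists(config$genesets),
               sprintf("missing gene set file: %s", config$genesets))
  }
  structure(config, class = c("run_config", "list"))
}

pipeline_log <- function(stage, t0) {
  inform(sprintf("[%s] done in %.1fs", stage,
                 as.numeric(Sys.time()) - as.numeric(t0)))
}

run_stage <- function(stage, expr) {
  t0 <- Sys.time()
  out <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
  pipeline_log(stage, t0)
  out
}

#' Run the full analysis pipeline from a config
#'
#' Executes the stages in order, writes every intermediate artifact under
#' `output_dir`, and returns a manifest of outputs with MD5 checksums.
#' Rerunning with the same config reproduces identical checksums.
#'
#' @param config a path, list or `run_config` (see [validate_config()]).
#' @return Invisibly, a list with the manifest tibble, the consensus gene
#'   set and the community assignment. The manifest is also written to
#'   `output_dir/manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  pars <- config$parameters
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_normalized.yaml"))
  outputs <- character(0)
  note <- function(path) outputs <<- c(outputs, path)

  datasets <- run_stage("load_data", {
    if (!is.null(config$datasets)) {
      ds <- lapply(config$datasets, function(d) {
        read_expression_dataset(d$dir, d$dataset_id, tissue = d$tissue)
      })
      names(ds) <- vapply(ds, function(x) x$dataset_id, character(1))
      ds
    } else {
      spec <- do.call(compendium_spec, config$simulate)
      generate_compendium(spec)$datasets
    }
  })

  datasets <- run_stage("preprocess", {
    lapply(datasets, function(d) {
      d <- collapse_duplicates(d)
      filter_missingness(d, pars$max_missing)
    })
  })

  partitions <- run_stage("detect_modules", {
    lapply(datasets, detect_modules, power = pars$power,
           min_module_size = pars$min_module_size,
           merge_height = pars$merge_height)
  })
  for (d in names(partitions)) {
    p <- file.path(out_dir, sprintf("%s_partition.tsv", d))
    write_partition_tsv(partitions[[d]]$assignments, p); note(p)
    pe <- file.path(out_dir, sprintf("%s_eigengenes.tsv", d))
    write_expression_tsv(partitions[[d]]$eigengenes, pe); note(pe)
  }

  associations <- run_stage("associate_phenotypes", {
    lapply(names(partitions), function(d) {
      associate_phenotypes(partitions[[d]], datasets[[d]]$phenotypes)
    }) |> setNames(names(partitions))
  })
  for (d in names(associations)) {
    p <- file.path(out_dir, sprintf("%s_associations.tsv", d))
    write.table(as.data.frame(associations[[d]]), p, sep = "\t",
                quote = FALSE, row.names = FALSE); note(p)
  }

  network <- run_stage("overlap_network", {
    build_overlap_network(partitions,
                          threshold_policy = pars$threshold_policy,
                          alpha = pars$alpha)
  })
  p <- file.path(out_dir, "overlap_edges.tsv")
  write.table(as.data.frame(network$edges), p, sep = "\t", quote = FALSE,
              row.names = FALSE); note(p)

  assignment <- run_stage("communities", {
    top <- detect_top_level(network)
    detect_bottom_level(network, top, max_communities = pars$max_communities,
                        restarts = pars$restarts, seed = child_seed(seed, 2L))
  })
  p <- file.path(out_dir, "communities.tsv")
  write.table(as.data.frame(assignment$assignment), p, sep = "\t",
              quote = FALSE, row.names = FALSE); note(p)

  flags <- node_phenotype_flags(associations, alpha = pars$alpha)
  enrichment <- run_stage("phenotype_enrichment", {
    phenotype_enrichment(assignment, flags)
  })
  p <- file.path(out_dir, "community_enrichment.tsv")
  write.table(as.data.frame(enrichment), p, sep = "\t", quote = FALSE,
              row.names = FALSE); note(p)

  consensus <- run_stage("consensus", {
    tissue_map <- vapply(datasets, function(d) d$tissue, character(1))
    sel <- select_disease_communities(enrichment, assignment, flags,
                                      alpha = pars$alpha)
    if (length(sel$nodes)) {
      derive_tissue_consensus(partitions, sel$nodes, tissue_map)
    } else NULL
  })
  if (!is.null(consensus)) {
    p <- file.path(out_dir, "consensus_genes.tsv")
    write.table(as.data.frame(tidy(consensus)), p, sep = "\t", quote = FALSE,
                row.names = FALSE); note(p)
  }

  if (!is.null(config$networks) && !is.null(consensus) &&
      length(consensus$union_set) >= 2) {
    nets <- lapply(config$networks, read_functional_network)
    qres <- run_stage("netquery", {
      lapply(nets, query_network, query_genes = consensus$union_set,
             prune_below = pars$prune_below,
             max_communities = pars$max_communities,
             restarts = pars$restarts, seed = child_seed(seed, 3L))
    })
    for (nm in names(qres)) {
      p <- file.path(out_dir, sprintf("query_%s_modules.tsv", nm))
      write.table(as.data.frame(qres[[nm]]$modules), p, sep = "\t",
                  quote = FALSE, row.names = FALSE); note(p)
    }
    if (all(c("focal", "comparator", "baseline") %in% names(nets))) {
      diff <- run_stage("diffnet", {
        nodes <- common_nodes(qres$focal, qres$comparator)
        differential_adjacency(nets$focal, nets$comparator, nets$baseline,
                               nodes)
      })
      p <- file.path(out_dir, "differential_edges.tsv")
      write_edgelist_tsv(diff$edges, p); note(p)
      dmod <- run_stage("differential_communities", {
        differential_communities(diff, max_communities = pars$max_communities,
                                 restarts = pars$restarts,
                                 seed = child_seed(seed, 4L))
      })
      p <- file.path(out_dir, "differential_modules.tsv")
      write.table(as.data.frame(dmod), p, sep = "\t", quote = FALSE,
                  row.names = FALSE); note(p)
    }
  }

  if (!is.null(config$genesets)) {
    collection <- read_gmt(config$genesets)
    scores_all <- run_stage("scoring", {
      bind_rows(lapply(names(datasets), function(d) {
        z <- suppressWarnings(zscore_genes(datasets[[d]]$matrix))
        st <- score_genesets(z, collection, min_coverage = pars$min_coverage)
        mutate(st$scores, dataset_id = d)
      }))
    })
    p <- file.path(out_dir, "geneset_scores.tsv")
    write.table(as.data.frame(scores_all), p, sep = "\t", quote = FALSE,
                row.names = FALSE); note(p)
  }

  manifest <- tibble(
    file = basename(outputs),
    path = outputs,
    md5 = unname(tools::md5sum(outputs))
  )
  write.table(as.data.frame(manifest[, c("file", "md5")]),
              file.path(out_dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(manifest = manifest, consensus = consensus,
                 assignment = assignment, enrichment = enrichment))
}
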