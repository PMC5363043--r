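# Plain-text readers and writers for every on-disk format the pipeline
# touches: expression matrices (TSV, genes x samples), phenotype tables (TSV),
# weighted edge lists (TSV), gene-set collections (GMT) and gene->module maps.
# All numeric output is written at full double precision.

#' Write / read an expression matrix as TSV
#'
#' Rows are gene IDs, columns are sample IDs, with a leading `gene_id` header
#' column. Values round-trip at full double precision.
#'
#' @param mat numeric matrix with rownames (genes) and colnames (samples).
#' @param path file path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns the matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write / read a phenotype table as TSV
#'
#' One row per sample; columns `sample_id`, `dataset_id`, `tissue`,
#' `disease_status` plus any continuous covariates.
#'
#' @param pheno a data frame of per-sample phenotypes.
#' @param path file path.
#' @return A tibble for the reader; `path` invisibly for the writer.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a weighted edge list as TSV
#'
#' Three columns: `gene_a`, `gene_b`, `weight`. Used for functional networks
#' (weights are interaction probabilities in \[0, 1\]) and for differential
#' networks.
#'
#' @param edges a data frame with columns `gene_a`, `gene_b`, `weight`.
#' @param path file path.
#' @return A tibble for the reader; `path` invisibly for the writer.
#' @export
write_edgelist_tsv <- function(edges, path) {
  write.table(as.data.frame(edges)[, c("gene_a", "gene_b", "weight")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_tsv
#' @export
read_edgelist_tsv <- function(path) {
  df <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  check_that(all(c("gene_a", "gene_b", "weight") %in% names(df)),
             "edge list must have columns gene_a, gene_b, weight")
  df
}

#' Read and write gene-set collections in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line with
#' its name, a description, then the member gene IDs.
#'
#' @param path file path.
#' @param collection a named list of character vectors (gene IDs), or a
#'   `geneset_collection` as returned by [generate_genesets()].
#' @param descriptions optional character vector of per-set descriptions.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  check_that(!anyDuplicated(names(sets)), "duplicate gene-set names in GMT")
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(collection, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("na", length(collection)), names(collection))
  }
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a gene-to-module assignment table
#'
#' @param assignments tibble with columns `gene_id`, `module`.
#' @param path file path.
#' @return A tibble for the reader; `path` invisibly for the writer.
#' @export
write_partition_tsv <- function(assignments, path) {
  write.table(as.data.frame(assignments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE,
                       colClasses = "character"))
}
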