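# The per-cohort container: one gene-by-sample matrix plus its phenotype
# table. Kept as a light S3 list; tidy() gives the long tibble view.

#' Construct an expression dataset
#'
#' Bundles a gene-by-sample expression matrix (log-scale values or ratios)
#' with its per-sample phenotype table, tissue label and dataset identifier.
#'
#' @param matrix numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param phenotypes data frame with one row per sample and a `sample_id`
#'   column matching `colnames(matrix)` exactly (same order not required).
#' @param dataset_id label for the cohort.
#' @param tissue tissue-of-origin label.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(matrix, phenotypes, dataset_id, tissue = NA_character_) {
  check_that(is.matrix(matrix) && is.numeric(matrix), "matrix must be numeric")
  check_that(!is.null(rownames(matrix)) && !is.null(colnames(matrix)),
             "matrix needs gene rownames and sample colnames")
  phenotypes <- as_tibble(phenotypes)
  check_that("sample_id" %in% names(phenotypes), "phenotypes need a sample_id column")
  check_that(setequal(phenotypes$sample_id, colnames(matrix)) &&
               !anyDuplicated(phenotypes$sample_id),
             "sample_ids must match matrix columns exactly")
  phenotypes <- phenotypes[match(colnames(matrix), phenotypes$sample_id), ]
  structure(
    list(matrix = matrix, phenotypes = phenotypes,
         dataset_id = dataset_id, tissue = tissue),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s (%s): %d genes x %d samples\n",
              x$dataset_id, x$tissue, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Tidy an expression dataset into long form
#'
#' @param x an `expression_dataset`.
#' @param ... unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `expression`, joined
#'   with the phenotype table.
#' @export
tidy.expression_dataset <- function(x, ...) {
  long <- tibble(
    gene_id = rep(rownames(x$matrix), times = ncol(x$matrix)),
    sample_id = rep(colnames(x$matrix), each = nrow(x$matrix)),
    expression = as.vector(x$matrix)
  )
  left_join(long, x$phenotypes, by = "sample_id")
}

#' @export
glance.expression_dataset <- function(x, ...) {
  tibble(
    dataset_id = x$dataset_id,
    tissue = x$tissue,
    n_genes = nrow(x$matrix),
    n_samples = ncol(x$matrix),
    missing_fraction = mean(is.na(x$matrix))
  )
}

#' Write / read an expression dataset to a directory
#'
#' Writes `<id>_expression.tsv` and `<id>_phenotypes.tsv`; the reader
#' reassembles the object, so datasets round-trip without loss.
#'
#' @param x an `expression_dataset`.
#' @param dir directory (created if needed).
#' @param dataset_id the id used when writing.
#' @param tissue optional tissue override for the reader (defaults to the
#'   phenotype table's `tissue` column when present).
#' @return The reader returns an `expression_dataset`; the writer returns the
#'   file paths invisibly.
#' @export
write_expression_dataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pe <- file.path(dir, paste0(x$dataset_id, "_expression.tsv"))
  pp <- file.path(dir, paste0(x$dataset_id, "_phenotypes.tsv"))
  write_expression_tsv(x$matrix, pe)
  write_phenotype_tsv(x$phenotypes, pp)
  invisible(c(expression = pe, phenotypes = pp))
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(dir, dataset_id, tissue = NULL) {
  mat <- read_expression_tsv(file.path(dir, paste0(dataset_id, "_expression.tsv")))
  pheno <- read_phenotype_tsv(file.path(dir, paste0(dataset_id, "_phenotypes.tsv")))
  if (is.null(tissue)) {
    tissue <- if ("tissue" %in% names(pheno)) pheno$tissue[1] else NA_character_
  }
  expression_dataset(mat, pheno, dataset_id = dataset_id, tissue = tissue)
}
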