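# Gene-level preprocessing: collapsing duplicate gene rows, missingness
# filtering, and per-gene z-scoring. Missing values are ignored
# (pairwise-complete) in means, medians and standard deviations.

#' Collapse duplicate gene rows to the gene mean, then median-center
#'
#' Rows sharing a gene ID are averaged (missing values ignored) so each gene
#' appears once, and every gene row is then centered at median zero.
#'
#' @param mat numeric matrix with (possibly repeated) gene IDs as rownames,
#'   or an `expression_dataset` whose matrix has repeated rownames.
#' @param ... passed through to methods.
#' @return Same shape of object as the input, with one median-centered row
#'   per gene. Gene order follows first appearance.
#' @export
collapse_duplicates <- function(mat, ...) UseMethod("collapse_duplicates")

#' @export
collapse_duplicates.default <- function(mat, ...) {
  check_that(is.matrix(mat) && nrow(mat) > 0, "empty or non-matrix input")
  check_that(!is.null(rownames(mat)), "matrix needs gene rownames")
  ids <- rownames(mat)
  keep <- unique(ids)
  grp <- factor(ids, levels = keep)
  counts <- rowsum(1 - is.na(mat), grp, reorder = FALSE)
  sums <- rowsum(ifelse(is.na(mat), 0, mat), grp, reorder = FALSE)
  out <- sums / counts            # NaN where a gene is missing in all rows
  out[counts == 0] <- NA_real_
  meds <- apply(out, 1, median, na.rm = TRUE)
  out <- out - meds
  rownames(out) <- keep
  out
}

#' @export
collapse_duplicates.expression_dataset <- function(mat, ...) {
  x <- mat
  x$matrix <- collapse_duplicates(x$matrix)
  x
}

#' Remove genes with too much missing data
#'
#' Retains exactly the genes whose fraction of missing samples is at most
#' `max_missing` (the boundary is kept), preserving row order.
#'
#' @param x numeric matrix or `expression_dataset`.
#' @param max_missing maximum tolerated missing fraction per gene, in
#'   \[0, 1\]. Default 0.20.
#' @return Filtered object of the same type. Emits a warning (not an error)
#'   if no gene survives.
#' @export
filter_missingness <- function(x, max_missing = 0.20) UseMethod("filter_missingness")

#' @export
filter_missingness.default <- function(x, max_missing = 0.20) {
  check_that(is.numeric(max_missing) && max_missing >= 0 && max_missing <= 1,
             "max_missing must be a fraction in [0, 1]")
  frac <- rowMeans(is.na(x))
  out <- x[frac <= max_missing, , drop = FALSE]
  if (nrow(out) == 0) warn("all genes removed by missingness filter")
  out
}

#' @export
filter_missingness.expression_dataset <- function(x, max_missing = 0.20) {
  x$matrix <- filter_missingness(x$matrix, max_missing)
  x
}

#' Per-gene z-score standardization
#'
#' Each gene row is centered at its mean and scaled by its sample standard
#' deviation (denominator n - 1), missing values ignored and propagated.
#' Zero-variance genes cannot be standardized and are dropped with a warning.
#'
#' @param x numeric matrix (genes x samples) or `expression_dataset`.
#' @return Matrix of z-scores (or the dataset with its matrix replaced);
#'   every retained row has mean 0 and sd 1 over its observed values.
#' @export
zscore_genes <- function(x) UseMethod("zscore_genes")

#' @export
zscore_genes.default <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  sigma <- apply(x, 1, sd, na.rm = TRUE)
  bad <- !is.finite(sigma) | sigma == 0
  if (any(bad)) {
    warn(sprintf("dropping %d zero-variance gene(s): %s", sum(bad),
                 paste(head(rownames(x)[bad], 5), collapse = ", ")))
  }
  (x[!bad, , drop = FALSE] - mu[!bad]) / sigma[!bad]
}

#' @export
zscore_genes.expression_dataset <- function(x) {
  x$matrix <- zscore_genes(x$matrix)
  x
}
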