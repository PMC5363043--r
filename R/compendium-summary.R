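#' Published multi-tissue compendium summary
#'
#' Per-dataset array and co-expression module counts of the ten-cohort
#' systemic sclerosis compendium (skin, lung, esophagus and PBMC cohorts)
#' that motivates this package, shipped as a plain TSV. Useful as a sizing
#' reference for simulations and for checking the compendium totals.
#'
#' @return A tibble with columns `dataset`, `tissue`, `n_arrays`,
#'   `n_modules`.
#' @export
#' @examples
#' cs <- compendium_summary()
#' sum(cs$n_arrays)   # total arrays in the compendium
#' sum(cs$n_modules)  # total co-expression modules
compendium_summary <- function() {
  path <- system.file("extdata", "compendium_summary.tsv", package = "miccnet",
                      mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
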