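# Internal helpers shared across modules.

#' Derive a reproducible child seed from a global seed
#'
#' Stages of the pipeline (and restarts of stochastic optimizers) each draw a
#' deterministic child seed from the global seed so that any stage can be rerun
#' in isolation with identical results. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param offset integer stage/replicate offset.
#' @return An integer seed.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %% 2147483587L)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# stopifnot with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  check_that(length(a) == length(b), "labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# two-sided Mann-Whitney wrapper: exact null distribution whenever the data
# are tie-free, else normal approximation with continuity and tie correction
# (wilcox.test applies both). Returns list(statistic, p, direction).
mw_test <- function(x, y) {
  exact <- !any(duplicated(c(x, y)))
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- res$p.value
  if (is.nan(p)) p <- 1  # all values tied in both groups
  list(
    statistic = unname(res$statistic),
    p = min(1, p),
    direction = sign(median(y) - median(x))
  )
}
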