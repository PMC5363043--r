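# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# two-sided Fisher p by full hypergeometric enumeration: sum of the
# probabilities of all tables with the observed margins whose probability
# does not exceed the observed one (standard probability-mass rule, with the
# customary relative tolerance on "does not exceed").
brute_fisher_two_sided <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# one-sided hypergeometric upper tail by summation
brute_hyper_upper <- function(overlap, set_size, universe, draw) {
  support <- overlap:min(set_size, draw)
  sum(dhyper(support, set_size, universe - set_size, draw))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of the
# pooled tie-free values
brute_mw_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- combn(length(pooled), n1)
  u_null <- apply(combs, 2, u_of)
  min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
}

# mutual information of two label vectors, computed from joint frequencies
# with explicit loops (independent of the package's vectorized route)
brute_mi_bits <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (la in unique(a)) {
    for (lb in unique(b)) {
      nij <- sum(a == la & b == lb)
      if (nij == 0) next
      ni <- sum(a == la); nj <- sum(b == lb)
      mi <- mi + (nij / n) * log2(n * nij / (ni * nj))
    }
  }
  mi
}

# all set partitions of 1..n (for brute-force max-modularity search)
all_set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# per-edge loop oracle for the differential adjacency
brute_differential <- function(focal, comparator, baseline, nodes) {
  get_w <- function(net, g1, g2) {
    ed <- net$edges
    hit <- (ed$gene_a == g1 & ed$gene_b == g2) |
      (ed$gene_a == g2 & ed$gene_b == g1)
    if (any(hit)) ed$weight[hit][1] else 0
  }
  out <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      d <- max(get_w(focal, nodes[i], nodes[j]) -
                 max(get_w(comparator, nodes[i], nodes[j]),
                     get_w(baseline, nodes[i], nodes[j])), 0)
      if (d > 0) {
        out[[length(out) + 1]] <- data.frame(
          gene_a = min(nodes[i], nodes[j]),
          gene_b = max(nodes[i], nodes[j]), weight = d)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$gene_a, df$gene_b), ]
}

# random functional network on a node set (every pair, uniform weights)
random_network <- function(nodes, tissue = "t") {
  pairs <- combn(nodes, 2)
  functional_network(
    data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
               weight = runif(ncol(pairs))),
    tissue = tissue
  )
}
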