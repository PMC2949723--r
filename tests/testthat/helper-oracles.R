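# Independent oracles, deliberately naive: loop-based KS scan and O(n^3)
# complete-linkage agglomeration. They never call the package's
# implementations.

# Brute-force enrichment score: scan every step of the tag ECDF against the
# uniform CDF, tracking the largest excursion above and below.
ks_oracle <- function(positions, n) {
  V <- sort(positions)
  t <- length(V)
  above <- -Inf
  below <- -Inf
  for (j in seq_len(t)) {
    # just after the j-th tag the ECDF is j/t; just before it is (j-1)/t
    above <- max(above, j / t - V[j] / n)
    below <- max(below, V[j] / n - (j - 1) / t)
  }
  if (above > below) above else -below
}

# Naive complete-linkage agglomeration from a distance matrix: at each step
# merge the pair of clusters with the smallest maximum inter-point distance.
# Returns the merge heights in order.
complete_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Brute-force rank-stability selection by explicit per-probe comparison.
stable_probes_oracle <- function(a, b, rank_tol) {
  n <- length(a)
  ra <- rank(a)
  rb <- rank(b)
  keep <- integer(0)
  for (i in seq_len(n)) {
    if (abs(ra[i] - rb[i]) / n < rank_tol) keep <- c(keep, i)
  }
  keep
}
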