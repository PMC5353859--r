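# Independent oracles used across the suite. These deliberately do not share
# code with the package implementations they check.

# Benjamini-Hochberg step-up oracle: the adjusted p-value of hypothesis i is
# the smallest level alpha at which the BH decision procedure (find the
# largest k with p_(k) <= k * alpha / n, reject everything at or below
# p_(k)) rejects hypothesis i. Levels only change at p_j * n / k, so
# scanning that candidate set is exact.
bh_oracle <- function(p) {
  n <- length(p)
  cand <- sort(unique(pmin(as.vector(outer(p * n, seq_len(n), "/")), 1)))
  bh_rejects <- function(alpha) {
    ps <- sort(p)
    # tiny epsilon guards against p * n / k round-trip rounding
    ok <- which(ps <= seq_len(n) * alpha / n + 1e-12)
    if (!length(ok)) return(rep(FALSE, n))
    p <= ps[max(ok)]
  }
  vapply(seq_len(n), function(i) {
    for (alpha in cand) if (bh_rejects(alpha)[i]) return(alpha)
    1
  }, numeric(1))
}

# Hypergeometric upper-tail oracle by direct enumeration of all tables with
# the observed margins, using exact factorial ratios (N <= 60 keeps doubles
# exact enough for 1e-10 agreement).
fisher_oracle <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  ks <- max(0, K + n - N):min(K, n)
  pmf <- vapply(ks, function(k) {
    exp(lfactorial(K) - lfactorial(k) - lfactorial(K - k) +
          lfactorial(N - K) - lfactorial(n - k) - lfactorial(N - K - n + k) -
          (lfactorial(N) - lfactorial(n) - lfactorial(N - n)))
  }, numeric(1))
  sum(pmf[ks >= a])
}

# UPGMA oracle recomputing every cluster distance from the raw matrix as the
# mean over all cross pairs (no Lance-Williams update), with the same
# deterministic tie-break: sorted labels, clusters indexed by lowest member,
# lowest (i, j) pair first.
upgma_oracle <- function(d) {
  labels <- sort(rownames(d))
  d <- d[labels, labels]
  clusters <- as.list(seq_along(labels))
  heights <- numeric(0)
  leafsets <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        key <- c(min(clusters[[i]]), min(clusters[[j]]))
        if (is.null(best) || avg < best$avg - 1e-12 ||
            (abs(avg - best$avg) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, avg = avg, key = key)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$avg)
    leafsets <- c(leafsets, list(labels[merged]))
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, leafsets = leafsets)
}

# Rule-table oracle for tiered homolog acceptance of a single best hit.
tier_oracle <- function(pident, bitscore, evalue, pseudogene,
                        thr = homology_thresholds()) {
  if (pseudogene) return("unmapped")
  if (pident > thr$high_pident) return("high")
  if (pident > thr$mod_pident && bitscore > thr$mod_bitscore &&
      evalue <= thr$mod_evalue) return("moderate")
  "unmapped"
}
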