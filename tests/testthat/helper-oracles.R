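# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from its definition with naive
# loops, never by calling the package's own fast paths.

# full-permutation two-sided Mann-Whitney p-value: enumerate every way of
# assigning n1 of the pooled values to the first group, compute U for each,
# and count arrangements at least as extreme (two-sided, symmetric about
# n1*n2/2) as the observed one
oracle_mw_perm_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_stat(x, y)
  centre <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - centre) >= abs(obs - centre) - 1e-12)
}

# GMD from the definition, polarity-minimized RMS of GFP-normalized maps
oracle_gmd <- function(u, v) {
  norm_map <- function(w) {
    w <- w - mean(w)
    w / sqrt(mean(w^2))
  }
  u <- norm_map(u)
  v <- norm_map(v)
  min(sqrt(mean((u - v)^2)), sqrt(mean((u + v)^2)))
}

# GEV by direct per-sample evaluation: squared Pearson correlation between
# sample and assigned map, weighted by the sample's share of total GFP^2
oracle_gev <- function(ep, seg, ms) {
  k <- ms$k
  num <- numeric(k)
  den <- 0
  for (e in seq_len(dim(ep$data)[1])) {
    for (s in seq_len(dim(ep$data)[3])) {
      v <- ep$data[e, , s]
      v <- v - mean(v)
      g2 <- mean(v^2)
      den <- den + g2
      if (g2 < 1e-30) next
      m <- ms$maps[seg$labels[e, s], ]
      r <- stats::cor(v, m)
      num[seg$labels[e, s]] <- num[seg$labels[e, s]] + g2 * r^2
    }
  }
  list(gev_per_map = num / den, gev_total = sum(num) / den)
}

# transition counts by explicit pair loop within epochs
oracle_transition_counts <- function(labels, k) {
  counts <- matrix(0L, k, k)
  for (e in seq_len(nrow(labels))) {
    for (s in seq_len(ncol(labels) - 1L)) {
      counts[labels[e, s], labels[e, s + 1L]] <-
        counts[labels[e, s], labels[e, s + 1L]] + 1L
    }
  }
  counts
}

# best label assignment by explicit search over all permutations of the
# correlation matrix rows
oracle_best_assignment <- function(C) {
  k <- nrow(C)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- tuples[apply(tuples, 1L, function(r) length(unique(r)) == k), ,
                  drop = FALSE]
  totals <- apply(perms, 1L, function(p) sum(C[cbind(seq_len(k), p)]))
  best <- perms[which.max(totals), ]
  list(assignment = unname(best), total = max(totals))
}

# small shared fixtures ------------------------------------------------------

tiny_layout <- function(n = 16L) grid_layout(n)

# layout with no edge channels, for stages where trimming is not under test
full_layout <- function(n = 64L) {
  lay <- grid_layout(n)
  lay$edge <- rep(FALSE, nrow(lay))
  lay
}

# a segmentation wrapped around a plain label vector (single epoch)
seg_from_labels <- function(labels, k, sfreq = 250) {
  segmentation(matrix(labels, nrow = 1L), k = k, sfreq = sfreq)
}
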