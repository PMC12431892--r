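#' Global map dissimilarity
#'
#' Amplitude-invariant distance between two topographies: each is
#' average-referenced and scaled to unit GFP, and the root-mean-square
#' difference is minimized over polarity. Identical (or polarity-flipped)
#' maps give 0; orthogonal maps give sqrt(2).
#'
#' @param u,v Numeric channel vectors, non-zero after average referencing.
#' @return The dissimilarity in \[0, sqrt(2)\].
#' @export
#' @examples
#' gmd(c(1, -1, 0, 0), c(-1, 1, 0, 0))  # 0: polarity-invariant
gmd <- function(u, v) {
  u <- u - mean(u)
  v <- v - mean(v)
  gu <- sqrt(mean(u^2))
  gv <- sqrt(mean(v^2))
  if (gu < 1e-15 || gv < 1e-15) rlang::abort("GMD undefined for zero-GFP input")
  u <- u / gu
  v <- v / gv
  min(sqrt(mean((u - v)^2)), sqrt(mean((u + v)^2)))
}

#' Segmentation container
#'
#' @param labels Integer matrix, epochs x samples, entries in `1..k`.
#' @param k Number of maps.
#' @param sfreq Sampling rate (Hz).
#' @param map_ref Optional identifier of the map set used.
#' @return An object of class `segmentation`.
#' @export
segmentation <- function(labels, k, sfreq, map_ref = NULL) {
  labels <- as.matrix(labels)
  if (any(labels < 1L | labels > k)) rlang::abort("labels must lie in 1..k")
  structure(list(labels = labels, k = as.integer(k), sfreq = sfreq,
                 map_ref = map_ref),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d epochs x %d samples, k = %d @ %g Hz\n",
              nrow(x$labels), ncol(x$labels), x$k, x$sfreq))
  invisible(x)
}

#' Back-fit microstate maps to every EEG sample
#'
#' Labels each sample of each epoch with the map of minimal global map
#' dissimilarity — equivalently, maximal absolute spatial correlation — so
#' the whole recording (not only GFP peaks) is segmented. Ties break toward
#' the lowest map index. Samples with near-zero GFP, where GMD is undefined,
#' inherit the previous sample's label (the first labeled sample for a
#' leading run).
#'
#' @param ep An [eeg_epochs()] on the same channel set as `ms`.
#' @param ms A [mapset()].
#' @return A `segmentation`.
#' @export
backfit <- function(ep, ms) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(ms, "mapset"))
  if (n_channels(ep) != length(ms$channels)) {
    rlang::abort("channel spaces of epochs and maps do not match")
  }
  nE <- n_epochs(ep)
  nS <- n_samples(ep)
  V <- stack_epochs(ep)
  V <- V - rowMeans(V)
  norm2 <- rowSums(V^2)
  A <- V %*% t(ms$maps)
  # squared spatial correlation; rows with ~zero GFP handled below
  L <- max.col(A * A, ties.method = "first")
  zero <- norm2 < (1e-9)^2 * ncol(V)
  lab <- matrix(L, nrow = nE, ncol = nS, byrow = TRUE)
  zm <- matrix(zero, nrow = nE, ncol = nS, byrow = TRUE)
  if (any(zero)) {
    for (e in seq_len(nE)) {
      z <- zm[e, ]
      if (!any(z)) next
      if (all(z)) {
        lab[e, ] <- 1L
        next
      }
      good_idx <- which(!z)
      for (s in which(z)) {
        prev <- good_idx[good_idx < s]
        lab[e, s] <- if (length(prev)) lab[e, max(prev)] else
          lab[e, min(good_idx)]
      }
    }
  }
  segmentation(lab, ms$k, ep$sfreq, map_ref = ms$canonical_labels)
}

#' Window-smooth a segmentation
#'
#' Iteratively relabels samples to minimize the per-sample unexplained
#' variance minus `penalty` times the number of same-label neighbors within
#' `half_window` samples on either side — the classic window-smoothing
#' scheme that absorbs short, weakly supported label intrusions. Costs are
#' normalized by the mean squared sample norm so `penalty` is scale-free.
#' Epochs are smoothed independently; iteration stops at a fixed point or
#' after `max_pass` sweeps. `penalty = 0` returns the back-fit labels
#' unchanged.
#'
#' @param seg A `segmentation` from [backfit()].
#' @param ep The [eeg_epochs()] the segmentation was fitted to.
#' @param ms The [mapset()] used.
#' @param half_window Neighborhood half-width in samples (default 3,
#'   i.e. 12 ms at 250 Hz).
#' @param penalty Non-negative smoothing strength (default 5).
#' @param max_pass Maximum relabeling sweeps (default 1000).
#' @return A smoothed `segmentation`.
#' @export
smooth_segmentation <- function(seg, ep, ms, half_window = 3L, penalty = 5,
                                max_pass = 1000L) {
  stopifnot(inherits(seg, "segmentation"), inherits(ep, "eeg_epochs"),
            inherits(ms, "mapset"))
  if (half_window < 1L) rlang::abort("`half_window` must be >= 1")
  if (penalty < 0) rlang::abort("`penalty` must be >= 0")
  if (penalty == 0) return(seg)
  nE <- n_epochs(ep)
  nS <- n_samples(ep)
  k <- ms$k
  V <- stack_epochs(ep)
  V <- V - rowMeans(V)
  norm2 <- rowSums(V^2)
  A2 <- (V %*% t(ms$maps))^2
  scale <- mean(norm2)
  if (scale < 1e-30) return(seg)
  cost <- (norm2 - A2) / scale               # (epochs*samples) x k
  lab <- seg$labels
  for (e in seq_len(nE)) {
    rows <- ((e - 1L) * nS + 1L):(e * nS)
    ce <- cost[rows, , drop = FALSE]
    l <- lab[e, ]
    for (pass in seq_len(max_pass)) {
      # same-label neighbor counts within the window, per candidate map
      counts <- matrix(0, nrow = nS, ncol = k)
      for (c in seq_len(k)) {
        ind <- as.numeric(l == c)
        counts[, c] <- running_edge_count(ind, half_window)
      }
      obj <- ce - penalty * counts / (2L * half_window)
      l_new <- max.col(-obj, ties.method = "first")
      if (all(l_new == l)) break
      l <- l_new
    }
    lab[e, ] <- l
  }
  segmentation(lab, k, seg$sfreq, map_ref = seg$map_ref)
}

# windowed neighbor count near the epoch edges, where stats::filter returns NA
running_edge_count <- function(ind, hw) {
  n <- length(ind)
  cs <- cumsum(ind)
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  cs[hi] - c(0, cs)[lo] - ind
}
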