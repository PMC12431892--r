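#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the instantaneous topography:
#' the root mean square of the voltages about their channel mean, one scalar
#' per sample. High GFP marks strong, stable topographies; microstate maps
#' are extracted at its peaks.
#'
#' @param ep An [eeg_epochs()] (>= 2 channels).
#' @return A `gfp_series`: a list with `values` (epochs x samples matrix of
#'   microvolt scalars) and `sfreq`.
#' @export
#' @examples
#' sim <- simulate_participant(grid_layout(16), diag(2) * 0 + 0.5,
#'                             n_epochs = 2, epoch_len = 100, noise_sd = 0)
#' gfp <- compute_gfp(sim$epochs)
compute_gfp <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (n_channels(ep) < 2L) rlang::abort("GFP needs at least 2 channels")
  mu <- apply(ep$data, c(1L, 3L), mean)
  ss <- apply(ep$data^2, c(1L, 3L), mean)
  vals <- sqrt(pmax(ss - mu^2, 0))
  structure(list(values = vals, sfreq = ep$sfreq), class = "gfp_series")
}

#' Find GFP peaks
#'
#' Strict local maxima of the GFP within each epoch (peaks are never detected
#' across epoch boundaries). For a flat plateau the first sample counts as
#' the peak. Peaks closer than `min_distance` samples are thinned, keeping
#' the larger of any conflicting pair (ties keep the earlier one).
#'
#' @param gfp A `gfp_series` from [compute_gfp()].
#' @param min_distance Minimal distance between retained peaks in samples
#'   (default 2).
#' @return A tibble with columns `epoch`, `sample`, `gfp`.
#' @export
find_gfp_peaks <- function(gfp, min_distance = 2L) {
  stopifnot(inherits(gfp, "gfp_series"))
  if (min_distance < 1L) rlang::abort("`min_distance` must be >= 1")
  per_epoch <- lapply(seq_len(nrow(gfp$values)), function(e) {
    v <- gfp$values[e, ]
    idx <- local_maxima(v)
    idx <- thin_peaks(idx, v[idx], min_distance)
    if (length(idx)) tibble::tibble(epoch = e, sample = idx, gfp = v[idx])
  })
  out <- dplyr::bind_rows(per_epoch)
  if (nrow(out) == 0L) tibble::tibble(epoch = integer(), sample = integer(),
                                      gfp = numeric()) else out
}

# strict local maxima with plateau handling: first sample of any flat run
# whose neighbours on both sides are lower
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer())
  mid <- 2:(k - 1L)
  is_peak <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_peak]
}

# greedy min-distance thinning: visit candidates tallest first (earlier index
# wins ties), keep those not within `min_dist` of an already kept peak
thin_peaks <- function(idx, height, min_dist) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(-height, idx)
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(idx[i] - kept) >= min_dist)) {
      kept <- c(kept, idx[i])
    }
  }
  sort(kept)
}

#' Filter GFP peaks by amplitude criteria
#'
#' Two criteria, both computed against the full GFP series of the recording
#' (all samples, not only peaks): peaks whose GFP exceeds
#' `mean + sd_mult * SD` of the series are removed (unusually strong
#' topographies, often artifact), and peaks lying within the lowest
#' `low_pct` percent of the GFP distribution are removed (weak topographies
#' nearly equidistant from all cluster maps).
#'
#' @param gfp A `gfp_series`.
#' @param peaks Tibble from [find_gfp_peaks()].
#' @param sd_mult Upper criterion multiplier (default 1); `Inf` disables it.
#' @param low_pct Lower percentile cutoff in percent (default 15); 0 disables.
#' @return The retained rows of `peaks`.
#' @export
filter_gfp_peaks <- function(gfp, peaks, sd_mult = 1, low_pct = 15) {
  stopifnot(inherits(gfp, "gfp_series"))
  all_vals <- as.vector(gfp$values)
  hi <- mean(all_vals) + sd_mult * stats::sd(all_vals)
  lo <- stats::quantile(all_vals, low_pct / 100, names = FALSE)
  keep <- peaks$gfp <= hi & peaks$gfp > lo
  if (!any(keep) && nrow(peaks) > 0L) {
    rlang::warn("all GFP peaks removed by the amplitude criteria")
  }
  peaks[keep, ]
}

#' Extract peak topographies
#'
#' Pulls the instantaneous topography at every retained GFP peak into a
#' `peak_set`: an n_peaks x channels matrix plus provenance (epoch, sample,
#' GFP at peak).
#'
#' @param ep An [eeg_epochs()] (average-referenced).
#' @param peaks Tibble of peak locations (`epoch`, `sample`, `gfp`).
#' @return A `peak_set` object.
#' @export
extract_peaks <- function(ep, peaks) {
  stopifnot(inherits(ep, "eeg_epochs"))
  topo <- matrix(0, nrow = nrow(peaks), ncol = n_channels(ep))
  for (i in seq_len(nrow(peaks))) {
    topo[i, ] <- ep$data[peaks$epoch[i], , peaks$sample[i]]
  }
  topo <- topo - rowMeans(topo)   # enforce average reference per topography
  peak_set(topo, ep$layout$channel, peaks$epoch, peaks$sample, peaks$gfp)
}

#' Peak set constructor
#'
#' @param topographies n_peaks x channels microvolt matrix (zero row means).
#' @param channels Channel names.
#' @param epoch,sample Provenance indices.
#' @param gfp GFP value at each peak.
#' @return A `peak_set` object.
#' @export
peak_set <- function(topographies, channels, epoch = integer(),
                     sample = integer(), gfp = numeric()) {
  topographies <- as.matrix(topographies)
  structure(
    list(topographies = topographies, channels = as.character(channels),
         epoch = epoch, sample = sample, gfp = gfp,
         n_peaks = nrow(topographies)),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak topographies x %d channels\n",
              x$n_peaks, length(x$channels)))
  invisible(x)
}

#' Random subsample of a peak set
#'
#' Uniform subsample without replacement down to `max_n` peaks (identity when
#' the set is already small enough); keeps clustering cost bounded.
#'
#' @param ps A `peak_set`.
#' @param max_n Maximum number of peaks retained (default 100000).
#' @param seed Integer seed.
#' @return A `peak_set` with at most `max_n` peaks.
#' @export
subsample_peaks <- function(ps, max_n = 100000L, seed = 1L) {
  stopifnot(inherits(ps, "peak_set"))
  if (ps$n_peaks <= max_n) return(ps)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  keep <- sort(sample.int(ps$n_peaks, max_n))
  peak_set(ps$topographies[keep, , drop = FALSE], ps$channels,
           ps$epoch[keep], ps$sample[keep], ps$gfp[keep])
}

#' GFP peaks for a whole recording in one call
#'
#' Compute GFP, find and filter the peaks, extract and subsample the
#' topographies.
#'
#' @param ep An [eeg_epochs()].
#' @param min_distance,sd_mult,low_pct,max_n,seed Stage parameters (see the
#'   individual functions).
#' @return A `peak_set`.
#' @export
gfp_peak_set <- function(ep, min_distance = 2L, sd_mult = 1, low_pct = 15,
                         max_n = 100000L, seed = 1L) {
  gfp <- compute_gfp(ep)
  pk <- find_gfp_peaks(gfp, min_distance)
  pk <- filter_gfp_peaks(gfp, pk, sd_mult, low_pct)
  subsample_peaks(extract_peaks(ep, pk), max_n, seed)
}
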