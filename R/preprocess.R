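#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel of a continuous recording. Zero-phase filtering avoids latency
#' shifts that would distort instantaneous topographies.
#'
#' @param raw A [raw_eeg()].
#' @param low,high Band edges in Hz (defaults 0.5 and 45).
#' @param order Butterworth order (default 4).
#' @return A filtered [raw_eeg()].
#' @export
eeg_bandpass <- function(raw, low = 0.5, high = 45, order = 4L) {
  stopifnot(inherits(raw, "raw_eeg"))
  nyq <- raw$sfreq / 2
  if (!(low > 0 && low < high && high < nyq)) {
    rlang::abort("need 0 < low < high < sfreq/2")
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # remove the per-channel mean first: the DC offset is outside the pass band
  # and would otherwise only decay through slow edge transients
  filt <- t(apply(raw$data, 1L, function(ch) {
    signal::filtfilt(bf, ch - mean(ch))
  }))
  raw_eeg(filt, raw$sfreq, raw$layout, raw$events)
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per event, spanning `tmin` to `tmax` seconds around the onset,
#' inclusive of both endpoint samples (at 250 Hz the default window of
#' -0.200 to +1.344 s gives 387 samples). Events whose window falls outside
#' the recording are dropped with a warning.
#'
#' @param raw A [raw_eeg()] with events.
#' @param tmin,tmax Window edges in seconds relative to onset.
#' @return An [eeg_epochs()].
#' @export
eeg_epoch <- function(raw, tmin = -0.200, tmax = 1.344) {
  stopifnot(inherits(raw, "raw_eeg"))
  if (length(raw$events) == 0L) rlang::abort("no events to epoch around")
  if (tmin > 0 || tmax <= tmin) rlang::abort("need tmin <= 0 < tmax - tmin")
  off0 <- round(tmin * raw$sfreq)
  off1 <- round(tmax * raw$sfreq)
  starts <- raw$events + off0
  stops <- raw$events + off1
  ok <- starts >= 1L & stops <= ncol(raw$data)
  if (any(!ok)) {
    rlang::warn(sprintf("dropping %d event(s) whose epoch window leaves the recording",
                        sum(!ok)))
  }
  if (!any(ok)) rlang::abort("no epoch window fits inside the recording")
  len <- off1 - off0 + 1L
  arr <- array(0, dim = c(sum(ok), nrow(raw$data), len))
  idx <- which(ok)
  for (i in seq_along(idx)) {
    arr[i, , ] <- raw$data[, starts[idx[i]]:stops[idx[i]]]
  }
  eeg_epochs(arr, raw$sfreq, tmin = tmin, layout = raw$layout)
}

#' Iterative bad-channel detection
#'
#' Two criteria: (a) channels whose peak absolute voltage exceeds
#' `amp_thresh` microvolts in more than `epoch_frac` of the epochs, computed
#' once on the input; and (b) channels whose voltage variance Z-score —
#' relative to the mean and SD of the variances of the currently good
#' channels — exceeds `z_thresh`, recomputed `n_iter` times, removing freshly
#' flagged channels before each recomputation.
#'
#' @param ep An [eeg_epochs()].
#' @param amp_thresh Amplitude threshold in microvolts (default 100).
#' @param epoch_frac Epoch fraction for criterion (a) (default 0.5).
#' @param z_thresh Variance Z-score threshold (default 4).
#' @param n_iter Z-score iterations (default 4).
#' @param peak_to_peak Use peak-to-peak instead of peak absolute amplitude
#'   for criterion (a) (default FALSE).
#' @return Character vector of bad channel names, with an attribute
#'   `iterations` listing the channels flagged at each stage.
#' @export
detect_bad_channels <- function(ep, amp_thresh = 100, epoch_frac = 0.5,
                                z_thresh = 4, n_iter = 4L,
                                peak_to_peak = FALSE) {
  stopifnot(inherits(ep, "eeg_epochs"))
  chans <- ep$layout$channel
  # (a) amplitude criterion, once on the original data
  extreme <- apply(ep$data, c(1L, 2L), function(v) {
    if (peak_to_peak) diff(range(v)) else max(abs(v))
  })                                       # epochs x channels
  frac_bad <- colMeans(extreme > amp_thresh)
  bad_amp <- chans[frac_bad > epoch_frac]
  iterations <- list(amplitude = bad_amp)
  # (b) variance criterion, iterated
  bad <- bad_amp
  for (it in seq_len(n_iter)) {
    good <- setdiff(chans, bad)
    if (length(good) < 2L) break
    gi <- match(good, chans)
    v <- apply(ep$data[, gi, , drop = FALSE], 2L,
               function(m) stats::var(as.vector(m)))
    z <- (v - mean(v)) / stats::sd(v)
    flagged <- good[!is.na(z) & z > z_thresh]
    iterations[[paste0("variance_", it)]] <- flagged
    bad <- union(bad, flagged)
  }
  if (length(bad) >= length(chans)) {
    rlang::abort("all channels flagged bad: unusable recording")
  }
  structure(bad, iterations = iterations)
}

#' Interpolate bad channels by inverse-distance weighting
#'
#' Each bad channel is replaced, sample by sample, by an inverse-distance-
#' weighted (exponent `p`) average of its `n_neighbors` nearest good
#' channels on the 2-D head-plane layout (ties at the cutoff distance are
#' all included, keeping the neighborhood symmetric on regular montages).
#' A simple, documented surrogate for spline interpolation on a dense net.
#'
#' @param ep An [eeg_epochs()].
#' @param bad Character vector of bad channel names.
#' @param n_neighbors Number of nearest good channels used (default 6).
#' @param p Inverse-distance exponent (default 2).
#' @return An [eeg_epochs()] with bad channels replaced.
#' @export
interpolate_channels <- function(ep, bad, n_neighbors = 6L, p = 2) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (length(bad) == 0L) return(ep)
  chans <- ep$layout$channel
  if (!all(bad %in% chans)) rlang::abort("`bad` contains unknown channels")
  good <- setdiff(chans, bad)
  if (length(good) < 3L) rlang::abort("fewer than 3 good channels to interpolate from")
  dat <- ep$data
  for (b in bad) {
    bi <- match(b, chans)
    gi <- match(good, chans)
    d <- sqrt((ep$layout$x[gi] - ep$layout$x[bi])^2 +
              (ep$layout$y[gi] - ep$layout$y[bi])^2)
    cutoff <- sort(d)[min(n_neighbors, length(gi))]
    ord <- which(d <= cutoff + 1e-12)   # include ties: symmetric on grids
    w <- 1 / pmax(d[ord], 1e-9)^p
    w <- w / sum(w)
    # weighted average across the selected neighbors, all epochs and samples
    acc <- array(0, dim = dim(dat)[c(1L, 3L)])
    for (j in seq_along(ord)) acc <- acc + w[j] * dat[, gi[ord[j]], ]
    dat[, bi, ] <- acc
  }
  eeg_epochs(dat, ep$sfreq, ep$tmin, ep$layout, ep$channel_mask, ep$epoch_mask)
}

#' Reject artifacted epochs
#'
#' An epoch is discarded when more than `chan_frac` of the channels exceed
#' `amp_thresh` microvolts (peak absolute voltage) anywhere in the epoch.
#' When more than half of the epochs are rejected the participant is flagged
#' for exclusion — a report flag, never an error.
#'
#' @param ep An [eeg_epochs()].
#' @param amp_thresh Amplitude threshold in microvolts (default 100).
#' @param chan_frac Channel fraction above which an epoch is bad (default 0.1).
#' @param bad_channels Channels already flagged (informational, stored in the
#'   report).
#' @return A list with `epochs` (retained [eeg_epochs()]) and `report`, a
#'   `qc_report` list: `bad_channels`, `n_bad_epochs`, `n_epochs`,
#'   `participant_excluded`, and the thresholds used.
#' @export
reject_bad_epochs <- function(ep, amp_thresh = 100, chan_frac = 0.1,
                              bad_channels = character()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  extreme <- apply(ep$data, c(1L, 2L), function(v) max(abs(v)))
  frac <- rowMeans(extreme > amp_thresh)
  bad_ep <- frac > chan_frac
  keep <- !bad_ep
  report <- structure(
    list(bad_channels = bad_channels,
         n_bad_epochs = sum(bad_ep),
         n_epochs = length(bad_ep),
         participant_excluded = mean(bad_ep) > 0.5,
         amp_thresh = amp_thresh, chan_frac = chan_frac),
    class = "qc_report"
  )
  epoch_mask <- ep$epoch_mask
  epoch_mask[epoch_mask][bad_ep] <- FALSE
  out <- eeg_epochs(ep$data[keep, , , drop = FALSE], ep$sfreq, ep$tmin,
                    ep$layout, ep$channel_mask, epoch_mask)
  list(epochs = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d bad epochs, %d bad channels, excluded = %s\n",
              x$n_bad_epochs, x$n_epochs, length(x$bad_channels),
              x$participant_excluded))
  invisible(x)
}

#' Drop edge channels and apply the average reference
#'
#' Removes channels flagged as peripheral in the layout, then subtracts the
#' instantaneous mean across the retained channels from every sample, so each
#' topography has zero channel mean. Idempotent.
#'
#' @param ep An [eeg_epochs()].
#' @return An [eeg_epochs()] on the trimmed montage, average-referenced.
#' @export
rereference_and_trim <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  keep <- !ep$layout$edge
  dat <- ep$data[, keep, , drop = FALSE]
  lay <- ep$layout[keep, ]
  class(lay) <- c("sensor_layout", class(tibble::tibble()))
  mu <- apply(dat, c(1L, 3L), mean)          # epochs x samples
  for (ch in seq_len(dim(dat)[2L])) dat[, ch, ] <- dat[, ch, ] - mu
  channel_mask <- ep$channel_mask
  channel_mask[channel_mask][!keep] <- FALSE
  eeg_epochs(dat, ep$sfreq, ep$tmin, lay, channel_mask, ep$epoch_mask)
}

#' Full preprocessing chain
#'
#' Filter, epoch, detect and interpolate bad channels, reject bad epochs,
#' trim edge channels and average-reference — in that fixed order.
#'
#' @param raw A [raw_eeg()] with events.
#' @param low,high Band-pass edges (Hz).
#' @param tmin,tmax Epoch window (s).
#' @param amp_thresh Amplitude threshold (microvolts), used by both the
#'   channel and epoch criteria.
#' @param epoch_frac,z_thresh,n_iter See [detect_bad_channels()].
#' @param chan_frac See [reject_bad_epochs()].
#' @return A list with `epochs` (cleaned [eeg_epochs()]) and `report`
#'   (`qc_report`).
#' @export
preprocess <- function(raw, low = 0.5, high = 45, tmin = -0.200, tmax = 1.344,
                       amp_thresh = 100, epoch_frac = 0.5, z_thresh = 4,
                       n_iter = 4L, chan_frac = 0.1) {
  raw |>
    eeg_bandpass(low, high) |>
    eeg_epoch(tmin, tmax) -> ep
  bad <- detect_bad_channels(ep, amp_thresh, epoch_frac, z_thresh, n_iter)
  ep <- interpolate_channels(ep, bad)
  rej <- reject_bad_epochs(ep, amp_thresh, chan_frac, bad_channels = bad)
  list(epochs = rereference_and_trim(rej$epochs), report = rej$report)
}
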