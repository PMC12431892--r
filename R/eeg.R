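#' Continuous multichannel EEG
#'
#' Container for a continuous recording: a channels x samples voltage matrix
#' (microvolts), its sampling rate, the sensor layout, and stimulus onset
#' events used for epoching.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sfreq Sampling rate in Hz.
#' @param layout A [sensor_layout()] with one row per data row.
#' @param events Integer sample indices (1-based) of stimulus onsets.
#'
#' @return An object of class `raw_eeg`.
#' @export
raw_eeg <- function(data, sfreq, layout, events = integer()) {
  data <- as.matrix(data)
  assert_layout(layout)
  if (nrow(data) != nrow(layout)) {
    rlang::abort("`data` must have one row per layout channel")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    rlang::abort("`sfreq` must be a positive scalar (Hz)")
  }
  if (!all(is.finite(data))) rlang::abort("`data` must be finite")
  events <- as.integer(events)
  if (length(events) && (min(events) < 1L || max(events) > ncol(data))) {
    rlang::abort("`events` must lie within the recording")
  }
  structure(list(data = data, sfreq = sfreq, layout = layout, events = events),
            class = "raw_eeg")
}

#' Epoched multichannel EEG
#'
#' Container for epoched voltages: an epochs x channels x samples array in
#' microvolts, the sampling rate, the epoch start time relative to stimulus
#' onset, and the sensor layout. `channel_mask` / `epoch_mask` record which of
#' the original channels and epochs survive preprocessing.
#'
#' @param data Numeric array, epochs x channels x samples (microvolts).
#' @param sfreq Sampling rate in Hz.
#' @param tmin Epoch start in seconds relative to onset (<= 0).
#' @param layout A [sensor_layout()] describing the channel dimension.
#' @param channel_mask,epoch_mask Logical vectors over the *original*
#'   channels / epochs; defaults mark everything retained.
#'
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, sfreq, tmin = 0, layout,
                       channel_mask = NULL, epoch_mask = NULL) {
  if (length(dim(data)) != 3L) {
    rlang::abort("`data` must be an epochs x channels x samples array")
  }
  assert_layout(layout)
  if (dim(data)[2L] != nrow(layout)) {
    rlang::abort("channel dimension must match the layout")
  }
  if (tmin > 0) rlang::abort("`tmin` must be <= 0 (pre-stimulus start)")
  channel_mask <- channel_mask %||% rep(TRUE, nrow(layout))
  epoch_mask <- epoch_mask %||% rep(TRUE, dim(data)[1L])
  if (sum(channel_mask) != dim(data)[2L] && length(channel_mask) != dim(data)[2L]) {
    rlang::abort("`channel_mask` inconsistent with the channel dimension")
  }
  structure(
    list(data = data, sfreq = sfreq, tmin = tmin, layout = layout,
         channel_mask = channel_mask, epoch_mask = epoch_mask),
    class = "eeg_epochs"
  )
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq, length(x$events)))
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (tmin = %g s)\n",
              d[1L], d[2L], d[3L], x$sfreq, x$tmin))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[1L]
n_channels <- function(ep) dim(ep$data)[2L]
n_samples <- function(ep) dim(ep$data)[3L]

# stack epochs into a (epochs*samples) x channels matrix, samples within an
# epoch contiguous; inverse of the epoch reshape used by the simulator
stack_epochs <- function(ep) {
  d <- dim(ep$data)
  m <- matrix(aperm(ep$data, c(3L, 1L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
  m
}
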