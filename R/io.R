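#' Write epoched EEG to the plain-matrix interchange format
#'
#' Writes `<prefix>.csv`, a long table (`epoch`, `sample`, `channel`,
#' `value`), and `<prefix>.json`, a sidecar with the sampling rate, epoch
#' start time, and sensor layout. A deliberately simple, text-only format
#' every tool can read.
#'
#' @param ep An [eeg_epochs()].
#' @param prefix Path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_epochs <- function(ep, prefix) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  long <- data.frame(
    epoch = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    channel = rep(rep(ep$layout$channel, each = d[1L]), times = d[3L]),
    sample = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value = as.vector(ep$data)
  )
  utils::write.csv(long, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(sfreq = ep$sfreq, tmin = ep$tmin,
               n_epochs = d[1L], n_channels = d[2L], n_samples = d[3L],
               layout = as.data.frame(ep$layout))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read epoched EEG from the plain-matrix interchange format
#'
#' @param prefix Path prefix used by [write_epochs()].
#' @return An [eeg_epochs()].
#' @export
read_epochs <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(js)) {
    rlang::abort(sprintf("missing epochs file(s) at prefix '%s'", prefix))
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  long <- utils::read.csv(csv)
  lay <- sensor_layout(meta$layout$channel, meta$layout$x, meta$layout$y,
                       meta$layout$edge)
  arr <- array(0, dim = c(meta$n_epochs, meta$n_channels, meta$n_samples))
  ci <- match(long$channel, lay$channel)
  arr[cbind(long$epoch, ci, long$sample)] <- long$value
  eeg_epochs(arr, meta$sfreq, meta$tmin, lay)
}

#' Write a map set as CSV
#'
#' Channels in rows, one column per map (plus a `channel` column), so the
#' file opens cleanly in any table tool.
#'
#' @param ms A [mapset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mapset <- function(ms, path) {
  stopifnot(inherits(ms, "mapset"))
  labs <- ms$canonical_labels %||% paste0("map_", seq_len(ms$k))
  df <- data.frame(channel = ms$channels, t(ms$maps))
  names(df)[-1L] <- labs
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a map set written by [write_mapset()]
#'
#' @param path CSV path.
#' @return A [mapset()].
#' @export
read_mapset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  maps <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(maps) <- df$channel
  mapset(maps, channels = df$channel,
         canonical_labels = rownames(maps))
}

#' Write a segmentation as long-format CSV
#'
#' @param seg A `segmentation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  d <- dim(seg$labels)
  long <- data.frame(epoch = rep(seq_len(d[1L]), times = d[2L]),
                     sample = rep(seq_len(d[2L]), each = d[1L]),
                     label = as.vector(seg$labels))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
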