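#' Sensor layout
#'
#' A sensor layout is a tibble with one row per channel: a channel name, 2-D
#' head-plane coordinates (unitless projection, nose up along +y), and a flag
#' marking peripheral ("edge") sensors that are removed before average
#' referencing.
#'
#' @param channel Character vector of channel names (unique).
#' @param x,y Numeric head-plane coordinates, one per channel.
#' @param edge Logical vector marking peripheral channels.
#'
#' @return A tibble of class `sensor_layout` with columns `channel`, `x`, `y`,
#'   `edge`.
#' @export
#' @examples
#' sensor_layout(paste0("ch", 1:8), x = cos(1:8), y = sin(1:8),
#'               edge = rep(FALSE, 8))
sensor_layout <- function(channel, x, y, edge = rep(FALSE, length(channel))) {
  channel <- as.character(channel)
  n <- length(channel)
  if (n < 8L) {
    rlang::abort("a sensor layout needs at least 8 channels")
  }
  if (anyDuplicated(channel)) {
    rlang::abort("channel names must be unique")
  }
  if (length(x) != n || length(y) != n || length(edge) != n) {
    rlang::abort("`x`, `y` and `edge` must have one entry per channel")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    rlang::abort("sensor positions must be finite")
  }
  out <- tibble::tibble(channel = channel, x = as.numeric(x),
                        y = as.numeric(y), edge = as.logical(edge))
  class(out) <- c("sensor_layout", class(out))
  out
}

#' Regular grid montage on the head plane
#'
#' Places `n_channels` sensors on a near-square grid spanning the head plane,
#' centred on the origin with coordinates in \[-1, 1\]. Channels on the outer
#' border of the grid are flagged as edge channels, mimicking the peripheral
#' ring of a high-density net that carries face/neck artifact and is trimmed
#' before analysis.
#'
#' @param n_channels Number of sensors; must be a perfect square >= 9
#'   (default 64, an 8 x 8 grid).
#'
#' @return A [sensor_layout()] tibble.
#' @export
#' @examples
#' lay <- grid_layout(64)
#' sum(lay$edge)  # 28 border channels on an 8 x 8 grid
grid_layout <- function(n_channels = 64) {
  side <- sqrt(n_channels)
  if (side != floor(side) || n_channels < 9) {
    rlang::abort("`n_channels` must be a perfect square >= 9")
  }
  side <- as.integer(side)
  coords <- seq(-1, 1, length.out = side)
  grid <- expand.grid(x = coords, y = coords)
  border <- grid$x %in% range(coords) | grid$y %in% range(coords)
  sensor_layout(
    channel = sprintf("E%03d", seq_len(n_channels)),
    x = grid$x, y = grid$y, edge = border
  )
}

assert_layout <- function(layout) {
  if (!inherits(layout, "sensor_layout")) {
    rlang::abort("`layout` must be a `sensor_layout` (see `sensor_layout()`)")
  }
  invisible(layout)
}
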