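#' Microstate map set
#'
#' A `mapset` holds k microstate topographies as a k x channels matrix. Each
#' map is average-referenced (zero channel mean) and unit-norm; the overall
#' sign is a display convention only — every operation in the package treats a
#' map and its negation as the same class (polarity invariance).
#'
#' @param maps Numeric matrix, k x channels; rows are topographies.
#' @param channels Character vector of channel names (defaults to the matrix
#'   column names).
#' @param canonical_labels Optional character vector of per-map labels
#'   (e.g. "A".."D") set by [order_canonical()].
#' @param gev_train Global explained variance of the training peak set, if the
#'   maps come from clustering.
#'
#' @return An object of class `mapset`.
#' @export
mapset <- function(maps, channels = colnames(maps), canonical_labels = NULL,
                   gev_train = NA_real_) {
  maps <- as.matrix(maps)
  if (is.null(channels)) channels <- sprintf("ch%03d", seq_len(ncol(maps)))
  maps <- normalize_maps(maps)
  dimnames(maps) <- list(NULL, channels)
  structure(
    list(maps = maps, k = nrow(maps), channels = channels,
         canonical_labels = canonical_labels, gev_train = gev_train),
    class = "mapset"
  )
}

# zero-mean each row, scale to unit norm, fix sign so the channel with the
# largest absolute loading is positive
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < 1e-12)) {
    rlang::abort("a topography is zero after average referencing")
  }
  maps <- maps / nrm
  sgn <- apply(maps, 1L, function(m) sign(m[which.max(abs(m))]))
  maps * sgn
}

#' @export
print.mapset <- function(x, ...) {
  lab <- if (is.null(x$canonical_labels)) "" else
    paste0(" [", paste(x$canonical_labels, collapse = ""), "]")
  cat(sprintf("<mapset> %d maps x %d channels%s, training GEV = %s\n",
              x$k, length(x$channels), lab,
              ifelse(is.na(x$gev_train), "NA", sprintf("%.3f", x$gev_train))))
  invisible(x)
}

#' Pairwise polarity-invariant spatial correlation
#'
#' Pearson correlation across channels between two topographies (or between
#' the rows of two map matrices), taken in absolute value so that a map and
#' its polarity flip are maximally similar.
#'
#' @param a,b Numeric vectors (single topographies), matrices with maps in
#'   rows, or `mapset` objects.
#' @return A matrix of absolute spatial correlations (rows of `a` x rows of
#'   `b`), or a scalar when both inputs are vectors.
#' @export
spatial_correlation <- function(a, b) {
  scalar <- is.vector(a) && is.vector(b)
  A <- as_map_matrix(a)
  B <- as_map_matrix(b)
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  A <- A / sqrt(rowSums(A^2))
  B <- B / sqrt(rowSums(B^2))
  out <- abs(tcrossprod(A, B))
  if (scalar) out[1L, 1L] else out
}

as_map_matrix <- function(x) {
  if (inherits(x, "mapset")) return(x$maps)
  if (is.vector(x)) return(matrix(as.numeric(x), nrow = 1L))
  as.matrix(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a map set into a long tibble
#'
#' @param x A `mapset`.
#' @param layout Optional [sensor_layout()]; when supplied, sensor coordinates
#'   are joined in for plotting.
#' @param ... Unused.
#' @return A tibble with columns `map`, `channel`, `value` (and `x`, `y` when
#'   a layout is given).
#' @export
tidy.mapset <- function(x, layout = NULL, ...) {
  lab <- x$canonical_labels %||% as.character(seq_len(x$k))
  out <- tibble::tibble(
    map = rep(lab, each = length(x$channels)),
    channel = rep(x$channels, times = x$k),
    value = as.vector(t(x$maps))
  )
  if (!is.null(layout)) {
    out <- dplyr::left_join(out, layout, by = "channel")
  }
  out
}

#' One-row summary of a map set
#'
#' @param x A `mapset`.
#' @param ... Unused.
#' @return A tibble with `k`, `n_channels`, `gev_train`.
#' @export
glance.mapset <- function(x, ...) {
  tibble::tibble(k = x$k, n_channels = length(x$channels),
                 gev_train = x$gev_train)
}
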