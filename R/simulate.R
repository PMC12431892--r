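#' Generate planted microstate topographies
#'
#' Builds k zero-mean, unit-norm topographies over a sensor layout. The first
#' four follow the canonical microstate shapes: two oblique left-right /
#' right-left dipolar gradients (maps A and B), an anterior-posterior gradient
#' (map C), and a frontocentral Gaussian maximum (map D). Maps beyond four are
#' smooth random fields. A seeded smooth perturbation is blended into every
#' map so that different seeds give different (but equally canonical-looking)
#' map sets. All pairwise absolute spatial correlations are guaranteed below
#' `max_corr`.
#'
#' @param layout A [sensor_layout()].
#' @param k Number of maps (>= 2, at most the channel count).
#' @param seed Integer seed.
#' @param perturbation Relative amplitude of the seeded smooth perturbation
#'   blended into each canonical base shape (0 disables it).
#' @param max_corr Upper bound on pairwise absolute spatial correlation.
#'
#' @return A [mapset()] with canonical labels `A`, `B`, ... where applicable.
#' @export
#' @examples
#' maps <- make_topographies(grid_layout(64), k = 4, seed = 1)
#' max(spatial_correlation(maps, maps)[upper.tri(diag(4))])  # < 0.8
make_topographies <- function(layout, k, seed = 1L, perturbation = 0.25,
                              max_corr = 0.8) {
  assert_layout(layout)
  if (k < 2L) rlang::abort("`k` must be at least 2")
  if (k > nrow(layout)) rlang::abort("`k` cannot exceed the channel count")
  x <- layout$x
  y <- layout$y
  # oblique dipolar axes at ~31 degrees: keeps the A/B pair and the
  # anterior-posterior map clearly separable (pairwise |corr| ~ 0.5) while
  # preserving the canonical left-right / right-left orientations
  bases <- list(
    (x + 0.6 * y),                               # A: oblique left-right
    (x - 0.6 * y),                               # B: oblique right-left
    y,                                           # C: anterior-posterior
    exp(-((x - 0)^2 + (y - 0.4)^2) / (2 * 0.35^2))  # D: frontocentral max
  )
  set.seed(as.integer(seed) %% .Machine$integer.max)
  smooth_field <- function() {
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    kern <- exp(-d2 / (2 * 0.4^2))
    drop(kern %*% stats::rnorm(length(x)))
  }
  for (attempt in 1:50) {
    maps <- matrix(0, nrow = k, ncol = nrow(layout))
    for (i in seq_len(k)) {
      base <- if (i <= 4L) bases[[i]] else smooth_field()
      base <- unit_map(base)
      if (perturbation > 0) {
        pert <- unit_map(smooth_field())
        base <- unit_map(base + perturbation * pert)
      }
      maps[i, ] <- base
    }
    cors <- spatial_correlation(maps, maps)
    if (k == 1L || max(cors[upper.tri(cors)]) < max_corr) {
      labels <- c("A", "B", "C", "D", LETTERS[5:26])[seq_len(k)]
      return(mapset(maps, channels = layout$channel, canonical_labels = labels))
    }
  }
  rlang::abort("could not draw maps satisfying the pairwise correlation bound")
}

unit_map <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Stationary distribution of a transition matrix
#'
#' @param P A row-stochastic k x k matrix.
#' @return A probability vector pi with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  P <- validate_transition_probs(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

validate_transition_probs <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) rlang::abort("`P` must be square")
  if (any(P < -1e-12)) rlang::abort("`P` must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    rlang::abort("`P` rows must each sum to 1 (row-stochastic)")
  }
  P
}

#' Simulate a first-order Markov label sequence
#'
#' Draws `n_samples` states from the chain defined by `P`, starting from the
#' stationary distribution, so that the empirical coverage and transition
#' frequencies converge to their planted values.
#'
#' @param P Row-stochastic k x k transition matrix (rows = source state).
#' @param n_samples Sequence length (>= 1).
#' @param seed Integer seed.
#' @return An integer vector of states in `1..k`.
#' @export
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
#' s <- sample_state_sequence(P, 1000, seed = 7)
sample_state_sequence <- function(P, n_samples, seed = 1L) {
  P <- validate_transition_probs(P)
  if (n_samples < 1L) rlang::abort("`n_samples` must be >= 1")
  k <- nrow(P)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pi0 <- stationary_distribution(P)
  cum <- t(apply(P, 1L, cumsum))
  out <- integer(n_samples)
  out[1L] <- findInterval(stats::runif(1L), cumsum(pi0)) + 1L
  u <- stats::runif(n_samples)
  for (t in seq_len(n_samples - 1L)) {
    out[t + 1L] <- findInterval(u[t], cum[out[t], ]) + 1L
  }
  pmin(out, k)
}

#' Synthesize epoched EEG with planted microstate structure
#'
#' Builds `signal(t) = amplitude * sin(2 pi osc_freq t) * map(label(t)) +
#' noise`: the active topography is scaled by a signed oscillatory envelope,
#' so global field power peaks at the envelope extrema and the instantaneous
#' polarity alternates with the sine sign — exactly the structure
#' polarity-invariant clustering must cope with. Gaussian sensor noise is
#' added and the continuous signal is cut into fixed-length epochs.
#'
#' @param maps A [mapset()] with the planted topographies.
#' @param labels Integer state sequence in `1..k`, e.g. from
#'   [sample_state_sequence()]; its length must be a multiple of `epoch_len`.
#' @param sfreq Sampling rate (Hz).
#' @param osc_freq Envelope oscillation frequency (Hz), below Nyquist.
#' @param amplitude Envelope amplitude (microvolts).
#' @param noise_sd Sensor noise standard deviation (microvolts).
#' @param epoch_len Epoch length in samples.
#' @param seed Integer seed (noise only).
#' @param layout Optional [sensor_layout()]; defaults to a grid layout sized
#'   to the map channel count when the map channels look like grid channels.
#' @param P Optional planted transition matrix, recorded in the ground truth.
#'
#' @return A list with components `epochs` (an [eeg_epochs()]) and `truth`
#'   (a `ground_truth` object recording maps, labels, transition matrix,
#'   mean duration, noise level and seed).
#' @export
synthesize_eeg <- function(maps, labels, sfreq = 250, osc_freq = 10,
                           amplitude = 10, noise_sd = 1, epoch_len = 375,
                           seed = 1L, layout = NULL, P = NULL) {
  stopifnot(inherits(maps, "mapset"))
  n <- length(labels)
  if (n %% epoch_len != 0) {
    rlang::abort("`length(labels)` must be divisible by `epoch_len`")
  }
  if (osc_freq >= sfreq / 2) rlang::abort("`osc_freq` must be below Nyquist")
  if (amplitude == 0 && noise_sd == 0) {
    rlang::abort("degenerate all-zero signal: amplitude and noise_sd both 0")
  }
  if (min(labels) < 1L || max(labels) > maps$k) {
    rlang::abort("labels must lie in 1..k")
  }
  if (is.null(layout)) {
    nc <- length(maps$channels)
    layout <- sensor_layout(maps$channels,
                            x = rep(seq_len(ceiling(sqrt(nc))), length.out = nc),
                            y = rep(seq_len(ceiling(sqrt(nc))), each = ceiling(sqrt(nc)))[seq_len(nc)])
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env <- amplitude * sin(2 * pi * osc_freq * (seq_len(n) - 1L) / sfreq)
  X <- maps$maps[labels, , drop = FALSE] * env
  if (noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow = n)
  }
  n_ep <- n %/% epoch_len
  # rows of X are samples (epoch-contiguous); reshape to [epoch, channel, sample]
  arr <- aperm(array(t(X), dim = c(ncol(X), epoch_len, n_ep)), c(3L, 1L, 2L))
  ep <- eeg_epochs(arr, sfreq = sfreq, tmin = 0, layout = layout)
  truth <- structure(
    list(
      true_maps = maps,
      true_labels = matrix(labels, nrow = n_ep, ncol = epoch_len, byrow = TRUE),
      true_transition_matrix = P,
      true_mean_duration_ms = planted_mean_duration(labels, P, sfreq),
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "ground_truth"
  )
  list(epochs = ep, truth = truth)
}

# expected visit length under the planted chain (ms); empirical when P absent
planted_mean_duration <- function(labels, P, sfreq) {
  if (!is.null(P)) {
    pi0 <- stationary_distribution(P)
    leave <- 1 - diag(P)
    if (all(leave == 0)) return(Inf)
    (sum(pi0) / sum(pi0 * leave)) * 1000 / sfreq
  } else {
    r <- rle(labels)
    mean(r$lengths) * 1000 / sfreq
  }
}

#' Simulate one participant end to end
#'
#' Convenience wrapper: planted maps (shared or per-participant), a planted
#' Markov chain, and synthesized epoched EEG.
#'
#' @param layout A [sensor_layout()].
#' @param P Planted transition matrix (k inferred from it).
#' @param n_epochs Number of epochs.
#' @param epoch_len Samples per epoch.
#' @param sfreq,osc_freq,amplitude,noise_sd See [synthesize_eeg()].
#' @param maps Optional [mapset()]; drawn via [make_topographies()] when NULL.
#' @param seed Integer seed.
#' @return As [synthesize_eeg()].
#' @export
simulate_participant <- function(layout, P, n_epochs = 40, epoch_len = 375,
                                 sfreq = 250, osc_freq = 10, amplitude = 10,
                                 noise_sd = 2, maps = NULL, seed = 1L) {
  k <- nrow(P)
  if (is.null(maps)) maps <- make_topographies(layout, k, seed = seed)
  labels <- sample_state_sequence(P, n_epochs * epoch_len, seed = seed + 1L)
  synthesize_eeg(maps, labels, sfreq = sfreq, osc_freq = osc_freq,
                 amplitude = amplitude, noise_sd = noise_sd,
                 epoch_len = epoch_len, seed = seed + 2L, layout = layout,
                 P = P)
}
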