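#' Map coverage
#'
#' Fraction of all labeled samples, pooled over epochs, spent in each map.
#'
#' @param seg A `segmentation`.
#' @return A numeric k-vector summing to 1.
#' @export
coverage <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  tab <- tabulate(as.vector(seg$labels), nbins = seg$k)
  tab / sum(tab)
}

#' Shannon entropy of the coverage distribution
#'
#' `-sum(c_i * ln(c_i))` in nats, with `0 * ln 0 = 0`; ranges from 0 (one map
#' dominates completely) to `ln k` (uniform occupancy). Summarizes how
#' balanced map occupancy is.
#'
#' @param cov A probability vector (sums to 1).
#' @return Entropy in nats.
#' @export
coverage_entropy <- function(cov) {
  if (any(cov < 0)) rlang::abort("coverage entries must be non-negative")
  if (abs(sum(cov) - 1) > 1e-6) rlang::abort("coverage must sum to 1")
  nz <- cov[cov > 0]
  -sum(nz * log(nz))
}

#' Global explained variance of a segmentation
#'
#' GEV weights the squared spatial correlation between each sample and its
#' assigned map by that sample's share of the total squared GFP:
#' `gev_total = sum_t GFP_t^2 corr(v_t, map_{L_t})^2 / sum_t GFP_t^2`.
#' The per-map values restrict the numerator to samples assigned to that map
#' (same denominator), so they sum to the total.
#'
#' @param ep An [eeg_epochs()].
#' @param seg The `segmentation` of `ep`.
#' @param ms The [mapset()] used.
#' @return A list with `gev_per_map` (k-vector) and `gev_total`.
#' @export
gev <- function(ep, seg, ms) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(seg, "segmentation"),
            inherits(ms, "mapset"))
  V <- stack_epochs(ep)
  V <- V - rowMeans(V)
  norm2 <- rowSums(V^2)
  if (sum(norm2) < 1e-30) rlang::abort("zero total GFP")
  L <- as.vector(t(seg$labels))          # sample-major, matching stack order
  A <- V %*% t(ms$maps)
  a2 <- A[cbind(seq_along(L), L)]^2      # gfp^2 * corr^2 (up to 1/nch)
  a2[norm2 < 1e-30] <- 0
  denom <- sum(norm2)
  per_map <- vapply(seq_len(ms$k),
                    function(c) sum(a2[L == c]) / denom, numeric(1))
  list(gev_per_map = per_map, gev_total = sum(per_map))
}

#' Microstate run durations
#'
#' Maximal constant-label runs within each epoch; a run's duration is its
#' length in samples times `1000 / sfreq` ms. Runs never span epoch
#' boundaries, and runs truncated by an epoch edge are included.
#'
#' @param seg A `segmentation`.
#' @return A tibble with columns `epoch`, `map`, `n_samples`, `duration_ms`.
#' @export
run_durations <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  per_epoch <- lapply(seq_len(nrow(seg$labels)), function(e) {
    r <- rle(seg$labels[e, ])
    tibble::tibble(epoch = e, map = r$values, n_samples = r$lengths,
                   duration_ms = r$lengths * 1000 / seg$sfreq)
  })
  dplyr::bind_rows(per_epoch)
}

#' Mean microstate duration and duration variance
#'
#' Mean (MMD, ms) and population variance (MDV, ms^2) of all run durations
#' pooled over maps, plus per-map variants.
#'
#' @param durs A tibble from [run_durations()].
#' @return A list with `mmd`, `mdv` (NA with a warning when fewer than two
#'   runs exist), and `per_map`, a tibble of per-map mean/variance/count.
#' @export
mmd_mdv <- function(durs) {
  d <- durs$duration_ms
  pop_var <- function(x) if (length(x) < 2L) NA_real_ else
    mean((x - mean(x))^2)
  if (length(d) < 2L) {
    rlang::warn("fewer than 2 runs: duration variance undefined")
  }
  per_map <- durs |>
    dplyr::group_by(.data$map) |>
    dplyr::summarise(mmd = mean(.data$duration_ms),
                     mdv = pop_var(.data$duration_ms),
                     n_runs = dplyr::n(), .groups = "drop")
  list(mmd = mean(d), mdv = pop_var(d), per_map = per_map)
}

#' Transition matrix of a segmentation
#'
#' Counts consecutive-sample label pairs within epochs (never across epoch
#' boundaries) and normalizes each row to probabilities. With
#' `include_self = TRUE` (default) self-transitions stay on the diagonal,
#' matching sample-wise counting; with `FALSE` only label changes are
#' counted (rows condition on leaving the state).
#'
#' @param seg A `segmentation` (>= 2 samples per epoch).
#' @param include_self Keep self-transitions (default TRUE).
#' @return A `transition_matrix`: list with `P` (row-stochastic k x k;
#'   all-zero rows are left at 0 and listed in `undefined_rows`), `counts`,
#'   `include_self`.
#' @export
transition_matrix <- function(seg, include_self = TRUE) {
  stopifnot(inherits(seg, "segmentation"))
  if (ncol(seg$labels) < 2L) rlang::abort("need >= 2 samples per epoch")
  k <- seg$k
  counts <- matrix(0L, k, k)
  for (e in seq_len(nrow(seg$labels))) {
    l <- seg$labels[e, ]
    from <- l[-length(l)]
    to <- l[-1L]
    counts <- counts + as.matrix(table(factor(from, levels = 1:k),
                                       factor(to, levels = 1:k)))
  }
  if (!include_self) diag(counts) <- 0L
  dimnames(counts) <- NULL
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  structure(list(P = P, counts = counts, include_self = include_self,
                 undefined_rows = which(rs == 0)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d states, %s self-transitions, %d transitions\n",
              nrow(x$P), ifelse(x$include_self, "with", "without"),
              sum(x$counts)))
  print(round(x$P, 3))
  invisible(x)
}

#' Tidy a transition matrix
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `count`, `prob`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  k <- nrow(x$P)
  tibble::tibble(
    from = rep(seq_len(k), each = k),
    to = rep(seq_len(k), times = k),
    count = as.vector(t(x$counts)),
    prob = as.vector(t(x$P))
  )
}

#' Entropy production of a transition matrix
#'
#' `EP = sum_ij P_ij ln(P_ij / P_ji)`, a Kullback-Leibler measure of broken
#' detailed balance: zero iff the matrix is symmetric on its support
#' (time-reversible dynamics), positive when transition probabilities are
#' asymmetric. Diagonal terms cancel. Pairs with `P_ij > 0` but `P_ji = 0`
#' would make the sum infinite under the plug-in estimate; they are excluded
#' and counted in the `irreversible_pairs` attribute with a warning, unless
#' `regularize = TRUE`, which adds one pseudo-count spread over all cells
#' (`1/total` per cell) before normalizing.
#'
#' @param tm A `transition_matrix`, or a row-stochastic matrix.
#' @param regularize Add a uniform pseudo-count to the counts before
#'   computing EP (only for `transition_matrix` inputs with counts).
#' @return Entropy production in nats (>= 0); attribute `irreversible_pairs`
#'   gives the number of excluded one-sided pairs.
#' @export
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
#' entropy_production(P)  # 0.2 * log(3)
entropy_production <- function(tm, regularize = FALSE) {
  if (inherits(tm, "transition_matrix")) {
    if (regularize) {
      counts <- tm$counts + 1 / sum(tm$counts)
      P <- counts / rowSums(counts)
    } else {
      P <- tm$P
    }
  } else {
    P <- validate_transition_probs(tm)
  }
  k <- nrow(P)
  ep <- 0
  excluded <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (P[i, j] > 0 && P[j, i] > 0) {
        ep <- ep + P[i, j] * log(P[i, j] / P[j, i])
      } else if (P[i, j] > 0) {
        excluded <- excluded + 1L
      }
    }
  }
  if (excluded > 0L) {
    rlang::warn(sprintf("%d one-sided (irreversible) pair(s) excluded from EP",
                        excluded))
  }
  structure(max(ep, 0), irreversible_pairs = excluded)
}

#' All microstate markers for one participant
#'
#' Computes the full marker record from a segmentation: per-map coverage and
#' its entropy, per-map and total GEV, mean microstate duration, duration
#' variance, and entropy production — one tidy row, ready to bind into a
#' cohort table.
#'
#' @param ep The [eeg_epochs()] the segmentation was fitted to.
#' @param seg A `segmentation`.
#' @param ms The [mapset()] used.
#' @param participant Optional participant identifier.
#' @param group Optional group label.
#' @param include_self Passed to [transition_matrix()].
#' @return A one-row tibble with columns `participant`, `group`,
#'   `coverage_1..k`, `coverage_entropy`, `gev_1..k`, `gev_total`, `mmd`,
#'   `mdv`, `ep`, `n_runs`.
#' @export
microstate_markers <- function(ep, seg, ms, participant = NA_character_,
                               group = NA_character_, include_self = TRUE) {
  cov <- coverage(seg)
  g <- gev(ep, seg, ms)
  durs <- run_durations(seg)
  md <- mmd_mdv(durs)
  tm <- transition_matrix(seg, include_self = include_self)
  epv <- suppressWarnings(as.numeric(entropy_production(tm)))
  row <- tibble::tibble(participant = participant, group = group)
  for (i in seq_len(seg$k)) row[[paste0("coverage_", i)]] <- cov[i]
  row$coverage_entropy <- coverage_entropy(cov)
  for (i in seq_len(seg$k)) row[[paste0("gev_", i)]] <- g$gev_per_map[i]
  row$gev_total <- g$gev_total
  row$mmd <- md$mmd
  row$mdv <- md$mdv
  row$ep <- epv
  row$n_runs <- nrow(durs)
  row
}
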