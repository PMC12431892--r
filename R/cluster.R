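#' Polarity-invariant modified k-means
#'
#' Clusters peak topographies into k microstate maps. Unlike ordinary
#' k-means, assignment uses the *squared* spatial correlation, so a
#' topography and its polarity flip land in the same class, and each
#' prototype is updated as the dominant eigenvector (first principal axis) of
#' the outer-product sum of its assigned topographies. The algorithm is
#' restarted `n_init` times from random topographies and the restart with the
#' highest global explained variance (GEV) on the peak set wins.
#'
#' @param ps A `peak_set`, or a numeric matrix with topographies in rows.
#' @param k Number of maps.
#' @param n_init Number of random restarts (default 100).
#' @param max_iter Maximum iterations per restart (default 300).
#' @param tol Relative residual-variance change below which a restart stops
#'   (default 1e-6).
#' @param seed Integer seed.
#' @param keep_all Also return the GEV of every restart (for diagnostics).
#' @return A [mapset()] with `gev_train` set; when `keep_all = TRUE`, an
#'   attribute `restart_gev` carries all restart GEVs.
#' @export
mod_kmeans <- function(ps, k, n_init = 100L, max_iter = 300L, tol = 1e-6,
                       seed = 1L, keep_all = FALSE) {
  X <- if (inherits(ps, "peak_set")) ps$topographies else as.matrix(ps)
  channels <- if (inherits(ps, "peak_set")) ps$channels else colnames(ps)
  n <- nrow(X)
  if (n < k) rlang::abort("need at least k peak topographies")
  X <- X - rowMeans(X)
  norm2 <- rowSums(X^2)
  keep_rows <- norm2 > 1e-18
  X <- X[keep_rows, , drop = FALSE]
  norm2 <- norm2[keep_rows]
  n <- nrow(X)
  total_ss <- sum(norm2)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  best <- NULL
  best_gev <- -Inf
  all_gev <- numeric(n_init)
  for (r in seq_len(n_init)) {
    M <- X[sample.int(n, k), , drop = FALSE]
    M <- M / sqrt(rowSums(M^2))
    prev_res <- Inf
    for (it in seq_len(max_iter)) {
      A <- X %*% t(M)                       # n x k activations
      L <- max.col(A * A, ties.method = "first")
      expl <- A[cbind(seq_len(n), L)]^2
      res <- (total_ss - sum(expl)) / n
      for (c in seq_len(k)) {
        rows <- which(L == c)
        if (!length(rows)) {                # empty cluster: re-seed
          j <- sample.int(n, 1L)
          M[c, ] <- X[j, ] / sqrt(norm2[j])
          next
        }
        S <- crossprod(X[rows, , drop = FALSE])
        M[c, ] <- dominant_eigenvector(S, M[c, ])
      }
      if (is.finite(prev_res) &&
          abs(prev_res - res) <= tol * max(prev_res, 1e-30)) break
      prev_res <- res
    }
    A <- X %*% t(M)
    L <- max.col(A * A, ties.method = "first")
    gev <- sum(A[cbind(seq_len(n), L)]^2) / total_ss
    all_gev[r] <- gev
    if (gev > best_gev) {
      best_gev <- gev
      best <- M
    }
  }
  out <- mapset(best, channels = channels, gev_train = best_gev)
  if (keep_all) attr(out, "restart_gev") <- all_gev
  out
}

# power iteration for the leading eigenvector of a symmetric PSD matrix,
# warm-started at the current prototype
dominant_eigenvector <- function(S, v0) {
  v <- v0
  for (i in 1:100) {
    w <- drop(S %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-30) return(v0)
    w <- w / nw
    if (sum(abs(w - v)) < 1e-12 || sum(abs(w + v)) < 1e-12) {
      v <- w
      break
    }
    v <- w
  }
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Three-level bootstrap group clustering
#'
#' Stage 1 clusters every participant's peak set into `k1` maps. Stage 2
#' repeats `n_boot` times: draw `boot_size` participants with replacement
#' (from every group separately when `per_group = TRUE`, balancing unequal
#' group sizes; from the pooled cohort otherwise), pool their stage-1 maps
#' and cluster them into `k2` maps. Stage 3 clusters the resulting
#' `k2 * n_boot` maps into the final `k2` group maps.
#'
#' @param participant_peaks Named list of `peak_set`s, one per participant.
#' @param groups Character/factor vector of group membership, parallel to
#'   `participant_peaks`.
#' @param k1 Participant-level map count (default 10).
#' @param k2 Final map count (default 4).
#' @param n_boot Bootstrap iterations (default 2000).
#' @param boot_size Participants drawn per group per iteration; defaults to
#'   the smallest group size.
#' @param per_group Draw the bootstrap sample from every group separately
#'   (default TRUE).
#' @param n_init1,n_init2,n_init3 Restarts for the three stages (defaults
#'   20, 20, 100).
#' @param seed Integer seed.
#' @return A [mapset()] of the final `k2` maps; attribute `stage2_maps`
#'   holds the `k2 * n_boot` x channels bootstrap map array.
#' @export
multilevel_cluster <- function(participant_peaks, groups, k1 = 10L, k2 = 4L,
                               n_boot = 2000L, boot_size = NULL,
                               per_group = TRUE, n_init1 = 20L, n_init2 = 20L,
                               n_init3 = 100L, seed = 1L) {
  stopifnot(length(participant_peaks) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes == 0L)) rlang::abort("every group must have participants")
  if (is.null(boot_size)) boot_size <- min(sizes)
  seed <- as.integer(seed) %% 100000000L
  # stage 1: participant-level maps
  stage1 <- purrr::map(seq_along(participant_peaks), function(i) {
    mod_kmeans(participant_peaks[[i]], k1, n_init = n_init1,
               seed = seed + 13L * i)$maps
  })
  channels <- if (inherits(participant_peaks[[1]], "peak_set")) {
    participant_peaks[[1]]$channels
  } else colnames(participant_peaks[[1]])
  # stage 2: bootstrap clustering
  stage2 <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(seed + 200000000L + 3L * b)
    draw <- if (per_group) {
      unlist(lapply(unique(groups), function(g) {
        idx <- which(groups == g)
        sample(idx, boot_size, replace = TRUE)
      }))
    } else {
      sample(seq_along(groups), boot_size, replace = TRUE)
    }
    pooled <- do.call(rbind, stage1[draw])
    stage2[[b]] <- mod_kmeans(pooled, k2, n_init = n_init2,
                              seed = seed + 400000000L + 3L * b)$maps
  }
  stage2_maps <- do.call(rbind, stage2)
  colnames(stage2_maps) <- channels
  # stage 3: final maps
  final <- mod_kmeans(stage2_maps, k2, n_init = n_init3,
                      seed = seed + 999000000L)
  final$channels <- channels
  colnames(final$maps) <- channels
  attr(final, "stage2_maps") <- stage2_maps
  final
}

#' Match maps to canonical templates
#'
#' Finds the one-to-one assignment between a map set and a template set that
#' maximizes the total absolute spatial correlation (exact search over all
#' permutations; k <= 8), and labels the maps with the matched template
#' labels. Sign flips and row order of the input never change the result.
#'
#' @param ms A [mapset()] to label.
#' @param templates A [mapset()] with `canonical_labels` (same k).
#' @return `ms` with `canonical_labels` set; attributes `assignment` (index
#'   of the matched template per map) and `match_correlation` (per-map
#'   absolute correlation with the matched template).
#' @export
order_canonical <- function(ms, templates) {
  stopifnot(inherits(ms, "mapset"), inherits(templates, "mapset"))
  if (ms$k != templates$k) rlang::abort("map sets must have equal k")
  k <- ms$k
  if (k > 8L) rlang::abort("exact template matching supports k <= 8")
  C <- spatial_correlation(ms, templates)     # ms rows x template cols
  perms <- all_permutations(k)
  totals <- vapply(perms, function(p) sum(C[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.max(totals)]]
  labs <- templates$canonical_labels %||% as.character(seq_len(k))
  ms$canonical_labels <- labs[best]
  attr(ms, "assignment") <- best
  attr(ms, "match_correlation") <- C[cbind(seq_len(k), best)]
  ms
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
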