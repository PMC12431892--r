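#' Default pipeline configuration
#'
#' All stage parameters in one nested list, pre-filled with the analysis
#' defaults: 0.5-45 Hz band, -200/+1344 ms epochs, 100 microvolt thresholds,
#' 50% bad-epoch channel criterion with Z = 4 over 4 iterations, 10%
#' bad-epoch channel fraction, GFP peaks at minimum distance 2 filtered at 1
#' SD above the mean and the lowest 15%, at most 100000 maps, three-level
#' clustering with k1 = 10 participant maps, k = 4 final maps and 2000
#' bootstraps, 100 restarts for the final stage, and alpha = 0.05. Cohort
#' simulation parameters are desk-scale (64 channels, 20 epochs of 1.5 s).
#' Override any entry, or load overrides from YAML with [load_config()].
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_channels = 64L,
    sfreq = 250,
    osc_freq = 10,
    amplitude = 10,
    noise_sd = 2,
    k = 4L,
    n_epochs = 20L,
    epoch_len = 375L,
    preprocess = list(low = 0.5, high = 45, tmin = -0.200, tmax = 1.344,
                      amp_thresh = 100, epoch_frac = 0.5, z_thresh = 4,
                      n_iter = 4L, chan_frac = 0.1),
    peaks = list(min_distance = 2L, sd_mult = 1, low_pct = 15,
                 max_n = 100000L),
    cluster = list(k1 = 10L, k2 = 4L, n_boot = 2000L, boot_size = NULL,
                   per_group = TRUE, n_init1 = 20L, n_init2 = 20L,
                   n_init3 = 100L),
    segment = list(half_window = 3L, penalty = 5),
    stats = list(alpha = 0.05, group_order = c("UWS", "MCS", "EMCS", "HC")),
    groups = list()
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of overrides and merges it into [default_config()].
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return The merged configuration list.
#' @export
load_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  merge_config(default_config(), overrides)
}

merge_config <- function(base, overrides, path = character()) {
  for (key in names(overrides)) {
    if (!key %in% names(base) && length(path) <= 1L && key != "groups") {
      rlang::abort(sprintf("unknown configuration key: %s",
                           paste(c(path, key), collapse = "$")))
    }
    if (is.list(base[[key]]) && is.list(overrides[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], overrides[[key]], c(path, key))
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

#' Planted transition matrix generator
#'
#' Builds a k-state row-stochastic matrix with a common stay probability.
#' The leaving mass `1 - stay_prob` is spread over the other states; with
#' `asymmetry > 0` the cyclically next state receives `1 + asymmetry` times
#' the weight of the others, producing a rotationally biased — hence
#' detailed-balance-breaking — chain, while `asymmetry = 0` gives a
#' symmetric (time-reversible) matrix.
#'
#' @param k Number of states.
#' @param stay_prob Self-transition probability (mean run length
#'   `1 / (1 - stay_prob)` samples).
#' @param asymmetry Extra weight on the cyclic successor (default 0).
#' @return A k x k row-stochastic matrix.
#' @export
#' @examples
#' make_transition_matrix(4, 0.95, asymmetry = 6)
make_transition_matrix <- function(k, stay_prob = 0.95, asymmetry = 0) {
  stopifnot(k >= 2, stay_prob >= 0, stay_prob < 1, asymmetry >= 0)
  P <- matrix(0, k, k)
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    w <- rep(1, k - 1L)
    nxt <- if (i == k) 1L else i + 1L
    w[match(nxt, others)] <- 1 + asymmetry
    P[i, others] <- (1 - stay_prob) * w / sum(w)
    P[i, i] <- stay_prob
  }
  P
}

#' Run the full microstate pipeline
#'
#' Orchestrates simulate (or load) -> reference/trim -> GFP peaks ->
#' three-level clustering -> back-fit + smooth -> markers -> group
#' statistics, from a single configuration, with a provenance record.
#'
#' Input comes either from `config$groups` — a list of
#' `list(name=, n=, stay_prob=, asymmetry=)` (or an explicit matrix `P`)
#' entries describing a simulated cohort sharing one planted map set — or
#' from `manifest`, a tibble with columns `participant`, `file` (an epochs
#' prefix readable by [read_epochs()]) and `group`.
#'
#' @param config Configuration list, see [default_config()].
#' @param manifest Optional tibble of pre-recorded participants.
#' @param out_dir Optional output directory; when given, the marker table,
#'   final maps, group statistics and a provenance JSON are written there.
#' @return A list: `markers` (tibble, one row per participant), `maps`
#'   (final [mapset()]), `stats` (from [compare_groups()]), `truths`
#'   (per-participant ground truth, simulated input only), `provenance`.
#' @export
run_pipeline <- function(config = default_config(), manifest = NULL,
                         out_dir = NULL) {
  seed <- as.integer(config$seed)
  layout <- grid_layout(config$n_channels)
  participants <- list()
  truths <- list()
  if (!is.null(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      ep <- tryCatch(read_epochs(manifest$file[i]), error = function(e) {
        rlang::abort(sprintf(
          "stage 'load': cannot read data for participant '%s': %s",
          manifest$participant[i], conditionMessage(e)))
      })
      participants[[i]] <- list(id = manifest$participant[i],
                                group = manifest$group[i], epochs = ep)
    }
  } else {
    if (!length(config$groups)) {
      rlang::abort("either `manifest` or `config$groups` must be supplied")
    }
    maps <- make_topographies(layout, config$k, seed = seed)
    idx <- 0L
    for (g in config$groups) {
      P <- if (!is.null(g$P)) as.matrix(g$P) else
        make_transition_matrix(config$k, g$stay_prob %||% 0.95,
                               g$asymmetry %||% 0)
      for (j in seq_len(g$n)) {
        idx <- idx + 1L
        sim <- simulate_participant(
          layout, P, n_epochs = config$n_epochs,
          epoch_len = config$epoch_len, sfreq = config$sfreq,
          osc_freq = config$osc_freq, amplitude = config$amplitude,
          noise_sd = config$noise_sd, maps = maps,
          seed = seed + 101L * idx)
        id <- sprintf("%s_%02d", g$name, j)
        participants[[idx]] <- list(id = id, group = g$name,
                                    epochs = sim$epochs)
        truths[[id]] <- sim$truth
      }
    }
  }
  # reference & trim, then per-participant peak sets
  peak_sets <- vector("list", length(participants))
  for (i in seq_along(participants)) {
    ep <- rereference_and_trim(participants[[i]]$epochs)
    participants[[i]]$epochs <- ep
    peak_sets[[i]] <- gfp_peak_set(
      ep, min_distance = config$peaks$min_distance,
      sd_mult = config$peaks$sd_mult, low_pct = config$peaks$low_pct,
      max_n = config$peaks$max_n, seed = seed + 7L * i)
  }
  groups <- vapply(participants, function(p) p$group, character(1))
  cl <- config$cluster
  maps_final <- multilevel_cluster(
    peak_sets, groups, k1 = cl$k1, k2 = cl$k2, n_boot = cl$n_boot,
    boot_size = cl$boot_size, per_group = cl$per_group,
    n_init1 = cl$n_init1, n_init2 = cl$n_init2, n_init3 = cl$n_init3,
    seed = seed)
  if (cl$k2 == 4L) {
    trimmed_layout <- participants[[1]]$epochs$layout
    templates <- make_topographies(trimmed_layout, 4L, seed = 1L,
                                   perturbation = 0)
    maps_final <- order_canonical(maps_final, templates)
  }
  markers <- purrr::map_dfr(participants, function(p) {
    seg <- backfit(p$epochs, maps_final)
    seg <- smooth_segmentation(seg, p$epochs, maps_final,
                               half_window = config$segment$half_window,
                               penalty = config$segment$penalty)
    microstate_markers(p$epochs, seg, maps_final,
                       participant = p$id, group = p$group)
  })
  stats_out <- if (length(unique(groups)) >= 2L) {
    compare_groups(markers, order = config$stats$group_order,
                   alpha = config$stats$alpha)
  } else NULL
  provenance <- list(config = config, seed = seed,
                     package_version = as.character(utils::packageVersion("microdyn")),
                     n_participants = length(participants))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(markers, file.path(out_dir, "markers.csv"),
                     row.names = FALSE)
    write_mapset(maps_final, file.path(out_dir, "maps.csv"))
    if (!is.null(stats_out)) {
      utils::write.csv(stats_out$pairwise,
                       file.path(out_dir, "pairwise_tests.csv"),
                       row.names = FALSE)
    }
    provenance$checksums <- as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE, pattern = "\\.csv$")))
    names(provenance$checksums) <- basename(names(provenance$checksums))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(markers = markers, maps = maps_final, stats = stats_out,
       truths = truths, provenance = provenance)
}
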