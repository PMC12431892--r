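test_that("coverage counts label fractions and sums to one", {
  seg <- seg_from_labels(c(1, 1, 2, 2), k = 4)
  expect_equal(coverage(seg), c(0.5, 0.5, 0, 0))
  expect_equal(coverage(seg_from_labels(rep(3, 10), k = 4)),
               c(0, 0, 1, 0))
  # planted uniform-stationary chain covers each state equally
  U <- matrix(0.25, 4, 4)
  s <- sample_state_sequence(U, 100000, seed = 7)
  cov <- coverage(seg_from_labels(s, k = 4))
  expect_lt(max(abs(cov - 0.25)), 0.01)
  expect_equal(sum(cov), 1, tolerance = 1e-12)
})

test_that("coverage entropy follows the Shannon formula in nats", {
  expect_equal(coverage_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(coverage_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(coverage_entropy(c(0.5, 0.5, 0, 0)), log(2), tolerance = 1e-12)
  expect_error(coverage_entropy(c(1.2, -0.2, 0, 0)), "non-negative")
})

test_that("GEV matches the direct per-sample evaluation", {
  lay <- full_layout(16)
  ms <- make_topographies(lay, 3, seed = 2)
  # samples exactly proportional to their assigned maps: total GEV 1
  lab <- c(1, 2, 3, 1)
  mat <- t(ms$maps[lab, ] * c(2, -1, 0.5, 4))
  ep <- eeg_epochs(array(mat, dim = c(1, 16, 4)), 250, 0, lay)
  seg <- seg_from_labels(lab, k = 3)
  g <- gev(ep, seg, ms)
  expect_equal(g$gev_total, 1, tolerance = 1e-9)
  expect_equal(sum(g$gev_per_map), g$gev_total, tolerance = 1e-12)
  # random fixture: equals the brute-force oracle
  set.seed(9)
  noisy <- matrix(rnorm(16 * 20), 16, 20)
  ep2 <- eeg_epochs(array(noisy, dim = c(1, 16, 20)), 250, 0, lay)
  seg2 <- backfit(ep2, ms)
  g2 <- gev(ep2, seg2, ms)
  o2 <- oracle_gev(ep2, seg2, ms)
  expect_equal(g2$gev_per_map, o2$gev_per_map, tolerance = 1e-9)
  expect_equal(g2$gev_total, o2$gev_total, tolerance = 1e-9)
})

test_that("run durations are within-epoch maximal runs in milliseconds", {
  seg <- seg_from_labels(c(1, 1, 1, 2, 2, 3), k = 3)
  d <- run_durations(seg)
  expect_equal(d$map, c(1, 2, 3))
  expect_equal(d$duration_ms, c(12, 8, 4))
  # one full epoch of 387 samples: a single 1548 ms run
  d387 <- run_durations(seg_from_labels(rep(2, 387), k = 3))
  expect_equal(nrow(d387), 1)
  expect_equal(d387$duration_ms, 1548)
  # runs never merge across epoch boundaries
  two <- segmentation(rbind(c(1, 1, 1), c(1, 1, 2)), k = 2, sfreq = 250)
  d2 <- run_durations(two)
  expect_equal(nrow(d2), 3)
  expect_equal(d2$n_samples[1:2], c(3, 2))
})

test_that("MMD and MDV are the pooled mean and population variance", {
  durs <- tibble::tibble(epoch = 1L, map = c(1, 2, 3),
                         n_samples = c(3, 2, 1),
                         duration_ms = c(12, 8, 4))
  md <- mmd_mdv(durs)
  expect_equal(md$mmd, 8)
  expect_equal(md$mdv, mean((c(12, 8, 4) - 8)^2))
  # equal durations: zero variance
  eq <- tibble::tibble(epoch = 1L, map = 1, n_samples = 2,
                       duration_ms = rep(8, 5))
  expect_equal(mmd_mdv(eq)$mdv, 0)
  # single run: variance undefined, flagged by warning
  one <- durs[1, ]
  expect_warning(md1 <- mmd_mdv(one), "undefined")
  expect_true(is.na(md1$mdv))
})

test_that("planted geometric run lengths give the expected mean duration", {
  P <- make_transition_matrix(4, 0.95)
  s <- sample_state_sequence(P, 100000, seed = 11)
  md <- mmd_mdv(run_durations(seg_from_labels(s, k = 4)))
  expect_equal(md$mmd, 80, tolerance = 0.05)          # 20 samples = 80 ms
  var_geom <- 0.95 / 0.05^2 * (1000 / 250)^2          # geometric, in ms^2
  expect_equal(md$mdv, var_geom, tolerance = 0.10)
})

test_that("transition matrix counts consecutive pairs within epochs", {
  seg <- seg_from_labels(c(1, 1, 2, 2, 1), k = 2)
  tm <- transition_matrix(seg)
  expect_equal(tm$counts, matrix(c(1L, 1L, 1L, 1L), 2, byrow = TRUE))
  expect_equal(tm$P[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  # constant labels: identity row for that map, other rows flagged undefined
  tmc <- transition_matrix(seg_from_labels(rep(2, 10), k = 3))
  expect_equal(tmc$P[2, 2], 1)
  expect_equal(tmc$undefined_rows, c(1L, 3L), ignore_attr = TRUE)
  # no cross-epoch pairs
  two <- segmentation(rbind(c(1, 1), c(2, 2)), k = 2, sfreq = 250)
  tm2 <- transition_matrix(two)
  expect_equal(sum(tm2$counts), 2)
  expect_equal(tm2$counts[1, 2], 0L)
  # switch-only variant zeroes the diagonal
  tm_sw <- transition_matrix(seg, include_self = FALSE)
  expect_equal(diag(tm_sw$counts), c(0L, 0L))
  # estimator consistency on a planted chain
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  s <- sample_state_sequence(P, 100000, seed = 13)
  tmp <- transition_matrix(seg_from_labels(s, k = 2))
  expect_lt(max(abs(tmp$P - P)), 0.01)
  # against the explicit pair-loop oracle on a random fixture
  set.seed(3)
  labs <- matrix(sample(1:3, 60, replace = TRUE), nrow = 3)
  tmo <- transition_matrix(segmentation(labs, k = 3, sfreq = 250))
  expect_equal(tmo$counts, oracle_transition_counts(labs, 3),
               ignore_attr = TRUE)
})

test_that("entropy production measures broken detailed balance", {
  # symmetric matrices produce zero entropy
  S <- matrix(c(0.8, 0.1, 0.1,
                0.1, 0.8, 0.1,
                0.1, 0.1, 0.8), 3, byrow = TRUE)
  expect_equal(as.numeric(entropy_production(S)), 0, tolerance = 1e-15)
  expect_equal(as.numeric(entropy_production(diag(4))), 0)
  # two-state analytic value
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(as.numeric(entropy_production(P)), 0.2 * log(3),
               tolerance = 1e-12)
  # invariant under simultaneous row/column permutation
  perm <- c(2, 1)
  expect_equal(as.numeric(entropy_production(P[perm, perm])),
               as.numeric(entropy_production(P)), tolerance = 1e-12)
  # one-sided pairs are excluded with a warning
  Q <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE)
  expect_warning(epq <- entropy_production(Q), "irreversible")
  expect_equal(attr(epq, "irreversible_pairs"), 1L)
  expect_equal(as.numeric(epq), 0)
  # EP is non-negative on random stochastic matrices
  set.seed(21)
  for (i in 1:10) {
    R <- matrix(stats::rexp(16), 4)
    R <- R / rowSums(R)
    expect_gte(as.numeric(entropy_production(R)), 0)
  }
})

test_that("regularized EP from counts stays finite with empty reverse cells", {
  seg <- seg_from_labels(c(1, 1, 2, 2, 2, 3, 3), k = 3)  # no 2->1, 3->2 back
  tm <- transition_matrix(seg)
  expect_warning(entropy_production(tm), "irreversible")
  epr <- entropy_production(tm, regularize = TRUE)
  expect_true(is.finite(as.numeric(epr)))
  expect_gte(as.numeric(epr), 0)
})

test_that("the marker record assembles all statistics consistently", {
  lay <- full_layout(16)
  ms <- make_topographies(lay, 4, seed = 3)
  P <- make_transition_matrix(4, 0.9)
  sim <- simulate_participant(lay, P, n_epochs = 5, epoch_len = 250,
                              amplitude = 10, noise_sd = 1, maps = ms,
                              seed = 77)
  seg <- backfit(sim$epochs, ms)
  row <- microstate_markers(sim$epochs, seg, ms, participant = "p1",
                            group = "HC")
  expect_equal(nrow(row), 1)
  cov <- unlist(row[paste0("coverage_", 1:4)])
  expect_equal(sum(cov), 1, tolerance = 1e-12)
  gevs <- unlist(row[paste0("gev_", 1:4)])
  expect_equal(sum(gevs), row$gev_total, tolerance = 1e-12)
  expect_gt(row$mmd, 0)
  expect_gte(row$ep, 0)
  # coverage, durations and transitions reconcile: stationary of the
  # estimated transition matrix approximates the coverage
  tm <- transition_matrix(seg)
  expect_lt(max(abs(stationary_distribution(tm$P) - cov)), 0.05)
})
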