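test_that("planted topographies are zero-mean, unit-norm and well separated", {
  lay <- grid_layout(64)
  maps <- make_topographies(lay, k = 4, seed = 1)
  expect_equal(rowMeans(maps$maps), rep(0, 4), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(maps$maps^2)), rep(1, 4), tolerance = 1e-9)
  # pairwise correlation bound, checked by direct computation
  C <- abs(stats::cor(t(maps$maps)))
  expect_lt(max(C[upper.tri(C)]), 0.8)
})

test_that("topographies depend on the seed but keep their invariants", {
  lay <- grid_layout(64)
  m1 <- make_topographies(lay, k = 2, seed = 1)
  m2 <- make_topographies(lay, k = 2, seed = 2)
  expect_false(isTRUE(all.equal(m1$maps, m2$maps)))
  for (m in list(m1, m2)) {
    expect_equal(rowMeans(m$maps), rep(0, 2), tolerance = 1e-12)
    expect_equal(sqrt(rowSums(m$maps^2)), rep(1, 2), tolerance = 1e-9)
  }
  expect_error(make_topographies(lay, k = 65), "channel count")
  expect_error(make_topographies(lay, k = 1), "at least 2")
})

test_that("Markov sampler reproduces the planted chain", {
  # absorbing self-transitions give a constant sequence
  s <- sample_state_sequence(diag(3), n_samples = 100, seed = 5)
  expect_length(unique(s), 1L)
  # empirical transition frequencies converge to P
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  s <- sample_state_sequence(P, 100000, seed = 7)
  emp <- table(factor(s[-length(s)], 1:2), factor(s[-1], 1:2))
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - P)), 0.01)
  # uniform chain visits each state a quarter of the time
  U <- matrix(0.25, 4, 4)
  s4 <- sample_state_sequence(U, 100000, seed = 7)
  expect_lt(max(abs(tabulate(s4, 4) / 1e5 - 0.25)), 0.01)
  expect_error(sample_state_sequence(matrix(c(0.5, 0.2, 0.3, 0.7), 2), 10),
               "row-stochastic|sum to 1")
})

test_that("synthesized EEG carries the planted topography at envelope extrema", {
  lay <- full_layout(16)
  maps <- make_topographies(lay, 4, seed = 3)
  labels <- sample_state_sequence(make_transition_matrix(4, 0.9), 750, seed = 4)
  sim <- synthesize_eeg(maps, labels, sfreq = 250, osc_freq = 10,
                        amplitude = 10, noise_sd = 0, epoch_len = 375,
                        seed = 1, layout = lay)
  # envelope extrema sit where |sin| = 1: t = 6.25 + 12.5 m -> no integer
  # sample is exact, so check near-extremum samples instead
  env <- sin(2 * pi * 10 * (0:749) / 250)
  strong <- which(abs(env) > 0.9)
  for (t in strong[c(1, 10, 50)]) {
    e <- (t - 1) %/% 375 + 1
    s <- (t - 1) %% 375 + 1
    v <- sim$epochs$data[e, , s]
    expect_equal(abs(stats::cor(v, maps$maps[labels[t], ])), 1,
                 tolerance = 1e-9)
  }
  expect_error(synthesize_eeg(maps, labels, amplitude = 0, noise_sd = 0,
                              epoch_len = 375, layout = lay),
               "degenerate")
  expect_error(synthesize_eeg(maps, labels[1:100], epoch_len = 375,
                              layout = lay), "divisible")
})

test_that("noiseless GFP maxima are spaced at the envelope half-period", {
  lay <- full_layout(16)
  maps <- make_topographies(lay, 2, seed = 1)
  labels <- rep(1L, 750)
  sim <- synthesize_eeg(maps, labels, sfreq = 250, osc_freq = 10,
                        amplitude = 5, noise_sd = 0, epoch_len = 750,
                        layout = lay)
  gfp <- compute_gfp(sim$epochs)
  pk <- find_gfp_peaks(gfp)
  gaps <- diff(pk$sample)
  expect_true(all(gaps >= 12 & gaps <= 13))
})

test_that("regeneration with the same seed is bit-identical", {
  lay <- full_layout(16)
  maps <- make_topographies(lay, 4, seed = 2)
  labels <- sample_state_sequence(make_transition_matrix(4, 0.9), 375, seed = 9)
  a <- synthesize_eeg(maps, labels, noise_sd = 1, epoch_len = 375,
                      seed = 11, layout = lay)
  b <- synthesize_eeg(maps, labels, noise_sd = 1, epoch_len = 375,
                      seed = 11, layout = lay)
  expect_identical(a$epochs$data, b$epochs$data)
  c <- synthesize_eeg(maps, labels, noise_sd = 1, epoch_len = 375,
                      seed = 12, layout = lay)
  expect_false(identical(a$epochs$data, c$epochs$data))
})

test_that("planted labels are recovered at GFP peaks", {
  lay <- full_layout(16)
  maps <- make_topographies(lay, 4, seed = 5)
  P <- make_transition_matrix(4, 0.95)
  labels <- sample_state_sequence(P, 10 * 375, seed = 6)
  # noiseless: exact recovery at every GFP peak
  sim0 <- synthesize_eeg(maps, labels, noise_sd = 0, epoch_len = 375,
                         layout = lay, P = P)
  pk0 <- find_gfp_peaks(compute_gfp(sim0$epochs))
  seg0 <- backfit(sim0$epochs, maps)
  at_peaks <- cbind(pk0$epoch, pk0$sample)
  expect_equal(seg0$labels[at_peaks], sim0$truth$true_labels[at_peaks])
  # moderate noise: >= 95% accuracy at GFP peaks
  sim1 <- synthesize_eeg(maps, labels, amplitude = 10, noise_sd = 1,
                         epoch_len = 375, seed = 8, layout = lay, P = P)
  pk1 <- find_gfp_peaks(compute_gfp(sim1$epochs))
  seg1 <- backfit(sim1$epochs, maps)
  at_peaks <- cbind(pk1$epoch, pk1$sample)
  acc <- mean(seg1$labels[at_peaks] == sim1$truth$true_labels[at_peaks])
  expect_gte(acc, 0.95)
})
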