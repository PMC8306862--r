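test_that("window splitting floors to whole windows", {
  rec <- make_recording(nch = 2, n = 120 * 50, fs = 50)
  expect_length(window_split(rec, 1), 120)
  rec2 <- make_recording(nch = 2, n = 119.5 * 50, fs = 50)
  expect_length(window_split(rec2, 1), 119)
  rec3 <- make_recording(nch = 1, n = 25, fs = 50)
  expect_error(window_split(rec3, 1), "shorter")
})

test_that("cross-spectra are Hermitian with the expected autospectrum peak", {
  n <- 3000
  x <- sin(2 * pi * 10 * (1:n) / 1000)
  rec <- recording(rbind(x, gen_noise(n, "white", seed = 2)), fs = 1000)
  cs <- cross_spectra(window_split(rec), fs = 1000)
  expect_equal(cs$csd[, 1, 2, ], Conj(cs$csd[, 2, 1, ]))
  expect_true(all(abs(Im(cs$csd[, 1, 1, ])) < 1e-8))
  expect_true(all(Re(cs$csd[, 1, 1, ]) >= -1e-12))
  # autospectrum peak of the sinusoid at the 10 Hz bin
  auto <- colMeans(Re(cs$csd[, 1, 1, ]))
  expect_equal(cs$freqs[which.max(auto)], 10)
})

test_that("WPLI detects lagged coupling, ignores zero-lag and rescaling", {
  pair <- gen_coupled_pair(30000, fs = 1000, freq = 10, phase_lag = pi / 2,
                           snr = 10, seed = 3)
  rec <- recording(pair, fs = 1000)
  W <- band_wpli(rec)
  expect_gt(W$alpha[1, 2], 0.95)
  expect_true(all(vapply(W, function(m) all(m >= 0 & m <= 1), logical(1))))
  expect_true(all(vapply(W, isSymmetric, logical(1))))
  expect_true(all(diag(W$alpha) == 0))
  # equality of the band-restricted path and the reference path
  cs <- cross_spectra(window_split(rec), fs = 1000)
  for (b in seq_len(nrow(default_bands()))) {
    expect_equal(wpli(cs, default_bands()[b, ]), W[[b]], tolerance = 1e-12)
  }
  # amplitude rescaling cancels
  rec10 <- recording(rec$data * c(10, 0.2), fs = 1000)
  expect_equal(band_wpli(rec10)$alpha, W$alpha, tolerance = 1e-9)
  # zero-lag identical signals: 0 by the 0/0 convention
  z <- gen_noise(5000, "pink", seed = 5)
  rec0 <- recording(rbind(z, z), fs = 1000, channel_labels = c("c1", "c2"))
  expect_equal(band_wpli(rec0)$alpha[1, 2], 0)
  expect_error(wpli(cs, list(lo = 13.2, hi = 13.8)), "no frequency bins")
})

test_that("phase-randomized surrogates preserve spectra and break coupling", {
  spec <- experiment_spec(n_subjects = 1, duration_s = 20, fs = 500,
                          coupling_freq = 35, coupling_amp = 0.6,
                          coupling_bw = 3, seed = 17)
  rec <- gen_experiment(spec)$s01_B
  sur <- phase_randomized_surrogate(rec, seed = 4)
  expect_identical(sur$data, phase_randomized_surrogate(rec, seed = 4)$data)
  for (ch in c(1, 10)) {
    a0 <- Mod(fft(rec$data[ch, ]))
    a1 <- Mod(fft(sur$data[ch, ]))
    expect_lt(max(abs(a0 - a1)) / max(a0), 1e-9)
  }
  # coupling of an injected pair survives in the data, not in the surrogate
  pair <- match(c("Fz", "Pz"), rec$channel_labels)
  Wr <- band_wpli(rec)$gamma[pair[1], pair[2]]
  Ws <- band_wpli(sur)$gamma[pair[1], pair[2]]
  expect_gt(Wr, 0.8)
  expect_lt(Ws, Wr - 0.3)
})

test_that("surrogate thresholding keeps true edges and drops null networks", {
  spec <- experiment_spec(n_subjects = 1, duration_s = 20, fs = 500,
                          coupling_amp = 0.6, coupling_bw = 3, seed = 23)
  rec <- gen_experiment(spec)$s01_B
  nets <- threshold_networks(rec, n_surrogates = 50, seed = 31)
  expect_named(nets, c("alpha", "beta", "gamma"))
  for (p in spec$coupled_pairs_B) {
    expect_identical(nets$gamma$adjacency[p[1], p[2]], 1L)
  }
  expect_true(isSymmetric(nets$gamma$adjacency))
  expect_true(all(diag(nets$gamma$adjacency) == 0))
  # all-zero recording yields an empty network
  rec0 <- recording(matrix(0, 3, 2000), fs = 500)
  expect_warning(
    net0 <- threshold_network(rec0, band_spec("alpha", 7, 13),
                              n_surrogates = 10, seed = 1),
    "unstable")
  expect_identical(gfc(net0), 0L)
})

test_that("GFC counts upper-triangle edges and respects complementation", {
  full <- matrix(1, 27, 27) - diag(27)
  expect_identical(gfc(full), 351)
  expect_identical(gfc(matrix(0, 5, 5)), 0)
  adj <- with_test_seed(12, {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8)
    a[lower.tri(a, diag = TRUE)] <- 0
    a + t(a)
  })
  comp <- (1 - adj) - diag(8)
  expect_identical(gfc(adj) + gfc(comp), 8L * 7L / 2L)
})
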