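test_that("noise generators are deterministic and validate their inputs", {
  expect_identical(gen_noise(1000, "white", seed = 7),
                   gen_noise(1000, "white", seed = 7))
  expect_identical(gen_noise(500, "pink", seed = 3),
                   gen_noise(500, "pink", seed = 3))
  # AR(1) with phi = 0 is exactly the white-noise construction
  expect_equal(gen_noise(1000, "ar1", phi = 0, seed = 7),
               gen_noise(1000, "white", seed = 7))
  expect_error(gen_noise(100, "ar1", phi = 1), "nonstationary")
  expect_error(gen_noise(0, "white"), "positive integer")
  # near-zero mean
  expect_lt(abs(mean(gen_noise(20000, "white", seed = 1))), 0.05)
  expect_lt(abs(mean(gen_noise(20000, "pink", seed = 1))), 1e-10)
})

test_that("pink noise has a log-log spectral slope near -1", {
  x <- gen_noise(2^14, "pink", seed = 1)
  spec <- Mod(fft(x))^2 / length(x)
  k <- 2:(length(x) / 2)
  f <- (k - 1) / length(x)
  fit <- stats::lm(log(spec[k]) ~ log(f))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.2)
})

test_that("logistic map follows the exact iteration and its fixed point", {
  expect_equal(gen_logistic_map(3, r = 4, x0 = 0.5), c(0.5, 1, 0))
  x <- gen_logistic_map(500, r = 2, x0 = 0.3)
  expect_equal(x[500], 0.5, tolerance = 1e-10)
  expect_error(gen_logistic_map(10, r = 4, x0 = 1.2), "inside")
})

test_that("chaotic map entropy sits between periodic and white-noise entropy", {
  n <- 10000
  sine <- sin(2 * pi * 5 * (1:n) / 1000)
  chaos <- gen_logistic_map(n, r = 4, x0 = 0.123)
  noise <- gen_noise(n, "white", seed = 2)
  pe <- function(x) permutation_entropy(pattern_probabilities(x, m = 5))
  expect_lt(pe(sine), pe(chaos))
  expect_lt(pe(chaos), pe(noise))
})

test_that("coupled pair respects lag, snr limits and the Nyquist bound", {
  expect_error(gen_coupled_pair(100, fs = 100, freq = 60), "fs/2")
  # zero lag, no noise: imaginary cross-spectrum identically zero
  pair <- gen_coupled_pair(2000, fs = 1000, freq = 10, phase_lag = 0, snr = Inf)
  cs <- cross_spectra(window_split(recording(pair, fs = 1000)), fs = 1000)
  expect_lt(max(abs(Im(cs$csd[, 1, 2, ]))), 1e-6)
  # snr = 0 yields independent noise with low band WPLI
  p0 <- gen_coupled_pair(30000, fs = 1000, freq = 10, snr = 0, seed = 4)
  expect_lt(band_wpli(recording(p0, fs = 1000))$alpha[1, 2], 0.4)
  expect_identical(gen_coupled_pair(100, 100, 10, seed = 5),
                   gen_coupled_pair(100, 100, 10, seed = 5))
})

test_that("experiment spec validates and the generator matches its shapes", {
  expect_error(experiment_spec(frontal_noise_mix_A = 1.5), "\\[0, 1\\]")
  expect_error(experiment_spec(coupling_freq = 800), "fs/2")
  expect_error(experiment_spec(n_channels = 4, coupled_pairs_B = list(c(1, 9))),
               "valid channels")
  spec <- experiment_spec(n_subjects = 2, duration_s = 2, fs = 200, seed = 9)
  recs <- gen_experiment(spec)
  expect_length(recs, 4)
  expect_named(recs, c("s01_A", "s01_B", "s02_A", "s02_B"))
  for (r in recs) {
    expect_identical(dim(r$data), c(27L, 400L))
    expect_identical(r$channel_labels, eeg_channel_labels())
  }
  # bit-identical regeneration from the same seed
  recs2 <- gen_experiment(spec)
  expect_identical(recs, recs2)
})

test_that("condition B frontal channels are more irregular than condition A", {
  spec <- experiment_spec(n_subjects = 3, duration_s = 6, fs = 500, seed = 21)
  recs <- gen_experiment(spec)
  frontal <- default_roi_scheme()$rois$frontal
  pe1 <- function(rec) {
    mean(vapply(frontal, function(ch) {
      permutation_entropy(pattern_probabilities(rec$data[ch, ], m = 5))
    }, numeric(1)))
  }
  for (s in c("s01", "s02", "s03")) {
    expect_gt(pe1(recs[[paste0(s, "_B")]]), pe1(recs[[paste0(s, "_A")]]))
  }
})
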