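#' Reference noise generators
#'
#' Generates white Gaussian noise, 1/f ("pink") noise via spectral shaping of
#' white noise, or a first-order autoregressive process. All generators are
#' deterministic for a fixed seed and return zero-mean series (exactly
#' zero-mean for pink noise, whose DC component is removed).
#'
#' @param n Length of the series (>= 1).
#' @param kind One of `"white"`, `"pink"`, `"ar1"`.
#' @param phi AR(1) coefficient, used only for `kind = "ar1"`; must satisfy
#'   `|phi| < 1` (stationarity).
#' @param seed Optional integer seed; the session RNG state is restored after
#'   the call.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- gen_noise(1024, "pink", seed = 1)
#' @export
gen_noise <- function(n, kind = c("white", "pink", "ar1"), phi = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!.is_count(n)) stop("`n` must be a positive integer")
  if (kind == "ar1" && (!is.finite(phi) || abs(phi) >= 1)) {
    stop("AR(1) with |phi| >= 1 is nonstationary; require |phi| < 1")
  }
  with_seed(seed, {
    w <- rnorm(n)
    switch(kind,
      white = w,
      ar1 = as.numeric(stats::filter(w, phi, method = "recursive")),
      pink = {
        if (n < 4) return(w) # too short for meaningful shaping
        X <- fft(w)
        k <- seq_len(n) - 1
        f <- pmin(k, n - k)        # cyclic frequency index, symmetric
        amp <- c(0, 1 / sqrt(f[-1]))  # power ~ 1/f, DC removed
        x <- Re(fft(X * amp, inverse = TRUE) / n)
        x / sd(x)
      }
    )
  })
}

#' Logistic map trajectory
#'
#' Iterates `x[t+1] = r * x[t] * (1 - x[t])`. At `r = 4` the map is fully
#' chaotic and is used as a reference process with entropy strictly between a
#' periodic signal and white noise.
#'
#' @param n Number of iterates to return (including `x0`).
#' @param r Map parameter in (0, 4].
#' @param x0 Starting point in (0, 1).
#' @return Numeric vector of length `n`.
#' @examples
#' gen_logistic_map(3, r = 4, x0 = 0.5)
#' @export
gen_logistic_map <- function(n, r = 4, x0 = 0.4) {
  if (!.is_count(n)) stop("`n` must be a positive integer")
  if (!is.numeric(x0) || length(x0) != 1L || x0 <= 0 || x0 >= 1) {
    stop("`x0` must lie strictly inside (0, 1)")
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 4) {
    stop("`r` must lie in (0, 4]")
  }
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1L)) x[t + 1L] <- r * x[t] * (1 - x[t])
  x
}

#' Lag-coupled sinusoid pair
#'
#' Two sinusoids at the same frequency with a fixed phase offset, each
#' corrupted by independent Gaussian noise scaled by the amplitude
#' signal-to-noise ratio. A non-zero `phase_lag` makes the pair detectable by
#' lag-sensitive phase coupling measures such as the weighted phase lag index;
#' `phase_lag = 0` yields an identically zero imaginary cross-spectrum.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param freq Oscillation frequency (Hz), strictly below the Nyquist `fs/2`.
#' @param phase_lag Phase offset (radians) of the second channel.
#' @param snr Amplitude ratio of sinusoid to noise. `Inf` gives noiseless
#'   sinusoids; `0` gives pure independent noise.
#' @param seed Optional integer seed.
#' @return Numeric matrix with 2 rows (`ch1`, `ch2`) and `n` columns.
#' @export
gen_coupled_pair <- function(n, fs, freq, phase_lag = pi / 2, snr = 1,
                             seed = NULL) {
  if (!.is_count(n)) stop("`n` must be a positive integer")
  if (freq <= 0 || freq >= fs / 2) {
    stop("`freq` must lie strictly inside (0, fs/2)")
  }
  if (snr < 0) stop("`snr` must be >= 0")
  tt <- (seq_len(n) - 1) / fs
  s1 <- sin(2 * pi * freq * tt)
  s2 <- sin(2 * pi * freq * tt - phase_lag)
  with_seed(seed, {
    n1 <- rnorm(n)
    n2 <- rnorm(n)
    out <- if (snr == 0) {
      rbind(n1, n2)
    } else if (is.infinite(snr)) {
      rbind(s1, s2)
    } else {
      rbind(s1 + n1 / snr, s2 + n2 / snr)
    }
    rownames(out) <- c("ch1", "ch2")
    out
  })
}

#' Specification of a synthetic two-condition experiment
#'
#' Describes a multi-subject, two-condition EEG-like dataset: a 1/f background
#' in every channel, a condition-dependent admixture of white noise in frontal
#' channels (raising their signal irregularity), and, in condition B only,
#' gamma-band lag-coupled channel pairs driven by a shared oscillator.
#' The defaults mirror a 20-subject, 27-channel, 120 s, 1 kHz study design.
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Number of channels. With 27 channels the standard montage
#'   labels of [eeg_channel_labels()] are used and "frontal" means the frontal
#'   region of [default_roi_scheme()]; otherwise generic labels are generated
#'   and the first quarter of channels is treated as frontal.
#' @param duration_s Recording duration per condition (seconds).
#' @param fs Sampling rate (Hz).
#' @param frontal_noise_mix_A,frontal_noise_mix_B Mixing fraction
#'   `lambda` in `[0, 1]` of white noise convexly mixed into the 1/f
#'   background of frontal channels, per condition. A larger `lambda` yields a
#'   more irregular (higher permutation entropy) signal.
#' @param coupled_pairs_B List of length-2 channel index or label pairs that
#'   receive the shared lagged oscillator in condition B. `NULL` selects twelve
#'   default fronto-posterior pairs for the 27-channel montage (none
#'   otherwise); enough excess edges over the thresholding false-positive
#'   noise (~5% of 351 pairs, sd ~4 edges) that the global connectivity
#'   increase is detectable in small cohorts.
#' @param coupling_freq Oscillator centre frequency in Hz (default 35, inside
#'   the gamma band).
#' @param coupling_phase_lag Phase lag (radians) between the two channels of
#'   each pair; non-zero so that lag-sensitive connectivity measures see it.
#' @param coupling_amp Oscillator RMS amplitude relative to the unit-variance
#'   channel background. The default 0.25 contributes ~6% of channel
#'   variance - little enough to leave broadband irregularity measures
#'   essentially untouched - while still dominating the 1/f background
#'   within its own narrow band (~0.5% of channel variance), as
#'   physiological gamma does.
#' @param noise_mix_sd Between-subject standard deviation of the noise mixing
#'   fraction: each subject-condition draws its own
#'   `lambda ~ N(lambda_cond, noise_mix_sd)` truncated to `[0, 1]`. Real
#'   cohorts vary; without this, paired t statistics are driven by estimation
#'   noise alone and become unrealistically large.
#' @param coupling_amp_jitter Relative between-subject spread of the coupling
#'   amplitude: per subject and pair the amplitude is scaled by
#'   `U(1 - j, 1 + j)`.
#' @param coupling_bw Oscillator bandwidth in Hz (default 2). The shared
#'   oscillator is band-limited Gaussian noise centred on `coupling_freq`
#'   with a constant phase lag across its band: like physiological gamma it
#'   is narrowband-stochastic rather than a deterministic sinusoid, so that
#'   phase-randomised surrogates genuinely destroy the coupling.
#' @param channel_labels Optional explicit channel labels.
#' @param seed Integer seed controlling the whole experiment.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(n_subjects = 20, n_channels = 27, duration_s = 120,
                            fs = 1000,
                            frontal_noise_mix_A = 0.2,
                            frontal_noise_mix_B = 0.7,
                            coupled_pairs_B = NULL,
                            coupling_freq = 35,
                            coupling_phase_lag = pi / 4,
                            coupling_amp = 0.25,
                            coupling_bw = 2,
                            noise_mix_sd = 0.05,
                            coupling_amp_jitter = 0.3,
                            channel_labels = NULL,
                            seed = 1) {
  stopifnot(.is_count(n_subjects), .is_count(n_channels))
  if (!is.numeric(duration_s) || duration_s <= 0) stop("`duration_s` must be > 0")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0")
  for (lam in c(frontal_noise_mix_A, frontal_noise_mix_B)) {
    if (!is.numeric(lam) || lam < 0 || lam > 1) {
      stop("noise mixing fractions must lie in [0, 1]")
    }
  }
  if (coupling_freq <= 0 || coupling_freq >= fs / 2) {
    stop("`coupling_freq` must lie strictly inside (0, fs/2)")
  }
  if (coupling_bw <= 0 || coupling_freq + coupling_bw / 2 >= fs / 2) {
    stop("`coupling_bw` must be positive with the band below Nyquist")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels == 27) eeg_channel_labels() else
      sprintf("ch%02d", seq_len(n_channels))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n_channels || anyDuplicated(channel_labels)) {
    stop("`channel_labels` must be ", n_channels, " unique labels")
  }
  frontal <- if (n_channels == 27 && all(eeg_channel_labels() %in% channel_labels)) {
    match(default_roi_scheme()$rois$frontal, channel_labels)
  } else {
    seq_len(max(1L, floor(n_channels / 4)))
  }
  if (is.null(coupled_pairs_B)) {
    coupled_pairs_B <- if (n_channels == 27) {
      lapply(list(c("Fz", "Pz"), c("F3", "P3"), c("F4", "P4"),
                  c("F7", "P7"), c("F8", "P8"), c("Fpz", "Oz"),
                  c("F9", "PO7"), c("F10", "PO8"),
                  c("F3", "C3"), c("F4", "C4"),
                  c("F7", "T7"), c("F8", "T8")),
             function(p) match(p, channel_labels))
    } else {
      list()
    }
  } else {
    coupled_pairs_B <- lapply(coupled_pairs_B, function(p) {
      if (is.character(p)) p <- match(p, channel_labels)
      p
    })
  }
  for (p in coupled_pairs_B) {
    if (length(p) != 2L || anyNA(p) || any(p < 1) || any(p > n_channels) ||
        p[1] == p[2]) {
      stop("each coupled pair must reference two distinct valid channels")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
         duration_s = duration_s, fs = fs,
         frontal_noise_mix_A = frontal_noise_mix_A,
         frontal_noise_mix_B = frontal_noise_mix_B,
         coupled_pairs_B = coupled_pairs_B,
         coupling_freq = coupling_freq,
         coupling_phase_lag = coupling_phase_lag,
         coupling_amp = coupling_amp,
         coupling_bw = coupling_bw,
         noise_mix_sd = noise_mix_sd,
         coupling_amp_jitter = coupling_amp_jitter,
         channel_labels = channel_labels,
         frontal_channels = frontal,
         seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf(paste0("<experiment_spec> %d subjects x 2 conditions, %d channels, ",
                     "%g s @ %g Hz\n  frontal white-noise mix: A = %.2f, B = %.2f; ",
                     "%d coupled pair(s) at %g Hz (lag %.3f rad) in B; seed %d\n"),
              x$n_subjects, x$n_channels, x$duration_s, x$fs,
              x$frontal_noise_mix_A, x$frontal_noise_mix_B,
              length(x$coupled_pairs_B), x$coupling_freq,
              x$coupling_phase_lag, x$seed))
  invisible(x)
}

# One synthetic channel: convex mix of white and 1/f noise, standardized.
.mixed_channel <- function(n, lambda) {
  pink <- gen_noise(n, "pink")
  x <- if (lambda > 0) lambda * rnorm(n) + (1 - lambda) * pink else pink
  (x - mean(x)) / sd(x)
}

# Band-limited Gaussian analytic signal centred on `freq` (one-sided
# spectrum), real part standardized to unit RMS. Re(z * exp(-1i * lag))
# reproduces the oscillator with a constant phase lag across its band.
.narrowband_oscillator <- function(n, fs, freq, bw) {
  freqs <- (seq_len(n) - 1) * fs / n
  pos <- which(freqs > 0 & freqs <= fs / 2 &
                 abs(freqs - freq) <= bw / 2)
  X <- complex(real = rep(0, n))
  X[pos] <- complex(real = rnorm(length(pos)), imaginary = rnorm(length(pos)))
  z <- fft(X, inverse = TRUE) / n
  z / sd(Re(z))
}

#' Generate a synthetic two-condition experiment
#'
#' Produces one [recording()] per subject and condition according to an
#' [experiment_spec()]. Frontal channels of each condition carry the
#' condition's white-noise mixing fraction; all other channels are
#' standardized 1/f noise. Channels belonging to a coupled pair carry a
#' narrowband stochastic gamma oscillator (band-limited Gaussian noise
#' centred on `coupling_freq`, fresh per subject and pair) in *both*
#' conditions, so the conditions' univariate statistics match; in condition B
#' the two channels of a pair share one oscillator with a constant
#' inter-channel phase lag across its band (phase coupling), whereas in
#' condition A each channel receives its own independent oscillator (no
#' coupling). Fully reproducible from `spec$seed`.
#'
#' @param spec An [experiment_spec()].
#' @return Named list of `recording` objects (`"<subject>_<condition>"`),
#'   `n_subjects * 2` in total, ordered subject-major.
#' @export
gen_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  n <- round(spec$duration_s * spec$fs)
  out <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("s%02d", s)
    for (cond in c("A", "B")) {
      lam <- if (cond == "A") spec$frontal_noise_mix_A else spec$frontal_noise_mix_B
      rec_seed <- derive_seed(spec$seed, 2L * s + (cond == "B"))
      data <- with_seed(rec_seed, {
        lam_s <- min(1, max(0, lam + rnorm(1, 0, spec$noise_mix_sd)))
        m <- matrix(0, nrow = spec$n_channels, ncol = n)
        for (ch in seq_len(spec$n_channels)) {
          ch_lam <- if (ch %in% spec$frontal_channels) lam_s else 0
          m[ch, ] <- .mixed_channel(n, ch_lam)
        }
        # both conditions carry gamma oscillators in the paired channels, so
        # their univariate statistics match; only condition B shares one
        # oscillator (with a lag) across each pair, creating phase coupling
        j <- spec$coupling_amp_jitter
        for (p in spec$coupled_pairs_B) {
          amp_s <- spec$coupling_amp * runif(1, 1 - j, 1 + j)
          if (cond == "B") {
            z <- .narrowband_oscillator(n, spec$fs, spec$coupling_freq,
                                        spec$coupling_bw)
            m[p[1], ] <- m[p[1], ] + amp_s * Re(z)
            m[p[2], ] <- m[p[2], ] +
              amp_s * Re(z * exp(-1i * spec$coupling_phase_lag))
          } else {
            z1 <- .narrowband_oscillator(n, spec$fs, spec$coupling_freq,
                                         spec$coupling_bw)
            z2 <- .narrowband_oscillator(n, spec$fs, spec$coupling_freq,
                                         spec$coupling_bw)
            m[p[1], ] <- m[p[1], ] + amp_s * Re(z1)
            m[p[2], ] <- m[p[2], ] + amp_s * Re(z2)
          }
        }
        m
      })
      out[[paste(sid, cond, sep = "_")]] <-
        recording(data, fs = spec$fs, channel_labels = spec$channel_labels,
                  subject_id = sid, condition = cond)
    }
  }
  out
}
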