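#' Frequency band definitions
#'
#' The canonical bands used for connectivity estimation: alpha 7-13 Hz, beta
#' 13-25 Hz, gamma 25-45 Hz. Bands are treated as half-open intervals
#' `[lo, hi)` so that shared edges (13 Hz, 25 Hz) are counted once, in the
#' lower band.
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return `band_spec()` returns a one-row data frame (`name`, `lo`, `hi`);
#'   `default_bands()` returns the three-row alpha/beta/gamma data frame.
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lo), is.numeric(hi), lo > 0, hi > lo)
  data.frame(name = name, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

#' @rdname band_spec
#' @export
default_bands <- function() {
  rbind(band_spec("alpha", 7, 13),
        band_spec("beta", 13, 25),
        band_spec("gamma", 25, 45))
}

#' Split a recording into non-overlapping windows
#'
#' Contiguous non-overlapping windows of `win_s` seconds; a trailing
#' remainder shorter than one window is dropped.
#'
#' @param rec A [recording()].
#' @param win_s Window length in seconds (default 1).
#' @return List of numeric matrices (channels x window samples).
#' @export
window_split <- function(rec, win_s = 1) {
  stopifnot(inherits(rec, "recording"), win_s > 0)
  nsamp <- floor(win_s * rec$fs)
  nw <- floor(ncol(rec$data) / nsamp)
  if (nw < 1) {
    stop("recording shorter than one window (", win_s, " s)")
  }
  lapply(seq_len(nw), function(w) {
    rec$data[, ((w - 1L) * nsamp + 1L):(w * nsamp), drop = FALSE]
  })
}

# Symmetric Hann taper.
.hann <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# Demean per channel, taper, and Fourier-transform one window.
# Returns an (nsamp x nch) complex matrix of DFT coefficients.
.window_fft <- function(seg, taper) {
  seg <- seg - rowMeans(seg)
  mvfft(t(seg) * taper)
}

#' Windowed cross-spectral densities
#'
#' Per window: demean each channel, apply a Hann taper, take the discrete
#' Fourier transform, and form `S_ij(f) = X_i(f) * Conj(X_j(f))`. The
#' frequency resolution is the reciprocal of the window length. The result is
#' Hermitian in the channel pair at every window and frequency, with real
#' non-negative diagonal.
#'
#' @param windows List of channels x samples matrices (from [window_split()]),
#'   all of equal size.
#' @param fs Sampling rate in Hz.
#' @param fmin,fmax Restrict the retained frequency grid (Hz); defaults keep
#'   all non-negative frequencies up to Nyquist.
#' @return A `cross_spectra` object: list with complex array `csd` of
#'   dimension windows x channels x channels x frequencies, and the `freqs`
#'   grid (Hz).
#' @export
cross_spectra <- function(windows, fs, fmin = 0, fmax = fs / 2) {
  stopifnot(is.list(windows), length(windows) >= 1)
  dims <- vapply(windows, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all windows must have identical dimensions")
  }
  nch <- dims[1, 1]
  nsamp <- dims[2, 1]
  freqs_all <- (seq_len(nsamp) - 1) * fs / nsamp
  sel <- which(freqs_all >= fmin & freqs_all <= fmax & freqs_all <= fs / 2)
  if (length(sel) == 0) stop("no frequency bins in the requested range")
  taper <- .hann(nsamp)
  nw <- length(windows)
  nf <- length(sel)
  csd <- array(complex(real = 0), dim = c(nw, nch, nch, nf))
  for (w in seq_len(nw)) {
    X <- .window_fft(windows[[w]], taper)[sel, , drop = FALSE]
    for (f in seq_len(nf)) {
      csd[w, , , f] <- outer(X[f, ], Conj(X[f, ]))
    }
  }
  structure(list(csd = csd, freqs = freqs_all[sel],
                 labels = rownames(windows[[1]])),
            class = "cross_spectra")
}

#' Weighted phase lag index in a band
#'
#' Per frequency bin inside the band (half-open `[lo, hi)`), the numerator
#' `|sum_w Im S_ij,w(f)|` and denominator `sum_w |Im S_ij,w(f)|` are
#' accumulated across windows; the band value is the ratio of their sums over
#' bins, `sum_f |sum_w Im S| / sum_f sum_w |Im S|`, i.e., an average of the
#' per-bin WPLI weighted by each bin's imaginary cross-spectral energy (a
#' uniform bin average would dilute narrowband coupling with the noise floor
#' of empty bins). Pairs whose imaginary cross-spectrum vanishes identically
#' (e.g., zero-lag identical signals) get 0 by convention. The estimator is
#' insensitive to per-channel amplitude rescaling and blind to zero-lag
#' coupling.
#'
#' @param cs A [cross_spectra()] object.
#' @param band One row of a band data frame (see [band_spec()]), or any list
#'   with elements `lo` and `hi`.
#' @return Symmetric channels x channels matrix of WPLI values in `[0, 1]`
#'   with zero diagonal.
#' @export
wpli <- function(cs, band) {
  stopifnot(inherits(cs, "cross_spectra"))
  bins <- which(cs$freqs >= band$lo & cs$freqs < band$hi)
  if (length(bins) == 0) {
    stop("no frequency bins inside band [", band$lo, ", ", band$hi, ")")
  }
  nch <- dim(cs$csd)[2]
  num_acc <- den_acc <- matrix(0, nch, nch)
  for (f in bins) {
    ImS <- Im(cs$csd[, , , f, drop = FALSE])
    dim(ImS) <- dim(cs$csd)[1:3]
    num_acc <- num_acc + abs(apply(ImS, c(2, 3), sum))
    den_acc <- den_acc + apply(abs(ImS), c(2, 3), sum)
  }
  W <- num_acc / den_acc
  W[den_acc == 0] <- 0
  diag(W) <- 0
  dimnames(W) <- list(cs$labels, cs$labels)
  W
}

# Efficient band-restricted WPLI for a whole recording: computes window FFTs
# only at the union of band bins and accumulates pair sums without
# materialising the full cross-spectral array. Numerically identical to
# wpli(cross_spectra(...), band).
.band_wpli_core <- function(data, fs, bands, win_s = 1) {
  nsamp <- floor(win_s * fs)
  nw <- floor(ncol(data) / nsamp)
  if (nw < 1) stop("recording shorter than one window (", win_s, " s)")
  nch <- nrow(data)
  freqs_all <- (seq_len(nsamp) - 1) * fs / nsamp
  band_bins <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs_all >= bands$lo[b] & freqs_all < bands$hi[b] &
            freqs_all <= fs / 2)
  })
  for (b in seq_along(band_bins)) {
    if (length(band_bins[[b]]) == 0) {
      stop("no frequency bins inside band ", bands$name[b])
    }
  }
  sel <- sort(unique(unlist(band_bins)))
  taper <- .hann(nsamp)
  nf <- length(sel)
  ReX <- ImX <- array(0, dim = c(nw, nch, nf))
  for (w in seq_len(nw)) {
    seg <- data[, ((w - 1L) * nsamp + 1L):(w * nsamp), drop = FALSE]
    X <- .window_fft(seg, taper)[sel, , drop = FALSE]
    ReX[w, , ] <- t(Re(X))
    ImX[w, , ] <- t(Im(X))
  }
  # per-bin pair sums over windows
  num <- den <- array(0, dim = c(nch, nch, nf))
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      imS <- ImX[, i, , drop = FALSE] * ReX[, j, , drop = FALSE] -
        ReX[, i, , drop = FALSE] * ImX[, j, , drop = FALSE]
      dim(imS) <- c(nw, nf)
      num[i, j, ] <- colSums(imS)
      den[i, j, ] <- colSums(abs(imS))
    }
  }
  out <- lapply(seq_len(nrow(bands)), function(b) {
    pos <- match(band_bins[[b]], sel)
    num_b <- den_b <- matrix(0, nch, nch)
    for (f in pos) {
      num_b <- num_b + abs(num[, , f])
      den_b <- den_b + den[, , f]
    }
    W <- num_b / den_b
    W[den_b == 0] <- 0
    W <- W + t(W)
    diag(W) <- 0
    dimnames(W) <- list(rownames(data), rownames(data))
    W
  })
  names(out) <- bands$name
  out
}

#' Band WPLI matrices for a recording
#'
#' Convenience wrapper that splits a recording into non-overlapping windows
#' and returns one WPLI matrix per requested band. Equivalent to calling
#' [wpli()] on [cross_spectra()] of the window list, but computed band by band
#' without materialising the full cross-spectral array.
#'
#' @param rec A [recording()].
#' @param bands Band data frame (default [default_bands()]).
#' @param win_s Window length in seconds (default 1).
#' @return Named list of symmetric WPLI matrices, one per band.
#' @export
band_wpli <- function(rec, bands = default_bands(), win_s = 1) {
  stopifnot(inherits(rec, "recording"))
  .band_wpli_core(rec$data, rec$fs, bands, win_s)
}

#' Phase-randomized surrogate of a recording
#'
#' Per channel independently: Fourier-transform, keep every amplitude, replace
#' the phase of each positive frequency by an i.i.d. draw from uniform(0, 2*pi)
#' (DC and Nyquist untouched), enforce Hermitian symmetry, and invert. The
#' surrogate preserves each channel's amplitude spectrum exactly while
#' destroying all cross-channel phase relations, providing the null for
#' connectivity thresholding.
#'
#' @param rec A [recording()].
#' @param seed Optional integer seed (same seed, same surrogate).
#' @return A [recording()] with surrogate data.
#' @export
phase_randomized_surrogate <- function(rec, seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$data)
  half <- floor((n - 1) / 2)       # positive, non-Nyquist frequencies
  pos <- if (half >= 1) 2:(half + 1) else integer(0)
  out <- with_seed(seed, {
    m <- rec$data
    for (ch in seq_len(nrow(m))) {
      X <- fft(m[ch, ])
      if (length(pos) > 0) {
        phases <- runif(length(pos), 0, 2 * pi)
        X[pos] <- Mod(X[pos]) * exp(1i * phases)
        X[n + 2 - pos] <- Conj(X[pos])
      }
      m[ch, ] <- Re(fft(X, inverse = TRUE) / n)
    }
    m
  })
  recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
            subject_id = rec$subject_id, condition = rec$condition)
}

#' Surrogate-thresholded binary connectivity networks
#'
#' Computes the band WPLI of the recording and of `n_surrogates`
#' phase-randomized surrogates, then keeps an edge iff its observed band WPLI
#' exceeds the `q`-quantile of that edge's own surrogate values (per edge and
#' per band). `threshold_networks()` handles all bands from a single shared
#' surrogate ensemble; `threshold_network()` is the single-band convenience
#' form.
#'
#' @inheritParams band_wpli
#' @param band One row of a band data frame.
#' @param n_surrogates Number of surrogates (default 200). Fewer than 20
#'   triggers a warning: the quantile becomes unstable.
#' @param q Quantile used as threshold (default 0.95).
#' @param seed Optional integer seed for the surrogate ensemble.
#' @return A `binary_network` (or a named list of them): list with the 0/1
#'   `adjacency` matrix (zero diagonal), the `band` row, per-edge `threshold`
#'   matrix, observed `wpli` matrix and `channel_labels`.
#' @export
threshold_networks <- function(rec, bands = default_bands(),
                               n_surrogates = 200, q = 0.95, seed = NULL,
                               win_s = 1) {
  stopifnot(inherits(rec, "recording"), .is_count(n_surrogates),
            q > 0, q < 1)
  if (n_surrogates < 20) {
    warning("fewer than 20 surrogates: threshold quantile is unstable")
  }
  actual <- band_wpli(rec, bands, win_s)
  nch <- nrow(rec$data)
  nb <- nrow(bands)
  surr <- array(NA_real_, dim = c(n_surrogates, nch, nch, nb))
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      sw <- band_wpli(phase_randomized_surrogate(rec), bands, win_s)
      for (b in seq_len(nb)) surr[s, , , b] <- sw[[b]]
    }
  })
  out <- lapply(seq_len(nb), function(b) {
    thr <- apply(surr[, , , b, drop = FALSE], c(2, 3), quantile, probs = q)
    adj <- (actual[[b]] > thr) * 1L
    diag(adj) <- 0L
    diag(thr) <- 0
    dimnames(adj) <- dimnames(thr) <- dimnames(actual[[b]])
    structure(list(adjacency = adj, band = bands[b, , drop = FALSE],
                   threshold = thr, wpli = actual[[b]],
                   channel_labels = rec$channel_labels),
              class = "binary_network")
  })
  names(out) <- bands$name
  out
}

#' @rdname threshold_networks
#' @export
threshold_network <- function(rec, band, n_surrogates = 200, q = 0.95,
                              seed = NULL, win_s = 1) {
  threshold_networks(rec, bands = band, n_surrogates = n_surrogates, q = q,
                     seed = seed, win_s = win_s)[[1]]
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %s band [%g, %g) Hz: %d nodes, %d significant edges\n",
              x$band$name, x$band$lo, x$band$hi, nrow(x$adjacency), gfc(x)))
  invisible(x)
}

#' Global functional connectivity
#'
#' The number of significant connections in a binarized network: the count of
#' 1-edges in the upper triangle of the adjacency matrix.
#'
#' @param net A `binary_network` (see [threshold_networks()]) or a symmetric
#'   0/1 adjacency matrix.
#' @return Integer edge count.
#' @export
gfc <- function(net) {
  adj <- if (inherits(net, "binary_network")) net$adjacency else net
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  sum(adj[upper.tri(adj)])
}
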