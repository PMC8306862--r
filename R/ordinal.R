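#' Time-delay embedding
#'
#' Embeds a series into `m`-dimensional delay vectors
#' `(x[k], x[k + tau], ..., x[k + (m - 1) tau])` for
#' `k = 1, ..., T - (m - 1) tau`.
#'
#' @param x Numeric vector of length `T >= (m - 1) * tau + 1`.
#' @param m Embedding dimension (>= 2, default 5).
#' @param tau Time delay in samples (>= 1, default 1).
#' @return Numeric matrix with `T - (m - 1) * tau` rows and `m` columns.
#' @examples
#' embed_series(c(1, 2, 3, 4), m = 2)
#' @export
embed_series <- function(x, m = 5, tau = 1) {
  stopifnot(is.numeric(x), .is_count(m), m >= 2, .is_count(tau))
  nwin <- length(x) - (m - 1) * tau
  if (nwin < 1) {
    stop("series too short for embedding: need at least (m-1)*tau + 1 = ",
         (m - 1) * tau + 1, " samples, got ", length(x))
  }
  out <- vapply(seq_len(m) - 1L, function(j) x[seq_len(nwin) + j * tau],
                numeric(nwin))
  matrix(out, nrow = nwin, ncol = m)
}

#' Ordinal pattern of one embedded vector
#'
#' Maps an `m`-dimensional vector to its ordinal pattern: the permutation of
#' positions that sorts the vector ascending, with exact ties broken by the
#' earlier position (stable). The pattern is encoded as its lexicographic
#' permutation rank, an integer in `0 ... m! - 1`, a bijection independent of
#' the data.
#'
#' @param v Numeric vector (one embedded window).
#' @return Integer pattern index in `0 ... m! - 1`.
#' @seealso [permutation_from_rank()] to decode the index.
#' @examples
#' ordinal_pattern(c(3, 1, 2))  # permutation (2, 3, 1), rank 3
#' @export
ordinal_pattern <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 2)
  rank_from_permutation(order(v))
}

#' Encode / decode permutations as lexicographic ranks
#'
#' `rank_from_permutation()` maps a permutation of `1:m` to its 0-based
#' lexicographic rank via the Lehmer code; `permutation_from_rank()` is the
#' inverse.
#'
#' @param perm Integer permutation of `1:m`.
#' @param rank Integer in `0 ... m! - 1`.
#' @param m Permutation length.
#' @return An integer rank, or an integer permutation of `1:m`.
#' @export
rank_from_permutation <- function(perm) {
  m <- length(perm)
  stopifnot(setequal(perm, seq_len(m)))
  fact <- cumprod(c(1, seq_len(m)))  # fact[i] = (i-1)!
  r <- 0
  for (j in seq_len(m - 1L)) {
    r <- r + sum(perm[(j + 1L):m] < perm[j]) * fact[m - j + 1L]
  }
  as.integer(r)
}

#' @rdname rank_from_permutation
#' @export
permutation_from_rank <- function(rank, m) {
  stopifnot(.is_count(m) || m == 0, rank >= 0, rank < factorial(m))
  avail <- seq_len(m)
  perm <- integer(m)
  r <- rank
  for (j in seq_len(m)) {
    f <- factorial(m - j)
    d <- r %/% f
    r <- r %% f
    perm[j] <- avail[d + 1L]
    avail <- avail[-(d + 1L)]
  }
  perm
}

.new_ordinal_distribution <- function(probs, m, weighted, counts_total) {
  structure(list(probs = probs, m = as.integer(m), weighted = weighted,
                 counts_total = counts_total),
            class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("<ordinal_distribution> m = %d (%d patterns), %s, effective mass %g\n",
              x$m, length(x$probs), if (x$weighted) "weighted" else "unweighted",
              x$counts_total))
  invisible(x)
}

#' Ordinal pattern distribution of a series
#'
#' Relative frequencies of the `m!` ordinal patterns over all embedded windows
#' of `x` (unobserved patterns have probability zero). The weighted variant
#' restores amplitude sensitivity by letting each window contribute its
#' variance `w = mean((window - mean(window))^2)` instead of a unit count;
#' probabilities are pattern-wise weight sums normalised by the total weight.
#'
#' @inheritParams embed_series
#' @return An `ordinal_distribution`: probabilities over the `m!` patterns
#'   indexed by lexicographic rank, plus `m`, a `weighted` flag, and the
#'   total mass (window count, or total weight).
#' @examples
#' pattern_probabilities(c(1, 3, 2, 5, 4), m = 3)
#' @export
pattern_probabilities <- function(x, m = 5, tau = 1) {
  ranks <- ordinal_pattern_ranks(as.numeric(x), as.integer(m), as.integer(tau))
  nb <- factorial(m)
  counts <- tabulate(ranks + 1L, nbins = nb)
  .new_ordinal_distribution(counts / length(ranks), m, FALSE, length(ranks))
}

#' @rdname pattern_probabilities
#' @export
weighted_pattern_probabilities <- function(x, m = 5, tau = 1) {
  x <- as.numeric(x)
  ranks <- ordinal_pattern_ranks(x, as.integer(m), as.integer(tau))
  w <- ordinal_window_weights(x, as.integer(m), as.integer(tau))
  total <- sum(w)
  if (total <= 0) {
    stop("all embedded windows have zero variance; weighted distribution is degenerate")
  }
  nb <- factorial(m)
  sums <- numeric(nb)
  agg <- rowsum(w, ranks)
  sums[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  .new_ordinal_distribution(sums / total, m, TRUE, total)
}

#' Normalized permutation entropy
#'
#' Shannon entropy (natural log) of an ordinal pattern distribution divided by
#' `log(m!)`, the entropy of the uniform distribution over patterns, giving a
#' value in `[0, 1]`. Applied to a weighted distribution this is the weighted
#' permutation entropy.
#'
#' @param dist An [`ordinal_distribution`][pattern_probabilities].
#' @return Normalized entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(dist) {
  stopifnot(inherits(dist, "ordinal_distribution"))
  .shannon(dist$probs) / log(factorial(dist$m))
}

#' Jensen-Shannon statistical complexity
#'
#' The product of the (normalized) Jensen-Shannon divergence between the
#' ordinal pattern distribution `p` and the uniform distribution `u` over the
#' `M = m!` patterns, and the normalized permutation entropy:
#' `C = Q0 * JSD(p, u) * Hnorm(p)` with
#' `JSD = H((p+u)/2) - H(p)/2 - H(u)/2` and normalization constant
#' `Q0 = -2 / (((M+1)/M) log(M+1) - 2 log(2M) + log M)`. The complexity is
#' zero for both fully ordered (degenerate) and fully random (uniform)
#' distributions, and positive in between, tracing a parabola-like region
#' against entropy.
#'
#' @inheritParams permutation_entropy
#' @return Non-negative complexity value.
#' @export
jensen_shannon_complexity <- function(dist) {
  stopifnot(inherits(dist, "ordinal_distribution"))
  p <- dist$probs
  M <- length(p)
  u <- 1 / M
  jsd <- .shannon((p + u) / 2) - .shannon(p) / 2 - log(M) / 2
  q0 <- -2 / (((M + 1) / M) * log(M + 1) - 2 * log(2 * M) + log(M))
  hnorm <- .shannon(p) / log(M)
  q0 * jsd * hnorm
}

#' Coarse-grain a series
#'
#' Replaces the series by means of consecutive non-overlapping blocks of
#' `theta` samples (scale factor); the trailing partial block is dropped, so
#' the result has `floor(T / theta)` points. `theta = 1` returns the input.
#'
#' @param x Numeric vector.
#' @param theta Integer scale factor (>= 1, at most `length(x)`).
#' @return Numeric vector of block means.
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), 2)
#' @export
coarse_grain <- function(x, theta) {
  stopifnot(is.numeric(x), .is_count(theta))
  if (theta == 1) return(x)
  K <- floor(length(x) / theta)
  if (K < 1) stop("series shorter than one block: length ", length(x),
                  " < theta = ", theta)
  colMeans(matrix(x[seq_len(K * theta)], nrow = theta))
}

#' Multiscale entropy-complexity profile of a recording
#'
#' For every channel and every time scale `theta`, coarse-grains the channel,
#' builds the (optionally weighted) ordinal pattern distribution, and computes
#' normalized permutation entropy and Jensen-Shannon complexity. With
#' `weighted = TRUE` this yields the multiscale weighted measures; with
#' `weighted = FALSE` their unweighted counterparts. The column at
#' `theta = 1` equals the single-scale measures.
#'
#' @param rec A [recording()].
#' @param m,tau Embedding parameters (defaults 5 and 1).
#' @param scales Integer vector of strictly increasing scale factors
#'   (default `1:20`).
#' @param weighted Use variance-weighted pattern probabilities (default TRUE).
#' @return A `complexity_profile`: list with `entropy` and `complexity`
#'   matrices (channels x scales), `scales`, `channel_labels`, `variant`,
#'   `subject_id` and `condition`.
#' @export
multiscale_profile <- function(rec, m = 5, tau = 1, scales = 1:20,
                               weighted = TRUE) {
  stopifnot(inherits(rec, "recording"))
  scales <- as.integer(scales)
  if (length(scales) < 1 || any(diff(scales) <= 0) || any(scales < 1)) {
    stop("`scales` must be strictly increasing positive integers")
  }
  nch <- nrow(rec$data)
  H <- Cx <- matrix(NA_real_, nch, length(scales),
                    dimnames = list(rec$channel_labels, paste0("s", scales)))
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, ]
    for (si in seq_along(scales)) {
      y <- coarse_grain(x, scales[si])
      dist <- if (weighted) weighted_pattern_probabilities(y, m, tau) else
        pattern_probabilities(y, m, tau)
      H[ch, si] <- permutation_entropy(dist)
      Cx[ch, si] <- jensen_shannon_complexity(dist)
    }
  }
  structure(
    list(entropy = H, complexity = Cx, scales = scales,
         channel_labels = rec$channel_labels,
         variant = if (weighted) "MWPE/MWJSC" else "MPE/MJSC",
         subject_id = rec$subject_id, condition = rec$condition),
    class = "complexity_profile"
  )
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat(sprintf("<complexity_profile> %s: %d channels x %d scales (subject %s, condition %s)\n",
              x$variant, nrow(x$entropy), length(x$scales), x$subject_id,
              x$condition))
  invisible(x)
}

#' @export
as.data.frame.complexity_profile <- function(x, ...) {
  data.frame(
    subject = x$subject_id,
    condition = x$condition,
    channel = rep(x$channel_labels, times = length(x$scales)),
    scale = rep(x$scales, each = length(x$channel_labels)),
    entropy = as.vector(x$entropy),
    complexity = as.vector(x$complexity),
    variant = x$variant,
    stringsAsFactors = FALSE
  )
}
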