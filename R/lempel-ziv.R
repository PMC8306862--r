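#' Symbol sequences for Lempel-Ziv analysis
#'
#' `binarize_median()` thresholds a signal at its median: values below the
#' median become 0, values at or above it become 1 (the at-median convention
#' is fixed; exact ties have measure zero for continuous signals).
#' `symbolize_ordinal()` replaces each embedded window by its ordinal pattern
#' index, giving an alphabet of `m!` symbols with the same embedding used for
#' permutation entropy.
#'
#' @param x Numeric vector (length >= 2 for median binarization).
#' @inheritParams embed_series
#' @return A `symbol_sequence`: list with integer `symbols` in
#'   `0 ... alphabet_size - 1` and `alphabet_size`.
#' @examples
#' binarize_median(c(1, 2, 3, 4))
#' @export
binarize_median <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  symbol_sequence(as.integer(x >= median(x)), 2L)
}

#' @rdname binarize_median
#' @export
symbolize_ordinal <- function(x, m = 5, tau = 1) {
  ranks <- ordinal_pattern_ranks(as.numeric(x), as.integer(m), as.integer(tau))
  symbol_sequence(ranks, factorial(m))
}

#' @rdname binarize_median
#' @param symbols Integer vector of symbols in `0 ... alphabet_size - 1`.
#' @param alphabet_size Alphabet size `A >= 2`.
#' @export
symbol_sequence <- function(symbols, alphabet_size) {
  symbols <- as.integer(symbols)
  stopifnot(.is_count(alphabet_size), alphabet_size >= 2,
            length(symbols) >= 1, !anyNA(symbols),
            all(symbols >= 0), all(symbols < alphabet_size))
  structure(list(symbols = symbols, alphabet_size = as.integer(alphabet_size)),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence> %d symbols, alphabet size %d\n",
              length(x$symbols), x$alphabet_size))
  invisible(x)
}

#' Lempel-Ziv (1976) complexity
#'
#' Counts the phrases `c(n)` of the exhaustive-history parsing of a symbol
#' sequence: each phrase is the shortest continuation not reproducible from
#' the preceding text. With `normalize = TRUE` the count is scaled by
#' `log_A(n) / n` (alphabet size `A`), which tends to 1 for i.i.d. uniform
#' symbols and makes different alphabet sizes comparable.
#'
#' @param s A [symbol_sequence()].
#' @param normalize Return the normalized value instead of the raw count.
#' @return Phrase count (integer) or normalized complexity (numeric).
#' @examples
#' s <- symbol_sequence(c(0,0,0,1,1,0,1,0,0,1,0,0,0,1,0,1), 2)
#' lz76_complexity(s)  # 6
#' @export
lz76_complexity <- function(s, normalize = FALSE) {
  stopifnot(inherits(s, "symbol_sequence"))
  cn <- lz76_phrase_count(s$symbols)
  if (!normalize) return(cn)
  n <- length(s$symbols)
  cn * (log(n) / log(s$alphabet_size)) / n
}

#' Multiscale Lempel-Ziv complexity of a recording
#'
#' For every channel and time scale: coarse-grain (see [coarse_grain()]),
#' symbolize with the median (`variant = "median"`, binary alphabet) or
#' ordinal-pattern (`variant = "permutation"`, alphabet `m!`) scheme, and
#' compute the normalized LZ76 complexity.
#'
#' @inheritParams multiscale_profile
#' @param variant `"median"` (mLZC) or `"permutation"` (pLZC).
#' @return Numeric matrix channels x scales of normalized LZ76 values, with
#'   attributes `variant`, `scales`, `subject_id`, `condition`.
#' @export
multiscale_lzc <- function(rec, variant = c("median", "permutation"),
                           m = 5, tau = 1, scales = 1:20) {
  stopifnot(inherits(rec, "recording"))
  variant <- match.arg(variant)
  scales <- as.integer(scales)
  if (length(scales) < 1 || any(diff(scales) <= 0) || any(scales < 1)) {
    stop("`scales` must be strictly increasing positive integers")
  }
  nch <- nrow(rec$data)
  out <- matrix(NA_real_, nch, length(scales),
                dimnames = list(rec$channel_labels, paste0("s", scales)))
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, ]
    for (si in seq_along(scales)) {
      y <- coarse_grain(x, scales[si])
      s <- if (variant == "median") binarize_median(y) else
        symbolize_ordinal(y, m, tau)
      out[ch, si] <- lz76_complexity(s, normalize = TRUE)
    }
  }
  structure(out,
            variant = if (variant == "median") "mLZC" else "pLZC",
            scales = scales, subject_id = rec$subject_id,
            condition = rec$condition)
}
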