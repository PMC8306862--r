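#' Multichannel recording container
#'
#' A `recording` holds one subject-condition multichannel signal: a numeric
#' matrix of channels x samples, its sampling rate and ordered channel labels.
#' All analysis functions in the package consume this container.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique labels, one per row of
#'   `data`. Defaults to the rownames of `data`.
#' @param subject_id Subject identifier string.
#' @param condition Condition label, `"A"` or `"B"` (the package convention is
#'   A = baseline viewing, B = perturbed viewing).
#'
#' @return An object of class `recording`: a list with elements `data`, `fs`,
#'   `channel_labels`, `subject_id`, `condition`.
#' @examples
#' x <- matrix(rnorm(2 * 100), nrow = 2, dimnames = list(c("Fz", "Pz"), NULL))
#' rec <- recording(x, fs = 100)
#' rec
#' @export
recording <- function(data, fs, channel_labels = rownames(data),
                      subject_id = "s01", condition = c("A", "B")) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)")
  }
  if (ncol(data) < 1L) stop("channels must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  condition <- match.arg(condition)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must have one entry per channel row")
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), condition = condition),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s, condition %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Standard 27-channel montage labels
#'
#' The 10-5 system electrode labels used by the default synthetic experiments
#' and by the default region-of-interest scheme.
#'
#' @return Character vector of 27 channel labels.
#' @export
eeg_channel_labels <- function() {
  c("Fpz", "Fz", "F3", "F4", "F7", "F8", "F9", "F10",
    "FC5", "FC6", "T7", "C3", "Cz", "C4", "T8", "CP5", "CP6",
    "P7", "P3", "Pz", "P4", "P8", "PO7", "PO8", "O1", "Oz", "O2")
}
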