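# Small reusable fixtures, all generated in code.

make_recording <- function(nch = 2, n = 1000, fs = 100, seed = 42,
                           labels = NULL, condition = "A", subject = "s01") {
  data <- with_test_seed(seed, matrix(rnorm(nch * n), nrow = nch))
  recording(data, fs = fs, channel_labels = labels,
            subject_id = subject, condition = condition)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Reduced synthetic experiment used by the effect-recovery tests.
small_experiment_spec <- function(n_subjects = 10, duration_s = 30,
                                  fs = 1000, seed = 11) {
  experiment_spec(n_subjects = n_subjects, duration_s = duration_s, fs = fs,
                  seed = seed)
}
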