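test_that("embedding produces the delay vectors and window count", {
  expect_equal(embed_series(c(1, 2, 3, 4), m = 2),
               cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(embed_series(c(1, 5, 2, 6, 3), m = 3, tau = 2),
               matrix(c(1, 2, 3), nrow = 1))
  x <- gen_noise(120000, "white", seed = 1)
  expect_identical(nrow(embed_series(x, m = 5, tau = 1)), 119996L)
  expect_length(ordinal_pattern_ranks(x, 5L, 1L), 119996L)
  expect_error(embed_series(1:3, m = 5), "too short")
})

test_that("ordinal patterns use stable ties and a bijective rank encoding", {
  expect_identical(ordinal_pattern(c(1, 2, 3, 4)), 0L)   # identity
  expect_identical(ordinal_pattern(c(3, 1, 2)),
                   rank_from_permutation(c(2, 3, 1)))
  # equal values keep position order: (2,2,1) sorts as positions 3,1,2
  expect_identical(ordinal_pattern(c(2, 2, 1)),
                   rank_from_permutation(c(3, 1, 2)))
  # rank encoding is a bijection for m up to 5
  for (m in 2:5) {
    ranks <- vapply(seq_len(factorial(m)) - 1L, function(r) {
      rank_from_permutation(permutation_from_rank(r, m))
    }, integer(1))
    expect_identical(ranks, seq_len(factorial(m)) - 1L)
  }
})

test_that("pattern probabilities match hand enumeration", {
  d <- pattern_probabilities(c(1, 3, 2, 5, 4), m = 3)
  expect_equal(sum(d$probs), 1)
  expect_equal(d$probs[rank_from_permutation(c(1, 3, 2)) + 1], 2 / 3)
  expect_equal(d$probs[rank_from_permutation(c(2, 1, 3)) + 1], 1 / 3)
  # constant series: all mass on the identity pattern via stable ties
  dc <- pattern_probabilities(rep(1, 50), m = 3)
  expect_equal(dc$probs[1], 1)
  expect_equal(permutation_entropy(dc), 0)
})

test_that("weighted probabilities weigh windows by variance", {
  dw <- weighted_pattern_probabilities(c(0, 0, 0, 5, 1), m = 2)
  expect_equal(dw$probs, c(6.25, 4) / 10.25)
  expect_equal(dw$counts_total, 10.25)
  # equal-variance windows: weighted equals unweighted
  x <- c(rep(c(1, -1), 30), 1)  # 60 windows at m = 2, alternating patterns
  expect_equal(weighted_pattern_probabilities(x, m = 2)$probs,
               pattern_probabilities(x, m = 2)$probs)
  expect_equal(weighted_pattern_probabilities(x, m = 2)$probs, c(0.5, 0.5))
  expect_error(weighted_pattern_probabilities(rep(3, 20), m = 3), "degenerate")
})

test_that("entropy and complexity agree with brute-force enumeration", {
  d <- pattern_probabilities(c(1, 3, 2, 5, 4), m = 3)
  expect_equal(permutation_entropy(d), 0.3552453, tolerance = 1e-6)
  cases <- with_test_seed(99, {
    c(lapply(1:10, function(i) rnorm(sample(6:25, 1))),
      lapply(1:5, function(i) sample(1:4, 20, replace = TRUE)))  # with ties
  })
  for (x in cases) {
    for (m in 2:4) {
      d <- pattern_probabilities(x, m)
      expect_equal(permutation_entropy(d), oracle_pe(x, m), tolerance = 1e-12)
      expect_equal(jensen_shannon_complexity(d),
                   oracle_jsc(sort(d$probs[d$probs > 0], decreasing = TRUE),
                              factorial(m)),
                   tolerance = 1e-12)
      if (sd(x) > 0) {
        expect_equal(permutation_entropy(weighted_pattern_probabilities(x, m)),
                     oracle_pe(x, m, weighted = TRUE), tolerance = 1e-12)
      }
    }
  }
})

test_that("complexity vanishes at both entropy extremes and is non-negative", {
  M <- factorial(5)
  uni <- structure(list(probs = rep(1 / M, M), m = 5L, weighted = FALSE,
                        counts_total = M), class = "ordinal_distribution")
  expect_equal(jensen_shannon_complexity(uni), 0)
  expect_equal(permutation_entropy(uni), 1)
  deg <- structure(list(probs = c(1, rep(0, M - 1)), m = 5L, weighted = FALSE,
                        counts_total = 1), class = "ordinal_distribution")
  expect_equal(jensen_shannon_complexity(deg), 0)
  expect_equal(permutation_entropy(deg), 0)
  # two-bin hand value (natural log)
  d2 <- structure(list(probs = c(0.75, 0.25), m = 2L, weighted = FALSE,
                       counts_total = 4), class = "ordinal_distribution")
  expect_equal(jensen_shannon_complexity(d2), 0.1271733, tolerance = 1e-6)
  # intermediate distributions have strictly positive complexity
  mix <- structure(list(probs = c(0.5, 0.3, 0.1, 0.1, 0, 0), m = 3L,
                        weighted = FALSE, counts_total = 10),
                   class = "ordinal_distribution")
  expect_gt(jensen_shannon_complexity(mix), 0)
})

test_that("coarse-graining averages non-overlapping blocks", {
  x <- rnorm(100)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_length(coarse_grain(1:7, 3), 2)
  expect_error(coarse_grain(1:3, 5), "shorter")
})

test_that("multiscale profiles have the right shape and variant dispatch", {
  rec <- make_recording(nch = 3, n = 4000, fs = 200, seed = 8)
  prof <- multiscale_profile(rec, scales = 1:10, weighted = TRUE)
  expect_identical(dim(prof$entropy), c(3L, 10L))
  expect_identical(dim(prof$complexity), c(3L, 10L))
  expect_identical(prof$variant, "MWPE/MWJSC")
  expect_true(all(prof$entropy >= 0 & prof$entropy <= 1))
  expect_true(all(prof$complexity >= 0))
  profu <- multiscale_profile(rec, scales = 1:10, weighted = FALSE)
  expect_identical(profu$variant, "MPE/MJSC")
  # scale-1 column equals the single-scale measures
  expect_equal(prof$entropy[1, 1],
               permutation_entropy(weighted_pattern_probabilities(rec$data[1, ], 5)))
  # long format export
  df <- as.data.frame(prof)
  expect_identical(nrow(df), 30L)
  expect_true(all(c("subject", "condition", "channel", "scale",
                    "entropy", "complexity", "variant") %in% names(df)))
})

test_that("relabelling channels permutes profile rows identically", {
  rec <- make_recording(nch = 4, n = 3000, fs = 100, seed = 13,
                        labels = c("a", "b", "c", "d"))
  perm <- c(3, 1, 4, 2)
  rec2 <- recording(rec$data[perm, ], fs = rec$fs,
                    channel_labels = rec$channel_labels[perm])
  p1 <- multiscale_profile(rec, scales = 1:5)
  p2 <- multiscale_profile(rec2, scales = 1:5)
  expect_equal(unname(p2$entropy), unname(p1$entropy[perm, ]))
  expect_equal(unname(p2$complexity), unname(p1$complexity[perm, ]))
})
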