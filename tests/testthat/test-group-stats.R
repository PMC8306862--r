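test_that("the default ROI scheme partitions the montage as declared", {
  sch <- default_roi_scheme()
  expect_length(sch$rois$frontal, 8)
  expect_length(sch$rois$`temporo-parietal`, 12)
  expect_length(sch$rois$occipital, 7)
  expect_setequal(unlist(sch$rois), eeg_channel_labels())
  expect_identical(nrow(sch$neighbors), 2L)
  expect_error(roi_scheme(list(a = c("x", "y"), b = c("y")), cbind("a", "b")),
               "disjoint")
})

test_that("ROI averaging is the channel mean and names missing channels", {
  rec <- make_recording(nch = 27, n = 600, fs = 100, seed = 3,
                        labels = eeg_channel_labels())
  prof <- multiscale_profile(rec, scales = 1:3)
  ra <- roi_average(prof, default_roi_scheme())
  expect_identical(dim(ra$entropy), c(3L, 3L))
  expect_equal(ra$entropy["frontal", 1],
               mean(prof$entropy[default_roi_scheme()$rois$frontal, 1]))
  # constant profile stays constant; 1-channel ROI is the identity
  m <- matrix(2.5, 3, 4, dimnames = list(c("x", "y", "z"), NULL))
  sch <- roi_scheme(list(one = "x", two = c("y", "z")), cbind("one", "two"))
  expect_true(all(roi_average(m, sch) == 2.5))
  m["x", ] <- c(1, 2, 3, 4)
  expect_equal(unname(roi_average(m, sch)["one", ]), c(1, 2, 3, 4))
  expect_error(roi_average(m[1:2, , drop = FALSE], sch), "z")
})

test_that("lattice adjacency joins scale steps within ROI and ROI neighbors", {
  adj <- roi_scale_adjacency(default_roi_scheme(), 1:4)
  expect_identical(dim(adj), c(12L, 12L))
  expect_true(isSymmetric(adj))
  expect_true(adj["frontal.s1", "frontal.s2"])
  expect_false(adj["frontal.s1", "frontal.s3"])
  expect_true(adj["frontal.s2", "temporo-parietal.s2"])
  expect_false(adj["frontal.s2", "occipital.s2"])     # not neighbors
  expect_false(adj["frontal.s2", "temporo-parietal.s3"])  # diagonal move
  ch <- chain_adjacency(c("alpha", "beta", "gamma"))
  expect_true(ch["alpha", "beta"] && ch["beta", "gamma"])
  expect_false(ch["alpha", "gamma"])
})

test_that("paired Cohen's d follows the difference-score definition", {
  expect_equal(cohens_d_paired(c(2, 3, 4), c(1, 1, 1)), 2)
  expect_equal(cohens_d_paired(c(1, 0), c(0, 1)), 0)
  expect_error(cohens_d_paired(c(3, 4, 5), c(1, 2, 3)), "undefined")
})

test_that("cluster test finds injected effects and nothing in identical data", {
  n <- 12
  adj <- roi_scale_adjacency(default_roi_scheme(), 1:6)
  base <- with_test_seed(4, matrix(rnorm(n * nrow(adj)), n,
                                   dimnames = list(NULL, rownames(adj))))
  # identical inputs: every cell is zero-variance (flagged), nothing rejected
  expect_warning(
    empty <- paired_cluster_test(base, base, adj, n_perm = 200, seed = 1),
    "zero-variance")
  expect_length(empty$clusters, 0)
  # effect in all frontal cells at scales 2-5, on top of measurement noise
  eff <- base + with_test_seed(5, matrix(0.3 * rnorm(length(base)), nrow(base)))
  hit <- grep("^frontal\\.s[2-5]$", colnames(base))
  eff[, hit] <- eff[, hit] + 1.5
  res <- paired_cluster_test(eff, base, adj, n_perm = 500, seed = 2)
  sig <- significant_clusters(res)
  expect_gte(length(sig), 1)
  expect_true(all(hit %in% sig[[1]]$cells))
  expect_gt(sig[[1]]$mass, 0)
  expect_lt(sig[[1]]$p, 0.05)
  expect_gt(sig[[1]]$d_mean, 0.5)
  expect_gte(sig[[1]]$d_max, sig[[1]]$d_mean)
})

test_that("cluster p-values are affine-invariant and sign-symmetric", {
  n <- 10
  a <- with_test_seed(6, matrix(rnorm(n * 8), n))
  b <- with_test_seed(7, matrix(rnorm(n * 8), n))
  a[, 3:5] <- a[, 3:5] + 1
  r1 <- paired_cluster_test(a, b, n_perm = 300, seed = 5)
  r2 <- paired_cluster_test(10 * a + 2, 10 * b + 2, n_perm = 300, seed = 5)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "p"),
               vapply(r2$clusters, `[[`, numeric(1), "p"))
  # swapping conditions flips cluster signs, preserves p
  r3 <- paired_cluster_test(b, a, n_perm = 300, seed = 5)
  expect_equal(vapply(r3$clusters, `[[`, numeric(1), "mass"),
               -vapply(r1$clusters, `[[`, numeric(1), "mass"))
  expect_equal(vapply(r3$clusters, `[[`, numeric(1), "p"),
               vapply(r1$clusters, `[[`, numeric(1), "p"))
})

test_that("zero-variance cells are excluded with a warning", {
  n <- 8
  a <- with_test_seed(9, matrix(rnorm(n * 4), n))
  b <- with_test_seed(10, matrix(rnorm(n * 4), n))
  a[, 2] <- 5
  b[, 2] <- 3                   # exact constant difference: zero variance
  expect_warning(res <- paired_cluster_test(a, b, n_perm = 100, seed = 3),
                 "zero-variance")
  expect_true(is.na(res$t[2]))
  expect_false(anyNA(res$t[-2]))
})

test_that("the regularized LDA separates and matches MASS on easy data", {
  tr <- with_test_seed(11, rbind(matrix(rnorm(40, 0), 20, 2),
                                 matrix(rnorm(40, 3), 20, 2)))
  y <- rep(c("A", "B"), each = 20)
  te <- rbind(c(0, 0), c(3, 3))
  sc <- lda_fit_predict(tr, y, te)
  expect_lt(sc[1], 0)
  expect_gt(sc[2], 0)
  # 1-D features reduce to a threshold on the feature
  tr1 <- matrix(c(1, 2, 3, 7, 8, 9), ncol = 1)
  y1 <- c("A", "A", "A", "B", "B", "B")
  sc1 <- lda_fit_predict(tr1, y1, matrix(c(2, 5, 8), ncol = 1), shrinkage = 0)
  expect_equal(sc1[2], 0, tolerance = 1e-9)  # midpoint scores zero
  expect_true(sc1[1] < 0 && sc1[3] > 0)
  # cross-check against MASS: identical ranking without shrinkage
  skip_if_not_installed("MASS")
  te2 <- with_test_seed(12, matrix(rnorm(40, 1.5), 20, 2))
  ours <- lda_fit_predict(tr, y, te2, shrinkage = 0)
  mass <- drop(stats::predict(MASS::lda(tr, grouping = y), te2)$x)
  expect_gt(abs(stats::cor(ours, mass)), 1 - 1e-9)
})

test_that("AUC uses rank-sums with ties counting one half", {
  expect_equal(auc_scores(c(1, 2, 3, 4), c("A", "A", "B", "B")), 1)
  expect_equal(auc_scores(c(4, 3, 2, 1), c("A", "A", "B", "B")), 0)
  expect_equal(auc_scores(c(1, 1, 1, 1), c("A", "B", "A", "B")), 0.5)
  expect_equal(auc_scores(c(1, 2, 2, 3), c("A", "A", "B", "B")), 0.875)
})

test_that("decoding is perfect on separable features and at chance on none", {
  ns <- 8; nsc <- 4
  feats <- with_test_seed(14, {
    base <- array(rnorm(ns * nsc * 6), c(ns, nsc, 6))
    list(a = base, b = base + 2, scales = 1:nsc,
         feature_names = paste0("f", 1:6))
  })
  res <- ech_decoding(feats, n_perm = 60, cluster_n_perm = 200, seed = 15)
  expect_true(all(res$auc_per_scale == 1))
  expect_gte(length(significant_clusters(res$scale_clusters)), 1)
  # the observed AUC clears the whole permuted-label distribution
  expect_true(all(res$auc_per_scale >=
                    apply(res$chance_auc, 2, quantile, 0.95)))
  # identical features: no information, AUC at one half exactly (ties)
  feats0 <- feats; feats0$b <- feats0$a
  res0 <- suppressWarnings(
    ech_decoding(feats0, n_perm = 30, cluster_n_perm = 100, seed = 16))
  expect_true(all(abs(res0$auc_per_scale - 0.5) < 1e-9))
  expect_length(significant_clusters(res0$scale_clusters), 0)
})

test_that("label-permutation AUC is centred at one half under the null", {
  ns <- 10
  feats <- with_test_seed(17, {
    list(a = array(rnorm(ns * 2 * 6), c(ns, 2, 6)),
         b = array(rnorm(ns * 2 * 6), c(ns, 2, 6)),
         scales = 1:2, feature_names = paste0("f", 1:6))
  })
  res <- ech_decoding(feats, n_perm = 150, cluster_n_perm = 100, seed = 18)
  expect_lt(abs(mean(res$chance_auc) - 0.5), 0.05)
  expect_lt(abs(mean(res$auc_per_scale) - 0.5), 0.25)
})

test_that("band test applies the chain machinery to band matrices", {
  n <- 10
  gfc_a <- with_test_seed(19, matrix(rnorm(n * 3, 10, 2), n,
                                     dimnames = list(NULL, c("alpha", "beta", "gamma"))))
  expect_warning(same <- band_test(gfc_a, gfc_a, n_perm = 100, seed = 1),
                 "zero-variance")
  expect_length(same$clusters, 0)
  gfc_b <- gfc_a + with_test_seed(20, matrix(rnorm(n * 3), n))
  gfc_b[, "gamma"] <- gfc_b[, "gamma"] + 6
  res <- band_test(gfc_b, gfc_a, n_perm = 500, seed = 2)
  sig <- significant_clusters(res)
  expect_gte(length(sig), 1)
  expect_true("gamma" %in% sig[[1]]$cell_names)
  expect_gt(sig[[1]]$mass, 0)
})
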