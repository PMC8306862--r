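#' Region-of-interest scheme
#'
#' Named, disjoint channel-label sets with a neighbor structure used for
#' cluster correction. The default scheme partitions the 27-channel montage
#' into frontal, temporo-parietal and occipital regions, with the
#' temporo-parietal region adjacent to the other two (and those the only two
#' adjacencies).
#'
#' @param rois Named list of character vectors of channel labels (disjoint).
#' @param neighbors Two-column character matrix of adjacent ROI name pairs.
#' @return An object of class `roi_scheme`.
#' @export
roi_scheme <- function(rois, neighbors) {
  stopifnot(is.list(rois), !is.null(names(rois)), length(rois) >= 1)
  all_ch <- unlist(rois)
  if (anyDuplicated(all_ch)) {
    stop("ROIs must be disjoint; duplicated: ",
         paste(unique(all_ch[duplicated(all_ch)]), collapse = ", "))
  }
  neighbors <- as.matrix(neighbors)
  if (ncol(neighbors) != 2 || !all(neighbors %in% names(rois))) {
    stop("`neighbors` must be a two-column matrix of ROI names")
  }
  structure(list(rois = rois, neighbors = neighbors), class = "roi_scheme")
}

#' @rdname roi_scheme
#' @export
default_roi_scheme <- function() {
  roi_scheme(
    rois = list(
      frontal = c("Fpz", "Fz", "F3", "F4", "F7", "F8", "F9", "F10"),
      `temporo-parietal` = c("FC5", "FC6", "T7", "C3", "Cz", "C4", "T8",
                             "CP5", "CP6", "P3", "Pz", "P4"),
      occipital = c("P8", "PO7", "PO8", "P7", "O1", "Oz", "O2")
    ),
    neighbors = rbind(c("frontal", "temporo-parietal"),
                      c("temporo-parietal", "occipital"))
  )
}

#' Average a profile over regions of interest
#'
#' Means of the per-channel entropy and complexity matrices over each ROI's
#' channels, at every scale.
#'
#' @param profile A `complexity_profile` (see [multiscale_profile()]), or a
#'   plain channels x scales matrix with channel-label rownames.
#' @param scheme A [roi_scheme()].
#' @return For a profile, a list with `entropy` and `complexity` matrices
#'   (ROI x scales); for a plain matrix, a single ROI x scales matrix.
#' @export
roi_average <- function(profile, scheme) {
  stopifnot(inherits(scheme, "roi_scheme"))
  avg_one <- function(mat) {
    missing <- setdiff(unlist(scheme$rois), rownames(mat))
    if (length(missing) > 0) {
      stop("channel(s) missing from profile: ", paste(missing, collapse = ", "))
    }
    out <- t(vapply(scheme$rois, function(ch) {
      colMeans(mat[ch, , drop = FALSE])
    }, numeric(ncol(mat))))
    rownames(out) <- names(scheme$rois)
    out
  }
  if (inherits(profile, "complexity_profile")) {
    list(entropy = avg_one(profile$entropy),
         complexity = avg_one(profile$complexity))
  } else {
    avg_one(profile)
  }
}

#' Cell adjacency over an ROI x scale lattice
#'
#' Cells are all ROI/scale combinations, named `"<roi>.s<scale>"`, ordered
#' scale-major within ROI. Two cells are adjacent iff they share the ROI and
#' differ by one scale step, or share the scale and their ROIs are neighbors
#' in the scheme.
#'
#' @param scheme A [roi_scheme()].
#' @param scales Integer vector of scales (ordered).
#' @return Logical adjacency matrix with cell names.
#' @export
roi_scale_adjacency <- function(scheme, scales) {
  stopifnot(inherits(scheme, "roi_scheme"))
  rois <- names(scheme$rois)
  cells <- expand.grid(scale = scales, roi = rois, stringsAsFactors = FALSE)
  cells <- cells[, c("roi", "scale")]
  nm <- paste0(cells$roi, ".s", cells$scale)
  n <- nrow(cells)
  adj <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  nb <- rbind(scheme$neighbors, scheme$neighbors[, 2:1, drop = FALSE])
  for (a in seq_len(n)) {
    same_roi <- cells$roi == cells$roi[a]
    step <- abs(match(cells$scale, scales) - match(cells$scale[a], scales))
    adj[a, same_roi & step == 1] <- TRUE
    is_nb <- cells$roi %in% nb[nb[, 1] == cells$roi[a], 2]
    adj[a, is_nb & cells$scale == cells$scale[a]] <- TRUE
  }
  adj
}

#' Chain adjacency over ordered cells
#'
#' Adjacency of a one-dimensional ordered lattice (e.g., frequency bands or
#' time scales): each cell is adjacent to its immediate neighbors.
#'
#' @param cell_names Character vector of ordered cell names.
#' @return Logical adjacency matrix.
#' @export
chain_adjacency <- function(cell_names) {
  n <- length(cell_names)
  adj <- matrix(FALSE, n, n, dimnames = list(cell_names, cell_names))
  if (n > 1) {
    idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
    adj[idx] <- TRUE
    adj[idx[, 2:1, drop = FALSE]] <- TRUE
  }
  adj
}

# Connected components of same-sign suprathreshold cells; returns a list of
# clusters, each with `cells` (indices) and `mass` (sum of t).
.find_clusters <- function(tvec, tcrit, adj) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(!is.na(tvec) & sgn * tvec >= tcrit)
    if (length(supra) == 0) next
    unseen <- rep(TRUE, length(supra))
    names(unseen) <- supra
    while (any(unseen)) {
      seedc <- supra[unseen][1]
      comp <- seedc
      frontier <- seedc
      unseen[as.character(seedc)] <- FALSE
      while (length(frontier) > 0) {
        nxt <- unique(unlist(lapply(frontier, function(a) {
          supra[unseen][adj[a, supra[unseen]]]
        })))
        nxt <- nxt[!is.na(nxt)]
        if (length(nxt) == 0) break
        unseen[as.character(nxt)] <- FALSE
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      out[[length(out) + 1]] <- list(cells = sort(comp),
                                     mass = sum(tvec[comp]))
    }
  }
  out
}

# Paired t statistics per cell for a subjects x cells difference matrix.
.cell_t <- function(d) {
  n <- nrow(d)
  mu <- colMeans(d)
  sdd <- apply(d, 2, sd)
  t <- mu / (sdd / sqrt(n))
  t[sdd == 0] <- NA_real_
  t
}

#' Cluster-corrected sign-flip permutation paired t-test
#'
#' Two-sided paired t-tests over a lattice of cells with cluster-based
#' family-wise correction. Cells whose |t| exceeds the two-sided
#' `alpha` quantile of `t(n - 1)` enter clusters; clusters are connected
#' components of same-sign suprathreshold cells under the supplied adjacency,
#' with mass the sum of t values. The null distribution is the maximum
#' absolute cluster mass over random within-subject condition sign flips
#' (exact for a paired design); cluster p-values use the `(b + 1) / (B + 1)`
#' estimator. Cells with zero-variance differences are excluded with a
#' warning. Per-cluster effect sizes are the mean and max of the absolute
#' paired Cohen's d over the cluster's cells.
#'
#' @param a,b Numeric subjects x cells matrices (same shape, paired rows).
#' @param adjacency Logical/0-1 cells x cells adjacency matrix; `NULL` uses a
#'   chain over the column order.
#' @param alpha Significance level, also used for the cluster-forming
#'   threshold (default 0.05).
#' @param n_perm Number of random sign flips (default 10000).
#' @param seed Optional integer seed.
#' @return A `cluster_result`: list with `clusters` (each with `cells`,
#'   `cell_names`, `mass`, `p`, `d_mean`, `d_max`), the per-cell `t` and `d`
#'   vectors, `threshold`, `alpha`, `n_perm` and the permutation
#'   `null_max_mass` vector.
#' @export
paired_cluster_test <- function(a, b, adjacency = NULL, alpha = 0.05,
                                n_perm = 10000, seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)), nrow(a) >= 2, .is_count(n_perm),
            alpha > 0, alpha < 1)
  d <- a - b
  n <- nrow(d)
  ncell <- ncol(d)
  cn <- colnames(d)
  if (is.null(cn)) cn <- paste0("cell", seq_len(ncell))
  if (is.null(adjacency)) adjacency <- chain_adjacency(cn)
  adjacency <- as.matrix(adjacency) != 0
  stopifnot(all(dim(adjacency) == ncell))
  tobs <- .cell_t(d)
  if (anyNA(tobs)) {
    warning("cell(s) with zero-variance differences excluded: ",
            paste(cn[is.na(tobs)], collapse = ", "))
  }
  tcrit <- qt(1 - alpha / 2, df = n - 1)
  obs <- .find_clusters(tobs, tcrit, adjacency)

  # permutation null: max |cluster mass| under random sign flips, vectorised
  # over cells (column sums of d and d^2 are flip-invariant for the variance)
  null_max <- with_seed(seed, {
    E <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    Mp <- crossprod(E, d) / n                       # n_perm x ncell means
    ssq <- matrix(colSums(d^2), n_perm, ncell, byrow = TRUE)
    varp <- (ssq - n * Mp^2) / (n - 1)
    varp[varp < 0] <- 0
    tp <- Mp / sqrt(varp / n)
    tp[!is.finite(tp)] <- NA_real_
    vapply(seq_len(n_perm), function(p) {
      cl <- .find_clusters(tp[p, ], tcrit, adjacency)
      if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
    }, numeric(1))
  })

  dcell <- colMeans(d) / apply(d, 2, sd)
  clusters <- lapply(obs, function(cl) {
    list(cells = cl$cells,
         cell_names = cn[cl$cells],
         mass = cl$mass,
         p = (sum(null_max >= abs(cl$mass)) + 1) / (n_perm + 1),
         d_mean = mean(abs(dcell[cl$cells])),
         d_max = max(abs(dcell[cl$cells])))
  })
  # order by p then |mass|
  if (length(clusters) > 1) {
    ord <- order(vapply(clusters, `[[`, numeric(1), "p"),
                 -abs(vapply(clusters, `[[`, numeric(1), "mass")))
    clusters <- clusters[ord]
  }
  structure(list(clusters = clusters, t = stats::setNames(tobs, cn),
                 d = stats::setNames(dcell, cn), threshold = tcrit,
                 alpha = alpha, n_perm = n_perm, null_max_mass = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), cluster-forming |t| > %.3f, %d sign-flip permutations\n",
              length(x$clusters), x$threshold, x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  cells [%s]: mass = %.2f, p = %.4f, d_mean = %.2f, d_max = %.2f\n",
                paste(cl$cell_names, collapse = ", "), cl$mass, cl$p,
                cl$d_mean, cl$d_max))
  }
  invisible(x)
}

#' Significant clusters of a cluster result
#'
#' @param x A `cluster_result`.
#' @param alpha Cutoff; defaults to the result's alpha.
#' @return The subset of clusters with `p <= alpha`.
#' @export
significant_clusters <- function(x, alpha = x$alpha) {
  stopifnot(inherits(x, "cluster_result"))
  Filter(function(cl) cl$p <= alpha, x$clusters)
}

#' Paired Cohen's d
#'
#' Effect size for paired samples: `mean(a - b) / sd(a - b)` with the `n - 1`
#' denominator in the standard deviation.
#'
#' @param a,b Paired per-subject values.
#' @return Scalar effect size.
#' @export
cohens_d_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("zero standard deviation of differences: effect size undefined")
  mean(d) / s
}

#' Regularized linear discriminant scores
#'
#' Two-class linear discriminant with pooled covariance and shrinkage toward
#' the scaled identity: `S_reg = (1 - shrinkage) * S + shrinkage * mean(diag(S)) * I`.
#' Returns signed decision values for the test rows (positive scores favor
#' the second class level); only the ranking of scores matters for AUC.
#'
#' @param train_x Numeric matrix of training features (rows = samples).
#' @param train_y Two-level factor (or coercible) of training labels.
#' @param test_x Numeric matrix of test features.
#' @param shrinkage Shrinkage weight in `[0, 1]` (default 0.1).
#' @return Numeric vector of decision values, one per test row.
#' @export
lda_fit_predict <- function(train_x, train_y, test_x, shrinkage = 0.1) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- factor(train_y)
  if (nlevels(train_y) != 2 || any(table(train_y) < 1)) {
    stop("training labels must contain both of exactly two classes")
  }
  if (!all(is.finite(train_x)) || !all(is.finite(test_x))) {
    stop("features must be finite")
  }
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  lv <- levels(train_y)
  x1 <- train_x[train_y == lv[1], , drop = FALSE]
  x2 <- train_x[train_y == lv[2], , drop = FALSE]
  mu1 <- colMeans(x1)
  mu2 <- colMeans(x2)
  p <- ncol(train_x)
  n1 <- nrow(x1); n2 <- nrow(x2)
  pool <- if (n1 + n2 > 2) {
    ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  } else {
    matrix(0, p, p)
  }
  S <- (1 - shrinkage) * pool + shrinkage * mean(diag(pool)) * diag(p)
  if (all(S == 0) || !is.finite(rcond(S)) || rcond(S) < 1e-12) {
    # degenerate covariance even after shrinkage: fall back to identity metric
    S <- diag(p)
  }
  w <- solve(S, mu2 - mu1)
  drop(test_x %*% w - sum(w * (mu1 + mu2) / 2))
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) AUC of decision scores against binary labels, with
#' tied scores contributing 1/2.
#'
#' @param scores Numeric decision values.
#' @param labels Binary labels (factor or coercible); the second level is the
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_scores <- function(scores, labels) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, length(scores) == length(labels))
  pos <- labels == levels(labels)[2]
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Entropy-complexity features for decoding
#'
#' Builds the per-scale feature arrays used by [ech_decoding()]: for each
#' subject, condition and scale, the ROI-averaged entropy and complexity
#' (2 measures x number of ROIs features; 6 with the default scheme).
#'
#' @param profiles_a,profiles_b Lists (one entry per subject, same order) of
#'   `complexity_profile` objects for conditions A and B.
#' @param scheme A [roi_scheme()].
#' @return List with arrays `a` and `b` of dimension
#'   subjects x scales x features, plus `scales` and `feature_names`.
#' @export
ech_features <- function(profiles_a, profiles_b, scheme = default_roi_scheme()) {
  stopifnot(length(profiles_a) == length(profiles_b), length(profiles_a) >= 2)
  scales <- profiles_a[[1]]$scales
  rois <- names(scheme$rois)
  fn <- c(paste0("entropy.", rois), paste0("complexity.", rois))
  build <- function(profiles) {
    arr <- array(NA_real_, dim = c(length(profiles), length(scales), length(fn)),
                 dimnames = list(NULL, paste0("s", scales), fn))
    for (s in seq_along(profiles)) {
      ra <- roi_average(profiles[[s]], scheme)
      arr[s, , ] <- cbind(t(ra$entropy), t(ra$complexity))
    }
    arr
  }
  list(a = build(profiles_a), b = build(profiles_b), scales = scales,
       feature_names = fn)
}

# LOSO decision values for one scale. feats_a/feats_b: subjects x features.
# flip: logical per subject; TRUE swaps that subject's training labels.
# Returns list(score_a, score_b): decision values of each held-out sample.
.loso_scores <- function(feats_a, feats_b, flip = NULL, shrinkage = 0.1) {
  ns <- nrow(feats_a)
  if (is.null(flip)) flip <- rep(FALSE, ns)
  score_a <- score_b <- numeric(ns)
  for (s in seq_len(ns)) {
    tr <- setdiff(seq_len(ns), s)
    xa <- feats_a[tr, , drop = FALSE]
    xb <- feats_b[tr, , drop = FALSE]
    la <- ifelse(flip[tr], "B", "A")
    lb <- ifelse(flip[tr], "A", "B")
    train_x <- rbind(xa, xb)
    train_y <- factor(c(la, lb), levels = c("A", "B"))
    if (nlevels(droplevels(train_y)) < 2) {
      score_a[s] <- score_b[s] <- 0
      next
    }
    sc <- lda_fit_predict(train_x, train_y,
                          rbind(feats_a[s, ], feats_b[s, ]), shrinkage)
    score_a[s] <- sc[1]
    score_b[s] <- sc[2]
  }
  list(score_a = score_a, score_b = score_b)
}

#' Decoding on the entropy-complexity hyperplane
#'
#' Leave-one-subject-out linear discriminant decoding of condition from
#' ROI-averaged entropy and complexity features, scale by scale. Both samples
#' of the held-out subject are scored by a discriminant trained on the
#' remaining subjects; pooled decision values give the per-scale AUC, and the
#' per-subject decision margin (score of the B sample minus score of the A
#' sample) summarises each fold. Chance is estimated by repeating the whole
#' procedure with random within-subject label swaps; observed margins are
#' compared to the mean chance margins with the cluster-corrected sign-flip
#' test over adjacent scales.
#'
#' @param features Output of [ech_features()].
#' @param n_perm Number of label permutations for the chance distribution
#'   (default 500).
#' @param cluster_n_perm Sign flips for the scale-cluster test (default 2000).
#' @param alpha Significance level (default 0.05).
#' @param shrinkage LDA shrinkage (see [lda_fit_predict()]).
#' @param seed Optional integer seed.
#' @return A `decoding_result`: list with `auc_per_scale`,
#'   `chance_auc_per_scale` (mean over permutations), `chance_auc` (the
#'   permutation x scale matrix), per-subject `margins` and `chance_margins`,
#'   and `scale_clusters` (a `cluster_result` over scales).
#' @export
ech_decoding <- function(features, n_perm = 500, cluster_n_perm = 2000,
                         alpha = 0.05, shrinkage = 0.1, seed = NULL) {
  stopifnot(is.list(features), !is.null(features$a), !is.null(features$b))
  ns <- dim(features$a)[1]
  nsc <- dim(features$a)[2]
  stopifnot(ns >= 3, dim(features$b)[1] == ns)
  scales <- features$scales
  auc_obs <- numeric(nsc)
  margins <- matrix(NA_real_, ns, nsc,
                    dimnames = list(NULL, paste0("s", scales)))
  labels <- factor(rep(c("A", "B"), each = ns), levels = c("A", "B"))
  # decision values are centred within each LOSO fold before pooling: the
  # discriminant scale and offset are not comparable across folds, the
  # within-fold contrast is
  pooled_auc <- function(margin) auc_scores(c(-margin, margin) / 2, labels)
  for (sc in seq_len(nsc)) {
    res <- .loso_scores(features$a[, sc, ], features$b[, sc, ],
                        shrinkage = shrinkage)
    margins[, sc] <- res$score_b - res$score_a
    auc_obs[sc] <- pooled_auc(margins[, sc])
  }
  chance_auc <- matrix(NA_real_, n_perm, nsc)
  chance_margins <- matrix(0, ns, nsc, dimnames = dimnames(margins))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      flip <- sample(c(TRUE, FALSE), ns, replace = TRUE)
      for (sc in seq_len(nsc)) {
        res <- .loso_scores(features$a[, sc, ], features$b[, sc, ],
                            flip = flip, shrinkage = shrinkage)
        # under flipped labels the "positive" sample of subject s is the one
        # relabelled B; score it accordingly so chance is symmetric
        sa <- ifelse(flip, res$score_b, res$score_a)
        sb <- ifelse(flip, res$score_a, res$score_b)
        chance_auc[p, sc] <- pooled_auc(sb - sa)
        chance_margins[, sc] <- chance_margins[, sc] + (sb - sa) / n_perm
      }
    }
  })
  clusters <- paired_cluster_test(margins, chance_margins,
                                  adjacency = chain_adjacency(colnames(margins)),
                                  alpha = alpha, n_perm = cluster_n_perm,
                                  seed = derive_seed(seed, 1L))
  structure(list(auc_per_scale = stats::setNames(auc_obs, paste0("s", scales)),
                 chance_auc_per_scale = colMeans(chance_auc),
                 chance_auc = chance_auc, margins = margins,
                 chance_margins = chance_margins, scale_clusters = clusters,
                 scales = scales),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> AUC over %d scales: mean %.3f (chance %.3f)\n",
              length(x$auc_per_scale), mean(x$auc_per_scale),
              mean(x$chance_auc_per_scale)))
  nsig <- length(significant_clusters(x$scale_clusters))
  cat(sprintf("  %d significant scale cluster(s) at alpha = %g\n", nsig,
              x$scale_clusters$alpha))
  invisible(x)
}

#' Cluster test across frequency bands
#'
#' The cluster-corrected sign-flip paired t-test applied over the ordered
#' frequency-band dimension (chain adjacency), e.g., for per-band global
#' functional connectivity or average geodesic entropy.
#'
#' @param values_a,values_b Subjects x bands matrices (band columns ordered).
#' @inheritParams paired_cluster_test
#' @return A `cluster_result`.
#' @export
band_test <- function(values_a, values_b, alpha = 0.05, n_perm = 10000,
                      seed = NULL) {
  values_a <- as.matrix(values_a)
  cn <- colnames(values_a)
  if (is.null(cn)) cn <- paste0("band", seq_len(ncol(values_a)))
  paired_cluster_test(values_a, values_b, adjacency = chain_adjacency(cn),
                      alpha = alpha, n_perm = n_perm, seed = seed)
}
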