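#' Analysis configuration
#'
#' Bundles every tunable of the full pipeline. Defaults reproduce the
#' reference analysis: embedding m = 5, tau = 1; scales 1-20; weighted and
#' unweighted entropy/complexity plus both Lempel-Ziv variants; alpha, beta
#' and gamma bands with 1 s windows; 200 surrogates thresholded at the 95th
#' percentile; 10,000 sign-flip permutations at alpha = 0.05; 500 label
#' permutations for decoding chance.
#'
#' @param recordings Named list of [recording()] objects (names
#'   `"<subject>_<condition>"`), or `NULL` to generate from `synthetic`.
#' @param synthetic An [experiment_spec()] used when `recordings` is `NULL`.
#' @param input_dir Directory of delimited recordings (see
#'   [write_recording()]) read when both `recordings` and `synthetic` are
#'   `NULL`.
#' @param out_dir Output directory for result tables and the run manifest
#'   (`NULL` writes nothing).
#' @param m,tau Embedding parameters.
#' @param scales Time scales for coarse-graining.
#' @param profile_variants Subset of `c("weighted", "unweighted")`.
#' @param lzc_variants Subset of `c("median", "permutation")` (empty to skip).
#' @param bands Band data frame (see [default_bands()]).
#' @param win_s Connectivity window length (seconds).
#' @param n_surrogates,q Surrogate count and threshold quantile.
#' @param n_perm Sign-flip permutations for cluster tests.
#' @param decode_n_perm Label permutations for decoding chance.
#' @param alpha Significance level.
#' @param seed Master seed controlling every stochastic stage.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(recordings = NULL, synthetic = NULL,
                            input_dir = NULL, out_dir = NULL,
                            m = 5, tau = 1, scales = 1:20,
                            profile_variants = c("weighted", "unweighted"),
                            lzc_variants = c("median", "permutation"),
                            bands = default_bands(), win_s = 1,
                            n_surrogates = 200, q = 0.95,
                            n_perm = 10000, decode_n_perm = 500,
                            alpha = 0.05, seed = 1) {
  profile_variants <- match.arg(profile_variants, several.ok = TRUE)
  if (length(lzc_variants) > 0) {
    lzc_variants <- match.arg(lzc_variants, c("median", "permutation"),
                              several.ok = TRUE)
  }
  if (is.null(recordings) && is.null(synthetic) && is.null(input_dir)) {
    stop("provide `recordings`, a `synthetic` experiment_spec, or `input_dir`")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "experiment_spec"))
  stopifnot(.is_count(m), m >= 2, .is_count(tau), .is_count(n_surrogates),
            .is_count(n_perm), .is_count(decode_n_perm),
            alpha > 0, alpha < 1, q > 0, q < 1, win_s > 0)
  structure(list(recordings = recordings, synthetic = synthetic,
                 input_dir = input_dir, out_dir = out_dir,
                 m = as.integer(m), tau = as.integer(tau),
                 scales = as.integer(scales),
                 profile_variants = profile_variants,
                 lzc_variants = lzc_variants,
                 bands = bands, win_s = win_s,
                 n_surrogates = as.integer(n_surrogates), q = q,
                 n_perm = as.integer(n_perm),
                 decode_n_perm = as.integer(decode_n_perm),
                 alpha = alpha, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Write / read a recording as a delimited matrix with manifest
#'
#' The data file is comma-separated with one column per channel and a header
#' row of channel labels; the sampling rate, subject and condition live in a
#' YAML sidecar manifest at `<path>.yaml`.
#'
#' @param rec A [recording()].
#' @param path Data file path (e.g., `"s01_A.csv"`).
#' @param format Input format; only `"delimited"` is currently supported
#'   (`"edf"` raises an informative error).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_labels
  write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(fs = rec$fs, subject_id = rec$subject_id,
                        condition = rec$condition,
                        channel_labels = as.list(rec$channel_labels)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("EDF input is not supported by this build; ",
         "convert to the delimited format (see ?write_recording)")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  man_path <- paste0(path, ".yaml")
  if (!file.exists(man_path)) {
    stop("missing sidecar manifest: ", man_path,
         " (must provide fs, subject_id, condition)")
  }
  man <- yaml::read_yaml(man_path)
  if (is.null(man$fs)) stop("manifest lacks the sampling rate `fs`")
  df <- read.csv(path, check.names = FALSE)
  if (anyDuplicated(colnames(df))) {
    stop("duplicate channel labels in ", path, ": ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  }
  recording(t(as.matrix(df)), fs = man$fs, channel_labels = colnames(df),
            subject_id = man$subject_id %||% "s01",
            condition = man$condition %||% "A")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Collect recordings according to the config.
.pipeline_recordings <- function(config) {
  if (!is.null(config$recordings)) return(config$recordings)
  if (!is.null(config$synthetic)) return(gen_experiment(config$synthetic))
  files <- list.files(config$input_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no .csv recordings found in ", config$input_dir)
  recs <- lapply(files, read_recording)
  names(recs) <- vapply(recs, function(r) paste(r$subject_id, r$condition, sep = "_"),
                        character(1))
  recs
}

# long-format profile table across recordings
.profiles_table <- function(profiles) {
  do.call(rbind, lapply(profiles, as.data.frame))
}

.lzc_table <- function(lzc_list) {
  do.call(rbind, lapply(lzc_list, function(m) {
    scales <- attr(m, "scales")
    data.frame(subject = attr(m, "subject_id"),
               condition = attr(m, "condition"),
               channel = rep(rownames(m), times = length(scales)),
               scale = rep(scales, each = nrow(m)),
               value = as.vector(unclass(m)[seq_len(nrow(m)), ]),
               measure = attr(m, "variant"),
               stringsAsFactors = FALSE)
  }))
}

.cluster_table <- function(res, measure) {
  if (length(res$clusters) == 0) {
    return(data.frame(measure = character(0), cluster = integer(0),
                      cells = character(0), mass = numeric(0), p = numeric(0),
                      d_mean = numeric(0), d_max = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(res$clusters), function(i) {
    cl <- res$clusters[[i]]
    data.frame(measure = measure, cluster = i,
               cells = paste(cl$cell_names, collapse = ";"),
               mass = cl$mass, p = cl$p, d_mean = cl$d_mean, d_max = cl$d_max,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study replica: data in (synthetic, in-memory, or read
#' from disk), per-recording multiscale entropy/complexity profiles and
#' Lempel-Ziv tables, surrogate-thresholded WPLI networks with global
#' functional connectivity and geodesic entropy per band, cluster-corrected
#' group statistics over the ROI x scale lattice and the band chain, and
#' entropy-complexity decoding. Fully deterministic for a fixed config seed;
#' when `out_dir` is set, writes delimited result tables, an edge list per
#' network, and a YAML run manifest.
#'
#' @param config An [analysis_config()].
#' @param stages Subset of `c("profile", "connect", "stats", "decode")`;
#'   stages required by a requested stage are run automatically.
#' @return A `pipeline_result` list with (depending on stages) `profiles`,
#'   `lzc`, `networks`, `network_summary`, `cluster_tests`, `band_tests`,
#'   `decoding`, plus the `config`.
#' @export
run_pipeline <- function(config,
                         stages = c("profile", "connect", "stats", "decode")) {
  stopifnot(inherits(config, "analysis_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if ("decode" %in% stages || "stats" %in% stages) {
    stages <- union(stages, "profile")
  }
  if ("stats" %in% stages) stages <- union(stages, "connect")
  recs <- .pipeline_recordings(config)
  conds <- vapply(recs, `[[`, character(1), "condition")
  subjects <- vapply(recs, `[[`, character(1), "subject_id")
  subj_ids <- unique(subjects)
  scheme <- default_roi_scheme()
  have_rois <- all(unlist(scheme$rois) %in% recs[[1]]$channel_labels)
  res <- list(config = config)

  if ("profile" %in% stages) {
    res$profiles <- list()
    for (v in config$profile_variants) {
      res$profiles[[v]] <- lapply(recs, multiscale_profile, m = config$m,
                                  tau = config$tau, scales = config$scales,
                                  weighted = (v == "weighted"))
    }
    if (length(config$lzc_variants) > 0) {
      res$lzc <- list()
      for (v in config$lzc_variants) {
        res$lzc[[v]] <- lapply(recs, multiscale_lzc, variant = v,
                               m = config$m, tau = config$tau,
                               scales = config$scales)
      }
    }
  }

  if ("connect" %in% stages) {
    res$networks <- list()
    summ <- list()
    for (k in seq_along(recs)) {
      nets <- threshold_networks(recs[[k]], bands = config$bands,
                                 n_surrogates = config$n_surrogates,
                                 q = config$q,
                                 seed = derive_seed(config$seed, 100L + k),
                                 win_s = config$win_s)
      res$networks[[names(recs)[k]]] <- nets
      for (b in seq_along(nets)) {
        gp <- geodesic_profile(nets[[b]])
        summ[[length(summ) + 1]] <- data.frame(
          subject = subjects[k], condition = conds[k],
          band = names(nets)[b], gfc = gfc(nets[[b]]), age = gp$age,
          stringsAsFactors = FALSE)
      }
    }
    res$network_summary <- do.call(rbind, summ)
  }

  if ("stats" %in% stages && have_rois) {
    adj <- roi_scale_adjacency(scheme, config$scales)
    res$cluster_tests <- list()
    stack_cells <- function(variant, what) {
      t(vapply(subj_ids, function(sid) {
        by_cond <- function(cond) {
          pr <- res$profiles[[variant]][[paste(sid, cond, sep = "_")]]
          ra <- roi_average(pr, scheme)[[what]]
          as.vector(t(ra))  # scale-major within ROI, matching adjacency order
        }
        c(by_cond("B"), by_cond("A"))
      }, numeric(2 * nrow(adj))))
    }
    k <- 0
    for (v in config$profile_variants) {
      for (what in c("entropy", "complexity")) {
        k <- k + 1
        ab <- stack_cells(v, what)
        ncell <- nrow(adj)
        b_mat <- ab[, seq_len(ncell), drop = FALSE]
        a_mat <- ab[, ncell + seq_len(ncell), drop = FALSE]
        colnames(b_mat) <- colnames(a_mat) <- rownames(adj)
        nm <- paste(v, what, sep = "_")
        res$cluster_tests[[nm]] <- paired_cluster_test(
          b_mat, a_mat, adjacency = adj, alpha = config$alpha,
          n_perm = config$n_perm, seed = derive_seed(config$seed, 200L + k))
      }
    }
    # band tests on GFC and AGE (B vs A)
    res$band_tests <- list()
    ns <- res$network_summary
    band_names <- config$bands$name
    for (what in c("gfc", "age")) {
      mat <- function(cond) {
        t(vapply(subj_ids, function(sid) {
          vapply(band_names, function(b) {
            ns[[what]][ns$subject == sid & ns$condition == cond & ns$band == b]
          }, numeric(1))
        }, numeric(length(band_names))))
      }
      res$band_tests[[what]] <- band_test(
        mat("B"), mat("A"), alpha = config$alpha, n_perm = config$n_perm,
        seed = derive_seed(config$seed, 300L + match(what, c("gfc", "age"))))
    }
  }

  if ("decode" %in% stages && have_rois &&
      "weighted" %in% config$profile_variants) {
    pr <- res$profiles[["weighted"]]
    pa <- pr[paste(subj_ids, "A", sep = "_")]
    pb <- pr[paste(subj_ids, "B", sep = "_")]
    feats <- ech_features(pa, pb, scheme)
    res$decoding <- ech_decoding(feats, n_perm = config$decode_n_perm,
                                 cluster_n_perm = config$n_perm,
                                 alpha = config$alpha,
                                 seed = derive_seed(config$seed, 400L))
  }

  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, recs)
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$profiles)) {
    cat(sprintf("  profiles: %s over %d recordings\n",
                paste(names(x$profiles), collapse = ", "),
                length(x$profiles[[1]])))
  }
  if (!is.null(x$network_summary)) {
    cat(sprintf("  networks: %d recording x band summaries\n",
                nrow(x$network_summary)))
  }
  for (nm in names(x$cluster_tests)) {
    sig <- significant_clusters(x$cluster_tests[[nm]])
    cat(sprintf("  cluster test %s: %d significant cluster(s)\n", nm,
                length(sig)))
  }
  for (nm in names(x$band_tests)) {
    sig <- significant_clusters(x$band_tests[[nm]])
    cat(sprintf("  band test %s: %d significant cluster(s)\n", nm, length(sig)))
  }
  if (!is.null(x$decoding)) {
    cat(sprintf("  decoding: mean AUC %.3f (chance %.3f), %d significant scale cluster(s)\n",
                mean(x$decoding$auc_per_scale),
                mean(x$decoding$chance_auc_per_scale),
                length(significant_clusters(x$decoding$scale_clusters))))
  }
  invisible(x)
}

.write_pipeline_outputs <- function(res, recs) {
  out <- res$config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$profiles)) {
    tabs <- lapply(res$profiles, .profiles_table)
    write.csv(do.call(rbind, tabs), file.path(out, "profiles.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$lzc)) {
    write.csv(do.call(rbind, lapply(res$lzc, .lzc_table)),
              file.path(out, "lzc.csv"), row.names = FALSE)
  }
  if (!is.null(res$networks)) {
    edges <- list()
    for (nm in names(res$networks)) {
      for (b in names(res$networks[[nm]])) {
        net <- res$networks[[nm]][[b]]
        ut <- which(upper.tri(net$adjacency), arr.ind = TRUE)
        edges[[length(edges) + 1]] <- data.frame(
          recording = nm, band = b,
          channel_a = net$channel_labels[ut[, 1]],
          channel_b = net$channel_labels[ut[, 2]],
          wpli = net$wpli[ut], threshold = net$threshold[ut],
          kept = net$adjacency[ut], stringsAsFactors = FALSE)
      }
    }
    write.csv(do.call(rbind, edges), file.path(out, "network_edges.csv"),
              row.names = FALSE)
    write.csv(res$network_summary, file.path(out, "network_summary.csv"),
              row.names = FALSE)
  }
  cl <- list()
  for (nm in names(res$cluster_tests)) {
    cl[[length(cl) + 1]] <- .cluster_table(res$cluster_tests[[nm]], nm)
  }
  for (nm in names(res$band_tests)) {
    cl[[length(cl) + 1]] <- .cluster_table(res$band_tests[[nm]],
                                           paste0("band_", nm))
  }
  if (!is.null(res$decoding)) {
    cl[[length(cl) + 1]] <- .cluster_table(res$decoding$scale_clusters,
                                           "ech_decoding")
    write.csv(data.frame(scale = res$decoding$scales,
                         auc = res$decoding$auc_per_scale,
                         chance_auc = res$decoding$chance_auc_per_scale),
              file.path(out, "decoding.csv"), row.names = FALSE)
  }
  if (length(cl) > 0) {
    write.csv(do.call(rbind, cl), file.path(out, "clusters.csv"),
              row.names = FALSE)
  }
  cfg <- res$config
  manifest <- list(
    package = "entropica",
    version = as.character(utils::packageVersion("entropica")),
    seed = cfg$seed, m = cfg$m, tau = cfg$tau,
    scales = as.list(cfg$scales),
    profile_variants = as.list(cfg$profile_variants),
    lzc_variants = as.list(cfg$lzc_variants),
    bands = lapply(seq_len(nrow(cfg$bands)), function(b) as.list(cfg$bands[b, ])),
    win_s = cfg$win_s, n_surrogates = cfg$n_surrogates, q = cfg$q,
    n_perm = cfg$n_perm, decode_n_perm = cfg$decode_n_perm, alpha = cfg$alpha,
    n_recordings = length(recs)
  )
  if (!is.null(cfg$synthetic)) {
    sp <- cfg$synthetic
    manifest$synthetic <- list(
      n_subjects = sp$n_subjects, n_channels = sp$n_channels,
      duration_s = sp$duration_s, fs = sp$fs,
      frontal_noise_mix_A = sp$frontal_noise_mix_A,
      frontal_noise_mix_B = sp$frontal_noise_mix_B,
      n_coupled_pairs = length(sp$coupled_pairs_B),
      coupling_freq = sp$coupling_freq,
      coupling_phase_lag = sp$coupling_phase_lag,
      coupling_amp = sp$coupling_amp, seed = sp$seed)
  }
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(out)
}
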