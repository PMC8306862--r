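# entropica

Multiscale entropy, statistical complexity and phase-based connectivity for
multichannel EEG-like time series, with the group statistics needed to compare
two within-subject conditions.

## The problem

How does the irregularity and functional organisation of cortical activity
change between two viewing conditions — for example, between a normal visual
stimulus and a perceptually perturbed one? A standard way to ask this with EEG
is to quantify, per channel and per time scale, how disordered the signal is
(entropy), how structured its disorder is (statistical complexity), and how
strongly channels phase-couple within canonical frequency bands
(connectivity), and then to test condition differences with nonparametric
cluster statistics and multivariate decoding. `entropica` implements that
entire chain for researchers working with clean multichannel recordings, and
ships a synthetic-data generator with known injected effects so every stage
can be validated end to end without any proprietary data.

## The measures

* **Permutation entropy (PE).** Each window of `m` consecutive (τ-spaced)
  samples is mapped to its ordinal pattern, the permutation sorting the window
  (ties stable); with `m = 5` there are `m! = 120` patterns. PE is the Shannon
  entropy of the pattern distribution `p(π)`, normalized by `log m!` to
  `[0, 1]`. The **weighted** variant (WPE) weights each window by its variance
  `ω = mean((x − x̄)²)`, restoring amplitude sensitivity.
* **Jensen–Shannon complexity (JSC).** `C = Q₀ · JSD(p, u) · H(p)/log M`,
  where `u` is the uniform distribution over the `M = m!` patterns,
  `JSD = H((p+u)/2) − H(p)/2 − H(u)/2`, and
  `Q₀ = −2 / [((M+1)/M) log(M+1) − 2 log 2M + log M]`. C vanishes for both
  fully ordered and fully random signals and is positive in between.
* **Multiscale profiles.** Signals are coarse-grained by non-overlapping block
  means at scales θ = 1…20 before computing (W)PE and (W)JSC, giving
  channel × scale entropy–complexity profiles (the entropy–complexity
  hyperplane, ECH).
* **Lempel–Ziv complexity (LZ76).** Phrase count of the exhaustive-history
  parsing, normalized by `n / log_A n`, under median binarization (mLZC) or
  ordinal symbolization (pLZC).
* **WPLI networks.** One-second Hann-tapered windows give cross-spectra
  `S_ij(f)`; the weighted phase lag index per band is
  `Σ_f |Σ_w Im S_ij,w(f)| / Σ_f Σ_w |Im S_ij,w(f)|` — lag-sensitive and blind
  to zero-lag (volume-conduction-like) coupling. Edges are kept when they
  exceed the 95th percentile of 200 phase-randomized surrogates (per edge and
  band), giving binary networks; **GFC** counts the surviving edges.
* **Geodesic entropy (GE/AGE).** Per node, the Shannon entropy of its
  distribution of shortest-path distances to the other (reachable) nodes;
  AGE is the network mean.
* **Statistics.** Cluster-corrected two-sided paired t-tests with a
  within-subject sign-flip permutation null (10,000 flips, α = 0.05) over an
  ROI × scale lattice (frontal / temporo-parietal / occipital, chain
  neighborhood) or the band chain; paired Cohen's d per cluster; LOSO
  linear-discriminant decoding of condition from ROI-averaged ECH features
  with rank AUC and a permuted-label chance distribution.

## Worked example

A six-subject synthetic experiment in which condition B has more irregular
frontal channels and extra gamma-band lagged coupling:

```r
library(entropica)

spec <- experiment_spec(n_subjects = 6, duration_s = 20, fs = 500, seed = 3)
config <- analysis_config(synthetic = spec, scales = 1:10,
                          profile_variants = "weighted",
                          lzc_variants = character(0),
                          n_surrogates = 40, n_perm = 1000,
                          decode_n_perm = 100, seed = 3)
res <- run_pipeline(config)
res
#> <pipeline_result>
#>   profiles: weighted over 12 recordings
#>   networks: 36 recording x band summaries
#>   cluster test weighted_entropy: 1 significant cluster(s)
#>   cluster test weighted_complexity: 1 significant cluster(s)
#>   band test gfc: 1 significant cluster(s)
#>   band test age: 0 significant cluster(s)
#>   decoding: mean AUC 1.000 (chance 0.378), 1 significant scale cluster(s)

res$cluster_tests$weighted_entropy
#> <cluster_result> 2 cluster(s), cluster-forming |t| > 2.571, 1000 sign-flip permutations
#>   cells [frontal.s1, ..., frontal.s10]: mass = 166.03, p = 0.0010, d_mean = 6.78, d_max = 11.38
#>   cells [occipital.s4]: mass = 3.75, p = 0.2917, d_mean = 1.53, d_max = 1.53
```

The positive-mass frontal cluster (p = 0.001) says that weighted permutation
entropy is higher in condition B than A across the whole frontal ROI at
scales 1–10 — the injected irregularity, recovered. The single-cell occipital
cluster does not survive correction (p = 0.29). The gamma-band connectivity
increase shows up in the per-recording network summary:

```r
subset(aggregate(cbind(gfc, age) ~ condition + band, res$network_summary, mean),
       band == "gamma")
#>   condition  band  gfc      age
#> 5         A gamma 24.0 1.225281
#> 6         B gamma 34.5 1.528445
```

Condition B has on average ~10 more significant gamma edges (GFC) and higher
average geodesic entropy, as injected. With `out_dir` set, all profiles,
edge lists, network summaries, cluster tables, decoding results and a YAML
run manifest are written as delimited text files. A command-line front end
over the same pipeline lives at `inst/cli/entropica-pipeline.R`.

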