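---
title: "Multiscale entropy, complexity and connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy, complexity and connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(entropica)
```

`entropica` quantifies how the irregularity, statistical complexity and
phase-coupling structure of multichannel EEG-like signals differ between two
within-subject conditions. This vignette explains the models and estimators,
the numerical conventions the package commits to where the literature leaves
choices open, what the synthetic-data generator does and does not emulate,
and the known limitations.

## Ordinal symbolization and permutation entropy

A series $\{x_t\}$ is embedded into delay vectors
$x_k^* = (x_k, x_{k+\tau}, \dots, x_{k+(m-1)\tau})$,
$k = 1 \dots T-(m-1)\tau$. Each vector is mapped to its *ordinal pattern*:
the permutation of positions that sorts it ascending. With the default
$m = 5$, $\tau = 1$ there are $m! = 120$ patterns, a good compromise between
pattern resolution and the sample sizes at which relative frequencies are
estimable (at the largest time scale used here a 120 s, 1 kHz channel still
has 6,000 points).

Conventions the package fixes:

* **Ties** are broken stably (earlier position first). Exact ties are
  measure-zero for continuous signals, but the convention makes the map
  deterministic — a constant series maps entirely onto the identity pattern.
* **Pattern encoding** is the lexicographic permutation rank (Lehmer code),
  a data-independent bijection onto $0 \dots m!-1$.
* **Logarithms** are natural throughout. Every reported entropy is
  normalized (PE by $\log m!$), so the base is immaterial to the results.

Normalized permutation entropy is
$\mathrm{PE} = -\sum_i p(\pi_i)\log p(\pi_i) / \log m!$ with
$0 \log 0 = 0$. The *weighted* variant replaces each window's unit count by
its population variance $\omega = \frac1m \sum_j (x_j - \bar{x})^2$, so
large-amplitude excursions dominate the distribution; on signals whose
windows all have equal variance the weighted and unweighted distributions
coincide exactly (a property the test suite checks).

## Jensen–Shannon complexity

With $p$ the (possibly weighted) pattern distribution, $u$ the uniform
distribution over $M = m!$ bins and $H$ the Shannon entropy,

$$C = Q_0 \; \Big[ H\!\big(\tfrac{p+u}{2}\big) - \tfrac12 H(p) - \tfrac12 H(u) \Big] \; \frac{H(p)}{\log M},
\qquad
Q_0 = \frac{-2}{\frac{M+1}{M}\log(M+1) - 2\log 2M + \log M}.$$

$Q_0$ normalizes the Jensen–Shannon divergence by its maximum (attained by a
degenerate distribution), so $C$ vanishes at both extremes — a delta
distribution (ordered signal, $H = 0$) and the uniform distribution (fully
random signal, JSD $= 0$) — and is positive in between, tracing the familiar
parabola-like band against entropy. This is the canonical complexity
normalization; the hand-checked reference value $C = 0.12717$ for
$M = 2$, $p = (0.75, 0.25)$ is frozen in the tests.

## Multiscale analysis

Coarse-graining at scale $\theta$ replaces the series by means of
consecutive non-overlapping blocks of $\theta$ samples (trailing partial
block dropped, so the length is $\lfloor T/\theta\rfloor$; $\theta = 1$ is
the identity). Profiles are computed per channel for $\theta = 1 \dots 20$;
at 1 kHz this spans 1–20 ms. The same coarse-graining feeds the Lempel–Ziv
variants.

## Lempel–Ziv complexity

`lz76_complexity()` counts the phrases of the exhaustive-history parsing:
each phrase is the shortest continuation that is not a substring of the text
preceding its final character. Two symbolizations are provided: median
binarization (values at or above the median map to 1 — the at-median case is
a fixed convention the source literature leaves open) and ordinal
symbolization with the same embedding as PE (alphabet $m!$). The count is
normalized by $n / \log_A n$, which makes the binary and 120-symbol variants
comparable and tends to 1 for i.i.d. uniform symbols; no standard
normalization is prescribed in the literature, so this choice is documented
here and asserted in the tests. The implementation is validated against a
definition-based brute-force parser on every binary string up to length 12.

## WPLI connectivity and surrogate thresholding

Recordings are split into non-overlapping 1 s windows; each window is
demeaned per channel (DC leakage suppression), Hann-tapered and Fourier
transformed, giving cross-spectra $S_{ij,w}(f)$ at 1 Hz resolution. Per
frequency bin, imaginary parts are aggregated across windows *before* the
ratio (a single-window ratio is degenerately $\pm 1$):
$\mathrm{num}_f = |\sum_w \mathrm{Im}\, S_{ij,w}(f)|$,
$\mathrm{den}_f = \sum_w |\mathrm{Im}\, S_{ij,w}(f)|$. The band value is
$\sum_{f \in \text{band}} \mathrm{num}_f / \sum_{f \in \text{band}} \mathrm{den}_f$
— an average of per-bin WPLI weighted by each bin's imaginary cross-spectral
energy. The weighting matters: a uniform average over band bins dilutes
narrowband coupling with the $\sim W^{-1/2}$ noise floor of coupling-free
bins, capping even a noiseless lag-coupled sinusoid pair near 0.5, whereas
the energy-weighted form reaches 1 on that fixture while leaving the
homogeneous null case unchanged (the calibration tests cover both). Bands
are half-open ($[7,13)$, $[13,25)$, $[25,45)$ Hz) so shared edges are counted
once. Pairs with identically zero imaginary cross-spectrum (e.g., zero-lag
identical signals) are assigned 0.

Significance is assessed per edge and band against 200 phase-randomized
surrogates: per channel independently, Fourier amplitudes are kept, phases
of positive frequencies are redrawn uniformly (DC and Nyquist untouched),
and Hermitian symmetry enforced. This preserves each channel's spectrum
exactly while destroying cross-channel phase relations. An edge is retained
if its observed band WPLI exceeds the 95th percentile of its own surrogate
values — per-edge rather than pooled, because the finite-sample WPLI bias is
edge-specific. Under the null the per-edge retention rate is the nominal 5%
(checked by Monte-Carlo at reduced surrogate counts). GFC is the number of
retained upper-triangle edges.

## Geodesic entropy

On the binarized network, $D(i,j)$ is the shortest path length in hops.
For node $i$, $p_i(r)$ is the fraction of *reachable* nodes at distance
$r$; its Shannon entropy (nats) is the node's geodesic entropy, and AGE is
the mean over nodes. The renormalization over the reachable set is a
deliberate choice: surrogate-thresholded EEG networks are frequently
disconnected, and the textbook $1/(N-1)$ normalization presumes
connectivity. Isolated nodes get GE $= 0$. The implementation (breadth-first
distances via igraph) is checked against an independent Floyd–Warshall
enumeration on *all* labelled graphs with up to 6 nodes.

## Cluster-corrected group statistics

Condition differences are tested cell-wise (paired t) over a lattice —
ROI × scale for the profiles, the alpha–beta–gamma chain for GFC and AGE —
with cluster-based family-wise correction: cells with $|t|$ above the
two-sided $t_{n-1}$ quantile at $\alpha = 0.05$ form clusters as connected
components of same-sign cells; cluster mass is the summed $t$; the null is
the maximum $|$mass$|$ over random within-subject condition sign flips
(exact for a paired design; 10,000 by default); p-values use the
$(b+1)/(B+1)$ estimator so they are never zero. The cluster-forming
threshold (parametric $t$ quantile at $\alpha$) is a required free parameter
of this framework and is stated here because published descriptions often
omit it. ROI adjacency is the stated two-edge chain
(frontal — temporo-parietal — occipital); lattice cells are adjacent if they
share an ROI and differ by one scale step or share a scale in neighboring
ROIs — diagonal moves are not adjacent, the most conservative reading of a
"space–time volume" neighborhood. Zero-variance cells are excluded with a
warning. Cluster effect sizes report the mean and maximum of the absolute
paired Cohen's d ($\bar{d} = \overline{|m_d / s_d|}$) over the cluster's
cells.

## ECH decoding

Per scale, each subject-condition contributes a 6-dimensional feature
vector: ROI-averaged weighted entropy and complexity for the three ROIs.
A two-class linear discriminant with pooled covariance, shrunk toward the
scaled identity ($S_\gamma = (1-\gamma) S + \gamma\, \overline{\mathrm{diag}\,S}\, I$,
default $\gamma = 0.1$ — the exact regularization is not fixed by the
literature, and any small $\gamma$ stabilizes the 6 × 6 pooled estimate at
these sample sizes), is trained leaving one subject out and scores that
subject's two samples. Decision values are centred within each fold before
pooling (fold-specific discriminant scale and offset are not comparable
across folds; the within-fold contrast is), then ranked into an AUC with
ties counting one half. Chance comes from re-running the whole LOSO
procedure under random within-subject label swaps; observed per-subject
decision margins are compared to mean chance margins with the same cluster
machinery over adjacent scales. Note one property of this design the test
suite documents: under a *true* effect the permuted-label AUC distribution
is left-skewed (the leave-one-out label-flip artifact), so "chance mean =
0.5" is asserted only under null data, where it holds.

## The synthetic-data generator

`gen_experiment()` emulates the study design the pipeline targets:
20 subjects × 2 conditions × 27 channels (standard 10-5 labels) × 120 s at
1 kHz, reproducible from one seed. Its ingredients, and why:

* **Background**: independent per-channel $1/f$ (pink) noise, standardized
  per channel — the minimal model with an EEG-like spectrum; no claim of
  physiological realism.
* **Irregularity manipulation**: frontal channels mix
  $\lambda\,\text{white} + (1-\lambda)\,\text{pink}$, with
  $\lambda_A = 0.2$, $\lambda_B = 0.7$ — a convex, monotonic dial on
  permutation entropy; the 0.5 separation gives a large, unambiguous frontal
  effect at small cohort sizes.
* **Subject heterogeneity**: each subject-condition draws
  $\lambda \sim N(\lambda_c, 0.05)$ (truncated to $[0,1]$) and scales its
  coupling amplitudes by $U(0.7, 1.3)$. Without between-subject variance,
  paired t statistics are driven solely by estimation noise and any
  microscopic systematic difference produces absurd cluster masses; real
  cohorts vary.
* **Gamma coupling**: twelve fronto-posterior channel pairs. Both conditions
  carry a narrowband stochastic oscillator (band-limited Gaussian noise,
  35 ± 1 Hz, RMS amplitude 0.25 ≈ 6% of channel variance) in the paired
  channels, so the conditions' univariate statistics match exactly; in
  condition B the two channels of a pair share *one* oscillator with a
  constant π/4 phase lag across its band, in condition A each channel has
  its own. Three properties motivated this construction: (i) WPLI is blind
  to zero-lag coupling, so the lag must be non-zero; (ii) a *deterministic*
  sinusoid occupies a single record-level Fourier bin and survives
  full-record phase randomization with its cross-channel coherence intact —
  only a stochastic narrowband oscillator (like physiological gamma) is
  genuinely destroyed by the surrogates; (iii) injecting oscillators in
  condition B only leaks the manipulation into the entropy contrast
  (oscillatory channels are more regular), producing spurious posterior
  clusters — matching the univariate content between conditions confines
  the B–A contrast to the phase coupling itself. Twelve pairs put the
  injected edge surplus well above the thresholding false-positive noise
  (≈ 5% of 351 pairs, sd ≈ 4 edges per network), sized so the scaled-down
  replica below has adequate power.

What the generator does **not** emulate: volume conduction and montage
geometry, artifacts (blinks, muscle), non-stationarity, genuine cross-
frequency or directed coupling, and any stimulus content. Passing the
recovery tests therefore shows the pipeline detects the *kinds* of effects
it targets at realistic magnitudes — not that real EEG would show them.

## Problem sizes used in tests and the acceptance script

The package's own validation runs at deliberately reduced sizes, chosen as a
balance between Monte-Carlo error and runtime on a single CPU: calibration
of the cluster test uses 200 null replicates × 500 sign flips on the full
3 × 20 lattice at 10 subjects (family-wise error asserted within 0.01–0.10
of the nominal 0.05; the Monte-Carlo SE is ±0.015); surrogate calibration
uses 20 replicates of 4-channel null recordings at 60 surrogates; effect
recovery runs 10 subjects × 30 s at 60 surrogates, 500 flips and 100 label
permutations. The acceptance script's study replica keeps the full
20-subject cohort but runs 40 s recordings with 60 surrogates, 2,000 flips
and 200 label permutations. At these sizes the frontal entropy/complexity
and gamma GFC effects are decisive (d ≳ 1), while the AGE effect is the
weakest of the battery (sample d around 0.5–0.9 depending on the seed), so
its band cluster hovers around α = 0.05 and can miss the cluster-forming
threshold entirely for some seeds; its direction (positive gamma increase)
is stable, and the script reports the per-band t alongside the cluster
p-value for this reason.

## Known limitations

* EDF input is not supported; recordings are exchanged as delimited matrices
  with a YAML sidecar manifest (`write_recording()` / `read_recording()`).
* The WPLI band aggregation is the energy-weighted form discussed above;
  per-bin WPLI spectra are not exposed directly (use `wpli()` with
  single-bin bands if needed).
* Geodesic entropy is defined on binarized networks only; no weighted-graph
  geodesics.
* The cluster test assumes within-subject exchangeability of the two
  conditions under the null (sign-flip symmetry); it is not a test for
  unpaired designs.
* `m > 7` is accepted but impractical (the pattern distribution becomes
  unestimable at these series lengths); `m > 12` is refused outright.
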