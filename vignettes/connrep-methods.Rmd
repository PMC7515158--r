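---
title: "Methods: quantifying scan-rescan variability of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying scan-rescan variability of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connrep)
```

## What the package computes and why

Functional connectivity estimates from resting-state fMRI fluctuate between
scans. `connrep` quantifies that fluctuation by contrasting two
distributions of a bounded, dimensionless asymmetry statistic — the
normalized difference (ND) — built from scan pairs of the *same* subject
(intra) and from scan pairs of *different* subjects (inter), in a four-scan
test-retest design. The contrast is run at three levels (raw adjacency
matrices, whole-network graph metrics, node-wise graph metrics) and for four
connectivity estimators, two undirected (Pearson and partial correlation) and
two directed (state-space multivariate Granger causality, multivariate
transfer entropy). Everything downstream of the node time series is
implemented here; acquisition, denoising and parcellation are assumed done
upstream.

## The statistic

For nonnegative scalars, `ND(a, b) = (a - b)/(a + b)`, bounded in [-1, 1],
invariant to common rescaling, and defined as 0 when both arguments vanish
(two degenerate measurements register no difference). For matrices the
package uses the squared-Frobenius form `ND(A, B) = ||A - B||_F^2 /
||A + B||_F^2`, bounded in [0, 1] for nonnegative matrices. A square-rooted
variant (a genuine ratio of Frobenius distances) is available behind
`nd_matrix(..., sqrt = TRUE)`; the two are monotonically related, so every
rank-based comparison in the package is identical under either choice — the
squared form is the default because it is the direct trace-ratio expression.
Scalar pairs are oriented earlier-scan minus later-scan, a fixed convention
that makes runs reproducible; the Mann-Whitney comparison is insensitive to
a global orientation flip.

## Pair sampling

Each subject's four scans yield `choose(4, 2) = 6` intra pairs; with S
subjects that is `6S` intra ND values per feature stream. The inter
distribution is built from repeated quadruples of four scans from four
distinct subjects, constrained so each quadruple holds exactly one first,
second, third and fourth scan — this balances scan-order (habituation)
effects between the two distributions. With S repeats the inter distribution
also holds `6S` values. Sampling is without replacement within a repeat;
subjects recur across repeats, which is unavoidable (and intended) when the
number of repeats approaches the number of subjects.

## Estimators and their numerical choices

**Pearson / partial correlation.** Sample correlation, and partial
correlation from the inverse correlation matrix. Negative values are clipped
to zero (the graph metrics and the matrix ND bound require nonnegative
weights). Partial correlation inverts the correlation matrix directly; with
15 nodes and 1200 points this is well-posed, and a `ridge` argument exists
for deficient inputs.

**State-space Granger causality.** One full VAR fit per scan by
equation-wise OLS, order chosen by minimizing the *median* Schwarz criterion
across scans. Conditional GC from i to j is `ln(sigma2_reduced/sigma2_full)`
where the reduced innovation variance comes from solving the discrete
algebraic Riccati equation of the state-space sub-process obtained by
dropping node i from the observation equation — no reduced VAR is refit, so
the reduced model is the exact sub-process of the full fit rather than a
truncated approximation. The Riccati equation is solved by fixed-point
iteration (relative tolerance 1e-11), which converges for the stable
companion matrices produced by stationary fits. Negative numerical estimates
are clipped to zero. The explicit dual-regression route is retained as an
independent cross-check (`granger_matrix_dual()`), fit at a deliberately
higher reduced order (default `max(4p, 30)`) because the sub-process is a
VARMA and a same-order reduced VAR carries visible truncation bias.

**Transfer entropy with non-uniform embedding.** Per target, candidate
terms are all nodes' pasts at lags 1..5. Greedy selection adds the candidate
that most reduces the conditional entropy of the target's present; the stop
rule is a shuffle test (100 permutations of the candidate, level 0.05): if
the observed entropy decrease does not exceed the null's 95th percentile,
selection stops. Entropies use the linear-Gaussian estimator (residual
variance of a linear predictor), the choice that makes the Gaussian
equivalence `TE = GC/2` (nats) testable; nonlinear estimators are out of
scope. TE from i to j is the conditional-entropy difference between the
selected set without i's terms and the full selected set, clipped at zero;
sources never selected contribute exactly 0. Because the embedding
conditions only on *selected* terms while GC conditions on all nodes' pasts,
the two can legitimately differ on indirect-path edges; the equivalence test
therefore checks the median relative deviation over true edges.

**Graph metrics.** Strength (undirected: incident weight sum; directed:
in + out), weighted betweenness on reciprocal-weight lengths with Brandes
accumulation over ordered pairs (symmetric matrices are treated as
bidirectional digraphs, matching the reference toolbox's convention), Onnela
weighted clustering (directed: Fagiolo generalization) with weights
normalized by the matrix maximum, weighted local efficiency on cube-rooted
lengths, and transitivity as the closed-to-total weighted triplet ratio.
Two deliberate conventions: path lengths are `1/w` (the largest silent
degree of freedom in weighted path metrics), and the *global efficiency is
the node average of local efficiencies* — following the analysis design this
package implements, not the classic inverse-shortest-path definition.
Disconnected pairs contribute infinite length (zero inverse distance);
isolated nodes get zero local metrics.

## Preprocessing

Series are standardized to zero mean, unit variance. Stationarity is
verified with an augmented Dickey-Fuller test (constant term, BIC lag
selection, MacKinnon approximate p-values); non-stationary nodes are flagged
and logged, not dropped — verification, not exclusion. Optional blind
haemodynamic deconvolution mirrors the event-triggered approach: pseudo-
events are local maxima above 1 SD, a node-specific double-gamma response is
fit to the event-triggered mean over a `round(10 s / TR) = 14`-point window
(the onset shift is tied to the candidate kernel's time-to-peak so nodes are
not deconvolved with arbitrarily phase-shifted kernels), and latent activity
is recovered by Wiener deconvolution with a regularization floor of 1e-3
times the peak spectral power. Two pass-through guards exist: fewer than
three detected events, and an adequacy gate — if the double-gamma explains
the triggered response poorly (relative residual energy above 0.1), the
haemodynamic model is unsupported and the series passes through unchanged.
In calibration runs, genuinely convolved series fit below 0.02 and
unsmoothed autoregressive series above 0.17, so the gate cleanly separates
the regimes; it is what keeps deconvolution from corrupting directed
structure when applied to data that were never haemodynamically smoothed.
Whether the 1-SD event threshold applies before or after standardization is
moot here: the pipeline standardizes first, where the two coincide.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` realizes the statistical structure the analysis assumes,
with known ground truth. A sparse population coupling pattern (off-diagonal
density 0.2, self-coupling on all nodes) is drawn once and rescaled to
companion spectral radius 0.8; each subject perturbs the nonzero
coefficients with Gaussian noise of SD 0.1; each scan adds jitter of SD
0.025 (a quarter of the subject scale, so intra-subject similarity exceeds
inter-subject similarity by construction) plus fresh unit innovations.
Non-stationary draws are rejection-resampled (at most 100 attempts); a
200-step burn-in is discarded; `hrf_enabled` convolves each node with a
canonical double-gamma response before standardization. Seeds fan out from a
single root seed to per-scan streams.

Defaults (4 scans, 15 nodes, 1200 points, TR 0.72 s) mirror the test-retest
design the package targets. The VAR generative model was chosen because it
realizes directed, lagged coupling that all four estimators can detect and
admits closed-form oracles; it does *not* model neurovascular coupling,
physiological noise spectra, or non-Gaussian/nonlinear dynamics. A green
end-to-end test therefore establishes that the pipeline detects a known
intra-vs-inter similarity margin in linear Gaussian dynamics — not that any
particular empirical dataset has that margin, and no quantitative
calibration of the jitter ratio against real scan-rescan data is claimed.

## Statistics

Intra and inter ND distributions are compared with a two-sided Mann-Whitney
U test (normal approximation with tie correction) and summarized by
`ES = median(inter) - median(intra)`. Node-localization effects pool
local-metric ND per node across all 4 metrics x 4 estimators = 16 streams
and use a Kruskal-Wallis test, followed (when significant) by pairwise
Mann-Whitney tests between nodes. The default decision rule is uncorrected
p < 0.05 with opt-in Benjamini-Hochberg or Bonferroni adjustment — the
uncorrected default reproduces the analysis convention this package
implements while exposing the stricter alternatives. All tests are two-sided
because effects in both directions are scientifically meaningful (several
regional metrics are *more* variable within subject than between subjects).

## Scale-downs and degenerate inputs

Test-suite simulations use the smallest sizes that exercise each claim: the
stationarity-rate invariant uses 25 default scans rather than 100, and the
Kruskal-Wallis null calibration draws 200 exchangeable synthetic ND tables
rather than 200 full estimator pipelines (the property under test is the
calibration of the test machinery, which the table-level null isolates; 200
pipelines would cost hours). Degenerate inputs are contracts, not surprises:
constant series abort standardization and the ADF test, zero-variance nodes
abort correlation estimators, singular correlation matrices abort partial
correlation with a ridge suggestion, subjects without exactly four scans
abort intra enumeration naming the subject, and `ND(0, 0) = 0` throughout.

## Known limitations

Linear-Gaussian transfer entropy only; no frequency-domain causality; no
dynamic (time-varying) connectivity; no ICC-style reliability coefficients
or variance-component models; the Kruskal-Wallis node test is rank-based and
thus has little power against purely symmetric scale differences between
nodes — its power target is location shifts of pooled ND.
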