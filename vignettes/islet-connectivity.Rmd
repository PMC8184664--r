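---
title: "Islet β-cell functional connectivity: model, calibration and design notes"
author: "isletcon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Islet β-cell functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletcon)
```

## The analysis

`isletcon` infers which β cells within an islet oscillate together. The input
is one mean-fluorescence time series per ROI, recorded at a uniform frame
rate (the package's defaults assume 0.5 Hz, i.e. a 2 s frame interval, and
roughly 50 ROIs per islet). The pipeline is

smooth → normalise to F/F₀ → all-pairs Pearson R → per-pair bootstrap p →
threshold (R > 0.25 and p < 0.001) → colour-binned line map and heatmap.

`islet_connectivity()` runs all stages and returns a classed fit; every stage
is also exported on its own.

## Preprocessing conventions

**Retrospective smoothing.** "Average of the previous 10 values" admits two
readings. `smooth_retrospective()` uses a causal trailing window of length
`window` *including* the current sample, with shortened windows at the start
of the trace, so the output has the input's length and never looks ahead. The
strict reading — exactly the `window` samples *before* the current one — is
available via `include_current = FALSE` (the first sample, having no
predecessors, is kept). The inclusive form is the default because it is the
standard trailing moving average and leaves constants exactly fixed at every
position.

**F₀.** The baseline is the mean of the first `f0_frames` samples of each
cell; use the pre-stimulus baseline length when it is known (the simulator's
default is 30 frames = 60 s), else the default 30 is a reasonable stand-in
for recordings that begin at low glucose. After `normalise_f0()` the mean of
each cell's baseline window is exactly 1. Cells with |F₀| < 1e-12 abort the
normalisation by name, and `drop_degenerate_cells()` removes zero-variance
traces (variance < 1e-12), which would make Pearson R undefined.

**Order.** Smoothing precedes normalisation. Because the trailing mean is
linear and F₀ division is a per-cell scalar, the two nearly commute (they
differ only through F₀ being computed on smoothed rather than raw baseline
frames); the chosen order matches the conventional description of the
procedure.

## Correlation and significance

`pearson_matrix()` is the standard product-moment coefficient per unordered
pair; autocorrelations are excluded (the diagonal is `NA`, not 1).

`bootstrap_pvalues()` attaches a per-pair significance. The default scheme
resamples frame indices with replacement, identically for both members of a
pair, recomputes R per replicate, and reports the one-sided

p = (1 + #{replicate R ≤ 0}) / (n_boot + 1),

which asks whether the bootstrap confidence interval of R excludes zero.
One-sided is deliberate: functional connectivity here means *positive*
co-activity, consistent with the R > 0.25 edge rule. The +1 smoothing means p
is never exactly 0; the minimum attainable value is 1/(n_boot + 1), and the
default `n_boot = 10000` makes the 0.001 threshold comfortably resolvable
(a warning is raised below 1000 replicates). A replicate in which either
resampled series is constant is discarded and redrawn; more than 10%
discarded replicates for a pair aborts that pair with an error, since the
data are then effectively degenerate.

Two alternatives are provided because the iid frame bootstrap assumes
exchangeable frames:

* `block_bootstrap` resamples contiguous blocks (default length = the
  smoothing window) and is the appropriate scheme for smoothed traces;
* `permutation` permutes one member's frames and tests the null R = 0
  directly, p = (1 + #{replicate R ≥ observed}) / (n_boot + 1).

**Calibration regime.** A trailing 10-frame average gives the smoothed noise
an autocorrelation that inflates the variance of a null pair's R̂ roughly
6–7-fold at 300 frames. The iid bootstrap does not see this, so on
*smoothed* noise the pairs bootstrap is strongly anticonservative — that is a
property of the scheme, not a bug in the code. The package's calibration
claims (type-I error within the binomial band around α = 0.001; planted
recovery with precision/recall ≥ 0.9) are therefore established on
serially independent (unsmoothed, normalised) traces, which is also how the
test suite and `scripts/acceptance.R` run them. For real, smoothed
recordings use the block bootstrap, or long recordings where the smoothing
window is negligible relative to the record length. `islet_connectivity()`
warns when smoothing is combined with the iid scheme.

**Reproducibility.** Each pair draws from its own RNG substream derived from
(`seed`, pair index) by a counter hash, independent of R's global RNG. The
same inputs, seed, method and replicate count give byte-identical results,
and `boot_replicate_indices()` regenerates any pair's exact resampling
indices so an external implementation can verify any single p-value.

**Multiplicity.** No multiple-testing correction is applied across cell
pairs by default — the edge rule is a fixed per-pair threshold. `bh_adjust()`
can be applied to the long-format pair table when a family-wise FDR is
wanted.

## Thresholds and bins

An edge requires **strictly** R > 0.25 and p < 0.001; a pair at R = 0.25 or
p = 0.001 exactly is not connected. Strength bins are green (0.25, 0.5),
yellow [0.5, 0.75), red [0.75, 1]: the published ranges overlap at 0.5 and
0.75, and the package assigns boundary values to the upper bin (half-open
upward). Values within 1e-9 above 1 — numeric noise from near-perfect
correlations — are clipped to 1 before binning; anything further outside
(0.25, 1] is an error. The line map draws nodes at the supplied ROI
coordinates and straight, bin-coloured edges; all plotting is a thin layer
over the exported tables, so every decision is testable headlessly.

## The simulator

`simulate_islet()` generates the study conditions the analysis is designed
for. Cell *i*'s trace is

F_i(t) = f0_i · (1 + a_i · s(t − τ_i) · 1[t ≥ t_stim]) + b·k + ε_ik

with a per-cell baseline f0_i ~ Normal(f0_mean, f0_sd), a shared
unit-variance periodic signal s (square burst train by default, sine
optional) switched on after `baseline_frames`, amplitude a_i =
`coupling_amplitude` for the coupled subpopulation and 0 otherwise, a
per-cell constant phase shift τ_i ~ Normal(0, `phase_jitter_s`), optional
linear drift b per frame k, and iid Gaussian noise.

Default conditions: 50 cells, 300 frames at 2 s (10 min of recording), 30
baseline frames (60 s), oscillation period 60 s — the slow glucose-driven
Ca²⁺ oscillation regime — coupling amplitude 0.10 (a 10% ΔF/F modulation),
baseline 100 ± 10 AU, and noise σ = 8 AU (~8% of baseline). The coupled
subpopulation is drawn once per simulation, Bernoulli(0.4), unless an
explicit mask is supplied. These were chosen once as a realistic islet
field-of-view and are not tuned per experiment.

The square wave is ±1 with 50% duty cycle, so it has zero mean and unit
variance over full cycles; the sine option is scaled by √2 for the same
normalisation. Phase jitter is a per-cell *constant* shift (not per-cycle),
which keeps the closed form below valid at zero jitter and interpretable
otherwise.

**Closed-form calibration.** With no jitter, no drift and a homogeneous
baseline (f0_sd = 0), two coupled traces are a common deterministic signal
plus independent noise, so their population correlation is

R = a²v / (a²v + σ²),  v = f0² · Var(s̃)

where s̃ is the gated signal on the actual frame grid (baseline frames, where
it is zero, included — they dilute the signal variance and the closed form
accounts for that exactly). `expected_pairwise_r()` evaluates this and
`noise_sd_for_target_r()` inverts it; the empirical coupled-pair R converges
to it as the recording grows (the tests check agreement within ±0.02 at
10,000 frames). With f0_sd > 0 the per-pair expectation varies slightly with
the drawn baselines, and the ground truth reports the pair-specific value
√(R_i R_j).

ROI coordinates are rejection-sampled uniformly on a disc with a minimum
spacing constraint; an infeasible packing errors out stating how many points
could be placed. Coordinates carry no signal — they exist for the line map
and for round-trip tests.

**What the simulator is not.** It is a statistical stand-in, not a
biophysical model: no electrophysiology, no dye kinetics, no bleaching beyond
linear drift, no pixel-level imagery, and coupled cells share one global
signal rather than propagating waves. Passing the recovery and type-I tests
shows the inference machinery is correct and calibrated under these
conditions; it does not by itself validate the edge thresholds on real
recordings, whose noise is neither Gaussian nor serially independent.

## Pre-ranked enrichment

`enrichment_score()` implements the running-sum statistic on a ranked gene
list: hits increment by |stat|^weight normalised over the set's in-list
members, misses decrement by 1/(N − N_hit), and the ES is the signed maximum
deviation. Defaults and conventions:

* `weight = 1` (the conventional weighted form); `weight = 0` gives the
  classic unweighted statistic. At weight 0 the ES is invariant to any
  monotone rescaling of the statistics; at weight 1 to positive scalar
  multiplication.
* Ties in the statistics are broken lexicographically by gene id when the
  list is built, so the ranking and the ES are deterministic.
* Set members absent from the ranked list are dropped with a message (they
  are not counted as misses).
* With ties at the extremum, the first (top-most) extremum defines the ES and
  the leading edge.

`permutation_significance()` uses a gene-label null — random same-size member
sets drawn without replacement — the only null available for pre-ranked
input. Significance is conditional on sign, the usual pre-ranked GSEA
convention: a positive score is compared with the non-negative null scores
only, p = (1 + #{same-sign null ≥ ES}) / (#same-sign + 1), and
NES = ES / mean(|same-sign null ES|). When C(N, N_hit) ≤ 20,000 the null is
enumerated exhaustively and p is the exact same-sign fraction (no +1, since
the observed placement is itself among the enumerated ones); the exact and
Monte-Carlo modes estimate the same quantity and the tests check they agree
within binomial error.

Across a family of sets, `gsea_preranked()` adjusts the permutation p-values
with Benjamini–Hochberg (`bh_adjust()`, standard step-up with monotonicity).
This is a deliberate simplification relative to the GSEA-style NES-based FDR:
BH on permutation p-values is exactly defined for any mixture of exact and
Monte-Carlo results and anchors on the adjustment actually quoted for the
differential-expression side of such analyses. The package ships a small
illustrative epithelial/mesenchymal GMT
(`inst/extdata/synthetic_emt_sets.gmt`, synthetic in the sense of being a
generic marker compilation, not a curated published appendix) and reads any
RNK/GMT pair.

## Numerical choices

* Zero-variance detection (traces, F₀, bootstrap replicates): absolute
  tolerance 1e-12 on the variance (replicates use a scale-aware equivalent).
* Frame-time uniformity: relative tolerance 1e-9 on the spacing.
* Correlations just above 1 from floating noise: clipped to 1 within 1e-9
  for binning and to [−1, 1] for heatmap export.
* Non-finite trace values abort construction with the frame and cell named;
  ragged or non-numeric trace files abort parsing with the row/column named.
* Degenerate bootstrap replicates are redrawn from the same substream, so a
  pair's p-value depends only on (seed, pair index, data).

## Problem sizes

The test suite and the acceptance script establish the quantitative claims at
the scale the analysis targets: 10 random 10×50 matrices ×2 for oracle
equivalence; 17 pure-noise islets of 50 cells × 300 frames (20,825 null
pairs, n_boot = 2000) for the type-I band around α = 0.001; five planted
islets (20 coupled cells of 50, expected R = 0.6) for recovery; one
10-cell × 10,000-frame recording per target for calibration; exhaustive
C(6,2) enumeration plus 4,000 permutations for the enrichment example. The
full suite runs in well under five minutes on one CPU.

## Known limitations

* No lagged cross-correlation, directionality, or partial correlation; the
  graph is undirected instantaneous co-activity.
* No multiple-testing correction across pairs in the edge rule itself.
* The iid bootstrap's miscalibration on smoothed traces is inherent; the
  block bootstrap mitigates but block length is a tuning choice.
* Graph summaries stop at degree and percentage connected; no community or
  small-world statistics.
* The enrichment module consumes ranked lists; it does not produce
  differential statistics (no count modelling) and does not download any
  gene-set database.
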