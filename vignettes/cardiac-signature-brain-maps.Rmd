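---
title: "From a cardiac amplitude signature to brain maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a cardiac amplitude signature to brain maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiohub)
```

## What this package computes

`cardiohub` links a scalar cardiac amplitude signature, the Ekappa score,
and NEO personality scores to functional and structural brain maps. The
whole chain runs on synthetic data with known ground truth, so every stage
is testable without access to any subject data:

1. **ECG signature.** From a 12-lead resting ECG, beats are detected,
   artifact-free beats are averaged per lead, four absolute amplitudes are
   measured, and the score

   $$E_\kappa = \alpha \left( \frac{T_{aVL}}{RS_{aVL}} -
   \frac{R_{III}}{RS_{Vmax}} \right), \qquad \alpha = 10$$

   is computed, where $T_{aVL}$ and $RS_{aVL}$ are the T-wave amplitude
   and R-to-S excursion of lead aVL, $R_{III}$ the R-wave amplitude of
   lead III, and $RS_{Vmax}$ the maximal R-to-S excursion over the chest
   leads V1–V6. $E_\kappa$ is exactly linear in $\alpha$; $\alpha$ only
   scales the score for readability.
2. **Phenotype statistics.** A Shapiro–Wilk gate decides between
   regression (p ≥ .05) and median-split dichotomization; the six NEO
   measures (neuroticism, extraversion, agreeableness; warmth, positive
   emotion, tender-mindedness) are compared between the Ekappa groups with
   directed one-sided t tests at the Bonferroni-corrected level
   $0.05/6 \times 2 = 0.017$.
3. **Eigenvector centrality mapping (ECM).** Each voxel receives the
   corresponding entry of the principal eigenvector of a nonnegative
   voxel–voxel similarity matrix, computed after temporal high-pass
   filtering (1/90 Hz) and 6 mm FWHM Gaussian smoothing, either for the
   whole session or per stimulus epoch.
4. **Voxel-wise inference.** Second-level OLS regressions or two-sample
   contrasts with nuisance covariates; t statistics are converted to
   signed z scores by quantile matching. Familywise error is controlled by
   Monte Carlo cluster-size/cluster-mass thresholds (cluster-forming
   z = 2.326) or, inside an a-priori region of interest, by a
   permutation max-statistic small-volume correction.

## The synthetic cohorts: what they emulate, and what they do not

The generators define the study conditions; their defaults follow the
design constants of the experiments they emulate.

**ECG generator.** Twelve leads at 1000 Hz. The six extremity leads are
derived from three simulated electrode potentials (RA, LA, LL), so the
Einthoven/Goldberger identities (III = II − I, aVL = I − II/2,
aVR = −(I + II)/2, aVF = II − I/2) hold to machine precision by
construction — this is what makes "the maximal RS at any chest lead" and
the aVL/III measurements meaningful. Each beat is a sum of asymmetric
Gaussian bumps (P, R, S, T) plus an ST plateau with cosine ramps; the T
bump rides on the plateau, so the convention "T measured against the first
plateau-like shape preceding the T peak" has a well-defined target. The
plateau parameter `st_offset_mv` is specified as the plateau level of a
waveform with the nominal 0.3 mV T amplitude, with other waveforms scaling
proportionally to their T amplitude: a fixed additive plateau would cancel
exactly in derived leads (III = II − I), whereas a T-proportional plateau
survives every linear lead combination. A 2-minute noiseless recording at
60 bpm contains exactly 120 complete cycles.

**Cohort structure.** Subjects belong to two equal latent
"tender-emotionality" groups. The high group's T amplitudes are scaled by
$1 + c/2$ and the low group's by $1 - c/2$ (default contrast $c = 0.6$),
which moves $T_{aVL}$ and therefore Ekappa apart between groups.
Between-subject variability has three components chosen to mimic how real
amplitude variation factors: a common per-subject gain (log-normal,
SD 0.2 — body habitus and electrode placement scale all amplitudes
together and cancel in the Ekappa ratios), per-wave-type gains (SD 0.05)
and per-waveform jitter (SD 0.03). With these settings the latent groups
separate by roughly d ≈ 1.8 on measured Ekappa, so a median split
recovers them at ~90–100 % agreement — separated but not trivially so.
NEO scores are standard-normal scales linearly coupled to the latent group
(coupling 0.5; neuroticism negatively, the other five positively), the
emulated study having reported only that NEO scores were normal.

**BOLD generator.** The emulated experiment's design constants are fixed defaults:
48 trials of 48 s (30 s stimulus, 2 s signal, 12 s rating, 4 s rest) at
TR 2 s — 1152 volumes — with 16 trials per category (joy, fear, neutral)
in a pseudorandom order with at most two consecutive trials of one
category. The spatial grid is a desk-scale 12×12×10 box of 3 mm voxels; it
stands in for a registered brain volume and implies nothing anatomical. A
2×2×2 hub block shares a latent AR(1) time course; the surrounding
4×4×4 shell couples to the same course with strength
`network_base + network_slope * trait`, so network correlation — and hence
hub-region eigenvector centrality — increases monotonically with the
subject's trait. All other voxels are white noise plus slow cosine drifts
(below the 1/90 Hz cutoff) that exist to exercise the high-pass filter.
Per-condition epochs cover the stimulus volumes only (15 volumes per
trial): whether rating/rest volumes entered the original per-condition
maps is unstated, and stimulus-only is the cleaner operationalization; a
hemodynamic-lag shift is a config option defaulting to 0.

**GM generator.** Registered, modulated grey-matter-like maps on a
16×16×12 grid of 1.5 mm voxels: a shared smooth anatomical background in
[0.2, 0.8], iid subject noise (SD 0.1), a planted 27-voxel ROI shifted by
`effect_d × noise_sd` in the latent high group (default d = 1.2), and a
per-subject log-normal global scale (SD 0.05) with age/gender structure.
The total-volume covariate is the map sum. The shift is applied before
global scaling so "d" keeps its literal meaning in noise-SD units.

**What the generators do not emulate:** hemodynamic response shapes, MR
artifacts and motion, anatomically realistic cardiac dipoles, spatial
autocorrelation of GM noise, registration error. Passing tests therefore
demonstrate that the *analysis chain* is correct and calibrated under its
stated assumptions — not that it would behave identically on real
recordings, where artifact rates, smoothness and effect geometry differ.

## Measurement conventions (ECG)

The emulated study names only an in-house measurement tool, so the
operationalizations below are this package's own, each with a tunable
parameter:

- **R-peak detection**: band-pass 5–15 Hz, squared derivative, 150 ms
  integration, adaptive threshold (30 % of the 99th energy percentile),
  250 ms refractory period; peaks refined on the raw reference lead
  (default II).
- **Artifact rule**: a beat is excluded when its cycle correlates with the
  median beat template below 0.9, its R amplitude deviates more than
  3 MAD from the median, or its full cycle window leaves the recording.
- **Baseline**: mean of a 40 ms PR-segment window ending 20 ms before QRS
  onset (40 ms before the R peak). R and P are measured against it.
- **RS**: R-peak-to-S-trough excursion; the S trough is the minimum within
  80 ms after the R peak. The chest-lead maximum is taken over absolute
  RS excursions (polarity differences across V1–V6 would otherwise make
  the "maximum" ill-defined).
- **Plateau**: the earliest ≥ 20 ms window between QRS end (R + 80 ms) and
  the T peak whose absolute slope stays below 2.5 µV/ms; T is measured
  against its mean, falling back to the PR baseline (with a warning) when
  no such window exists.
- **Averaging window**: [−0.45, +0.55) × median RR around each R peak, the
  same alignment index for every lead, so lead identities survive
  averaging.

On noiseless cohorts these conventions recover the generator's amplitudes
to well under 1 % and Ekappa to under 5 % — the margins the test suite
enforces (2 % / 5 %).

## Numerical choices in the ECM core

- **Similarity**: $g(r) = (r+1)/2$ maps Pearson correlations into [0, 1],
  guaranteeing a nonnegative matrix to which Perron–Frobenius applies;
  $g(r) = \max(r, 0)$ is available for sensitivity checks (dense path
  only). The diagonal is 0; adding a constant diagonal shifts all
  eigenvalues equally and leaves the eigenvector unchanged.
- **Power iteration**: uniform positive start, update
  $v \leftarrow (S + I)v / \lVert (S+I)v \rVert_2$, tolerance 1e-9 on the
  update norm, 1000 iterations cap, deterministic and seed-free. The
  identity shift leaves the principal eigenvector untouched while
  preventing the two-cycle oscillation that plain power iteration exhibits
  on bipartite-like graphs (e.g. an exact star).
- **Matrix-free evaluation**: with standardized data $C$ (rows centred,
  unit norm), $S v = \tfrac12 (C C^\top v + \mathbf{1}^\top v) - v$, so the
  V×V matrix is never formed; dense and matrix-free paths agree to 1e-6 on
  instances up to 500 voxels (and to 1e-10 as raw products).
- **High-pass**: projection onto the orthogonal complement of the
  discrete-cosine functions with frequency $k/(2T \cdot TR)$ below the
  cutoff, plus the mean — the fMRI convention — rather than a recursive
  filter; a pure 1/200 Hz tone is attenuated below 10 % while 0.05 Hz
  passes above 95 %.
- **Smoothing**: separable truncated Gaussian (±4σ) with edge
  renormalization, so constants are preserved exactly and interior mass to
  1e-6.

## Cluster-level inference

Null fields for the Monte Carlo thresholds are white noise smoothed to the
pipeline's applied FWHM and standardized to unit in-mask variance — the
smoothness is known by construction for synthetic data (a residual-based
estimator would be needed for real data and is out of scope). Clusters are
formed at z = 2.326 separately for each sign (both signs are reported),
under 26-connectivity by default (6/18/26 configurable; the original
tool's convention is unknown).

A cluster is significant when **either** its size or its mass (sum of
suprathreshold |z|) reaches its critical value. Taking both critical
values at the marginal (1 − α) quantiles would inflate the familywise
error of the disjunction, so the two levels are calibrated jointly: the
largest per-criterion level is chosen whose disjunctive exceedance over
the null iterations stays within α. The acceptance suite verifies 0.05 ±
0.015 familywise error on 1000 fresh null fields. "Cluster value" is
interpreted as cluster mass; the original description does not define it.

The small-volume correction is a Freedman–Lane residual-permutation
max-statistic test restricted to the ROI: the nuisance-only model is
fitted, residuals are row-permuted and added back to the reduced fit, and
the full-model max |z| (peak level) and max cluster size/mass (cluster
level) over the ROI are recorded per permutation. At desk scale this is
exact up to Monte Carlo error and needs no smoothness estimation, which is
why it was chosen over random-field theory.

Design notes: t→z conversion uses log-scale tail probabilities, is
monotone and sign-preserving with z(0) = 0 exactly. Whether the original
centrality maps were rescaled before second-level analysis is unstated;
unit-Euclidean-norm maps are used as-is. The gate threshold (0.05), the
median-split tie rule (values equal to the median go to the low group) and
the pooled-variance default for the directed t tests (small balanced
groups; Welch optional) are package decisions where the source is silent.

## End-to-end chains and problem sizes

`run_exp1_chain()` composes the functional analysis: ECG cohort (n = 22) →
Ekappa → median split (11/11) → BOLD cohort with the hub coupled to the
latent group → session ECMs → two-sample z map with age/gender nuisance →
Monte Carlo cluster correction → does a significant positive cluster
overlap the planted hub region? `run_exp2_chain()` composes the structural
analysis: ECG cohort (n = 60) → Ekappa → median split → GM cohort with the
planted ROI effect → ROI small-volume permutation test controlling age,
gender and total volume.

Problem sizes used by the test and acceptance runs (the package's own
choices for desk-scale replication): chain ECGs of 60 s (functional) and
30 s at 500 Hz (structural) — the Ekappa measurement is
sampling-rate-invariant within 2 % and needs only a few dozen beats —
1152-volume BOLD series on the 12×12×10 grid, 1000–4000 Monte Carlo
iterations, 500–2000 permutations, and 50 seeded replicate runs per chain.
Under these conditions the hub region is flagged and the ROI effect
reaches FWE significance in well over 80 % of runs, and both procedures
hold their nominal error rates under null effects.

## Known limitations

- The amplitude conventions assume dominantly positive QRS complexes in
  the leads entering Ekappa; leads with inverted QRS (aVR) get the
  convention-consistent but physiologically less meaningful "absolute"
  readings.
- The Monte Carlo null assumes stationary Gaussian smoothness equal to the
  applied kernel; real data need a smoothness estimate.
- The rectified similarity option forms the dense matrix and is therefore
  limited to small masks.
- Noise is added at the electrode level, so derived limb leads carry
  combination noise (lead I has SD σ√2 when electrodes have SD σ); the
  per-sample noise-SD contract holds exactly for the chest leads.
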