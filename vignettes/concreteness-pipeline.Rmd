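---
title: "Methods: broadband-gamma analysis of concreteness judgements"
author: "concretecascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broadband-gamma analysis of concreteness judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package
implements, the assumptions behind them, the parameters that matter, and
the design decisions that were genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The scientific setting

In a concreteness-judgement task, a participant reads single words —
concrete (*table*), abstract (*justice*), or "midscale" words whose
population concreteness ratings sit mid-scale with high inter-rater
disagreement (*profit*) — and decides whether the referent is directly
perceptible. With intracranial EEG, the quantity of interest is
broadband gamma activity (BGA): the 70–150 Hz analytic amplitude,
expressed as percent change from a pre-stimulus baseline, a standard
proxy for local cortical processing. The pipeline asks where and when
BGA distinguishes concrete from abstract words, whether single trials
carry that information, whether midscale words track the participant's
judgement or an invariant intermediate code, how directed information
flows between regions, and whether behavior and stimulation statistics
corroborate the picture.

Patient recordings cannot be redistributed, so the package ships a
synthetic-cohort generator whose statistical structure matches what the
analyses assume; every planted quantity is serialized as ground truth
and every stage is validated by recovering it.

## Signal chain

The preprocessing chain is: zero-phase 2nd-order Butterworth band-stop
filters at the line frequency and harmonics (60 Hz by default, ±2 Hz);
common average reference over included channels; a frequency-domain
bandpass Hilbert transform; Savitzky–Golay smoothing (3rd order, 201 ms
frame) of the analytic amplitude; epoching to $[-0.7, 1.5]$ s around
word onset with percent-change normalization to the per-trial baseline
mean over $[-0.5, -0.1]$ s; and a responsiveness filter keeping
electrodes whose trial-mean BGA strictly exceeds 10% in 300–700 ms.

Numerical choices worth recording:

* **Flank parameterization.** The band mask uses paired logistic
  flanks, $\mathrm{mask}(f) = \sigma((f-70)/s)\,\sigma((150-f)/s)$ with
  $s$ chosen so the 10–90% transition spans $2 \times 1.5$ Hz
  ($s = 1.5/\ln 9$). The mask is exactly 0.5 at each band edge; the
  test suite asserts a 70 Hz tone comes out with envelope 0.5 and a
  30 Hz tone is suppressed below 0.01.
* **Per-trial baseline.** Baselines could be read per trial or per
  block; per-trial was chosen (each trial carries its own $[-0.5,-0.1]$
  s mean), which makes the baseline-zero invariant exact up to
  smoothing leakage and is asserted to within ±0.5 percentage points.
* **Strict responsiveness inequality.** An electrode at exactly 10% is
  excluded; ties are vanishingly likely but the rule must be fixed.
* **Rate invariance.** All filters are specified in physical units, so
  the same signal sampled at 500 Hz and 2 kHz yields window-mean BGA
  within 2 percentage points; the default synthetic rate is 500 Hz for
  speed, with 2 kHz available by configuration.
* **Artifact and error trials.** Epileptiform/saccade artifact
  rejection is represented as an input boolean column honored by
  epoching, not as a detector. Incorrect-response trials are dropped
  for neural contrasts but retained for behavioral statistics; midscale
  trials have no correct answer and are always retained.

## Hierarchical mixed-effects contrasts

At each time bin the package fits, by REML,

```
BGA ~ Concreteness + WordLength + WordFrequency
      + (1 | Patient) + (1 | Patient:Electrode)
```

with concreteness coded +1 (concrete) / −1 (abstract), so positive
$\beta$ (in % BGA per contrast unit) means concrete > abstract. For the
midscale rated-class analysis the same contrast is coded from the
participant's response instead of the stimulus class. Word length and
Zipf frequency are centered covariates. Significance bars are
contiguous bins with Benjamini–Hochberg $q < 0.01$.

Decisions: fits run on 10 ms-averaged bins rather than every raw
sample — the statistical content of smoothed BGA is unchanged and the
sweep becomes tractable; p-values are Wald (normal approximation on the
t statistic), appropriate at the thousands of observations per fit and
orders of magnitude faster than Satterthwaite corrections; singular or
non-converged bins are flagged and carried with $p = 1$ rather than
halting the sweep. ROI membership uses Euclidean distance to the ROI
center (default radius 10 mm) with geodesic assignment available when a
mesh is supplied; grouped traces average electrodes within patient
first, then across patients, which the tests verify equals a weighted
electrode average with weights $1/n_{\text{electrodes}}$ per patient.

## Surface-based mixed effects and cluster FWE

Each electrode's "recording zone" maps it onto a triangle mesh: the
electrode snaps to its nearest vertex and nearby vertices are weighted
$e^{-d/\lambda}$ by geodesic distance $d$, truncated at a cutoff. The
decay and cutoff have no canonical values; defaults are $\lambda = 3$ mm and
10 mm, both configurable and logged. At each vertex covered by the
minimum number of patients, the same concreteness LME is fitted to
window-mean BGA with the zone weights as observation weights (weighting
the observations was chosen over pre-averaging because it preserves
trial-level covariates and the hierarchical error structure).

Two threshold presets ship — a strict one ($t > 2.5$, ≥3 patients)
and a methods variant ($t > 2$, ≥3 patients), plus a lenient $t > 1$
preset for exploratory maps; none is hard-coded, since reporting
conventions for such maps genuinely vary.

Cluster correction uses extent (vertex count) as the cluster statistic
— mass and extent are equivalent for the smooth maps involved, and
extent is the simpler, more common choice. The null is Monte Carlo:
vertex white noise smoothed on the mesh by repeated neighbor averaging
until its mean neighbor correlation matches the observed map's within
0.02, standardized, thresholded identically, recording the maximum
cluster extent; corrected
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_{\text{iter}})$.
Iteration counts below 100 are refused because the $1-\alpha$ quantile
is unstable there. Test meshes are generated icospheres (the 1,280-face
sphere used in the calibration tests has 642 vertices); the algorithm
is mesh-agnostic. Family-wise error calibration is asserted at the
map level — repetitions draw null t-maps from the smoothed-noise
process the correction assumes — because repeating the full vertex-wise
LME hundreds of times would add nothing to the calibration question
while multiplying its cost a thousandfold.

## Decoding

The sliding decoder is a linear SVM (cost 1) per time bin on all
(responsive) electrodes' bin-averaged BGA, stratified 10-fold
cross-validation, features z-scored with training-fold statistics only;
performance is the AUC of pooled held-out decision values. The
permutation null shuffles labels within patient and re-runs the full
pipeline (1,000 shuffles at full scale; tests use 100–200), with the
pointwise threshold at the 97.5th percentile. The leakage guard is
itself tested: shuffling labels before the entire pipeline yields
chance-level AUC.

The midscale analysis gates patients on decodability: a window decoder
(500–800 ms features) must beat its own shuffle null at $p < 0.05$.
The gate uses the window decoder, not the sliding estimator — the
quantity being gated is the window representation the SVR uses. Gated
patients get a linear SVR trained on concrete (target 5) and abstract
(target 1) trials and evaluated on midscale trials against two label
sets: the response-based model (5/1 by the participant's rating) and
the midscale model (constant 3). Paired MSEs are compared by Wilcoxon
signed rank (exact for small samples without ties; tie-corrected
normal approximation otherwise).

Because the constant-3 label set has zero variance, MSE comparisons
can favor it artifactually. The generator therefore supports both an
*invariant* midscale regime (neural gain midway between classes,
independent of the simulated rating) and a *response-driven* regime
(gain follows the rating), and the test suite asserts the double
dissociation — the midscale model wins under the first regime and the
response model under the second — so a win by the constant model is
demonstrably not a variance artifact of the scoring. An approximate
default-prior (JZS, scale $\sqrt2/2$) paired Bayes factor accompanies
the signed-rank p-value; it is flagged approximate and optional,
because there is no canonical Bayes factor for rank tests and the
t-based one is only a companion, not a rank-based quantity.

## Partial directed coherence networks

Gamma envelopes aligned to word onset are divided into overlapping
100 ms windows shifted by 50 ms; each MVAR observation is one window's
mean envelope. With model order 3 the model memory spans three windows
= 300 ms, which is the only reading consistent with the stated frame
length (three 50 ms shifts would span 150 ms). MVAR coefficients are
ordinary least squares pooled across trials with no lag crossing a
trial boundary (shuffling trial order leaves the fit unchanged, and the
tests assert it). PDC follows the standard column-normalized
definition
$\pi_{ij}(f) = |\bar A_{ij}(f)| / \sqrt{\sum_k |\bar A_{kj}(f)|^2}$
with $\bar A(f) = I - \sum_r A_r e^{-i2\pi f r}$; the normalization
$\sum_i \pi_{ij}^2(f) = 1$ is asserted to $10^{-10}$ on random stable
models and the bivariate closed form to $10^{-6}$. Unsquared $|\pi|$
is used for edge weights; the band mean runs over all normalized
frequencies of the window-rate series, since no frequency range is
meaningful for envelope-domain PDC at a 20 Hz observation rate.

Modeling is *pairwise* (bivariate MVAR per cross-ROI electrode pair,
within patient), despite PDC's multivariate origins — pairwise fits
stay well-conditioned at realistic electrode counts, and a
full-multivariate fit is available through `fitMvar()` directly; edge inference then uses an LME per ordered ROI
pair with a concreteness fixed effect and electrode-pair-in-patient
random intercepts. One decision needed care: raw PDC has a positive
estimation noise floor, so testing the intercept against zero would
declare every edge "present". Edge presence in the overall network is
therefore tested as **net directed flow** — forward minus reverse PDC
within electrode pair, against zero — which matches how such networks
are interpreted (net information flow) and makes structure recovery
falsifiable: on a planted chain the reverse edges must *not* come out
significant, and the tests assert exactly that. The
concreteness-contrast network uses the concreteness $\beta$ directly,
FDR-corrected at $q < 0.05$ across the 42 ordered pairs. Centrality is
the weighted in/out degree; confidence intervals come from 500
bootstrap networks resampled within each inter-ROI connection. Both
the early (200–500 ms) and late (500–800 ms) windows are first-class.

## Behavior and stimulation

Judgement sensitivity is the log diagnostic odds ratio of the
concrete/abstract confusion table, with the Haldane correction (0.5 on
every cell) applied iff any cell is zero, and a Wald CI
($se = \sqrt{1/a + 1/b + 1/c + 1/d}$). "Performing significantly above
chance" is operationalized as the Wald CI excluding zero, since no
specific test is named in the source conventions. Accuracies are
computed over responded trials (the response rate is reported
separately); midscale trials are excluded from accuracy and ln(DOR).

The stimulation analysis is a binomial GLMM,
`correct ~ stim * class + (1 | session)` with sessions nested in
patients — a random intercept per session, so inference pools trials
across sessions while absorbing session-to-session baseline shifts. Class is coded ±1/2 and stimulation 0/1, so the stimulation
coefficient is the log-odds change under stimulation at the average
word class. Complete separation is detected and reported rather than
silently estimated; a single-session table falls back to plain
logistic regression with a warning.

## The synthetic cohort: what it emulates, and what it does not

Per electrode the signal is additive: $1/f^2$ background (SD 20 µV), a
60 Hz line component (5 µV, removed again by the notch — US-style
mains was assumed), and a 70–150 Hz band-limited Gaussian carrier
(SD 15 µV) whose envelope is multiplied, per trial, by a smooth
response profile. The profile is a gamma-density bump (shape 3) with
an ROI-specific onset latency, normalized so its mean over the
canonical 300–700 ms window is 1: a planted multiplicative gain $g$
then reads out *analytically* as window-mean BGA of $100(g-1)$ in that
window, which is what the recovery tests assert (±3 points absorbs
envelope-dilution and smoothing-edge effects). The trial schedule is
1,000 ms word + 1,500 ms fixation; lexica follow large-sample norming
class
moments (concrete 4.55 ± 0.17 on the 1–5 scale, abstract 1.61 ± 0.15,
midscale 3.02 ± 0.26 with inter-rater SD 1.51), with length, Zipf
frequency and syllables drawn class-independently (matched). Behavior
is generated from a planted ln(DOR) (default 2.2, split symmetrically
on the logit scale around a response bias of −0.25, giving class
accuracies near 70% / 79%), a 65% abstract bias on midscale words,
lognormal RTs with class-specific locations near 0.93–0.99 s, and a
98% response rate. Directed coupling, when configured, makes all
electrodes of an ROI share a per-trial VAR envelope modulation at the
20 Hz window rate, which is the structure the PDC stage estimates.

Defaults are desk-scale — 6 patients, 2 electrodes per ROI plus
off-network contacts, 500 Hz — because per-ROI effect sizes are not
available in units reusable as defaults; they are chosen for testability,
not fidelity, and the full 19-patient/2 kHz scale is reachable by
configuration. The generator deliberately omits: biophysical neural
mass or dipole modelling, volume conduction, epileptiform or saccade
artifacts, and any spatial correlation structure beyond the ROI
coupling. Passing tests therefore show that the *analysis chain* is
correct and calibrated under the assumed data-generating process; they
do not show that real cortical data satisfy those assumptions.

## Problem sizes used by the tests

The acceptance checks run at the largest sizes that keep the whole
suite interactive: 20 seeded cohorts for directionality recovery
(6 patients, 7 ROIs, 80 trials per condition), 200 Monte Carlo
repetitions with 200-iteration inner nulls for cluster FWE on the
642-vertex icosphere, the stated 8 patients × 20 electrodes × 150
trials for LME recovery, 200 label shuffles for the permutation-null
mean, 10 simulated patients per midscale regime, 1,000 simulated
confusion tables for Wald coverage, and 20 GLMM recovery runs at
8 sessions × 100 trials. `scripts/acceptance.R` recomputes the same
quantities at comparable sizes from a fresh seed.

## Known limitations

* The vertex LME masks failed fits but keeps variance-zero (singular)
  random-intercept fits; at three-patient coverage, singular fits are
  the norm rather than the exception and masking them would blank the
  map.
* Net-flow edge presence cannot detect symmetric bidirectional
  coupling (it is designed to be null there); the contrast network is
  unaffected.
* The pairwise MVAR inherits the usual transitivity caveat: a planted
  chain A→B→C induces genuine lagged dependence A→C in a bivariate
  model, so "extra" transitive edges in the overall network are
  expected, not errors.
* Wald inference for the LMEs is asymptotic; at very small cohort
  sizes (two patients, few electrodes) its p-values are approximate.
* The synthetic sphere stands in for a cortical surface; geodesics and
  zone sizes are realistic in scale but not in geometry.
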