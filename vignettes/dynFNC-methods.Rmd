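---
title: "Estimating dynamic connectivity states from component time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic connectivity states from component time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynFNC)
```

## The problem

Resting-state fMRI connectivity is usually summarised by a single
correlation matrix per scan. That static view averages over whatever
happens during the scan; dynamic functional network connectivity (dFNC)
instead estimates connectivity on short sliding windows of the
component time courses, clusters the windowed patterns into a small set
of recurring *connectivity states*, and asks how long subjects dwell in
each state, how often they occupy it, and how they move between states.
Those occupancy statistics — not the average connectivity itself — are
often where clinical groups differ.

`dynFNC` implements this pipeline end to end for component time courses
(the per-subject T x C matrices produced by a group spatial ICA, which
is out of scope here): postprocessing, static connectivity with group
contrasts, tapered sliding-window connectivity with an L1-regularised
covariance estimator, L1 k-means state estimation, occupancy statistics
with bootstrap-screened group contrasts, and linear-SVM window
validation and classification. A Markov-switching simulator with known
ground truth stands in for scanner data, so every stage is testable.

## Postprocessing

Component time courses are cleaned in a fixed order, tracked by a stage
flag so no step can run twice or out of order:

1. **Framewise displacement regression.** FD at time t is the sum of
   absolute frame-to-frame changes of the three translations (mm) plus
   the three rotations converted to arc length on a 50 mm sphere;
   the first value is 0. Each component is replaced by its OLS residual
   on `[intercept, FD]`. A constant FD series degenerates to demeaning
   (notice, not error). We use the raw FD series as the single
   covariate — no derivatives or squares.
2. **Linear detrend** per component. Polynomial order is fixed at 1.
3. **Despiking.** Samples deviating from a centred running median
   (window 5 TRs) by more than 4 robust standard deviations
   (1.4826 x MAD of the residual) are replaced by the running-median
   value. The threshold and window are declared, configurable choices;
   despiking conventions vary and ours is intentionally simple and
   testable.
4. **Band-pass.** Fifth-order Butterworth, 0.01–0.15 Hz, applied
   forward and backward (`signal::filtfilt`). Zero-phase filtering is
   chosen so that windowed estimates are not phase-shifted relative to
   state boundaries; series length is preserved and band edges are
   validated against the Nyquist frequency 1/(2 TR).

## Static connectivity

Static FNC is the Pearson correlation of whole component time courses,
Fisher-z transformed (`atanh`). Correlations are clipped to
±(1 − 1e-12) first, so perfectly collinear components map to a large
finite z (about 14) rather than infinity. "z-scored correlation matrix"
is read here as the Fisher transform — the variance-stabilising
convention for group statistics on correlations. Element-wise group
differences use Welch (two-sample) or paired t-tests over the
C(C−1)/2 unique pairs with Benjamini–Hochberg FDR control across the
whole family; the FDR procedure is fixed to BH because only "FDR" is
conventionally specified in this literature.

## Windowed connectivity

A window of width w seconds (grid: 30, 40, 44, 50, 60 s) is a rectangle
of `round(w/TR)` timepoints convolved with a Gaussian of sd 3 TRs,
truncated to the rectangle's support and renormalised. The convolved
rectangle (rather than a bare Gaussian) is the established dFNC taper;
the bare-Gaussian reading of the convention is recovered in the limit
of small width. Windows advance one TR at a time, fully interior, so a
T-volume scan yields T − w/TR + 1 windows.

Each window's taper-weighted sample covariance is rescaled to a
correlation matrix and fed to a graphical LASSO: we minimise
`tr(S Θ) − log det Θ + λ Σ_{i≠j} |Θ_ij|` by blockwise coordinate
descent (compiled code; an independently written R implementation and a
KKT certificate back it in the test suite). The estimate reported per
window is the *covariance of the regularised inverse covariance* —
`Θ^{-1}` rescaled to correlation and Fisher-z transformed. The penalty
stabilises the 45-plus correlations estimated from a few dozen weighted
samples. λ defaults to 0.1 on the correlation scale; it is a fixed
per-run constant because no principled per-study value exists without
cross-validation, which is available to callers by fitting at several λ
and comparing out-of-window likelihoods. At λ = 0 the estimator reduces
exactly to the weighted sample correlation and no inversion is
performed (rank-deficient windows remain representable). A
non-converged fit is retried once at 2λ, then reported as an error
naming the window.

**ALFF-FC.** Connectivity variability per pair is summarised as the sum
of the one-sided Fourier amplitude spectrum of the windowed-correlation
series inside 0.01–0.08 Hz, divided by a normalisation constant. The
convention this follows divides by 0.5 Hz, which is kept as the
default; note that a series sampled once per TR has Nyquist 1/(2 TR) =
0.25 Hz at TR = 2 s, so the literal 0.5 Hz cannot be that series'
largest frequency. Because the intended normalisation is ambiguous, the
constant is configurable (`normConst = "nyquist"` uses 1/(2 TR)); the
choice rescales all subjects equally and therefore never affects
classification or contrasts.

## State estimation

Clustering all windows of all subjects is warm-started from a small
exemplar set: for each subject, the variance across the P connectivity
values of each window is computed, and windows at *strict* local maxima
of this series are kept (endpoints qualify by their single
neighbour; a constant series contributes its earliest maximum-variance
window with a notice). Strictness and one-sided endpoints are declared
choices — the neighbourhood convention for "relative maxima" is not
standardised.

Exemplars are clustered by k-means with L1 (sum of absolute
differences) distance and element-wise *median* centroid updates,
maximum 150 iterations, best of 10 seeded restarts by total L1 inertia.
Inertia is non-increasing across iterations by construction (both the
assignment and the median update minimise it), and an emptied cluster
is reseeded at the point farthest from its current centroid. The final
model then re-clusters *all* windows, warm-started at the exemplar
centroids with no further randomness, so the full stage is a
deterministic function of the data and the exemplar model. For
reporting, states are relabelled by ascending mean centroid
connectivity so "sparse / intermediate / abundant" labels are stable
across runs.

**Choosing k.** For k in 2..8 the exemplar-stage fit yields the ratio
of within-cluster to between-cluster sum of squares (squared Euclidean,
per the criterion's own definition, even though clustering uses L1 —
both conventions are honoured as stated). The selected k maximises the
perpendicular distance to the chord joining the curve's endpoints after
scaling both axes to [0, 1]. A knee is only trusted when the curve
flattens after it: if the largest relative ratio drop after the knee
exceeds 40 % of the largest drop before it, the selection is flagged
low-confidence (structureless data produce smoothly decaying curves
that trip this flag). The 40 % cut-off was fixed by contrasting
well-separated three-cluster data with structureless Gaussian data and
sits between the two regimes with a wide margin.

## Occupancy statistics

Runs of identical window labels define sojourns. Mean dwell time is the
mean sojourn length in windows (seconds = windows x TR; the output
table carries both, since the field reports either). Fraction of time
is the share of windows per state. Transition matrices are
row-normalised counts of consecutive label pairs *including*
self-transitions (the standard dFNC convention; the
probability-of-moving reading is recoverable by renormalising
off-diagonal rows). States a subject never visits get NA dwell — not
zero, which would conflate absence with brevity — and NaN transition
rows, and such subjects are excluded (with counts reported) from that
state's tests.

Group contrasts of state connectivity run element-wise t-tests with BH
FDR on the subjects' per-state median connectivity, then bootstrap the
subjects (resampling with replacement within group, 10,000 resamples in
the full profile) and call a pair *stable* only when it is significant
in at least 95 % of resamples and in the original sample. The bootstrap
unit is the subject: windowed values move with the subject they came
from, so resampling windows independently would understate dependence;
a window-level mode is deliberately not offered as a default.
Transition structure is compared by a chi-square homogeneity test on
the pooled per-group count tables, row by row (origin states never
entered in a group are dropped from both tables, expected counts below
5 are reported). Treatment response is the percent change in
positive-symptom score, `100 (baseline − follow-up) / baseline`,
correlated (Pearson) with each state's dwell and fraction; zero
baselines are excluded and degenerate inputs reported as undefined.

## Window validation and classification

A linear soft-margin SVM (cost fixed at 1; features standardised per
training fold) under leave-one-out cross-validation discriminates the
two contrasted groups from per-subject ALFF-FC maps, separately per
window width; the selected width maximises accuracy, ties resolved
towards 44 s and then the smaller width, and a maximum below 0.6 flags
the selection low-confidence. At every fold, features are screened by a
two-sample t-test on the *training* subjects only (p < 0.05), so the
feature count varies fold to fold; a fold with no surviving features
predicts the training majority. No statistic — screening, mean, sd —
ever sees the held-out subject, and the test suite includes a
chance-level calibration check that would catch leakage. The
permutation test re-runs the entire cross-validation per relabelling
and reports the add-one p-value, which can never be exactly zero.
Sensitivity is reported on the first-listed (control) class;
which class "sensitivity" names is a convention, so it is configurable
by reordering the factor levels.

Final classification compares three feature sets under the same LOOCV
with screening off (the features are already pre-selected): the top
significant static pairs (7 by default), the six occupancy summaries
(three fractions, three dwells), and their union. A subject who never
visited a state has no dwell there; for classification that value is
imputed with the training-fold mean and flagged.

## The synthetic cohort generator

The generator emulates what the analysis assumes: per subject, a
first-order Markov chain over k discrete states (group-specific
transition matrix and initial distribution), observations drawn from a
zero-mean multivariate Gaussian with the current state's correlation
matrix, plus white observation noise, occasional spikes (per timepoint
and component, magnitude five times the observation noise sd, random
sign — something for the despiker to remove), and a six-dimensional
Gaussian random-walk motion trace for the FD machinery. Scans default
to 150 volumes at TR = 2 s. Clinical scores are Gaussian with an
improved follow-up mean (ratios mirroring a roughly halved
positive-symptom scale) so percent-change response is computable; no
claim of clinical realism is made. Sessions of the same cohort share
pair keys and clinical scores, so paired contrasts are well defined.

State templates (`connectivityStateTemplates`) grade off-diagonal mass:
isolated pairs (sparse), a dense single-factor pattern (abundant), and
two blocks (intermediate), all with graded strengths so every state has
a non-constant pattern, and all positive definite by construction.

The generator does **not** simulate hemodynamics, spatial maps, ICA
mixing, scanner drift or autocorrelated motion. Passing tests on these
cohorts demonstrates that the estimators recover the structure they
model — switching covariance regimes — not that any particular clinical
dataset has that structure.

### The recovery benchmark

`recoveryCohortSpec()` fixes the conditions for parameter-recovery
studies: two groups of 20 subjects, C = 10 components, three templates
at strength 0.7, symmetric switching with transition diagonal 0.99
(expected sojourn 100 TRs ≈ 3.3 min), and no observation noise. Window
agreement with the truth is scored against the *modal* generating state
within each window, and the benchmark deliberately uses slowly
switching, well-separated states: when sojourns are comparable to the
window length most windows straddle a transition and carry genuinely
mixed connectivity, so no window-level clusterer can agree with the
modal labelling — at a transition diagonal of 0.95 even an oracle
Euclidean k-means stays near an adjusted Rand index of 0.35. Recovery
under the benchmark shows the estimator chain works; the mixed-window
ceiling is a property of windowing itself and is worth remembering when
interpreting real data with fast dynamics.

## Numerical choices

- Correlations are clipped to ±(1 − 1e-12) before `atanh`.
- Graphical-LASSO convergence: relative change of the working
  covariance below 1e-7 of the mean absolute off-diagonal, 200 sweeps
  maximum; penalty applies to off-diagonal precision entries only.
- k-means ties in assignment go to the lower state label; exemplar
  variance ties to the earlier window.
- All randomness flows through explicit seed arguments (simulation
  seed, clustering seed, bootstrap seed, permutation seed); callers'
  RNG state is saved and restored, and repeated seeded pipeline runs
  are byte-identical.
- Problem sizes in the shipped tests (cohorts of 8–40 subjects, 4–10
  components, bootstrap and permutation counts in the tens to hundreds)
  are chosen so the full suite runs on a laptop; the analysis defaults
  (10,000 bootstrap resamples and permutations) are the full-profile
  values.

## Known limitations

- Only first-order transition structure is summarised; no HMM is fitted
  to the assignments and no soft state membership is available.
- The despike rule, FDR procedure, elbow conventions and bootstrap unit
  are declared interpretations of underdetermined conventions (each is
  documented above); alternatives would change details, not structure.
- The five-cell default cohort's group differences are illustrative,
  not calibrated to any clinical effect size.

## A worked example

```{r example, eval = FALSE}
library(dynFNC)

spec <- recoveryCohortSpec(seed = 1)
cohort <- simulateCohort(spec)

filtered <- lapply(cohort, postprocessSubject)
window <- makeTaperedWindow(44, TR = 2)
wfnc <- lapply(filtered, windowedFNC, window = window, lambda = 0.1)

exemplars <- selectExemplars(wfnc)
elbow <- chooseK(exemplars, kGrid = 2:8, seed = 7)
model <- orderStatesByConnectivity(
  assignAllWindows(wfnc, fitStates(exemplars, elbow@kSelected, seed = 7)))

occ <- occupancyOfModel(model, wfnc)
occupancyContrast(occ[grep("^A", names(occ))], occ[grep("^B", names(occ))])
```

`runPipeline()` chains all stages with one configuration object and
writes every artifact as delimited text; see the README for the
end-to-end call and the output it produces.
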