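---
title: "Methods: intensity-matched comparison of pain and touch BOLD responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intensity-matched comparison of pain and touch BOLD responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isointense)
```

## The scientific problem

Transient painful (laser) and tactile (electrical) stimuli activate largely
the same brain network, and in most of that network the response amplitude
tracks the *perceived* intensity of the stimulus rather than its modality.
Any claim that a region "prefers" pain over touch is therefore confounded
unless perceived intensity is equated between the modalities. `isointense`
implements the full analysis chain for that comparison:

1. **Trial matching** — pair each painful trial with a tactile trial whose
   0–10 intensity rating lies within ±0.5, one-to-one.
2. **Model-based analysis** — first-level GLMs (a five-condition event
   model and a parametric-intensity model), second-level one-sample
   sign-flip permutation tests with voxel-level and cluster-extent FWE
   correction, union and conjunction masks.
3. **Model-free analysis** — region-wise trial-averaged BOLD time courses,
   removal of the rating-period response, and area-under-the-curve (AUC)
   statistics compared with paired sign-flip permutation tests.
4. **Intensity-mismatch analysis** — a pooled median split of ratings with
   count equalization, comparing low-intensity preferred-modality trials
   against high-intensity non-preferred trials.

Because no raw data accompany the design this package emulates, a synthetic
cohort generator is a first-class module: it reproduces the trial structure,
rating distributions and region-specific response structure the analyses
assume, so every stage is testable end to end with known ground truth.

## The emulated study design

Each subject completes 2 sessions of 24 trials. A trial occupies 25 s: a 2-s
lead-in, a 10-s stimulation window containing exactly one brief stimulus at
a uniformly random time, a 3-s gap, and a 10-s rating period. Trials come in
six alternating same-modality blocks of four (two low and two high physical
intensity, randomly ordered); the starting modality alternates across
sessions and subjects. Volumes are acquired at TR = 0.8 s, so a session is
750 scans (600 s). The stimulus-to-rating lag is consequently jittered
between 3 and 13 s.

Ratings are truncated Gaussians on [0, 10], one distribution per
(modality, physical level) cell with observed moments: pain-low 2.76 ± 1.54,
pain-high 5.59 ± 1.51, tactile-low 3.06 ± 1.14, tactile-high 5.65 ± 1.26.
The parent parameters are solved numerically so the *truncated* distribution
attains those moments exactly; with ≥ 10⁴ draws the sample mean of each
cell lands within 3 standard errors of the target.

## The generative model

For every voxel of region $g$, the noiseless signal is a linear
superposition built with the same microtime HRF machinery the design
builder uses:

$$y(t) = \sum_{\text{trials } i} A_{g,i}\, (h_g * u_i)(t)
       + a_r\, (h * b_i)(t) + \text{drift} + \varepsilon(t),$$

where $u_i$ is an impulse at the stimulus onset (for pain, shifted by
`peak_shift_s` and convolved with a `duration_s` boxcar), $b_i$ is the 10-s
rating-period boxcar, $h$ is the canonical double-gamma HRF, and the
amplitude is

$$A_{g,i} = \text{amp}_{\text{modality}(i)}(g)
          + \text{slope}(g)\,\bigl(r_i - 5\bigr).$$

Centring the rating term at the scale midpoint keeps `amp_*` interpretable
as the mid-scale response, decoupling the modality effect from the
intensity slope. A region is pain-preferential iff
`amp_pain > amp_tactile`.

Design choices worth making explicit:

* **Pain's longer, later response** is modelled with two interpretable
  knobs, `peak_shift_s` (default 0.8 s) and `duration_s` (default 1.5 s),
  rather than a different HRF family. They are applied to the
  *pain-preferential* regions, where such dynamics were observed; in
  modality-neutral regions both modalities evoke identical responses, so
  those regions are genuinely null for every downstream comparison — the
  property the recovery tests rely on.
* **Default amplitudes** are 1.0 (preferred) vs 0.5 (non-preferred) and
  0.7/0.7 in neutral regions, with intensity slope 0.12 a.u. per rating
  unit. The rating-period response has a common amplitude (default
  0.5 a.u.) across regions.
* **Noise** is AR(1)-coloured white noise (defaults: SD 1 a.u.,
  ρ = 0.3) plus slow drifts built from the first high-pass DCT basis
  functions with random per-voxel coefficients. Using the filter's own
  basis makes the drifts exactly removable by the 128-s high-pass, which
  turns "filtering leaves condition betas unchanged" into an exact
  invariant rather than an approximation. Motion parameters are smooth
  random walks, generated and stored even though their leak into the
  signal defaults to 0, so the GLM's covariate path is always exercised.
* **Randomness** derives from per-(seed, subject, stage) streams, so the
  same configuration is bitwise reproducible and subjects are independent.
* The generator does **not** emulate physiological noise (cardiac or
  respiratory cycles), susceptibility artifacts, anatomical variability,
  or between-subject amplitude variance (the observed rating moments are
  not decomposed into between- and within-subject parts). Passing
  recovery tests therefore demonstrates correctness of the analysis
  chain under its stated assumptions, not robustness to every property
  of real data.

## Trial matching

For each painful trial in chronological order, candidate tactile trials are
the not-yet-paired ones whose rating lies in the closed interval
$[r - 0.5, r + 0.5]$; the candidate with the smallest absolute rating
difference is selected (ties broken by earliest tactile onset). Matching is
one-to-one: re-using a tactile trial would double-count it in the GLM's
event partition. Greedy order effects are measured, not assumed away: the
test suite compares the greedy pair count against the exact maximum
bipartite matching (an `igraph` oracle) on randomized tables and records
the deficit, which is small because rating intervals overlap heavily. A
tolerance of `1e-9` guards the closed interval against floating-point
wobble.

For the median split, ratings exactly at the pooled median are *dropped*:
the split defines only strictly-higher and strictly-lower groups, and
assigning boundary trials to either side would be arbitrary. Count
equalization removes trials nearest the median from the larger group (ties:
earliest onset first).

## First-level GLMs

Regressors are built at microtime resolution (16 bins per TR, sampled at
bin 8, a middle-slice equivalent) by convolving stimulus impulses
(duration 0 — the stimuli are brief pulses; a config override exists) and
rating boxcars with the canonical double-gamma HRF (peak delay 6 s,
undershoot delay 16 s, dispersions 1, undershoot ratio 1/6, 32-s kernel,
normalized to peak 1). The five-condition model adds temporal derivatives
(finite differences of the kernel, not orthogonalized against their
parents — amplitude contrasts use only the canonical columns), six motion
covariates, DCT drift regressors for periods above 128 s (9 per 600-s
session), and a session mean. The parametric model collapses all stimuli
into one regressor plus a modulator whose impulse heights are the
session-mean-centred ratings; the modulator is *not* additionally
orthogonalized — centring alone makes its coefficient the intensity slope.
Empty conditions (e.g. no unmatched pain trials in a session) drop their
column with a warning and a recorded column map.

Fitting is per-voxel OLS through a QR decomposition, falling back to the
SVD pseudoinverse for rank-deficient designs with `dof = T - rank`.
Contrasts combine sessions by averaging each condition's per-session
columns. No prewhitening is applied: second-level inference is
permutation-based and does not rely on first-level whiteness.

## Permutation inference

The second level is nonparametric throughout. For $n$ subject effect maps,
the one-sample null is generated by whole-subject sign flips (one sign per
subject per permutation, 5000 by default); family-wise error is controlled
by the distribution of the maximum statistic — max $|t|$ (or signed max)
over voxels for voxel-level correction, and max suprathreshold cluster size
for cluster-extent correction with a cluster-defining threshold of
one-tailed $p < 0.001$ (Student-t quantile at $n-1$ dof). P-values use the
$(b+1)/(m+1)$ estimator, which guarantees validity; when $2^n \le$
`n_perm` all flips are enumerated exactly and the estimator becomes
$b/2^n$. The exhaustive path doubles as the oracle for the sampled path in
the tests. Sign flips are drawn without enforcing uniqueness.

Cluster connectivity defaults to 18 (faces + edges), the convention of the
software family this pipeline mirrors, and is configurable (6/26) because
the choice is not universal. The two difference directions (pain > tactile,
tactile > pain) are run as one-tailed tests inside the union of the two
thresholded activation maps, which restricts both the statistic image and
the max-statistic null. Region-wise AUC comparisons use the same machinery
with regions in place of voxels and paired differences in place of maps.

Degenerate inputs are handled explicitly: zero-variance voxels yield
$t = 0$ when the mean is 0 (and ±Inf otherwise), identically zero cohorts
give $p = 1$ everywhere, and fewer than two subjects is an error.

## Time courses, template removal, AUC

Region time courses are the spatial mean over region voxels, sampled at the
volumes nearest stimulus onset + offset for offsets in [−1.6 s, +20 s]
(no temporal interpolation — at TR 0.8 s the grid is fine and interpolation
would bias the AUC). The pre-stimulus samples (2 at default settings)
define the baseline. The 20-s extent covers the hemodynamic return plus
the prolonged pain response; trials whose window leaves the session are
dropped and counted.

The rating act itself (button presses, the visual scale) evokes a response
that overlaps the stimulus response because the stimulus-to-rating lag is
only 3–13 s. The correction exploits the design's fixed 25-s trial period:
the rating-locked average course, taken over one full period, estimates the
periodic rating-response train, and each stimulus-locked sample subtracts
the template at its exact phase relative to that trial's rating onset
(linear interpolation between template samples), after which the course is
re-baselined. Subtracting only within the naive [lag, lag + window] support
would leave the *previous* trial's rating response — which peaks inside the
pre-stimulus baseline — untouched; the periodic-phase formulation removes
it, and on a generator emitting only rating-locked responses the residual
is about 2% of the template peak. The cost is that samples at negative
offsets are corrected too (they must be), and that the phase-smeared
average of the *stimulus* responses enters the template and is subtracted
equally from both conditions — a condition-neutral bias shared with any
average-removal scheme, harmless to paired comparisons.

AUC is the signed trapezoidal integral of the baseline-subtracted course
from offset 0 to the end of the window (negative dips subtract; a rectified
variant is deliberately not the default). By linearity of the trapezoid
rule, the trial-mean of AUCs equals the AUC of the trial-mean course
exactly. Per-timepoint paired t-tests on condition-average courses are
reported uncorrected, as descriptive annotation; inference rests on the
AUC permutation tests. When a paired SEM is exactly zero the statistic is
reported as ±Inf with p = 0, flagged rather than hidden.

## The intensity-mismatch comparison

All of a subject's stimuli are pooled and median-split. For
pain-preferential regions, responses to low-intensity painful stimuli are
compared with responses to high-intensity tactile stimuli (and conversely
for tactile-preferential regions), with counts equalized near the median.
In the generator's linear model the comparison has a closed-form
cancellation point: the modality gap `amp_pref − amp_nonpref` offsets the
slope term `slope × (rating_high − rating_low)`, so with a dominant slope
the preference reverses (the non-preferred high-intensity stimulus wins)
and with slope 0 it can never reverse. Both regimes are asserted in the
acceptance tests.

## Problem sizes used by the tests

The package's own verification runs at desk scale, chosen so the full
suite completes in a few minutes while every statistical property is still
sharply testable: noiseless recovery on a 12³ grid with 2 × 750 scans;
sampled-vs-exhaustive permutation agreement at n = 8 subjects on a 6³
grid; FWER calibration over 200 null replicates (n = 16, 10³ voxels, 500
permutations); modality-preference recovery over 5 replicates of n = 30
subjects with 50 regions; regime behaviour of the mismatch comparison over
10 replicates per regime. The acceptance script re-runs the same
computations from scratch at comparable sizes with a caller-supplied seed.

## Known limitations

* The permutation engine assumes exchangeable, sign-symmetric subject
  effects; it does not implement variance smoothing or TFCE.
* Cluster-extent inference at a sparse cluster-defining threshold is
  discrete and mildly conservative on small grids.
* Random-field-theory corrections, realignment, spatial normalization and
  slice timing are out of scope; synthetic data are generated pre-aligned,
  and spatial smoothing is an optional stage that defaults to off for
  synthetic runs (preprocessing, which the generator bypasses, is where
  smoothing belongs).
* The greedy matcher is order-dependent by construction; the
  maximum-matching comparison quantifies (and bounds) what is lost.
* Whether one tactile trial may serve several painful trials is a genuine
  design ambiguity; the one-to-one choice is flagged for sensitivity
  analysis via the recorded match tables.
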