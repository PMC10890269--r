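---
title: "Recovering FDG plasma input peaks from late blood samples: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering FDG plasma input peaks from late blood samples: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgir)
```

## The problem

Quantitative [18F]FDG PET needs the arterial (or arterialized-venous) plasma
input function \(C_p(t)\) from injection to the end of the scan. The early
bolus peak — roughly the first two to five minutes — carries a large share of
the input integral, and it is exactly the part that venous sampling most
often ruins: a missed, attenuated, or late-started early sampling sequence
leaves a curve whose tail is perfectly usable but whose peak is not. Feeding
such a curve into compartmental modelling inflates the delivery constant
\(K_1\), often beyond what cerebral plasma flow can physically supply, and
biases every downstream quantity.

`fdgir` implements an input-recovery (IR) procedure that reconstructs the
peak from the curve tail (5–100 min) plus population knowledge, and a
validation tool-chain around it: quality classification, irreversible
two-tissue compartment (3k) modelling with a perfusion-derived plausibility
bound on \(K_1\), and the fractional uptake rate (FUR).

## The input model

All input curves are described by the seven-parameter Feng bolus model

\[
C_p(t) = \bigl(A_1 (t-\tau) - A_2 - A_3\bigr) e^{\lambda_1 (t-\tau)}
 + A_2 e^{\lambda_2 (t-\tau)} + A_3 e^{\lambda_3 (t-\tau)},\qquad t>\tau,
\]

zero before the onset delay \(\tau\). \(A_1\) (kBq/mL/min) and \(\lambda_1\)
(fast, about \(-4\)/min) shape the bolus spike; \(\lambda_2\) (about
\(-0.12\)/min) the fast clearance; \(\lambda_3\) (about \(-0.01\)/min) the
slow metabolic tail. Parameters are held in the vector order
\(p_1=\tau, p_2=A_1, p_3=A_2, p_4=A_3, p_5=\lambda_1, p_6=\lambda_2,
p_7=\lambda_3\); the ratio \(p_5/p_2\) (`ratio52`) characterizes the fast
component and appears in one of the recovery constraints.

## Preprocessing

1. **Onset flooring.** The population threshold is the median over curves of
   the first non-zero activity; leading samples below it are set to zero
   (iteratively by default — the single-pass variant is available via
   `iterative = FALSE`, and on realistic onsets the two differ only when
   several successive leading samples sit below the threshold).
2. **Peak detection.** Time of the global maximum; two local maxima within
   10% of each other return their mid-time.
3. **Ascent start.** With at most two samples strictly between the first
   non-zero sample and the peak a straight line is fitted, otherwise a
   quadratic — the lowest order able to represent a convex ascent. The
   latest root before the peak is used, clamped between the last observed
   zero and the first non-zero time.
4. **Peak alignment.** The population delay time UAVt is the upper adjacent
   value of the peak-time distribution (largest observation within
   Q3 + 1.5 IQR, quartiles by the linear-interpolation convention). Earlier
   peaks are delayed to UAVt; the per-curve delay `dt` is stored and removed
   again after recovery, before any kinetic modelling.

## Reference selection and quality classification

Reference-grade curves satisfy three conditions on the peak-aligned curves:
peak-to-tail ratio RT (peak over activity at UAVt + 2.5 min) at or above the
75th percentile of the population RT distribution (read as "the boundary
between the third and fourth quarters"), peak time within 1 min of UAVt, and
an absolute peak of at least 50 kBq/mL.

Every curve is also scored by the linear rule

\[
\mathrm{selection} = -0.36 + 0.038\,\mathrm{maxSUV}
 + 0.052\,\mathrm{peak/5th},
\]

good when the score reaches 0.47 (ties count as good; the rule's
coefficients are fixed constants with config override, not re-estimated
here). SUV is body-weight normalized — activity (kBq/mL) times weight (kg)
over dose (MBq) — and the 5th-minute denominator is interpolated at exactly
5 min.

## The recovery objective

Recovery fits nine parameters — the seven Feng parameters plus two fitted
weights \(p_8, p_9\) — to the curve tail by bounded least squares
(Levenberg–Marquardt with box constraints) over six residual groups:

1. tail misfit, normalized by the per-timepoint population SD of reference
   activities (floored at 1% of the population mean so near-identical
   samples cannot dominate);
2. ridge shrinkage of the parameters toward the population prior mean,
   normalized by the prior SD — magnitude shrinkage without the SD scaling
   would be unit-inconsistent across amplitudes and eigenvalues;
3. model peak activity against \(149.05 + 10943\,(p_5/p_2)\);
4. \(p_2\) against \(6357.91 - 520\,V_{SS}\), where
   \(V_{SS} = \mathrm{dose}\cdot\mathrm{MRT}/\mathrm{AUC}\) is computed from
   the model curve on a 300-min horizon (dose in kBq, AUC in kBq/mL·min, so
   \(V_{SS}\) comes out in mL and is reported in liters — the unit choice
   that makes the regression constants produce positive \(A_1\) at
   physiologic \(V_{SS}\approx\) 10–12 L);
5. model AUC over 2–4 min against \(33.47 + 0.23\,\mathrm{dose}\) (MBq);
6. model-versus-data mean residence time over the tail window.

Terms 1, 2, 5 and 6 carry fixed weights; terms 3 and 4 carry the fitted
weights, squared so the solver cannot exploit negative values and bounded
away from zero. The assignment of the fitted weights was a genuinely open
design choice. Assigning them to the two weakest regressions (terms 4 and 5)
looks natural but fails in practice: a weight that is itself a fitted
parameter is driven to its lower bound whenever its residual is imperfect,
and term 5 is the *only* term that carries per-subject scale information
(injected dose) into the unobserved peak. Silencing it leaves the peak
pinned to the population mean and recovery errors that track the dose
spread. The weights are therefore fitted on the peak-geometry and amplitude
constraints (terms 3 and 4, which the tail plus prior largely determine
anyway) and fixed — and tuned — on the noise, prior, early-AUC and MRT
terms. `tune_weights()` performs the reference-set tuning loop: coordinate
search over multiplicative factors, minimizing the mean absolute percent
difference of maxSUV, AUC and MRT between curves recovered from their tails
and their known full versions.

Numerical choices: the model peak is located by dense-grid search (0.01 min)
over [0, 5] min; \(V_{SS}\) integrals use a 0.25-min grid to 300 min (the
model AUC changes by well under 0.1% beyond that for reference-like
parameters); solver tolerance 1e−10 with at most 150 iterations. Recovered
output splices the model curve before 5 min with the measured tail beyond
(real data is kept where it exists); `splice = FALSE` returns the pure model
curve. Fits that go negative on a dense grid are flagged "unrealistic fit"
rather than silently accepted, mirroring a visual-rejection step.

Two further safeguards matter in cohort use. First, the trusted tail starts
5 min post-injection *on the original clock*: for a curve delayed by `dt`
during alignment, `recover_cohort()` starts the fit at `5 + dt` aligned
minutes, so samples the alignment shifted out of the degradation-prone early
window never masquerade as tail data. Second, the onset delay \(\tau\) is
bounded above near the aligned population onset (prior mean plus four prior
SDs, at least 0.5 min): an unconstrained \(\tau\) can drift toward the tail
start — a spurious late-bolus minimum that satisfies the tail but places the
peak where the constraints no longer see it.

## Kinetic validation

The irreversible two-tissue model with vascular fraction fixed at
\(v_B = 0.05\) is fitted in the \((K_1, K_1/k_2, k_3)\) parameterization;
parameters finishing on a box bound are flagged as saturated. Tissue curves
are simulated analytically: the exponential convolution of the
piecewise-linear input is evaluated by an exact per-segment recursion on a
0.02-min grid and averaged within acquisition frames. The net influx
constant defaults to the canonical \(K_i = K_1 k_3/(k_2+k_3)\); the variant
\(K_1 k_3/(K_1+k_2)\) found in parts of the applied literature is available
behind `derive_ki(..., variant = "printed")` and is never silently
substituted. The vascular term uses plasma activity, acceptable for FDG
where whole-blood and plasma activities are close; a whole-blood variant
would only change \(v_B\)'s interpretation.

Plausibility screening compares fitted \(K_1\) against
\(K_{1,\max} = \mathrm{CBF}\,(1-\mathrm{Htk})\cdot E\) with the extraction
fraction \(E\) fixed at its upper limit of 1; CBF is consumed as a number
(mL/mL/min), never computed from images. FUR — late tissue activity over the
input integral from injection — is evaluated per late frame and averaged,
rather than at a single arbitrary time point.

## What the synthetic cohort emulates — and what it does not

No real cohort ships with the package, so every experiment runs on synthetic
cohorts (`cohort_spec()`, `generate_cohort()`), fully determined by a seed.
The generator emulates:

* Feng-shaped inputs with a sharp peak of roughly 60–130 kBq/mL near 2 min
  and tails of 5–15 kBq/mL by 30 min, on a frequent-sampling schedule
  (10-s early samples, sparse to 100 min);
* the study dose distribution (187 ± 30 MBq, truncated positive), with
  amplitude scale tied to dose the way the early-AUC regression describes
  (affine, normalized to 1 at the mean dose);
* reference means calibrated once so the three printed regression
  constraints are mutually consistent at the cohort mean
  (\(\tau = 1.6\) min, \(A_1 = 851\), \(A_2 = 13.5\), \(A_3 = 12.8\),
  \(\lambda = -4.13, -0.119, -0.0104\); this puts model \(V_{SS}\) near
  10.4 L, predicted \(A_1\) within 10% of the actual value, and predicted
  peak within 3% of the actual peak);
* a homogeneous reference shape (6% log-normal component spread, \(\tau\)
  SD 0.15 min) — reference sets are by construction the most homogeneous
  sub-population, selected for sharp peaks of similar timing;
* near-zero pre-bolus background samples (additive SD 0.11 kBq/mL, making
  the population median of first non-zero activities about 0.074 kBq/mL, and
  occasionally negative values as decay correction produces);
* 2% multiplicative plasma noise; tissue frame noise scaled by
  1/sqrt(frame duration);
* the failure modes that create poor-quality curves: attenuated peaks
  (factor 0.25–0.40), missed early samples (8–14 dropped ascent samples),
  and modestly delayed early sampling (0.2–0.6 min). The attenuation range
  is bounded below so the observed maximum stays in the early window — a
  curve whose largest value sits at the tail edge has no meaningful peak
  time, and feeding such times into the population-delay statistics would
  let gross failures drag the alignment clock late (the Tukey fence is
  meant to exclude them, which it does for the missed-peak mode whose bogus
  maxima are far out). A merely *delayed* peak of full height is not peak
  degradation, and the quality rule correctly keeps such curves;
  classification-agreement checks therefore use the two peak-degrading
  modes.

It does **not** emulate inter-site calibration differences, dispersion or
metabolite effects (irrelevant for FDG), realistic demographic covariance
beyond dose, or image-derived input functions. Passing tests on this cohort
show that the machinery is self-consistent under the stated generative
assumptions, not that any specific clinical cohort would reproduce specific
effect sizes.

## Problem sizes

The test-suite and acceptance experiments use the scales at which the method
is defined: 13-curve reference sets for fit fidelity and recovery fidelity,
100 random physiologic draws for forward–inverse consistency of the 3k
model, and 50 simulated subjects for the \(K_1\)-inflation/plausibility
experiment. These sizes were chosen to match the reference-set size and to
give stable Monte-Carlo estimates.

## Known limitations

* The recovery rests entirely on population structure (prior plus
  regressions) for the unobserved peak; a curve from a population with a
  different bolus geometry needs retrained constants (`recovery_config`
  exposes all of them).
* The regression constraints use raw residuals with tunable weights;
  normalizing by each regression's RMSE would be an equally defensible
  convention and would change only the weight scales.
* The amplitude regression (term 4) is informative only when the population
  \(V_{SS}\) spread is modest; its printed slope makes its predictions
  unreliable for \(V_{SS}\) excursions beyond roughly ±1 L, which is exactly
  why its weight is left to the optimizer.
* FUR is reported unscaled (1/min); conversion to a metabolic rate would
  multiply by plasma glucose over a lumped constant, which is out of scope.
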