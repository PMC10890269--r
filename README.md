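# fdgir — recovery of [18F]FDG plasma input-function peaks from late blood samples

Quantitative FDG-PET kinetic modelling needs the plasma input function
C<sub>p</sub>(t) from injection to the end of the scan. In practice the early
bolus peak (0–5 min) is the fragile part: venous or arterialized sampling
that starts late, misses samples, or under-measures the first minutes leaves
a curve whose 5–100 min tail is fine but whose peak is unusable. Fitting the
two-tissue compartment model with such an input inflates the delivery
constant K<sub>1</sub> — often beyond the perfusion limit
K<sub>1,max</sub> = CBF·(1 − Htk) — and biases every downstream estimate.

`fdgir` is an R toolkit for **input recovery (IR)**: it reconstructs the
early peak of a poor-quality input from its tail, using the seven-parameter
Feng bolus model

> C<sub>p</sub>(t) = (A₁(t−τ) − A₂ − A₃)·e^{λ₁(t−τ)} + A₂·e^{λ₂(t−τ)} + A₃·e^{λ₃(t−τ)},  t > τ

fitted under a penalized least-squares objective that combines six terms:
the tail misfit (normalized by the population SD), ridge shrinkage toward a
population prior built from reference-grade curves, three population
regression constraints — peak activity vs λ₁/A₁, A₁ vs the steady-state
distribution volume V<sub>SS</sub> = Dose·MRT/AUC, and the 2–4 min AUC vs
injected dose — and a mean-residence-time match on the tail. Two of the six
weights are fitted alongside the Feng parameters (nine fitted parameters in
total). Around the recovery sit the supporting stages: onset flooring, peak
detection and population peak alignment (UAV of the peak-time
distribution), reference selection (RT ratio, peak-time window, 50 kBq/mL
peak floor), a linear good/poor quality rule
(−0.36 + 0.038·maxSUV + 0.052·peak/5th, cutoff 0.47), irreversible 2TCM
fitting with v<sub>B</sub> = 0.05 and K<sub>1,max</sub> screening, FUR, a
fully seeded synthetic-cohort simulator, and paired-comparison reporting
(Cohen's d, Bonferroni-corrected paired t). See the methods vignette
(`vignettes/input-recovery-methods.Rmd`) for the model details and design
rationale.

## Worked example

```r
library(fdgir)

# a synthetic cohort: 20 subjects, 70% with degraded early peaks
spec <- cohort_spec(n_subjects = 20, seed = 42)
cohort <- generate_cohort(spec)
#> <cohort> 20 subjects (14 degraded), seed 42, spec 70d88658

# preprocess: floor noisy onsets, align peaks to the population delay time
fl <- floor_low_onsets(cohort$inputs)
al <- align_peaks(fl$curves)
al$alignment
#> <peak_alignment> UAVt = 2.27 min, 20 curves, delays 0-0.602 min

# classify curve quality and build the population prior from the good ones
qc <- qc_report(al$curves, cohort$metas, al$alignment)
table(qc$label)
#> good poor
#>    9   11
fits <- lapply(al$curves[qc$label == "good"], fit_feng_full)
prior <- build_population_prior(fits, al$curves[qc$label == "good"])
#> <population_prior> n = 9 reference fits, grid [0, 100] min
#> <feng_params> tau 2 | A1 865.8 A2 13.65 A3 13.12 | l1 -4.144 l2 -0.1209 l3 -0.01031

# recover every poor curve from its tail, restoring per-curve delays
config <- recovery_config(prior)
rec <- recover_cohort(al$curves, qc$label == "poor", al$alignment, config,
                      metas = cohort$metas)
i <- which(qc$label == "poor")[1]
rec$results[[i]]
#> <recovery_result> ok | tail RMS 1.81% | p8 0.1 p9 0.1
#> <feng_params> tau 2.03 | A1 739.2 A2 14.52 A3 12.84 | l1 -4.338 l2 -0.1077 l3 -0.01082

c(degraded = max(al$curves[[i]]$activities),
  recovered = max(rec$curves[[i]]$activities),
  truth = max(cohort$true_inputs[[i]]$activities))
#>  degraded recovered     truth
#>  35.61315  80.30379  90.96135
```

The degraded curve's peak (35.6 kBq/mL) is restored to 80.3 kBq/mL against
a ground truth of 91.0 — the tail alone plus population structure brings the
peak back to within ~12%. The kinetic consequence is what matters:

```r
tissue <- cohort$tissues[[i]]
before <- restore_delay(al$curves[[i]], al$alignment$delays[i])
fit_deg <- fit_2tcm(tissue, before)
fit_rec <- fit_2tcm(tissue, rec$curves[[i]])
bound <- k1max(cohort$metas[[i]]$cbf, cohort$metas[[i]]$hematocrit)
round(c(k1_degraded = fit_deg$k1, k1_recovered = fit_rec$k1,
        k1_true = cohort$true_kinetics[[i]]$k1, k1max = bound$k1max), 4)
#>  k1_degraded k1_recovered      k1_true        k1max
#>       0.4465       0.0899       0.0797       0.2652
```

With the degraded input, fitted K<sub>1</sub> = 0.45 mL/mL/min — far above
the perfusion bound of 0.27 and 5.6× the true 0.08. With the recovered
input it returns to 0.09, physiologically plausible and within 13% of
truth.

A thin command-line front end over the same functions lives at
`inst/cli/fdgir.R` (`simulate`, `qc`, `kinetics`, `pipeline` subcommands),
and `run_pipeline()` executes the whole chain — simulation, preprocessing,
selection, prior, recovery, kinetics, FUR, reports — writing every
intermediate as delimited text.

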