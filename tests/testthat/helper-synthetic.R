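# Shared synthetic fixtures, built in code. The reference bundle (13 curves,
# whole-curve fits, prior, config) is expensive enough to cache per session.

.fixture_cache <- new.env(parent = emptyenv())

ref_bundle <- function(seed = 42, n = 13) {
  key <- sprintf("ref_%d_%d", seed, n)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- cohort_spec(n_subjects = n, seed = seed, degrade_frac = 0)
  subj <- lapply(seq_len(n), function(i) generate_input(spec, i))
  curves <- lapply(subj, `[[`, "curve")
  metas <- lapply(subj, `[[`, "meta")
  fl <- floor_low_onsets(curves)
  al <- align_peaks(fl$curves)
  fits <- lapply(al$curves, fit_feng_full)
  prior <- build_population_prior(fits, al$curves)
  out <- list(spec = spec, subjects = subj, curves = curves, metas = metas,
              aligned = al$curves, alignment = al$alignment,
              fits = fits, prior = prior,
              config = recovery_config(prior))
  .fixture_cache[[key]] <- out
  out
}

# a clean analytic test curve: known Feng parameters on a frequent schedule
ref_feng <- function() {
  feng_params(tau = 1.6, a1 = 851, a2 = 13.5, a3 = 12.8,
              l1 = -4.13, l2 = -0.119, l3 = -0.0104)
}

ref_curve <- function(params = ref_feng(), times = default_schedule(),
                      meta = NULL) {
  tac(times, feng_eval(params, times), label = "plasma", meta = meta)
}

tac_interp_for_test <- function(curve, t) {
  approx(curve$times, curve$activities, xout = t, yleft = 0,
         yright = curve$activities[length(curve$activities)])$y
}

restrict_tail_for_test <- function(curve, start = 5) {
  keep <- curve$times >= start
  tac(curve$times[keep], curve$activities[keep], label = curve$label,
      meta = curve$meta)
}

ref_meta <- function(dose = 187, weight = 75, htk = 0.43, cbf = 0.55) {
  subject_meta("T001", dose = dose, weight = weight, hematocrit = htk,
               cbf = cbf)
}
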