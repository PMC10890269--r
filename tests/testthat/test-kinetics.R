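test_that("2TCM limits: no delivery, pure vascular, equilibrium ratio", {
  meta <- ref_meta()
  inp <- ref_curve(meta = meta)
  # K1 = 0 -> tissue is exactly the vascular term
  sim0 <- simulate_2tcm(inp, kinetic_params(0, 0.1, 0.05), c(1, 5, 20, 60))
  expect_equal(sim0$activities, 0.05 * tac_interp_for_test(inp, c(1, 5, 20, 60)),
               tolerance = 1e-9)

  # k3 = 0 with constant input: late tissue/plasma -> (1-vb)K1/k2 + vb
  const <- tac(seq(0, 300, by = 1), rep(10, 301))
  k1 <- 0.1; k2 <- 0.2
  sim <- simulate_2tcm(const, kinetic_params(k1, k2, 0), c(200, 225, 250))
  expect_equal(sim$activities[3] / 10, (1 - 0.05) * k1 / k2 + 0.05,
               tolerance = 1e-3)
})

test_that("analytic convolution matches an independent stiff ODE solution", {
  skip_if_not_installed("deSolve")
  inp <- ref_curve()
  kin <- kinetic_params(k1 = 0.08, k2 = 0.15, k3 = 0.05)
  cpf <- approxfun(inp$times, inp$activities, yleft = 0, rule = 2)
  rhs <- function(t, y, p)
    list(c(p$k1 * cpf(t) - (p$k2 + p$k3) * y[1], p$k3 * y[1]))
  tt <- seq(0, 100, by = 0.5)
  sol <- deSolve::lsoda(c(0, 0), tt, rhs,
                        list(k1 = 0.08, k2 = 0.15, k3 = 0.05),
                        rtol = 1e-10, atol = 1e-10)
  ct_ode <- (1 - 0.05) * (sol[, 2] + sol[, 3]) + 0.05 * cpf(tt)
  sim <- simulate_2tcm(inp, kin, tt)
  # compare past the onset, where the signal is non-trivial; relative
  # differences on near-zero pre-bolus values are ill-conditioned
  sel <- tt >= 3
  rel <- abs(sim$activities[sel] - ct_ode[sel]) / ct_ode[sel]
  expect_lt(max(rel), 1e-3)
})

test_that("noiseless tissue fits recover the rate constants", {
  inp <- ref_curve()
  truth <- kinetic_params(k1 = 0.08, k2 = 0.15, k3 = 0.05)
  tis <- simulate_2tcm(inp, truth, default_frames())
  fit <- fit_2tcm(tis, inp)
  expect_true(fit$converged)
  expect_lt(abs(fit$k1 - 0.08) / 0.08, 0.01)
  expect_lt(abs(fit$k2 - 0.15) / 0.15, 0.01)
  expect_lt(abs(fit$k3 - 0.05) / 0.05, 0.01)
  expect_equal(fit$vb, 0.05)

  # K1 = 0 tissue drives the fitted K1 to its lower bound
  tis0 <- simulate_2tcm(inp, kinetic_params(0, 0.1, 0.02), default_frames())
  fit0 <- fit_2tcm(tis0, inp)
  expect_lt(fit0$k1, 1e-4)
  expect_true(fit0$at_bound[["k1"]])

  # multi-start: perturbed initializations converge to the same optimum
  for (f in c(0.5, 0.8, 1.5, 2)) {
    fi <- fit_2tcm(tis, inp, init = c(k1 = 0.1 * f, v1 = 0.7 * f,
                                      k3 = 0.05 * f))
    expect_equal(fi$k1, fit$k1, tolerance = 1e-4)
    expect_equal(fi$k3, fit$k3, tolerance = 1e-3)
  }
})

test_that("Ki arithmetic: canonical and printed variants", {
  expect_equal(derive_ki(0.1, 0.2, 0.05), 0.02)
  expect_equal(derive_ki(0.1, 0.2, 0), 0)            # no trapping
  expect_equal(derive_ki(0.1, 0, 0.05), 0.1)         # all delivered trapped
  expect_equal(derive_ki(0.1, 0.2, 0.05, variant = "printed"),
               0.1 * 0.05 / (0.1 + 0.2))
  expect_error(derive_ki(0.1, 0, 0), "denominator")
  # Ki <= K1 and monotone in k3
  set.seed(5)
  for (i in 1:20) {
    k1 <- runif(1, 0.01, 0.3); k2 <- runif(1, 0.01, 0.5)
    k3 <- runif(1, 0, 0.3)
    expect_lte(derive_ki(k1, k2, k3), k1)
    expect_gt(derive_ki(k1, k2, k3 + 0.01), derive_ki(k1, k2, k3))
  }
})

test_that("perfusion bound: CPF = CBF(1 - Htk), extraction fixed at 1", {
  pc <- k1max(0.5, 0.4)
  expect_equal(pc$cpf, 0.30)
  expect_equal(pc$k1max, 0.30)
  expect_equal(pc$extraction, 1)
  # k1max approaches cbf as hematocrit vanishes
  expect_equal(k1max(0.5, 1e-9)$k1max, 0.5, tolerance = 1e-6)
  expect_error(k1max(0.5, 1.2), "hematocrit")
  expect_error(k1max(-1, 0.4), "cbf")
})

test_that("plausibility screen counts exceedances per ROI and subject", {
  fits <- data.frame(subject = rep(c("a", "b"), each = 4),
                     roi = rep(c("fr", "te", "pa", "oc"), 2),
                     k1 = c(0.35, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  cons <- data.frame(subject = c("a", "b"), k1max = c(0.3, 0.3))
  scr <- plausibility_screen(fits, cons)
  expect_equal(scr$subjects_exceeding, 1)     # subject a counted once
  expect_equal(sum(scr$by_roi$exceeds), 1)
  expect_equal(scr$n_subjects, 2)

  # all below the bound -> zero everywhere
  fits$k1 <- 0.05
  scr0 <- plausibility_screen(fits, cons)
  expect_equal(scr0$subjects_exceeding, 0)

  # before/after layout
  scr2 <- plausibility_screen(
    transform(fits, k1 = 0.5), cons, fits_after = fits)
  expect_equal(scr2$subjects_exceeding, 2)
  expect_equal(scr2$subjects_exceeding_after, 0)
  expect_true(all(scr2$by_roi$exceeds_after == 0))
})

test_that("FUR: direct ratio, scale behavior, correlation with Ki", {
  # constant tissue c over frames, input AUC(0,T) = A -> FUR = c/A
  inp <- tac(seq(0, 100, by = 1), rep(2, 101))
  tis <- tac(c(60, 70, 80), c(6, 6, 6), label = "tissue")
  fr <- compute_fur(tis, inp)
  expect_equal(fr$per_frame, 6 / (2 * c(60, 70, 80)))
  # doubling the input halves FUR
  inp2 <- tac(inp$times, inp$activities * 2)
  expect_equal(compute_fur(tis, inp2)$fur, fr$fur / 2)
  # joint rescaling leaves FUR unchanged
  tis2 <- tac(tis$times, tis$activities * 2, label = "tissue")
  expect_equal(compute_fur(tis2, inp2)$fur, fr$fur)
  expect_error(compute_fur(tac(c(60, 70, 120), c(1, 1, 1), label = "tissue"),
                           inp), "cover")

  # rank correlation with true Ki across a small cohort
  spec <- cohort_spec(n_subjects = 15, seed = 3)
  furs <- kis <- numeric(15)
  for (i in 1:15) {
    s <- generate_input(spec, i, noiseless = TRUE)
    t2 <- simulate_2tcm(s$curve, s$kinetics, late_frames())
    furs[i] <- compute_fur(t2, s$curve)$fur
    kis[i] <- s$kinetics$ki
  }
  expect_gt(cor(furs, kis, method = "spearman"), 0.9)
})

test_that("attenuating the input peak inflates fitted K1", {
  spec <- cohort_spec(n_subjects = 6, seed = 11)
  for (i in 1:4) {
    s <- generate_input(spec, i, noiseless = TRUE)
    tis <- simulate_2tcm(s$curve, s$kinetics, default_frames())
    k1s <- vapply(c(1, 0.7, 0.5), function(f) {
      fit_2tcm(tis, degrade_input(s$curve, "attenuate", f = f))$k1
    }, 0)
    expect_lt(abs(k1s[1] - s$kinetics$k1) / s$kinetics$k1, 0.02)
    expect_true(all(diff(k1s) > 0))   # monotone in the attenuation depth
  }
})
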