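test_that("objective terms vanish for a perfect prior-mean fit", {
  b <- ref_bundle()
  cfg <- b$config
  mu <- b$prior$mean_params
  # tail sampled on the same grid the model MRT uses, so the data and model
  # quadratures coincide exactly
  tt <- seq(5, 100, by = 0.25)
  tail <- tac(tt, feng_eval(mu, tt), meta = ref_meta())
  theta <- c(feng_vector(mu), 1, 1)
  r <- ir_objective(theta, tail, ref_meta(), cfg)
  expect_lt(max(abs(r[startsWith(names(r), "noise")])), 1e-9)
  expect_lt(max(abs(r[startsWith(names(r), "param")])), 1e-9)
  expect_lt(abs(r[["mrt"]]), 1e-9)
})

test_that("objective residuals are linear in their weights", {
  b <- ref_bundle()
  tail <- restrict_tail_for_test(b$aligned[[1]])
  theta <- c(feng_vector(b$prior$mean_params), 1, 1)
  r1 <- ir_objective(theta, tail, b$metas[[1]], b$config)
  cfg2 <- b$config; cfg2$w_mrt <- 2 * b$config$w_mrt
  r2 <- ir_objective(theta, tail, b$metas[[1]], cfg2)
  expect_equal(r2[["mrt"]], 2 * r1[["mrt"]])
  # fitted weights enter squared
  theta2 <- theta; theta2[8] <- 2
  r3 <- ir_objective(theta2, tail, b$metas[[1]], b$config)
  expect_equal(r3[["maxpa"]], 4 * r1[["maxpa"]])
})

test_that("peak constraint arithmetic follows the published regression", {
  b <- ref_bundle()
  tail <- restrict_tail_for_test(b$aligned[[1]])
  # ratio52 = -4/800 = -0.005 -> prediction 149.05 + 10943*(-0.005) = 94.335
  p <- feng_params(tau = 1.6, a1 = 800, a2 = 13.5, a3 = 12.8,
                   l1 = -4, l2 = -0.119, l3 = -0.0104)
  theta <- c(feng_vector(p), 1, 1)
  r <- ir_objective(theta, tail, b$metas[[1]], b$config)
  g <- seq(0, 5, by = b$config$peak_step)
  maxpa_model <- max(feng_eval(p, g))
  expect_equal(149.05 + 10943 * (-0.005), 94.335)
  expect_equal(unname(r[["maxpa"]]), maxpa_model - 94.335, tolerance = 1e-9)
})

test_that("a noiseless reference-like tail recovers the true peak within 5%", {
  b <- ref_bundle()
  truth <- ref_feng()
  meta <- ref_meta()
  cv <- ref_curve(truth, meta = meta)
  res <- recover_input(cv, meta, b$config, splice = FALSE)
  expect_true(res$diagnostics$converged)
  perf <- recovery_performance(res, cv, meta)
  expect_lt(perf[["maxsuv_pct"]], 5)
  expect_lt(perf[["auc_pct"]], 5)
  expect_lt(perf[["mrt_pct"]], 5)
  # the recovered tail tracks the measured tail
  expect_lt(res$diagnostics$tail_rms_rel, 0.05)
})

test_that("recovery is deterministic and splices measured tails by default", {
  b <- ref_bundle()
  cv <- b$aligned[[2]]; meta <- b$metas[[2]]
  r1 <- recover_input(cv, meta, b$config)
  r2 <- recover_input(cv, meta, b$config)
  expect_identical(feng_vector(r1$params), feng_vector(r2$params))
  expect_identical(r1$recovered_curve$activities, r2$recovered_curve$activities)
  # spliced output keeps the original measured samples beyond the tail start
  keep <- cv$times >= 5
  tail_times <- cv$times[keep]
  rec_tail <- r1$recovered_curve$activities[
    match(tail_times, r1$recovered_curve$times)]
  expect_identical(rec_tail, cv$activities[keep])
  expect_true(all(r1$recovered_curve$activities >= 0))
  # too-short tails are refused
  short <- tac(c(5, 20, 40), c(10, 6, 4))
  expect_error(recover_input(short, meta, b$config), "60")
})

test_that("weight tuning never worsens the reference-set score", {
  b <- ref_bundle()
  cfg0 <- b$config
  eval_cfg <- function(cfg) {
    perfs <- mapply(function(cv, m) {
      res <- recover_input(cv, m, cfg, splice = FALSE)
      mean(recovery_performance(res, cv, m))
    }, b$aligned[1:6], b$metas[1:6])
    mean(perfs)
  }
  cfg1 <- suppressWarnings(
    tune_weights(b$aligned[1:6], cfg0, metas = b$metas[1:6],
                 which = "w_auc24", candidates = c(0.5, 1, 2), passes = 1))
  expect_lte(attr(cfg1, "achieved"), eval_cfg(cfg0) + 1e-9)
  # the reported score equals an independent re-evaluation of the tuned config
  expect_equal(attr(cfg1, "achieved"), eval_cfg(cfg1), tolerance = 1e-9)
})

test_that("cohort recovery touches only poor curves and restores time grids", {
  b <- ref_bundle()
  n <- length(b$aligned)
  labels <- rep("good", n)
  out <- recover_cohort(b$aligned, labels, b$alignment, b$config,
                        metas = b$metas)
  expect_identical(out$curves, b$aligned)
  expect_true(all(out$diagnostics$flag == "passthrough"))

  labels[c(2, 5)] <- "poor"
  out2 <- recover_cohort(b$aligned, labels, b$alignment, b$config,
                         metas = b$metas)
  expect_equal(sum(!vapply(out2$results, is.null, TRUE)), 2L)
  # recovered curves are back on the original (pre-alignment) time base:
  # every original tail sample time reappears in the restored curve
  for (i in c(2, 5)) {
    rec <- out2$curves[[i]]
    expect_equal(max(rec$times), max(b$curves[[i]]$times), tolerance = 1e-9)
    tail_orig <- b$curves[[i]]$times[b$curves[[i]]$times >= 5]
    nearest <- vapply(tail_orig, function(t) min(abs(rec$times - t)), 0)
    expect_lt(max(nearest), 1e-9)
  }
  expect_identical(out2$curves[[1]], b$aligned[[1]])
})

test_that("recovery raises degraded peaks", {
  b <- ref_bundle()
  raised <- 0L
  idx <- 1:8
  for (i in idx) {
    deg <- degrade_input(b$curves[[i]], "attenuate", f = 0.3)
    res <- recover_input(deg, b$metas[[i]], b$config, splice = FALSE)
    rec_max <- max(res$recovered_curve$activities)
    if (rec_max > max(deg$activities)) raised <- raised + 1L
  }
  expect_gte(raised, length(idx) - 1L)
})
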