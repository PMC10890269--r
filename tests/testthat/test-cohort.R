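test_that("generation is fully determined by the seed", {
  spec <- cohort_spec(n_subjects = 5, seed = 9)
  a <- generate_input(spec, 3)
  b <- generate_input(spec, 3)
  expect_identical(a$curve$activities, b$curve$activities)
  expect_identical(feng_vector(a$params), feng_vector(b$params))
  expect_identical(a$meta$dose, b$meta$dose)
  # different subjects differ
  expect_false(identical(a$curve$activities,
                         generate_input(spec, 4)$curve$activities))
  # noiseless draws equal the model evaluated on the schedule
  nl <- generate_input(spec, 3, noiseless = TRUE)
  expect_identical(nl$curve$activities, feng_eval(nl$params, spec$schedule))
})

test_that("reference-like draws look like reference curves", {
  spec <- cohort_spec(n_subjects = 40, seed = 23, degrade_frac = 0)
  peaks <- ptimes <- numeric(40)
  for (i in 1:40) {
    s <- generate_input(spec, i, noiseless = TRUE)
    peaks[i] <- max(s$curve$activities)
    ptimes[i] <- find_peak_time(s$curve)
  }
  expect_gte(mean(peaks >= 50), 0.95)
  expect_gte(mean(ptimes <= 3), 0.95)
})

test_that("degradation modes behave as specified on the windows they touch", {
  spec <- cohort_spec(n_subjects = 2, seed = 4)
  cv <- generate_input(spec, 1, noiseless = TRUE)$curve

  # attenuate(1) is the identity
  expect_identical(degrade_input(cv, "attenuate", f = 1)$activities,
                   cv$activities)
  # attenuate(0.5) halves the peak, leaves AUC(5, 100) untouched
  half <- degrade_input(cv, "attenuate", f = 0.5)
  expect_equal(max(half$activities), max(cv$activities) / 2)
  expect_equal(trapezoid_auc(half, 5, 100), trapezoid_auc(cv, 5, 100))

  # drop_early removes ascent samples but not the tail
  drop <- degrade_input(cv, "drop_early", k = 6)
  expect_equal(length(drop$times), length(cv$times) - 6)
  expect_lt(max(drop$activities), max(cv$activities))
  expect_equal(trapezoid_auc(drop, 5, 100), trapezoid_auc(cv, 5, 100))

  # delay shifts early samples late, keeps times strictly increasing
  del <- degrade_input(cv, "delay", d = 1)
  expect_true(all(diff(del$times) > 0))
  expect_equal(find_peak_time(del), find_peak_time(cv) + 1, tolerance = 0.2)

  expect_error(degrade_input(cv, "smear"), "unknown")
})

test_that("degraded curves score poor under the selection rule", {
  spec <- cohort_spec(n_subjects = 20, seed = 29)
  n_poor <- 0L
  for (i in 1:20) {
    s <- generate_input(spec, i)
    deg <- degrade_input(s$curve, "attenuate", f = 0.35)
    n_poor <- n_poor + (quality_score(deg, s$meta)$label == "poor")
  }
  expect_gte(n_poor / 20, 0.9)
})

test_that("tissue simulation with zero noise matches the forward model", {
  spec <- cohort_spec(n_subjects = 2, seed = 13)
  s <- generate_input(spec, 1, noiseless = TRUE)
  gt <- generate_tissue(s$curve, s$kinetics, noise_sd = 0)
  direct <- simulate_2tcm(s$curve, s$kinetics, default_frames())
  expect_identical(gt$tissue$activities, direct$activities)
  # seeded noise is reproducible
  g1 <- generate_tissue(s$curve, s$kinetics, noise_sd = 0.03, seed = 5)
  g2 <- generate_tissue(s$curve, s$kinetics, noise_sd = 0.03, seed = 5)
  expect_identical(g1$tissue$activities, g2$tissue$activities)
})

test_that("cohort bundles are complete, hashed, and byte-reproducible", {
  spec <- cohort_spec(n_subjects = 8, seed = 17)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  coh1 <- generate_cohort(spec, out_dir = d1)
  coh2 <- generate_cohort(spec, out_dir = d2)
  expect_length(coh1$inputs, 8)
  expect_equal(length(list.files(d1, pattern = "plasma")), 8)
  expect_true(file.exists(file.path(d1, "manifest.tsv")))

  # regeneration is byte-identical
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # the spec hash changes iff the spec changes
  h1 <- attr(coh1$manifest, "spec_hash")
  expect_identical(h1, attr(coh2$manifest, "spec_hash"))
  coh3 <- generate_cohort(cohort_spec(n_subjects = 8, seed = 18),
                          tissue = FALSE)
  expect_false(identical(h1, attr(coh3$manifest, "spec_hash")))

  # cohort TAC files round-trip through the readers
  back <- read_tac(f1[grepl("S001_plasma", f1)])
  expect_equal(back$activities, coh1$inputs[["S001"]]$activities)
})
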