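test_that("tac constructor enforces its invariants", {
  expect_s3_class(tac(0:2, c(0, 10, 5)), "tac")
  expect_error(tac(c(0, 1, 1), c(0, 1, 2)), "strictly increasing")
  expect_error(tac(c(0, 2, 1), c(0, 1, 2)), "strictly increasing")
  expect_error(tac(0:1, 0:1), "at least 3")
  expect_error(tac(0:2, c(0, NA, 1)), "finite")
})

test_that("TAC files round-trip losslessly and unit headers convert", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  cv <- tac(c(0, 1.25, 2.7, 10), c(0, 10.123456789012345, 5.5, 0.1))
  write_tac(cv, tmp)
  back <- read_tac(tmp)
  expect_identical(back$times, cv$times)
  expect_identical(back$activities, cv$activities)

  # two writes of the same curve are byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_tac(cv, tmp2)
  expect_identical(unname(tools::md5sum(tmp)), unname(tools::md5sum(tmp2)))

  # seconds and Bq/cc are converted to minutes and kBq/mL
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# time[s], Bq/cc", "0,0", "60,10000", "120,5000"), tmp3)
  cv3 <- read_tac(tmp3)
  expect_equal(cv3$times, c(0, 1, 2))
  expect_equal(cv3$activities, c(0, 10, 5))

  # unknown units are a hard error naming the offending token
  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# time[h], kBq/mL", "0,0", "1,1", "2,2"), tmp4)
  expect_error(read_tac(tmp4), "time\\[h\\]")

  # non-monotonic data is rejected at parse time
  tmp5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0", "2,1", "1,2"), tmp5)
  expect_error(read_tac(tmp5), "strictly increasing")
})

test_that("round trip is lossless over random curves", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  set.seed(101)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    cv <- tac(sort(runif(n, 0, 100)) + seq_len(n) * 1e-6,
              rexp(n, 1 / 20))
    write_tac(cv, tmp)
    back <- read_tac(tmp)
    expect_identical(back$times, cv$times)
    expect_identical(back$activities, cv$activities)
  }
})

test_that("multi-ROI tissue files read into one curve per column", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# time[min]\tkBq/mL\ttissue",
               "time\tfrontal\tparietal",
               "0\t0\t0", "1\t2\t3", "2\t4\t6"), tmp)
  rois <- read_tacs(tmp)
  expect_named(rois, c("frontal", "parietal"))
  expect_equal(rois$parietal$activities, c(0, 3, 6))
  expect_equal(rois$frontal$label, "tissue")
})

test_that("SUV conversion is body-weight normalized", {
  meta <- subject_meta("s", dose = 187, weight = 1, hematocrit = 0.4)
  cv <- tac(c(0, 1, 2), c(0, 187, 93.5))
  suv <- to_suv(cv, meta)
  expect_equal(suv$activities, c(0, 1, 0.5))

  z <- to_suv(tac(0:2, c(0, 0, 0)), meta)
  expect_equal(z$activities, rep(0, 3))

  # maxSUV of a synthetic curve matches hand arithmetic
  meta2 <- subject_meta("s2", dose = 150, weight = 80, hematocrit = 0.4)
  cv2 <- ref_curve(meta = meta2)
  expect_equal(max(to_suv(cv2, meta2)$activities),
               max(cv2$activities) * 80 / 150)
  expect_error(to_suv(cv2, NULL), "dose")
})

test_that("trapezoid AUC matches hand values and closed forms", {
  cv <- tac(c(0, 1, 2), c(0, 2, 2))
  expect_equal(trapezoid_auc(cv, 0, 2), 3)          # triangle + rectangle
  const <- tac(c(0, 5, 10), c(4, 4, 4))
  expect_equal(trapezoid_auc(const, 1, 9), 4 * 8)   # c * (t1 - t0)
  # dense mono-exponential against the closed form (1 - e^{-k t1})/k
  k <- 0.3
  tt <- seq(0, 20, by = 0.01)
  mono <- tac(tt, exp(-k * tt))
  expect_lt(abs(trapezoid_auc(mono, 0, 10) - (1 - exp(-k * 10)) / k) /
              ((1 - exp(-k * 10)) / k), 1e-3)
  expect_error(trapezoid_auc(cv, 5, 10), "outside")
  expect_error(trapezoid_auc(cv, 2, 1), "t0 < t1")
})

test_that("AUC is additive over adjacent windows", {
  set.seed(7)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    cv <- tac(sort(runif(n, 0, 60)) + seq_len(n) * 1e-9, rexp(n))
    a <- runif(1, min(cv$times), max(cv$times) - 2)
    c_ <- runif(1, a + 1, max(cv$times))
    b <- runif(1, a, c_)
    whole <- trapezoid_auc(cv, a, c_)
    parts <- trapezoid_auc(cv, a, b) + trapezoid_auc(cv, b, c_)
    expect_lt(abs(whole - parts) / abs(whole), 1e-9)
  }
})

test_that("curve metrics: MRT, VSS and scale invariance", {
  tt <- seq(0, 50, by = 0.01)
  cv <- tac(tt, exp(-tt))
  m <- curve_metrics(cv)
  expect_equal(m$mrt, 1, tolerance = 1e-3)  # exponential residence = 1/k

  # VSS arithmetic: dose 187 MBq, mrt 40 min, auc 600 -> 12.4667 L
  meta <- subject_meta("s", dose = 187, weight = 75, hematocrit = 0.4)
  expect_equal(187000 * 40 / 600 / 1000, 12.46667, tolerance = 1e-6)
  cv2 <- ref_curve(meta = meta)
  m2 <- curve_metrics(cv2, meta)
  expect_equal(m2$vss, meta$dose * m2$mrt / m2$auc)   # MBq*min/(kBq/mL*min)->L
  expect_equal(m2$mrt, m2$aumc / m2$auc)

  # MRT invariant under activity rescaling
  s <- 7.3
  cv3 <- tac(cv2$times, cv2$activities * s)
  expect_equal(curve_metrics(cv3)$mrt, m2$mrt)
  expect_error(curve_metrics(tac(0:2, c(0, 0, 0))), "AUC")
})
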