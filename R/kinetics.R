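#' Irreversible two-tissue compartment model, K1max screening, and FUR
#'
#' The FDG brain model has plasma activity Cp feeding a free compartment Cf
#' (rates K1 in, k2 out) which feeds an irreversibly trapped compartment Cb
#' (rate k3, no k4). With a = k2 + k3 the tissue impulse response is
#' \deqn{C_f + C_b = \frac{K_1 k_3}{k_2+k_3}\int_0^t C_p
#'       + \frac{K_1 k_2}{k_2+k_3}\, e^{-(k_2+k_3)t} * C_p}
#' and the measured PET signal is
#' `C_PET = (1 - vB) (Cf + Cb) + vB Cp` with the vascular fraction fixed at
#' `vB = 0.05`. The net influx constant is `Ki = K1 k3/(k2 + k3)`.
#'
#' @name kinetics
NULL

#' Kinetic parameter container
#'
#' @param k1 mL plasma/mL tissue/min, >= 0.
#' @param k2,k3 1/min, >= 0.
#' @param vb vascular fraction (fixed at 0.05 in this pipeline).
#' @param ... diagnostics stored alongside (wrss, at_bound, converged, ...).
#' @return Object of class `kinetic_params` with derived `ki`.
#' @export
kinetic_params <- function(k1, k2, k3, vb = 0.05, ...) {
  stopifnot(k1 >= 0, k2 >= 0, k3 >= 0, vb >= 0, vb < 1)
  ki <- if (k2 + k3 > 0) k1 * k3 / (k2 + k3) else 0
  structure(c(list(k1 = k1, k2 = k2, k3 = k3, vb = vb, ki = ki), list(...)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> K1 %.4g | k2 %.4g | k3 %.4g | Ki %.4g | vB %.3g\n",
              x$k1, x$k2, x$k3, x$ki, x$vb))
  invisible(x)
}

#' Net influx rate constant Ki
#'
#' The canonical irreversible-model influx constant is
#' `Ki = K1 k3 / (k2 + k3)`. A printed variant `K1 k3 / (K1 + k2)` circulates
#' in parts of the FDG literature; it is available behind an explicit
#' compatibility flag and is never silently substituted.
#'
#' @param k1,k2,k3 non-negative rate constants; the relevant denominator must
#'   be positive.
#' @param variant `"canonical"` (default) or `"printed"`.
#' @return Ki in 1/min.
#' @export
derive_ki <- function(k1, k2, k3, variant = c("canonical", "printed")) {
  variant <- match.arg(variant)
  stopifnot(all(k1 >= 0), all(k2 >= 0), all(k3 >= 0))
  den <- if (variant == "canonical") k2 + k3 else k1 + k2
  if (any(den <= 0)) stop("zero denominator in Ki")
  k1 * k3 / den
}

## cumulative trapezoid and exact exponential convolution of a piecewise
## linear signal on a uniform grid (recursion vectorized via stats::filter)
expconv_uniform <- function(y, dt, a) {
  n <- length(y)
  if (a == 0) return(pracma::cumtrapz(seq(0, by = dt, length.out = n), y)[, 1L])
  E <- exp(-a * dt)
  ci <- y[-n]; m <- (y[-1L] - ci) / dt
  q <- ci * (1 - E) / a + m * (dt / a - (1 - E) / a^2)
  c(0, as.numeric(stats::filter(q, E, method = "recursive")))
}

#' Simulate a tissue curve from the irreversible 2TCM
#'
#' Analytic impulse-response solution evaluated by exact convolution of the
#' piecewise-linear input on a dense uniform grid, then averaged within the
#' acquisition frames by the trapezoid rule. The vascular term uses plasma
#' activity (`vb * Cp`).
#'
#' @param input plasma [tac()] covering `[0, max frame end]`.
#' @param params [kinetic_params()] (k2 + k3 = 0 falls back to pure trapping
#'   `K1 * integral of Cp`).
#' @param frames data.frame with columns `start`, `end` (minutes), or a
#'   numeric vector of instantaneous evaluation times.
#' @param step convolution grid step, minutes.
#' @return Tissue [tac()] at the frame mid-times, with the frame table kept
#'   in `attr(, "frames")` (NULL for instantaneous times).
#' @export
simulate_2tcm <- function(input, params, frames, step = 0.02) {
  stopifnot(is_tac(input), inherits(params, "kinetic_params"))
  instant <- is.numeric(frames) && is.null(dim(frames))
  t_end <- if (instant) max(frames) else max(frames$end)
  if (max(input$times) < t_end - 1e-9)
    stop("input does not cover the frame times")
  ## uniform grid that lands exactly on t_end (exponential recursion needs it)
  dt <- t_end / ceiling(t_end / step)
  g <- seq(0, t_end, by = dt)
  cp <- stats::approx(input$times, input$activities, xout = g,
                      yleft = 0, rule = 2)$y
  a <- params$k2 + params$k3
  cum <- pracma::cumtrapz(g, cp)[, 1L]
  if (a == 0) {
    cfb <- params$k1 * cum
  } else {
    conv <- expconv_uniform(cp, dt, a)
    cfb <- (params$k1 * params$k3 / a) * cum +
           (params$k1 * params$k2 / a) * conv
  }
  ct <- (1 - params$vb) * cfb + params$vb * cp
  if (instant) {
    y <- stats::approx(g, ct, xout = frames)$y
    return(tac(frames, y, label = "tissue", meta = input$meta))
  }
  mids <- (frames$start + frames$end) / 2
  y <- mapply(function(s, e) {
    tt <- unique(c(s, g[g > s & g < e], e))
    yy <- stats::approx(g, ct, xout = tt)$y
    pracma::trapz(tt, yy) / (e - s)
  }, frames$start, frames$end)
  out <- tac(mids, y, label = "tissue", meta = input$meta)
  attr(out, "frames") <- frames
  out
}

#' Fit the irreversible 2TCM to a tissue curve
#'
#' Bounded least squares in the `(K1, K1/k2, k3)` parameterization with the
#' vascular fraction fixed at 0.05. Parameters that finish on a box bound are
#' flagged as saturated. Non-convergence is flagged, never raised.
#'
#' @param tissue tissue [tac()]; if it carries a `frames` attribute the model
#'   is frame-averaged, otherwise evaluated at the sample times.
#' @param input plasma [tac()] covering the tissue support.
#' @param vb fixed vascular fraction.
#' @param lower,upper bounds on `(K1, K1/k2, k3)`.
#' @param init starting values for `(K1, K1/k2, k3)`.
#' @param weights per-frame weights (uniform by default).
#' @param step convolution grid step, minutes.
#' @return [kinetic_params()] with `wrss`, `at_bound` (logical, named),
#'   `converged` and `v1` (= K1/k2) diagnostics.
#' @export
fit_2tcm <- function(tissue, input, vb = 0.05,
                     lower = c(k1 = 0, v1 = 0.01, k3 = 0),
                     upper = c(k1 = 1, v1 = 10, k3 = 0.5),
                     init = c(k1 = 0.1, v1 = 0.7, k3 = 0.05),
                     weights = NULL, step = 0.02) {
  stopifnot(is_tac(tissue), is_tac(input))
  frames <- attr(tissue, "frames")
  eval_at <- if (is.null(frames)) tissue$times else frames
  if (is.null(weights)) weights <- rep(1, length(tissue$times))
  w <- sqrt(weights)
  res_fn <- function(th) {
    th <- pmin(pmax(th, lower), upper)  # jacobian probes can graze the box
    pars <- kinetic_params(k1 = th[1L], k2 = th[1L] / th[2L], k3 = th[3L],
                           vb = vb)
    sim <- simulate_2tcm(input, pars, eval_at, step = step)
    w * (sim$activities - tissue$activities)
  }
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, ptol = 1e-12, maxiter = 200))
  th <- fit$par
  tol <- pmax(1e-8, 1e-6 * (upper - lower))
  at_bound <- (th - lower < tol) | (upper - th < tol)
  names(at_bound) <- c("k1", "v1", "k3")
  kinetic_params(k1 = th[[1L]], k2 = th[[1L]] / th[[2L]], k3 = th[[3L]],
                 vb = vb, v1 = th[[2L]], wrss = sum(fit$fvec^2),
                 at_bound = at_bound, converged = fit$info %in% 1:4,
                 message = fit$message)
}

#' Perfusion-derived upper bound on K1
#'
#' Cerebral plasma flow is `CPF = CBF * (1 - hematocrit)`; with the
#' first-pass extraction fixed at its upper limit of 1,
#' `K1max = CPF * 1 = CPF`. Fitted K1 values above K1max are physiologically
#' implausible and indicate an input curve with a deficient early peak.
#'
#' @param cbf cerebral blood flow, mL blood/mL tissue/min (> 0).
#' @param hematocrit fraction in (0, 1).
#' @return Object of class `perfusion_constraint`: `cbf`, `hematocrit`,
#'   `extraction` (always 1), `cpf`, `k1max`.
#' @export
k1max <- function(cbf, hematocrit) {
  if (!is.finite(cbf) || cbf <= 0) stop("cbf must be > 0")
  if (!is.finite(hematocrit) || hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie in (0, 1)")
  cpf <- cbf * (1 - hematocrit)
  structure(list(cbf = cbf, hematocrit = hematocrit, extraction = 1,
                 cpf = cpf, k1max = cpf),
            class = "perfusion_constraint")
}

#' @export
print.perfusion_constraint <- function(x, ...) {
  cat(sprintf("<perfusion_constraint> CBF %.3g, Htk %.2f -> CPF = K1max = %.4g mL/mL/min\n",
              x$cbf, x$hematocrit, x$k1max))
  invisible(x)
}

#' Screen fitted K1 values against the perfusion bound
#'
#' Counts, per ROI and per subject, fits whose K1 exceeds the subject's
#' K1max; when a second set of fits (after input recovery) is supplied the
#' same counts are reported side by side. A subject is counted once when at
#' least one of its ROIs exceeds the bound.
#'
#' @param fits data.frame with columns `subject`, `roi`, `k1`.
#' @param constraints data.frame with columns `subject`, `k1max`.
#' @param fits_after optional data.frame like `fits`, post-recovery.
#' @return List with `by_roi` (data.frame of exceedance counts per ROI),
#'   `subjects_exceeding` (and `_after`), `n_subjects`.
#' @export
plausibility_screen <- function(fits, constraints, fits_after = NULL) {
  stopifnot(all(c("subject", "roi", "k1") %in% names(fits)),
            all(c("subject", "k1max") %in% names(constraints)))
  tally <- function(f) {
    f$k1max <- constraints$k1max[match(f$subject, constraints$subject)]
    f$exceeds <- f$k1 > f$k1max
    list(by_roi = stats::aggregate(exceeds ~ roi, data = f, FUN = sum),
         subjects = sum(tapply(f$exceeds, f$subject, any)))
  }
  before <- tally(fits)
  out <- list(by_roi = before$by_roi,
              subjects_exceeding = before$subjects,
              n_subjects = length(unique(fits$subject)))
  if (!is.null(fits_after)) {
    after <- tally(fits_after)
    names(after$by_roi)[2L] <- "exceeds_after"
    out$by_roi <- merge(out$by_roi, after$by_roi, by = "roi", all = TRUE)
    out$subjects_exceeding_after <- after$subjects
  }
  out
}

#' Fractional uptake rate
#'
#' `FUR(T) = C_tissue(T) / integral of Cp over [0, T]`, a late-scan retention
#' index approximating Ki. Computed per tissue frame and averaged.
#'
#' @param tissue tissue [tac()] (may be late-only).
#' @param input plasma [tac()] covering every tissue time from injection.
#' @return Object of class `fur_result`: `fur` (1/min, mean over frames),
#'   `per_frame`, `eval_time` (mean frame time), `input_auc_0_T` (at the last
#'   frame).
#' @export
compute_fur <- function(tissue, input) {
  stopifnot(is_tac(tissue), is_tac(input))
  if (max(input$times) < max(tissue$times) - 1e-9)
    stop("input does not cover the tissue frame times")
  aucs <- vapply(tissue$times, function(T) trapezoid_auc(input, 0, T), 0)
  if (any(aucs <= 0)) stop("input AUC is not positive at a frame time")
  per_frame <- tissue$activities / aucs
  structure(list(fur = mean(per_frame), per_frame = per_frame,
                 eval_time = mean(tissue$times),
                 input_auc_0_T = aucs[length(aucs)]),
            class = "fur_result")
}

#' @export
print.fur_result <- function(x, ...) {
  cat(sprintf("<fur_result> FUR %.4g /min over %d frames (mean t %.3g min)\n",
              x$fur, length(x$per_frame), x$eval_time))
  invisible(x)
}
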