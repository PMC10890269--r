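#' Curve-onset cleaning and population peak alignment
#'
#' Venous/arterialized sampling leaves input curves with noisy near-zero
#' onsets and peaks that occur at slightly different times across subjects.
#' These helpers (i) floor spuriously low leading samples, (ii) locate peaks
#' with a tie rule for near-equal double peaks, (iii) extrapolate the start of
#' the ascending phase, and (iv) time-shift every curve so its peak sits at a
#' common population delay time (the upper adjacent value of the peak-time
#' distribution), storing the per-curve delay so it can be undone before
#' kinetic modelling.
#'
#' @name preprocess
NULL

first_nonzero_idx <- function(curve) {
  i <- which(curve$activities != 0)
  if (!length(i)) stop("curve is all zero")
  i[1L]
}

#' Floor spuriously low curve onsets
#'
#' The population threshold is the median over curves of each curve's first
#' non-zero activity. Leading samples of a curve are set to 0 while its first
#' non-zero value lies below the threshold; by default the rule is applied
#' iteratively to successive leading points (`iterative = FALSE` floors at
#' most one leading value per curve). Tails are never touched.
#'
#' @param curves list of [tac()] (>= 2), each with at least one non-zero value.
#' @param iterative apply the rule repeatedly to successive leading samples.
#' @return List with `curves` (floored) and `threshold` (kBq/mL).
#' @export
floor_low_onsets <- function(curves, iterative = TRUE) {
  stopifnot(length(curves) >= 2L, all(vapply(curves, is_tac, TRUE)))
  firsts <- vapply(curves, function(cv) cv$activities[first_nonzero_idx(cv)], 0)
  threshold <- stats::median(firsts)
  floored <- lapply(curves, function(cv) {
    repeat {
      i <- which(cv$activities != 0)
      if (!length(i))
        stop("flooring would zero out an entire curve; raw onset below threshold everywhere")
      i <- i[1L]
      if (cv$activities[i] >= threshold) break
      cv$activities[i] <- 0
      if (!iterative) break
    }
    cv
  })
  list(curves = floored, threshold = threshold)
}

local_maxima_idx <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1L] > y[2L]) idx <- c(1L, idx)
  if (y[n] > y[n - 1L]) idx <- c(idx, n)
  idx[y[idx] > 0]
}

#' Time of a curve's maximum peak
#'
#' Returns the time of the global maximum. When a second local maximum lies
#' within 10% of the global maximum, the mid-time between the two peaks is
#' returned instead (near-equal double peaks).
#'
#' @param curve non-negative [tac()] with a positive maximum.
#' @return Peak time, minutes.
#' @export
find_peak_time <- function(curve) {
  stopifnot(is_tac(curve))
  y <- curve$activities
  if (max(y) <= 0) stop("curve has no positive peak")
  lm_idx <- local_maxima_idx(y)
  if (!length(lm_idx)) lm_idx <- which.max(y)
  ord <- lm_idx[order(y[lm_idx], decreasing = TRUE)]
  t1 <- curve$times[ord[1L]]
  if (length(ord) >= 2L) {
    v1 <- y[ord[1L]]; v2 <- y[ord[2L]]
    if ((v1 - v2) / v1 < 0.10)
      return(mean(c(t1, curve$times[ord[2L]])))
  }
  t1
}

#' Extrapolated start of the ascending phase
#'
#' Estimates the time at which the input crosses zero on its way up. With at
#' most two samples strictly between the first non-zero sample and the peak, a
#' straight line is fitted through the ascending samples and its zero-crossing
#' returned; with more points a quadratic is fitted and its latest real root
#' before the peak is used. An observed zero sample immediately preceding the
#' ascent joins the fit and bounds the result from below; zero-crossings are
#' clamped to `[max(0, last observed zero time), first non-zero time]`.
#'
#' @param curve [tac()] whose first non-zero sample precedes its peak.
#' @return Ascent-start time, minutes.
#' @export
estimate_ascent_start <- function(curve) {
  stopifnot(is_tac(curve))
  i0 <- first_nonzero_idx(curve)
  ip <- which.max(curve$activities)
  if (ip <= i0)
    stop("peak at or before the first non-zero sample; cannot extrapolate ascent")
  lo <- if (i0 > 1L) i0 - 1L else i0  # include adjacent observed zero, if any
  tt <- curve$times[lo:ip]
  yy <- curve$activities[lo:ip]
  n_between <- ip - i0 - 1L
  t_first <- curve$times[i0]
  t_lastzero <- if (i0 > 1L) curve$times[i0 - 1L] else 0
  root <- NA_real_
  if (n_between > 2L) {
    fit <- stats::lm(yy ~ tt + I(tt^2))
    cf <- stats::coef(fit)
    disc <- cf[[2L]]^2 - 4 * cf[[3L]] * cf[[1L]]
    ## a grazing (double) root makes the discriminant tiny negative in FP
    if (is.finite(disc) && abs(disc) < 1e-8 * max(cf[[2L]]^2, 1)) disc <- 0
    if (is.finite(disc) && disc >= 0 && abs(cf[[3L]]) > 1e-12) {
      roots <- (-cf[[2L]] + c(-1, 1) * sqrt(disc)) / (2 * cf[[3L]])
      roots <- roots[roots < curve$times[ip]]
      if (length(roots)) root <- max(roots)
    }
  }
  if (!is.finite(root)) { # linear rule, also the quadratic fallback
    fit <- stats::lm(yy ~ tt)
    cf <- stats::coef(fit)
    if (abs(cf[[2L]]) < 1e-12) stop("flat ascent; cannot extrapolate")
    root <- -cf[[1L]] / cf[[2L]]
  }
  min(max(root, 0, t_lastzero), t_first)
}

#' Align all peaks to the population delay time (UAVt)
#'
#' The population delay time is the upper adjacent value of the peak-time
#' distribution: the largest observed peak time that does not exceed the upper
#' inner fence Q3 + 1.5 IQR (quartiles by linear interpolation). Every curve
#' peaking earlier is delayed to UAVt by shifting its time grid right and
#' inserting a single (0, 0) anchor sample; the delay `dt` is stored per curve
#' for later restoration with [restore_delay()].
#'
#' @param curves list of >= 4 [tac()] objects.
#' @return List with `curves` (aligned) and `alignment`, a `peak_alignment`
#'   object holding `uav_t`, per-curve `delays` and `peak_times`.
#' @export
align_peaks <- function(curves) {
  stopifnot(all(vapply(curves, is_tac, TRUE)))
  if (length(curves) < 4L)
    stop("peak alignment needs at least 4 curves for meaningful quartiles")
  peaks <- vapply(curves, find_peak_time, 0)
  q <- stats::quantile(peaks, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  uav_t <- max(peaks[peaks <= fence])
  delays <- pmax(0, uav_t - peaks)
  delays[peaks >= uav_t] <- 0
  aligned <- mapply(function(cv, dt) {
    if (dt <= 0) return(cv)
    tt <- cv$times + dt
    yy <- cv$activities
    if (tt[1L] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
    tac(tt, yy, label = cv$label, meta = cv$meta)
  }, curves, delays, SIMPLIFY = FALSE)
  names(aligned) <- names(curves)
  alignment <- structure(list(uav_t = uav_t, delays = delays,
                              peak_times = peaks),
                         class = "peak_alignment")
  list(curves = aligned, alignment = alignment)
}

#' @export
print.peak_alignment <- function(x, ...) {
  cat(sprintf("<peak_alignment> UAVt = %.3g min, %d curves, delays 0-%.3g min\n",
              x$uav_t, length(x$delays), max(x$delays)))
  invisible(x)
}

#' Remove a stored alignment delay from a curve
#'
#' Inverse of the shift applied by [align_peaks()]: subtracts `dt` from the
#' time grid and drops samples that would land at negative times (including
#' the inserted (0,0) anchor).
#'
#' @param curve a [tac()].
#' @param dt delay in minutes, >= 0.
#' @return The restored [tac()].
#' @export
restore_delay <- function(curve, dt) {
  stopifnot(is_tac(curve))
  if (!is.finite(dt) || dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(curve)
  tt <- curve$times - dt
  keep <- tt >= -1e-9
  tac(pmax(tt[keep], 0), curve$activities[keep],
      label = curve$label, meta = curve$meta)
}

#' Tabular audit report of a peak alignment
#'
#' @param alignment a `peak_alignment` from [align_peaks()].
#' @param ids optional curve identifiers.
#' @return data.frame with one row per curve (id, peak time, dt).
#' @export
alignment_report <- function(alignment, ids = NULL) {
  n <- length(alignment$delays)
  if (is.null(ids)) ids <- sprintf("curve%02d", seq_len(n))
  data.frame(id = ids, peak_time = alignment$peak_times,
             dt = alignment$delays, uav_t = alignment$uav_t)
}
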