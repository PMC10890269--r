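#' Reference selection and good/poor quality classification
#'
#' Two decisions are made on peak-aligned input curves. First, a small set of
#' reference-grade curves is selected by a peak-to-tail ratio criterion:
#' RT = peak activity / activity at UAVt + 2.5 min, with threshold RT1 taken
#' at the boundary between the third and fourth quarters of the RT
#' distribution (the 75th percentile by default), combined with a peak-time
#' window and an absolute 50 kBq/mL peak floor. Second, every curve receives
#' a linear quality score
#' `selection_value = -0.36 + 0.038 * maxSUV + 0.052 * peak/5th`
#' and is labelled good when the score reaches the 0.47 cutoff (ties count as
#' good). Both rules use fixed published coefficients, overridable in the
#' arguments; they are not re-calibrated here.
#'
#' @name quality_selection
NULL

#' Peak-to-tail ratio RT of a peak-aligned curve
#'
#' @param curve peak-aligned [tac()].
#' @param uav_t population delay time, minutes (see [align_peaks()]).
#' @return `max activity / activity at uav_t + 2.5 min` (linear
#'   interpolation at the denominator time).
#' @export
compute_rt <- function(curve, uav_t) {
  stopifnot(is_tac(curve))
  denom <- tac_interp(curve, uav_t + 2.5)
  if (!is.finite(denom) || denom <= 0)
    stop("activity at UAVt + 2.5 min is not positive")
  max(curve$activities) / denom
}

#' Select reference-grade curves
#'
#' A curve is reference-grade when `RT >= RT1`, its peak time does not exceed
#' `uav_t + time_margin`, and its peak reaches `peak_floor` kBq/mL.
#'
#' @param curves list of >= 8 peak-aligned [tac()] objects.
#' @param alignment `peak_alignment` from [align_peaks()].
#' @param peak_floor minimum absolute peak, kBq/mL.
#' @param rt_percentile percentile of the RT distribution used for RT1.
#' @param time_margin allowed peak-time excess over UAVt, minutes.
#' @return List with `selected` (logical), `rt` (per curve), `rt1`.
#' @export
select_reference <- function(curves, alignment, peak_floor = 50,
                             rt_percentile = 0.75, time_margin = 1) {
  stopifnot(length(curves) >= 8L, inherits(alignment, "peak_alignment"))
  rt <- vapply(curves, compute_rt, 0, uav_t = alignment$uav_t)
  rt1 <- stats::quantile(rt, rt_percentile, names = FALSE, type = 7)
  peak_time <- vapply(curves, find_peak_time, 0)
  peak_max <- vapply(curves, function(cv) max(cv$activities), 0)
  selected <- rt >= rt1 & peak_time <= alignment$uav_t + time_margin &
    peak_max >= peak_floor
  if (!any(selected))
    warning("no curve satisfies the reference criteria")
  list(selected = selected, rt = rt, rt1 = rt1)
}

#' Linear quality score of an input curve
#'
#' @param curve [tac()] covering at least `[0, 5]` min.
#' @param meta [subject_meta()] with dose and weight (for SUV).
#' @param coef intercept and coefficients of maxSUV and peak/5th.
#' @param cutoff good/poor decision threshold on the score; ties are good.
#' @return Object of class `quality_score`: `max_suv`, `peak_to_5th`,
#'   `selection_value`, `label` (`"good"`/`"poor"`).
#' @export
quality_score <- function(curve, meta = curve$meta,
                          coef = c(-0.36, 0.038, 0.052), cutoff = 0.47) {
  stopifnot(is_tac(curve))
  if (is.null(meta) || !is.finite(meta$dose) || !is.finite(meta$weight))
    stop("quality_score needs subject dose and weight")
  if (max(curve$times) < 5)
    stop("curve must cover [0, 5] min")
  peak <- max(curve$activities)
  max_suv <- peak * meta$weight / meta$dose
  at5 <- tac_interp(curve, 5)
  peak_to_5th <- if (peak == 0 && at5 == 0) 0 else {
    if (at5 <= 0) stop("activity at 5 min is not positive")
    peak / at5
  }
  value <- coef[1L] + coef[2L] * max_suv + coef[3L] * peak_to_5th
  structure(list(max_suv = max_suv, peak_to_5th = peak_to_5th,
                 selection_value = value,
                 label = if (value >= cutoff) "good" else "poor"),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("<quality_score> maxSUV %.3g, peak/5th %.3g, value %.3g -> %s\n",
              x$max_suv, x$peak_to_5th, x$selection_value, x$label))
  invisible(x)
}

#' Per-curve QC report
#'
#' @param curves list of peak-aligned [tac()] objects.
#' @param metas list of [subject_meta()] (recycled from curve meta if NULL).
#' @param alignment `peak_alignment` used for RT and reference flags.
#' @param ... passed to [select_reference()].
#' @return data.frame, one row per curve: max_suv, peak_to_5th,
#'   selection_value, label, rt, reference flag.
#' @export
qc_report <- function(curves, metas = NULL, alignment, ...) {
  if (is.null(metas)) metas <- lapply(curves, `[[`, "meta")
  qs <- mapply(function(cv, m) quality_score(cv, m), curves, metas,
               SIMPLIFY = FALSE)
  sel <- select_reference(curves, alignment, ...)
  data.frame(
    id = if (!is.null(names(curves))) names(curves)
         else sprintf("curve%02d", seq_along(curves)),
    max_suv = vapply(qs, `[[`, 0, "max_suv"),
    peak_to_5th = vapply(qs, `[[`, 0, "peak_to_5th"),
    selection_value = vapply(qs, `[[`, 0, "selection_value"),
    label = vapply(qs, `[[`, "", "label"),
    rt = sel$rt,
    reference = sel$selected,
    row.names = NULL)
}
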