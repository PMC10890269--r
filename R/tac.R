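#' Time-activity curves and subject metadata
#'
#' A `tac` is the universal currency of the pipeline: sampled, decay-corrected
#' activity concentration versus time for plasma or a tissue region. Times are
#' minutes post-injection, activities kBq/mL. Curves are assumed
#' decay-corrected on input; no decay handling is performed anywhere.
#'
#' @param times numeric, minutes post-injection; strictly increasing, >= 0.
#' @param activities numeric, kBq/mL; finite, same length as `times`.
#' @param label `"plasma"` or `"tissue"`.
#' @param meta optional [subject_meta()] attached to the curve.
#' @return An object of class `tac`: a list with elements `times`,
#'   `activities`, `label`, `meta`.
#' @examples
#' cv <- tac(c(0, 1, 2), c(0, 10, 5))
#' max(cv$activities)
#' @export
tac <- function(times, activities, label = c("plasma", "tissue"), meta = NULL) {
  label <- match.arg(label)
  times <- as.numeric(times)
  activities <- as.numeric(activities)
  if (length(times) != length(activities))
    stop("times and activities must have equal length")
  if (length(times) < 3L)
    stop("a tac needs at least 3 samples")
  if (anyNA(times) || anyNA(activities) || any(!is.finite(activities)))
    stop("times and activities must be finite")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (times[1L] < 0)
    stop("times must be >= 0")
  structure(list(times = times, activities = activities,
                 label = label, meta = meta),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac:%s> %d samples, t = [%.3g, %.3g] min, peak %.4g kBq/mL\n",
              x$label, length(x$times), min(x$times), max(x$times),
              max(x$activities)))
  invisible(x)
}

#' @export
length.tac <- function(x) length(x$times)

is_tac <- function(x) inherits(x, "tac")

#' Per-subject study metadata
#'
#' @param subject_id opaque identifier.
#' @param dose injected activity, MBq (> 0).
#' @param weight body weight, kg (> 0).
#' @param hematocrit haematocrit fraction, in (0, 1).
#' @param cbf optional cerebral blood flow, mL blood/mL tissue/min; consumed
#'   as a number by [k1max()], never computed from images.
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, dose, weight, hematocrit, cbf = NA_real_) {
  if (!is.finite(dose) || dose <= 0) stop("dose must be > 0 MBq")
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0 kg")
  if (!is.finite(hematocrit) || hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie in (0, 1)")
  structure(list(subject_id = as.character(subject_id), dose = dose,
                 weight = weight, hematocrit = hematocrit, cbf = cbf),
            class = "subject_meta")
}

#' @export
print.subject_meta <- function(x, ...) {
  cat(sprintf("<subject %s> dose %.1f MBq, weight %.1f kg, Htk %.2f, CBF %s\n",
              x$subject_id, x$dose, x$weight, x$hematocrit,
              ifelse(is.na(x$cbf), "NA", sprintf("%.3f", x$cbf))))
  invisible(x)
}

## linear interpolation on the curve; 0 before support, last value after
tac_interp <- function(curve, t) {
  stats::approx(curve$times, curve$activities, xout = t,
                yleft = 0, yright = curve$activities[length(curve$activities)],
                ties = "ordered")$y
}

# ---------------------------------------------------------------------------
# file I/O
#
# TAC file: delimited text (comma or tab), two columns time/activity, optional
# '#'-prefixed header lines declaring units ("time[min]" or "time[s]";
# "kBq/mL" or "Bq/cc") and the label ("plasma"/"tissue"). One curve per file;
# multi-ROI tissue files have a time column plus one named column per ROI and
# are read with read_tacs().
# ---------------------------------------------------------------------------

parse_tac_header <- function(lines) {
  hdr <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  time_scale <- 1
  act_scale <- 1
  label <- "plasma"
  for (h in hdr) {
    toks <- strsplit(h, "[,\t ]+")[[1]]
    for (tok in toks) {
      lt <- tolower(tok)
      if (grepl("^time\\[", lt)) {
        if (lt == "time[min]") time_scale <- 1
        else if (lt == "time[s]" || lt == "time[sec]") time_scale <- 1 / 60
        else stop("unknown time unit in header: ", tok)
      } else if (grepl("/", lt, fixed = TRUE)) {
        if (lt %in% c("kbq/ml", "kbq/cc")) act_scale <- 1
        else if (lt %in% c("bq/cc", "bq/ml")) act_scale <- 1 / 1000
        else stop("unknown activity unit in header: ", tok)
      } else if (lt %in% c("plasma", "tissue")) {
        label <- lt
      }
    }
  }
  list(time_scale = time_scale, act_scale = act_scale, label = label)
}

read_tac_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  units <- parse_tac_header(lines)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  sep <- if (grepl(",", body[1L], fixed = TRUE)) "," else "\t"
  tab <- utils::read.table(text = body, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE)
  ## a leading non-numeric row is a column-name header (multi-ROI files)
  if (!is.numeric(tab[[1L]])) {
    nm <- as.character(unlist(tab[1L, ]))
    tab <- utils::read.table(text = body[-1L], sep = sep, header = FALSE,
                             stringsAsFactors = FALSE)
    names(tab) <- nm
  }
  list(tab = tab, units = units)
}

#' Read a time-activity curve from a delimited text file
#'
#' Accepts comma- or tab-separated files with two numeric columns
#' (time, activity). Lines starting with `#` may declare units
#' (`time[min]`/`time[s]`, `kBq/mL`/`Bq/cc`) and a label
#' (`plasma`/`tissue`); values are converted to minutes and kBq/mL.
#'
#' @param path file path.
#' @param meta optional [subject_meta()] to attach.
#' @return A [tac()].
#' @seealso [write_tac()], [read_tacs()]
#' @export
read_tac <- function(path, meta = NULL) {
  r <- read_tac_table(path)
  if (ncol(r$tab) < 2L) stop("expected two columns in ", path)
  tac(r$tab[[1L]] * r$units$time_scale,
      r$tab[[2L]] * r$units$act_scale,
      label = r$units$label, meta = meta)
}

#' Read a multi-ROI tissue TAC file
#'
#' @param path file with a time column plus one named activity column per ROI.
#' @param meta optional [subject_meta()].
#' @return Named list of tissue [tac()] objects, one per ROI column.
#' @export
read_tacs <- function(path, meta = NULL) {
  r <- read_tac_table(path)
  if (ncol(r$tab) < 2L) stop("expected time plus >= 1 activity column in ", path)
  tt <- r$tab[[1L]] * r$units$time_scale
  out <- lapply(seq_len(ncol(r$tab) - 1L) + 1L, function(j)
    tac(tt, r$tab[[j]] * r$units$act_scale, label = "tissue", meta = meta))
  nm <- names(r$tab)[-1L]
  if (is.null(nm) || any(!nzchar(nm)) || all(grepl("^V\\d+$", nm)))
    nm <- paste0("roi", seq_along(out))
  names(out) <- nm
  out
}

#' Write a time-activity curve to a delimited text file
#'
#' Output is tab-separated with a unit header and is byte-stable: writing the
#' same curve twice produces identical files, and `read_tac(write_tac(x))`
#' round-trips values to full double precision.
#'
#' @param curve a [tac()].
#' @param path output path.
#' @export
write_tac <- function(curve, path) {
  stopifnot(is_tac(curve))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# time[min]\tkBq/mL\t%s", curve$label), con, sep = "\n")
  writeLines(sprintf("%.17g\t%.17g", curve$times, curve$activities),
             con, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------------
# curve metrics
# ---------------------------------------------------------------------------

#' Convert a curve to standardized uptake value (SUV) units
#'
#' SUV uses body-weight normalization: `suv(t) = activity(t) * weight / dose`
#' with activity in kBq/mL, weight in kg, dose in MBq (so 187 kBq/mL at
#' 187 MBq in a 1 kg body gives SUV 1).
#'
#' @param curve a [tac()].
#' @param meta [subject_meta()] supplying dose and weight (defaults to the
#'   curve's own `meta`).
#' @return A [tac()] whose activities are SUV.
#' @export
to_suv <- function(curve, meta = curve$meta) {
  stopifnot(is_tac(curve))
  if (is.null(meta) || !is.finite(meta$dose) || !is.finite(meta$weight))
    stop("to_suv needs subject dose and weight")
  tac(curve$times, curve$activities * meta$weight / meta$dose,
      label = curve$label, meta = meta)
}

#' Trapezoidal area under the curve over a time window
#'
#' Integrates the sampled curve between `t0` and `t1` by the trapezoid rule,
#' linearly interpolating the curve value at the window edges.
#'
#' @param curve a [tac()].
#' @param t0,t1 window in minutes, `t0 < t1`; must overlap the curve support.
#' @return AUC in kBq/mL.min.
#' @export
trapezoid_auc <- function(curve, t0 = min(curve$times), t1 = max(curve$times)) {
  stopifnot(is_tac(curve))
  if (t0 >= t1) stop("need t0 < t1")
  lo <- min(curve$times); hi <- max(curve$times)
  if (t1 <= lo || t0 >= hi)
    stop(sprintf("window [%g, %g] lies outside curve support [%g, %g]",
                 t0, t1, lo, hi))
  a <- max(t0, lo); b <- min(t1, hi)
  inside <- curve$times > a & curve$times < b
  tt <- c(a, curve$times[inside], b)
  yy <- tac_interp(curve, tt)
  pracma::trapz(tt, yy)
}

#' Summary metrics of a curve: AUC, AUMC, MRT, peak, VSS
#'
#' AUMC is the area under the first-moment curve `integral c(t) t dt` over the
#' full sampled support; `MRT = AUMC/AUC` and the steady-state distribution
#' volume `VSS = dose * MRT / AUC` (dose converted to kBq so that VSS comes
#' out in mL; reported in liters).
#'
#' @param curve a non-negative [tac()] with positive AUC.
#' @param meta optional [subject_meta()]; needed only for `vss`.
#' @return List of class `curve_metrics` with `auc`, `aumc`, `mrt`,
#'   `max_activity`, `max_time`, `vss` (liters, `NA` without dose).
#' @export
curve_metrics <- function(curve, meta = curve$meta) {
  stopifnot(is_tac(curve))
  auc <- pracma::trapz(curve$times, curve$activities)
  if (auc <= 0) stop("curve has non-positive AUC")
  aumc <- pracma::trapz(curve$times, curve$activities * curve$times)
  mrt <- aumc / auc
  imax <- which.max(curve$activities)
  vss <- NA_real_
  if (!is.null(meta) && is.finite(meta$dose))
    vss <- meta$dose * 1000 * mrt / auc / 1000  # kBq.min/(kBq/mL.min) -> mL -> L
  structure(list(auc = auc, aumc = aumc, mrt = mrt,
                 max_activity = curve$activities[imax],
                 max_time = curve$times[imax], vss = vss),
            class = "curve_metrics")
}

#' @export
print.curve_metrics <- function(x, ...) {
  cat(sprintf("AUC %.4g kBq/mL.min | MRT %.4g min | peak %.4g kBq/mL @ %.3g min | VSS %s L\n",
              x$auc, x$mrt, x$max_activity, x$max_time,
              ifelse(is.na(x$vss), "NA", sprintf("%.3g", x$vss))))
  invisible(x)
}
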