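#' Periodic boundary waveform
#'
#' A periodic signal defined by control points `(phase, value)` on
#' `[0, period)` and evaluated anywhere in time by monotone piecewise-cubic
#' (Fritsch-Carlson) interpolation in phase. Monotone interpolation avoids
#' overshoot between control points, so e.g. a strictly positive pressure
#' trace stays positive. Evaluation is exactly periodic: `t` is reduced
#' modulo `period` before interpolation.
#'
#' @param phases Strictly increasing phases in `[0, period)` (s).
#' @param values Signal values at the phases (m/s or Pa).
#' @param period Cardiac period (s), > 0.
#' @param kind `"velocity"` or `"pressure"`.
#' @param note Provenance note (free text).
#' @return An object of class `waveform`; evaluate with [wf_eval()].
#' @export
waveform <- function(phases, values, period = 1, kind = c("velocity", "pressure"),
                     note = "") {
  kind <- match.arg(kind)
  if (!is.finite(period) || period <= 0) stop("period must be > 0", call. = FALSE)
  if (length(phases) != length(values) || length(phases) < 2) {
    stop("need >= 2 control points", call. = FALSE)
  }
  if (any(phases < 0) || any(phases >= period) || any(diff(phases) <= 0)) {
    stop("phases must be strictly increasing in [0, period)", call. = FALSE)
  }
  if (kind == "pressure" && any(values <= 0)) {
    stop("pressure waveforms must be strictly positive", call. = FALSE)
  }
  # periodic monotone (Fritsch-Butland) cubic Hermite interpolant: slopes are
  # zero at local extrema and harmonically limited elsewhere, so the signal
  # never overshoots its control values and closes smoothly across the seam
  n <- length(phases)
  hseg <- diff(c(phases, phases[1] + period))        # n interval widths
  dseg <- diff(c(values, values[1])) / hseg          # n secant slopes
  d_prev <- dseg[c(n, seq_len(n - 1))]
  m <- ifelse(d_prev * dseg <= 0, 0,
              2 * d_prev * dseg / (d_prev + dseg))   # harmonic mean
  fun <- function(tt) {
    k <- findInterval(tt, phases)
    k[k == 0L] <- n                                  # phase before first point
    x0 <- phases[k]
    tt <- ifelse(k == n & tt < phases[1], tt + period, tt)
    s <- (tt - x0) / hseg[k]
    h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s); h11 <- s^2 * (s - 1)
    kk <- k %% n + 1L
    h00 * values[k] + h10 * hseg[k] * m[k] +
      h01 * values[kk] + h11 * hseg[k] * m[kk]
  }
  structure(
    list(period = period, kind = kind, phases = phases, values = values,
         note = note, fun = fun),
    class = "waveform"
  )
}

#' Evaluate a waveform at arbitrary times
#' @param w A [waveform()].
#' @param t Times (s), any real values.
#' @return Signal values at `t`; exactly periodic in `w$period`.
#' @export
wf_eval <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  w$fun(t %% w$period)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %s, period %g s, %d control points, range [%g, %g]>\n",
              x$kind, x$period, length(x$phases), min(x$values), max(x$values)))
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Pulsatile inlet velocity waveform
#'
#' Parametric stand-in for a physiological ascending-aorta velocity trace:
#' a half-sine systolic pulse over `[systole_start, systole_end]` peaking at
#' the mid-systolic phase, on a flat diastolic baseline. With the defaults
#' (period 1 s, systole 0.05-0.45 s) the peak falls at phase 0.25 s, i.e.
#' t = 3.25 s within the fourth cardiac cycle. The solver applies the value
#' as a spatially flat inlet profile.
#'
#' The default peak is set by the laminar-flow premise rather than by the
#' physiological velocity scale: with blood properties and the channel's
#' 2D hydraulic diameter (2 x 20 mm), `peak = 0.125` m/s keeps the maximum
#' in-domain Reynolds number below the critical value of about 2300. See the
#' methods vignette for the reasoning behind this velocity-scale reduction.
#'
#' @param peak Peak systolic velocity (m/s).
#' @param period Cardiac period (s).
#' @param systole_start,systole_end Systolic interval bounds (s).
#' @param baseline Diastolic velocity (m/s), `< peak`.
#' @return A velocity [waveform()].
#' @export
inlet_velocity_waveform <- function(peak = 0.125, period = 1.0,
                                    systole_start = 0.05, systole_end = 0.45,
                                    baseline = 0.0) {
  if (peak <= baseline) stop("peak must exceed baseline", call. = FALSE)
  if (!(systole_start >= 0 && systole_end > systole_start && systole_end < period)) {
    stop("systolic interval must satisfy 0 <= start < end < period", call. = FALSE)
  }
  ts <- seq(systole_start, systole_end, length.out = 21)
  vs <- baseline + (peak - baseline) *
    sin(pi * (ts - systole_start) / (systole_end - systole_start))
  ph <- c(0, ts, min(systole_end + 0.05 * period, 0.999 * period))
  va <- c(baseline, vs, baseline)
  keep <- !duplicated(ph)
  waveform(ph[keep], va[keep], period, "velocity",
           note = "parametric half-sine systolic pulse (approximation of a physiological trace)")
}

#' Pulsatile outlet pressure waveform
#'
#' Two-phase pressure trace between configured diastolic and systolic levels
#' (defaults 10.6 and 16.0 kPa, i.e. about 80/120 mmHg), peaking shortly
#' after the velocity peak and relaxing back to the diastolic level.
#'
#' @param diastolic,systolic Pressure levels (Pa), `systolic > diastolic > 0`.
#' @param period Cardiac period (s).
#' @param peak_phase Phase of the systolic pressure peak (s).
#' @return A pressure [waveform()].
#' @export
outlet_pressure_waveform <- function(diastolic = 10.6e3, systolic = 16.0e3,
                                     period = 1.0, peak_phase = 0.30) {
  if (systolic <= diastolic) stop("systolic must exceed diastolic", call. = FALSE)
  if (diastolic <= 0) stop("pressure must be strictly positive", call. = FALSE)
  mid <- diastolic + 0.45 * (systolic - diastolic)
  ph <- c(0, 0.05, peak_phase, peak_phase + 0.25, peak_phase + 0.45, 0.95) * period
  va <- c(diastolic, diastolic, systolic, mid, diastolic * 1.02, diastolic)
  waveform(ph, va, period, "pressure",
           note = "parametric two-phase arterial pressure (approximation of a physiological trace)")
}

#' Branch outflow velocity waveform from a flow split
#'
#' Velocity signal for a branch outflow slot such that the instantaneous
#' volumetric flow through the slot (2D: velocity x width, per unit depth)
#' equals `fraction` of the instantaneous inlet volumetric flow.
#'
#' @param inlet Inlet velocity [waveform()].
#' @param fraction Diverted fraction of inlet flow, in (0, 1).
#' @param inlet_width Inlet width (any length unit, same as `branch_width`).
#' @param branch_width Branch slot width.
#' @return A velocity [waveform()] for the branch slot.
#' @export
branch_outflow_waveform <- function(inlet, fraction, inlet_width, branch_width) {
  stopifnot(inherits(inlet, "waveform"))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  if (inlet_width <= 0 || branch_width <= 0) {
    stop("widths must be positive", call. = FALSE)
  }
  scale <- fraction * inlet_width / branch_width
  waveform(inlet$phases, inlet$values * scale, inlet$period, "velocity",
           note = sprintf("branch outflow: %.3g of inlet flow", fraction))
}

#' Sample a waveform to a two-column table
#' @param w A [waveform()].
#' @param n Number of samples over one period.
#' @return Tibble with columns `time_s`, `value`.
#' @export
wf_table <- function(w, n = 200) {
  t <- seq(0, w$period, length.out = n + 1)[-(n + 1)]
  tibble::tibble(time_s = t, value = wf_eval(w, t))
}

#' Export a waveform sampling as CSV
#' @param w A [waveform()].
#' @param path Output file path.
#' @param n Number of samples.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path, n = 200) {
  utils::write.csv(wf_table(w, n), path, row.names = FALSE)
  invisible(path)
}
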