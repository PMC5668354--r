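#' Construct a force trace
#'
#' A force trace is a tibble with a strictly increasing time column `t_s`
#' (seconds) and a force column `F_N` (newtons) or a photodiode-voltage column
#' `Vd_V` (volts), carrying the cantilever spec and optional event annotations
#' (named event times in seconds, e.g. `NEBD`, `metaphase_plate`,
#' `anaphase_onset`, `release`) as attributes.
#'
#' @param t_s Time stamps in seconds, strictly increasing.
#' @param F_N Force in N (give exactly one of `F_N` or `Vd_V`).
#' @param Vd_V Photodiode voltage in V.
#' @param spec Optional [cantilever_spec()].
#' @param annotations Optional named numeric vector of event times (s).
#' @return A tibble of class `force_trace`.
#' @examples
#' force_trace(0:9, F_N = rep(5e-8, 10))
#' @export
force_trace <- function(t_s, F_N = NULL, Vd_V = NULL, spec = NULL,
                        annotations = NULL) {
  if (is.null(F_N) == is.null(Vd_V)) {
    abort("give exactly one of `F_N` or `Vd_V`.",
          class = "mitomech_invalid_input")
  }
  if (length(t_s) < 2L || any(diff(t_s) <= 0)) {
    abort("`t_s` must be strictly increasing with length >= 2.",
          class = "mitomech_invalid_input")
  }
  y <- if (is.null(F_N)) Vd_V else F_N
  if (length(y) != length(t_s) || any(!is.finite(y))) {
    abort("signal must be finite and the same length as `t_s`.",
          class = "mitomech_invalid_input")
  }
  if (!is.null(annotations)) {
    if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
      abort("`annotations` must be a named numeric vector.",
            class = "mitomech_annotation_error")
    }
    if (any(annotations < min(t_s) | annotations > max(t_s))) {
      abort("annotated events must lie within the trace time span.",
            class = "mitomech_annotation_error")
    }
  }
  tr <- if (is.null(F_N)) tibble(t_s = t_s, Vd_V = Vd_V)
        else tibble(t_s = t_s, F_N = F_N)
  structure(tr,
            spec = spec,
            annotations = annotations,
            class = c("force_trace", class(tr)))
}

trace_annotations <- function(trace) attr(trace, "annotations")

#' Convert photodiode voltage to force
#'
#' Applies the optical-lever calibration: `F = k * sensitivity * Vd`, with `k`
#' the spring constant (N/m) and the deflection sensitivity in m/V.
#'
#' @param trace A [force_trace()] carrying a `Vd_V` column, or a bare numeric
#'   voltage vector.
#' @param spec A [cantilever_spec()] with `deflection_sensitivity` set;
#'   defaults to the spec attached to the trace.
#' @return The trace with `Vd_V` replaced by `F_N` (or a numeric force vector
#'   for numeric input).
#' @export
deflection_to_force <- function(trace, spec = NULL) {
  if (is.numeric(trace)) {
    if (is.null(spec) || is.null(spec$deflection_sensitivity)) {
      abort("deflection sensitivity missing from cantilever spec.",
            class = "mitomech_config_error")
    }
    return(spec$k * spec$deflection_sensitivity * trace)
  }
  stopifnot(inherits(trace, "force_trace"))
  spec <- spec %||% attr(trace, "spec")
  if (is.null(spec) || is.null(spec$deflection_sensitivity)) {
    abort("deflection sensitivity missing from cantilever spec.",
          class = "mitomech_config_error")
  }
  if (!"Vd_V" %in% names(trace)) {
    abort("trace has no `Vd_V` column.", class = "mitomech_invalid_input")
  }
  force_trace(trace$t_s,
              F_N = spec$k * spec$deflection_sensitivity * trace$Vd_V,
              spec = spec, annotations = trace_annotations(trace))
}

#' Linear drift estimate
#'
#' Drift rates in the force signal and cantilever height, typically determined
#' by probing the glass surface at the end of an experiment and assuming the
#' drift was linear in time.
#'
#' @param force_offset_rate Force drift in N/s.
#' @param height_offset_rate Height drift in um/s.
#' @param reference_times Ordered pair of probe times (s) the rates refer to.
#' @return An object of class `drift_estimate`.
#' @export
drift_estimate <- function(force_offset_rate = 0, height_offset_rate = 0,
                           reference_times = c(0, 0)) {
  if (!all(is.finite(c(force_offset_rate, height_offset_rate)))) {
    abort("drift rates must be finite.", class = "mitomech_invalid_input")
  }
  if (length(reference_times) != 2L || reference_times[2] < reference_times[1]) {
    abort("`reference_times` must be an ordered pair.",
          class = "mitomech_invalid_input")
  }
  structure(list(force_offset_rate = force_offset_rate,
                 height_offset_rate = height_offset_rate,
                 reference_times = reference_times),
            class = "drift_estimate")
}

#' Estimate force drift from a trailing glass-probe segment
#'
#' When a recording ends with the cantilever pressed on the bare glass surface,
#' the apparent force offset there, divided by the elapsed time since the
#' reference time, estimates the linear force drift rate.
#'
#' @param trace A [force_trace()] with an `F_N` column.
#' @param probe_start Time (s) at which the glass-probe segment begins.
#' @param t_ref Reference time (s) at which drift is taken to be zero
#'   (default: trace start).
#' @return A [drift_estimate()].
#' @export
estimate_drift_from_probe <- function(trace, probe_start, t_ref = NULL) {
  stopifnot(inherits(trace, "force_trace"), "F_N" %in% names(trace))
  t_ref <- t_ref %||% trace$t_s[1]
  seg <- trace$t_s >= probe_start
  if (!any(seg)) {
    abort("no samples at or after `probe_start`.",
          class = "mitomech_invalid_input")
  }
  t_probe <- mean(trace$t_s[seg])
  if (t_probe <= t_ref) {
    abort("glass probe must follow the reference time.",
          class = "mitomech_invalid_input")
  }
  drift_estimate(force_offset_rate = mean(trace$F_N[seg]) / (t_probe - t_ref),
                 reference_times = c(t_ref, t_probe))
}

#' Remove linear drift from a force trace
#'
#' Subtracts `force_offset_rate * (t - t_ref)` from the force signal, with
#' `t_ref` the first reference time of the drift estimate. Zero rates leave
#' the trace untouched.
#'
#' @param trace A [force_trace()] with an `F_N` column.
#' @param drift A [drift_estimate()].
#' @return The corrected `force_trace`.
#' @export
correct_linear_drift <- function(trace, drift) {
  stopifnot(inherits(trace, "force_trace"), inherits(drift, "drift_estimate"))
  if (!"F_N" %in% names(trace)) {
    abort("trace has no `F_N` column; convert voltage first.",
          class = "mitomech_invalid_input")
  }
  t_ref <- drift$reference_times[1]
  force_trace(trace$t_s,
              F_N = trace$F_N - drift$force_offset_rate * (trace$t_s - t_ref),
              spec = attr(trace, "spec"),
              annotations = trace_annotations(trace))
}

# Time-weighted least-squares slope of y on t; robust to irregular sampling.
ls_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Extract the equilibrium rounding force
#'
#' A confined mitotic cell relaxes to its equilibrium rounding force within
#' tens of seconds. This scans windows of length `window_s` forward in time
#' and takes the earliest window whose fitted slope magnitude is at or below
#' `slope_tol`; the equilibrium force is the mean over that window. If no
#' window qualifies the final window is used and `equilibrated` is `FALSE`.
#'
#' @param trace A [force_trace()] with an `F_N` column.
#' @param window_s Window length in seconds (default 10).
#' @param slope_tol Absolute slope tolerance in N/s; overrides
#'   `rel_slope_tol` when given.
#' @param rel_slope_tol Slope tolerance as a fraction of the window mean per
#'   second (default `1e-3`, i.e. 1% of the window mean per 10 s), evaluated
#'   per window. Tighten it (with a longer trace) when the asymptote itself
#'   is wanted to high precision.
#' @return A one-row tibble: `F_eq_N` (window mean), `se_N` (standard error of
#'   that mean), `equilibrated` (flag), `t_eq_s` (window start time).
#' @examples
#' tr <- force_trace(seq(0, 60, 0.1), F_N = 1e-7 * (1 - exp(-seq(0, 60, 0.1) / 5)))
#' extract_equilibrium_force(tr)
#' @export
extract_equilibrium_force <- function(trace, window_s = 10, slope_tol = NULL,
                                      rel_slope_tol = 1e-3) {
  stopifnot(inherits(trace, "force_trace"))
  if (!"F_N" %in% names(trace)) {
    abort("trace has no `F_N` column; convert voltage first.",
          class = "mitomech_invalid_input")
  }
  t <- trace$t_s
  y <- trace$F_N
  if (diff(range(t)) < window_s) {
    abort("trace shorter than the equilibrium window.",
          class = "mitomech_invalid_input")
  }
  n <- length(t)
  # candidate windows start at each sample whose window fits in the trace
  starts <- which(t <= t[n] - window_s)
  ends <- findInterval(t[starts] + window_s, t)
  pick <- NULL
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    if (length(idx) < 3L) next
    slope <- ls_slope(t[idx], y[idx])
    tol <- slope_tol %||% (rel_slope_tol * abs(mean(y[idx])))
    if (abs(slope) <= tol) { pick <- idx; break }
  }
  equilibrated <- !is.null(pick)
  if (!equilibrated) pick <- starts[length(starts)]:n
  f <- y[pick]
  tibble(F_eq_N = mean(f),
         se_N = sd(f) / sqrt(length(f)),
         equilibrated = equilibrated,
         t_eq_s = t[pick[1]])
}

#' Mean rounding pressure over a mitotic phase
#'
#' Averages the per-frame rounding pressure (force over contact area) over all
#' frames between two annotated events, typically metaphase-plate formation
#' and anaphase onset (the metaphase plateau).
#'
#' @param trace An annotated [force_trace()].
#' @param geometry Data frame of per-frame geometry with columns `t_s` and
#'   `A_c_um2` (contact area per frame, um^2) aligned to trace times.
#' @param phase Character pair naming the bounding events (default
#'   `c("metaphase_plate", "anaphase_onset")`).
#' @return Mean plateau pressure in Pa.
#' @export
plateau_pressure <- function(trace, geometry,
                             phase = c("metaphase_plate", "anaphase_onset")) {
  stopifnot(inherits(trace, "force_trace"), is.data.frame(geometry))
  ann <- trace_annotations(trace)
  if (is.null(ann) || !all(phase %in% names(ann))) {
    abort(paste0("events not annotated: ", paste(phase, collapse = ", ")),
          class = "mitomech_annotation_error")
  }
  t0 <- ann[[phase[1]]]; t1 <- ann[[phase[2]]]
  frames <- dplyr::inner_join(
    tibble(t_s = trace$t_s, F_N = trace$F_N),
    as_tibble(geometry)[, c("t_s", "A_c_um2")],
    by = "t_s"
  )
  frames <- dplyr::filter(frames, .data$t_s >= t0, .data$t_s <= t1)
  if (nrow(frames) == 0L) {
    abort("no frames with geometry inside the phase.",
          class = "mitomech_annotation_error")
  }
  mean(rounding_pressure(frames$F_N, frames$A_c_um2))
}

#' Mitotic phase durations
#'
#' Differences between the annotated times of nuclear envelope breakdown,
#' metaphase-plate formation and anaphase onset, in minutes.
#'
#' @param annotations Named numeric vector of event times in seconds,
#'   containing `NEBD`, `metaphase_plate` and `anaphase_onset`, or a
#'   [force_trace()] carrying such annotations.
#' @return A one-row tibble: `nebd_to_plate_min`, `plate_to_anaphase_min`.
#' @examples
#' phase_durations(c(NEBD = 0, metaphase_plate = 720, anaphase_onset = 1800))
#' @export
phase_durations <- function(annotations) {
  if (inherits(annotations, "force_trace")) {
    annotations <- trace_annotations(annotations)
  }
  needed <- c("NEBD", "metaphase_plate", "anaphase_onset")
  if (is.null(annotations) || !all(needed %in% names(annotations))) {
    abort(paste0("events required: ", paste(needed, collapse = ", ")),
          class = "mitomech_annotation_error")
  }
  tt <- annotations[needed]
  if (any(diff(tt) <= 0)) {
    abort("events must be strictly ordered NEBD < metaphase_plate < anaphase_onset.",
          class = "mitomech_annotation_error")
  }
  tibble(nebd_to_plate_min = unname(tt[2] - tt[1]) / 60,
         plate_to_anaphase_min = unname(tt[3] - tt[2]) / 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
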