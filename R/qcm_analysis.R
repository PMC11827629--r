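# QCM frequency-trace processing: Sauerbrey conversion, smoothing/baseline,
# 5-min capture slopes, concentration sensitivity, dissociation and
# regeneration, plus a synthetic trace generator driven by the transport
# simulator.

#' QCM frequency trace container
#'
#' @param times times (s), strictly increasing.
#' @param frequency resonance frequency shift (Hz).
#' @param phases optional data.frame annotating phase boundaries with
#'   columns `phase`, `start`, `end` (s); e.g. phases "capture", "rinse",
#'   "capture2".
#' @return A data.frame of class `qcm_trace` with columns `time_s`,
#'   `frequency_hz`; phases stored as an attribute.
#' @export
qcm_trace <- function(times, frequency, phases = NULL) {
  stopifnot(length(times) == length(frequency), all(diff(times) > 0))
  structure(data.frame(time_s = times, frequency_hz = frequency),
            phases = phases, class = c("qcm_trace", "data.frame"))
}

#' Sauerbrey frequency-to-mass conversion
#'
#' Areal mass change from a frequency shift using the quartz crystal
#' sensitivity constant: `dm = -C * df`. Mass added to the crystal lowers
#' the resonance frequency, hence the sign.
#'
#' @param delta_f frequency shift (Hz).
#' @param C sensitivity constant (ng Hz^-1 cm^-2); default 17.7 for a
#'   5 MHz AT-cut crystal.
#' @return Areal mass change (ng/cm^2).
#' @export
sauerbrey_mass <- function(delta_f, C = 17.7) {
  -C * delta_f
}

#' Moving-average smoothing and baseline subtraction
#'
#' Centered moving average with the stated window (100 samples in the
#' study's processing); near the edges the window shrinks to the available
#' samples. If a baseline interval is given, the mean of the smoothed trace
#' over that (pre-capture) interval is subtracted from the whole trace.
#'
#' @param trace a [qcm_trace()].
#' @param window moving-average window (samples, >= 1).
#' @param baseline_interval optional `c(t0, t1)` (s) marking the
#'   pre-capture interval whose mean defines the baseline.
#' @return A `qcm_trace` with the processed frequency.
#' @export
smooth_and_baseline <- function(trace, window = 100,
                                baseline_interval = NULL) {
  n <- nrow(trace)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window longer than trace")
  f <- trace$frequency_hz
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  cs <- cumsum(c(0, f))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1)
  hi <- pmin(i + half_hi, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  if (!is.null(baseline_interval)) {
    sel <- trace$time_s >= baseline_interval[1] &
      trace$time_s <= baseline_interval[2]
    if (!any(sel)) stop("baseline interval contains no samples")
    sm <- sm - mean(sm[sel])
  }
  qcm_trace(trace$time_s, sm, phases = attr(trace, "phases"))
}

window_mean <- function(trace, t0, t1) {
  sel <- trace$time_s >= t0 & trace$time_s <= t1
  if (!any(sel)) stop(sprintf("window [%g, %g] s out of trace range", t0, t1))
  mean(trace$frequency_hz[sel])
}

#' Five-minute capture slope of a QCM trace
#'
#' Frequency values are averaged over `avg_window` seconds ending at the
#' capture onset and again over the window ending `capture_window` seconds
#' later; the slope is their difference per elapsed time, in Hz/min. This
#' windowed-difference estimate suppresses both noise and drift.
#'
#' @param trace a [qcm_trace()].
#' @param onset capture onset time (s).
#' @param capture_window evaluation span after onset (s); default 5 min.
#' @param avg_window averaging window (s); default 30 s.
#' @return Capture slope (Hz/min), negative when mass is being captured.
#' @export
capture_slope <- function(trace, onset, capture_window = 300,
                          avg_window = 30) {
  f0 <- window_mean(trace, onset - avg_window, onset)
  f1 <- window_mean(trace, onset + capture_window - avg_window,
                    onset + capture_window)
  (f1 - f0) / (capture_window / 60)
}

#' Concentration sensitivity from capture slopes
#'
#' Ordinary least squares of capture slope against analyte concentration
#' over the points flagged as in the linear range; the fitted slope is the
#' sensor's sensitivity. Points below the linear range (sub-LOQ) are
#' excluded from the fit but reported.
#'
#' @param concentrations analyte concentrations (nM).
#' @param slopes capture slopes (Hz/min), same length.
#' @param in_range logical flags (default all TRUE); at least 3 points must
#'   be in range.
#' @return A list of class `sensitivity_curve`: `sensitivity` (Hz/min per
#'   nM), `intercept`, `r_squared`, `points` (data.frame with flags).
#' @export
sensitivity_fit <- function(concentrations, slopes, in_range = NULL) {
  stopifnot(length(concentrations) == length(slopes))
  if (is.null(in_range)) in_range <- rep(TRUE, length(slopes))
  if (sum(in_range) < 3) stop("need at least 3 in-range points")
  fit <- lm(slopes[in_range] ~ concentrations[in_range])
  structure(list(
    sensitivity = coef(fit)[[2]], intercept = coef(fit)[[1]],
    r_squared = summary(fit)$r.squared,
    points = data.frame(concentration = concentrations, slope = slopes,
                        in_range = in_range)),
    class = "sensitivity_curve")
}

phase_window <- function(trace, phase) {
  ph <- attr(trace, "phases")
  if (is.null(ph) || !phase %in% ph$phase)
    stop(sprintf("trace has no '%s' phase annotated", phase))
  ph[ph$phase == phase, c("start", "end")][1, ]
}

#' Normalized dissociation rate and regeneration recovery
#'
#' Dissociation: linear-regression slope of the frequency over the first
#' `window` seconds of the annotated rinse phase, normalized by the total
#' captured frequency shift (so traces with different loadings are
#' comparable). Recovery: the second capture cycle's frequency shift as a
#' percentage of the first cycle's.
#'
#' @param trace a [qcm_trace()] with annotated phases `"capture"` and
#'   `"rinse"`, and `"capture2"` for recovery.
#' @param window dissociation evaluation window (s); default 5 min.
#' @param avg_window averaging window for capture shifts (s).
#' @return A list of class `dissociation_result`: `dissociation_rate`
#'   (fraction of captured signal released per minute), `captured_df` (Hz),
#'   `recovery_pct` (NA when no second cycle is annotated).
#' @export
dissociation_and_regeneration <- function(trace, window = 300,
                                          avg_window = 30) {
  cap <- phase_window(trace, "capture")
  rinse <- phase_window(trace, "rinse")
  f_pre <- window_mean(trace, cap$start - avg_window, cap$start)
  f_end <- window_mean(trace, cap$end - avg_window, cap$end)
  captured <- f_pre - f_end            # positive Hz drop when mass captured
  if (abs(captured) <= .Machine$double.eps)
    stop("zero captured signal in first cycle")
  sel <- trace$time_s >= rinse$start &
    trace$time_s <= min(rinse$start + window, rinse$end)
  if (sum(sel) < 2) stop("rinse window contains too few samples")
  fit <- lm(trace$frequency_hz[sel] ~ trace$time_s[sel])
  rate <- coef(fit)[[2]] * 60 / captured   # fraction of captured / min
  recovery <- NA_real_
  ph <- attr(trace, "phases")
  if (!is.null(ph) && "capture2" %in% ph$phase) {
    cap2 <- phase_window(trace, "capture2")
    f_pre2 <- window_mean(trace, cap2$start - avg_window, cap2$start)
    f_end2 <- window_mean(trace, cap2$end - avg_window, cap2$end)
    recovery <- (f_pre2 - f_end2) / captured * 100
  }
  structure(list(dissociation_rate = rate, captured_df = captured,
                 recovery_pct = recovery),
            class = "dissociation_result")
}

#' Synthesize a QCM trace from a simulated sensor response
#'
#' Converts the surface complex density B(t) to a frequency shift via the
#' inverted Sauerbrey relation
#' `df = -B * M * 1e5 / C` (mol/m^2 times g/mol is g/m^2; 1 g/m^2 =
#' 1e5 ng/cm^2), then adds linear drift and Gaussian noise. Closes the loop
#' so the QCM analysis is testable against programmed ground truth.
#'
#' @param response a `sensor_response` (or any list with `times` and `B`).
#' @param molar_mass analyte molar mass (g/mol); default 36.7 kDa for
#'   alpha-thrombin (literature constant).
#' @param noise_sd Gaussian noise SD (Hz).
#' @param drift baseline drift (Hz/min).
#' @param C Sauerbrey constant (ng Hz^-1 cm^-2).
#' @param seed RNG seed for the noise.
#' @return A [qcm_trace()].
#' @export
synthesize_qcm <- function(response, molar_mass = 36700, noise_sd = 0,
                           drift = 0, C = 17.7, seed = 1L) {
  set.seed(seed)
  t <- response$times
  mass_ng_cm2 <- response$B * molar_mass * 1e5
  f <- -mass_ng_cm2 / C + drift * t / 60 + rnorm(length(t), 0, noise_sd)
  qcm_trace(t, f)
}
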