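# Dwell-time extraction and exponential maximum-likelihood kinetics.
#
# Bound dwells below the segment length filter are invisible, so the bound
# dwell sample is left-truncated; by memorylessness the MLE of the
# exponential mean is simply mean(d) - truncation for d >= truncation.

#' Extract bound and unbound dwell times from segmented traces
#'
#' Bound dwells come from the length-filtered segments; with the half-frame
#' continuity correction a run of n frames is scored as (n - 0.5) frame
#' intervals, the expected true duration of an event observed over n
#' majority-bound exposures. Unbound dwells are the gaps between
#' consecutive *candidate* runs (before the length filter): a discarded
#' short binding event still separates two genuine unbound episodes, and
#' bridging across it would sum several unbound dwells into one
#' (`gap_source = "segments"` restores that literal behavior for
#' comparison). Dwells touching the first or last frame are flagged
#' censored; censored dwells are excluded from fitting.
#'
#' @param segmented list of `segmented_trace` (or an `ensemble_analysis`).
#' @param c aptamer concentration (M), stored for the rate calculation.
#' @param frame_interval frame interval (s).
#' @param half_frame_correction logical; apply the (n - 0.5) frame scoring
#'   to bound dwells.
#' @param gap_source `"candidates"` (default) or `"segments"`; see above.
#' @return A list of class `dwell_set`: data.frames `bound` and `unbound`
#'   (columns duration, censored), `c`, `frame_interval`, `min_frames`
#'   (smallest surviving segment length, used for the fit truncation),
#'   `censored_fraction`.
#' @export
extract_dwells <- function(segmented, c, frame_interval,
                           half_frame_correction = TRUE,
                           gap_source = c("candidates", "segments")) {
  gap_source <- match.arg(gap_source)
  if (inherits(segmented, "ensemble_analysis")) {
    frame_interval <- segmented$frame_interval
    segmented <- segmented$segmented
  }
  stopifnot(c > 0, frame_interval > 0)
  dt <- frame_interval
  bound <- list(); unbound <- list()
  min_seg <- Inf
  for (seg in segmented) {
    n_tot <- seg$n_frames_total
    s <- seg$segments
    if (nrow(s) > 0) {
      nf <- s$n_frames
      min_seg <- min(min_seg, min(nf))
      dur <- if (half_frame_correction) (nf - 0.5) * dt else nf * dt
      cens <- s$start_frame == 0 | s$end_frame == n_tot
      bound[[length(bound) + 1]] <- data.frame(duration = dur, censored = cens)
    }
    g <- if (gap_source == "candidates") seg$candidates else seg$segments
    if (nrow(g) > 1) {
      gap_frames <- g$start_frame[-1] - g$end_frame[-nrow(g)]
      pos <- gap_frames > 0
      if (any(pos))
        unbound[[length(unbound) + 1]] <-
          data.frame(duration = gap_frames[pos] * dt,
                     censored = rep(FALSE, sum(pos)))
    }
  }
  bound <- if (length(bound)) do.call(rbind, bound)
           else data.frame(duration = numeric(0), censored = logical(0))
  unbound <- if (length(unbound)) do.call(rbind, unbound)
             else data.frame(duration = numeric(0), censored = logical(0))
  cens_frac <- if (nrow(bound)) mean(bound$censored) else NA_real_
  structure(list(bound = bound, unbound = unbound, c = c,
                 frame_interval = dt,
                 min_frames = if (is.finite(min_seg)) min_seg else NA_integer_,
                 censored_fraction = cens_frac),
            class = "dwell_set")
}

#' Left-truncated exponential fit of dwell times
#'
#' Maximum-likelihood estimate of the exponential mean from dwells observed
#' only above a truncation point: by memorylessness
#' `E[X | X > t] = t + 1/lambda`, so the MLE is the sample mean of dwells at
#' or above `truncation` minus `truncation`. The standard error is
#' `mean/sqrt(n)`. A least-squares fit to the log of a binned histogram is
#' available for comparison (`method = "histogram"`).
#'
#' @param dwells numeric dwell durations (s), uncensored.
#' @param truncation left-truncation point (s); dwells below it are
#'   discarded before fitting.
#' @param min_n minimum number of usable dwells.
#' @param side label ("bound"/"unbound") used in error messages.
#' @param method `"mle"` (default) or `"histogram"`.
#' @return A list of class `exp_fit`: `mean_dwell`, `stderr`, `n_used`,
#'   `truncation`, `method`.
#' @export
fit_exponential <- function(dwells, truncation = 0, min_n = 50,
                            side = "bound", method = c("mle", "histogram")) {
  method <- match.arg(method)
  d <- dwells[is.finite(dwells) & dwells >= truncation - 1e-12]
  n <- length(d)
  if (n < min_n)
    stop(sprintf("only %d uncensored %s dwells above truncation (need %d)",
                 n, side, min_n))
  if (method == "mle") {
    m <- mean(d) - truncation
  } else {
    h <- graphics::hist(d, breaks = "FD", plot = FALSE)
    keep <- h$counts > 0
    # count-weighted log-linear fit (var(log N) ~ 1/N)
    fit <- lm(log(h$counts[keep]) ~ h$mids[keep], weights = h$counts[keep])
    m <- -1 / coef(fit)[[2]]
  }
  if (m <= 0) stop(sprintf("non-positive fitted mean for %s dwells", side))
  structure(list(mean_dwell = m, stderr = m / sqrt(n), n_used = n,
                 truncation = truncation, method = method),
            class = "exp_fit")
}

#' Kinetic constants from one replicate's dwell fits
#'
#' `k_off = 1 / tau_b`, `k_on = 1 / (tau_ub * c)`, `K_d = k_off / k_on`.
#'
#' @param fit_bound,fit_unbound `exp_fit` objects for the bound and unbound
#'   dwell distributions.
#' @param c aptamer concentration (M), > 0.
#' @return A list of class `kinetic_estimate`: `k_off` (1/s), `k_on`
#'   (1/M/s), `K_d` (M), plus the two mean dwell times.
#' @export
kinetic_rates <- function(fit_bound, fit_unbound, c) {
  stopifnot(inherits(fit_bound, "exp_fit"), inherits(fit_unbound, "exp_fit"),
            c > 0)
  k_off <- 1 / fit_bound$mean_dwell
  k_on <- 1 / (fit_unbound$mean_dwell * c)
  structure(list(k_off = k_off, k_on = k_on, K_d = k_off / k_on,
                 tau_b = fit_bound$mean_dwell,
                 tau_ub = fit_unbound$mean_dwell, c = c),
            class = "kinetic_estimate")
}

#' Mean and SD of kinetic constants across replicates
#'
#' @param estimates list of `kinetic_estimate` (>= 1).
#' @return A list of class `kinetic_summary`: `replicates` (data.frame of
#'   per-replicate k_off, k_on, K_d), `mean` and `sd` (named vectors; `sd`
#'   is NA with a single replicate and `sd_defined` is FALSE).
#' @export
summarize_replicates <- function(estimates) {
  if (length(estimates) == 0) stop("no replicates supplied")
  reps <- do.call(rbind, lapply(estimates, function(e)
    data.frame(k_off = e$k_off, k_on = e$k_on, K_d = e$K_d)))
  m <- vapply(reps, mean, numeric(1))
  s <- if (nrow(reps) >= 2) vapply(reps, sd, numeric(1))
       else setNames(rep(NA_real_, 3), names(reps))
  structure(list(replicates = reps, mean = m, sd = s,
                 sd_defined = nrow(reps) >= 2),
            class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat("<kinetic_summary>", nrow(x$replicates), "replicate(s)\n")
  cat(sprintf("  k_off = %.3g %s %.2g 1/s\n", x$mean[["k_off"]],
              "±", x$sd[["k_off"]]))
  cat(sprintf("  k_on  = %.3g %s %.2g 1/M/s\n", x$mean[["k_on"]],
              "±", x$sd[["k_on"]]))
  cat(sprintf("  K_d   = %.3g %s %.2g nM\n", x$mean[["K_d"]] * 1e9,
              "±", x$sd[["K_d"]] * 1e9))
  invisible(x)
}

#' Full kinetic pipeline for one ensemble (one replicate)
#'
#' Convenience wrapper: threshold, segment, QC-filter, extract dwells and
#' fit both exponential means, returning the kinetic constants. Truncation
#' points default to `(min_frames - 0.5) * frame_interval` for bound dwells
#' (the shortest surviving segment under the half-frame correction) and
#' half a frame for unbound dwells (gaps shorter than that are never
#' detected).
#'
#' @param traces list of `fluor_trace` or a `fret_ensemble`.
#' @param c aptamer concentration (M).
#' @param min_frames segment length filter (frames).
#' @param min_events QC filter: molecules with fewer events are dropped.
#' @param min_n minimum dwell count per side for the exponential fits.
#' @param ... passed to [analyze_traces()].
#' @return A list of class `kinetic_estimate` (see [kinetic_rates()]) with
#'   extra elements `fits` (the two `exp_fit`s), `dwells` (the `dwell_set`),
#'   `analysis`, and `qc`.
#' @export
estimate_kinetics <- function(traces, c, min_frames = 4, min_events = 10,
                              min_n = 50, ...) {
  if (inherits(traces, "fret_ensemble")) {
    if (missing(c)) c <- traces$config$c
    traces <- traces$traces
  }
  an <- analyze_traces(traces, min_frames = min_frames, ...)
  qc <- qc_filter(an$events, min_events = min_events)
  keep <- names(an$segmented) %in% qc$kept
  dw <- extract_dwells(an$segmented[keep], c = c,
                       frame_interval = an$frame_interval)
  dt <- an$frame_interval
  trunc_b <- (min_frames - 0.5) * dt
  fb <- fit_exponential(dw$bound$duration[!dw$bound$censored],
                        truncation = trunc_b, min_n = min_n, side = "bound")
  fu <- fit_exponential(dw$unbound$duration[!dw$unbound$censored],
                        truncation = 0.5 * dt, min_n = min_n,
                        side = "unbound")
  est <- kinetic_rates(fb, fu, c)
  est$fits <- list(bound = fb, unbound = fu)
  est$dwells <- dw
  est$analysis <- an
  est$qc <- qc
  est
}
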