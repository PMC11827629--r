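# Segmentation of traces into bound/unbound episodes and classification of
# the resulting FRET populations.

#' Two-state intensity threshold for one trace
#'
#' Applies 1-D two-state K-means to the summed donor + acceptor intensity
#' and returns the midpoint of the two cluster centers. Centers are
#' initialized at the 10th and 90th percentiles of the summed signal, which
#' makes the clustering deterministic. A trace whose two centers are not
#' separated by more than three times the within-cluster robust noise
#' (residual MAD) is flagged as showing no binding; callers treat such a
#' molecule as event-free.
#'
#' @param trace a `fluor_trace`.
#' @return A list of class `intensity_threshold`: `threshold`, `centers`
#'   (sorted), `no_binding` flag.
#' @export
threshold_total_intensity <- function(trace) {
  s <- trace$donor + trace$acceptor
  if (length(s) < 10) stop("trace has fewer than 10 frames")
  init <- unname(stats::quantile(s, c(0.1, 0.9)))
  if (diff(init) == 0) {   # (near-)constant signal: nothing to cluster
    return(structure(list(threshold = init[1], centers = init,
                          no_binding = TRUE),
                     class = "intensity_threshold"))
  }
  km <- suppressWarnings(
    kmeans(s, centers = matrix(init, ncol = 1), algorithm = "Lloyd",
           iter.max = 200))
  centers <- sort(as.numeric(km$centers))
  resid <- s - as.numeric(km$centers)[km$cluster]
  noise <- mad(resid)
  gap <- centers[2] - centers[1]
  tol <- 1e-8 * max(abs(s), 1)
  no_binding <- gap <= 3 * noise + tol
  structure(list(threshold = mean(centers), centers = centers,
                 no_binding = no_binding),
            class = "intensity_threshold")
}

#' Segment a trace at an intensity threshold
#'
#' Frames with donor + acceptor above the threshold form candidate
#' high-intensity runs. Runs lasting more than three consecutive frames
#' (i.e. at least `min_frames`, default 4) are kept as binding segments;
#' shorter runs are discarded, not merged. Candidate runs of every length
#' are also retained: the gaps between consecutive candidates are the true
#' unbound episodes and are what the dwell-time analysis consumes.
#'
#' @param trace a `fluor_trace`.
#' @param threshold an `intensity_threshold` or a numeric threshold.
#' @param min_frames minimum number of frames for a segment to survive the
#'   length filter. The default 4 reads "more than three consecutive
#'   frames" strictly; pass 3 for the inclusive reading.
#' @return A list of class `segmented_trace`: `molecule_id`, `threshold`,
#'   `segments` and `candidates` (data.frames with 0-based half-open
#'   `start_frame`, `end_frame` and `n_frames`), `n_frames_total`.
#' @export
segment_trace <- function(trace, threshold, min_frames = 4) {
  thr <- if (inherits(threshold, "intensity_threshold")) threshold
         else list(threshold = threshold, no_binding = FALSE)
  n <- length(trace$donor)
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      n_frames = integer(0))
  if (isTRUE(thr$no_binding)) {
    return(structure(list(molecule_id = trace$molecule_id,
                          threshold = thr$threshold, segments = empty,
                          candidates = empty, n_frames_total = n),
                     class = "segmented_trace"))
  }
  high <- (trace$donor + trace$acceptor) > thr$threshold
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  candidates <- data.frame(start_frame = starts[keep], end_frame = ends[keep],
                           n_frames = r$lengths[keep])
  segments <- candidates[candidates$n_frames >= min_frames, , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(molecule_id = trace$molecule_id, threshold = thr$threshold,
                 segments = segments, candidates = candidates,
                 n_frames_total = n),
            class = "segmented_trace")
}

#' Per-trace background from below-threshold frames
#'
#' Robust background estimate per channel: the median over frames whose
#' summed intensity is below the threshold. Falls back to the whole-trace
#' median when no frame is below threshold.
#'
#' @param trace a `fluor_trace`.
#' @param threshold numeric threshold or `intensity_threshold`.
#' @return Named numeric vector `c(donor =, acceptor =)`.
#' @export
trace_background <- function(trace, threshold) {
  thr <- if (inherits(threshold, "intensity_threshold")) threshold$threshold
         else threshold
  low <- (trace$donor + trace$acceptor) <= thr
  if (!any(low)) low <- rep(TRUE, length(trace$donor))
  c(donor = median(trace$donor[low]), acceptor = median(trace$acceptor[low]))
}

#' Mean FRET efficiency of one binding segment
#'
#' Per-frame apparent FRET efficiency E = I_A / (I_A + I_D) on
#' background-subtracted intensities, averaged over the segment and clipped
#' to \[0, 1\]. Frames with non-positive total intensity after background
#' subtraction are excluded from the average.
#'
#' @param trace a `fluor_trace`.
#' @param segment one row of a `segments` data.frame (or any list with
#'   0-based half-open `start_frame`, `end_frame`).
#' @param background named vector from [trace_background()]; defaults to no
#'   subtraction.
#' @return Mean FRET efficiency (scalar in \[0, 1\]).
#' @export
event_fret <- function(trace, segment, background = c(donor = 0, acceptor = 0)) {
  i <- seq.int(segment$start_frame + 1, segment$end_frame)
  if (segment$start_frame < 0 || segment$end_frame > length(trace$donor))
    stop("segment out of trace bounds")
  id <- trace$donor[i] - background[["donor"]]
  ia <- trace$acceptor[i] - background[["acceptor"]]
  tot <- id + ia
  ok <- tot > 0
  if (!any(ok)) stop("all frames in segment have non-positive total intensity")
  e <- mean(ia[ok] / tot[ok])
  min(max(e, 0), 1)
}

#' Segment a whole ensemble and tabulate binding events
#'
#' Runs [threshold_total_intensity()], [segment_trace()] and [event_fret()]
#' over a list of traces and returns the per-event table the downstream
#' kinetic and population analyses consume.
#'
#' @param traces list of `fluor_trace` (e.g. `ensemble$traces`).
#' @param min_frames passed to [segment_trace()].
#' @param donor_only_cut events with mean FRET below this value are labeled
#'   `"donor_only"`, the rest `"fret_event"`.
#' @param subtract_background logical; subtract the per-trace
#'   below-threshold median background before computing FRET.
#' @return A list of class `ensemble_analysis`: `events` (data.frame with
#'   molecule_id, start_frame, end_frame, n_frames, duration_s, mean_fret,
#'   label), `segmented` (list of `segmented_trace`), `frame_interval`.
#' @export
analyze_traces <- function(traces, min_frames = 4, donor_only_cut = 0.15,
                           subtract_background = TRUE) {
  stopifnot(length(traces) >= 1)
  dt <- traces[[1]]$frame_interval
  segmented <- vector("list", length(traces))
  rows <- vector("list", length(traces))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    thr <- threshold_total_intensity(tr)
    seg <- segment_trace(tr, thr, min_frames = min_frames)
    segmented[[k]] <- seg
    if (nrow(seg$segments) == 0) next
    bg <- if (subtract_background) trace_background(tr, thr)
          else c(donor = 0, acceptor = 0)
    fr <- vapply(seq_len(nrow(seg$segments)), function(j)
      event_fret(tr, seg$segments[j, ], background = bg), numeric(1))
    rows[[k]] <- data.frame(
      molecule_id = tr$molecule_id,
      start_frame = seg$segments$start_frame,
      end_frame = seg$segments$end_frame,
      n_frames = seg$segments$n_frames,
      duration_s = seg$segments$n_frames * dt,
      mean_fret = fr,
      label = ifelse(fr < donor_only_cut, "donor_only", "fret_event"),
      stringsAsFactors = FALSE)
  }
  names(segmented) <- vapply(traces, `[[`, "", "molecule_id")
  events <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(events)) events <- data.frame(
    molecule_id = character(0), start_frame = integer(0),
    end_frame = integer(0), n_frames = integer(0), duration_s = numeric(0),
    mean_fret = numeric(0), label = character(0))
  rownames(events) <- NULL
  structure(list(events = events, segmented = segmented,
                 frame_interval = dt),
            class = "ensemble_analysis")
}

#' Fit and classify FRET populations with a Gaussian mixture model
#'
#' Fits Gaussian mixtures with 1 to `max_components` components (unequal
#' variances) to the per-event mean FRET efficiencies, selecting the
#' component count by BIC, and uses the fitted mixture to *classify* the
#' events into populations. Components whose mean lies below
#' `donor_only_cut` form the donor-only population (absent/bleached
#' acceptor, FRET near 0); all others form the FRET-event population. Both
#' the raw mixture components and the classified-population summaries
#' (empirical weight, mean and SD of the assigned events) are reported; the
#' population summaries are what correspond to the peaks of the event
#' histogram. The fit is regularized with a conjugate prior on the
#' variances: clipping at FRET 0 gives the donor-only events a point mass
#' at exactly 0 on which an unregularized mixture likelihood degenerates.
#'
#' @param events numeric vector of per-event mean FRET efficiencies
#'   (at least 20).
#' @param max_components maximum number of mixture components.
#' @param donor_only_cut components with mean below this are donor-only.
#' @return A list of class `fret_population_model`: `components`
#'   (data.frame weight/mean/sd/label, sorted by mean, weights sum to 1),
#'   `populations` (data.frame label/weight/mean/sd over classified
#'   events), `n_events_used`, `bic`.
#' @export
fit_fret_populations <- function(events, max_components = 3,
                                 donor_only_cut = 0.15) {
  events <- events[is.finite(events)]
  if (length(events) < 20) stop("need at least 20 events for a mixture fit")
  fit <- Mclust(events, G = seq_len(max_components), modelNames = "V",
                verbose = FALSE, prior = mclust::priorControl())
  if (is.null(fit)) stop("mixture fit failed")
  comp <- data.frame(weight = fit$parameters$pro,
                     mean = fit$parameters$mean,
                     sd = sqrt(fit$parameters$variance$sigmasq))
  labels <- ifelse(comp$mean < donor_only_cut, "donor_only", "fret_event")
  ev_label <- labels[fit$classification]
  pops <- do.call(rbind, lapply(unique(labels), function(l) {
    x <- events[ev_label == l]
    data.frame(label = l, weight = length(x) / length(events),
               mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)
  }))
  comp$label <- labels
  if (nrow(comp) > 1) comp <- comp[order(comp$mean), , drop = FALSE]
  comp$weight <- comp$weight / sum(comp$weight)
  rownames(comp) <- rownames(pops) <- NULL
  structure(list(components = comp, populations = pops,
                 n_events_used = length(events), bic = fit$bic),
            class = "fret_population_model")
}

#' @export
print.fret_population_model <- function(x, ...) {
  cat("<fret_population_model> fitted on", x$n_events_used, "events\n")
  cat("mixture components:\n")
  print(x$components, digits = 3)
  cat("classified populations:\n")
  print(x$populations, digits = 3)
  invisible(x)
}

#' Molecule-level quality filter on event counts
#'
#' Removes molecules with fewer than `min_events` surviving binding events,
#' mirroring the study's rejection of molecules with fewer than 10 events.
#'
#' @param events event table from [analyze_traces()].
#' @param min_events minimum events per molecule to keep it.
#' @return A list: `events` (filtered table), `kept`/`rejected` (molecule
#'   ids), `n_kept`, `n_rejected`.
#' @export
qc_filter <- function(events, min_events = 10) {
  if (nrow(events) == 0)
    return(list(events = events, kept = character(0), rejected = character(0),
                n_kept = 0L, n_rejected = 0L))
  counts <- table(events$molecule_id)
  kept <- names(counts)[counts >= min_events]
  rejected <- names(counts)[counts < min_events]
  list(events = events[events$molecule_id %in% kept, , drop = FALSE],
       kept = kept, rejected = rejected,
       n_kept = length(kept), n_rejected = length(rejected))
}
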