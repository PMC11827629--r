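test_that("two-level signals threshold at the midpoint with exact classification", {
  tr <- square_trace(200, 1200)
  thr <- threshold_total_intensity(tr)
  expect_false(thr$no_binding)
  expect_equal(thr$threshold, 700)
  seg <- segment_trace(tr, thr, min_frames = 4)
  s <- tr$donor + tr$acceptor
  expect_equal(sum(seg$segments$n_frames), sum(s > 700))
})

test_that("noisy two-level thresholding misclassifies < 0.1% of frames", {
  set.seed(5)
  truth <- rep(rep(c(FALSE, TRUE), length.out = 60), each = 50)  # 3000 frames
  s <- ifelse(truth, rnorm(3000, 1000, 50), rnorm(3000, 200, 30))
  tr <- structure(list(molecule_id = "m", frame_interval = 0.1,
                       donor = s / 2, acceptor = s / 2),
                  class = "fluor_trace")
  thr <- threshold_total_intensity(tr)
  called <- s > thr$threshold
  # oracle: classify by distance to the true level means
  oracle <- abs(s - 1000) < abs(s - 200)
  expect_lt(mean(called != oracle), 0.001)
  expect_lt(mean(called != truth), 0.001)
})

test_that("degenerate traces are flagged as showing no binding", {
  tr <- structure(list(molecule_id = "m", frame_interval = 0.1,
                       donor = rep(100, 50), acceptor = rep(100, 50)),
                  class = "fluor_trace")
  thr <- threshold_total_intensity(tr)
  expect_true(thr$no_binding)
  expect_equal(nrow(segment_trace(tr, thr)$segments), 0L)

  set.seed(6)  # pure noise, no intensity states
  tr$donor <- rnorm(50, 100, 10); tr$acceptor <- rnorm(50, 100, 10)
  expect_true(threshold_total_intensity(tr)$no_binding)
})

test_that("threshold is equivariant under an affine intensity shift", {
  set.seed(8)
  truth <- rep(rep(c(FALSE, TRUE), length.out = 20), each = 25)
  s <- ifelse(truth, rnorm(500, 1000, 50), rnorm(500, 200, 30))
  tr <- structure(list(molecule_id = "m", frame_interval = 0.1,
                       donor = s / 2, acceptor = s / 2),
                  class = "fluor_trace")
  t0 <- threshold_total_intensity(tr)$threshold
  tr$donor <- tr$donor + 150; tr$acceptor <- tr$acceptor + 150
  expect_equal(threshold_total_intensity(tr)$threshold, t0 + 300,
               tolerance = 1e-10)
})

test_that("segment length filter keeps runs of min_frames and longer", {
  high <- c(rep(FALSE, 10), rep(TRUE, 3), rep(FALSE, 10), rep(TRUE, 4),
            rep(FALSE, 10))
  s <- ifelse(high, 1000, 100)
  tr <- structure(list(molecule_id = "m", frame_interval = 0.1,
                       donor = s / 2, acceptor = s / 2),
                  class = "fluor_trace")
  seg <- segment_trace(tr, 500, min_frames = 4)
  expect_equal(nrow(seg$segments), 1L)       # 3-frame run discarded
  expect_equal(seg$segments$n_frames, 4L)
  expect_equal(seg$segments$start_frame, 23L)
  expect_equal(nrow(seg$candidates), 2L)     # but retained as a candidate
  seg3 <- segment_trace(tr, 500, min_frames = 3)
  expect_equal(nrow(seg3$segments), 2L)      # inclusive reading

  s_low <- rep(100, 30)
  tr$donor <- s_low / 2; tr$acceptor <- s_low / 2
  expect_equal(nrow(segment_trace(tr, 500)$segments), 0L)
})

test_that("segmentation equals the ground-truth run-length oracle on noiseless traces", {
  for (seed in 1:5) {
    cfg <- noiseless_config(n_frames = 1500, seed = seed)
    e <- simulate_ensemble(cfg, 3)
    for (id in names(e$traces)) {
      tr <- e$traces[[id]]
      thr <- threshold_total_intensity(tr)
      if (thr$no_binding) next
      seg <- segment_trace(tr, thr)
      orc <- oracle_segments(e$truth$paths[[id]], cfg, thr$threshold)
      expect_equal(seg$segments$start_frame, orc$start_frame)
      expect_equal(seg$segments$end_frame, orc$end_frame)
    }
  }
})

test_that("event FRET is the clipped mean of per-frame acceptor fractions", {
  tr <- structure(list(molecule_id = "m", frame_interval = 0.1,
                       donor = rep(62, 10), acceptor = rep(38, 10)),
                  class = "fluor_trace")
  seg <- list(start_frame = 0, end_frame = 10)
  expect_equal(event_fret(tr, seg), 0.38)
  tr$acceptor <- rep(0, 10)
  expect_equal(event_fret(tr, seg), 0)        # donor-only
  tr$acceptor <- tr$donor
  expect_equal(event_fret(tr, seg), 0.5)
  expect_error(event_fret(tr, list(start_frame = 0, end_frame = 99)),
               "bounds")
  tr$acceptor <- rep(-100, 10)                # non-positive totals excluded
  expect_error(event_fret(tr, seg), "non-positive")
})

test_that("mixture classifier recovers two planted FRET populations", {
  set.seed(7)
  x <- c(rnorm(300, 0, 0.05), rnorm(700, 0.38, 0.14))
  fp <- fit_fret_populations(x)
  expect_equal(sum(fp$components$weight), 1)
  expect_equal(sum(fp$populations$weight), 1)
  pops <- fp$populations
  expect_lt(abs(pops$mean[pops$label == "donor_only"] - 0), 0.02)
  expect_lt(abs(pops$mean[pops$label == "fret_event"] - 0.38), 0.02)
})

test_that("single-component fit returns the sample mean", {
  set.seed(9)
  x <- rnorm(500, 0.4, 0.1)
  fp <- fit_fret_populations(x, max_components = 1)
  expect_equal(fp$components$mean, mean(x), tolerance = 1e-6)
  expect_error(fit_fret_populations(rnorm(10)), "at least 20")
})

test_that("molecule QC drops molecules below the event-count floor", {
  ev <- data.frame(molecule_id = rep(c("a", "b"), c(9, 10)),
                   mean_fret = runif(19))
  qc <- qc_filter(ev, min_events = 10)
  expect_equal(qc$kept, "b")
  expect_equal(qc$rejected, "a")
  expect_equal(nrow(qc$events), 10L)

  empty <- qc_filter(ev[0, ], min_events = 10)
  expect_equal(nrow(empty$events), 0L)
  expect_equal(empty$n_kept + empty$n_rejected, 0L)
})
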