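make_seg <- function(segments, candidates = segments, n_total = 1000) {
  structure(list(molecule_id = "m", threshold = 500,
                 segments = segments, candidates = candidates,
                 n_frames_total = n_total),
            class = "segmented_trace")
}

test_that("dwell extraction converts frame spans and flags boundary censoring", {
  seg <- make_seg(data.frame(start_frame = c(100, 130),
                             end_frame = c(110, 140),
                             n_frames = c(10L, 10L)))
  dw <- extract_dwells(list(seg), c = 5e-9, frame_interval = 0.1)
  expect_equal(dw$unbound$duration, 2.0)          # 20-frame gap at 0.1 s
  expect_equal(dw$bound$duration, c(0.95, 0.95))  # half-frame correction
  expect_false(any(dw$bound$censored))

  seg0 <- make_seg(data.frame(start_frame = c(0, 50),
                              end_frame = c(10, 60),
                              n_frames = c(10L, 10L)))
  dw <- extract_dwells(list(seg0), c = 5e-9, frame_interval = 0.1)
  expect_equal(dw$bound$censored, c(TRUE, FALSE)) # touches first frame

  dw_raw <- extract_dwells(list(seg), c = 5e-9, frame_interval = 0.1,
                           half_frame_correction = FALSE)
  expect_equal(dw_raw$bound$duration, c(1.0, 1.0))
})

test_that("unbound gaps come from candidate runs, not length-filtered segments", {
  # a short (discarded) event sits inside a long gap: literal segment gaps
  # would bridge it into one 30-frame dwell
  cand <- data.frame(start_frame = c(100, 120, 140),
                     end_frame = c(110, 122, 150),
                     n_frames = c(10L, 2L, 10L))
  seg <- make_seg(cand[cand$n_frames >= 4, ], cand)
  dw <- extract_dwells(list(seg), c = 5e-9, frame_interval = 0.1)
  expect_equal(sort(dw$unbound$duration), c(1.0, 1.8))
  dw_lit <- extract_dwells(list(seg), c = 5e-9, frame_interval = 0.1,
                           gap_source = "segments")
  expect_equal(dw_lit$unbound$duration, 3.0)
})

test_that("interior dwells of noiseless ensembles match ground truth to one frame", {
  cfg <- noiseless_config(n_frames = 3000, seed = 11)
  e <- simulate_ensemble(cfg, 5)
  an <- analyze_traces(e$traces)
  dw <- extract_dwells(an, c = cfg$c)
  truth_b <- unlist(lapply(e$truth$paths, function(p) {
    b <- p[p$state == "bound" & p$start > 0 & p$end < 300, ]
    (b$end - b$start)
  }))
  truth_b <- truth_b[truth_b >= 4 * 0.1]  # events long enough to survive
  obs <- dw$bound$duration[!dw$bound$censored]
  # counts agree up to events within a frame of the filter edge, and the
  # dwell distributions agree to frame quantization
  expect_lt(abs(length(obs) - length(truth_b)) / length(truth_b), 0.15)
  expect_lt(abs(mean(obs) - mean(truth_b)), 0.15)
  expect_lt(abs(median(obs) - median(truth_b)), 0.15)
})

test_that("left-truncated exponential MLE is unbiased within 3 SE at n = 10000", {
  set.seed(13)
  d <- rexp(30000, rate = 0.5)
  d <- d[d >= 0.4][1:10000]
  fit <- fit_exponential(d, truncation = 0.4)
  expect_equal(fit$n_used, 10000L)
  expect_lt(abs(fit$mean_dwell - 2.0), 3 * fit$stderr)

  # truncation 0 reduces to the sample mean
  x <- rexp(200, 1)
  expect_equal(fit_exponential(x, truncation = 0, min_n = 50)$mean_dwell,
               mean(x))
  expect_error(fit_exponential(rexp(10, 1), min_n = 50, side = "unbound"),
               "unbound")
})

test_that("histogram fit agrees with the MLE on clean exponential data", {
  set.seed(14)
  d <- rexp(20000, rate = 0.7)
  m1 <- fit_exponential(d, truncation = 0)$mean_dwell
  m2 <- fit_exponential(d, truncation = 0, method = "histogram")$mean_dwell
  expect_lt(abs(m2 - m1) / m1, 0.1)
})

test_that("kinetic rates follow the reciprocal dwell-time definitions", {
  fb <- structure(list(mean_dwell = 1.429, stderr = 0.01, n_used = 1000,
                       truncation = 0.35, method = "mle"), class = "exp_fit")
  fu <- structure(list(mean_dwell = 2.857, stderr = 0.02, n_used = 1000,
                       truncation = 0.05, method = "mle"), class = "exp_fit")
  est <- kinetic_rates(fb, fu, c = 5e-9)
  expect_equal(est$k_off, 1 / 1.429)                    # ~0.70 1/s
  expect_equal(est$k_on, 1 / (2.857 * 5e-9))            # ~7.0e7 1/M/s
  expect_equal(est$K_d, est$k_off / est$k_on)           # identity, ~10 nM
  expect_equal(est$K_d * 1e9, 10, tolerance = 0.01)
})

test_that("replicate summaries report mean and sample SD", {
  mk <- function(k_off) structure(list(k_off = k_off, k_on = 7e7,
                                       K_d = k_off / 7e7),
                                  class = "kinetic_estimate")
  s <- summarize_replicates(lapply(c(0.6, 0.7, 0.8), mk))
  expect_equal(unname(s$mean["k_off"]), 0.7)
  expect_equal(unname(s$sd["k_off"]), 0.1)
  s1 <- summarize_replicates(list(mk(0.7)))
  expect_false(s1$sd_defined)
  expect_true(is.na(s1$sd["k_off"]))
  s0 <- summarize_replicates(lapply(c(0.7, 0.7, 0.7), mk))
  expect_equal(unname(s0$sd["k_off"]), 0)
  expect_error(summarize_replicates(list()), "no replicates")
})
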