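test_that("Sauerbrey conversion is linear with the stated constant and sign", {
  expect_equal(sauerbrey_mass(-1), 17.7)    # 1 Hz drop = 17.7 ng/cm^2 added
  expect_equal(sauerbrey_mass(0), 0)
  expect_equal(sauerbrey_mass(-10), 177)
  expect_equal(sauerbrey_mass(5), -88.5)    # mass loss raises frequency
})

test_that("moving average preserves constants and reduces noise as expected", {
  tt <- seq(0, 999)
  tr <- qcm_trace(tt, rep(5, 1000))
  expect_equal(smooth_and_baseline(tr, window = 100)$frequency_hz,
               rep(5, 1000))
  expect_equal(smooth_and_baseline(tr, window = 1)$frequency_hz,
               rep(5, 1000))
  expect_error(smooth_and_baseline(qcm_trace(1:10, 1:10), window = 100),
               "longer than trace")

  set.seed(21)  # step + white noise: plateau SD shrinks ~ 1/sqrt(window)
  f <- c(rep(0, 500), rep(-5, 500)) + rnorm(1000, 0, 0.2)
  sm <- smooth_and_baseline(qcm_trace(tt, f), window = 100)
  expect_lt(sd(sm$frequency_hz[150:350]), 0.03)

  bl <- smooth_and_baseline(qcm_trace(tt, f + 100), window = 100,
                            baseline_interval = c(100, 400))
  expect_lt(abs(mean(bl$frequency_hz[150:350])), 0.05)
})

test_that("capture slope recovers linear trends and ignores offsets", {
  tt <- seq(0, 900)
  tr <- qcm_trace(tt, -0.5 / 60 * tt)       # -0.5 Hz/min ramp
  expect_equal(capture_slope(tr, onset = 100), -0.5, tolerance = 1e-9)
  expect_equal(capture_slope(qcm_trace(tt, rep(3, 901)), onset = 100), 0)
  tr2 <- qcm_trace(tt, -0.5 / 60 * tt + 42) # baseline independence
  expect_equal(capture_slope(tr2, onset = 100),
               capture_slope(tr, onset = 100))
  expect_error(capture_slope(tr, onset = 880), "out of trace range")
})

test_that("sensitivity fit recovers an exact line and rejects short inputs", {
  conc <- c(1.65, 5, 10, 16.5)
  # suppressWarnings: lm warns that the noise-free fit is exact
  sf <- suppressWarnings(sensitivity_fit(conc, -0.04 * conc))
  expect_equal(sf$sensitivity, -0.04)
  expect_equal(sf$intercept, 0, tolerance = 1e-12)
  expect_equal(sf$r_squared, 1)
  expect_error(sensitivity_fit(c(1, 2), c(-1, -2)), "at least 3")
  # sub-LOQ points are excluded from the fit but reported
  sf2 <- suppressWarnings(
    sensitivity_fit(c(0.3, conc), c(0.05, -0.04 * conc),
                    in_range = c(FALSE, rep(TRUE, 4))))
  expect_equal(sf2$sensitivity, -0.04)
  expect_equal(sum(!sf2$points$in_range), 1L)
})

two_cycle_trace <- function(second_scale = 1) {
  # piecewise: baseline, capture to -10 Hz, rinse back, second capture
  tt <- seq(0, 2400)
  f <- numeric(length(tt))
  f[tt >= 300 & tt < 600] <- -10 * (tt[tt >= 300 & tt < 600] - 300) / 300
  f[tt >= 600 & tt < 1200] <- -10 + 8 * (tt[tt >= 600 & tt < 1200] - 600) / 600
  f[tt >= 1200 & tt < 1500] <- -2
  i <- tt >= 1500 & tt < 1800
  f[i] <- -2 - second_scale * 10 * (tt[i] - 1500) / 300
  f[tt >= 1800] <- -2 - second_scale * 10
  phases <- data.frame(phase = c("capture", "rinse", "capture2"),
                       start = c(300, 600, 1500), end = c(600, 1200, 1800))
  qcm_trace(tt, f, phases = phases)
}

test_that("dissociation rate is normalized and recovery compares capture cycles", {
  tr <- two_cycle_trace(1)
  d <- dissociation_and_regeneration(tr)
  expect_equal(d$recovery_pct, 100, tolerance = 0.02)   # identical cycles
  # captured shift: 30-s windowed means straddle the ramp end (~9.5 Hz)
  expect_equal(d$captured_df, 9.5, tolerance = 0.01)
  # rinse slope +8 Hz / 600 s, normalized by the captured shift
  expect_equal(d$dissociation_rate, (8 / 600 * 60) / d$captured_df,
               tolerance = 1e-6)

  d79 <- dissociation_and_regeneration(two_cycle_trace(0.79))
  expect_equal(d79$recovery_pct, 79, tolerance = 0.02)

  no_rinse <- qcm_trace(0:100, rep(0, 101),
                        phases = data.frame(phase = "capture", start = 10,
                                            end = 50))
  expect_error(dissociation_and_regeneration(no_rinse), "rinse")
  flat <- qcm_trace(0:2400, rep(0, 2401),
                    phases = data.frame(phase = c("capture", "rinse"),
                                        start = c(300, 600),
                                        end = c(600, 1200)))
  expect_error(dissociation_and_regeneration(flat), "zero captured")
})

test_that("synthetic QCM traces invert back through Sauerbrey", {
  resp <- list(times = seq(0, 100, 0.5), B = seq(0, 1e-10, length.out = 201))
  q <- synthesize_qcm(resp, molar_mass = 36700, noise_sd = 0, drift = 0)
  mass <- sauerbrey_mass(q$frequency_hz)            # ng/cm^2
  expect_equal(mass, resp$B * 36700 * 1e5, tolerance = 1e-9)
  # drift only: linear baseline of the programmed slope
  q <- synthesize_qcm(list(times = 0:600, B = rep(0, 601)), noise_sd = 0,
                      drift = 0.1)
  expect_equal(coef(lm(q$frequency_hz ~ q$time_s))[[2]] * 60, 0.1,
               tolerance = 1e-9)
})

test_that("programmed capture slopes survive the synthesize-analyze round trip", {
  tt <- seq(0, 600)
  a <- 0.5 / 60 * 17.7 / (36700 * 1e5)    # B ramp giving -0.5 Hz/min
  resp <- list(times = tt, B = a * tt)
  for (seed in 1:3) {
    q <- synthesize_qcm(resp, noise_sd = 0.1, seed = seed)
    cs <- capture_slope(smooth_and_baseline(q, window = 100), onset = 150)
    expect_lt(abs(cs - (-0.5)) / 0.5, 0.05)
  }
})
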