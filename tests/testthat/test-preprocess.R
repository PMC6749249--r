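test_that("low-pass passes DC and high-pass removes it", {
  tr <- signal_trace(rep(2, 200), rate = 4, kind = "GSR")
  lo <- butterworth(tr, filter_spec(1, 0.5, "lowpass"))
  expect_equal(lo$values, rep(2, 200), tolerance = 1e-8)
  hi <- butterworth(tr, filter_spec(1, 0.05, "highpass"))
  expect_lt(max(abs(hi$values)), 1e-6)
})

test_that("stop-band attenuation matches the analytic Butterworth response", {
  # order-2 low-pass, cut-off 1 Hz, probe tone at 3 Hz sampled at 128 Hz:
  # |H|^2 = 1 / (1 + (f/fc)^(2n)) = 1/82 per pass, applied twice by the
  # forward-backward filter.
  fs <- 128; fc <- 1; f <- 3
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  tr <- signal_trace(sin(2 * pi * f * t), rate = fs, kind = "GSR")
  out <- butterworth(tr, filter_spec(2, fc, "lowpass"))
  mid <- t > 5 & t < 25
  a <- 2 * mean(out$values[mid] * sin(2 * pi * f * t[mid]))
  b <- 2 * mean(out$values[mid] * cos(2 * pi * f * t[mid]))
  measured <- sqrt(a^2 + b^2)
  expected <- 1 / (1 + (f / fc)^4)   # squared magnitude (two passes)
  expect_equal(measured, expected, tolerance = 0.05)
})

test_that("filtering is linear and clamps cut-offs above Nyquist", {
  set.seed(1)
  x <- rnorm(400); y <- rnorm(400)
  spec <- filter_spec(1, 0.3, "highpass")
  fx <- butterworth(signal_trace(x, 4, kind = "GSR"), spec)$values
  fy <- butterworth(signal_trace(y, 4, kind = "GSR"), spec)$values
  fxy <- butterworth(signal_trace(2 * x + 3 * y, 4, kind = "GSR"), spec)$values
  expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-9)
  # 5 Hz cut-off on a 4 Hz stream is unrealizable; it is clamped, logged,
  # and acts as a near-pass-through
  tr <- signal_trace(x, 4, kind = "GSR")
  expect_message(out <- butterworth(tr, filter_spec(1, 5, "lowpass")),
                 "clamped")
  expect_equal(length(out$values), 400)
  expect_error(butterworth(signal_trace(c(1, 2), 4, kind = "GSR"),
                           filter_spec(1, 0.5, "lowpass")), "too short")
})

test_that("phasic/tonic decomposition reconstructs the filtered signal", {
  ses <- generate_session(session_spec(duration = 300, n_events = 3, seed = 2))
  parts <- suppressMessages(preprocess_gsr(ses$gsr))
  expect_equal(parts$phasic$values + parts$tonic$values,
               parts$filtered$values, tolerance = 1e-9)
  # constant input: phasic ~ 0, tonic ~ input
  const <- signal_trace(rep(2.5, 400), 4, kind = "GSR")
  pc <- suppressMessages(preprocess_gsr(const))
  expect_lt(max(abs(pc$phasic$values)), 1e-6)
  expect_equal(pc$tonic$values, rep(2.5, 400), tolerance = 1e-6)
})

test_that("phasic component retains the injected event bumps", {
  # the two zero-phase passes of the 0.05 Hz separation high-pass attenuate
  # a canonical response (rise 4 s, half-recovery 5 s) to roughly 40% of
  # its amplitude but keep it at the onset, far above the flat background
  ses <- generate_session(session_spec(duration = 300, n_events = 2, seed = 4,
                                       noise_sd_gsr = 0, noise_sd_st = 0))
  parts <- suppressMessages(preprocess_gsr(ses$gsr))
  t <- trace_times(ses$gsr)
  near <- rep(FALSE, length(t))
  for (k in seq_len(2)) {
    win <- t >= ses$truth$onset[k] & t <= ses$truth$onset[k] + 6
    near <- near | (t >= ses$truth$onset[k] - 10 &
                    t <= ses$truth$onset[k] + 40)
    expect_gt(max(parts$phasic$values[win]), 0.3 * ses$truth$amplitude[k])
  }
  expect_lt(max(abs(parts$phasic$values[!near])), 0.05)
})

test_that("filtered ST tracks a downward ramp; band-pass flags its onset", {
  # 33 degC baseline with a linear downward ramp between 100 and 110 s
  t <- seq(0, 200 - 0.25, by = 0.25)
  st <- 33 - 0.05 * pmin(pmax(t - 100, 0), 10)
  tr <- signal_trace(st, 4, kind = "ST")
  # the noise-filtered (low-passed) temperature keeps the analytic ramp
  # derivative sign over the whole interior — this is the channel the
  # temperature-decrease rule reads
  low <- butterworth(tr, filter_spec(2, 1, "lowpass"))
  d_low <- diff(low$values)
  interior <- t[-1] > 101 & t[-1] < 109
  expect_true(all(d_low[interior] < 0))
  # the band-passed signal reacts with a negative derivative at the ramp
  # onset, then returns within the ramp (high-pass behaviour)
  band <- preprocess_st(tr)
  d_band <- diff(band$values)
  early <- t[-1] > 100.5 & t[-1] < 102.5
  expect_true(all(d_band[early] < 0))
  # constant input maps to ~0
  flat <- preprocess_st(signal_trace(rep(33, 400), 4, kind = "ST"))
  expect_lt(max(abs(flat$values)), 1e-6)
  expect_equal(flat$rate, 4)
})

test_that("downsampling to 1 Hz takes window means and spline-fills edges", {
  expect_equal(downsample_1hz(signal_trace(rep(2.5, 8), 4, kind = "GSR"))$values,
               c(2.5, 2.5))
  expect_equal(downsample_1hz(signal_trace(1:4, 4, kind = "GSR"))$values, 2.5)
  # 600 s at 4 Hz -> exactly 600 rows at 1 Hz
  long <- signal_trace(rnorm(2400), 4, kind = "GSR")
  out <- downsample_1hz(long)
  expect_equal(length(out$values), 600)
  expect_equal(out$rate, 1)
  # full windows preserve means exactly
  expect_equal(out$values[3], mean(long$values[9:12]))
  # partial trailing window: natural spline through complete-window means
  # (1..10 at 4 Hz: means 2.5, 6.5, extrapolated edge 10.5)
  part <- downsample_1hz(signal_trace(1:10, 4, kind = "GSR"))
  expect_equal(part$values, c(2.5, 6.5, 10.5))
  expect_error(downsample_1hz(signal_trace(1:2, 4, kind = "GSR")), "shorter")
})

test_that("imputation averages nearest valid neighbours and limits gaps", {
  tr <- signal_trace(c(1, NA, 3), 1, kind = "GSR")
  expect_equal(impute_missing(tr)$values, c(1, 2, 3))
  expect_false(any(impute_missing(tr)$missing))
  # identity on complete traces
  ok <- signal_trace(c(1, 2, 3), 1, kind = "GSR")
  expect_identical(impute_missing(ok)$values, ok$values)
  # edge missing takes its single neighbour
  expect_equal(impute_missing(signal_trace(c(NA, 2, 3), 1, kind = "GSR"))$values,
               c(2, 2, 3))
  # two consecutive missing exceed the default gap
  bad <- signal_trace(c(NA, NA, 3), 1, kind = "GSR")
  expect_error(impute_missing(bad), "data-quality")
  # but are linearly interpolated when explicitly allowed
  expect_equal(impute_missing(signal_trace(c(1, NA, NA, 4), 1, kind = "GSR"),
                              max_gap = 2)$values, c(1, 2, 3, 4))
})

test_that("the bio-geodatabase has one located row per second", {
  ses <- generate_session(session_spec(duration = 120, n_events = 1, seed = 9))
  tk <- generate_track(120, seed = 9)
  tab <- quiet_preprocess(ses$gsr, ses$st, geo = tk$track)
  expect_equal(nrow(tab), 120)
  expect_equal(tab$t, 0:119)
  expect_true(all(!is.na(tab$lat)))
  # without geolocation the rows carry null coordinates
  tab2 <- quiet_preprocess(ses$gsr, ses$st)
  expect_true(all(is.na(tab2$lat)) && all(is.na(tab2$lon)))
  # nearest-fix assignment matches a brute-force nearest neighbour in time
  g1 <- downsample_1hz(impute_missing(ses$gsr))
  sparse <- geo_track(c(10.4, 50.2, 100.1), c(47, 47.1, 47.2), c(13, 13.1, 13.2))
  tab3 <- build_biogeo(g1, g1, g1, g1, g1, geo = sparse)
  for (row in c(11, 51, 101)) {  # seconds 10, 50, 100
    j <- which.min(abs(sparse$t - tab3$t[row]))
    expect_equal(tab3$lat[row], sparse$lat[j])
  }
  expect_true(is.na(tab3$lat[60]))  # no fix within 5 s of t = 59
})

test_that("a zero-noise constant session preprocesses to a constant table", {
  ses <- generate_session(session_spec(duration = 120, n_events = 0,
                                       noise_sd_gsr = 0, noise_sd_st = 0,
                                       baseline_drift = 0, seed = 1))
  tab <- quiet_preprocess(ses$gsr, ses$st)
  expect_equal(tab$g, rep(2, 120), tolerance = 1e-6)
  expect_equal(tab$st, rep(33, 120), tolerance = 1e-6)
  expect_equal(tab$phasic, rep(0, 120), tolerance = 1e-6)
})
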