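test_that("candidate extraction matches an exhaustive scan of diff signs", {
  expect_equal(nrow(find_candidates(c(1, 1, 1))), 0)
  one <- find_candidates(c(1, 2, 3, 4, 3))
  expect_equal(nrow(one), 1)
  expect_equal(one$onset_t, 0)
  expect_equal(one$peak_t, 3)
  expect_equal(one$rise_run, 3)
  expect_equal(one$g_onset, 1)
  expect_equal(one$g_peak, 4)
  two <- find_candidates(c(1, 2, 1, 1, 2, 3, 2))
  expect_equal(nrow(two), 2)
  expect_equal(two$onset_t, c(0, 3))
  # property: every candidate is a maximal run of positive differences
  set.seed(11)
  for (rep in 1:20) {
    g <- cumsum(rnorm(50))
    cands <- find_candidates(g)
    d <- diff(g)
    for (i in seq_len(nrow(cands))) {
      cd <- cands[i, ]
      expect_true(all(d[cd$onset_idx:(cd$peak_idx - 1)] > 0))
      if (cd$onset_idx > 1) expect_false(d[cd$onset_idx - 1] > 0)
      if (cd$peak_idx <= length(d)) expect_false(d[cd$peak_idx] > 0)
    }
  }
})

test_that("rule scores reproduce the critical-value bands", {
  # R1: conductance rise duration
  expect_equal(score_r1(3), 1)
  expect_equal(score_r1(7), 0.5)
  expect_equal(score_r1(1), 0)
  expect_equal(score_r1(c(2, 5, 8, 9)), c(1, 1, 0.5, 0))
  # R3: rising time
  expect_equal(score_r3(4), 1)
  expect_equal(score_r3(10), 0.5)
  expect_equal(score_r3(16), 0)
  # R4: response slope in degrees, atan(delta_g / delta_t)
  expect_equal(atan(0.25) * 180 / pi, 14.04, tolerance = 1e-3)
  expect_equal(score_r4(1.0, 4), 1)    # 14.04 deg
  expect_equal(score_r4(0.6, 4), 0.5)  # 8.53 deg
  expect_equal(score_r4(0, 4), 0)
  # R5: refractory window
  expect_equal(score_r5(100, numeric(0)), 1)
  expect_equal(score_r5(100, 95), 0)
  expect_equal(score_r5(100, 89), 1)
})

test_that("the temperature-decrease rule distinguishes full/partial onsets", {
  n <- 40; onset_idx <- 11  # onset second t = 10
  ramp_at <- function(o, len = 4) {
    # temperature constant through second 10 + o, then falling 0.1 degC/s
    # for len seconds (first negative forward difference at second 10 + o)
    st <- rep(33, n)
    d0 <- 10 + o
    st[(d0 + 2):n] <- 33 - 0.1 * pmin(seq_len(n - d0 - 1), len)
    st
  }
  expect_equal(score_r2(ramp_at(3, 4), onset_idx), 1)
  expect_equal(score_r2(ramp_at(5, 3), onset_idx), 0.5)
  expect_equal(score_r2(ramp_at(2, 3), onset_idx), 0.5)
  expect_equal(score_r2(rep(33, n), onset_idx), 0)
  # rising temperature scores 0
  expect_equal(score_r2(33 + 0.01 * seq_len(n), onset_idx), 0)
  # insufficient coverage scores 0 with a warning
  expect_warning(s <- score_r2(rep(33, 12), onset_idx), "coverage")
  expect_equal(s, 0)
})

test_that("total score is the weighted sum with ceiling 100 and floor 0", {
  w <- default_rule_weights()
  expect_equal(sum(w), 100)
  expect_equal(total_score(rep(1, 5), w), 100)
  expect_equal(total_score(rep(0, 5), w), 0)
  expect_equal(total_score(c(1, 1, 1, 0.5, 1), c(30, 25, 15, 15, 15)), 92.5)
  # any valid positive weight vector gives the same ceiling
  set.seed(2)
  for (rep in 1:5) {
    wr <- rexp(5); wr <- wr / sum(wr) * 100
    expect_equal(total_score(rep(1, 5), wr), 100)
  }
  expect_error(total_score(rep(1, 5), c(30, 25, 15, 15, 10)), "configuration")
  expect_error(validate_weights(c(50, 50, 10, -5, -5)), "configuration")
  expect_error(total_score(c(1, 1, 1, 1, 0.7), w), "0, 0.5, 1")
})

test_that("detector agrees with the brute-force oracle on short series", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(20:60, 1)
    g <- cumsum(rnorm(n, sd = 0.3))
    st <- 33 + cumsum(rnorm(n, sd = 0.05))
    tab <- make_table(g, st)
    got <- quiet_detect(tab)
    want <- oracle_detect(g, st)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$t, want$t, tolerance = 1e-10)
      expect_equal(got$ts, want$ts, tolerance = 1e-10)
    }
  }
})

test_that("flat signals yield no events and empty tables are handled", {
  tab <- make_table(rep(1, 30), rep(33, 30))
  expect_equal(nrow(quiet_detect(tab)), 0)
  expect_equal(nrow(detect_mos(tab[0, ])), 0)
})

test_that("a canonical event is detected at its onset", {
  ses <- generate_session(session_spec(duration = 120, n_events = 1, seed = 5,
                                       noise_sd_gsr = 0, noise_sd_st = 0))
  tab <- quiet_preprocess(ses$gsr, ses$st)
  ev <- quiet_detect(tab)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$t - ses$truth$onset), 2)
  expect_gte(ev$ts, 75)
})

test_that("the refractory rule suppresses the second of two close events", {
  # two clean rises 8 s apart with matching temperature drops
  p1 <- make_event_pair(n = 60, onset = 20)
  g <- p1$g; st <- p1$st
  g[29:33] <- g[29:33] + seq(0, 1, length.out = 5)   # second rise at t = 28
  g[34:60] <- g[33]
  st[32:60] <- st[32:60] - 0.1 * pmin(seq_along(32:60), 4)  # drop at t = 31
  ev <- quiet_detect(make_table(g, st))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t, 20)
  # moved 12 s apart the second event survives
  g2 <- p1$g; st2 <- p1$st
  g2[33:37] <- g2[33:37] + seq(0, 1, length.out = 5)  # second rise at t = 32
  g2[38:60] <- g2[37]
  st2[36:44] <- st2[36:44] - 0.1 * pmin(seq_along(36:44), 4)
  ev2 <- quiet_detect(make_table(g2, st2))
  expect_equal(nrow(ev2), 2)
  expect_true(all(diff(ev2$t) > 10))
})

test_that("raising the critical score never yields more detections", {
  for (s in 1:10) {
    ses <- generate_session(session_spec(duration = 300, n_events = 3, seed = s))
    tab <- quiet_preprocess(ses$gsr, ses$st)
    counts <- vapply(c(60, 75, 85, 95),
                     function(cs) nrow(quiet_detect(tab, cs = cs)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("evaluation performs greedy one-to-one matching", {
  truth <- c(100, 200, 300)
  m <- evaluate_detections(c(100, 200, 300), truth)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 0, 0))
  expect_equal(m$accuracy, 1)
  m2 <- evaluate_detections(numeric(0), truth)
  expect_equal(c(m2$tp, m2$fn), c(0, 3))
  m3 <- evaluate_detections(c(100, 205, 400), truth)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(2, 1, 1))
  expect_equal(m3$accuracy, 0.5)
  # two detections cannot claim the same stimulus
  m4 <- evaluate_detections(c(99, 101), c(100))
  expect_equal(c(m4$tp, m4$fp), c(1, 1))
})

test_that("weight calibration is deterministic and finds a working setting", {
  sessions <- lapply(1:2, function(s) {
    ses <- recovery_session(s)
    list(table = quiet_preprocess(ses$gsr, ses$st), truth = ses$truth)
  })
  suppressWarnings({
    a <- calibrate_weights(sessions, n_draws = 10, seed = 3)
    b <- calibrate_weights(sessions, n_draws = 10, seed = 3)
  })
  expect_identical(a$weights, b$weights)
  expect_identical(a$cs, b$cs)
  # defaults already detect everything on zero-noise sessions
  best <- a$report[which.max(a$report$objective), ]
  expect_equal(best$tp, 20)
  expect_error(calibrate_weights(list()), "configuration")
  expect_error(calibrate_weights(sessions, cs_grid = numeric(0)),
               "configuration")
})
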