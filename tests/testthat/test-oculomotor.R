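test_that("gap interpolation follows the 75 ms rule", {
  rate <- 50
  n <- 100L
  t <- (seq_len(n) - 1L) / rate
  d <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  # 40 ms both-eye gap (2 samples): filled
  v <- rep(TRUE, n); v[50:51] <- FALSE
  tr <- binocular_trace(t, d, d, v, v)
  pre <- preprocess_gaze(tr)
  expect_true(all(pre$valid))
  expect_equal(attr(pre, "residual_loss_pct"), 0)
  expect_equal(attr(pre, "data_loss_pct"), 100 * 2 / n)
  # 200 ms both-eye gap (10 samples): retained as invalid
  v2 <- rep(TRUE, n); v2[40:49] <- FALSE
  pre2 <- preprocess_gaze(binocular_trace(t, d, d, v2, v2))
  expect_equal(sum(!pre2$valid), 10L)
  # interpolation is linear on the components: a gap inside a rotation
  az <- seq(0, 10, length.out = n) * pi / 180
  dr <- cbind(sin(az), 0, cos(az))
  v3 <- rep(TRUE, n); v3[30:32] <- FALSE
  pre3 <- preprocess_gaze(binocular_trace(t, dr, dr, v3, v3))
  expect_true(all(pre3$valid))
  expect_equal(pre3$dx[31], sin(az[31]), tolerance = 1e-4)
})

test_that("one-eye loss is compensated from the other eye", {
  n <- 60L
  t <- (seq_len(n) - 1L) / 50
  dl <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  dr <- matrix(rep(dir_to(c(0.5, 1.2, 3)), each = n), n, 3L)
  pre <- preprocess_gaze(binocular_trace(t, dl, dr, rep(FALSE, n), rep(TRUE, n)))
  expect_true(all(pre$valid))
  expect_equal(as.matrix(pre[, c("dx", "dy", "dz")]), unname(dr),
               tolerance = 1e-12, ignore_attr = TRUE)
  # both valid: renormalized average
  pre2 <- preprocess_gaze(binocular_trace(t, dl, dr, rep(TRUE, n), rep(TRUE, n)))
  avg <- normalize_rows((dl + dr) / 2)
  expect_equal(as.matrix(pre2[, c("dx", "dy", "dz")]), unname(avg),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(preprocess_gaze(binocular_trace(t, dl, dr, rep(FALSE, n),
                                               rep(FALSE, n))),
               "no valid samples")
})

test_that("reported data loss matches an injected dropout rate", {
  # the study reports mean loss of 2.75% per participant; inject that rate
  # and recover it within 0.5 percentage points
  prof <- participant_profile("HC", blink_free = TRUE)
  sch <- build_phase_schedule("DP", 2, 120)
  acts <- distractor_schedule(sch, seed = 1, collider_ids = "box_left")
  att <- simulate_attention(prof, sch, acts, seed = 2)
  rg <- render_gaze(att$track, tiny_scene(), seed = 3, loss_rate = 0.0275)
  pre <- preprocess_gaze(rg$trace)
  expect_lt(abs(attr(pre, "data_loss_pct") - 2.75), 0.5)
})

test_that("angular velocity recovers a constant rotation within 2%", {
  n <- 500L
  t <- (seq_len(n) - 1L) / 50
  az <- 10 * t * pi / 180                    # 10 deg/s rotation
  pre <- data.frame(t = t, dx = sin(az), dy = 0, dz = cos(az), valid = TRUE)
  v <- compute_velocity(pre)
  expect_lt(max(abs(v$velocity[10:490] - 10)) / 10, 0.02)
  # constant direction: identically zero
  pre0 <- data.frame(t = t, dx = 0, dy = 0, dz = 1, valid = TRUE)
  expect_equal(max(compute_velocity(pre0)$velocity), 0)
  # a 5 degree step in one 20 ms sample is a 250 deg/s raw spike
  ang <- c(rep(0, 250), rep(5, 250)) * pi / 180
  pre5 <- data.frame(t = t, dx = sin(ang), dy = 0, dz = cos(ang), valid = TRUE)
  raw_peak <- 5 / 0.02
  expect_equal(raw_peak, 250)
  v5 <- compute_velocity(pre5)
  expect_gt(max(v5$velocity), 100)           # smoothing spreads the spike
  expect_error(compute_velocity(pre5[1:3, ]), "shorter")
})

test_that("the adaptive threshold converges to its fixed points", {
  p <- detector_params()
  # all velocities equal: PT equals that value (zero SD)
  expect_equal(adaptive_threshold(rep(5, 200), p), 5)
  expect_equal(adaptive_threshold(rep(42, 200), p), 42)
  # bimodal: fixation noise around 5, saccade peaks at 300
  set.seed(4)
  v <- c(abs(rnorm(2000, 5, 2)), rep(300, 40))
  pt <- adaptive_threshold(v, p)
  expect_gt(pt, 5)
  expect_lt(pt, 300)
  # determinism
  expect_identical(adaptive_threshold(v, p), pt)
  expect_error(adaptive_threshold(numeric()), "no finite")
})

test_that("detection recovers known event structure", {
  # constant direction: no saccades, one fixation spanning the trace
  st <- synthetic_fixation_trace(2, numeric(0), seed = 1)
  ev <- detect_events(preprocess_gaze(st$trace))
  expect_equal(nrow(ev$saccades), 0L)
  expect_equal(nrow(ev$fixations), 1L)
  expect_equal(ev$fixations$duration_ms, (nrow(st$trace) - 1) * 20)
  # three step shifts at known times
  st3 <- synthetic_fixation_trace(rep(0.5, 4), rep(0.02, 3),
                                  gap_kind = "saccade", amplitude_deg = 6,
                                  seed = 2)
  ev3 <- detect_events(preprocess_gaze(st3$trace))
  expect_equal(nrow(ev3$saccades), 3L)
  expect_equal(nrow(ev3$fixations), 4L)
  shift_times <- st3$truth$end[1:3]
  expect_true(all(abs(ev3$saccades$start - shift_times) < 0.06))
  expect_true(all(abs(ev3$saccades$amplitude_deg - 6) < 1))
})

test_that("fixation filtering and merging enforce the 60 ms / 40 ms rules", {
  # a 50 ms candidate fixation between two saccades is discarded
  st <- synthetic_fixation_trace(c(0.5, 0.05, 0.5), rep(0.02, 2),
                                 gap_kind = "saccade", amplitude_deg = 6,
                                 seed = 3)
  ev <- detect_events(preprocess_gaze(st$trace))
  expect_true(all(ev$fixations$duration_ms >= 60))
  expect_equal(nrow(ev$fixations), 2L)
  # post-merge property on a mixed random trace
  set.seed(8)
  nf <- 25L
  st2 <- synthetic_fixation_trace(runif(nf, 0.03, 0.5),
                                  runif(nf - 1L, 0.02, 0.2),
                                  gap_kind = sample(c("saccade", "blink"),
                                                    nf - 1L, TRUE),
                                  amplitude_deg = 5, seed = 8)
  ev2 <- detect_events(preprocess_gaze(st2$trace))
  fx <- ev2$fixations
  expect_true(all(fx$duration_ms >= 60))
  if (nrow(fx) > 1) {
    gaps <- (fx$start[-1] - fx$end[-nrow(fx)]) * 1000
    expect_true(all(gaps > 40))
  }
  # saccades and fixations never overlap
  sa <- ev2$saccades
  if (nrow(sa) && nrow(fx)) {
    for (j in seq_len(nrow(sa))) {
      expect_false(any(sa$start[j] < fx$end & sa$end[j] > fx$start))
    }
  }
})

test_that("the detector recovers >= 95% of >= 2 degree saccades and stays
          silent on pure fixation noise", {
  prof <- participant_profile("HC", blink_free = TRUE)
  sch <- build_phase_schedule("DP", 2, 60)
  acts <- distractor_schedule(sch, seed = 5, collider_ids = "box_left")
  att <- simulate_attention(prof, sch, acts, seed = 6)
  rg <- render_gaze(att$track, tiny_scene(), seed = 7)
  ev <- detect_events(preprocess_gaze(rg$trace))
  truth <- rg$truth$saccades
  big <- truth[truth$amplitude_deg >= 2, ]
  recovered <- vapply(big$t, function(tt) {
    any(ev$saccades$start - 0.05 <= tt & tt <= ev$saccades$end + 0.05)
  }, logical(1L))
  expect_gte(mean(recovered), 0.95)
  # pure noise: a single steady fixation yields zero saccades
  stn <- synthetic_fixation_trace(30, numeric(0), jitter_deg = 0.05, seed = 9)
  evn <- detect_events(preprocess_gaze(stn$trace))
  expect_equal(nrow(evn$saccades), 0L)
})

test_that("saccade summaries conserve counts across phases", {
  sch <- build_phase_schedule("DP", 4, 15)
  sa <- data.frame(start = runif(50, 0, 60), end = NA, duration_ms = 30,
                   amplitude_deg = 4, peak_velocity = 200)
  sa$end <- sa$start + 0.03
  sm <- summarize_saccades(sa, sch)
  expect_equal(sum(sm$n_saccades), 50L)
  # empty input: zero counts, missing means
  sm0 <- summarize_saccades(sa[0, ], sch)
  expect_equal(sm0$n_saccades, c(0L, 0L))
  expect_true(all(is.na(sm0$mean_duration_ms)))
  # when gaze shifts are driven by DP-locked distractor capture alone, the
  # detected saccade count is higher in DP than NDP
  prof <- participant_profile("ADHD", blink_free = TRUE,
                              wander_hazard = 1e-4)
  sch2 <- build_phase_schedule("DP", 2, 120)
  counts <- rowSums(vapply(1:3, function(s) {
    acts <- distractor_schedule(sch2, seed = s, collider_ids = "box_left")
    att <- simulate_attention(prof, sch2, acts, seed = s + 50)
    rg <- render_gaze(att$track, tiny_scene(), seed = s + 100,
                      relocation_rate = 0)
    ev <- detect_events(preprocess_gaze(rg$trace))
    out <- summarize_saccades(ev$saccades, sch2)
    setNames(out$n_saccades, out$phase_type)
  }, c(DP = 0, NDP = 0)))
  expect_gt(counts[["DP"]], counts[["NDP"]])
})
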