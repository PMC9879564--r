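test_that("distractor schedules place 6 events per standard DP, 30 s apart", {
  sch <- build_phase_schedule("DP", 6, 180)
  acts <- distractor_schedule(sch, seed = 5)
  dp_starts <- sch$start[sch$phase_type == "DP"]
  expect_equal(nrow(acts), 18L)
  for (p in unique(acts$phase_index)) {
    on <- acts$onset[acts$phase_index == p]
    expect_length(on, 6L)
    expect_equal(diff(on), rep(30, 5))
    expect_equal(on[1], sch$start[p])
    # selection without replacement within a phase
    expect_equal(anyDuplicated(acts$distractor_id[acts$phase_index == p]), 0L)
  }
  # none during NDP
  ph <- phase_at(sch, acts$onset)
  expect_true(all(sch$phase_type[ph] == "DP"))
  # determinism
  expect_identical(distractor_schedule(sch, seed = 5)$distractor_id,
                   acts$distractor_id)
  expect_false(identical(distractor_schedule(sch, seed = 6)$distractor_id,
                         acts$distractor_id))
})

test_that("an NDP-only schedule yields no activations; oversized interval warns", {
  ndp <- build_phase_schedule("NDP", 1, 180)
  expect_equal(nrow(distractor_schedule(ndp, seed = 1)), 0L)
  tiny <- build_phase_schedule("DP", 1, 10)
  expect_warning(acts <- distractor_schedule(tiny, interval = 30, seed = 1),
                 "no distractors")
  expect_equal(nrow(acts), 0L)
  expect_error(distractor_schedule(ndp, interval = 0), "positive")
})

test_that("trivial rays classify as expected", {
  sc <- tiny_scene()
  acts <- data.frame(onset = 0, end = 10, phase_index = 1,
                     distractor_id = "visual_01", modality = "visual",
                     collider_id = "box_left")
  # straight at the canvas center
  r1 <- classify_gaze_samples(1, eye_origin(), matrix(dir_to(c(0, 1.5, 3)), 1),
                              TRUE, sc, acts)
  expect_equal(r1$state, "task_focus")
  expect_equal(r1$hit_object_id, "canvas")
  # at the active distractor box
  r2 <- classify_gaze_samples(1, eye_origin(),
                              matrix(dir_to(c(-2.5, 1.2, 2)), 1), TRUE, sc, acts)
  expect_equal(r2$state, "distractor_focus")
  expect_equal(r2$hit_object_id, "box_left")
  # same ray outside the activation window: gaze wandering
  r3 <- classify_gaze_samples(20, eye_origin(),
                              matrix(dir_to(c(-2.5, 1.2, 2)), 1), TRUE, sc, acts)
  expect_equal(r3$state, "gaze_wandering")
  # invalid and zero-length directions
  r4 <- classify_gaze_samples(1, eye_origin(), matrix(c(0, 0, 1), 1), FALSE,
                              sc, acts)
  expect_equal(r4$state, "invalid")
  r5 <- classify_gaze_samples(1, eye_origin(), matrix(0, 1, 3), TRUE, sc, acts)
  expect_equal(r5$state, "invalid")
})

test_that("ray classification agrees with a point-marching inclusion oracle", {
  # 10^4 random rays against one box and one sphere, always-active
  set.seed(99)
  n <- 10000L
  sc2 <- scene(list(
    collider("canvas", "canvas", "box", c(0, 1.5, 3.0), c(1.2, 0.8, 0.05)),
    collider("ball", "distractor", "sphere", c(1.4, 1.0, 1.5), radius = 0.35)
  ))
  acts <- data.frame(onset = -1, end = 1e6, phase_index = 1,
                     distractor_id = "d", modality = "visual",
                     collider_id = "ball")
  dirs <- matrix(rnorm(3L * n), n, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # bias half the rays toward the scene so hits are well represented
  half <- seq_len(n / 2L)
  targets <- cbind(runif(length(half), -1.6, 1.8),
                   runif(length(half), 0.2, 2.5),
                   runif(length(half), 1.0, 3.2))
  dirs[half, ] <- normalize_rows(targets - matrix(c(0, 1.2, 0),
                                                  length(half), 3L, TRUE))
  res <- classify_gaze_samples(seq_len(n) * 1e-3, eye_origin(n), dirs,
                               rep(TRUE, n), sc2, acts)
  origin <- c(0, 1.2, 0)
  for (i in sample.int(n, 400L)) {   # oracle is slow; spot-check densely
    hit_canvas <- oracle_ray_hits(origin, dirs[i, ], sc2$colliders[[1]])
    hit_ball <- oracle_ray_hits(origin, dirs[i, ], sc2$colliders[[2]])
    expected <- if (hit_canvas || hit_ball) {
      # nearest hit wins: compare march distances
      if (!hit_ball) "task_focus" else if (!hit_canvas) "distractor_focus"
      else stop("fixture rays should not hit both")
    } else "gaze_wandering"
    expect_equal(res$state[i], expected,
                 label = sprintf("ray %d (%s)", i, res$state[i]))
  }
  # full-set agreement on hit/miss against a vectorized form of the oracle
  agree <- vapply(seq_len(n), function(i) {
    any_hit <- oracle_ray_hits(origin, dirs[i, ], sc2$colliders[[1]]) ||
      oracle_ray_hits(origin, dirs[i, ], sc2$colliders[[2]])
    any_hit == (res$state[i] != "gaze_wandering")
  }, logical(1L))
  expect_true(mean(agree) > 0.999)  # the marching oracle can graze corners
})

test_that("state intervals are a contiguous alternating run-length encoding", {
  cls <- data.frame(t = (0:9) / 50,
                    state = c("task_focus", "task_focus", "gaze_wandering",
                              "gaze_wandering", "gaze_wandering",
                              "task_focus", "invalid", "invalid",
                              "task_focus", "task_focus"),
                    hit_object_id = NA_character_)
  iv <- intervals_from_samples(cls)
  expect_equal(nrow(iv), 5L)
  expect_equal(iv$start[-1], iv$end[-5])
  expect_true(all(iv$state[-1] != iv$state[-5]))
  expect_equal(sum(iv$end - iv$start), max(cls$t) - min(cls$t))
  # constant state: single interval; per-sample alternation: one per sample
  one <- intervals_from_samples(data.frame(t = (0:99) / 50,
                                           state = "task_focus"))
  expect_equal(nrow(one), 1L)
  alt <- intervals_from_samples(data.frame(
    t = (0:9) / 50, state = rep(c("task_focus", "invalid"), 5)))
  expect_equal(nrow(alt), 10L)
  expect_error(intervals_from_samples(data.frame(t = c(1, 0), state = "a")),
               "time-ordered")
  # conservation on random inputs
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200L
    cls2 <- data.frame(t = cumsum(runif(n, 0.01, 0.05)),
                       state = sample(GAZE_STATES, n, TRUE))
    iv2 <- intervals_from_samples(cls2)
    expect_equal(sum(iv2$end - iv2$start), max(cls2$t) - min(cls2$t))
  }
})

test_that("dwell percentages close to 100 and the score follows its formula", {
  iv <- data.frame(state = c("task_focus", "distractor_focus",
                             "gaze_wandering"),
                   start = c(0, 80, 85), end = c(80, 85, 100),
                   hit_object_id = NA)
  dw <- dwell_summary(iv, 100)
  expect_equal(dw$pct_task_focus, 80)
  expect_equal(dw$pct_distractor_focus, 5)
  expect_equal(dw$pct_gaze_wandering, 15)
  expect_equal(dw$distractibility_score, (5 + 15) / 80)
  expect_equal(dw$pct_task_focus + dw$pct_distractor_focus +
                 dw$pct_gaze_wandering + dw$pct_invalid, 100)
  # pure task focus: zero distraction score
  dw2 <- dwell_summary(data.frame(state = "task_focus", start = 0, end = 50,
                                  hit_object_id = NA), 50)
  expect_equal(dw2$distractibility_score, 0)
  # undefined score when no task focus at all
  expect_error(dwell_summary(data.frame(state = "gaze_wandering", start = 0,
                                        end = 50, hit_object_id = NA), 50),
               "undefined")
  # closure on simulated sessions
  sch <- short_schedule()
  for (seed in c(3, 4)) {
    sb <- simulate_block(participant_profile("HC"), "none", sch, seed = seed,
                         include_eeg = FALSE)
    dw3 <- dwell_summary(intervals_from_samples(sb$truth$classified), 120)
    expect_equal(dw3$pct_task_focus + dw3$pct_distractor_focus +
                   dw3$pct_gaze_wandering + dw3$pct_invalid, 100)
  }
})

test_that("matched-seed ADHD profile is more distractible than HC", {
  sch <- build_phase_schedule("DP", 2, 120)
  scores <- sapply(c("ADHD", "HC"), function(g) {
    mean(sapply(1:4, function(s) {
      sb <- simulate_block(participant_profile(g), "none", sch, seed = s * 17,
                           include_eeg = FALSE)
      dwell_summary(intervals_from_samples(sb$truth$classified),
                    240)$distractibility_score
    }))
  })
  expect_gt(scores[["ADHD"]], scores[["HC"]])
})
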