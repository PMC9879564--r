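# Shared fixtures: short schedules and small streams built in code.

short_schedule <- function(n_phases = 2L, phase_seconds = 60) {
  build_phase_schedule("DP", n_phases, phase_seconds)
}

# a minimal two-collider scene: canvas ahead, one distractor box to the left
tiny_scene <- function() {
  scene(list(
    collider("canvas", "canvas", "box", c(0, 1.5, 3.0), c(1.5, 1.0, 0.05)),
    collider("box_left", "distractor", "box", c(-2.5, 1.2, 2.0),
             c(0.4, 1.0, 0.2))
  ))
}

eye_origin <- function(n = 1L) matrix(c(0, 1.2, 0), n, 3L, byrow = TRUE)

# direction from the default eye position toward a point
dir_to <- function(p, origin = c(0, 1.2, 0)) {
  d <- p - origin
  d / sqrt(sum(d^2))
}

# sinusoid EEG stream helper
sine_eeg <- function(freq, amp = 1, dur = 20, fs = 500, channel = "Fz") {
  t <- (0:(dur * fs - 1)) / fs
  v <- data.frame(x = amp * sin(2 * pi * freq * t))
  names(v) <- channel
  time_series_stream("eeg", fs, t, v)
}

# brute-force CPT rescoring oracle: trial-by-trial loop over disjoint
# response windows (window equal to the stimulus-onset asynchrony), fully
# independent of the vectorized implementation
oracle_score_cpt <- function(block, responses, window = 1.2) {
  responses <- sort(responses)
  om <- 0L; com <- 0L; rts <- numeric(0)
  for (i in seq_len(nrow(block))) {
    on <- block$onset[i]
    rs <- responses[responses >= on & responses < on + window]
    responded <- length(rs) > 0L
    if (block$class[i] == "target") {
      if (!responded) om <- om + 1L else rts <- c(rts, (rs[1L] - on) * 1000)
    } else if (responded) com <- com + 1L
  }
  list(omissions = om, commissions = com, rts = rts)
}

# brute-force point-marching ray/collider inclusion oracle
oracle_ray_hits <- function(origin, direction, cl, t_max = 20, dt = 0.002) {
  ts <- seq(dt, t_max, by = dt)
  pts <- outer(ts, direction) + matrix(origin, length(ts), 3L, byrow = TRUE)
  if (cl$shape == "box") {
    lo <- cl$center - cl$half_extents
    hi <- cl$center + cl$half_extents
    any(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
          pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
          pts[, 3] >= lo[3] & pts[, 3] <= hi[3])
  } else {
    any(rowSums(sweep(pts, 2L, cl$center)^2) <= cl$radius^2)
  }
}

# offline interval-scan oracle for real-mode controller event counts on a
# trace that contains no invalid samples: scans off-canvas runs and counts
# threshold crossings with max-duration and refractory bookkeeping
oracle_event_count <- function(trace, off_thr = 2, dist_thr = 0.5,
                               max_dur = 2, refractory = 5) {
  n <- nrow(trace)
  dt <- diff(trace$t)[1L]
  off_t <- 0; dist_t <- 0
  count <- 0L
  active_until <- -Inf; refract_until <- -Inf; active <- FALSE
  for (i in seq_len(n)) {
    t <- trace$t[i]; s <- trace$state[i]
    if (active && (s == "task_focus" || t >= active_until)) {
      active <- FALSE
      refract_until <- min(t, active_until) + refractory
      off_t <- 0; dist_t <- 0
    }
    if (!active) {
      if (s == "task_focus") { off_t <- 0; dist_t <- 0 }
      else {
        off_t <- off_t + dt
        dist_t <- if (s == "distractor_focus") dist_t + dt else 0
      }
      if ((off_t > off_thr + 1e-9 || dist_t > dist_thr + 1e-9) &&
          t >= refract_until &&
          i < n) {   # an onset at the very last sample has no duration
        count <- count + 1L
        active <- TRUE
        active_until <- t + max_dur
      }
    }
  }
  count
}

# independent split-plot decomposition oracle for the balanced 2 x 3 x 2
# design: every effect and error sum of squares is written directly from
# cell and marginal means, without any model-fitting machinery
oracle_anova_2x3x2 <- function(data, dv, between = "group",
                               within = c("condition", "phase_type"),
                               subject = "participant_id") {
  y <- data[[dv]]
  G <- factor(data[[between]]); W1 <- factor(data[[within[1]]])
  W2 <- factor(data[[within[2]]]); S <- factor(data[[subject]])
  gm <- mean(y)
  a <- nlevels(G); b <- nlevels(W1); cc <- nlevels(W2)
  N <- nlevels(S)                     # total subjects
  m <- function(...) tapply(y, list(...), mean)
  mA <- m(G); mB <- m(W1); mC <- m(W2)
  mAB <- m(G, W1); mAC <- m(G, W2); mBC <- m(W1, W2); mABC <- m(G, W1, W2)
  mS <- m(S); mSB <- m(S, W1); mSC <- m(S, W2)
  gS <- tapply(as.character(G), S, function(x) x[1])

  ssA <- b * cc * (N / a) * sum((mA - gm)^2)
  ssB <- a * cc * (N / a) * sum((mB - gm)^2)
  ssC <- a * b * (N / a) * sum((mC - gm)^2)
  ssAB <- cc * (N / a) * sum((sweep(sweep(mAB, 1, mA), 2, mB) + gm)^2)
  ssAC <- b * (N / a) * sum((sweep(sweep(mAC, 1, mA), 2, mC) + gm)^2)
  ssBC <- N * sum((sweep(sweep(mBC, 1, mB), 2, mC) + gm)^2)
  dev <- mABC
  for (i in seq_len(a)) for (j in seq_len(b)) for (k in seq_len(cc)) {
    dev[i, j, k] <- mABC[i, j, k] - mAB[i, j] - mAC[i, k] - mBC[j, k] +
      mA[i] + mB[j] + mC[k] - gm
  }
  ssABC <- (N / a) * sum(dev^2)
  # error strata
  err_subj <- b * cc * sum((mS - mA[gS])^2)
  err_B <- cc * sum((mSB - outer(mS, rep(1, b)) - mAB[gS, ] +
                       outer(mA[gS], rep(1, b)))^2)
  err_C <- b * sum((mSC - outer(mS, rep(1, cc)) - mAC[gS, ] +
                      outer(mA[gS], rep(1, cc)))^2)
  resid <- 0
  for (r in seq_len(nrow(data))) {
    s <- as.character(S[r]); j <- as.integer(W1[r]); k <- as.integer(W2[r])
    g <- gS[s]
    resid <- resid + unname(y[r] - mSB[s, j] - mSC[s, k] - mABC[g, j, k] +
                              mS[s] + mAB[g, j] + mAC[g, k] - mA[g])^2
  }
  list(
    F = c(
      A = (ssA / (a - 1)) / (err_subj / (N - a)),
      B = (ssB / (b - 1)) / (err_B / ((b - 1) * (N - a))),
      AB = (ssAB / ((a - 1) * (b - 1))) / (err_B / ((b - 1) * (N - a))),
      C = (ssC / (cc - 1)) / (err_C / ((cc - 1) * (N - a))),
      AC = (ssAC / ((a - 1) * (cc - 1))) / (err_C / ((cc - 1) * (N - a))),
      BC = (ssBC / ((b - 1) * (cc - 1))) /
        (resid / ((b - 1) * (cc - 1) * (N - a))),
      ABC = (ssABC / ((a - 1) * (b - 1) * (cc - 1))) /
        (resid / ((b - 1) * (cc - 1) * (N - a)))),
    ss = list(A = ssA, B = ssB, C = ssC, AB = ssAB, AC = ssAC, BC = ssBC,
              ABC = ssABC, err_subj = err_subj, err_B = err_B, err_C = err_C,
              resid = resid),
    total = sum((y - gm)^2)
  )
}

make_design <- function(n_per = 5, seed = 1, effect = 0) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("s%02d", 1:(2 * n_per)),
                   condition = c("real", "sham", "none"),
                   phase_type = c("DP", "NDP"), stringsAsFactors = FALSE)
  g$group <- ifelse(as.integer(sub("s", "", g$participant_id)) <= n_per,
                    "ADHD", "HC")
  subj_int <- rnorm(2 * n_per, 0, 1)[as.integer(sub("s", "", g$participant_id))]
  g$y <- rnorm(nrow(g)) + subj_int + effect * (g$group == "ADHD")
  g
}

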