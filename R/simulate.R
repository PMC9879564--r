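# Closed-loop synthetic participant and session generator.
#
# A participant's attention is a continuous-time Markov jump process over
# the latent states on_task / gaze_wandering / distracted / blink
# (exponential holding times; piecewise-constant hazards).  Distractor
# onsets multiply the distraction hazard during their activation window;
# active feedback can multiply the refocus hazard.  The latent track is
# rendered into all recorded streams (binocular gaze with ground-truth
# saccade labels, CPT keypresses, EEG, head position) so that every
# analysis stage has an oracle.  Group default profiles are calibrated so
# that simulated cohort means approximate the group means reported for the
# 18 + 18 participant study (omission errors, reaction times, dwell
# percentages, head movement).

ATTENTION_STATES <- c("on_task", "gaze_wandering", "distracted", "blink")

#' Synthetic participant profile
#'
#' All hazards are rates in 1/s.  Group defaults ("ADHD" vs "HC") are
#' calibrated against the published group means: more off-task time, more
#' distractor capture, slower and more variable reaction times, more
#' omissions when off task, and larger head movement for the ADHD profile.
#' Any field can be overridden through `...`.
#'
#' @param group `"ADHD"` or `"HC"`.
#' @param ... named overrides of individual profile fields.
#' @return a `participant_profile` list.
#' @export
participant_profile <- function(group = c("ADHD", "HC"), ...) {
  group <- match.arg(group)
  base <- if (group == "ADHD") {
    list(
      wander_hazard = 0.050,        # rate of drifting into mind wandering
      distraction_hazard = 0.002,   # baseline capture by distractor objects
      distractor_boost = 500,       # capture multiplier during activations
      refocus_wander = 0.45,        # return-to-task rate from wandering
      refocus_distractor = 0.80,    # disengagement rate from a distractor
      blink_rate = 0.15, blink_recovery = 8,
      feedback_refocus_boost = 1,   # no immediate feedback effect by default
      rt_median = 465, rt_sigma = 0.18,          # ms, log-scale SD
      omission_prob_offtask = 0.12, omission_lapse = 0.004,
      commission_prob = 0.0036, commission_dp_factor = 1.2,
      theta_amp = 3.0, beta_amp = 2.6, eeg_noise_amp = 4.0,
      theta_dp_boost = 1.08,
      head_step_sigma = 4.6e-4,     # meters per 90 Hz step
      jitter_deg = 0.06, blink_free = FALSE,
      es_mean = 1.3, recognition_accuracy = 0.70
    )
  } else {
    list(
      wander_hazard = 0.032,
      distraction_hazard = 0.0015,
      distractor_boost = 190,
      refocus_wander = 0.62,
      refocus_distractor = 1.10,
      blink_rate = 0.15, blink_recovery = 8,
      feedback_refocus_boost = 1,
      rt_median = 430, rt_sigma = 0.15,
      omission_prob_offtask = 0.06, omission_lapse = 0.002,
      commission_prob = 0.0033, commission_dp_factor = 1.2,
      theta_amp = 2.7, beta_amp = 2.6, eeg_noise_amp = 4.0,
      theta_dp_boost = 1.08,
      head_step_sigma = 2.1e-4,
      jitter_deg = 0.06, blink_free = FALSE,
      es_mean = -1.5, recognition_accuracy = 0.73
    )
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown profile field(s): %s", paste(unknown, collapse = ", ")))
  }
  base[names(over)] <- over
  structure(c(list(group = group), base), class = "participant_profile")
}

# transition rate vector out of a state given the momentary modifiers
attention_rates <- function(profile, state, dist_active, fb_active) {
  boost <- if (fb_active) profile$feedback_refocus_boost else 1
  br <- if (profile$blink_free) 0 else profile$blink_rate
  switch(state,
    on_task = c(
      gaze_wandering = profile$wander_hazard,
      distracted = profile$distraction_hazard *
        (if (dist_active) profile$distractor_boost else 1),
      blink = br),
    gaze_wandering = c(on_task = profile$refocus_wander * boost, blink = br),
    distracted = c(on_task = profile$refocus_distractor * boost, blink = br),
    blink = c(back = profile$blink_recovery)
  )
}

#' Simulate a latent attention track
#'
#' Continuous-time jump process with exponential holding times over
#' `[0, duration]`.  Distractor activations multiply the distraction hazard
#' within their window.  When `feedback_mode = "real"` and the profile's
#' `feedback_refocus_boost` differs from 1, a continuous-time replica of
#' the feedback controller runs inside the simulation so that active
#' feedback multiplies the refocus hazard (holding times are re-sampled at
#' modifier changes, which is exact by memorylessness).
#'
#' @param profile a [participant_profile()].
#' @param schedule a `phase_schedule` (sets the duration).
#' @param activations distractor activation table from
#'   [distractor_schedule()].
#' @param feedback_mode `"real"`, `"sham"` or `"none"` (coupling only acts
#'   in real mode).
#' @param seed RNG seed.
#' @return list `track` (data frame `state`, `start`, `end`, `target_id`)
#'   and `feedback_episodes` (onset/offset of the coupled replica's events;
#'   empty unless coupling is active).
#' @export
simulate_attention <- function(profile, schedule, activations,
                               feedback_mode = "none", seed = NULL) {
  T_end <- schedule$end[nrow(schedule)]
  act_on <- activations$onset
  act_off <- activations$end
  boundaries <- sort(unique(c(act_on, act_off)))
  boundaries <- boundaries[boundaries > 0 & boundaries < T_end]
  coupled <- identical(feedback_mode, "real") &&
    profile$feedback_refocus_boost != 1
  d_ids <- activations$collider_id

  with_seed(seed, {
    t <- 0
    state <- "on_task"
    prev_state <- "on_task"
    seg_start <- 0
    target <- NA_character_
    rows <- list()
    episodes <- list()
    # controller replica state (coupled mode only)
    off_since <- NA_real_; dist_since <- NA_real_
    fb_on <- FALSE; fb_until <- Inf; refract_until <- -Inf

    active_at <- function(tt) {
      any(tt >= act_on & tt < act_off)
    }
    current_target <- function(tt) {
      i <- which(tt >= act_on & tt < act_off)
      if (length(i)) d_ids[i[1L]] else if (length(d_ids))
        sample(unique(d_ids), 1L) else NA_character_
    }
    close_seg <- function(tt) {
      rows[[length(rows) + 1L]] <<- data.frame(
        state = state, start = seg_start, end = tt, target_id = target,
        stringsAsFactors = FALSE)
      seg_start <<- tt
    }
    end_feedback <- function(tt) {
      episodes[[length(episodes) + 1L]] <<- data.frame(
        onset = fb_start, offset = tt)
      fb_on <<- FALSE
      refract_until <<- tt + 5
    }
    fb_start <- NA_real_

    while (t < T_end) {
      dist_act <- active_at(t)
      # candidate boundary times where rates change
      nb <- boundaries[boundaries > t]
      next_b <- if (length(nb)) nb[1L] else T_end
      trigger_at <- Inf
      if (coupled && !fb_on && state != "on_task" && !is.na(off_since)) {
        cand <- off_since + 2
        if (state == "distracted" && !is.na(dist_since)) {
          cand <- min(cand, dist_since + 0.5)
        }
        trigger_at <- max(cand, refract_until)
      }
      fb_end_at <- if (fb_on) fb_until else Inf
      seg_end <- min(next_b, trigger_at, fb_end_at, T_end)

      rates <- attention_rates(profile, state, dist_act, fb_on)
      lambda <- sum(rates)
      tau <- if (lambda > 0) rexp(1L, lambda) else Inf
      if (t + tau < seg_end) {
        t <- t + tau
        nxt <- sample(names(rates), 1L, prob = rates)
        if (nxt == "back") nxt <- prev_state
        close_seg(t)
        if (state != "blink") prev_state <- state
        if (nxt == "on_task") {
          off_since <- NA_real_; dist_since <- NA_real_
          if (fb_on) end_feedback(t)
          target <- NA_character_
        } else if (nxt == "distracted") {
          if (is.na(off_since)) off_since <- t
          dist_since <- t
          target <- current_target(t)
        } else if (nxt == "gaze_wandering") {
          if (is.na(off_since)) off_since <- t
          dist_since <- NA_real_
          target <- NA_character_
        }
        # blink keeps off_since frozen-in-place and the previous target
        state <- nxt
      } else {
        t <- seg_end
        if (fb_on && t >= fb_until) end_feedback(t)
        if (coupled && !fb_on && t >= trigger_at && t < T_end) {
          fb_on <- TRUE
          fb_start <- t
          fb_until <- t + 2
        }
      }
    }
    close_seg(T_end)
    track <- do.call(rbind, rows)
    track <- track[track$end > track$start, , drop = FALSE]
    list(track = track,
         feedback_episodes = if (length(episodes)) do.call(rbind, episodes)
         else data.frame(onset = numeric(), offset = numeric()))
  })
}

slerp_dir <- function(a, b, f) {
  d <- a + f * (b - a)
  d / sqrt(sum(d^2))
}

#' Render a latent attention track into a binocular gaze trace
#'
#' On-task intervals fixate jittered points on the central canvas area with
#' Poisson relocations; distracted intervals fixate the active distractor's
#' collider; wandering intervals fixate off-object regions (table, ceiling,
#' room corners); blinks render as invalid samples.  Target relocations are
#' rendered as short high-velocity transitions, and their times and
#' amplitudes are retained as ground truth for the saccade detector.
#'
#' @param track attention track from [simulate_attention()].
#' @param sc a `scene`.
#' @param rate gaze sampling rate in Hz (default 50).
#' @param seed RNG seed.
#' @param jitter_deg per-sample fixation jitter SD in degrees.
#' @param eye_jitter_deg additional independent per-eye jitter (degrees).
#' @param relocation_rate within-state fixation relocation rate (1/s).
#' @param loss_rate probability that a sample is lost in both eyes
#'   (tracking dropouts, independent of blinks).
#' @param origin cyclopean eye position in meters.
#' @return list `trace` (a `binocular_trace`), `origins` (left/right eye
#'   positions), `truth` (ground-truth saccade table `t`, `amplitude_deg`
#'   and the latent `track`).
#' @export
render_gaze <- function(track, sc, rate = 50, seed = NULL,
                        jitter_deg = 0.06, eye_jitter_deg = 0.03,
                        relocation_rate = 1.2, loss_rate = 0,
                        origin = c(0, 1.2, 0)) {
  T_end <- max(track$end)
  n <- floor(T_end * rate)
  t <- (seq_len(n) - 1L) / rate
  canvas <- sc$colliders[[1L]]
  stopifnot(canvas$kind == "canvas")
  cz <- canvas$center[3L] - canvas$half_extents[3L]
  dist_centers <- lapply(sc$colliders, function(cl) cl$center)
  names(dist_centers) <- vapply(sc$colliders, function(cl) cl$object_id,
                                character(1L))
  wander_regions <- list(
    c(0, 0.35, 1.2), c(0, 2.95, 1.4), c(-0.95, 0.6, 0.75), c(0.6, 0.35, 0.9))

  with_seed(seed, {
    sample_point <- function(state, target) {
      if (state == "on_task") {
        canvas$center + c(runif(1L, -0.45, 0.45), runif(1L, -0.3, 0.3), 0) -
          c(0, 0, canvas$half_extents[3L])
      } else if (state == "distracted") {
        ctr <- if (!is.na(target) && target %in% names(dist_centers))
          dist_centers[[target]] else dist_centers[[2L]]
        ctr + rnorm(3L, 0, 0.05)
      } else {
        base <- wander_regions[[sample.int(length(wander_regions), 1L)]]
        base + rnorm(3L, 0, 0.1)
      }
    }
    # piecewise-constant fixation targets: state intervals plus relocations
    seg_start <- numeric(0); seg_dir <- list(); seg_blink <- logical(0)
    for (i in seq_len(nrow(track))) {
      st <- track$state[i]
      s0 <- track$start[i]; s1 <- track$end[i]
      if (st == "blink") {
        seg_start <- c(seg_start, s0)
        seg_dir[[length(seg_dir) + 1L]] <- c(NA_real_, NA_real_, NA_real_)
        seg_blink <- c(seg_blink, TRUE)
        next
      }
      rr <- if (st == "on_task") relocation_rate else
        if (st == "gaze_wandering") 0.7 * relocation_rate else 0.2
      k <- if (rr > 0) rpois(1L, rr * (s1 - s0)) else 0L
      starts <- sort(c(s0, if (k > 0L) runif(k, s0, s1)))
      for (s in starts) {
        p <- sample_point(st, track$target_id[i])
        seg_start <- c(seg_start, s)
        seg_dir[[length(seg_dir) + 1L]] <-
          (p - origin) / sqrt(sum((p - origin)^2))
        seg_blink <- c(seg_blink, FALSE)
      }
    }
    seg_idx <- findInterval(t, seg_start)
    dmat <- do.call(rbind, seg_dir)[seg_idx, , drop = FALSE]
    blink <- seg_blink[seg_idx]

    # ground-truth saccades: boundaries between two seeing segments
    truth_t <- numeric(0); truth_amp <- numeric(0)
    changes <- which(diff(seg_idx) != 0) + 1L
    for (ci in changes) {
      a <- seg_idx[ci - 1L]; b <- seg_idx[ci]
      if (!seg_blink[a] && !seg_blink[b]) {
        amp <- acos(pmin(pmax(sum(seg_dir[[a]] * seg_dir[[b]]), -1), 1)) *
          180 / pi
        truth_t <- c(truth_t, t[ci])
        truth_amp <- c(truth_amp, amp)
        # render the transition: one intermediate sample mid-way
        dmat[ci, ] <- slerp_dir(seg_dir[[a]], seg_dir[[b]], 0.5)
      }
    }
    jig <- function(m, sigma_deg) {
      s <- sigma_deg * pi / 180
      normalize_rows(m + matrix(rnorm(3L * nrow(m), 0, s), ncol = 3L))
    }
    base <- jig(dmat, jitter_deg)
    left <- jig(base, eye_jitter_deg)
    right <- jig(base, eye_jitter_deg)
    lost <- runif(n) < loss_rate
    valid <- !blink & !lost & !is.na(dmat[, 1L])
    left[!valid, ] <- 0; right[!valid, ] <- 0
    trace <- binocular_trace(t, left, right, valid, valid)
    list(trace = trace,
         origins = list(left = origin + c(-0.032, 0, 0),
                        right = origin + c(0.032, 0, 0),
                        cyclopean = origin),
         truth = list(saccades = data.frame(t = truth_t,
                                            amplitude_deg = truth_amp),
                      track = track))
  })
}

#' Render a synthetic fixation/saccade trace with known ground truth
#'
#' Builds a binocular gaze trace consisting of fixations of the requested
#' durations, separated either by saccadic jumps to a new location
#' (`gap_kind = "saccade"`, gaze shifts of `amplitude_deg`) or by invalid
#' blink/dropout gaps at the same location (`gap_kind = "blink"`).  Used to
#' exercise the event detector against known event structure.
#'
#' @param fix_durations fixation durations in seconds.
#' @param gap_durations gap durations in seconds (one fewer than
#'   fixations); for saccade gaps this is the transition time, for blink
#'   gaps the invalid span.
#' @param gap_kind `"saccade"` or `"blink"`, scalar or per-gap vector.
#' @param amplitude_deg angular distance between successive fixation
#'   locations for saccade gaps.
#' @param jitter_deg per-sample angular noise SD in degrees.
#' @param rate sampling rate in Hz.
#' @param seed RNG seed for the jitter.
#' @return list `trace` (a `binocular_trace`) and `truth` (data frame of
#'   intended fixations: `start`, `end`, `duration_ms`).
#' @export
synthetic_fixation_trace <- function(fix_durations, gap_durations,
                                     gap_kind = "saccade",
                                     amplitude_deg = 5, jitter_deg = 0.05,
                                     rate = 50, seed = NULL) {
  nf <- length(fix_durations)
  stopifnot(length(gap_durations) == nf - 1L)
  gap_kind <- rep(gap_kind, length.out = nf - 1L)
  # fixation locations on a horizontal arc, amplitude_deg apart when the
  # preceding gap is a saccade
  az <- numeric(nf)
  for (i in seq_len(nf - 1L)) {
    az[i + 1L] <- az[i] + if (gap_kind[i] == "saccade")
      amplitude_deg * (if (i %% 2L == 1L) 1 else -1) else 0
  }
  dir_of <- function(a) c(sin(a * pi / 180), 0, cos(a * pi / 180))
  dirs <- list(); valid <- logical(0)
  truth <- data.frame(start = numeric(), end = numeric())
  tcur <- 0
  push <- function(d, k, v) {
    for (j in seq_len(k)) dirs[[length(dirs) + 1L]] <<- d
    valid <<- c(valid, rep(v, k))
  }
  for (i in seq_len(nf)) {
    k <- max(1L, round(fix_durations[i] * rate))
    truth <- rbind(truth, data.frame(start = tcur,
                                     end = tcur + k / rate))
    push(dir_of(az[i]), k, TRUE)
    tcur <- tcur + k / rate
    if (i < nf) {
      kg <- round(gap_durations[i] * rate)
      if (kg > 0L) {
        if (gap_kind[i] == "blink") {
          push(dir_of(az[i]), kg, FALSE)
        } else {
          f <- seq_len(kg) / (kg + 1L)
          for (ff in f) {
            dirs[[length(dirs) + 1L]] <- slerp_dir(dir_of(az[i]),
                                                   dir_of(az[i + 1L]), ff)
            valid <- c(valid, TRUE)
          }
        }
        tcur <- tcur + kg / rate
      }
    }
  }
  n <- length(dirs)
  t <- (seq_len(n) - 1L) / rate
  m <- do.call(rbind, dirs)
  with_seed(seed, {
    s <- jitter_deg * pi / 180
    left <- normalize_rows(m + matrix(rnorm(3L * n, 0, s), ncol = 3L))
    right <- normalize_rows(m + matrix(rnorm(3L * n, 0, s), ncol = 3L))
    left[!valid, ] <- 0; right[!valid, ] <- 0
    truth$duration_ms <- (truth$end - truth$start) * 1000
    list(trace = binocular_trace(t, left, right, valid, valid),
         truth = truth)
  })
}

#' Combine a binocular trace into cyclopean samples for classification
#'
#' Valid-eye averaging (renormalized); a sample is valid when either eye is.
#'
#' @param trace a `binocular_trace`.
#' @return list `t`, `directions` (n x 3), `valid`.
#' @export
combine_binocular <- function(trace) {
  L <- as.matrix(trace[, c("ldx", "ldy", "ldz")])
  R <- as.matrix(trace[, c("rdx", "rdy", "rdz")])
  w <- trace$valid_l + trace$valid_r
  d <- (L * trace$valid_l + R * trace$valid_r) / pmax(w, 1L)
  list(t = trace$t, directions = normalize_rows(d), valid = w > 0)
}

synth_eeg <- function(profile, schedule, fs = 500,
                      channels = EEG_CHANNELS, seed = NULL) {
  T_end <- schedule$end[nrow(schedule)]
  n <- floor(T_end * fs)
  t <- (seq_len(n) - 1L) / fs
  in_dp <- rep(FALSE, n)
  for (i in which(schedule$phase_type == "DP")) {
    in_dp <- in_dp | (t >= schedule$start[i] & t < schedule$end[i])
  }
  with_seed(seed, {
    pink <- function() {
      # 1/f-shaped noise via spectral shaping
      half <- floor(n / 2)
      f <- seq_len(half) * fs / n
      amp <- 1 / sqrt(f)
      ph <- runif(half, 0, 2 * pi)
      spec <- complex(modulus = amp, argument = ph)
      full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-half])) else
        Conj(rev(spec)))
      x <- Re(fft(full, inverse = TRUE)) / n
      x / sd(x)
    }
    vals <- as.data.frame(matrix(0, n, length(channels)))
    names(vals) <- channels
    theta_f <- 5.5; beta_f <- 20
    for (ch in channels) {
      th_amp <- profile$theta_amp *
        ifelse(in_dp, profile$theta_dp_boost, 1) *
        (1 + 0.2 * sin(2 * pi * 0.05 * t + runif(1L, 0, 2 * pi)))
      x <- profile$eeg_noise_amp * pink() +
        th_amp * sin(2 * pi * theta_f * t + runif(1L, 0, 2 * pi)) +
        profile$beta_amp * sin(2 * pi * beta_f * t + runif(1L, 0, 2 * pi))
      vals[[ch]] <- x
    }
    time_series_stream("eeg", fs, t, vals)
  })
}

synth_head <- function(profile, duration, fs = 90, seed = NULL,
                       start = c(0, 1.6, 0)) {
  n <- floor(duration * fs)
  with_seed(seed, {
    steps <- matrix(rnorm(3L * n, 0, profile$head_step_sigma), n, 3L)
    pos <- sweep(apply(steps, 2L, cumsum), 2L, start, "+")
    time_series_stream("head", fs, (seq_len(n) - 1L) / fs,
                       data.frame(x = pos[, 1L], y = pos[, 2L], z = pos[, 3L]))
  })
}

simulate_responses <- function(profile, cpt, track, schedule, seed = NULL) {
  with_seed(seed, {
    state_at <- track$state[findInterval(cpt$onset, track$start)]
    on_task <- state_at == "on_task"
    is_target <- cpt$class == "target"
    # targets: respond unless lapsing (on task) / unless omitted (off task)
    hit <- is_target & (runif(nrow(cpt)) < ifelse(
      on_task, 1 - profile$omission_lapse,
      1 - profile$omission_prob_offtask))
    rts <- rlnorm(sum(hit), log(profile$rt_median / 1000), profile$rt_sigma)
    rts <- pmin(pmax(rts, 0.15), 1.15)
    resp <- cpt$onset[hit] + rts
    # commissions: rare impulsive presses to non-targets, more during DP
    ph <- phase_at(schedule, cpt$onset)
    dp <- schedule$phase_type[ph] == "DP"
    p_comm <- profile$commission_prob *
      ifelse(dp, profile$commission_dp_factor, 1)
    comm <- !is_target & (runif(nrow(cpt)) < p_comm)
    if (any(comm)) {
      crts <- rlnorm(sum(comm), log(profile$rt_median / 1000),
                     profile$rt_sigma)
      resp <- c(resp, cpt$onset[comm] + pmin(pmax(crts, 0.15), 1.15))
    }
    sort(resp)
  })
}

#' Simulate one experimental block
#'
#' Generates the CPT stimulus stream, the latent attention track (with
#' distractor activations and, in real mode, feedback coupling), renders
#' gaze / head / EEG streams and keypresses, classifies the rendered gaze
#' against the scene, and runs the feedback controller on the classified
#' state trace to produce the recorded feedback events.
#'
#' @param profile a [participant_profile()].
#' @param condition `"real"`, `"sham"` or `"none"`.
#' @param schedule a `phase_schedule`.
#' @param sc a `scene`.
#' @param seed RNG seed (sub-seeds are derived per stream).
#' @param include_eeg simulate the EEG stream (the slowest stream; disable
#'   for analyses that do not need it).
#' @param include_gaze render the gaze stream and run the feedback
#'   controller on it; disable for response-only simulations.
#' @param loss_rate per-sample both-eye dropout probability.
#' @return list: `block` (a `block_record`), `truth` (latent track,
#'   ground-truth saccades, classified samples, activations).
#' @export
simulate_block <- function(profile, condition, schedule = build_phase_schedule(),
                           sc = default_scene(), seed = 1L,
                           include_eeg = TRUE, include_gaze = TRUE,
                           loss_rate = 0) {
  sub <- function(k) as.integer((as.numeric(seed) * 97 + k) %% 2147483562)
  activations <- distractor_schedule(schedule, seed = sub(1L),
                                     collider_ids = scene_distractor_ids(sc))
  att <- simulate_attention(profile, schedule, activations,
                            feedback_mode = condition, seed = sub(2L))
  if (include_gaze) {
    rg <- render_gaze(att$track, sc, seed = sub(3L),
                      jitter_deg = profile$jitter_deg, loss_rate = loss_rate)
    comb <- combine_binocular(rg$trace)
    n <- length(comb$t)
    origins <- matrix(rg$origins$cyclopean, n, 3L, byrow = TRUE)
    classified <- classify_gaze_samples(comb$t, origins, comb$directions,
                                        comb$valid, sc, activations)
    fb_cfg <- feedback_config(condition, seed = sub(4L))
    fb <- if (condition == "none") empty_feedback_events() else
      run_controller(classified, fb_cfg)
  } else {
    rg <- NULL; classified <- NULL; fb <- empty_feedback_events()
  }
  cpt <- generate_cpt_block(seed = sub(5L),
                            n_trials = max(2L, floor(schedule_duration(schedule) / 1.2)))
  responses <- simulate_responses(profile, cpt, att$track, schedule,
                                  seed = sub(6L))
  head <- synth_head(profile, schedule_duration(schedule), seed = sub(7L))
  eeg <- if (include_eeg) synth_eeg(profile, schedule, seed = sub(8L)) else NULL
  es <- with_seed(sub(9L), {
    v <- round(rnorm(3L, profile$es_mean, 0.7))
    setNames(pmin(pmax(v, -3), 3),
             c("inattention", "hyperactivity", "impulsivity"))
  })
  gaze <- NULL
  if (include_gaze) {
    ori <- rg$origins
    gaze_vals <- data.frame(
      lx = ori$left[1L], ly = ori$left[2L], lz = ori$left[3L],
      ldx = rg$trace$ldx, ldy = rg$trace$ldy, ldz = rg$trace$ldz,
      validity_l = rg$trace$valid_l,
      rx = ori$right[1L], ry = ori$right[2L], rz = ori$right[3L],
      rdx = rg$trace$rdx, rdy = rg$trace$rdy, rdz = rg$trace$rdz,
      validity_r = rg$trace$valid_r)
    gaze <- time_series_stream("gaze", 50, rg$trace$t, gaze_vals,
                               validity = rg$trace$valid_l | rg$trace$valid_r)
  }
  blk <- block_record(condition, schedule, gaze = gaze, head = head,
                      eeg = eeg, cpt_block = cpt, responses = responses,
                      feedback_events = fb, activations = activations,
                      experience_sampling = es)
  list(block = blk,
       truth = list(track = att$track,
                    saccades = if (include_gaze) rg$truth$saccades else NULL,
                    classified = classified, activations = activations,
                    feedback_episodes = att$feedback_episodes))
}

#' Simulate a full three-block session
#'
#' @param participant_id identifier.
#' @param group `"ADHD"` or `"HC"`.
#' @param condition_order permutation of the three feedback conditions.
#' @param profile optional [participant_profile()] (defaults to the group
#'   default).
#' @param schedule a `phase_schedule` shared by the blocks (whether the
#'   block starts with DP or NDP is the caller's counterbalancing choice).
#' @param sc a `scene`.
#' @param seed RNG seed.
#' @param include_eeg simulate EEG streams.
#' @param include_gaze render gaze streams (see [simulate_block()]).
#' @param loss_rate per-sample both-eye dropout probability.
#' @return list `session` (a `session_record`) and `truth` (per-block
#'   ground truth).
#' @export
simulate_session <- function(participant_id, group,
                             condition_order = c("real", "sham", "none"),
                             profile = NULL,
                             schedule = build_phase_schedule(),
                             sc = default_scene(), seed = 1L,
                             include_eeg = TRUE, include_gaze = TRUE,
                             loss_rate = 0) {
  if (is.null(profile)) profile <- participant_profile(group)
  blocks <- vector("list", 3L)
  truth <- vector("list", 3L)
  for (i in seq_len(3L)) {
    sb <- simulate_block(profile, condition_order[i], schedule, sc,
                         seed = as.integer((as.numeric(seed) * 131 + i) %% 2147483562),
                         include_eeg = include_eeg,
                         include_gaze = include_gaze, loss_rate = loss_rate)
    blocks[[i]] <- sb$block
    truth[[i]] <- sb$truth
  }
  recog <- with_seed(as.integer((as.numeric(seed) * 131 + 7) %% 2147483562), {
    tr <- sample(rep(c(TRUE, FALSE), 30L))
    correct <- runif(60L) < profile$recognition_accuracy
    data.frame(judgment = ifelse(correct, tr, !tr), truth = tr)
  })
  list(session = session_record(participant_id, group, condition_order,
                                blocks, recognition = recog),
       truth = truth)
}

#' Simulate a two-group cohort
#'
#' Condition orders cycle through all six permutations and the starting
#' phase type alternates across participants, mirroring the study's
#' counterbalancing.  The study-sized cohort is 18 ADHD + 18 HC.
#'
#' @param n_adhd,n_hc group sizes.
#' @param seed RNG seed.
#' @param phase_seconds,n_phases block phase structure (defaults: six
#'   3-minute phases).
#' @param sc a `scene`.
#' @param include_eeg simulate EEG streams.
#' @param include_gaze render gaze streams (see [simulate_block()]).
#' @param profiles optional named list `list(ADHD = , HC = )` of profiles.
#' @return list of `simulate_session()` results.
#' @export
simulate_cohort <- function(n_adhd = 18L, n_hc = 18L, seed = 7L,
                            phase_seconds = 180, n_phases = 6L,
                            sc = default_scene(), include_eeg = TRUE,
                            include_gaze = TRUE, profiles = NULL) {
  perms <- list(c("real", "sham", "none"), c("real", "none", "sham"),
                c("sham", "real", "none"), c("sham", "none", "real"),
                c("none", "real", "sham"), c("none", "sham", "real"))
  groups <- c(rep("ADHD", n_adhd), rep("HC", n_hc))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    prof <- if (!is.null(profiles)) profiles[[g]] else participant_profile(g)
    schedule <- build_phase_schedule(
      if (i %% 2L == 1L) "DP" else "NDP", n_phases, phase_seconds)
    out[[i]] <- simulate_session(
      sprintf("%s_%02d", tolower(g), i), g,
      condition_order = perms[[(i - 1L) %% 6L + 1L]],
      profile = prof, schedule = schedule, sc = sc,
      seed = as.integer((as.numeric(seed) * 7919 + i) %% 2147483562),
      include_eeg = include_eeg, include_gaze = include_gaze)
  }
  out
}
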