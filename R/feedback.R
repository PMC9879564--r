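# Gaze-contingent feedback controller: a deterministic state machine that
# consumes the 50 Hz gaze-state stream and emits audiovisual feedback events
# under a real, sham, or no-feedback policy.
#
# A loss of task focus is registered when the gaze has been off the canvas
# for more than 2 s, or on a distractor for more than 0.5 s.  Real mode
# plays feedback immediately; sham mode delays it by a quasi-random 20-30 s
# (frequency-matched but decoupled from behaviour); feedback stops when the
# gaze returns to the canvas or after 2 s, and a 5 s refractory period
# prevents over-extensive triggering.

#' Feedback controller configuration
#'
#' Defaults follow the study protocol: 2 s off-canvas threshold, 0.5 s
#' distractor threshold, 5 s refractory period, 2 s maximum feedback
#' duration, 0.5 s fade-in to 35% screen coverage, and a 20-30 s sham
#' delay.
#'
#' @param mode `"real"`, `"sham"` or `"none"`.
#' @param off_canvas_threshold seconds off the canvas before registration.
#' @param distractor_threshold seconds on a distractor before registration.
#' @param refractory minimum seconds between a feedback offset and the next
#'   onset.
#' @param max_duration maximum feedback duration in seconds.
#' @param fade_in fade-in time of the black overlay in seconds.
#' @param fade_max maximum overlay opacity/coverage fraction.
#' @param sham_delay_range two-element range (seconds) of the sham delay.
#' @param seed RNG seed used by [run_controller()] for the sham delays.
#' @return a `feedback_config` list.
#' @export
feedback_config <- function(mode = c("real", "sham", "none"),
                            off_canvas_threshold = 2.0,
                            distractor_threshold = 0.5,
                            refractory = 5.0, max_duration = 2.0,
                            fade_in = 0.5, fade_max = 0.35,
                            sham_delay_range = c(20, 30), seed = NULL) {
  mode <- match.arg(mode)
  durs <- c(off_canvas_threshold, distractor_threshold, refractory,
            max_duration, fade_in)
  if (any(durs <= 0)) stop("all controller durations must be positive")
  if (length(sham_delay_range) != 2L ||
      sham_delay_range[1L] > sham_delay_range[2L]) {
    stop("sham_delay_range must be an increasing two-element range")
  }
  structure(list(mode = mode, off_canvas_threshold = off_canvas_threshold,
                 distractor_threshold = distractor_threshold,
                 refractory = refractory, max_duration = max_duration,
                 fade_in = fade_in, fade_max = fade_max,
                 sham_delay_range = sham_delay_range, seed = seed),
            class = "feedback_config")
}

#' Build a sampled gaze-state trace from state/duration segments
#'
#' Convenience constructor for controller inputs: a 50 Hz (by default)
#' trace visiting the given states for the given durations.
#'
#' @param states character vector of gaze states.
#' @param durations matching vector of segment durations in seconds.
#' @param rate sampling rate in Hz.
#' @return data frame `t`, `state` suitable for [run_controller()].
#' @export
state_trace <- function(states, durations, rate = 50) {
  stopifnot(length(states) == length(durations), all(durations > 0))
  n <- floor(sum(durations) * rate)
  t <- (seq_len(n) - 1L) / rate
  bounds <- cumsum(c(0, durations))
  idx <- findInterval(t, bounds, rightmost.closed = TRUE)
  idx[idx > length(states)] <- length(states)
  data.frame(t = t, state = states[idx], stringsAsFactors = FALSE)
}

#' Initial controller state
#'
#' @return a `controller_state` list with zeroed timers, no active event,
#'   no pending sham, and an expired refractory clock.
#' @export
controller_init <- function() {
  structure(list(off_timer = 0, distractor_timer = 0,
                 active = NULL, refractory_until = -Inf,
                 pending_sham = NULL, registration = NULL,
                 last_t = NA_real_),
            class = "controller_state")
}

#' Advance the controller by one gaze sample
#'
#' Pure transition function: consumes one classified gaze-state sample and
#' returns the updated state plus any feedback event completed at this step.
#' Timers accumulate while the gaze is off the canvas (the distractor timer
#' only during distractor fixation), reset on any task-focus sample, and
#' freeze during invalid (blink) samples.  An active event ends at the first
#' task-focus sample or after `max_duration`, whichever comes first; its
#' offset starts the refractory period.  Sham onsets fire at their scheduled
#' delay regardless of the momentary gaze state (subject to the refractory
#' rule); at most one sham is pending at a time.
#'
#' @param state a `controller_state`.
#' @param gaze_state one of `task_focus`, `distractor_focus`,
#'   `gaze_wandering`, `invalid`.
#' @param t sample time in seconds (strictly increasing across calls).
#' @param dt time since the previous sample (> 0).
#' @param config a `feedback_config`.
#' @return list with elements `state` (updated) and `event` (a one-row data
#'   frame when an event completed at this step, else `NULL`).
#' @export
step_controller <- function(state, gaze_state, t, dt, config) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.na(state$last_t) && t <= state$last_t) {
    stop(sprintf("non-monotonic time: %g after %g", t, state$last_t))
  }
  state$last_t <- t
  completed <- NULL
  on_canvas <- identical(gaze_state, "task_focus")
  is_invalid <- identical(gaze_state, "invalid")

  # 1. terminate an active event
  if (!is.null(state$active)) {
    hard_end <- state$active$onset + config$max_duration
    if (on_canvas || t >= hard_end) {
      offset <- min(t, hard_end)
      completed <- data.frame(
        onset = state$active$onset, offset = offset,
        cause = state$active$cause, mode = config$mode,
        registration_time = state$active$registration_time,
        stringsAsFactors = FALSE)
      state$refractory_until <- offset + config$refractory
      state$active <- NULL
      state$off_timer <- 0
      state$distractor_timer <- 0
      state$registration <- NULL
    }
  }

  # 2. timer accumulation (invalid samples freeze both timers)
  if (!is_invalid && is.null(state$active)) {
    if (on_canvas) {
      state$off_timer <- 0
      state$distractor_timer <- 0
      state$registration <- NULL
    } else {
      state$off_timer <- state$off_timer + dt
      state$distractor_timer <- if (identical(gaze_state, "distractor_focus"))
        state$distractor_timer + dt else 0
    }
  }

  # 3. registration: first sample at which a threshold is strictly exceeded
  # (a one-nanosecond guard keeps accumulated floating-point error from
  # moving the crossing by one sample)
  eps <- 1e-9
  crossed <- state$distractor_timer > config$distractor_threshold + eps ||
    state$off_timer > config$off_canvas_threshold + eps
  if (crossed && is.null(state$registration) && is.null(state$active)) {
    cause <- if (state$distractor_timer > config$distractor_threshold + eps)
      "distractor" else "off_canvas"
    state$registration <- list(time = t, cause = cause)
    if (config$mode == "sham" && is.null(state$pending_sham)) {
      delay <- runif(1L, config$sham_delay_range[1L],
                     config$sham_delay_range[2L])
      state$pending_sham <- list(fire_at = t + delay, registration_time = t)
    }
  }

  # 4. onset
  if (is.null(state$active) && t >= state$refractory_until) {
    if (config$mode == "real" && crossed) {
      state$active <- list(onset = t, cause = state$registration$cause,
                           registration_time = state$registration$time)
    } else if (config$mode == "sham" && !is.null(state$pending_sham) &&
               t >= state$pending_sham$fire_at) {
      state$active <- list(onset = t, cause = "sham",
                           registration_time = state$pending_sham$registration_time)
      state$pending_sham <- NULL
    }
  }

  list(state = state, event = completed)
}

#' Run the controller over a full gaze-state trace
#'
#' Left fold of [step_controller()] over a time-ordered trace.  Real and
#' no-feedback modes are fully deterministic; sham mode is reproducible via
#' `config$seed`.  An event still active at the end of the trace is closed
#' at `min(trace end, onset + max_duration)`.
#'
#' @param trace data frame with columns `t` (seconds, strictly increasing)
#'   and `state` (gaze states as in [classify_gaze_samples()]).
#' @param config a `feedback_config`.
#' @return data frame of feedback events: `onset`, `offset`, `cause`,
#'   `mode`, `registration_time`.
#' @export
run_controller <- function(trace, config) {
  stopifnot(all(c("t", "state") %in% names(trace)))
  n <- nrow(trace)
  if (n == 0L) return(empty_feedback_events())
  tt <- trace$t
  if (n > 1L && any(diff(tt) <= 0)) stop("trace times must be strictly increasing")
  dts <- if (n > 1L) c(diff(tt)[1L], diff(tt)) else 1 / 50
  with_seed(config$seed, {
    state <- controller_init()
    events <- vector("list", 32L)
    k <- 0L
    for (i in seq_len(n)) {
      res <- step_controller(state, trace$state[i], tt[i], dts[i], config)
      state <- res$state
      if (!is.null(res$event)) {
        k <- k + 1L
        events[[k]] <- res$event
      }
    }
    if (!is.null(state$active)) {
      offset <- min(tt[n], state$active$onset + config$max_duration)
      if (offset > state$active$onset) {
        k <- k + 1L
        events[[k]] <- data.frame(
          onset = state$active$onset, offset = offset,
          cause = state$active$cause, mode = config$mode,
          registration_time = state$active$registration_time,
          stringsAsFactors = FALSE)
      }
    }
    if (k == 0L) empty_feedback_events() else
      do.call(rbind, events[seq_len(k)])
  })
}

#' Overlay opacity envelope of a feedback event
#'
#' Linear ramp from 0 to `fade_max` over the fade-in time, then constant
#' until the event offset; 0 outside the event.
#'
#' @param event one-row feedback event (fields `onset`, `offset`).
#' @param t time(s) at which to evaluate the envelope.
#' @param config a `feedback_config`.
#' @return numeric opacity fraction(s) in `[0, fade_max]`.
#' @export
feedback_envelope <- function(event, t, config = feedback_config("real")) {
  inside <- t >= event$onset & t <= event$offset
  ramp <- pmin((t - event$onset) / config$fade_in, 1) * config$fade_max
  ifelse(inside, ramp, 0)
}
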