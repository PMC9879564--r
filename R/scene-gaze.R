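# Gaze-state classification by ray-collider intersection, distractor event
# scheduling, state-interval construction, and dwell-time / distractibility
# summaries.
#
# Three mutually exclusive gaze-direction states (plus invalid for blinks):
#   task_focus       gaze ray hits the CPT canvas
#   distractor_focus gaze ray hits the collider of a currently active
#                    distractor (auditory distractors get generous colliders
#                    at the sound-source location)
#   gaze_wandering   gaze hits neither - an oculomotor proxy for mind
#                    wandering

GAZE_STATES <- c("task_focus", "distractor_focus", "gaze_wandering", "invalid")
DISTRACTOR_MODALITIES <- c("visual", "auditory", "audiovisual")

#' Define a scene collider
#'
#' @param object_id identifier string.
#' @param kind `"canvas"`, `"distractor"` or `"other"`.
#' @param shape `"box"` (axis-aligned) or `"sphere"`.
#' @param center numeric length-3 center in meters (scene coordinates).
#' @param half_extents for boxes: numeric length-3 positive half-widths.
#' @param radius for spheres: positive radius in meters.
#' @return a `collider` list.
#' @export
collider <- function(object_id, kind = c("canvas", "distractor", "other"),
                     shape = c("box", "sphere"), center,
                     half_extents = NULL, radius = NULL) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (shape == "box") {
    half_extents <- as.numeric(half_extents)
    if (length(half_extents) != 3L || any(half_extents <= 0)) {
      stop("box colliders need three positive half extents")
    }
  } else {
    if (is.null(radius) || radius <= 0) stop("sphere colliders need radius > 0")
  }
  structure(list(object_id = object_id, kind = kind, shape = shape,
                 center = center, half_extents = half_extents,
                 radius = radius),
            class = "collider")
}

#' Assemble a scene from colliders
#'
#' Exactly one canvas collider is required.
#'
#' @param colliders list of [collider()] objects.
#' @return a `scene` list with the canvas first.
#' @export
scene <- function(colliders) {
  kinds <- vapply(colliders, function(cl) cl$kind, character(1L))
  if (sum(kinds == "canvas") != 1L) {
    stop("a scene must contain exactly one canvas collider")
  }
  structure(list(colliders = colliders[order(kinds != "canvas")]),
            class = "scene")
}

#' Default virtual seminar room geometry
#'
#' A seated participant (eyes near `(0, 1.2, 0)`, looking toward +z) faces a
#' 3 x 2 m canvas at 3 m; six distractor colliders (door, window, phone,
#' walking avatar, cabinet, passing fire truck) sit outside the canvas
#' frustum so that a canvas-directed ray can never be occluded.
#'
#' @return a `scene`.
#' @export
default_scene <- function() {
  scene(list(
    collider("canvas", "canvas", "box", c(0, 1.5, 3.0), c(1.5, 1.0, 0.05)),
    collider("door", "distractor", "box", c(-2.5, 1.2, 2.0), c(0.4, 1.0, 0.2)),
    collider("window_birds", "distractor", "box", c(2.4, 1.6, 1.8),
             c(0.5, 0.6, 0.2)),
    collider("desk_phone", "distractor", "sphere", c(1.6, 0.9, 1.2),
             radius = 0.25),
    collider("avatar_walk", "distractor", "box", c(-1.9, 1.0, 2.6),
             c(0.4, 0.9, 0.3)),
    collider("cabinet", "distractor", "box", c(-2.4, 1.4, 3.4),
             c(0.5, 0.9, 0.3)),
    collider("fire_truck", "distractor", "box", c(2.8, 1.5, 2.8),
             c(0.7, 0.9, 0.5))
  ))
}

scene_distractor_ids <- function(sc) {
  ids <- vapply(sc$colliders, function(cl) cl$object_id, character(1L))
  ids[vapply(sc$colliders, function(cl) cl$kind, character(1L)) == "distractor"]
}

# Vectorized ray-collider intersection distances for n rays against one
# collider; returns Inf for misses.  origins/directions are n x 3 matrices.
ray_collider_distance <- function(origins, directions, cl) {
  n <- nrow(directions)
  if (cl$shape == "box") {
    lo <- matrix(cl$center - cl$half_extents, n, 3L, byrow = TRUE)
    hi <- matrix(cl$center + cl$half_extents, n, 3L, byrow = TRUE)
    d <- directions
    d[abs(d) < 1e-12] <- 1e-12          # avoid 0/0 on slab boundaries
    t1 <- (lo - origins) / d
    t2 <- (hi - origins) / d
    tmin <- pmax(pmin(t1[, 1], t2[, 1]), pmin(t1[, 2], t2[, 2]),
                 pmin(t1[, 3], t2[, 3]))
    tmax <- pmin(pmax(t1[, 1], t2[, 1]), pmax(t1[, 2], t2[, 2]),
                 pmax(t1[, 3], t2[, 3]))
    hit <- tmax >= pmax(tmin, 0)
    dist <- ifelse(tmin > 0, tmin, tmax)
    ifelse(hit & dist > 0, dist, Inf)
  } else {
    oc <- origins - matrix(cl$center, n, 3L, byrow = TRUE)
    b <- rowSums(directions * oc)
    cc <- rowSums(oc * oc) - cl$radius^2
    disc <- b^2 - cc
    root <- sqrt(pmax(disc, 0))
    near <- -b - root
    far <- -b + root
    dist <- ifelse(near > 0, near, far)
    ifelse(disc >= 0 & dist > 0, dist, Inf)
  }
}

#' Schedule distractor activations for the DP phases
#'
#' Within each distractor phase, `floor(duration / interval)` activations
#' are placed exactly `interval` seconds apart starting at the phase onset
#' (six per standard 3-min DP at 30 s); none occur during NDP.  Distractor
#' identities are drawn without replacement within a phase from the pooled
#' visual/auditory/audiovisual inventories.
#'
#' @param phase_schedule a `phase_schedule`.
#' @param pools named integer vector of pool sizes per modality
#'   (default `c(visual = 18, auditory = 18, audiovisual = 18)`).
#' @param interval spacing between activations in seconds (default 30).
#' @param seed RNG seed for the random selection.
#' @param collider_ids optional character vector of distractor collider ids;
#'   each activation is assigned one (sampled per activation) so the gaze
#'   classifier knows where the event plays.
#' @param linger seconds a distractor collider stays hittable after its
#'   onset, emulating the animation duration (default 3).
#' @return data frame of activations: `onset`, `end`, `phase_index`,
#'   `distractor_id`, `modality`, `collider_id`.
#' @export
distractor_schedule <- function(phase_schedule,
                                pools = c(visual = 18L, auditory = 18L,
                                          audiovisual = 18L),
                                interval = 30, seed = NULL,
                                collider_ids = NULL, linger = 3) {
  if (interval <= 0) stop("interval must be positive")
  pool_ids <- unlist(lapply(names(pools), function(m) {
    sprintf("%s_%02d", m, seq_len(pools[[m]]))
  }))
  pool_mod <- rep(names(pools), pools)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(phase_schedule))) {
      if (phase_schedule$phase_type[i] != "DP") next
      dur <- phase_schedule$end[i] - phase_schedule$start[i]
      k <- floor(dur / interval)
      if (k == 0L) {
        warning(sprintf("phase %d shorter than the %g s interval: no distractors",
                        i, interval))
        next
      }
      pick <- sample.int(length(pool_ids), k)   # without replacement per phase
      rows[[length(rows) + 1L]] <- data.frame(
        onset = phase_schedule$start[i] + (seq_len(k) - 1L) * interval,
        phase_index = i,
        distractor_id = pool_ids[pick],
        modality = pool_mod[pick],
        collider_id = if (is.null(collider_ids)) NA_character_ else
          sample(collider_ids, k, replace = k > length(collider_ids)),
        stringsAsFactors = FALSE
      )
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(onset = numeric(), phase_index = integer(),
                 distractor_id = character(), modality = character(),
                 collider_id = character(), stringsAsFactors = FALSE)
    out$end <- out$onset + linger
    out[, c("onset", "end", "phase_index", "distractor_id", "modality",
            "collider_id")]
  })
}

#' Classify gaze samples against the scene
#'
#' Casts each valid gaze ray against the canvas and every distractor
#' collider active at the sample time; the nearest intersection wins, with
#' ties broken canvas-first.  Invalid samples (blinks, zero-length
#' directions) are classed `invalid`.
#'
#' @param t numeric vector of sample times (seconds).
#' @param origins n x 3 matrix of ray origins (meters).
#' @param directions n x 3 matrix of gaze directions (unit vectors).
#' @param valid logical vector of per-sample validity.
#' @param sc a `scene`.
#' @param activations distractor activation table from
#'   [distractor_schedule()] (with `collider_id` filled); `NULL` means no
#'   distractor is ever active.
#' @return data frame `t`, `state`, `hit_object_id`.
#' @export
classify_gaze_samples <- function(t, origins, directions, valid, sc,
                                  activations = NULL) {
  n <- length(t)
  origins <- matrix(as.numeric(origins), n, 3L)
  directions <- matrix(as.numeric(directions), n, 3L)
  norms <- sqrt(rowSums(directions^2))
  valid <- as.logical(valid) & norms > 1e-9
  directions[valid, ] <- directions[valid, , drop = FALSE] / norms[valid]

  best_dist <- rep(Inf, n)
  best_id <- rep(NA_character_, n)
  best_kind <- rep(NA_character_, n)
  for (cl in sc$colliders) {
    active <- rep(TRUE, n)
    if (cl$kind == "distractor") {
      active <- rep(FALSE, n)
      if (!is.null(activations) && nrow(activations)) {
        acts <- activations[activations$collider_id == cl$object_id, ,
                            drop = FALSE]
        for (j in seq_len(nrow(acts))) {
          active <- active | (t >= acts$onset[j] & t < acts$end[j])
        }
      }
    }
    d <- ray_collider_distance(origins, directions, cl)
    d[!active] <- Inf
    # canvas-first tie break: strict < for later colliders, <= never used
    better <- d < best_dist
    best_dist[better] <- d[better]
    best_id[better] <- cl$object_id
    best_kind[better] <- cl$kind
  }
  state <- rep("gaze_wandering", n)
  state[best_kind %in% "canvas"] <- "task_focus"
  state[best_kind %in% "distractor"] <- "distractor_focus"
  state[!valid] <- "invalid"
  best_id[!valid | state == "gaze_wandering"] <- NA_character_
  data.frame(t = t, state = state, hit_object_id = best_id,
             stringsAsFactors = FALSE)
}

#' Run-length encode classified samples into state intervals
#'
#' Each interval ends at the time of the next state change; the final
#' interval ends at the last timestamp, so the intervals exactly tile
#' `[t_1, t_n]`.
#'
#' @param classified data frame with columns `t` and `state` (and optionally
#'   `hit_object_id`), time-ordered.
#' @return data frame `state`, `start`, `end`, `hit_object_id` with
#'   contiguous, state-alternating rows.
#' @export
intervals_from_samples <- function(classified) {
  t <- classified$t
  if (is.unsorted(t, strictly = TRUE)) stop("samples must be time-ordered")
  n <- length(t)
  if (n == 0L) {
    return(data.frame(state = character(), start = numeric(), end = numeric(),
                      hit_object_id = character(), stringsAsFactors = FALSE))
  }
  r <- rle(classified$state)
  starts_idx <- cumsum(c(1L, head(r$lengths, -1L)))
  ends_idx <- cumsum(r$lengths)
  hit <- if (is.null(classified$hit_object_id)) rep(NA_character_, length(r$values))
         else classified$hit_object_id[starts_idx]
  data.frame(
    state = r$values,
    start = t[starts_idx],
    end = c(t[starts_idx[-1L]], t[n]),
    hit_object_id = hit,
    stringsAsFactors = FALSE
  )
}

#' Dwell-time percentages and the distractibility score
#'
#' Percentages are of the total block duration (invalid/blink time absorbs
#' any uncovered remainder so the four percentages always close to 100).
#' The composite score is
#' `(distractor-focus % + gaze-wandering %) / task-focus %`; higher values
#' indicate a higher level of distraction.
#'
#' @param intervals state intervals from [intervals_from_samples()].
#' @param block_duration block length in seconds.
#' @return a `dwell_summary` list: `pct_task_focus`,
#'   `pct_distractor_focus`, `pct_gaze_wandering`, `pct_invalid`,
#'   `distractibility_score`.
#' @export
dwell_summary <- function(intervals, block_duration) {
  if (block_duration <= 0) stop("block_duration must be positive")
  dur <- intervals$end - intervals$start
  tot <- vapply(GAZE_STATES, function(s) sum(dur[intervals$state == s]),
                numeric(1L))
  pct <- 100 * tot / block_duration
  pct["invalid"] <- 100 - sum(pct[c("task_focus", "distractor_focus",
                                    "gaze_wandering")])
  if (pct[["task_focus"]] == 0) {
    stop("distractibility score undefined: task-focus time is zero")
  }
  structure(
    list(pct_task_focus = pct[["task_focus"]],
         pct_distractor_focus = pct[["distractor_focus"]],
         pct_gaze_wandering = pct[["gaze_wandering"]],
         pct_invalid = pct[["invalid"]],
         distractibility_score =
           (pct[["distractor_focus"]] + pct[["gaze_wandering"]]) /
           pct[["task_focus"]]),
    class = "dwell_summary"
  )
}

#' @export
print.dwell_summary <- function(x, ...) {
  cat(sprintf(
    "<dwell_summary> task %.2f%% | distractor %.2f%% | wandering %.2f%% | invalid %.2f%% | score %.3f\n",
    x$pct_task_focus, x$pct_distractor_focus, x$pct_gaze_wandering,
    x$pct_invalid, x$distractibility_score))
  invisible(x)
}
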