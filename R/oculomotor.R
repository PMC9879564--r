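# Offline eye-movement preprocessing and adaptive velocity-based
# saccade/fixation detection.
#
# Pipeline: per-eye linear interpolation across gaps of at most 75 ms,
# one-eye loss compensated from the other eye, binocular averaging,
# sample-to-sample angular velocities smoothed with a 2nd-order
# Savitzky-Golay filter, an adaptive data-driven velocity threshold
# (iterative mean + 6 SD of sub-threshold samples), fixations shorter than
# 60 ms discarded and fixations separated by gaps of at most 40 ms merged.

#' Detector parameters
#'
#' @param sg_order Savitzky-Golay polynomial order (2).
#' @param sg_window Savitzky-Golay window length in samples (odd, > order;
#'   default 5, about 100 ms at 50 Hz).
#' @param max_gap_interp longest interpolatable gap in seconds (0.075).
#' @param min_fixation minimum retained fixation duration in seconds (0.060).
#' @param merge_interval maximum inter-fixation gap that is merged, in
#'   seconds (0.040).
#' @param threshold_multiplier SD multiplier of the adaptive threshold (6).
#' @param threshold_init initial peak-velocity threshold in deg/s (100).
#' @param threshold_tol convergence tolerance in deg/s (1).
#' @return a `detector_params` list.
#' @export
detector_params <- function(sg_order = 2L, sg_window = 5L,
                            max_gap_interp = 0.075, min_fixation = 0.060,
                            merge_interval = 0.040,
                            threshold_multiplier = 6,
                            threshold_init = 100, threshold_tol = 1) {
  if (sg_window %% 2L != 1L || sg_window <= sg_order) {
    stop("sg_window must be odd and larger than sg_order")
  }
  if (any(c(max_gap_interp, min_fixation, merge_interval, threshold_init,
            threshold_tol) <= 0)) {
    stop("all detector durations and thresholds must be positive")
  }
  structure(list(sg_order = as.integer(sg_order),
                 sg_window = as.integer(sg_window),
                 max_gap_interp = max_gap_interp,
                 min_fixation = min_fixation,
                 merge_interval = merge_interval,
                 threshold_multiplier = threshold_multiplier,
                 threshold_init = threshold_init,
                 threshold_tol = threshold_tol),
            class = "detector_params")
}

#' Construct a binocular gaze-direction trace
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param left,right n x 3 matrices of per-eye gaze direction vectors.
#' @param valid_left,valid_right logical validity flags per eye.
#' @return a `binocular_trace` data frame.
#' @export
binocular_trace <- function(t, left, right, valid_left, valid_right) {
  left <- matrix(as.numeric(left), length(t), 3L)
  right <- matrix(as.numeric(right), length(t), 3L)
  out <- data.frame(t = t,
                    ldx = left[, 1], ldy = left[, 2], ldz = left[, 3],
                    rdx = right[, 1], rdy = right[, 2], rdz = right[, 3],
                    valid_l = as.logical(valid_left),
                    valid_r = as.logical(valid_right))
  class(out) <- c("binocular_trace", "data.frame")
  out
}

#' Extract a binocular trace from a gaze stream
#'
#' @param stream the `gaze` `ts_stream` of a block (direction columns
#'   `ldx..ldz`, `rdx..rdz` plus `validity_l`/`validity_r`).
#' @return a `binocular_trace`.
#' @export
as_binocular_trace <- function(stream) {
  v <- stream$values
  binocular_trace(stream$t,
                  as.matrix(v[, c("ldx", "ldy", "ldz")]),
                  as.matrix(v[, c("rdx", "rdy", "rdz")]),
                  v$validity_l, v$validity_r)
}

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# linear interpolation of direction components across invalid runs whose
# missing-data duration (run span minus one nominal sample period) does not
# exceed max_gap; longer gaps stay invalid.
interpolate_gaps <- function(t, dirs, valid, max_gap) {
  if (all(valid) || !any(valid)) return(list(dirs = dirs, valid = valid))
  dt_nom <- median(diff(t))
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(!r$values)) {
    i0 <- starts[k] - 1L
    i1 <- ends[k] + 1L
    if (i0 < 1L || i1 > length(t)) next      # gap touches trace boundary
    gap_dur <- t[i1] - t[i0] - dt_nom
    if (gap_dur <= max_gap + 1e-9) {
      idx <- starts[k]:ends[k]
      for (c in 1:3) {
        dirs[idx, c] <- approx(x = t[c(i0, i1)], y = dirs[c(i0, i1), c],
                               xout = t[idx])$y
      }
      dirs[idx, ] <- normalize_rows(dirs[idx, , drop = FALSE])
      valid[idx] <- TRUE
    }
  }
  list(dirs = dirs, valid = valid)
}

#' Preprocess a binocular trace to a combined monocular trace
#'
#' Per eye, gaps of at most `max_gap_interp` are linearly interpolated on
#' the direction components (renormalized); loss of one eye is compensated
#' from the other; where both eyes are valid the directions are averaged and
#' renormalized.  Longer gaps remain invalid.  The fraction of raw samples
#' with no valid eye is reported as `data_loss_pct`, the post-interpolation
#' fraction as `residual_loss_pct` (attributes of the result).
#'
#' @param trace a `binocular_trace`.
#' @param params a [detector_params()].
#' @return data frame `t`, `dx`, `dy`, `dz`, `valid` with loss attributes.
#' @export
preprocess_gaze <- function(trace, params = detector_params()) {
  t <- trace$t
  if (!any(trace$valid_l | trace$valid_r)) {
    stop("trace contains no valid samples in either eye")
  }
  raw_loss <- 100 * mean(!(trace$valid_l | trace$valid_r))
  L <- interpolate_gaps(t, as.matrix(trace[, c("ldx", "ldy", "ldz")]),
                        trace$valid_l, params$max_gap_interp)
  R <- interpolate_gaps(t, as.matrix(trace[, c("rdx", "rdy", "rdz")]),
                        trace$valid_r, params$max_gap_interp)
  both <- L$valid & R$valid
  only_l <- L$valid & !R$valid
  only_r <- R$valid & !L$valid
  dirs <- matrix(NA_real_, length(t), 3L)
  if (any(both)) {
    dirs[both, ] <- normalize_rows(
      (normalize_rows(L$dirs[both, , drop = FALSE]) +
         normalize_rows(R$dirs[both, , drop = FALSE])) / 2)
  }
  dirs[only_l, ] <- normalize_rows(L$dirs[only_l, , drop = FALSE])
  dirs[only_r, ] <- normalize_rows(R$dirs[only_r, , drop = FALSE])
  valid <- both | only_l | only_r
  out <- data.frame(t = t, dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                    valid = valid)
  attr(out, "data_loss_pct") <- raw_loss
  attr(out, "residual_loss_pct") <- 100 * mean(!valid)
  out
}

#' Angular velocity and acceleration of a direction trace
#'
#' Sample-to-sample angular displacement (arccos of the dot product of
#' consecutive unit direction vectors, in degrees) divided by the sample
#' interval, smoothed with a second-order Savitzky-Golay filter applied
#' per contiguous valid segment; acceleration is the first difference of
#' the smoothed velocity.  Velocities are clamped at zero after smoothing.
#'
#' @param pre preprocessed trace from [preprocess_gaze()].
#' @param params a [detector_params()].
#' @return data frame `t`, `velocity` (deg/s), `acceleration` (deg/s^2),
#'   `valid`; invalid samples carry `NA` velocity.
#' @export
compute_velocity <- function(pre, params = detector_params()) {
  n <- nrow(pre)
  if (n < params$sg_window) stop("trace shorter than the smoothing window")
  d <- as.matrix(pre[, c("dx", "dy", "dz")])
  dots <- pmin(pmax(rowSums(d[-n, , drop = FALSE] * d[-1L, , drop = FALSE]),
                    -1), 1)
  ang <- acos(dots) * 180 / pi
  dt <- diff(pre$t)
  v <- c(NA_real_, ang / dt)
  v[1L] <- v[2L]
  # a velocity sample is defined only when both flanking samples are valid
  ok <- pre$valid & c(pre$valid[1L], pre$valid[-n])
  v[!ok] <- NA_real_
  vs <- v
  r <- rle(!is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    if (length(idx) >= params$sg_window) {
      vs[idx] <- signal::sgolayfilt(v[idx], p = params$sg_order,
                                    n = params$sg_window)
    }
  }
  vs <- pmax(vs, 0)
  acc <- c(0, diff(vs)) / c(dt[1L], dt)
  data.frame(t = pre$t, velocity = vs, acceleration = acc, valid = ok)
}

#' Adaptive data-driven velocity threshold
#'
#' Iterative scheme: starting from `threshold_init`, the threshold is
#' repeatedly re-estimated as mean + `threshold_multiplier` x SD of all
#' velocity samples at or below the current threshold, until successive
#' estimates differ by less than `threshold_tol`.
#'
#' @param velocities numeric vector of angular velocities (deg/s); `NA`s
#'   are ignored.
#' @param params a [detector_params()].
#' @param max_iter iteration cap (default 100).
#' @return converged peak-velocity threshold in deg/s.
#' @export
adaptive_threshold <- function(velocities, params = detector_params(),
                               max_iter = 100L) {
  v <- velocities[is.finite(velocities)]
  if (!length(v)) stop("no finite velocity samples")
  pt <- params$threshold_init
  for (i in seq_len(max_iter)) {
    sub <- v[v <= pt]
    if (!length(sub)) sub <- min(v)
    s <- sd(sub)
    if (is.na(s)) s <- 0
    pt_new <- mean(sub) + params$threshold_multiplier * s
    if (abs(pt_new - pt) < params$threshold_tol) return(pt_new)
    pt <- pt_new
  }
  stop(sprintf(
    "adaptive threshold did not converge in %d iterations (last PT = %.2f deg/s, n = %d)",
    max_iter, pt, length(v)))
}

#' Detect saccades and fixations
#'
#' Supra-threshold velocity runs become saccades, with onsets/offsets
#' refined outward to the adjacent local velocity minima.  Contiguous valid
#' spans between saccades become fixation candidates; candidates shorter
#' than `min_fixation` are discarded, and retained fixations separated by
#' gaps of at most `merge_interval` are merged (any saccade entirely inside
#' a merged gap is dropped, so events of the two kinds never overlap).
#'
#' @param pre preprocessed trace from [preprocess_gaze()].
#' @param params a [detector_params()].
#' @param vel optional precomputed velocity trace.
#' @return list with data frames `saccades` (`start`, `end`, `duration_ms`,
#'   `amplitude_deg`, `peak_velocity`), `fixations` (`start`, `end`,
#'   `duration_ms`, centroid direction), and the scalar `threshold`.
#' @export
detect_events <- function(pre, params = detector_params(), vel = NULL) {
  if (is.null(vel)) vel <- compute_velocity(pre, params)
  v <- vel$velocity
  t <- vel$t
  n <- length(t)
  pt <- adaptive_threshold(v, params)
  above <- !is.na(v) & v > pt

  sac <- integer(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # refine to adjacent local minima of the smoothed velocity
    for (j in seq_len(nrow(runs))) {
      i <- runs[j, 1L]
      while (i > 1L && !is.na(v[i - 1L]) && v[i - 1L] < v[i]) i <- i - 1L
      k <- runs[j, 2L]
      while (k < n && !is.na(v[k + 1L]) && v[k + 1L] < v[k]) k <- k + 1L
      runs[j, ] <- c(i, k)
    }
    # merge runs that became overlapping after refinement
    keep <- list()
    cur <- runs[1L, ]
    for (j in seq_len(nrow(runs))[-1L]) {
      if (runs[j, 1L] <= cur[2L]) cur[2L] <- max(cur[2L], runs[j, 2L])
      else { keep[[length(keep) + 1L]] <- cur; cur <- runs[j, ] }
    }
    keep[[length(keep) + 1L]] <- cur
    runs <- do.call(rbind, keep)
  } else runs <- matrix(integer(0), 0L, 2L)

  dmat <- as.matrix(pre[, c("dx", "dy", "dz")])
  sacc <- if (nrow(runs)) {
    amp <- vapply(seq_len(nrow(runs)), function(j) {
      i <- runs[j, 1L]; k <- runs[j, 2L]
      acos(pmin(pmax(sum(dmat[i, ] * dmat[k, ]), -1), 1)) * 180 / pi
    }, numeric(1L))
    pv <- vapply(seq_len(nrow(runs)), function(j) {
      max(v[runs[j, 1L]:runs[j, 2L]], na.rm = TRUE)
    }, numeric(1L))
    data.frame(start = t[runs[, 1L]], end = t[runs[, 2L]],
               duration_ms = (t[runs[, 2L]] - t[runs[, 1L]]) * 1000,
               amplitude_deg = amp, peak_velocity = pv)
  } else {
    data.frame(start = numeric(), end = numeric(), duration_ms = numeric(),
               amplitude_deg = numeric(), peak_velocity = numeric())
  }

  # fixation candidates: valid samples in no saccade run
  in_sac <- rep(FALSE, n)
  for (j in seq_len(nrow(runs))) in_sac[runs[j, 1L]:runs[j, 2L]] <- TRUE
  fixable <- vel$valid & !in_sac
  fr <- rle(fixable)
  f_ends <- cumsum(fr$lengths)
  f_starts <- f_ends - fr$lengths + 1L
  cand <- cbind(f_starts[fr$values], f_ends[fr$values])
  if (nrow(cand)) {
    dur <- t[cand[, 2L]] - t[cand[, 1L]]
    cand <- cand[dur >= params$min_fixation - 1e-9, , drop = FALSE]
  }
  # merge retained fixations across gaps of at most merge_interval
  merged <- list()
  if (nrow(cand)) {
    cur <- cand[1L, ]
    for (j in seq_len(nrow(cand))[-1L]) {
      gap <- t[cand[j, 1L]] - t[cur[2L]]
      if (gap <= params$merge_interval + 1e-9) cur[2L] <- cand[j, 2L]
      else { merged[[length(merged) + 1L]] <- cur; cur <- cand[j, ] }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  fix <- if (length(merged)) {
    m <- do.call(rbind, merged)
    cent <- t(vapply(seq_len(nrow(m)), function(j) {
      idx <- m[j, 1L]:m[j, 2L]
      cm <- colMeans(dmat[idx[pre$valid[idx]], , drop = FALSE])
      cm / sqrt(sum(cm^2))
    }, numeric(3L)))
    data.frame(start = t[m[, 1L]], end = t[m[, 2L]],
               duration_ms = (t[m[, 2L]] - t[m[, 1L]]) * 1000,
               cx = cent[, 1L], cy = cent[, 2L], cz = cent[, 3L])
  } else {
    data.frame(start = numeric(), end = numeric(), duration_ms = numeric(),
               cx = numeric(), cy = numeric(), cz = numeric())
  }
  # drop saccades swallowed by a fixation merge
  if (nrow(sacc) && nrow(fix)) {
    inside <- vapply(seq_len(nrow(sacc)), function(j) {
      any(sacc$start[j] >= fix$start & sacc$end[j] <= fix$end)
    }, logical(1L))
    sacc <- sacc[!inside, , drop = FALSE]
  }
  list(saccades = sacc, fixations = fix, threshold = pt)
}

#' Saccade counts and mean durations per phase
#'
#' Events are assigned to the phase containing their onset (half-open
#' windows).
#'
#' @param saccades saccade table from [detect_events()].
#' @param schedule a `phase_schedule`.
#' @return data frame per phase type: `n_saccades`, `mean_duration_ms`
#'   (`NA` when a cell has no events).
#' @export
summarize_saccades <- function(saccades, schedule) {
  ph <- phase_at(schedule, saccades$start)
  types <- schedule$phase_type[ph]
  out <- lapply(PHASE_TYPES, function(pt) {
    sel <- !is.na(types) & types == pt
    data.frame(phase_type = pt, n_saccades = sum(sel),
               mean_duration_ms = if (any(sel))
                 mean(saccades$duration_ms[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
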