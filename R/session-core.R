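# Canonical data model, stream I/O and phase scheduling for a
# three-condition session.  One clock per block (seconds, t = 0 at block
# start); all windows are half-open [start, end).

FEEDBACK_CONDITIONS <- c("real", "sham", "none")
PHASE_TYPES <- c("DP", "NDP")

# 10-20 montage used by the recording cap (ground DRL at FPz, reference CMS
# at FCz are not data channels).
EEG_CHANNELS <- c(
  "Fp1", "Fp2", "AFz", "F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
  "CPz", "P7", "P3", "Pz", "P4", "P8", "POz", "O1", "O2", "M1", "M2"
)

#' Construct a timestamped multichannel stream
#'
#' The common container for gaze, head and EEG recordings: a strictly
#' increasing time vector, one value row per timestamp, and an optional
#' per-sample validity flag.
#'
#' @param name identifier for the stream (used in error messages).
#' @param nominal_rate nominal sampling rate in Hz (> 0); purely
#'   informational, the timestamps are authoritative.
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param values data frame (or matrix) of named channels, one row per
#'   timestamp.
#' @param validity optional logical vector, one flag per sample; `NULL`
#'   means all samples valid.
#' @return an object of class `ts_stream`.
#' @export
time_series_stream <- function(name, nominal_rate, t, values, validity = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0) {
    stop("nominal_rate must be a single positive number")
  }
  t <- as.numeric(t)
  values <- as.data.frame(values)
  if (nrow(values) != length(t)) {
    stop(sprintf("stream '%s': %d timestamps but %d value rows",
                 name, length(t), nrow(values)))
  }
  if (length(t) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop(sprintf("stream '%s': timestamps not strictly increasing at row %d",
                   name, bad[1L] + 1L))
    }
  }
  if (!is.null(validity)) {
    validity <- as.logical(validity)
    if (length(validity) != length(t)) {
      stop(sprintf("stream '%s': validity length mismatch", name))
    }
  }
  structure(
    list(name = name, nominal_rate = nominal_rate, t = t,
         values = values, validity = validity),
    class = "ts_stream"
  )
}

#' @export
print.ts_stream <- function(x, ...) {
  cat(sprintf("<ts_stream '%s'> %d samples @ %g Hz nominal, %d channel(s)",
              x$name, length(x$t), x$nominal_rate, ncol(x$values)))
  if (length(x$t)) {
    cat(sprintf(", t in [%.3f, %.3f] s", x$t[1L], x$t[length(x$t)]))
  }
  cat("\n")
  invisible(x)
}

n_samples <- function(stream) length(stream$t)

#' Build an alternating DP/NDP phase schedule
#'
#' Phases are contiguous, strictly alternating, and of equal duration; the
#' default study block is six three-minute phases (18 min total).
#'
#' @param start_phase `"DP"` or `"NDP"` for the first phase.
#' @param n_phases number of phases (>= 1).
#' @param phase_seconds duration of each phase in seconds (> 0).
#' @return a `phase_schedule` data frame with columns `phase_type`, `start`,
#'   `end` (half-open intervals).
#' @examples
#' build_phase_schedule("DP", 6, 180)  # the standard 18-min block
#' @export
build_phase_schedule <- function(start_phase = "DP", n_phases = 6L,
                                 phase_seconds = 180) {
  start_phase <- match.arg(start_phase, PHASE_TYPES)
  if (!is.numeric(n_phases) || length(n_phases) != 1L || n_phases < 1 ||
      n_phases != round(n_phases)) {
    stop("n_phases must be a positive whole number")
  }
  if (!is.numeric(phase_seconds) || length(phase_seconds) != 1L ||
      phase_seconds <= 0) {
    stop("phase_seconds must be a positive duration in seconds")
  }
  n_phases <- as.integer(n_phases)
  other <- setdiff(PHASE_TYPES, start_phase)
  types <- rep(c(start_phase, other), length.out = n_phases)
  starts <- (seq_len(n_phases) - 1L) * phase_seconds
  out <- data.frame(
    phase_type = types,
    start = starts,
    end = starts + phase_seconds,
    stringsAsFactors = FALSE
  )
  class(out) <- c("phase_schedule", "data.frame")
  out
}

schedule_duration <- function(schedule) {
  schedule$end[nrow(schedule)] - schedule$start[1L]
}

#' Locate schedule phases containing given times
#'
#' @param schedule a `phase_schedule`.
#' @param t numeric vector of times (seconds).
#' @return integer vector of phase indices (`NA` outside the schedule);
#'   boundary times belong to the later phase (half-open rule).
#' @export
phase_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$start)
  idx[t < schedule$start[1L] | t >= schedule$end[nrow(schedule)]] <- NA_integer_
  idx
}

#' Slice a stream to a half-open time window
#'
#' Returns exactly the samples with `start <= t < end`; an empty result is a
#' valid (empty) stream.
#'
#' @param stream a `ts_stream`.
#' @param start,end window bounds in seconds, `start < end`.
#' @return a `ts_stream` with the selected samples.
#' @export
slice_stream <- function(stream, start, end) {
  stopifnot(inherits(stream, "ts_stream"))
  if (!is.numeric(start) || !is.numeric(end) || start >= end) {
    stop("slice window must satisfy start < end")
  }
  keep <- stream$t >= start & stream$t < end
  structure(
    list(name = stream$name, nominal_rate = stream$nominal_rate,
         t = stream$t[keep],
         values = stream$values[keep, , drop = FALSE],
         validity = if (is.null(stream$validity)) NULL else stream$validity[keep]),
    class = "ts_stream"
  )
}

#' Assemble one experimental block
#'
#' @param condition feedback condition, one of `"real"`, `"sham"`, `"none"`.
#' @param phase_schedule a `phase_schedule` for the block.
#' @param gaze,head,eeg `ts_stream` objects (any may be `NULL` when a
#'   modality was not recorded/simulated).
#' @param cpt_block a `cpt_block` (see [generate_cpt_block()]).
#' @param responses numeric vector of keypress times in seconds, sorted.
#' @param feedback_events data frame with columns `onset`, `offset`, `cause`,
#'   `mode` (may have zero rows).
#' @param activations distractor activation table (see
#'   [distractor_schedule()]); needed to re-classify gaze offline.
#' @param experience_sampling named integer vector
#'   `c(inattention=, hyperactivity=, impulsivity=)`, each in \[-3, 3\].
#' @return an object of class `block_record`.
#' @export
block_record <- function(condition, phase_schedule, gaze = NULL, head = NULL,
                         eeg = NULL, cpt_block = NULL, responses = numeric(),
                         feedback_events = empty_feedback_events(),
                         activations = NULL,
                         experience_sampling = NULL) {
  condition <- match.arg(condition, FEEDBACK_CONDITIONS)
  stopifnot(inherits(phase_schedule, "phase_schedule"))
  if (!is.null(experience_sampling)) {
    es <- experience_sampling
    if (length(es) != 3L || any(es < -3 | es > 3)) {
      stop("experience_sampling must be three Likert values in [-3, 3]")
    }
    if (is.null(names(es))) {
      names(es) <- c("inattention", "hyperactivity", "impulsivity")
    }
    experience_sampling <- es
  }
  structure(
    list(condition = condition, phase_schedule = phase_schedule,
         gaze = gaze, head = head, eeg = eeg, cpt_block = cpt_block,
         responses = as.numeric(responses),
         feedback_events = feedback_events,
         activations = activations,
         experience_sampling = experience_sampling),
    class = "block_record"
  )
}

empty_feedback_events <- function() {
  data.frame(onset = numeric(), offset = numeric(),
             cause = character(), mode = character(),
             registration_time = numeric(), stringsAsFactors = FALSE)
}

#' Assemble a full three-block session
#'
#' @param participant_id identifier string.
#' @param group `"ADHD"` or `"HC"`.
#' @param condition_order permutation of `c("real","sham","none")`.
#' @param blocks list of three `block_record`s whose conditions match
#'   `condition_order`.
#' @param recognition optional data frame with logical columns `judgment`
#'   and `truth` (60 items, half of them actually played).
#' @return an object of class `session_record`.
#' @export
session_record <- function(participant_id, group, condition_order, blocks,
                           recognition = NULL) {
  group <- match.arg(group, c("ADHD", "HC"))
  if (length(condition_order) != 3L ||
      !setequal(condition_order, FEEDBACK_CONDITIONS)) {
    stop("condition_order must be a permutation of real/sham/none")
  }
  if (length(blocks) != 3L) stop("a session has exactly 3 blocks")
  got <- vapply(blocks, function(b) b$condition, character(1L))
  if (!identical(got, as.character(condition_order))) {
    stop("block conditions do not match condition_order")
  }
  if (!is.null(recognition)) {
    stopifnot(is.data.frame(recognition),
              all(c("judgment", "truth") %in% names(recognition)))
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         condition_order = as.character(condition_order), blocks = blocks,
         recognition = recognition),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record '%s'> group %s, conditions %s\n",
              x$participant_id, x$group, paste(x$condition_order, collapse = " > ")))
  invisible(x)
}

block_by_condition <- function(session, condition) {
  session$blocks[[match(condition, session$condition_order)]]
}

## ---------------------------------------------------------------------------
## File I/O.  Layout: <dir>/session.json plus <dir>/block1..block3/ with
## gaze.csv, head.csv, eeg.csv, cpt.csv, responses.csv, feedback.csv.

GAZE_COLUMNS <- c("t", "lx", "ly", "lz", "ldx", "ldy", "ldz", "validity_l",
                  "rx", "ry", "rz", "rdx", "rdy", "rdz", "validity_r")

read_csv_checked <- function(path, required, stream_name) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  dt <- data.table::fread(path, data.table = FALSE)
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(miss, collapse = ", ")))
  }
  dt
}

check_monotonic <- function(t, stream_name) {
  if (length(t) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      stop(sprintf("stream '%s': non-monotonic timestamp at row %d",
                   stream_name, bad[1L] + 1L))
    }
  }
  invisible(TRUE)
}

read_block_dir <- function(dir, condition, schedule) {
  gz <- read_csv_checked(file.path(dir, "gaze.csv"),
                         setdiff(GAZE_COLUMNS, c("validity_l", "validity_r")),
                         "gaze")
  check_monotonic(gz$t, "gaze")
  for (vc in c("validity_l", "validity_r")) {
    if (is.null(gz[[vc]])) {
      warning(sprintf("%s: no %s column, defaulting to all-valid",
                      file.path(dir, "gaze.csv"), vc))
      gz[[vc]] <- TRUE
    }
  }
  gz$validity_l <- as.logical(gz$validity_l)
  gz$validity_r <- as.logical(gz$validity_r)
  gaze <- time_series_stream("gaze", 50, gz$t, gz[, setdiff(GAZE_COLUMNS, "t")],
                             validity = gz$validity_l | gz$validity_r)

  hd <- read_csv_checked(file.path(dir, "head.csv"), c("t", "x", "y", "z"), "head")
  check_monotonic(hd$t, "head")
  head <- time_series_stream("head", 90, hd$t, hd[, c("x", "y", "z")])

  eeg <- NULL
  eeg_path <- file.path(dir, "eeg.csv")
  if (file.exists(eeg_path)) {
    ee <- read_csv_checked(eeg_path, "t", "eeg")
    check_monotonic(ee$t, "eeg")
    chans <- intersect(EEG_CHANNELS, names(ee))
    if (!length(chans)) stop("eeg.csv: no recognised 10-20 channel columns")
    eeg <- time_series_stream("eeg", 500, ee$t, ee[, chans, drop = FALSE])
  }

  cp <- read_csv_checked(file.path(dir, "cpt.csv"),
                         c("index", "letter", "onset", "class"), "cpt")
  check_monotonic(cp$onset, "cpt")
  cpt <- as_cpt_block(cp)

  rp <- read_csv_checked(file.path(dir, "responses.csv"), "t", "responses")
  fb <- read_csv_checked(file.path(dir, "feedback.csv"),
                         c("onset", "offset", "cause", "mode"), "feedback")
  if (is.null(fb$registration_time)) fb$registration_time <- NA_real_
  # zero-row files carry no type information
  for (col in c("onset", "offset", "registration_time")) {
    fb[[col]] <- as.numeric(fb[[col]])
  }
  for (col in c("cause", "mode")) fb[[col]] <- as.character(fb[[col]])

  acts <- NULL
  act_path <- file.path(dir, "distractors.csv")
  if (file.exists(act_path)) {
    acts <- read_csv_checked(act_path,
                             c("onset", "end", "phase_index", "distractor_id",
                               "modality", "collider_id"), "distractors")
  }

  block_record(condition, schedule, gaze = gaze, head = head, eeg = eeg,
               cpt_block = cpt, responses = rp$t, feedback_events = fb,
               activations = acts)
}

#' Read a session from its on-disk layout
#'
#' Expects `session.json` plus one `blockN/` directory per block, each with
#' `gaze.csv`, `head.csv`, `cpt.csv`, `responses.csv`, `feedback.csv` and
#' optionally `eeg.csv`.  Malformed files are reported with the offending
#' stream and row; a missing gaze validity column defaults to all-valid with
#' a warning.
#'
#' @param dir session directory written by [write_session()].
#' @return a `session_record`.
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "session.json")
  if (!file.exists(meta_path)) stop(sprintf("missing file: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (!all(meta$condition_order %in% FEEDBACK_CONDITIONS)) {
    stop(sprintf("session.json: unknown condition label(s): %s",
                 paste(setdiff(meta$condition_order, FEEDBACK_CONDITIONS),
                       collapse = ", ")))
  }
  blocks <- vector("list", 3L)
  for (i in seq_len(3L)) {
    sch <- meta$blocks[[i]]$phase_schedule
    schedule <- build_phase_schedule(sch$start_phase, sch$n_phases,
                                     sch$phase_seconds)
    b <- read_block_dir(file.path(dir, sprintf("block%d", i)),
                        meta$condition_order[i], schedule)
    es <- meta$blocks[[i]]$experience_sampling
    if (!is.null(es)) {
      b$experience_sampling <- setNames(as.numeric(unlist(es)), names(es))
    }
    blocks[[i]] <- b
  }
  recog <- NULL
  if (!is.null(meta$recognition)) {
    recog <- data.frame(judgment = as.logical(meta$recognition$judgment),
                        truth = as.logical(meta$recognition$truth))
  }
  session_record(meta$participant_id, meta$group, meta$condition_order,
                 blocks, recognition = recog)
}

#' Write a session to disk
#'
#' Inverse of [read_session()]; `write_session` followed by `read_session`
#' is the identity on the data model up to floating-point round-trip.
#'
#' @param session a `session_record`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    participant_id = session$participant_id,
    group = session$group,
    condition_order = session$condition_order,
    blocks = lapply(session$blocks, function(b) {
      sch <- b$phase_schedule
      list(condition = b$condition,
           phase_schedule = list(start_phase = sch$phase_type[1L],
                                 n_phases = nrow(sch),
                                 phase_seconds = sch$end[1L] - sch$start[1L]),
           experience_sampling = as.list(b$experience_sampling))
    }),
    recognition = if (is.null(session$recognition)) NULL else
      list(judgment = session$recognition$judgment,
           truth = session$recognition$truth)
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(session$blocks)) {
    b <- session$blocks[[i]]
    bdir <- file.path(dir, sprintf("block%d", i))
    dir.create(bdir, showWarnings = FALSE)
    gz <- cbind(t = b$gaze$t, b$gaze$values)
    data.table::fwrite(gz, file.path(bdir, "gaze.csv"))
    data.table::fwrite(cbind(t = b$head$t, b$head$values),
                       file.path(bdir, "head.csv"))
    if (!is.null(b$eeg)) {
      data.table::fwrite(cbind(t = b$eeg$t, b$eeg$values),
                         file.path(bdir, "eeg.csv"))
    }
    data.table::fwrite(as.data.frame(b$cpt_block), file.path(bdir, "cpt.csv"))
    data.table::fwrite(data.frame(t = b$responses),
                       file.path(bdir, "responses.csv"))
    data.table::fwrite(b$feedback_events, file.path(bdir, "feedback.csv"))
    if (!is.null(b$activations)) {
      data.table::fwrite(b$activations, file.path(bdir, "distractors.csv"))
    }
  }
  invisible(dir)
}
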