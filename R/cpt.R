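# Letter-stream continuous performance task: stimulus schedule generation
# and response scoring (omissions, commissions, reaction times).
#
# Task rule: press a key as quickly as possible when a 'K' follows an 'A',
# withhold for any other letter sequence.  Each trial after the first is
# classified by its (previous letter, current letter) transition:
#   target        A -> K
#   pseudo-target A -> non-K  or  non-A -> K   (exactly one target letter in
#                                               the defining slot)
#   nontarget     anything else
# Trial 0 has no preceding letter and is classed "opener".

CPT_CLASSES <- c("target", "pseudo_target", "nontarget", "opener")
NEUTRAL_LETTERS <- setdiff(LETTERS, c("A", "K"))

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Classify a letter stream into CPT trial classes
#'
#' Independent of the generator: re-derives the class of every trial from
#' the emitted letters alone.
#'
#' @param letters character vector of single uppercase letters.
#' @return character vector of classes (`opener` for trial 1).
#' @export
classify_letter_stream <- function(letters) {
  n <- length(letters)
  if (n == 0L) return(character())
  cls <- rep("nontarget", n)
  cls[1L] <- "opener"
  if (n > 1L) {
    prev <- letters[-n]
    cur <- letters[-1L]
    tgt <- prev == "A" & cur == "K"
    pseudo <- (prev == "A" & cur != "K") | (prev != "A" & cur == "K")
    cls[-1L][pseudo] <- "pseudo_target"
    cls[-1L][tgt] <- "target"
  }
  cls
}

as_cpt_block <- function(df, seed = NA_integer_, stimulus_duration = 0.100,
                         isi = 1.100, p_target = NA_real_, p_pseudo = NA_real_) {
  df <- as.data.frame(df)[, c("index", "letter", "onset", "class")]
  structure(df, class = c("cpt_block", "data.frame"),
            seed = seed, stimulus_duration = stimulus_duration, isi = isi,
            p_target = p_target, p_pseudo = p_pseudo)
}

#' Generate a CPT stimulus block
#'
#' Builds a deterministic (per seed) letter stream realizing the requested
#' class composition over the `n_trials - 1` classifiable transitions:
#' `round(p_target * (n-1))` targets and
#' `round(p_pseudo * (1 - p_target) * (n-1))` pseudo-targets, the remainder
#' nontargets (`p_pseudo` is the pseudo-target share within non-targets).
#' An 'A' is only ever emitted immediately before a scheduled target 'K',
#' so no target can arise accidentally.
#'
#' @param seed integer RNG seed.
#' @param n_trials number of trials (default 900, spanning 18 min at the
#'   default timing).
#' @param p_target proportion of target transitions (default 0.30).
#' @param p_pseudo pseudo-target proportion within non-target transitions
#'   (default 0.50).
#' @param stimulus_duration stimulus presentation time in seconds (0.100).
#' @param isi interstimulus interval in seconds (1.100).
#' @return a `cpt_block` data frame (`index`, `letter`, `onset`, `class`)
#'   with timing/composition attributes.
#' @examples
#' blk <- generate_cpt_block(seed = 1)
#' nrow(blk)                       # 900
#' table(blk$class)
#' @export
generate_cpt_block <- function(seed = 1L, n_trials = 900L, p_target = 0.30,
                               p_pseudo = 0.50, stimulus_duration = 0.100,
                               isi = 1.100) {
  if (n_trials < 2L) stop("n_trials must be at least 2")
  if (p_target < 0 || p_target > 1 || p_pseudo < 0 || p_pseudo > 1) {
    stop("proportions must lie in [0, 1]")
  }
  m <- n_trials - 1L                    # classifiable transitions
  n_t <- round(p_target * m)
  n_p <- round(p_pseudo * (1 - p_target) * m)
  n_n <- m - n_t - n_p
  # every target needs an immediately preceding transition that ends in 'A'
  # (classed nontarget); infeasible when targets outnumber nontargets.
  if (n_n < n_t) {
    stop(sprintf(paste("infeasible composition: %d targets need %d",
                       "preceding-'A' transitions but only %d nontargets",
                       "are available (p_target too high)"),
                 n_t, n_t, n_n))
  }
  with_seed(seed, {
    # units: T = (->A nontarget, ->K target); P = (->K pseudo); N = neutral
    units <- c(rep("T", n_t), rep("P", n_p), rep("N", n_n - n_t))
    units <- sample(units)
    letters_out <- character(n_trials)
    letters_out[1L] <- sample(NEUTRAL_LETTERS, 1L)
    pos <- 1L
    for (u in units) {
      if (u == "T") {
        letters_out[pos + 1L] <- "A"
        letters_out[pos + 2L] <- "K"
        pos <- pos + 2L
      } else if (u == "P") {
        letters_out[pos + 1L] <- "K"
        pos <- pos + 1L
      } else {
        letters_out[pos + 1L] <- sample(NEUTRAL_LETTERS, 1L)
        pos <- pos + 1L
      }
    }
    stopifnot(pos == n_trials)
    onset <- (seq_len(n_trials) - 1L) * (stimulus_duration + isi)
    as_cpt_block(
      data.frame(index = seq_len(n_trials) - 1L, letter = letters_out,
                 onset = onset, class = classify_letter_stream(letters_out),
                 stringsAsFactors = FALSE),
      seed = seed, stimulus_duration = stimulus_duration, isi = isi,
      p_target = p_target, p_pseudo = p_pseudo)
  })
}

# Per-trial scoring detail shared by score_cpt() and the phase splitter.
# Each response is assigned to the most recent onset within the response
# window; only the first response per trial counts.
score_cpt_detail <- function(block, responses, response_window) {
  stopifnot(inherits(block, "cpt_block"))
  if (response_window <= 0) stop("response_window must be positive")
  responses <- sort(as.numeric(responses))
  onsets <- block$onset
  n_before <- sum(responses < onsets[1L])
  if (n_before > 0L) {
    warning(sprintf("%d response(s) before the first stimulus onset ignored",
                    n_before))
  }
  responses <- responses[responses >= onsets[1L]]
  idx <- findInterval(responses, onsets)
  in_window <- (responses - onsets[idx]) < response_window
  idx <- idx[in_window]
  rts <- (responses[in_window] - onsets[idx]) * 1000  # ms
  first <- !duplicated(idx)
  trial_rt <- rep(NA_real_, nrow(block))
  trial_rt[idx[first]] <- rts[first]
  data.frame(
    index = block$index, onset = onsets, class = block$class,
    responded = !is.na(trial_rt), rt_ms = trial_rt,
    n_ignored = c(n_before + sum(!in_window), rep(0L, nrow(block) - 1L))
  )
}

summarize_cpt_detail <- function(detail, rt_on = "hits") {
  is_target <- detail$class == "target"
  hits <- detail$responded & is_target
  rts <- if (rt_on == "hits") detail$rt_ms[hits] else
    detail$rt_ms[detail$responded]
  rts <- rts[!is.na(rts)]
  structure(
    list(
      omission_errors = sum(is_target & !detail$responded),
      commission_errors = sum(!is_target & detail$responded),
      hits = sum(hits),
      reaction_times = rts,
      mean_rt = if (length(rts)) mean(rts) else NA_real_,
      n_targets = sum(is_target),
      n_nontargets = sum(!is_target),
      n_ignored_responses = sum(detail$n_ignored)
    ),
    class = "cpt_performance"
  )
}

#' @export
print.cpt_performance <- function(x, ...) {
  cat(sprintf(
    "<cpt_performance> %d targets: %d hits, %d omissions; %d commissions; mean RT %.1f ms\n",
    x$n_targets, x$hits, x$omission_errors, x$commission_errors, x$mean_rt))
  invisible(x)
}

#' Score CPT responses
#'
#' Assigns each keypress to the most recent stimulus onset within the
#' response window (default: one full stimulus-onset asynchrony, 1.2 s).
#' A first response to a target is a hit (reaction time in ms); a first
#' response to any other trial is a commission error; a target with no
#' response in its window is an omission error.  Responses before the first
#' onset or outside every window are counted as ignored with a warning.
#'
#' @param block a `cpt_block`.
#' @param responses numeric vector of keypress times (seconds).
#' @param response_window seconds from onset during which a response is
#'   attributed to a trial.
#' @param rt_on `"hits"` (default) to compute mean RT over correct target
#'   responses only, `"all"` to include commissions.
#' @return a `cpt_performance` list: omission/commission counts, hit count,
#'   RT vector (ms), mean RT, target and non-target counts.
#' @export
score_cpt <- function(block, responses, response_window = NULL,
                      rt_on = c("hits", "all")) {
  rt_on <- match.arg(rt_on)
  if (is.null(response_window)) {
    response_window <- attr(block, "stimulus_duration") + attr(block, "isi")
  }
  summarize_cpt_detail(score_cpt_detail(block, responses, response_window),
                       rt_on)
}

#' Split CPT performance by DP/NDP phase
#'
#' Trials belong to the phase containing their onset (half-open windows; a
#' boundary onset belongs to the later phase).  Per-phase counts sum to the
#' whole-block totals.
#'
#' @inheritParams score_cpt
#' @param schedule a `phase_schedule` covering every trial onset.
#' @return data frame with one row per phase type (`DP`, `NDP`):
#'   omission/commission counts, hits, targets, non-targets, mean RT (ms).
#' @export
split_performance_by_phase <- function(block, responses, schedule,
                                       response_window = NULL,
                                       rt_on = c("hits", "all")) {
  rt_on <- match.arg(rt_on)
  if (is.null(response_window)) {
    response_window <- attr(block, "stimulus_duration") + attr(block, "isi")
  }
  detail <- score_cpt_detail(block, responses, response_window)
  ph <- phase_at(schedule, detail$onset)
  if (anyNA(ph)) {
    stop(sprintf("phase schedule does not cover trial onset at %.3f s",
                 detail$onset[which(is.na(ph))[1L]]))
  }
  types <- schedule$phase_type[ph]
  out <- lapply(PHASE_TYPES, function(pt) {
    sub <- detail[types == pt, , drop = FALSE]
    perf <- summarize_cpt_detail(sub, rt_on)
    data.frame(phase_type = pt, n_trials = nrow(sub),
               n_targets = perf$n_targets, hits = perf$hits,
               omission_errors = perf$omission_errors,
               commission_errors = perf$commission_errors,
               mean_rt = perf$mean_rt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
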