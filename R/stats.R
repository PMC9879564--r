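# The study's statistical battery: mixed-design ANOVAs with sphericity
# handling (Huynh-Feldt when epsilon > 0.75, Greenhouse-Geisser otherwise),
# Bonferroni post-hocs, t-tests with Cohen's d, Pearson/Spearman
# correlation matrices with Benjamini-Hochberg correction, recognition
# scoring, and the tidy outcome-table assembler feeding all of them.

#' Assemble the per-cell outcome table from simulated or recorded sessions
#'
#' One row per participant x feedback condition x phase type.  Phase-varying
#' measures (CPT errors and RT, saccade count/duration, TBR, head movement)
#' differ across the two phase rows; condition-level measures (dwell
#' percentages, distractibility score, experience sampling) repeat across
#' them so the table can feed both the 2x3x2 and the 2x3 analyses.
#'
#' @param sessions list of `session_record`s (or of `simulate_session()`
#'   results, whose `$session` is used).
#' @param sc the `scene` used for gaze classification.
#' @param measures subset of
#'   `c("cpt", "gaze", "saccades", "eeg", "head", "es")` to compute.
#' @return an `outcome_table` data frame.
#' @export
assemble_outcomes <- function(sessions, sc = default_scene(),
                              measures = c("cpt", "gaze", "saccades",
                                           "eeg", "head", "es")) {
  rows <- list()
  for (s in sessions) {
    if (!inherits(s, "session_record") && !is.null(s$session)) s <- s$session
    for (b in s$blocks) {
      schedule <- b$phase_schedule
      dur <- schedule_duration(schedule)
      base <- data.frame(participant_id = s$participant_id, group = s$group,
                         condition = b$condition, stringsAsFactors = FALSE)

      cpt_ph <- if ("cpt" %in% measures && !is.null(b$cpt_block))
        split_performance_by_phase(b$cpt_block, b$responses, schedule) else NULL

      sac_ph <- dloss <- NULL
      if ("saccades" %in% measures && !is.null(b$gaze)) {
        pre <- preprocess_gaze(as_binocular_trace(b$gaze))
        ev <- detect_events(pre)
        sac_ph <- summarize_saccades(ev$saccades, schedule)
        dloss <- attr(pre, "data_loss_pct")
      }

      dw <- NULL
      if ("gaze" %in% measures && !is.null(b$gaze)) {
        comb <- combine_binocular(as_binocular_trace(b$gaze))
        origins <- matrix(c(0, 1.2, 0), length(comb$t), 3L, byrow = TRUE)
        cls <- classify_gaze_samples(comb$t, origins, comb$directions,
                                     comb$valid, sc, b$activations)
        dw <- dwell_summary(intervals_from_samples(cls), dur)
      }

      tbr_ph <- if ("eeg" %in% measures && !is.null(b$eeg))
        compute_tbr(b$eeg, schedule) else NULL

      head_ph <- if ("head" %in% measures && !is.null(b$head))
        head_displacement(b$head, schedule = schedule)$by_phase else NULL

      for (pt in PHASE_TYPES) {
        row <- cbind(base, data.frame(phase_type = pt))
        if (!is.null(cpt_ph)) {
          cp <- cpt_ph[cpt_ph$phase_type == pt, ]
          row$omission_errors <- cp$omission_errors
          row$commission_errors <- cp$commission_errors
          row$mean_rt <- cp$mean_rt
        }
        if (!is.null(sac_ph)) {
          sp <- sac_ph[sac_ph$phase_type == pt, ]
          row$saccade_count <- sp$n_saccades
          row$saccade_duration <- sp$mean_duration_ms
          row$data_loss_pct <- dloss
        }
        if (!is.null(tbr_ph)) {
          tp <- tbr_ph[tbr_ph$phase_type == pt, ]
          row$tbr <- tp$tbr
          row$theta_power <- tp$theta_power
          row$beta_power <- tp$beta_power
        }
        if (!is.null(head_ph)) {
          hp <- head_ph[head_ph$phase_type == pt, ]
          row$head_movement <- hp$mean_displacement * 1000  # mm per step
        }
        if (!is.null(dw)) {
          row$pct_task_focus <- dw$pct_task_focus
          row$pct_distractor_focus <- dw$pct_distractor_focus
          row$pct_gaze_wandering <- dw$pct_gaze_wandering
          row$distractibility_score <- dw$distractibility_score
        }
        if ("es" %in% measures && !is.null(b$experience_sampling)) {
          row$es_inattention <- b$experience_sampling[["inattention"]]
          row$es_hyperactivity <- b$experience_sampling[["hyperactivity"]]
          row$es_impulsivity <- b$experience_sampling[["impulsivity"]]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- data.table::rbindlist(rows, fill = TRUE)
  out <- as.data.frame(out)
  class(out) <- c("outcome_table", "data.frame")
  out
}

check_complete_design <- function(data, cells, subject) {
  tab <- table(data[[subject]])
  bad <- names(tab)[tab != cells]
  if (length(bad)) {
    stop(sprintf("incomplete design for participant(s): %s",
                 paste(bad, collapse = ", ")))
  }
}

#' Mixed-design ANOVA with sphericity corrections
#'
#' Type-III mixed ANOVA with one between-subjects factor and one or two
#' within-subject factors, computed via a multivariate linear model
#' (car::Anova).  For within-subject effects with more than one numerator
#' df, Greenhouse-Geisser and Huynh-Feldt epsilons are reported and the
#' corrected p-value follows the switching rule: Huynh-Feldt when the GG
#' epsilon exceeds 0.75, Greenhouse-Geisser otherwise.  Partial eta squared
#' is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data outcome table (long format, one row per cell).
#' @param dv name of the dependent-variable column.
#' @param between name of the between-subjects factor (default `"group"`).
#' @param within character vector of within-subject factor names (one or
#'   two, e.g. `c("condition", "phase_type")`).
#' @param subject name of the subject identifier column.
#' @return an `anova_result` data frame: `effect`, `F`, `df_num`, `df_den`,
#'   `p`, `partial_eta_sq`, `eps_GG`, `eps_HF`, `correction_applied`,
#'   `p_corrected`, `df_num_corr`, `df_den_corr`.
#' @export
mixed_anova <- function(data, dv, between = "group",
                        within = c("condition", "phase_type"),
                        subject = "participant_id") {
  data <- as.data.frame(data)
  for (f in c(between, within, subject)) data[[f]] <- factor(data[[f]])
  lv <- lapply(within, function(f) levels(data[[f]]))
  names(lv) <- within
  cells <- prod(vapply(lv, length, integer(1L)))
  data <- data[!is.na(data[[dv]]), , drop = FALSE]
  check_complete_design(data, cells, subject)

  # wide subject x cell matrix, cells ordered by the within-factor grid
  grid <- expand.grid(rev(lv), stringsAsFactors = FALSE)[, rev(seq_along(lv)),
                                                         drop = FALSE]
  names(grid) <- within
  subjects <- levels(droplevels(data[[subject]]))
  wide <- matrix(NA_real_, length(subjects), nrow(grid))
  grp <- factor(rep(NA_character_, length(subjects)),
                levels = levels(data[[between]]))
  key_data <- do.call(paste, c(data[within], sep = "\r"))
  key_grid <- do.call(paste, c(grid, sep = "\r"))
  for (i in seq_along(subjects)) {
    sub <- data[data[[subject]] == subjects[i], , drop = FALSE]
    wide[i, ] <- sub[[dv]][match(key_grid, key_data[data[[subject]] == subjects[i]])]
    grp[i] <- sub[[between]][1L]
  }
  if (anyNA(wide)) stop("missing cells after reshaping; design not complete")

  effects_template <- function() {
    within_effects <- unlist(lapply(seq_along(within), function(k) {
      utils::combn(within, k, paste, collapse = ":", simplify = TRUE)
    }))
    c(between, within_effects,
      paste(between, within_effects, sep = ":"))
  }
  if (var(as.numeric(wide)) == 0) {
    eff <- effects_template()
    return(structure(data.frame(
      effect = eff, F = NA_real_, df_num = NA_real_, df_den = NA_real_,
      p = NA_real_, partial_eta_sq = NA_real_, eps_GG = NA_real_,
      eps_HF = NA_real_, correction_applied = "none",
      p_corrected = NA_real_, df_num_corr = NA_real_, df_den_corr = NA_real_,
      stringsAsFactors = FALSE), class = c("anova_result", "data.frame")))
  }

  idata <- grid
  for (f in within) idata[[f]] <- factor(idata[[f]], levels = lv[[f]])
  df_fit <- data.frame(grp = grp)
  # sum-to-zero contrasts so type-III tests are meaningful
  mlm <- lm(wide ~ grp, data = df_fit,
            contrasts = list(grp = "contr.sum"))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  # summary warns when the HF epsilon estimate exceeds 1; it is clamped below
  sm <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- sm$univariate.tests
  pa <- sm$pval.adjustments

  rows <- list()
  for (eff in rownames(ut)) {
    if (eff == "(Intercept)") next
    ss <- ut[eff, "Sum Sq"]; sse <- ut[eff, "Error SS"]
    dfn <- ut[eff, "num Df"]; dfd <- ut[eff, "den Df"]
    Fv <- ut[eff, "F value"]; p <- ut[eff, "Pr(>F)"]
    eps_gg <- eps_hf <- NA_real_
    corr <- "none"; p_corr <- p; dfn_c <- dfn; dfd_c <- dfd
    if (!is.null(pa) && eff %in% rownames(pa) && is.finite(pa[eff, "GG eps"])) {
      eps_gg <- pa[eff, "GG eps"]
      eps_hf <- min(pa[eff, "HF eps"], 1)
      corr <- if (eps_gg > 0.75) "HF" else "GG"
      eps_use <- if (corr == "HF") eps_hf else eps_gg
      dfn_c <- dfn * eps_use; dfd_c <- dfd * eps_use
      p_corr <- stats::pf(Fv, dfn_c, dfd_c, lower.tail = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      effect = gsub("^grp$", between, gsub("grp:", paste0(between, ":"), eff)),
      F = Fv, df_num = dfn, df_den = dfd, p = p,
      partial_eta_sq = ss / (ss + sse),
      eps_GG = eps_gg, eps_HF = eps_hf, correction_applied = corr,
      p_corrected = p_corr, df_num_corr = dfn_c, df_den_corr = dfd_c,
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("anova_result", "data.frame"))
}

#' Bonferroni-adjusted pairwise post-hoc t-tests
#'
#' Pairwise comparisons across the levels of one factor, collapsing the
#' data to per-subject level means.  Within-subject factors use paired
#' t-tests, the between-subjects factor an independent-samples t-test.
#' Adjusted p = `min(1, m * p_raw)` with m the number of pairs.
#'
#' @param data outcome table.
#' @param dv dependent-variable column name.
#' @param factor factor column name.
#' @param subject subject identifier column.
#' @param paired whether levels are within-subject (default `TRUE`).
#' @return data frame of pairwise results with raw and adjusted p-values.
#' @export
posthoc_bonferroni <- function(data, dv, factor, subject = "participant_id",
                               paired = TRUE) {
  data <- as.data.frame(data)
  data <- data[!is.na(data[[dv]]), , drop = FALSE]
  agg <- aggregate(data[[dv]],
                   list(subject = data[[subject]], level = data[[factor]]),
                   mean)
  levs <- unique(as.character(agg$level))
  if (length(levs) < 2L) stop("factor needs at least 2 levels")
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- agg[agg$level == pr[1L], ]
    b <- agg[agg$level == pr[2L], ]
    if (paired) {
      b <- b[match(a$subject, b$subject), ]
      tt <- t.test(a$x, b$x, paired = TRUE)
    } else {
      tt <- t.test(a$x, b$x, var.equal = TRUE)
    }
    data.frame(level_1 = pr[1L], level_2 = pr[2L],
               mean_diff = mean(a$x) - mean(b$x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, m * tt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cohen_d_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Independent-samples t-test with Cohen's d
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return list `t`, `df`, `p`, `cohen_d`, `mean_x`, `mean_y`.
#' @export
independent_ttest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per sample")
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1, cohen_d = 0,
                mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohen_d = cohen_d_pooled(x, y), mean_x = mean(x), mean_y = mean(y))
}

#' One-sample t-test against a reference value with Cohen's d
#'
#' The study uses this against 0, the "moderate" anchor of the
#' satisfaction/cybersickness scales.
#'
#' @param x numeric sample (n >= 2).
#' @param mu reference value (default 0).
#' @return list `t`, `df`, `p`, `cohen_d`, `mean`.
#' @export
one_sample_ttest <- function(x, mu = 0) {
  if (length(x) < 2L) stop("need at least 2 values")
  if (var(x) == 0) stop("zero variance sample")
  tt <- t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohen_d = (mean(x) - mu) / sd(x), mean = mean(x))
}

#' Correlation matrix with Benjamini-Hochberg correction
#'
#' Pairwise Pearson or Spearman correlations over the numeric columns of a
#' data frame; the BH step-up procedure is applied across the off-diagonal
#' tests of the matrix.  Constant columns yield `NA` entries with a
#' warning; pairs with fewer than 3 complete observations are `NA`.
#'
#' @param df data frame of outcome variables (non-numeric columns dropped).
#' @param method `"pearson"` or `"spearman"`.
#' @return list `r` (correlations), `p_raw`, `p_adj` (BH-adjusted),
#'   `n` (pairwise complete counts), `method`.
#' @export
correlation_matrix <- function(df, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- as.data.frame(df)
  df <- df[vapply(df, is.numeric, logical(1L))]
  vars <- names(df)
  k <- length(vars)
  if (k < 2L) stop("need at least two numeric variables")
  const <- vapply(df, function(x) var(x, na.rm = TRUE) == 0 ||
                    sum(!is.na(x)) < 2L, logical(1L))
  if (any(const)) {
    warning(sprintf("constant column(s): %s; entries set to NA",
                    paste(vars[const], collapse = ", ")))
  }
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- complete.cases(df[[i]], df[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L || const[i] || const[j]) next
      ct <- suppressWarnings(cor.test(df[[i]][ok], df[[j]][ok],
                                      method = method, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  up <- upper.tri(p)
  padj <- p
  padj[up] <- p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(r = r, p_raw = p, p_adj = padj, n = nmat, method = method)
}

#' Recognition accuracy
#'
#' Proportion of correct old/new judgments over the recognition items
#' (60 distractors, half actually played during the session).
#'
#' @param judgments logical vector: "was played" responses.
#' @param ground_truth logical vector of the same length: actually played.
#' @return fraction correct in `[0, 1]`.
#' @export
recognition_accuracy <- function(judgments, ground_truth) {
  if (length(judgments) != length(ground_truth)) {
    stop("judgments and ground truth differ in length")
  }
  mean(judgments == ground_truth)
}
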