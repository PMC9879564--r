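test_that("mixed ANOVA F statistics match the independent SS oracle", {
  for (seed in c(42, 43)) {
    d <- make_design(n_per = 3, seed = seed)
    av <- mixed_anova(d, "y")
    orc <- oracle_anova_2x3x2(d, "y")
    f_of <- function(eff) av$F[av$effect == eff]
    expect_equal(f_of("group"), unname(orc$F["A"]), tolerance = 1e-9)
    expect_equal(f_of("condition"), unname(orc$F["B"]), tolerance = 1e-9)
    expect_equal(f_of("group:condition"), unname(orc$F["AB"]),
                 tolerance = 1e-9)
    expect_equal(f_of("phase_type"), unname(orc$F["C"]), tolerance = 1e-9)
    expect_equal(f_of("group:phase_type"), unname(orc$F["AC"]),
                 tolerance = 1e-9)
    expect_equal(f_of("condition:phase_type"), unname(orc$F["BC"]),
                 tolerance = 1e-9)
    expect_equal(f_of("group:condition:phase_type"), unname(orc$F["ABC"]),
                 tolerance = 1e-9)
    # SS decomposition is conservative: all pieces tile the total
    expect_equal(Reduce(`+`, orc$ss), orc$total, tolerance = 1e-9)
  }
})

test_that("sphericity epsilons are reported and the switching rule applied", {
  d <- make_design(n_per = 6, seed = 7)
  av <- mixed_anova(d, "y")
  cond <- av[av$effect == "condition", ]
  expect_true(cond$eps_GG > 0 && cond$eps_GG <= 1)
  expect_true(cond$correction_applied %in% c("GG", "HF"))
  expect_equal(cond$correction_applied, ifelse(cond$eps_GG > 0.75, "HF", "GG"))
  # two-level factors need no correction
  expect_equal(av$correction_applied[av$effect == "phase_type"], "none")
  # corrected p never smaller than the uncorrected one for eps <= 1
  expect_gte(cond$p_corrected, cond$p - 1e-12)
})

test_that("constant outcomes and incomplete designs are reported as such", {
  d <- make_design(n_per = 3, seed = 1)
  d$y <- 5
  av <- mixed_anova(d, "y")
  expect_true(all(is.na(av$F)))
  d2 <- make_design(n_per = 3, seed = 1)
  d2 <- d2[-1, ]
  expect_error(mixed_anova(d2, "y"), "s01")
})

test_that("the 2 x 3 variant detects a pure group effect", {
  d <- make_design(n_per = 8, seed = 3, effect = 2)
  d <- d[d$phase_type == "DP", ]
  av <- mixed_anova(d, "y", within = "condition")
  expect_equal(nrow(av), 3L)
  expect_lt(av$p[av$effect == "group"], 0.05)
})

test_that("ANOVA type-I error is near nominal on null simulations", {
  # dv with no programmed effects: the group effect should reject ~5%
  rej <- 0L
  n_rep <- 120L
  for (r in seq_len(n_rep)) {
    d <- make_design(n_per = 4, seed = 1000 + r)
    av <- mixed_anova(d, "y")
    if (av$p[av$effect == "group"] < 0.05) rej <- rej + 1L
  }
  # binomial(120, .05): P(rej > 13) < 0.002
  expect_lte(rej, 13L)
  expect_gte(rej, 0L)
})

test_that("Bonferroni post-hocs scale p by the number of pairs", {
  d <- make_design(n_per = 5, seed = 9)
  ph3 <- posthoc_bonferroni(d, "y", "condition")
  expect_equal(nrow(ph3), 3L)
  expect_equal(ph3$p_adj, pmin(1, 3 * ph3$p_raw))
  expect_true(all(ph3$p_adj >= ph3$p_raw))
  ph1 <- posthoc_bonferroni(d, "y", "phase_type")
  expect_equal(nrow(ph1), 1L)
  expect_equal(ph1$p_adj, ph1$p_raw)
  ph2 <- posthoc_bonferroni(d, "y", "group", paired = FALSE)
  expect_equal(nrow(ph2), 1L)
})

test_that("t-tests handle degenerate and textbook cases", {
  x <- c(1, 2, 3, 4, 5)
  same <- independent_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # two-sample case cross-checked against a permutation oracle
  set.seed(11)
  a <- rnorm(12, 0.8); b <- rnorm(12, 0)
  tt <- independent_ttest(a, b)
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  perm <- replicate(4000, {
    idx <- sample(24, 12)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(abs(tt$p - p_perm), 0.05)
  expect_equal(sign(tt$cohen_d), sign(obs))
  # one-sample null behaviour
  set.seed(12)
  ps <- replicate(200, one_sample_ttest(rnorm(10))$p)
  expect_gt(mean(ps < 0.05), 0)   # some rejections happen
  expect_lt(mean(ps < 0.05), 0.12)
  expect_error(one_sample_ttest(rep(1, 5)), "zero variance")
})

test_that("correlation matrices are symmetric with BH-corrected p-values", {
  set.seed(13)
  df <- data.frame(a = rnorm(30))
  df$b <- 2 * df$a
  df$c <- rnorm(30)
  cm <- correlation_matrix(df, "pearson")
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_true(all(cm$p_adj >= cm$p_raw - 1e-15, na.rm = TRUE))
  # BH step-up hand computation: p = (.01,.02,.03,.04) all pass at q = .05
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_true(all(p.adjust(p, "BH") < 0.05))
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.04))
  # BH monotone in the raw p-values
  up <- upper.tri(cm$p_raw)
  o <- order(cm$p_raw[up])
  expect_true(all(diff(cm$p_adj[up][o]) >= -1e-15))
  # Spearman invariant under monotone transforms
  cs1 <- correlation_matrix(df, "spearman")
  df2 <- data.frame(a = exp(df$a), b = df$b^3, c = df$c)
  cs2 <- correlation_matrix(df2, "spearman")
  expect_equal(cs1$r, cs2$r, tolerance = 1e-12)
  # constant column warning
  df$d <- 1
  expect_warning(cm2 <- correlation_matrix(df), "constant")
  expect_true(is.na(cm2$r["a", "d"]))
})

test_that("recognition accuracy is the fraction of correct judgments", {
  truth <- rep(c(TRUE, FALSE), 30)
  expect_equal(recognition_accuracy(truth, truth), 1)
  expect_equal(recognition_accuracy(rep(TRUE, 60), truth), 0.5)
  expect_error(recognition_accuracy(truth[1:59], truth), "length")
  # random guessing converges to 0.5
  set.seed(14)
  acc <- replicate(300, recognition_accuracy(runif(60) < 0.5, truth))
  expect_lt(abs(mean(acc) - 0.5), 0.02)
})

test_that("the outcome assembler produces the full factorial table", {
  coh <- simulate_cohort(n_adhd = 2, n_hc = 2, seed = 31,
                         phase_seconds = 60, n_phases = 2,
                         include_eeg = FALSE)
  ot <- assemble_outcomes(coh, measures = c("cpt", "gaze", "head", "es"))
  expect_equal(nrow(ot), 4 * 3 * 2)
  expect_setequal(unique(ot$condition), c("real", "sham", "none"))
  expect_setequal(unique(ot$phase_type), c("DP", "NDP"))
  expect_true(all(c("omission_errors", "commission_errors", "mean_rt",
                    "head_movement", "pct_task_focus",
                    "distractibility_score", "es_inattention") %in% names(ot)))
  # dwell percentages repeat across the phase rows of a condition
  one <- ot[ot$participant_id == ot$participant_id[1] &
              ot$condition == ot$condition[1], ]
  expect_equal(one$pct_task_focus[1], one$pct_task_focus[2])
  # the assembled table feeds the ANOVA without complaint
  av <- mixed_anova(ot, "omission_errors")
  expect_s3_class(av, "anova_result")
})
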