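test_that("the EEG filter attenuates 50 Hz by > 20 dB and keeps 10 Hz", {
  # FFT-based response measurement on sinusoid inputs
  amp_at <- function(x, f, fs) {
    n <- length(x)
    sp <- Mod(fft(x))[seq_len(n / 2)] * 2 / n
    sp[round(f * n / fs) + 1L]
  }
  fs <- 500
  f50 <- preprocess_eeg(sine_eeg(50, dur = 20))$values$Fz
  f10 <- preprocess_eeg(sine_eeg(10, dur = 20))$values$Fz
  g50 <- amp_at(f50, 50, fs)
  g10 <- amp_at(f10, 10, fs)
  expect_lt(20 * log10(g50), -20)
  expect_lt(abs(g10 - 1), 0.05)
  # pure linear drift is removed by the detrend
  n <- 10 * fs
  drift <- time_series_stream("eeg", fs, (0:(n - 1)) / fs,
                              data.frame(Fz = seq(0, 100, length.out = n)))
  expect_lt(max(abs(preprocess_eeg(drift)$values$Fz)), 1e-8)
  # insufficient rate
  low <- time_series_stream("eeg", 60, (0:599) / 60, data.frame(Fz = rnorm(600)))
  expect_error(preprocess_eeg(low), "too low")
})

test_that("epoching yields floor(duration/5) epochs and rejects artifacts", {
  fs <- 500
  sch <- build_phase_schedule("DP", 2, 180)
  n <- 360 * fs
  set.seed(1)
  x <- rnorm(n, 0, 10)
  x[100000] <- 500                    # one spike in one epoch
  eeg <- time_series_stream("eeg", fs, (0:(n - 1)) / fs, data.frame(Fz = x))
  seg <- segment_eeg(eeg, sch)
  expect_equal(nrow(seg$info), 72L)            # 2 x 180/5
  expect_equal(seg$n_rejected, 1L)
  expect_false(seg$info$retained[seg$info$start == 195])
  # retained epochs are baseline corrected and bounded
  expect_true(all(vapply(seg$epochs, function(m) abs(mean(m)) < 1, logical(1L))))
  # concatenated epoch samples never exceed the phase sample count
  expect_lte(sum(vapply(seg$epochs, nrow, integer(1L))), n)
})

test_that("wavelet band power separates theta from beta", {
  fs <- 500
  t <- (0:(5 * fs - 1)) / fs
  wp5 <- wavelet_power(sin(2 * pi * 5 * t), fs)
  expect_gt(band_power(wp5, c(4, 7)) / band_power(wp5, c(13, 30)), 100)
  wp20 <- wavelet_power(sin(2 * pi * 20 * t), fs)
  expect_gt(band_power(wp20, c(13, 30)) / band_power(wp20, c(4, 7)), 100)
  # the analysis grid: 85 log-spaced steps between 0.1 and 35 Hz, 4 ms step
  expect_length(wp5$freqs, 85L)
  expect_equal(range(wp5$freqs), c(0.1, 35))
  expect_equal(diff(wp5$times)[1], 0.004)
})

test_that("wavelet TBR matches a closed-form Morlet response oracle", {
  # composite 5 + 20 Hz signal with amplitudes tuned so that the oracle
  # (analytic Morlet frequency response accumulated over the same log-grid
  # band bins) predicts a ratio of 1
  fs <- 500
  t <- (0:(5 * fs - 1)) / fs
  freqs <- cwt_frequencies()
  theta_bins <- freqs[freqs >= 4 & freqs <= 7]
  beta_bins <- freqs[freqs >= 13 & freqs <= 30]
  # analytic response of the unit-gain Morlet (width 6) at bin f to a
  # sinusoid of frequency f0 and amplitude A: power = (A/2)^2 *
  # exp(-omega0^2 (f0/f - 1)^2)
  oracle_band <- function(bins, f0, A) {
    mean((A / 2)^2 * exp(-36 * (f0 / bins - 1)^2))
  }
  A5 <- 1
  # choose A20 so oracle theta mean equals oracle beta mean
  A20 <- sqrt(oracle_band(theta_bins, 5, A5) / oracle_band(beta_bins, 20, 1))
  x <- A5 * sin(2 * pi * 5 * t) + A20 * sin(2 * pi * 20 * t)
  wp <- wavelet_power(x, fs)
  ratio <- band_power(wp, c(4, 7)) / band_power(wp, c(13, 30))
  expect_lt(abs(ratio - 1), 0.15)
  # and each band individually agrees with the oracle within 15%
  expect_lt(abs(band_power(wp, c(4, 7)) /
                  (oracle_band(theta_bins, 5, A5) +
                     oracle_band(theta_bins, 20, A20)) - 1), 0.15)
})

test_that("TBR is the theta/beta quotient and is gain invariant", {
  expect_equal(tbr(1, 1), 1)
  expect_equal(tbr(2, 1), 2)
  expect_error(tbr(1, 0), "positive")
  fs <- 500
  set.seed(2)
  t <- (0:(5 * fs - 1)) / fs
  for (i in 1:5) {
    x <- rnorm(length(t)) + sin(2 * pi * runif(1, 4, 25) * t)
    w1 <- wavelet_power(x, fs)
    w3 <- wavelet_power(3 * x, fs)
    r1 <- band_power(w1, c(4, 7)) / band_power(w1, c(13, 30))
    r3 <- band_power(w3, c(4, 7)) / band_power(w3, c(13, 30))
    expect_equal(r1, r3, tolerance = 1e-10)
    expect_gt(band_power(w1, c(4, 7)), 0)
  }
})

test_that("the full TBR pipeline recovers the DP > NDP theta modulation", {
  sch <- build_phase_schedule("DP", 2, 60)
  prof <- participant_profile("ADHD", theta_dp_boost = 1.3)
  eeg <- gart:::synth_eeg(prof, sch, seed = 3)
  res <- compute_tbr(eeg, sch)
  expect_equal(res$n_segments_used, c(12L, 12L))
  expect_gt(res$tbr[res$phase_type == "DP"], res$tbr[res$phase_type == "NDP"])
  expect_true(all(res$theta_power > 0) && all(res$beta_power > 0))
})

test_that("head displacement reproduces constant motion and is invariant
          to offsets and rotations", {
  fs <- 90
  n <- 30 * fs
  t <- (0:(n - 1)) / fs
  hs <- time_series_stream("head", fs, t,
                           data.frame(x = 0.05 * t, y = rep(1.6, n),
                                      z = rep(0, n)))
  hd <- head_displacement(hs)
  expect_equal(hd$mean_displacement, 0.05 / 10, tolerance = 1e-3)
  expect_equal(hd$rate, 10)
  # stationary head: zero
  hs0 <- time_series_stream("head", fs, t,
                            data.frame(x = rep(0, n), y = rep(1.6, n),
                                       z = rep(0, n)))
  expect_lt(head_displacement(hs0)$mean_displacement, 1e-6)
  # offset and rotation invariance on a random walk
  set.seed(5)
  pos <- apply(matrix(rnorm(3 * n, 0, 4e-4), n, 3), 2, cumsum)
  mk <- function(p) time_series_stream("head", fs, t,
                                       data.frame(x = p[, 1], y = p[, 2],
                                                  z = p[, 3]))
  base <- head_displacement(mk(pos))$mean_displacement
  shifted <- head_displacement(mk(sweep(pos, 2, c(5, -2, 1), "+")))
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- head_displacement(mk(pos %*% Rz))
  expect_equal(shifted$mean_displacement, base, tolerance = 1e-3)
  expect_equal(rotated$mean_displacement, base, tolerance = 1e-9)
  expect_error(head_displacement(time_series_stream("head", fs, t[1:45],
                                                    data.frame(x = rep(0, 45),
                                                               y = rep(0, 45),
                                                               z = rep(0, 45)))),
               "longer than 1 s")
})

test_that("ADHD-profile head traces move more than HC on matched seeds", {
  means <- sapply(c("ADHD", "HC"), function(g) {
    mean(sapply(1:3, function(s) {
      hs <- gart:::synth_head(participant_profile(g), 60, seed = s)
      head_displacement(hs)$mean_displacement
    }))
  })
  expect_gt(means[["ADHD"]], means[["HC"]])
})
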