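# EEG theta/beta-ratio pipeline at Fz and head-actigraphy displacement.
#
# EEG: zero-phase low-pass at 35 Hz, linear detrend, non-overlapping 5 s
# epochs per condition x phase, per-epoch mean (baseline) subtraction,
# amplitude-threshold artifact rejection, complex Morlet continuous wavelet
# transform on a log-spaced 0.1-35 Hz grid (85 steps, 4 ms time
# resolution), and theta (4-7 Hz) / beta (13-30 Hz) band powers averaged
# over 0.5-4.5 s of each epoch.  Head actigraphy: anti-aliased downsampling
# to ~10 Hz and the mean Euclidean distance between consecutive positions.

stream_rate <- function(stream) {
  if (length(stream$t) < 2L) stop("stream too short to estimate a rate")
  1 / median(diff(stream$t))
}

#' Detrend and low-pass filter an EEG recording
#'
#' Per-channel linear detrend followed by a zero-phase (forward-backward)
#' 4th-order Butterworth low-pass; detrending first keeps slow drifts from
#' smearing into filter edge transients.
#'
#' @param eeg an EEG `ts_stream` (microvolts).
#' @param low_pass cutoff frequency in Hz (default 35).
#' @return the filtered `ts_stream`.
#' @export
preprocess_eeg <- function(eeg, low_pass = 35) {
  fs <- stream_rate(eeg)
  if (fs < 2 * low_pass) {
    stop(sprintf("sampling rate %.1f Hz too low for a %.0f Hz low-pass",
                 fs, low_pass))
  }
  bf <- signal::butter(4, low_pass / (fs / 2), type = "low")
  vals <- eeg$values
  n <- nrow(vals)
  tt <- seq_len(n)
  for (ch in names(vals)) {
    fit <- lm.fit(cbind(1, tt), vals[[ch]])
    vals[[ch]] <- signal::filtfilt(bf, vals[[ch]] - fit$fitted.values)
  }
  time_series_stream(eeg$name, eeg$nominal_rate, eeg$t, vals, eeg$validity)
}

#' Cut a recording into artifact-screened 5 s epochs per phase
#'
#' Each schedule phase is epoched into as many non-overlapping
#' `epoch_seconds` segments as fit; each epoch is baseline-corrected by
#' subtracting its per-channel mean, and epochs containing any sample with
#' absolute amplitude above `amplitude_threshold` (after baseline
#' correction) are rejected.
#'
#' @param eeg a preprocessed EEG `ts_stream`.
#' @param schedule a `phase_schedule` covering the recording.
#' @param epoch_seconds epoch length in seconds (default 5).
#' @param amplitude_threshold artifact rejection bound in microvolts (100).
#' @return list with `epochs` (list of samples x channels matrices of the
#'   retained epochs), `info` (data frame `phase_index`, `phase_type`,
#'   `start`, `retained`), and `n_rejected`.
#' @export
segment_eeg <- function(eeg, schedule, epoch_seconds = 5,
                        amplitude_threshold = 100) {
  epochs <- list()
  info <- list()
  for (i in seq_len(nrow(schedule))) {
    p0 <- schedule$start[i]
    k <- floor((schedule$end[i] - p0) / epoch_seconds)
    for (j in seq_len(k)) {
      e0 <- p0 + (j - 1L) * epoch_seconds
      sel <- eeg$t >= e0 & eeg$t < e0 + epoch_seconds
      m <- as.matrix(eeg$values[sel, , drop = FALSE])
      m <- sweep(m, 2L, colMeans(m))            # baseline correction
      ok <- all(abs(m) <= amplitude_threshold)
      if (ok) epochs[[length(epochs) + 1L]] <- m
      info[[length(info) + 1L]] <- data.frame(
        phase_index = i, phase_type = schedule$phase_type[i], start = e0,
        retained = ok, stringsAsFactors = FALSE)
    }
  }
  info <- do.call(rbind, info)
  list(epochs = epochs, info = info, n_rejected = sum(!info$retained))
}

#' The log-spaced analysis frequency grid
#'
#' @param from,to frequency range in Hz (defaults 0.1 and 35).
#' @param n number of steps on a log scale (default 85).
#' @return numeric vector of frequencies.
#' @export
cwt_frequencies <- function(from = 0.1, to = 35, n = 85L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Complex Morlet continuous wavelet transform power
#'
#' FFT-based CWT with an analytic complex Morlet wavelet (default width 6
#' cycles).  The wavelet is amplitude-normalized per frequency (unit gain at
#' its center frequency), so a sinusoid of amplitude A yields power A^2/4 at
#' its frequency regardless of where it sits on the grid -- the property
#' that makes theta/beta power ratios meaningful.
#'
#' @param x numeric vector, one channel of one epoch (microvolts).
#' @param fs sampling rate in Hz.
#' @param freqs analysis frequencies (default [cwt_frequencies()]).
#' @param time_resolution spacing of the output time grid in seconds
#'   (default 0.004).
#' @param omega0 wavelet width parameter (cycles; default 6).
#' @return list `freqs`, `times` (seconds from epoch start), `power`
#'   (frequencies x times matrix, microvolts^2).
#' @export
wavelet_power <- function(x, fs, freqs = cwt_frequencies(),
                          time_resolution = 0.004, omega0 = 6) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2L * n))              # zero-pad against wrap-around
  X <- fft(c(x, rep(0, nfft - n)))
  fft_f <- (seq_len(nfft) - 1L) / nfft * fs
  pos <- fft_f <= fs / 2 & fft_f > 0
  step <- max(1L, round(time_resolution * fs))
  keep <- seq(1L, n, by = step)
  pw <- matrix(0, length(freqs), length(keep))
  for (i in seq_along(freqs)) {
    H <- numeric(nfft)
    H[pos] <- exp(-omega0^2 * (fft_f[pos] / freqs[i] - 1)^2 / 2)
    w <- fft(X * H, inverse = TRUE) / nfft
    pw[i, ] <- Mod(w[keep])^2
  }
  list(freqs = freqs, times = (keep - 1L) / fs, power = pw)
}

#' Mean band power of a wavelet power map
#'
#' @param wp result of [wavelet_power()].
#' @param band two-element frequency range in Hz (inclusive).
#' @param time_window two-element time window in seconds (default
#'   `c(0.5, 4.5)`).
#' @return mean power over the band's frequency bins and the time window.
#' @export
band_power <- function(wp, band, time_window = c(0.5, 4.5)) {
  fi <- wp$freqs >= band[1L] & wp$freqs <= band[2L]
  ti <- wp$times >= time_window[1L] & wp$times <= time_window[2L]
  if (!any(fi)) stop("no analysis frequency falls inside the band")
  mean(wp$power[fi, ti])
}

#' Theta/beta ratio
#'
#' @param theta_power,beta_power band powers in microvolts^2.
#' @return `theta_power / beta_power` (dimensionless, gain-invariant).
#' @export
tbr <- function(theta_power, beta_power) {
  if (any(beta_power <= 0)) stop("beta power must be positive")
  theta_power / beta_power
}

#' Full TBR pipeline for one block
#'
#' Filters and detrends the recording, epochs it per phase, and averages
#' theta (4-7 Hz) and beta (13-30 Hz) wavelet power at the target channel
#' over 0.5-4.5 s of each retained epoch, separately for DP and NDP.
#'
#' @param eeg raw EEG `ts_stream` of a block.
#' @param schedule the block's `phase_schedule`.
#' @param channel channel analyzed (default `"Fz"`).
#' @param theta_band,beta_band frequency bands in Hz.
#' @param epoch_seconds,amplitude_threshold see [segment_eeg()].
#' @return data frame per phase type: `theta_power`, `beta_power`, `tbr`,
#'   `n_segments_used`, `n_rejected`.
#' @export
compute_tbr <- function(eeg, schedule, channel = "Fz",
                        theta_band = c(4, 7), beta_band = c(13, 30),
                        epoch_seconds = 5, amplitude_threshold = 100) {
  if (!channel %in% names(eeg$values)) {
    stop(sprintf("channel '%s' not present in the recording", channel))
  }
  fs <- stream_rate(eeg)
  filtered <- preprocess_eeg(eeg)
  seg <- segment_eeg(filtered, schedule, epoch_seconds, amplitude_threshold)
  kept_types <- seg$info$phase_type[seg$info$retained]
  ch_idx <- match(channel, colnames(seg$epochs[[1L]]))
  out <- lapply(PHASE_TYPES, function(pt) {
    idx <- which(kept_types == pt)
    if (!length(idx)) {
      return(data.frame(phase_type = pt, theta_power = NA_real_,
                        beta_power = NA_real_, tbr = NA_real_,
                        n_segments_used = 0L,
                        n_rejected = sum(seg$info$phase_type == pt &
                                           !seg$info$retained)))
    }
    th <- be <- numeric(length(idx))
    for (j in seq_along(idx)) {
      wp <- wavelet_power(seg$epochs[[idx[j]]][, ch_idx], fs)
      th[j] <- band_power(wp, theta_band)
      be[j] <- band_power(wp, beta_band)
    }
    data.frame(phase_type = pt, theta_power = mean(th), beta_power = mean(be),
               tbr = tbr(mean(th), mean(be)), n_segments_used = length(idx),
               n_rejected = sum(seg$info$phase_type == pt & !seg$info$retained),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Head actigraphy: mean displacement per downsampled step
#'
#' Anti-aliased downsampling of the 3D head position to about
#' `target_rate`, then the mean of the Euclidean distances between
#' consecutive positions.  Invariant to constant positional offsets and to
#' global rotations of the coordinate frame.
#'
#' @param head a head-position `ts_stream` (meters).
#' @param target_rate target sampling rate in Hz (default 10).
#' @param schedule optional `phase_schedule`; when given, mean
#'   displacements are also reported per phase type (steps assigned by the
#'   time of their first sample, half-open).
#' @return list `mean_displacement` (meters per step), `n_steps`, `rate`,
#'   and, with a schedule, `by_phase` (data frame per phase type).
#' @export
head_displacement <- function(head, target_rate = 10, schedule = NULL) {
  if (!length(head$t)) stop("empty head trace")
  if (diff(range(head$t)) <= 1) stop("head trace must be longer than 1 s")
  fs <- stream_rate(head)
  q <- max(1L, round(fs / target_rate))
  pos <- as.matrix(head$values[, c("x", "y", "z")])
  if (q > 1L) {
    # zero-phase low-pass at 80% of the target Nyquist, then subsample
    bf <- signal::butter(4, 0.8 / q)
    pos <- vapply(1:3, function(c) {
      signal::filtfilt(bf, pos[, c])[seq(1L, nrow(pos), by = q)]
    }, numeric(length(seq(1L, nrow(pos), by = q))))
    tds <- head$t[seq(1L, length(head$t), by = q)]
  } else tds <- head$t
  # trim filter edge transients (up to ~1 s at the target rate)
  trim <- min(10L, max(1L, floor(nrow(pos) / 5L)))
  if (nrow(pos) > 2L * trim + 2L) {
    pos <- pos[(trim + 1L):(nrow(pos) - trim), , drop = FALSE]
    tds <- tds[(trim + 1L):(length(tds) - trim)]
  }
  steps <- sqrt(rowSums(diff(pos)^2))
  out <- list(mean_displacement = mean(steps), n_steps = length(steps),
              rate = fs / q)
  if (!is.null(schedule)) {
    ph <- phase_at(schedule, tds[-length(tds)])
    types <- schedule$phase_type[ph]
    out$by_phase <- do.call(rbind, lapply(PHASE_TYPES, function(pt) {
      sel <- !is.na(types) & types == pt
      data.frame(phase_type = pt,
                 mean_displacement = if (any(sel)) mean(steps[sel]) else NA_real_,
                 n_steps = sum(sel), stringsAsFactors = FALSE)
    }))
  }
  out
}
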