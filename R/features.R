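# Per-window tremor feature extraction.
#
# All spectral features share one estimator: the one-sided magnitude-squared
# FFT periodogram of the mean-removed, Hann-windowed block. Band powers and
# dominant-frequency features evaluate it with 5x zero-padding (finer
# frequency grid for integration and peak location); spectral entropy uses
# the native resolution, where the bins are uncorrelated and the entropy of
# a pure tone is not inflated by interpolation.

#' Segment a recording into fixed-length windows
#'
#' Cuts the recording into `window_s`-second windows with the given overlap;
#' the trailing partial window is discarded. With `N` samples, window length
#' `W` and step `S = W * (1 - overlap)`, the number of windows is
#' `floor((N - W) / S) + 1` (0 when `N < W`).
#'
#' @param rec a [gyro_recording()].
#' @param window_s window length in seconds (default 5).
#' @param overlap fraction of overlap between consecutive windows in
#'   `[0, 1)` (default 0).
#' @return a list of `W x 3` matrices (axes X, Y, Z), in temporal order.
#' @export
segment <- function(rec, window_s = 5, overlap = 0) {
  stopifnot(inherits(rec, "gyro_recording"), overlap >= 0, overlap < 1)
  fs <- rec$sampling_rate_hz
  w <- window_s * fs
  if (abs(w - round(w)) > 1e-9 || w < 64)
    stop("window_s * sampling_rate_hz must be an integer >= 64")
  w <- as.integer(round(w))
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  n <- n_samples(rec)
  if (n < w) {
    warning("recording shorter than one window; no windows produced")
    return(list())
  }
  starts <- seq.int(1L, n - w + 1L, by = step)
  lapply(starts, function(s) rec$axes[s:(s + w - 1L), , drop = FALSE])
}

# One-sided Hann periodogram. Returns frequencies (Hz, DC excluded), power
# spectral density values and the bin width.
psd_estimate <- function(x, fs, pad = 5L) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  nfft <- as.integer(pad * n)
  X <- stats::fft(c(x * w, rep(0, nfft - n)))
  nb <- nfft %/% 2L
  p <- Mod(X[2:(nb + 1L)])^2 / (fs * sum(w^2))
  # fold the negative frequencies in (Nyquist bin of an even nfft is unpaired)
  if (nfft %% 2L == 0L) p[-nb] <- 2 * p[-nb] else p <- 2 * p
  list(f = (1:nb) * fs / nfft, p = p, df = fs / nfft)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Band power of a window
#'
#' Integral (trapezoidal) of the one-sided periodogram over the frequency
#' band `[f_lo, f_hi]`. Scales with the square of the signal amplitude; an
#' all-zero window yields 0.
#'
#' @param x numeric vector, one axis of one window.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @param fs sampling rate in Hz (default 64).
#' @return non-negative scalar, (deg/s)^2.
#' @export
band_power <- function(x, f_lo, f_hi, fs = 64) {
  stopifnot(f_lo >= 0, f_lo < f_hi, f_hi <= fs / 2)
  if (all(x == x[1])) return(0)
  sp <- psd_estimate(x, fs)
  sel <- sp$f >= f_lo & sp$f <= f_hi
  if (sum(sel) < 2L) return(0)
  trapz(sp$f[sel], sp$p[sel])
}

#' Fraction of signal power above a frequency threshold
#'
#' Power in `(f_threshold, fs/2]` divided by total power in `(0, fs/2]`
#' (DC excluded). Returns 0 for an all-zero or constant window.
#'
#' @inheritParams band_power
#' @param f_threshold threshold frequency in Hz (default 4).
#' @return scalar in `[0, 1]`.
#' @export
percent_power_above <- function(x, f_threshold = 4, fs = 64) {
  stopifnot(f_threshold > 0, f_threshold < fs / 2)
  if (all(x == x[1])) return(0)
  sp <- psd_estimate(x, fs)
  tot <- sum(sp$p)
  if (tot <= 0) return(0)
  sum(sp$p[sp$f > f_threshold]) / tot
}

#' Autocorrelation peak features of a window
#'
#' Computes the biased, zero-lag-normalized autocorrelation over lags
#' `1 .. W-1` and finds its peaks: strict local maxima with normalized
#' amplitude above `amp_threshold` at lags of at least `min_lag` samples.
#' The default threshold of 0.25 sits around 4.5 standard deviations of the
#' autocorrelation of white noise at the 5-s/64-Hz window size, so noise
#' windows report (close to) zero peaks while oscillatory windows keep
#' every harmonic peak.
#' Returns the number of peaks, the sum of their amplitudes, and the
#' amplitude and lag of the smallest-lag ("first") peak. A window with no
#' qualifying peak (including all-zero windows) yields `(0, 0, 0, 0)`.
#'
#' @inheritParams band_power
#' @param amp_threshold minimum normalized peak amplitude (default 0.25).
#' @param min_lag minimum peak lag in samples (default 2).
#' @return named numeric vector `n_peaks`, `sum_peaks`, `first_amp`,
#'   `first_lag`.
#' @export
autocorr_peak_features <- function(x, amp_threshold = 0.25, min_lag = 2L,
                                   fs = 64) {
  stopifnot(length(x) >= 3L)
  zero <- c(n_peaks = 0, sum_peaks = 0, first_amp = 0, first_lag = 0)
  if (stats::sd(x) == 0) return(zero)
  r <- as.numeric(stats::acf(x, lag.max = length(x) - 1L, plot = FALSE,
                             demean = TRUE)$acf)[-1]  # lags 1 .. W-1
  k <- 2:(length(r) - 1L)
  is_peak <- r[k] > r[k - 1L] & r[k] > r[k + 1L] &
    r[k] > amp_threshold & k >= min_lag
  lags <- k[is_peak]
  if (!length(lags)) return(zero)
  amps <- r[lags]
  c(n_peaks = length(lags), sum_peaks = sum(amps),
    first_amp = amps[1], first_lag = lags[1])
}

#' Normalized spectral entropy of a window
#'
#' Shannon entropy of the periodogram normalized to a probability mass over
#' frequency bins, divided by `log(n_bins)` so the value lies in `[0, 1]`
#' (1 = flat/noise-like spectrum, small = tonal). An all-zero window yields
#' 1 by convention (maximally uninformative).
#'
#' @inheritParams band_power
#' @return scalar in `[0, 1]`.
#' @export
spectral_entropy <- function(x, fs = 64) {
  stopifnot(length(x) >= 8L)
  if (all(x == x[1])) return(1)
  sp <- psd_estimate(x, fs, pad = 1L)
  p <- sp$p / sum(sp$p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(sp$p))
}

#' Dominant frequencies of a window
#'
#' Locates the two largest strict local maxima of the periodogram (peaks
#' below 1% of the maximum PSD value are ignored, which discards window
#' sidelobes). Returns the frequency and power of each; if fewer than two
#' qualifying maxima exist the missing slots are 0. Exact power ties are
#' broken toward the lower frequency.
#'
#' @inheritParams band_power
#' @return named numeric vector `f1`, `p1`, `f2`, `p2`.
#' @export
dominant_frequencies <- function(x, fs = 64) {
  stopifnot(length(x) >= 8L)
  zero <- c(f1 = 0, p1 = 0, f2 = 0, p2 = 0)
  if (all(x == x[1])) return(zero)
  sp <- psd_estimate(x, fs)
  p <- sp$p
  k <- 2:(length(p) - 1L)
  pk <- k[p[k] > p[k - 1L] & p[k] > p[k + 1L] & p[k] >= 0.01 * max(p)]
  if (!length(pk)) return(zero)
  ord <- pk[order(-p[pk], sp$f[pk])]
  f1 <- sp$f[ord[1]]; p1 <- p[ord[1]]
  if (length(ord) < 2L) return(c(f1 = f1, p1 = p1, f2 = 0, p2 = 0))
  c(f1 = f1, p1 = p1, f2 = sp$f[ord[2]], p2 = p[ord[2]])
}

#' Lag-max cross-correlation between two axes
#'
#' Maximum, over lags within `±max_lag_s`, of the normalized
#' cross-correlation of the mean-removed signals. `max_lag_s = 0` gives the
#' plain (zero-lag) correlation. Returns 0 when either input is constant.
#'
#' @param a,b numeric vectors of equal length.
#' @param max_lag_s lag range in seconds (default 0.5).
#' @param fs sampling rate in Hz (default 64).
#' @return scalar in `[-1, 1]`.
#' @export
axis_cross_correlation <- function(a, b, max_lag_s = 0.5, fs = 64) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  a <- a - mean(a); b <- b - mean(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  L <- as.integer(round(max_lag_s * fs))
  n <- length(a)
  best <- -Inf
  for (l in -L:L) {
    if (l >= 0) v <- sum(a[seq_len(n - l)] * b[(1 + l):n])
    else        v <- sum(a[(1 - l):n] * b[seq_len(n + l)])
    if (v > best) best <- v
  }
  best / denom
}

# All 12 per-axis features for one axis of one window, in registry order.
axis_features <- function(x, fs, cfg) {
  sp5 <- if (all(x == x[1])) NULL else psd_estimate(x, fs, pad = 5L)
  bp <- function(lo, hi) {
    if (is.null(sp5)) return(0)
    sel <- sp5$f >= lo & sp5$f <= hi
    if (sum(sel) < 2L) 0 else trapz(sp5$f[sel], sp5$p[sel])
  }
  pct <- if (is.null(sp5) || sum(sp5$p) <= 0) 0 else
    sum(sp5$p[sp5$f > cfg$pct_threshold_hz]) / sum(sp5$p)
  ac <- autocorr_peak_features(x, cfg$acf_amp_threshold, cfg$acf_min_lag, fs)
  se <- spectral_entropy(x, fs)
  dm <- if (is.null(sp5)) c(f1 = 0, p1 = 0, f2 = 0, p2 = 0) else {
    p <- sp5$p
    k <- 2:(length(p) - 1L)
    pk <- k[p[k] > p[k - 1L] & p[k] > p[k + 1L] & p[k] >= 0.01 * max(p)]
    if (!length(pk)) c(f1 = 0, p1 = 0, f2 = 0, p2 = 0) else {
      ord <- pk[order(-p[pk], sp5$f[pk])]
      c(f1 = sp5$f[ord[1]], p1 = p[ord[1]],
        f2 = if (length(ord) > 1L) sp5$f[ord[2]] else 0,
        p2 = if (length(ord) > 1L) p[ord[2]] else 0)
    }
  }
  c(bp(4, 6), bp(0.5, 15), pct,
    ac[["n_peaks"]], ac[["sum_peaks"]], ac[["first_amp"]], ac[["first_lag"]],
    se, dm[["f1"]], dm[["p1"]], dm[["f2"]], dm[["p2"]])
}

#' Feature-extraction configuration
#'
#' Tunable constants of the feature registry: the >4 Hz percentage-power
#' threshold, the autocorrelation peak criterion and the cross-correlation
#' lag range.
#'
#' @param pct_threshold_hz threshold of the percentage-power feature (Hz).
#' @param acf_amp_threshold minimum normalized autocorrelation peak height.
#' @param acf_min_lag minimum autocorrelation peak lag (samples).
#' @param xcorr_max_lag_s cross-correlation lag range (seconds).
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(pct_threshold_hz = 4, acf_amp_threshold = 0.25,
                           acf_min_lag = 2L, xcorr_max_lag_s = 0.5) {
  structure(list(pct_threshold_hz = pct_threshold_hz,
                 acf_amp_threshold = acf_amp_threshold,
                 acf_min_lag = acf_min_lag,
                 xcorr_max_lag_s = xcorr_max_lag_s),
            class = "feature_config")
}

# Feature vector (39 values, registry order) for one sensor's window block.
sensor_window_features <- function(block, fs, cfg) {
  per_axis <- vapply(1:3, function(j) axis_features(block[, j], fs, cfg),
                     numeric(12))
  # per_axis is 12 x 3 (feature x axis); registry order is axis-minor
  xc <- c(axis_cross_correlation(block[, 1], block[, 2], cfg$xcorr_max_lag_s, fs),
          axis_cross_correlation(block[, 1], block[, 3], cfg$xcorr_max_lag_s, fs),
          axis_cross_correlation(block[, 2], block[, 3], cfg$xcorr_max_lag_s, fs))
  c(as.vector(t(per_axis)), xc)
}

#' Extract the 78-feature matrix of a round
#'
#' Segments the round's (already band-pass filtered) wrist and ankle
#' recordings into windows and computes, per window, the 12 per-axis
#' features on each of the 6 sensor-axis signals plus the 3 cross-axis
#' correlations per sensor — 78 features in canonical registry order
#' (see [feature_registry()]).
#'
#' @param round a [round_record()].
#' @param window_s window length in seconds (default 5).
#' @param overlap overlap fraction in `[0, 1)` (default 0).
#' @param config a [feature_config()].
#' @return a data.frame with key columns `subject_id`, `round_index`,
#'   `window_index` followed by the 78 feature columns. Zero windows give a
#'   zero-row frame.
#' @export
extract_features <- function(round, window_s = 5, overlap = 0,
                             config = feature_config()) {
  stopifnot(inherits(round, "round_record"))
  fs <- round$wrist$sampling_rate_hz
  ww <- suppressWarnings(segment(round$wrist, window_s, overlap))
  wa <- suppressWarnings(segment(round$ankle, window_s, overlap))
  nw <- min(length(ww), length(wa))
  reg <- feature_registry()
  if (nw == 0L) {
    out <- data.frame(subject_id = character(0), round_index = integer(0),
                      window_index = integer(0))
    out[reg] <- numeric(0)
    return(out)
  }
  feat <- t(vapply(seq_len(nw), function(i)
    c(sensor_window_features(ww[[i]], fs, config),
      sensor_window_features(wa[[i]], fs, config)),
    numeric(78)))
  colnames(feat) <- reg
  cbind(data.frame(subject_id = round$subject_id,
                   round_index = round$round_index,
                   window_index = seq_len(nw), stringsAsFactors = FALSE),
        as.data.frame(feat))
}

#' Extract features for a whole cohort
#'
#' @param rounds a list of [round_record()]s (e.g. from [assemble_rounds()]).
#' @param ... passed to [extract_features()].
#' @return one data.frame stacking every round's windows.
#' @export
extract_cohort_features <- function(rounds, ...) {
  out <- do.call(rbind, lapply(rounds, extract_features, ...))
  rownames(out) <- NULL
  out
}
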