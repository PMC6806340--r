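# Gyroscope recordings and band-pass preprocessing.

#' Construct a gyroscope recording
#'
#' A `gyro_recording` holds one sensor site's triaxial angular-velocity
#' stream (deg/s) at a fixed sampling rate. All three axes must have the
#' same length and contain only finite values; the sampling rate must sit
#' above twice the preprocessing band's upper cutoff (15 Hz) so the tremor
#' band is representable.
#'
#' @param x,y,z numeric vectors of equal length, angular velocity in deg/s.
#' @param site `"wrist"` or `"ankle"`.
#' @param sampling_rate_hz samples per second (default 64).
#' @param t0 time of the first sample in seconds from experiment start.
#' @return an object of class `gyro_recording` with fields `axes`
#'   (n x 3 matrix, columns X/Y/Z), `site`, `sampling_rate_hz`, `t0`.
#' @export
gyro_recording <- function(x, y, z, site = c("wrist", "ankle"),
                           sampling_rate_hz = 64, t0 = 0) {
  site <- match.arg(site)
  if (!(length(x) == length(y) && length(y) == length(z)))
    stop("axis sequences must have identical length")
  if (length(x) < 1L) stop("recording must contain at least one sample")
  axes <- cbind(X = as.numeric(x), Y = as.numeric(y), Z = as.numeric(z))
  if (!all(is.finite(axes)))
    stop("recording contains non-finite samples")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 30)
    stop("sampling_rate_hz must exceed 30 Hz (Nyquist above the 15 Hz cutoff)")
  structure(list(axes = axes, site = site,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 t0 = as.numeric(t0)),
            class = "gyro_recording")
}

#' @export
print.gyro_recording <- function(x, ...) {
  cat(sprintf("<gyro_recording> site=%s  n=%d  rate=%g Hz  duration=%.2f s\n",
              x$site, nrow(x$axes), x$sampling_rate_hz,
              nrow(x$axes) / x$sampling_rate_hz))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$axes)
duration_s <- function(rec) nrow(rec$axes) / rec$sampling_rate_hz

#' Read a sensor CSV file
#'
#' Reads one site's recording from the sensor CSV dialect: header
#' `time_s,gyro_x,gyro_y,gyro_z` with angular velocity in deg/s. Extra
#' columns (e.g. accelerometer channels `acc_*`) are parsed and discarded
#' with a notice: the estimation pipeline is gyroscope-only. Non-numeric
#' cells and missing values are rejected by default; gaps of at most
#' `max_gap` consecutive missing samples can instead be repaired by linear
#' interpolation with `na_policy = "interpolate"`.
#'
#' @param path path to the CSV file.
#' @param site `"wrist"` or `"ankle"`.
#' @param sampling_rate_hz nominal sampling rate of the file (default 64).
#' @param na_policy `"reject"` (default) or `"interpolate"`.
#' @param max_gap largest interpolatable run of missing samples (default 3).
#' @return a [gyro_recording()].
#' @export
load_recording <- function(path, site = c("wrist", "ankle"),
                           sampling_rate_hz = 64,
                           na_policy = c("reject", "interpolate"),
                           max_gap = 3L) {
  site <- match.arg(site)
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("time_s", "gyro_x", "gyro_y", "gyro_z")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(dt), need)
  if (length(extra))
    message("discarding non-gyroscope column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  if (nrow(dt) == 0L) stop("file ", path, " contains no samples")
  for (col in need) {
    v <- dt[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' in ", path, " is not numeric (first offending row ",
           which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1], ")")
  }
  gyro <- as.matrix(dt[, c("gyro_x", "gyro_y", "gyro_z")])
  bad <- which(!is.finite(gyro), arr.ind = TRUE)
  if (nrow(bad)) {
    if (na_policy == "reject")
      stop("non-finite value in ", path, " at row ", bad[1, 1],
           ", column '", c("gyro_x", "gyro_y", "gyro_z")[bad[1, 2]],
           "' (na_policy = \"reject\")")
    for (j in 1:3) gyro[, j] <- interpolate_gaps(gyro[, j], max_gap, path)
  }
  gyro_recording(gyro[, 1], gyro[, 2], gyro[, 3], site = site,
                 sampling_rate_hz = sampling_rate_hz, t0 = dt$time_s[1])
}

interpolate_gaps <- function(v, max_gap, path) {
  na <- !is.finite(v)
  if (!any(na)) return(v)
  r <- rle(na)
  if (any(r$values & r$lengths > max_gap))
    stop("gap of more than ", max_gap, " consecutive missing samples in ", path)
  if (na[1] || na[length(v)])
    stop("missing samples at the edge of ", path, " cannot be interpolated")
  idx <- which(!na)
  stats::approx(idx, v[idx], xout = seq_along(v))$y
}

#' Write a recording in the sensor CSV dialect
#'
#' Inverse of [load_recording()]: values round-trip bit-identically.
#'
#' @param rec a [gyro_recording()].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  t <- rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$sampling_rate_hz
  # %.17g guarantees the doubles parse back bit-identically
  dt <- data.table::data.table(time_s = sprintf("%.17g", t),
                               gyro_x = sprintf("%.17g", rec$axes[, 1]),
                               gyro_y = sprintf("%.17g", rec$axes[, 2]),
                               gyro_z = sprintf("%.17g", rec$axes[, 3]))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

# ---- band-pass FIR preprocessing -------------------------------------------

.filter_cache <- new.env(parent = emptyenv())

# Amplitude response of a FIR filter at frequencies f (Hz).
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  abs(vapply(f, function(fi) sum(h * exp(-2i * pi * fi * k / fs)), complex(1)))
}

#' Design the tremor band-pass FIR filter
#'
#' Linear-phase windowed-sinc (Hamming) band-pass whose -3 dB points are
#' calibrated to `low_hz` and `high_hz`: the nominal windowed-sinc cutoffs
#' sit at the -6 dB points, so the design edges are moved outward by
#' bisection until the realized response crosses 1/sqrt(2) at the requested
#' frequencies.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param low_hz,high_hz -3 dB edges (defaults 0.5 and 15 Hz).
#' @param n_taps filter length; default 4 s of samples plus one (257 at
#'   64 Hz), forced odd so the filter has integer group delay.
#' @return numeric vector of filter coefficients.
#' @export
design_bandpass <- function(sampling_rate_hz, low_hz = 0.5, high_hz = 15,
                            n_taps = NULL) {
  fs <- sampling_rate_hz
  if (is.null(n_taps)) n_taps <- round(4 * fs) + 1L
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs / 2))
    stop("need 0 < low_hz < high_hz < sampling_rate_hz/2")
  key <- paste(fs, low_hz, high_hz, n_taps, sep = "|")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])

  nyq <- fs / 2
  design <- function(lo, hi)
    as.numeric(signal::fir1(n_taps - 1L, c(lo, hi) / nyq, type = "pass"))
  # calibrate each edge so |H| = 1/sqrt(2) at the requested frequency
  target <- 1 / sqrt(2)
  lo_d <- stats::uniroot(function(lo)
    fir_response(design(lo, high_hz), low_hz, fs) - target,
    interval = c(low_hz * 0.2, low_hz), tol = 1e-6)$root
  hi_d <- stats::uniroot(function(hi)
    fir_response(design(lo_d, hi), high_hz, fs) - target,
    interval = c(high_hz, min(high_hz * 1.3, nyq * 0.999)), tol = 1e-6)$root
  h <- design(lo_d, hi_d)
  .filter_cache[[key]] <- h
  h
}

#' Band-pass filter a recording
#'
#' Applies the 0.5-15 Hz linear-phase FIR band-pass to each axis with exact
#' group-delay compensation (the symmetric kernel is centred on each output
#' sample), so features downstream are not lag-shifted. Edge transients are
#' handled by reflection padding; output length equals input length.
#'
#' @param rec a [gyro_recording()].
#' @param low_hz,high_hz -3 dB cutoff frequencies (defaults 0.5 and 15 Hz).
#' @param n_taps filter length (default 4 s of samples + 1; see
#'   [design_bandpass()]).
#' @return the filtered [gyro_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 15, n_taps = NULL) {
  stopifnot(inherits(rec, "gyro_recording"))
  fs <- rec$sampling_rate_hz
  h <- design_bandpass(fs, low_hz, high_hz, n_taps)
  m <- (length(h) - 1L) / 2L
  n <- n_samples(rec)
  if (n <= m + 1L)
    stop(sprintf(paste0("recording too short for the filter transient: need ",
                        "more than %.2f s (%d samples), got %.2f s"),
                 (m + 1) / fs, m + 1L, n / fs))
  out <- apply(rec$axes, 2, function(v) {
    padded <- c(v[(m + 1L):2L], v, v[(n - 1L):(n - m)])
    filt <- stats::filter(padded, h, method = "convolution", sides = 2)
    as.numeric(filt[(m + 1L):(m + n)])
  })
  res <- rec
  res$axes <- out
  colnames(res$axes) <- c("X", "Y", "Z")
  attr(res, "filtered") <- TRUE
  res
}
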