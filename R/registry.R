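# Canonical feature registry. Order is part of the package contract: fitted
# models store the registry hash and refuse feature tables laid out otherwise.

.axes <- c("X", "Y", "Z")
.sensors <- c("wrist", "ankle")
.axis_pairs <- c("XY", "XZ", "YZ")

# 12 per-axis feature codes, in registry order.
.per_axis_features <- c(
  "power_4_6",      # 4-6 Hz band power, (deg/s)^2
  "power_0p5_15",   # 0.5-15 Hz band power, (deg/s)^2
  "pct_power_gt4",  # fraction of power above 4 Hz, [0, 1]
  "acf_n_peaks",    # number of autocorrelation peaks
  "acf_sum_peaks",  # sum of autocorrelation peak amplitudes
  "acf_first_amp",  # amplitude of first autocorrelation peak
  "acf_first_lag",  # lag of first autocorrelation peak (samples)
  "spec_entropy",   # normalized spectral entropy, [0, 1]
  "f1_hz",          # first dominant frequency (Hz)
  "f1_power",       # power at first dominant frequency
  "f2_hz",          # second dominant frequency (Hz)
  "f2_power"        # power at second dominant frequency
)

#' Canonical tremor feature registry
#'
#' Returns the ordered names of the 78 per-window features: for each sensor
#' (wrist, then ankle), the 12 per-axis features unrolled axis-minor
#' (X, Y, Z within each feature), followed by the three cross-axis
#' correlation features (XY, XZ, YZ). Fitted models and serialized feature
#' tables always use this order.
#'
#' @param sensors character vector, subset of `c("wrist", "ankle")`, in the
#'   order they should appear. Defaults to both.
#' @return character vector of feature names (78 for both sensors, 39 for one).
#' @examples
#' length(feature_registry())       # 78
#' feature_registry("wrist")[1:4]
#' @export
feature_registry <- function(sensors = c("wrist", "ankle")) {
  sensors <- match.arg(sensors, .sensors, several.ok = TRUE)
  unlist(lapply(sensors, function(s) {
    per_axis <- as.vector(vapply(.per_axis_features, function(f)
      paste(s, .axes, f, sep = "_"), character(3)))
    c(per_axis, paste(s, .axis_pairs, "xcorr", sep = "_"))
  }), use.names = FALSE)
}

# Feature columns a model of the given sensor scope consumes.
scope_features <- function(sensor_scope) {
  switch(sensor_scope,
    wrist_and_ankle = feature_registry(),
    wrist_only      = feature_registry("wrist"),
    ankle_only      = feature_registry("ankle"),
    stop("unknown sensor_scope: ", sensor_scope)
  )
}

# Sensor scope implied by a regression target: hand targets are estimated
# from the wrist sensor only, the foot target from the ankle only, and
# composite targets from both.
target_scope <- function(target) {
  switch(target,
    total          = "wrist_and_ankle",
    rest_hand_foot = "wrist_and_ankle",
    rest_hand      = "wrist_only",
    rest_foot      = "ankle_only",
    action         = "wrist_only",
    stop("unknown target: ", target)
  )
}

# Small stable polynomial hash of the registry, stored with persisted models
# so a model is never applied to a table with a different feature layout.
registry_hash <- function(names = feature_registry()) {
  h <- 0
  for (b in utf8ToInt(paste(names, collapse = "|")))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.onLoad <- function(libname, pkgname) {
  stopifnot(length(feature_registry()) == 78L,
            length(feature_registry("wrist")) == 39L)
}
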