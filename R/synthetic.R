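# Synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: subjects wearing
# wrist and ankle gyroscopes on the most-affected side during free body
# movements, recorded in labeled rounds. Each signal is the sum of
#  (a) voluntary-movement background: 0.5-3 Hz band-limited noise whose
#      envelope alternates between active bursts and rest intervals,
#  (b) resting tremor: an amplitude-modulated sinusoid in the 4-8 Hz band,
#      gated ON during rest intervals, amplitude proportional to the
#      resting subscore, concentrated on one wrist axis (hand tremor) and
#      spread evenly across ankle axes (foot tremor),
#  (c) action tremor: the same construction gated ON during movement with
#      the action subscore, on the wrist only (action items are hand items),
#  (d) white sensor noise.
# Subscore 0 means a zero-amplitude tremor component; amplitude is monotone
# (linear) in the subscore, so severity is recoverable in principle.

#' Per-subject tremor profile
#'
#' @param rest_hand,rest_foot,action tremor items of the most-affected
#'   limbs, integers 0-4.
#' @param tremor_freq_hz tremor frequency in Hz, within 4-8 (default 6.5:
#'   wrist tremor tends to sit above 6 Hz).
#' @param amp_per_point oscillation amplitude per subscore point, deg/s
#'   (default 10).
#' @param post_med_attenuation multiplicative tremor attenuation after
#'   medication, in (0, 1] (default 0.5).
#' @param dominant_wrist_axis wrist axis carrying the hand tremor
#'   (default "Y").
#' @param most_affected_side `"right"` or `"left"`.
#' @return a list of class `tremor_profile`.
#' @export
tremor_profile <- function(rest_hand = 0, rest_foot = 0, action = 0,
                           tremor_freq_hz = 6.5, amp_per_point = 10,
                           post_med_attenuation = 0.5,
                           dominant_wrist_axis = c("Y", "X", "Z"),
                           most_affected_side = c("right", "left")) {
  dominant_wrist_axis <- match.arg(dominant_wrist_axis)
  most_affected_side <- match.arg(most_affected_side)
  stopifnot(rest_hand %in% 0:4, rest_foot %in% 0:4, action %in% 0:4,
            tremor_freq_hz >= 4, tremor_freq_hz <= 8,
            post_med_attenuation > 0, post_med_attenuation <= 1)
  structure(list(rest_hand = as.integer(rest_hand),
                 rest_foot = as.integer(rest_foot),
                 action = as.integer(action),
                 tremor_freq_hz = tremor_freq_hz,
                 amp_per_point = amp_per_point,
                 post_med_attenuation = post_med_attenuation,
                 dominant_wrist_axis = dominant_wrist_axis,
                 most_affected_side = most_affected_side),
            class = "tremor_profile")
}

#' Synthetic cohort specification
#'
#' Fully determines a cohort given a seed. Defaults mirror the clinical
#' study design the package targets: 24 subjects, 15 recorded in discrete
#' rounds of daily-living activities (up to 5 min per round) and 9 recorded
#' continuously (up to 10 min per round), 2-4 rounds each, about a quarter
#' of subjects without tremor, and labels skewed toward low subscores.
#'
#' @param n_subjects number of subjects (default 24).
#' @param rounds_per_subject integer range rounds are drawn from
#'   (default `2:4`).
#' @param round_duration_s fixed round duration in seconds; `NULL` (default)
#'   draws 150-300 s for `adl_rounds` subjects and uses 600 s for
#'   `continuous` subjects.
#' @param sampling_rate_hz sampling rate (default 64).
#' @param fraction_continuous fraction of subjects on the continuous
#'   protocol (default 9/24).
#' @param fraction_non_tremor fraction of subjects with all-zero labels
#'   (default 0.25).
#' @param amp_per_point tremor amplitude per subscore point, deg/s
#'   (default 10).
#' @param background_amp standard deviation of the active-movement
#'   background, deg/s (default 25).
#' @param rest_floor background attenuation during rest intervals
#'   (default 0.15).
#' @param noise_sd white sensor-noise standard deviation, deg/s (default 1).
#' @param rest_mean_s,active_mean_s mean rest / active interval durations,
#'   seconds (defaults 20 and 40; both truncated to 5-60 s).
#' @param post_med_attenuation tremor attenuation after medication
#'   (default 0.5).
#' @param tremor_freq_range range subject tremor frequencies are drawn from
#'   (default `c(5.5, 7.5)`).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24L, rounds_per_subject = 2:4,
                        round_duration_s = NULL, sampling_rate_hz = 64,
                        fraction_continuous = 9 / 24,
                        fraction_non_tremor = 0.25,
                        amp_per_point = 10, background_amp = 25,
                        rest_floor = 0.15, noise_sd = 1,
                        rest_mean_s = 20, active_mean_s = 40,
                        post_med_attenuation = 0.5,
                        tremor_freq_range = c(5.5, 7.5)) {
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects")
  structure(list(n_subjects = as.integer(n_subjects),
                 rounds_per_subject = rounds_per_subject,
                 round_duration_s = round_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 fraction_continuous = fraction_continuous,
                 fraction_non_tremor = fraction_non_tremor,
                 amp_per_point = amp_per_point,
                 background_amp = background_amp,
                 rest_floor = rest_floor, noise_sd = noise_sd,
                 rest_mean_s = rest_mean_s, active_mean_s = active_mean_s,
                 post_med_attenuation = post_med_attenuation,
                 tremor_freq_range = tremor_freq_range),
            class = "cohort_spec")
}

#' The reference cohort layout
#'
#' Round counts and total recording durations, per subject, of the
#' 24-subject clinical cohort design this package emulates: subjects 1-15
#' on the discrete daily-living-rounds protocol (91 rounds in total across
#' the cohort, 58 of them in the first 15 subjects) and subjects 16-24
#' recorded continuously.
#'
#' @return data.frame with `subject_index`, `protocol`, `n_rounds`,
#'   `duration_min`.
#' @export
default_cohort_design <- function() {
  data.frame(
    subject_index = 1:24,
    protocol = rep(c("adl_rounds", "continuous"), c(15, 9)),
    n_rounds = c(4, 4, 4, 4, 4, 4, 3, 3, 4, 4, 4, 4, 4, 4, 4,
                 4, 4, 4, 3, 4, 4, 4, 2, 4),
    duration_min = c(12.20, 13.42, 14.38, 13.86, 14.95, 13.26, 10.33, 10.69,
                     14.30, 13.68, 15.62, 13.86, 14.28, 15.97, 10.61,
                     40.00, 37.92, 40.00, 26.60, 40.00, 40.00, 40.00, 20.00,
                     40.00))
}

# Smoothed 0/1 activity gate: alternating rest/active intervals with
# exponential durations truncated to [5, 60] s, 1-s raised-cosine ramps.
activity_gate <- function(n, fs, rest_mean_s, active_mean_s) {
  dur_draw <- function(mean_s) min(max(stats::rexp(1, 1 / mean_s), 5), 60)
  active <- stats::runif(1) < 0.5
  gate <- numeric(0)
  while (length(gate) < n) {
    d <- dur_draw(if (active) active_mean_s else rest_mean_s)
    gate <- c(gate, rep(as.numeric(active), round(d * fs)))
    active <- !active
  }
  gate <- gate[seq_len(n)]
  k <- as.integer(fs)  # 1-s Hann smoothing kernel
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  sm <- stats::filter(c(rep(gate[1], k), gate, rep(gate[n], k)),
                      w / sum(w), sides = 2)
  as.numeric(sm[(k + 1):(k + n)])
}

# Band-limited (0.5-3 Hz) unit-variance background noise.
background_noise <- function(n, fs) {
  h <- design_bandpass(fs, 0.5, 3, n_taps = round(4 * fs) + 1)
  m <- (length(h) - 1L) / 2L
  x <- stats::rnorm(n + 2L * m)
  v <- stats::filter(x, h, sides = 2)
  v <- as.numeric(v[(m + 1L):(m + n)])
  v / stats::sd(v)
}

# Amplitude-modulated tremor oscillation (unit peak amplitude).
tremor_wave <- function(t, freq_hz) {
  am <- 0.7 + 0.3 * cos(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
  am * sin(2 * pi * freq_hz * t + stats::runif(1, 0, 2 * pi))
}

#' Generate one synthetic labeled round
#'
#' Builds the wrist and ankle recordings for one round under the given
#' tremor profile. Post-medication rounds attenuate the tremor amplitude by
#' the profile's `post_med_attenuation`; the attached labels are the
#' attenuated severities rounded to the integer scale (emulating the
#' clinician's quantization). Deterministic given `seed`.
#'
#' @param profile a [tremor_profile()].
#' @param spec a [cohort_spec()] (noise/background/gating parameters).
#' @param med_state `"pre_medication"` or `"post_medication"`.
#' @param duration_s round duration in seconds (default 300).
#' @param subject_id,round_index identity attached to the round.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return an (unfiltered) [round_record()].
#' @export
generate_round <- function(profile, spec = cohort_spec(),
                           med_state = c("pre_medication", "post_medication"),
                           duration_s = 300, subject_id = "S01",
                           round_index = 1L, seed = NULL) {
  med_state <- match.arg(med_state)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  fs <- spec$sampling_rate_hz
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  att <- if (med_state == "post_medication") profile$post_med_attenuation else 1
  eff <- list(rest_hand = profile$rest_hand * att,
              rest_foot = profile$rest_foot * att,
              action = profile$action * att)
  lab <- lapply(eff, function(v) as.integer(floor(v + 0.5)))
  app <- profile$amp_per_point

  build_site <- function(site) {
    gate_act <- activity_gate(n, fs, spec$rest_mean_s, spec$active_mean_s)
    gate_rest <- 1 - gate_act
    env <- spec$rest_floor + (1 - spec$rest_floor) * gate_act
    axes <- matrix(0, n, 3)
    for (j in 1:3)
      axes[, j] <- spec$background_amp * env * background_noise(n, fs) +
        stats::rnorm(n, 0, spec$noise_sd)
    if (site == "wrist") {
      jdom <- match(profile$dominant_wrist_axis, c("X", "Y", "Z"))
      axes[, jdom] <- axes[, jdom] +
        app * eff$rest_hand * tremor_wave(t, profile$tremor_freq_hz) * gate_rest +
        app * eff$action * tremor_wave(t, profile$tremor_freq_hz) * gate_act
    } else {
      for (j in 1:3)
        axes[, j] <- axes[, j] + (app * eff$rest_foot / sqrt(3)) *
          tremor_wave(t, profile$tremor_freq_hz) * gate_rest
    }
    gyro_recording(axes[, 1], axes[, 2], axes[, 3], site = site,
                   sampling_rate_hz = fs)
  }

  side <- profile$most_affected_side
  labels <- tremor_labels(
    rest_hand_left = if (side == "left") lab$rest_hand else 0,
    rest_hand_right = if (side == "right") lab$rest_hand else 0,
    rest_leg_left = if (side == "left") lab$rest_foot else 0,
    rest_leg_right = if (side == "right") lab$rest_foot else 0,
    action_hand_left = if (side == "left") lab$action else 0,
    action_hand_right = if (side == "right") lab$action else 0,
    most_affected_side = side)
  round_record(subject_id, round_index, build_site("wrist"),
               build_site("ankle"), labels, med_state = med_state)
}

draw_profile <- function(spec, non_tremor) {
  if (non_tremor) {
    items <- c(0L, 0L, 0L)
  } else {
    items <- c(sample(0:4, 1, prob = c(0.15, 0.40, 0.25, 0.12, 0.08)),
               sample(0:4, 1, prob = c(0.45, 0.30, 0.15, 0.07, 0.03)),
               sample(0:4, 1, prob = c(0.35, 0.35, 0.18, 0.08, 0.04)))
  }
  tremor_profile(rest_hand = items[1], rest_foot = items[2], action = items[3],
                 tremor_freq_hz = stats::runif(1, spec$tremor_freq_range[1],
                                               spec$tremor_freq_range[2]),
                 amp_per_point = spec$amp_per_point,
                 post_med_attenuation = spec$post_med_attenuation,
                 most_affected_side = sample(c("right", "left"), 1))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject tremor profiles and rounds under `spec`, builds the
#' manifest, realizes the sensor signals, and (optionally) writes the
#' sensor CSV files and `manifest.json` to `dir`. The whole cohort is
#' reproducible from `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param dir output directory for CSV files and manifest; `NULL` (default)
#'   keeps the cohort in memory only.
#' @param design optional data.frame like [default_cohort_design()] fixing
#'   per-subject protocol, round count and total duration (overrides the
#'   corresponding draws in `spec`).
#' @param filter band-pass filter the returned in-memory rounds
#'   (default TRUE; files on disk always hold the raw signals).
#' @param realize build the signals (default TRUE); `FALSE` returns the
#'   manifest and round table only, which is sufficient for design-level
#'   analyses.
#' @return list with `manifest` (a `tremor_manifest`), `rounds` (list of
#'   [round_record()], `NULL` when `realize = FALSE`), `round_table`, and
#'   `dir`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L, dir = NULL,
                            design = NULL, filter = TRUE, realize = TRUE) {
  if (is.null(design) && spec$n_subjects < 2L)
    stop("a cohort needs at least 2 subjects")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ns <- if (!is.null(design)) nrow(design) else spec$n_subjects
  n_cont <- if (!is.null(design)) sum(design$protocol == "continuous")
            else round(spec$fraction_continuous * ns)
  subjects <- list()
  rounds <- list()
  # exactly round(fraction * n) subjects carry no tremor at all
  non_tremor_ids <- sample(ns, round(spec$fraction_non_tremor * ns))
  for (i in seq_len(ns)) {
    sid <- sprintf("S%02d", i)
    protocol <- if (!is.null(design)) design$protocol[i]
                else if (i > ns - n_cont) "continuous" else "adl_rounds"
    prof <- draw_profile(spec, i %in% non_tremor_ids)
    nr <- if (!is.null(design)) design$n_rounds[i]
          else if (length(spec$rounds_per_subject) == 1L) spec$rounds_per_subject
          else sample(spec$rounds_per_subject, 1)
    sex <- sample(c("female", "male"), 1)
    cap <- ROUND_CAP_S[[protocol]]
    rentries <- list()
    for (r in seq_len(nr)) {
      dur <- if (!is.null(design)) min(design$duration_min[i] * 60 / nr, cap)
             else if (!is.null(spec$round_duration_s)) spec$round_duration_s
             else if (protocol == "continuous") 600
             else stats::runif(1, 150, 300)
      dur <- round(dur)
      med <- if (r <= ceiling(nr / 2)) "pre_medication" else "post_medication"
      att <- if (med == "post_medication") prof$post_med_attenuation else 1
      li <- function(v) as.integer(floor(v * att + 0.5))
      side <- prof$most_affected_side
      rentries[[r]] <- list(
        round_index = r,
        wrist_file = sprintf("%s_%d_wrist.csv", sid, r),
        ankle_file = sprintf("%s_%d_ankle.csv", sid, r),
        duration_s = dur, med_state = med,
        assessment_time_s = -60,
        medication_time_s = if (nr > 1) 0 else NA,
        labels = list(rest_head = 0L,
                      rest_hand_left = if (side == "left") li(prof$rest_hand) else 0L,
                      rest_hand_right = if (side == "right") li(prof$rest_hand) else 0L,
                      rest_leg_left = if (side == "left") li(prof$rest_foot) else 0L,
                      rest_leg_right = if (side == "right") li(prof$rest_foot) else 0L,
                      action_hand_left = if (side == "left") li(prof$action) else 0L,
                      action_hand_right = if (side == "right") li(prof$action) else 0L))
      if (realize) {
        rec <- generate_round(prof, spec, med, duration_s = dur,
                              subject_id = sid, round_index = r)
        rounds[[length(rounds) + 1L]] <- rec
      }
    }
    subjects[[i]] <- list(subject_id = sid, protocol = protocol, sex = sex,
                          most_affected_side = prof$most_affected_side,
                          profile = list(rest_hand = prof$rest_hand,
                                         rest_foot = prof$rest_foot,
                                         action = prof$action,
                                         tremor_freq_hz = prof$tremor_freq_hz),
                          rounds = rentries)
  }
  manifest <- structure(list(sampling_rate_hz = spec$sampling_rate_hz,
                             subjects = subjects),
                        class = "tremor_manifest")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (realize) {
      for (rec in rounds) {
        write_recording(rec$wrist, file.path(dir, sprintf("%s_%d_wrist.csv",
                                                          rec$subject_id,
                                                          rec$round_index)))
        write_recording(rec$ankle, file.path(dir, sprintf("%s_%d_ankle.csv",
                                                          rec$subject_id,
                                                          rec$round_index)))
      }
    }
    write_manifest(manifest, file.path(dir, "manifest.json"))
    attr(manifest, "dir") <- dir
  }
  if (realize && filter)
    rounds <- lapply(rounds, function(rr) {
      rr$wrist <- bandpass_filter(rr$wrist)
      rr$ankle <- bandpass_filter(rr$ankle)
      rr
    })
  list(manifest = manifest,
       rounds = if (realize) rounds else NULL,
       round_table = round_table(manifest),
       dir = dir)
}

#' Small cohort preset
#'
#' 6 subjects, 2 rounds each, 60 s per round — the quick-test configuration.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
cohort_spec_small <- function(...) {
  args <- list(n_subjects = 6L, rounds_per_subject = 2L,
               round_duration_s = 60)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}
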