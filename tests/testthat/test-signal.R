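test_that("gyro_recording validates its invariants", {
  expect_s3_class(gyro_recording(1:10, 1:10, 1:10, "wrist"), "gyro_recording")
  expect_error(gyro_recording(1:10, 1:9, 1:10, "wrist"), "identical length")
  expect_error(gyro_recording(numeric(0), numeric(0), numeric(0), "wrist"),
               "at least one sample")
  expect_error(gyro_recording(c(1, NA), c(1, 2), c(1, 2), "wrist"),
               "non-finite")
  expect_error(gyro_recording(1:10, 1:10, 1:10, "wrist",
                              sampling_rate_hz = 20), "Nyquist")
})

test_that("sensor CSV files round-trip bit-identically", {
  rec <- one_round()$wrist
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- load_recording(path, "wrist")
  expect_identical(back$axes, rec$axes)

  # length/duration arithmetic for a plain 3-column file
  small <- gyro_recording(rnorm(320), rnorm(320), rnorm(320), "ankle")
  write_recording(small, path)
  got <- load_recording(path, "ankle")
  expect_equal(nrow(got$axes), 320L)
  expect_equal(nrow(got$axes) / got$sampling_rate_hz, 5)
})

test_that("loader rejects malformed files and repairs small gaps on request", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,gyro_x,gyro_y", "0,1,2"), path)
  expect_error(load_recording(path, "wrist"), "missing required column")
  writeLines("time_s,gyro_x,gyro_y,gyro_z", path)
  expect_error(load_recording(path, "wrist"), "no samples")
  writeLines(c("time_s,gyro_x,gyro_y,gyro_z",
               "0,1,2,3", "0.015625,NA,2,3", "0.03125,1,2,3"), path)
  expect_error(load_recording(path, "wrist"), "non-finite")
  fixed <- load_recording(path, "wrist", na_policy = "interpolate")
  expect_equal(unname(fixed$axes[2, 1]), 1)  # linear interpolation of the gap
  # accelerometer columns are parsed and discarded with a notice
  writeLines(c("time_s,gyro_x,gyro_y,gyro_z,acc_x",
               "0,1,2,3,9.8", "0.02,1,2,3,9.8"), path)
  expect_message(load_recording(path, "wrist"), "acc_x")
})

test_that("band-pass filter realizes its -3 dB design points", {
  h <- design_bandpass(64)
  resp <- tremorsense:::fir_response(h, c(0.5, 15), 64)
  expect_equal(resp, rep(1 / sqrt(2), 2), tolerance = 1e-3)
})

test_that("filter passes the tremor band and rejects DC and high frequency", {
  fs <- 64
  t <- (0:999) / fs
  dc <- gyro_recording(rep(3, 1000), sin(2 * pi * 5 * t),
                       sin(2 * pi * 25 * t), "wrist")
  out <- bandpass_filter(dc)
  expect_lt(max(abs(out$axes[, 1])), 0.01 * 3)              # DC killed
  expect_equal(sd(out$axes[, 2]) / sd(dc$axes[, 2]), 1,
               tolerance = 0.05)                             # 5 Hz preserved
  expect_lt(sd(out$axes[, 3]) / sd(dc$axes[, 3]), 0.10)     # 25 Hz rejected
})

test_that("filtering is idempotent in the pass band", {
  t <- (0:999) / 64
  rec <- gyro_recording(sin(2 * pi * 5 * t), sin(2 * pi * 5 * t),
                        sin(2 * pi * 5 * t), "wrist")
  once <- bandpass_filter(rec)
  twice <- bandpass_filter(once)
  expect_equal(sd(twice$axes[, 1]) / sd(once$axes[, 1]), 1, tolerance = 0.05)
})

test_that("filtered broadband output is confined to the pass band", {
  set.seed(1)
  n <- 40 * 64  # 40 s
  rec <- gyro_recording(rnorm(n), rnorm(n), rnorm(n), "wrist")
  out <- bandpass_filter(rec)
  sp <- tremorsense:::psd_estimate(out$axes[, 1], 64, pad = 1L)
  tot <- sum(sp$p)
  expect_lt(sum(sp$p[sp$f < 0.25]) / tot, 0.01)
  expect_lt(sum(sp$p[sp$f > 20]) / tot, 0.01)
})

test_that("filter refuses signals shorter than its transient", {
  rec <- gyro_recording(rnorm(100), rnorm(100), rnorm(100), "wrist")
  expect_error(bandpass_filter(rec), "too short")
})

test_that("assemble_rounds loads, caps and labels rounds deterministically", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_subjects = 2, rounds_per_subject = 2L,
                      round_duration_s = 40, fraction_continuous = 0)
  generate_cohort(spec, seed = 5, dir = dir, filter = FALSE)
  m <- read_manifest(file.path(dir, "manifest.json"))
  r1 <- assemble_rounds(m, filter = FALSE)
  r2 <- assemble_rounds(m, filter = FALSE)
  expect_length(r1, 4L)
  expect_identical(r1[[1]]$wrist$axes, r2[[1]]$wrist$axes)
  expect_identical(vapply(r1, function(r) r$subject_id, character(1)),
                   c("S01", "S01", "S02", "S02"))
})

test_that("rounds longer than the protocol cap are truncated", {
  dir <- withr::local_tempdir()
  prof <- tremor_profile(rest_hand = 1)
  spec <- cohort_spec()
  rec <- generate_round(prof, spec, duration_s = 700, seed = 8)
  write_recording(rec$wrist, file.path(dir, "S01_1_wrist.csv"))
  write_recording(rec$ankle, file.path(dir, "S01_1_ankle.csv"))
  m <- structure(list(sampling_rate_hz = 64, subjects = list(list(
    subject_id = "S01", protocol = "continuous", most_affected_side = "right",
    rounds = list(list(round_index = 1, wrist_file = "S01_1_wrist.csv",
                       ankle_file = "S01_1_ankle.csv", duration_s = 700,
                       med_state = "unknown",
                       labels = list(rest_hand_right = 1)))))),
    class = "tremor_manifest")
  attr(m, "dir") <- dir
  out <- assemble_rounds(m, filter = FALSE)
  expect_equal(out[[1]]$duration_s, 600)
})

test_that("an empty manifest assembles to an empty round list", {
  m <- structure(list(sampling_rate_hz = 64, subjects = list()),
                 class = "tremor_manifest")
  expect_identical(assemble_rounds(m, dir = tempdir()), list())
})

test_that("samples inside flagged assessment intervals are dropped", {
  dir <- withr::local_tempdir()
  rec <- generate_round(tremor_profile(), cohort_spec(), duration_s = 100,
                        seed = 2)
  write_recording(rec$wrist, file.path(dir, "S01_1_wrist.csv"))
  write_recording(rec$ankle, file.path(dir, "S01_1_ankle.csv"))
  m <- structure(list(sampling_rate_hz = 64, subjects = list(list(
    subject_id = "S01", protocol = "adl_rounds", most_affected_side = "right",
    rounds = list(list(round_index = 1, wrist_file = "S01_1_wrist.csv",
                       ankle_file = "S01_1_ankle.csv", duration_s = 100,
                       med_state = "unknown",
                       excluded_intervals = list(c(10, 30)),
                       labels = list()))))),
    class = "tremor_manifest")
  attr(m, "dir") <- dir
  out <- assemble_rounds(m, filter = FALSE)
  expect_equal(out[[1]]$duration_s, 80)
})
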