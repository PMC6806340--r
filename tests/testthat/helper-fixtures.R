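# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A small filtered cohort with window features: 6 subjects x 2 rounds x 60 s.
small_cohort <- function() {
  fixture("small_cohort", function() {
    coh <- generate_cohort(cohort_spec_small(), seed = 3)
    list(coh = coh, windows = extract_cohort_features(coh$rounds))
  })
}

# One filtered synthetic round with moderate tremor.
one_round <- function() {
  fixture("one_round", function() {
    prof <- tremor_profile(rest_hand = 3, rest_foot = 2, action = 1)
    r <- generate_round(prof, cohort_spec(), duration_s = 60, seed = 42)
    r$wrist <- bandpass_filter(r$wrist)
    r$ankle <- bandpass_filter(r$ankle)
    r
  })
}

sine_window <- function(freq = 5, n = 320, fs = 64, amp = 1) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs)
}

# Round-table row constructor for hand-built datasets.
round_row <- function(subject_id, round_index, rest_hand = 0, rest_foot = 0,
                      action = 0, side = "right", protocol = "adl_rounds",
                      med_state = "unknown", sex = "female") {
  data.frame(subject_id = subject_id, round_index = round_index,
             protocol = protocol, sex = sex, most_affected_side = side,
             med_state = med_state, duration_s = NA_real_,
             rest_head = 0L,
             rest_hand_left = if (side == "left") rest_hand else 0L,
             rest_hand_right = if (side == "right") rest_hand else 0L,
             rest_leg_left = if (side == "left") rest_foot else 0L,
             rest_leg_right = if (side == "right") rest_foot else 0L,
             action_hand_left = if (side == "left") action else 0L,
             action_hand_right = if (side == "right") action else 0L,
             stringsAsFactors = FALSE)
}
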