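# tremorsense

Task-independent estimation of Parkinsonian tremor severity from two
wrist- and ankle-worn triaxial gyroscopes recorded during free body
movements.

Parkinsonian tremor is scored in the clinic on the UPDRS-III motor exam:
five resting-tremor items and two action-tremor items, each 0–4, summing to
a total tremor subscore of 0–28. The exam is episodic; tremor is not.
`tremorsense` estimates the subscores continuously from gyroscope
recordings of ordinary daily activities, without recognizing or scripting
any task. The unit of prediction is a *round* — a contiguous recording bout
labeled by the nearest clinical assessment.

The pipeline:

1. **Preprocess** — band-pass each round to 0.5–15 Hz with a zero-phase
   linear-phase FIR filter (−3 dB points calibrated to the cutoffs).
2. **Features** — cut into 5-s windows; per window compute 78 features in
   a fixed registry order: per axis (6 signals × 12) the 4–6 Hz and
   0.5–15 Hz band powers, fraction of power above 4 Hz, autocorrelation
   peak statistics (count, sum, first amplitude, first lag), normalized
   spectral entropy and the two dominant spectral peaks, plus 3 cross-axis
   correlations per sensor.
3. **Models** — two regression back-ends behind one interface
   (`tremor_fit()`):
   * *gradient tree boosting*: per-window examples inherit the round's
     label, `y_hat_t = sum_i f_i(fv_t)` over an ensemble of regression
     trees; the round estimate is the mean of its window estimates;
   * *many-to-one LSTM*: a trainable linear input transform, a 3-layer
     LSTM recurrence over the round's window sequence, and an affine
     readout of the final hidden state (compiled BPTT + Adam training
     with dropout, sequence tiling and random-start augmentation).
4. **Evaluation** — subject-disjoint held-out and leave-one-subject-out
   protocols with seeded hyperparameter search; round-level Pearson r and
   MAE; gain-based feature importance; medication-response and stratified
   analyses; rest-interval-removal experiment.
5. **Synthetic cohorts** — a generator that plants 4–8 Hz tremor
   oscillations (amplitude linear in the assigned subscore, gated on
   rest/activity) on top of band-limited voluntary-movement background, so
   the whole pipeline is testable without clinical data.

Targets: `total` (0–28), `rest_hand_foot` (0–8), `rest_hand`, `rest_foot`,
`action` (each 0–4). Hand targets use wrist features only, the foot target
ankle features only, composite targets both.

## Worked example

```r
library(tremorsense)

# simulate a small labeled cohort: 6 subjects, 2 rounds of 60 s each
cohort  <- generate_cohort(cohort_spec_small(), seed = 42)
windows <- extract_cohort_features(cohort$rounds)
dim(windows)
#> [1] 144  81    # 144 five-second windows, 3 key columns + 78 features

# leave-one-subject-out evaluation of the boosting estimator
eval <- run_loso(windows, cohort$round_table, target = "total",
                 method = "boosting", seed = 42)
eval
#> <tremor_eval> protocol=loso  method=boosting  target=total
#>   12 rounds: r = 0.688 (p = 0.0134), MAE = 0.882

fit <- tremor_fit(windows, cohort$round_table, target = "total")
summary(fit)
#> <tremor_model> method=boosting  target=total  scope=wrist_and_ankle
#>   trained on 12 rounds (144 windows), 78 features, standardized
#>   features with gain > 0.5%:
#>     wrist_Y_pct_power_gt4         15.13%
#>     wrist_Y_acf_n_peaks            9.71%
#>     wrist_Y_f1_hz                  5.49%
#>     ...
```

The pooled LOSO correlation of 0.69 on this deliberately tiny cohort rises
above 0.85 at the default 24-subject scale (see below). The importance list
shows the estimator looking where the generator planted the signal: hand
tremor is concentrated on the wrist Y axis, and high-frequency power
fractions and autocorrelation periodicity are its signatures.

A command-line wrapper is included (`inst/cli/tremorsense`):

```sh
Rscript inst/cli/tremorsense simulate --out cohort/ --small --seed 7
Rscript inst/cli/tremorsense extract  --data cohort/ --out features.csv
Rscript inst/cli/tremorsense evaluate --data cohort/ --features features.csv \
        --protocol loso --out report.json
```

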