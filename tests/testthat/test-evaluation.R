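test_that("pearson_r matches the hand-expanded covariance formula", {
  y <- c(0, 1, 2, 3); p <- c(0, 1, 2, 4)
  # oracle: direct two-pass formula + t-distribution p-value
  r_hand <- sum((y - mean(y)) * (p - mean(p))) /
    sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
  tt <- r_hand * sqrt(2 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(tt), df = 2)
  got <- pearson_r(y, p)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
  expect_equal(pearson_r(y, y)$r, 1)
  expect_equal(pearson_r(y, -y)$r, -1)
  expect_error(pearson_r(rep(1, 4), y), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_r equals a textbook implementation on random vectors", {
  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(10); b <- rnorm(10)
    r2 <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_r(a, b)$r, r2, tolerance = 1e-12)
  }
})

test_that("mae is the symmetric mean absolute difference", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 2), c(1, 3)), 1)
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(mae(a, b), mae(b, a))
  perm <- sample(10)
  expect_equal(mae(a[perm], b[perm]), mae(a, b))
})

test_that("LOSO runs one subject-disjoint fold per subject", {
  sc <- small_cohort()
  ev <- run_loso(sc$windows, sc$coh$round_table, target = "total",
                 method = "boosting", grid = boosting_config(n_trees = 20),
                 seed = 2)
  folds <- attr(ev, "folds")
  expect_length(folds, 6L)
  # pooled predictions partition the rounds
  rec <- ev$records
  expect_equal(nrow(rec), nrow(sc$coh$round_table))
  expect_equal(sort(paste(rec$subject_id, rec$round_index)),
               sort(paste(sc$coh$round_table$subject_id,
                          sc$coh$round_table$round_index)))
  # each fold's test subject is unique
  test_subj <- vapply(folds, function(f) unique(f$records$subject_id),
                      character(1))
  expect_length(unique(test_subj), 6L)
})

test_that("the 80/20 validation split is subject-stratified and disjoint", {
  rt <- do.call(rbind, lapply(1:5, function(s)
    do.call(rbind, lapply(1:4, function(r)
      round_row(sprintf("V%02d", s), r)))))
  sp <- tremorsense:::val_split(rt, frac = 0.2, seed = 9)
  expect_equal(nrow(sp$val), 5L)  # one of four rounds per subject
  expect_equal(nrow(sp$train) + nrow(sp$val), 20L)
  expect_equal(sort(unique(sp$val$subject_id)), sprintf("V%02d", 1:5))
  k1 <- paste(sp$train$subject_id, sp$train$round_index)
  k2 <- paste(sp$val$subject_id, sp$val$round_index)
  expect_length(intersect(k1, k2), 0L)
  # reproducible
  sp2 <- tremorsense:::val_split(rt, frac = 0.2, seed = 9)
  expect_identical(sp$val$round_index, sp2$val$round_index)
})

test_that("a one-point grid is selected without search", {
  sc <- small_cohort()
  cfg <- boosting_config(n_trees = 15, max_depth = 3)
  ev <- run_held_out(sc$windows, sc$coh$round_table, target = "total",
                     grid = cfg, seed = 1)
  expect_equal(ev$winner$n_trees, 15L)
  expect_equal(ev$winner$max_depth, 3L)
})

test_that("held-out protocol trains on adl subjects and tests the rest", {
  sc <- small_cohort()
  rt <- sc$coh$round_table
  ev <- run_held_out(sc$windows, rt, target = "total",
                     grid = boosting_config(n_trees = 20), seed = 1)
  test_ids <- unique(ev$records$subject_id)
  cont_ids <- unique(rt$subject_id[rt$protocol == "continuous"])
  expect_setequal(test_ids, cont_ids)
})

test_that("grid search winners are reproducible under a fixed seed", {
  sc <- small_cohort()
  grid <- data.frame(n_trees = c(10L, 40L), max_depth = 3L,
                     feature_subsample_fraction = 0.3)
  e1 <- run_loso(sc$windows, sc$coh$round_table, target = "total",
                 grid = grid, seed = 5)
  e2 <- run_loso(sc$windows, sc$coh$round_table, target = "total",
                 grid = grid, seed = 5)
  w1 <- vapply(attr(e1, "folds"), function(f) f$winner$n_trees, integer(1))
  w2 <- vapply(attr(e2, "folds"), function(f) f$winner$n_trees, integer(1))
  expect_identical(w1, w2)
  expect_identical(e1$records$y_pred, e2$records$y_pred)
})

test_that("rest-interval removal deletes long quiescent blocks only", {
  spec <- cohort_spec()
  prof <- tremor_profile(rest_hand = 1)
  base <- generate_round(prof, spec, duration_s = 60, seed = 33)
  fs <- 64
  plant <- function(r, at_s, len_s) {
    idx <- (at_s * fs + 1):((at_s + len_s) * fs)
    r$wrist$axes[idx, ] <- r$wrist$axes[idx, ] * 0.001
    r$ankle$axes[idx, ] <- r$ankle$axes[idx, ] * 0.001
    r
  }
  # active round, no sub-threshold samples: unchanged
  loud <- base
  loud$wrist$axes <- loud$wrist$axes + 50
  loud$ankle$axes <- loud$ankle$axes + 50
  out <- remove_rest_intervals(loud)
  expect_equal(out$duration_s, loud$duration_s)

  with20 <- plant(loud, 20, 20)
  out20 <- remove_rest_intervals(with20)
  expect_lt(abs((with20$duration_s - out20$duration_s) - 20), 2.5)

  with10 <- plant(loud, 20, 10)
  out10 <- remove_rest_intervals(with10)
  expect_equal(out10$duration_s, with10$duration_s)
})

test_that("medication response detects a planted post-medication reduction", {
  set.seed(17)
  subs <- sprintf("M%02d", 1:10)
  rt <- do.call(rbind, lapply(seq_along(subs), function(i)
    rbind(round_row(subs[i], 1, rest_hand = 2, med_state = "pre_medication"),
          round_row(subs[i], 2, rest_hand = 1, med_state = "post_medication"))))
  pred <- data.frame(subject_id = rep(subs, each = 2), round_index = c(1, 2),
                     y_pred = rep(c(2, 1), 10) + rnorm(20, sd = 0.05))
  mr <- medication_response(pred, rt)
  expect_lt(mr$overall$p, 0.05)
  expect_gt(mr$overall$mean_reduction, 0.5)

  # identical pre/post estimates: no significant reduction
  pred0 <- pred; pred0$y_pred <- rep(1.5, 20)
  mr0 <- medication_response(pred0, rt)
  expect_gte(mr0$overall$p, 0.5)

  expect_error(medication_response(pred[1:2, ], rt[1:2, ]),
               "at least 2 subjects")
})

test_that("stratified metrics collapse to pooled metrics for one stratum", {
  sc <- small_cohort()
  ev <- run_loso(sc$windows, sc$coh$round_table, target = "total",
                 grid = boosting_config(n_trees = 20), seed = 2)
  rt <- sc$coh$round_table
  rt$sex <- "female"
  st <- stratified_report(ev, rt, by = "gender")
  expect_equal(nrow(st), 1L)
  expect_equal(st$r, ev$pearson_r, tolerance = 1e-12)
  expect_equal(st$mae, ev$mae, tolerance = 1e-12)
  st2 <- stratified_report(ev, sc$coh$round_table, by = "tremor_dominance")
  expect_true(all(st2$stratum %in% c("tremor_dominant",
                                     "non_tremor_dominant")))
})
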