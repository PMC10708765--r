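test_that("evaluation matches an independent per-class oracle on random confusion matrices", {
  # oracle: rebuild prediction/label vectors and compute per-class metrics
  # from first principles
  oracle <- function(tp, fn, tn, fp) {
    truth <- c(rep(1, tp + fn), rep(0, tn + fp))
    pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
    per_class <- function(cls) {
      p <- if (sum(pred == cls) == 0) 0 else mean(truth[pred == cls] == cls)
      r <- if (sum(truth == cls) == 0) 0 else mean(pred[truth == cls] == cls)
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      c(p = p, r = r, f = f, support = sum(truth == cls))
    }
    pos <- per_class(1); neg <- per_class(0)
    w <- c(pos[["support"]], neg[["support"]]) / length(truth)
    c(accuracy = mean(pred == truth),
      macro_precision = (pos[["p"]] + neg[["p"]]) / 2,
      macro_recall = (pos[["r"]] + neg[["r"]]) / 2,
      macro_f1 = (pos[["f"]] + neg[["f"]]) / 2,
      weighted_precision = sum(w * c(pos[["p"]], neg[["p"]])),
      weighted_recall = sum(w * c(pos[["r"]], neg[["r"]])),
      weighted_f1 = sum(w * c(pos[["f"]], neg[["f"]]))) * 100
  }
  withr::local_seed(11)
  for (k in 1:1000) {
    cnt <- rmultinom(1, sample(4:60, 1), prob = runif(4, 0.05, 1))
    tp <- cnt[1]; fn <- cnt[2]; tn <- cnt[3]; fp <- cnt[4]
    rep_ <- suppressWarnings(metrics_from_counts(tp, fn, tn, fp))
    expect_equal(rep_$metrics, suppressWarnings(oracle(tp, fn, tn, fp)),
                 tolerance = 1e-9)
    # binary identity: support-weighted recall is accuracy
    expect_equal(rep_$metrics[["weighted_recall"]], rep_$metrics[["accuracy"]],
                 tolerance = 1e-12)
  }
})

test_that("evaluate_predictions counts the confusion cells and guards input", {
  pred <- c(1, 1, 0, 0, 1, 0)
  truth <- c(1, 0, 1, 0, 1, 0)
  r <- evaluate_predictions(pred, truth)
  expect_equal(unname(r$counts), c(2L, 1L, 2L, 1L)) # TP FN TN FP
  all_right <- evaluate_predictions(truth, truth)
  expect_true(all(all_right$metrics == 100))
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "empty")
  expect_error(evaluate_predictions(c(1, 0), c(1, 0, 1)), "length")
  expect_warning(metrics_from_counts(0, 5, 10, 0), "precision defined as 0")
})

test_that("rendered metric tables round-trip at 2-decimal precision", {
  r <- metrics_from_counts(10, 3, 34, 1)
  csv <- format_metric_table(r, format = "csv")
  parsed <- read.csv(text = csv)
  expect_equal(parsed$acc, round(r$metrics[["accuracy"]], 2))
  expect_equal(parsed$weighted_f1, round(r$metrics[["weighted_f1"]], 2))
  md <- format_metric_table(r, format = "markdown")
  expect_match(md, "\\| 91.67 \\|")
  tab <- format_metric_table(list(r, r), labels = c("a", "b"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$model, c("a", "b"))
})

test_that("training learns a separable synthetic cohort (with glm oracle)", {
  # between-participant effects off: the generator then guarantees the
  # classes are (near-)linearly separable in per-feature means
  sep_spec <- signature_spec(yaw_turn_rate = 18, gaze_wander_sd = 0.2,
                             eye_movement_speed_scale = 0.5,
                             au_up = c(AU26 = 2.5),
                             between_sd = c(au = 0, yaw = 0, gaze = 0),
                             duration_s = 10)
  co <- generate_cohort(c(normal = 10, mild = 10, moderate = 10, severe = 10),
                        sep_spec, seed = 101)
  samp <- cohort_to_samples(co)
  sp <- prepare_splits(samp, alpha = 0.1, seed = 1)

  # independent oracle: logistic regression on per-feature temporal means
  # separates the cohort almost perfectly
  feat <- t(vapply(samp, function(s) colMeans(s$series$values), numeric(40)))
  y <- vapply(samp, function(s) s$y, integer(1))
  keep <- c("pose_Ry", "AU26_r", "gaze_angle_x")
  df <- data.frame(feat[, keep], y = y)
  fitg <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  acc_oracle <- mean((fitted(fitg) >= 0.5) == y)
  expect_gte(acc_oracle, 0.95)

  mdl <- build_model(model_config("intermediate", "window_block_lstm",
                                  horizon = 300L), seed = 7)
  mdl <- fit_model(mdl, sp$train, sp$validation,
                   training_recipe(epochs = 6, patience = 3), seed = 7)
  expect_lte(nrow(mdl$history), 6L)
  expect_gte(max(mdl$history$val_acc), 0.9)
  te_y <- vapply(sp$test, function(s) s$y, integer(1))
  rep_ <- evaluate_predictions(predict(mdl, sp$test), te_y)
  expect_gte(rep_$metrics[["accuracy"]], 75) # 4-sample test split, one miss allowed
})

test_that("a zero-signal cohort trains to chance-level accuracy", {
  null_spec <- signature_spec(yaw_turn_rate = 0, gaze_wander_sd = 0,
                              eye_movement_speed_scale = 1,
                              au_up = c(AU26 = 0), au_down = c(AU12 = 0),
                              duration_s = 5)
  co <- generate_cohort(c(normal = 8, mild = 8, moderate = 8, severe = 8),
                        null_spec, seed = 55)
  samp <- cohort_to_samples(co)
  sp <- prepare_splits(samp, alpha = 0, seed = 2)
  mdl <- build_model(model_config("intermediate", "window_block_lstm",
                                  horizon = 150L,
                                  group_hidden = c(Pose = 8, Gaze = 8,
                                                   AU_r = 16, AU_c = 16)),
                     seed = 3)
  mdl <- fit_model(mdl, sp$train, sp$validation,
                   training_recipe(epochs = 3, patience = 3), seed = 3)
  pr <- predict(mdl, samp)
  correct <- sum(pr$decision == vapply(samp, function(s) s$y, integer(1)))
  # majority rate is 0.5 (16/16); accuracy must not beat chance significantly
  expect_gt(binom.test(correct, length(samp), 0.5,
                       alternative = "greater")$p.value, 0.01)
})

test_that("training is deterministic under a fixed seed", {
  co <- generate_cohort(c(normal = 4, severe = 4),
                        signature_spec(duration_s = 5), seed = 77)
  samp <- cohort_to_samples(co)
  man <- stratified_split(samp, seed = 1)
  tr <- set_label_smoothing(split_samples(samp, man, "train"), 0.1)
  va <- set_label_smoothing(split_samples(samp, man, "validation"), 0.1)
  cfg <- model_config("early", "window_block_lstm", horizon = 150L,
                      group_hidden = c(all = 8))
  run <- function() {
    fit_model(build_model(cfg, seed = 5), tr, va,
              training_recipe(epochs = 2, patience = 2), seed = 5)$history
  }
  expect_identical(run(), run())
})

test_that("label-smoothing sweep emits one row per alpha, identity at 0", {
  co <- generate_cohort(c(normal = 6, mild = 3, moderate = 3, severe = 6),
                        recovery_spec(duration_s = 5), seed = 31)
  samp <- cohort_to_samples(co)
  man <- stratified_split(samp, seed = 4)
  tr <- balance_by_duplication(split_samples(samp, man, "train"))
  va <- split_samples(samp, man, "validation")
  te <- split_samples(samp, man, "test")
  cfg <- model_config("intermediate", "window_block_lstm", horizon = 150L,
                      group_hidden = c(Pose = 8, Gaze = 8, AU_r = 8, AU_c = 8),
                      head_widths = c(16, 1))
  rec <- training_recipe(epochs = 2, patience = 2)
  # tiny models can predict a single class; the zero-precision warning is
  # by-design behavior asserted elsewhere
  sw <- suppressWarnings(
    sweep_label_smoothing(cfg, tr, va, te, alpha_grid = c(0, 0.1, 0.3),
                          recipe = rec, seed = 9))
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$soft_pos, c(1, 0.95, 0.85))
  expect_length(attr(sw, "reports"), 3L)

  # the alpha = 0 row equals a direct unsmoothed run under the same seed
  mdl <- fit_model(build_model(cfg, seed = 9), set_label_smoothing(tr, 0),
                   set_label_smoothing(va, 0), rec, seed = 9)
  direct <- suppressWarnings(
    evaluate_predictions(predict(mdl, te),
                         vapply(te, function(s) s$y, integer(1))))
  expect_identical(attr(sw, "reports")[[1]]$counts, direct$counts)
  expect_equal(attr(sw, "reports")[[1]]$metrics, direct$metrics)
})
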