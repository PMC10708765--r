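# Shared fixture builders. Everything is generated in code at test time.

# A minimal valid cohort sample carrying only labels (1-frame series), for
# split/balancing arithmetic where the feature values are irrelevant.
label_only_sample <- function(severity, id) {
  cohort_sample(feature_series(matrix(0, 1, 40),
                               participant_id = sprintf("P%04d", id)),
                severity)
}

# A full cohort with the reference severity composition, labels only.
table2_cohort <- function() {
  sev <- rep(severity_levels(), c(106, 234, 112, 22))
  Map(label_only_sample, sev, seq_along(sev))
}

# Write a small OpenFace-dialect CSV fixture; returns the path.
# `drop` removes columns, `extra` appends unrecognized ones.
write_openface_fixture <- function(n = 10, drop = character(0), extra = character(0),
                                   dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tab <- as.data.frame(generate_participant("normal",
                                            signature_spec(duration_s = n / 30),
                                            seed = 99))
  for (e in extra) tab[[e]] <- runif(nrow(tab))
  tab <- tab[, setdiff(names(tab), drop)]
  path <- file.path(dir, paste0("fixture_", paste0(sample(letters, 6), collapse = ""), ".csv"))
  utils::write.csv(tab, path, row.names = FALSE)
  path
}

# Standard preprocessing pipeline: split, normalize on train stats, balance
# and smooth. Returns the three ready splits.
prepare_splits <- function(samples, alpha = 0.1, seed = 42L) {
  man <- stratified_split(samples, seed = seed)
  sp <- lapply(c(train = "train", validation = "validation", test = "test"),
               function(k) split_samples(samples, man, k))
  scaler <- fit_feature_scaler(lapply(sp$train, function(s) s$series))
  sp <- lapply(sp, function(ss) {
    out <- lapply(ss, function(s) {
      s$series <- apply_feature_scaler(s$series, scaler)
      s
    })
    attributes(out) <- attributes(ss)
    out
  })
  sp$train <- set_label_smoothing(balance_by_duplication(sp$train), alpha)
  sp$validation <- set_label_smoothing(sp$validation, alpha)
  sp
}

# A linear scorer F(x) = sum_{t,f} w_f * x[t,f] built on the autodiff tape:
# constant gradient, so integrated gradients are exact at any step count.
linear_forward <- function(w) {
  function(X, input_grad = FALSE) {
    d <- dim(X)
    tape <- facedep:::ag_tape()
    xin <- facedep:::ag_leaf(tape, X, requires = input_grad)
    wn <- facedep:::ag_leaf(tape, matrix(w, ncol = 1))
    ones <- facedep:::ag_leaf(tape, matrix(1, 1, d[3]))
    rows <- lapply(seq_len(d[1]), function(b) {
      xb <- facedep:::ag_slice_sample(xin, b) # (T, F)
      facedep:::ag_matmul(ones, facedep:::ag_matmul(xb, wn)) # (1,1)
    })
    list(tape = tape, prob = facedep:::ag_stack_rows(rows), xin = xin)
  }
}

# High-signal cohort where yaw and AU26 are the planted features. The shifts
# are large relative to the between-participant baselines but no single
# channel separates the adjacent severities alone, so a trained model must
# combine the planted channels (see the methods vignette).
recovery_spec <- function(duration_s = 10) {
  signature_spec(yaw_turn_rate = 18, gaze_wander_sd = 0,
                 eye_movement_speed_scale = 1,
                 au_up = c(AU26 = 2.5), au_down = c(AU12 = 0),
                 duration_s = duration_s)
}
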