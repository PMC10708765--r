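test_that("read_openface_csv parses the 49-column dialect and drops extras", {
  path <- write_openface_fixture(n = 10)
  tab <- read_openface_csv(path)
  expect_s3_class(tab, "raw_feature_table")
  expect_equal(nrow(tab), 10L)
  expect_equal(sort(setdiff(names(tab), c("frame", "timestamp"))),
               sort(openface_all_columns()))

  withr::local_seed(1)
  path2 <- write_openface_fixture(n = 8, extra = c("confidence", "success"))
  expect_message(tab2 <- read_openface_csv(path2), "dropping 2 unrecognized")
  expect_false(any(c("confidence", "success") %in% names(tab2)))
  expect_equal(ncol(tab2), 51L) # frame + timestamp + 49
})

test_that("missing canonical columns raise a schema error naming them", {
  path <- write_openface_fixture(n = 5, drop = c("gaze_angle_x", "AU07_r"))
  expect_error(read_openface_csv(path), "gaze_angle_x")
  expect_error(read_openface_csv(path), "AU07_r")
  expect_error(read_openface_csv("/nonexistent/file.csv"), "does not exist")
})

test_that("join_participant_segments concatenates and renumbers frames", {
  dir <- withr::local_tempdir()
  tabs <- lapply(c(5, 7), function(n) {
    read_openface_csv(write_openface_fixture(n = n, dir = dir))
  })
  joined <- join_participant_segments(tabs)
  expect_equal(nrow(joined), 12L)

  # oracle: plain row-binding of three 10-row fixtures gives frames 0..29
  tabs3 <- lapply(1:3, function(i) {
    read_openface_csv(write_openface_fixture(n = 10, dir = dir))
  })
  joined3 <- join_participant_segments(tabs3)
  oracle <- do.call(rbind, lapply(tabs3, function(t) as.data.frame(t)[openface_all_columns()]))
  expect_equal(nrow(joined3), 30L)
  expect_equal(joined3$frame, 0:29)
  expect_equal(as.data.frame(joined3)[openface_all_columns()], oracle,
               ignore_attr = TRUE)

  single <- join_participant_segments(tabs[1])
  expect_equal(as.data.frame(single)[openface_all_columns()],
               as.data.frame(tabs[[1]])[openface_all_columns()])
  expect_error(join_participant_segments(list()), "no segments")
})

test_that("select_features keeps 40 columns in the fixed group partition", {
  tab <- generate_participant("mild", signature_spec(duration_s = 1), seed = 3)
  fs <- select_features(tab, participant_id = "P1")
  expect_s3_class(fs, "feature_series")
  expect_equal(ncol(fs$values), 40L)
  expect_equal(lengths(fs$group_slices), c(Pose = 3L, Gaze = 2L, AU_r = 17L, AU_c = 18L))
  expect_equal(unname(sort(unlist(fs$group_slices))), 1:40) # disjoint cover
  dropped <- c(openface_feature_columns()$pose_location,
               openface_feature_columns()$gaze_vectors)
  expect_false(any(dropped %in% colnames(fs$values)))
  # idempotent on its own output
  expect_identical(select_features(fs), fs)
})

test_that("pad_to_horizon appends zeros and preserves original rows bit-exact", {
  tab <- generate_participant("severe", signature_spec(duration_s = 100 / 30), seed = 5)
  fs <- select_features(tab, "P2")
  before <- fs$values
  padded <- pad_to_horizon(fs, 300L)
  expect_equal(nrow(padded$values), 300L)
  expect_equal(padded$original_length, 100L)
  expect_identical(padded$values[1:100, ], before)
  nonzero_rows <- which(rowSums(padded$values != 0) > 0)
  expect_lte(max(nonzero_rows), 100L)
  expect_true(all(padded$values[101:300, ] == 0))

  same <- pad_to_horizon(padded, 300L)
  expect_identical(same$values, padded$values)
  expect_error(pad_to_horizon(padded, 200L), "longer than")
})

test_that("join length equals the sum of segment lengths (property)", {
  dir <- withr::local_tempdir()
  withr::local_seed(7)
  for (rep in 1:5) {
    lens <- sample(3:15, sample(2:5, 1), replace = TRUE)
    tabs <- lapply(lens, function(n) read_openface_csv(write_openface_fixture(n = n, dir = dir)))
    joined <- join_participant_segments(tabs)
    expect_equal(nrow(joined), sum(lens))
    expect_equal(joined$frame, seq_len(sum(lens)) - 1L)
  }
})

test_that("z-scaling uses train stats and keeps padding exactly zero", {
  co <- generate_cohort(c(normal = 3, severe = 3),
                        signature_spec(duration_s = 2), seed = 21)
  samp <- cohort_to_samples(co, horizon = 90L)
  scaler <- fit_feature_scaler(lapply(samp[1:4], function(s) s$series))
  out <- apply_feature_scaler(samp[[1]]$series, scaler)
  expect_true(all(out$values[61:90, ] == 0))
  # train-stacked normalized features have mean ~0, sd ~1
  stacked <- do.call(rbind, lapply(samp[1:4], function(s) {
    apply_feature_scaler(s$series, scaler)$values[1:60, ]
  }))
  expect_lt(max(abs(colMeans(stacked))), 1e-10)
  nontrivial <- apply(stacked, 2, sd) > 0
  expect_equal(unname(apply(stacked, 2, sd)[nontrivial]),
               rep(1, sum(nontrivial)), tolerance = 1e-8)
})

test_that("load_cohort round-trips a written synthetic cohort", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(c(normal = 2, moderate = 1),
                        signature_spec(duration_s = 2), seed = 13)
  manifest <- write_cohort_csv(co, dir, segments = 2L)
  samples <- load_cohort(manifest, horizon = 90L)
  expect_length(samples, 3L)
  expect_equal(vapply(samples, function(s) s$severity, character(1)),
               c("normal", "normal", "moderate"))
  expect_equal(vapply(samples, function(s) nrow(s$series$values), integer(1)),
               rep(90L, 3))
  # values survive the CSV round-trip (joined segments = original series)
  direct <- cohort_to_samples(co, horizon = 90L)
  expect_equal(samples[[1]]$series$values, direct[[1]]$series$values,
               tolerance = 1e-12)
})
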