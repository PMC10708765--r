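test_that("window_reshape produces consecutive windows and round-trips", {
  x <- matrix(seq_len(60 * 4), 60, 4)
  w <- window_reshape(x, 30L)
  expect_equal(dim(w), c(2L, 30L, 4L))
  expect_equal(w[1, , ], x[1:30, ])
  expect_equal(w[2, , ], x[31:60, ])
  expect_identical(window_flatten(w), x)
  expect_error(window_reshape(x, 7L), "not divisible")

  # clinical horizon arithmetic: 19,800 frames -> 660 x 30 x 40
  big <- matrix(rnorm(19800 * 40), 19800, 40)
  wb <- window_reshape(big, 30L)
  expect_equal(dim(wb), c(660L, 30L, 40L))
  expect_identical(window_flatten(wb), big)
})

test_that("attention_pool matches a hand computation and its weights are a simplex", {
  # hand-set parameters on a 3 x 2 input
  h <- matrix(c(1, 0, -1,
                0.5, 1, 0), 3, 2)
  W <- matrix(c(0.2, -0.1, 0.3, 0.4), 2, 2)
  b <- c(0.05, -0.05)
  v <- c(1, -2)
  u <- tanh(sweep(h %*% W, 2, b, "+"))
  s <- as.numeric(u %*% v)
  w_oracle <- exp(s) / sum(exp(s))
  out_oracle <- as.numeric(t(h) %*% w_oracle)
  out <- attention_pool(h, W, b, v)
  expect_equal(as.numeric(out), out_oracle, tolerance = 1e-12)
  expect_equal(sum(attr(out, "weights")), 1)
  expect_true(all(attr(out, "weights") >= 0))

  # T = 1: pooling returns the single hidden state
  one <- attention_pool(matrix(c(3, -2), 1, 2))
  expect_equal(as.numeric(one), c(3, -2))
  # identical rows: output equals any row
  same <- attention_pool(matrix(1:2, 4, 2, byrow = TRUE))
  expect_equal(as.numeric(same), c(1, 2))
})

test_that("avg_pool_series and transformer_branch pooling follow the stride", {
  x <- matrix(rnorm(150 * 3), 150, 3)
  p <- avg_pool_series(x, 15L)
  expect_equal(dim(p), c(10L, 3L))
  expect_equal(p[1, ], colMeans(x[1:15, ]))
  expect_identical(avg_pool_series(x, 1L), x)
  const <- matrix(2, 30, 3)
  expect_true(all(avg_pool_series(const, 15L) == 2))

  cfg <- model_config("early", "transformer", horizon = 150,
                      transformer = list(blocks = 1, head_size = 16,
                                         n_heads = 1, ff_dim = 32,
                                         pool_stride = 15))
  br <- transformer_branch(x, cfg, seed = 1)
  expect_equal(nrow(br$pooled), 10L)
  expect_equal(length(br$representation), 3L)
  # pooled length at the clinical horizon: 19,800 / 15 = 1,320
  expect_equal(19800L %/% 15L, 1320L)
})

test_that("late_fusion_aggregate averages probabilities", {
  expect_equal(late_fusion_aggregate(c(1, 1, 1, 1))$p, 1)
  expect_equal(late_fusion_aggregate(c(0.2, 0.4, 0.6, 0.8))$p, 0.5)
  expect_equal(late_fusion_aggregate(c(0.2, 0.4, 0.6, 0.8))$decision, 1L)
  expect_error(late_fusion_aggregate(c(0.5, 1.2, 0.1, 0)), ">= 0")
})

test_that("all nine configs build and yield probabilities on a synthetic batch", {
  co <- generate_cohort(c(normal = 2, severe = 2),
                        signature_spec(duration_s = 5), seed = 8)
  samp <- cohort_to_samples(co, horizon = 150L)
  for (fu in c("early", "intermediate", "late")) {
    for (bb in c("bilstm", "window_block_lstm", "transformer")) {
      cfg <- model_config(fu, bb, horizon = 150L,
                          transformer = list(blocks = 1, head_size = 32,
                                             n_heads = 1, ff_dim = 64,
                                             pool_stride = 15))
      mdl <- build_model(cfg, seed = 2)
      pr <- predict(mdl, samp)
      expect_equal(nrow(pr), 4L)
      expect_true(all(pr$p >= 0 & pr$p <= 1), info = paste(fu, bb))
      expect_true(all(pr$decision %in% c(0L, 1L)))
    }
  }
})

test_that("parameter counts increase strictly with hidden widths", {
  n1 <- n_params(build_model(model_config("intermediate", "window_block_lstm",
                                          horizon = 60,
                                          group_hidden = c(Pose = 8, Gaze = 8,
                                                           AU_r = 16, AU_c = 16)),
                             seed = 1))
  n2 <- n_params(build_model(model_config("intermediate", "window_block_lstm",
                                          horizon = 60,
                                          group_hidden = c(Pose = 16, Gaze = 16,
                                                           AU_r = 32, AU_c = 32)),
                             seed = 1))
  expect_gt(n2, n1)
  n3 <- n_params(build_model(model_config("early", "bilstm", horizon = 60,
                                          group_hidden = c(all = 32)), seed = 1))
  n4 <- n_params(build_model(model_config("early", "bilstm", horizon = 60,
                                          group_hidden = c(all = 64)), seed = 1))
  expect_gt(n4, n3)
})

test_that("default configurations carry the reference layer widths", {
  eb <- model_config("early", "bilstm")
  expect_equal(unname(eb$group_hidden), 128)
  expect_equal(eb$head_widths, c(64, 32, 1))
  iw <- model_config("intermediate", "window_block_lstm")
  expect_equal(iw$group_hidden,
               c(Pose = 32, Gaze = 32, AU_r = 64, AU_c = 64))
  expect_equal(iw$head_widths, c(128, 64, 32, 16, 1))
  ib <- model_config("intermediate", "bilstm")
  expect_equal(ib$group_hidden,
               c(Pose = 64, Gaze = 16, AU_r = 128, AU_c = 128))
  expect_equal(iw$window, list(window_len = 30L, n_windows = 660L))
  tr <- model_config("early", "transformer")
  expect_equal(tr$transformer,
               list(blocks = 1L, head_size = 512L, n_heads = 1L,
                    ff_dim = 2048L, pool_stride = 15L))
  lb <- model_config("late", "bilstm")
  expect_equal(lb$head_widths, c(256, 128, 1)) # doubled intermediate head
  expect_error(model_config("early", "window_block_lstm", horizon = 100),
               "divisible")
  expect_error(model_config(head_widths = c(64, 32)), "terminate in 1")
})
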