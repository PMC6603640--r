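cv_task <- function(seed = 1) {
  sim_config(n_channels = 4, fragment_len = 64, sample_rate = 32,
             informative_channels = list("2" = c(2, 3)), burst_freq = 8,
             snr_db = 15, n_subjects = 5, fragments_per_subject = 10,
             subject_scale_sd = 0.05, seed = seed)
}

cv_builder <- function(seed) {
  fusionatt_model(4, 64, 2, encoder = tiny_encoder(8L), r = 8L, seed = seed)
}

test_that("cross-validation yields one metrics row per fold plus a consistent average", {
  fs <- generate_dataset(cv_task(91))
  folds <- make_subject_folds(fs, 5, seed = 91)
  tc <- train_config(batch_size = 16, max_epochs = 3, seed = 91)
  cv <- cross_validate(fs, folds, cv_builder, tc)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$average[["accuracy"]], mean(cv$per_fold$accuracy),
               tolerance = 1e-12)
  expect_equal(cv$average[["f1_macro"]], mean(cv$per_fold$f1_macro),
               tolerance = 1e-12)
  # pooled predictions cover every fragment exactly once
  expect_equal(length(cv$pooled$labels), length(fs$fragments))
  expect_s3_class(cv$pooled$metrics, "fa_metrics")
})

test_that("repeated cross-validation runs with the same seeds are identical", {
  fs <- generate_dataset(cv_task(92))
  folds <- make_subject_folds(fs, 5, seed = 92)
  tc <- train_config(batch_size = 16, max_epochs = 2, seed = 92)
  cv1 <- cross_validate(fs, folds, cv_builder, tc)
  cv2 <- cross_validate(fs, folds, cv_builder, tc)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$pooled$probs, cv2$pooled$probs)
})

test_that("a single-value sweep reproduces a plain cross-validation run", {
  fs <- generate_dataset(cv_task(93))
  folds <- make_subject_folds(fs, 5, seed = 93)
  tc <- train_config(batch_size = 16, max_epochs = 2, seed = 93)
  builder <- function(p, r, seed)
    fusionatt_model(4, 64, 2, encoder = tiny_encoder(as.integer(p)),
                    r = as.integer(r), seed = seed)
  tab <- sensitivity_sweep(fs, folds, "p", 8L, builder,
                           base_p = 8L, base_r = 8L, tc = tc)
  expect_equal(nrow(tab), 1)
  cv <- cross_validate(fs, folds, function(seed) builder(8L, 8L, seed), tc)
  expect_equal(tab$accuracy, cv$average[["accuracy"]], tolerance = 1e-12)
  # multi-value sweeps produce one row per value
  tab2 <- sensitivity_sweep(fs, folds, "r", c(4L, 8L), builder,
                            base_p = 8L, base_r = 8L, tc = tc)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$value, c(4, 8))
})

test_that("baseline variants have the advertised structure", {
  gc <- build_baseline("gcnn", C = 4, n = 64, n_classes = 2,
                       encoder = tiny_encoder(8L), seed = 94)
  # no channel-view parameters at all
  expect_null(gc$params$channel)
  expect_null(gc$params$proj_c)
  expect_null(gc$params$attn)
  expect_equal(dim(gc$params$head$W_h), c(8L, 8L))       # head on h_g alone
  mc <- build_baseline("mcnn", C = 4, n = 64, n_classes = 2,
                       encoder = tiny_encoder(8L), seed = 94)
  expect_equal(dim(mc$params$head$W_h), c(8L, 16L))      # [mean h_i, h_g]
  ca <- build_baseline("channelatt_global", C = 4, n = 64, n_classes = 2,
                       encoder = tiny_encoder(8L), seed = 94)
  expect_length(ca$params$attn$W_e, 16L)                 # energies on [h_i, h_g]
})

test_that("local channel attention with equal channel views reduces to the uniform mean", {
  m <- build_baseline("channelatt_local", C = 3, n = 32, n_classes = 2,
                      encoder = tiny_encoder(4L), seed = 95)
  set.seed(95)
  x <- rnorm(32)
  X <- array(0, c(1, 3, 32))
  for (i in 1:3) X[1, i, ] <- x                # identical channels
  fw <- fusionatt:::model_forward(m, X)
  expect_equal(fw$alpha[1, ], rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(fw$ctx[1, ], fw$h_i[1, 1, ], tolerance = 1e-12)
})
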