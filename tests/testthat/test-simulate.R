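# direct FFT bandpower around a target frequency, independent of the
# generator's internals
bandpower <- function(x, freq, rate, halfwidth = 2L) {
  n <- length(x)
  bin <- round(freq * n / rate) + 1L
  sp <- Mod(stats::fft(x))^2 / n
  sum(sp[max(1L, bin - halfwidth):min(n, bin + halfwidth)])
}

test_that("the generator produces the configured number and shape of fragments", {
  cfg <- sim_config(n_channels = 8, fragment_len = 256, n_subjects = 10,
                    fragments_per_subject = 50, seed = 3)
  fs <- generate_dataset(cfg)
  expect_length(fs$fragments, 500)
  expect_true(all(vapply(fs$fragments, function(f) all(dim(f) == c(8, 256)), TRUE)))
  expect_true(all(is.finite(unlist(fs$fragments[1:5]))))
  expect_setequal(unique(fs$subject), 1:10)
  # balanced labels up to subject granularity
  expect_equal(as.numeric(table(fs$label)), c(250, 250))
})

test_that("identical configurations give bitwise-identical datasets", {
  cfg <- sim_config(n_subjects = 2, fragments_per_subject = 6, seed = 77)
  fs1 <- generate_dataset(cfg)
  fs2 <- generate_dataset(cfg)
  expect_identical(fs1$fragments, fs2$fragments)
  expect_identical(fs1$label, fs2$label)
})

test_that("bursts appear only on the informative channels at the burst frequency", {
  cfg <- sim_config(n_channels = 6, fragment_len = 256, sample_rate = 64,
                    informative_channels = list("2" = c(3, 4)),
                    burst_freq = 8, snr_db = 15,
                    n_subjects = 4, fragments_per_subject = 20, seed = 5)
  fs <- generate_dataset(cfg)
  pos <- which(fs$label == 2)
  bp <- sapply(1:6, function(ch)
    mean(vapply(pos, function(i)
      bandpower(fs$fragments[[i]][ch, ], 8, 64), 1)))
  expect_true(min(bp[c(3, 4)]) > max(bp[-c(3, 4)]))
  # oracle detector recovers the informative set exactly at high SNR
  thr <- mean(range(bp))
  expect_equal(which(bp > thr), c(3, 4))
})

test_that("snr of -Inf produces no class signal anywhere", {
  cfg <- sim_config(n_channels = 4, fragment_len = 128, snr_db = -Inf,
                    informative_channels = list("2" = c(1, 2)),
                    n_subjects = 3, fragments_per_subject = 20, seed = 9)
  fs <- generate_dataset(cfg)
  bp <- function(lab) mean(vapply(which(fs$label == lab), function(i)
    bandpower(fs$fragments[[i]][1, ], cfg$burst_freq[1], cfg$sample_rate), 1))
  # bandpower indistinguishable between classes (same noise distribution)
  expect_lt(abs(bp(1) - bp(2)) / bp(1), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_classes = 1), "n_classes")
  expect_error(sim_config(informative_channels = list("2" = integer(0))),
               "empty informative channel set")
  expect_error(sim_config(n_channels = 4,
                          informative_channels = list("2" = c(5))),
               "out of")
  expect_error(sim_config(snr_db = Inf), "non-finite")
})

test_that("pink-noise option yields a decaying spectrum", {
  cfg <- sim_config(n_channels = 2, fragment_len = 256, snr_db = -Inf,
                    informative_channels = list("2" = 1L),
                    noise = "pink", n_subjects = 2, fragments_per_subject = 10,
                    seed = 21)
  fs <- generate_dataset(cfg)
  sp <- rowMeans(sapply(fs$fragments, function(f) Mod(stats::fft(f[1, ]))^2))
  lo <- mean(sp[2:10]); hi <- mean(sp[60:120])
  expect_gt(lo, 3 * hi)
})

test_that("subject folds partition subjects with disjoint train/val/test", {
  cfg <- sim_config(n_subjects = 10, fragments_per_subject = 10, seed = 1)
  fs <- generate_dataset(cfg)
  folds <- make_subject_folds(fs, 5, seed = 2)
  expect_length(folds, 5)
  test_sets <- lapply(folds, `[[`, "test_subjects")
  expect_true(all(vapply(test_sets, length, 1L) == 2))
  expect_setequal(unlist(test_sets), 1:10)
  expect_equal(sum(lengths(test_sets)), 10)    # each subject tested once
  for (f in folds) {
    expect_length(intersect(f$train_subjects, f$val_subjects), 0)
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
    expect_length(intersect(f$val_subjects, f$test_subjects), 0)
    expect_setequal(c(f$train_subjects, f$val_subjects, f$test_subjects), 1:10)
  }
})

test_that("fold fragment fractions approach 0.7:0.1:0.2 at subject granularity", {
  cfg <- sim_config(n_subjects = 25, fragments_per_subject = 4, seed = 1)
  fs <- generate_dataset(cfg)
  folds <- make_subject_folds(fs, 5, seed = 3)
  for (f in folds) {
    n_test <- sum(fs$subject %in% f$test_subjects)
    n_val <- sum(fs$subject %in% f$val_subjects)
    expect_equal(n_test / length(fs$fragments), 0.2)
    expect_equal(n_val / length(fs$fragments), 0.1, tolerance = 0.5)
  }
})

test_that("folds require at least k subjects", {
  cfg <- sim_config(n_subjects = 3, fragments_per_subject = 2, seed = 1)
  fs <- generate_dataset(cfg)
  expect_error(make_subject_folds(fs, 5), "at least k")
})
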