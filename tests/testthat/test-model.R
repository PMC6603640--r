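test_that("the attentional representation and classifier obey their closed forms", {
  m <- fusionatt_model(3, 32, 2, encoder = tiny_encoder(4L), r = 4L, seed = 4)
  # zero inputs, zero bias -> zero representation
  m0 <- m
  m0$params$head$b_h <- numeric(m$r)
  expect_equal(attentional_representation(numeric(4), numeric(4), m0),
               numeric(4))
  # matches a scalar computation on a random case
  set.seed(41)
  cg <- rnorm(4); hg <- rnorm(4)
  ref <- pmax(as.numeric(m$params$head$W_h %*% c(cg, hg) + m$params$head$b_h), 0)
  expect_equal(attentional_representation(cg, hg, m), ref)
  # zero classifier weights: uniform probabilities, tie broken to class 1
  mz <- m
  mz$params$head$W_s[] <- 0; mz$params$head$b_s[] <- 0
  pr <- classify_representation(rnorm(4), mz)
  expect_equal(pr$probs, c(0.5, 0.5))
  expect_equal(pr$label, 1L)
  # saturated bias
  mz$params$head$b_s <- c(10, -10)
  pr <- classify_representation(rnorm(4), mz)
  expect_equal(pr$probs[1], 1, tolerance = 1e-8)
})

test_that("cross-entropy loss matches closed forms and the per-sample oracle", {
  # uniform predictions: ln K
  logits <- matrix(0, 4, 2)
  expect_equal(model_loss(logits, c(1, 2, 1, 2)), log(2), tolerance = 1e-9)
  logits5 <- matrix(0, 3, 5)
  expect_equal(model_loss(logits5, c(1, 3, 5)), log(5), tolerance = 1e-9)
  # near-perfect one-hot predictions: ~0
  big <- matrix(c(50, 0, 0, 50), 2, 2, byrow = TRUE)
  expect_equal(model_loss(big, c(1, 2)), 0, tolerance = 1e-9)
  # random batch against a scalar per-sample computation
  set.seed(42)
  z <- matrix(rnorm(3 * 4), 3, 4)
  y <- c(2, 4, 1)
  ref <- mean(vapply(1:3, function(i) {
    p <- exp(z[i, ]) / sum(exp(z[i, ]))
    -log(p[y[i]])
  }, 1))
  expect_equal(model_loss(z, y), ref, tolerance = 1e-12)
})

test_that("L2 penalty covers weights but not biases", {
  m <- fusionatt_model(3, 32, 2, encoder = tiny_encoder(4L), seed = 6)
  pen <- fusionatt:::l2_penalty(m$params)
  manual <- sum(unlist(lapply(m$params$channel, function(cl)
    sum(vapply(cl$W, function(w) sum(w^2), 1))))) +
    sum(unlist(lapply(m$params$global, function(cl)
      sum(vapply(cl$W, function(w) sum(w^2), 1))))) +
    sum(m$params$proj_c$W^2) + sum(m$params$proj_g$W^2) +
    sum(m$params$attn$W_rg^2) + sum(m$params$attn$W_rc^2) +
    sum(m$params$attn$W_e^2) +
    sum(m$params$head$W_h^2) + sum(m$params$head$W_s^2)
  expect_equal(pen, manual)
  z <- matrix(0, 2, 2)
  expect_equal(model_loss(z, c(1, 2), m, l2 = 0.001),
               log(2) + 0.001 * pen, tolerance = 1e-12)
})

test_that("evaluation-mode forward passes are bitwise repeatable with dropout off", {
  m <- fusionatt_model(4, 64, 2, encoder = tiny_encoder(), seed = 7)
  X <- tiny_batch(3, 4, 64, seed = 71)
  f1 <- fusionatt:::model_forward(m, X, training = FALSE)
  set.seed(999)   # evaluation must not consume or depend on RNG
  f2 <- fusionatt:::model_forward(m, X, training = FALSE)
  expect_identical(f1$probs, f2$probs)
  expect_identical(f1$alpha, f2$alpha)
  # training mode with dropout is stochastic
  set.seed(1); t1 <- fusionatt:::model_forward(m, X, training = TRUE)$probs
  set.seed(2); t2 <- fusionatt:::model_forward(m, X, training = TRUE)$probs
  expect_false(identical(t1, t2))
})

test_that("every parameter group passes a finite-difference gradient check in all variants", {
  kinds <- list(c("fusionatt", FALSE), c("fusionatt", TRUE), c("gcnn", FALSE),
                c("mcnn", FALSE), c("channelatt_local", FALSE),
                c("channelatt_global", FALSE))
  X <- tiny_batch(4, 3, 24, seed = 81)
  y <- c(1, 2, 2, 1)
  enc <- encoder_config(
    channel_cells = list(cell_config(c(3, 5), 2, 2)),
    global_cells = list(cell_config(list(c(2, 3)), 2, c(NA, 2))),
    p = 4L)
  l2 <- 0.001
  for (kv in kinds) {
    m <- fusionatt_model(3, 24, 2, encoder = enc, r = 4L, kind = kv[[1]],
                         vector_gate = as.logical(kv[[2]]), seed = 8)
    fw <- fusionatt:::model_forward(m, X)
    grads <- fusionatt:::model_backward(m, fw, fusionatt:::ce_dlogits(fw$logits, y))
    fobj <- function(mm) {
      f <- fusionatt:::model_forward(mm, X)
      model_loss(f$logits, y, mm, l2)
    }
    eps <- 1e-5
    set.seed(82)
    for (path in fusionatt:::param_paths(m$params)) {
      leaf <- fusionatt:::get_leaf(m$params, path)
      g_leaf <- fusionatt:::get_leaf(grads, path)
      if (fusionatt:::is_weight_path(path)) g_leaf <- g_leaf + 2 * l2 * leaf
      for (ii in sample(length(leaf), min(3, length(leaf)))) {
        mp <- m; lp <- leaf; lp[ii] <- lp[ii] + eps
        mp$params <- fusionatt:::set_leaf(mp$params, path, lp)
        mm_ <- m; lm <- leaf; lm[ii] <- lm[ii] - eps
        mm_$params <- fusionatt:::set_leaf(mm_$params, path, lm)
        fd <- (fobj(mp) - fobj(mm_)) / (2 * eps)
        rel <- abs(fd - g_leaf[ii]) / max(1e-6, abs(fd) + abs(g_leaf[ii]))
        expect_lt(rel, 1e-4)
      }
    }
  }
})

test_that("contribution-score reports group fragments and flag the top channel", {
  cfg <- sim_config(n_channels = 4, fragment_len = 64, n_subjects = 1,
                    fragments_per_subject = 25, snr_db = -Inf, seed = 9)
  fs <- generate_dataset(cfg)
  m <- fusionatt_model(4, 64, 2, encoder = tiny_encoder(), seed = 10)
  rep5 <- export_contribution_scores(m, fs, group = 5)
  expect_equal(nrow(rep5), 5 * 4)               # 5 timestamps x 4 channels
  sums <- tapply(rep5$mean_score, rep5$timestamp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(as.numeric(tapply(rep5$is_max, rep5$timestamp, sum)), rep(1, 5))
  # a partial trailing group is kept and flagged by its size
  rep7 <- export_contribution_scores(m, fs, group = 7)
  expect_equal(max(rep7$timestamp), 4)
  expect_equal(unique(rep7$n_fragments[rep7$timestamp == 4]), 4)
  # forced-uniform scores tie-break to channel 1
  mu <- m
  mu$params$attn$W_e[] <- 0
  repu <- export_contribution_scores(mu, fs, group = 5)
  expect_true(all(repu$mean_score == 0.25))
  expect_true(all(repu$channel[repu$is_max] == 1))
})
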