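ap3 <- function(p, seed = 1) {
  set.seed(seed)
  list(W_rg = rnorm(p), W_rc = rnorm(p), b_rc = rnorm(1),
       W_e = rnorm(p), b_e = rnorm(1))
}

test_that("the fusion gate reproduces its analytic limits", {
  p <- 3
  zero <- list(W_rg = numeric(p), W_rc = numeric(p), b_rc = 0,
               W_e = numeric(p), b_e = 0)
  expect_identical(fusion_gate(rnorm(p), rnorm(p), zero), 0.5)  # sigmoid(0)
  sat <- zero; sat$b_rc <- 20
  expect_equal(fusion_gate(rnorm(p), rnorm(p), sat), 1, tolerance = 1e-8)
  sat$b_rc <- -20
  expect_equal(fusion_gate(rnorm(p), rnorm(p), sat), 0, tolerance = 1e-8)
  # random case against an explicit scalar computation
  set.seed(11)
  ap <- ap3(p); hg <- rnorm(p); hi <- rnorm(p)
  expect_equal(fusion_gate(hg, hi, ap),
               1 / (1 + exp(-(sum(ap$W_rg * hg) + sum(ap$W_rc * hi) + ap$b_rc))))
  expect_error(fusion_gate(rnorm(2), rnorm(p), ap), "dimension mismatch")
})

test_that("gated blending passes only the channel view at r = 1 and only the global view at r = 0", {
  set.seed(12)
  hg <- rnorm(5); hi <- rnorm(5)
  expect_identical(fuse_views(hg, hi, 1), hi)
  expect_identical(fuse_views(hg, hi, 0), hg)
  expect_equal(fuse_views(c(0, 2), c(2, 0), 0.5), c(1, 1))
})

test_that("attention energies are affine in the fused view", {
  p <- 4
  ap <- ap3(p, 13)
  zero_w <- ap; zero_w$W_e <- numeric(p)
  expect_identical(attention_energy(rnorm(p), zero_w), zero_w$b_e)
  expect_identical(attention_energy(numeric(p), ap), ap$b_e)
  set.seed(14)
  h <- rnorm(p)
  expect_equal(attention_energy(h, ap), sum(ap$W_e * h) + ap$b_e)
})

test_that("contribution scores are a stabilised softmax with exact closed forms", {
  expect_identical(contribution_scores(rep(2.5, 4)), rep(0.25, 4))
  expect_equal(contribution_scores(c(0, log(2))), c(1 / 3, 2 / 3))
  set.seed(15)
  e <- rnorm(6, sd = 3)
  ref <- exp(e) / sum(exp(e))    # small magnitudes: direct form is exact here
  expect_equal(contribution_scores(e), ref, tolerance = 1e-12)
  # shift invariance and simplex constraints
  expect_equal(contribution_scores(e + 1000), contribution_scores(e))
  s <- contribution_scores(rnorm(8, sd = 50))
  expect_true(all(s >= 0))
  expect_equal(sum(s), 1, tolerance = 1e-9)
})

test_that("the context vector is the score-weighted aggregate of fused views", {
  expect_equal(context_vector(1, list(c(3, 1))), c(3, 1))
  v <- c(2, -1, 5)
  expect_equal(context_vector(c(0.2, 0.3, 0.5), list(v, v, v)), v)
  set.seed(16)
  a <- contribution_scores(rnorm(3))
  fused <- lapply(1:3, function(i) rnorm(2))
  ref <- numeric(2)
  for (i in 1:3) for (k in 1:2) ref[k] <- ref[k] + a[i] * fused[[i]][k]
  expect_equal(context_vector(a, fused), ref)
})

test_that("the batched attention layer matches the scalar oracle end to end", {
  set.seed(17)
  for (case in 1:20) {
    B <- sample(1:3, 1); C <- sample(2:5, 1); p <- sample(2:8, 1)
    ap <- ap3(p, seed = 100 + case)
    h_i <- array(rnorm(B * C * p), c(B, C, p))
    h_g <- matrix(rnorm(B * p), B, p)
    out <- fusionatt:::attention_forward(h_i, h_g, ap)
    for (b in seq_len(B)) {
      ref <- oracle_attention(lapply(seq_len(C), function(i) h_i[b, i, ]),
                              h_g[b, ], ap)
      expect_equal(out$r[b, ], ref$r, tolerance = 1e-6)
      expect_equal(out$alpha[b, ], ref$alpha, tolerance = 1e-6)
      expect_equal(out$ctx[b, ], ref$ctx, tolerance = 1e-6)
    }
  }
})

test_that("attention is permutation-equivariant and the context convex", {
  set.seed(18)
  B <- 2; C <- 5; p <- 4
  ap <- ap3(p, 18)
  h_i <- array(rnorm(B * C * p), c(B, C, p))
  h_g <- matrix(rnorm(B * p), B, p)
  out <- fusionatt:::attention_forward(h_i, h_g, ap)
  perm <- sample(C)
  out_p <- fusionatt:::attention_forward(h_i[, perm, , drop = FALSE], h_g, ap)
  expect_equal(out_p$alpha, out$alpha[, perm])
  expect_equal(out_p$r, out$r[, perm])
  expect_equal(out_p$ctx, out$ctx, tolerance = 1e-12)
  # coordinate-wise convex hull
  for (b in 1:B) for (k in 1:p) {
    expect_gte(out$ctx[b, k], min(out$fused[b, , k]) - 1e-12)
    expect_lte(out$ctx[b, k], max(out$fused[b, , k]) + 1e-12)
  }
  # gates strictly inside (0, 1)
  expect_true(all(out$r > 0 & out$r < 1))
})
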