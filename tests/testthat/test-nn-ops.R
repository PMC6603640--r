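test_that("1-D convolution matches the scalar loop oracle on random cases", {
  set.seed(101)
  for (case in 1:10) {
    B <- sample(1:3, 1); L <- sample(8:20, 1); M <- sample(1:3, 1)
    k <- sample(2:4, 1); F <- sample(1:3, 1)
    x <- array(rnorm(B * L * M), c(B, L, M))
    W <- array(rnorm(k * M * F), c(k, M, F))
    b <- rnorm(F)
    out <- conv1d_forward(x, W, b)$out
    for (bb in seq_len(B)) {
      ob <- out[bb, , , drop = FALSE]
      dim(ob) <- dim(ob)[-1]
      expect_equal(ob, oracle_conv1d(matrix(x[bb, , ], L, M), W, b),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("2-D convolution matches the scalar loop oracle on random cases", {
  set.seed(102)
  for (case in 1:10) {
    B <- sample(1:2, 1); H <- sample(4:7, 1); Wd <- sample(6:12, 1)
    M <- sample(1:2, 1); kh <- sample(2:3, 1); kw <- sample(2:3, 1)
    F <- sample(1:3, 1)
    x <- array(rnorm(B * H * Wd * M), c(B, H, Wd, M))
    W <- array(rnorm(kh * kw * M * F), c(kh, kw, M, F))
    b <- rnorm(F)
    out <- conv2d_forward(x, W, b)$out
    for (bb in seq_len(B)) {
      ob <- out[bb, , , , drop = FALSE]
      dim(ob) <- dim(ob)[-1]
      expect_equal(ob, oracle_conv2d(array(x[bb, , , ], c(H, Wd, M)), W, b),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("kernel-width-3 convolution with pool 3 on a 12-vector gives lengths 10 then 3", {
  # hand-checkable sizing: valid conv of 12 with width 3 -> 10, pool 3 -> 3
  x <- array(seq_len(12), c(1, 12, 1))
  W <- array(c(1, -1, 2), c(3, 1, 1))
  cv <- conv1d_forward(x, W, 0)
  expect_equal(dim(cv$out), c(1, 10, 1))
  expect_equal(as.numeric(cv$out),
               vapply(1:10, function(t) sum(c(1, -1, 2) * (t:(t + 2))), 1))
  pl <- maxpool1d_forward(cv$out, 3)
  expect_equal(dim(pl$out), c(1, 3, 1))
  # increasing input => block maxima are the last element of each pool window
  expect_equal(as.numeric(pl$out), as.numeric(cv$out)[c(3, 6, 9)])
})

test_that("max pooling truncates the tail and records argmax for backprop", {
  set.seed(103)
  x <- array(rnorm(2 * 11 * 2), c(2, 11, 2))
  pl <- maxpool1d_forward(x, 4)
  expect_equal(dim(pl$out), c(2, 2, 2))   # floor(11 / 4) = 2, tail dropped
  for (b in 1:2) for (m in 1:2)
    expect_equal(pl$out[b, , m],
                 c(max(x[b, 1:4, m]), max(x[b, 5:8, m])))
  # backward routes gradient only to the argmax positions
  dout <- array(1, dim(pl$out))
  dx <- maxpool1d_backward(dout, pl$cache)
  expect_equal(sum(dx != 0), 2 * 2 * 2)
  expect_equal(sum(dx), sum(dout))
  expect_true(all(dx[, 9:11, ] == 0))
})

test_that("convolution backward passes a finite-difference check", {
  set.seed(104)
  x <- array(rnorm(2 * 10 * 2), c(2, 10, 2))
  W <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  b <- rnorm(2)
  fw <- conv1d_forward(x, W, b)
  dout <- array(rnorm(length(fw$out)), dim(fw$out))
  bw <- conv1d_backward(dout, fw$cache)
  fobj <- function(xx, WW, bb2) sum(conv1d_forward(xx, WW, bb2)$out * dout)
  eps <- 1e-6
  for (ii in sample(length(x), 5)) {
    xp <- x; xp[ii] <- xp[ii] + eps
    xm <- x; xm[ii] <- xm[ii] - eps
    expect_equal(bw$dx[ii], (fobj(xp, W, b) - fobj(xm, W, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (ii in sample(length(W), 5)) {
    Wp <- W; Wp[ii] <- Wp[ii] + eps
    Wm <- W; Wm[ii] <- Wm[ii] - eps
    expect_equal(bw$dW[ii], (fobj(x, Wp, b) - fobj(x, Wm, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("inputs shorter than a kernel raise a shape error naming the sizes", {
  x <- array(rnorm(2 * 4 * 1), c(2, 4, 1))
  W <- array(rnorm(6), c(6, 1, 1))
  expect_error(conv1d_forward(x, W, 0), "shorter than kernel width 6")
  x2 <- array(rnorm(2 * 3 * 5 * 1), c(2, 3, 5, 1))
  W2 <- array(rnorm(4 * 2), c(4, 2, 1, 1))
  expect_error(conv2d_forward(x2, W2, 0), "smaller than kernel")
})
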