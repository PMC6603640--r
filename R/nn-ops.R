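## Low-level differentiable ops. All forward functions return list(out, cache);
## all backward functions take (dout, cache) and return gradients w.r.t.
## inputs and parameters.
##
## Layout convention: batch first, spatial axes next, feature maps LAST —
## 1-D tensors are (B, L, M), 2-D tensors (B, H, W, M). This keeps every
## im2col-style slice a contiguous-stride copy, so the convolution inner loop
## is a plain GEMM per kernel offset with no transposes. Convolutions are
## valid (no padding) stride-1 cross-correlations; pooling is non-overlapping
## max with tail truncation.

## ---- 1-D convolution: x (B, L, M), W (k, M, F), b (F) -> (B, L - k + 1, F)

conv1d_forward <- function(x, W, b) {
  d <- dim(x); B <- d[1]; L <- d[2]; M <- d[3]
  k <- dim(W)[1]; F <- dim(W)[3]
  if (L < k) stop(sprintf("input length %d shorter than kernel width %d", L, k))
  Lo <- L - k + 1L
  Y <- matrix(rep(b, each = B * Lo), B * Lo, F)
  for (j in seq_len(k)) {
    Xj <- x[, j:(j + Lo - 1L), , drop = FALSE]
    dim(Xj) <- c(B * Lo, M)
    Wj <- W[j, , ]
    dim(Wj) <- c(M, F)
    Y <- Y + Xj %*% Wj
  }
  list(out = array(Y, c(B, Lo, F)),
       cache = list(x = x, W = W, dims = c(B, L, M, k, F, Lo)))
}

conv1d_backward <- function(dout, cache, need_dx = TRUE) {
  d <- cache$dims; B <- d[1]; L <- d[2]; M <- d[3]; k <- d[4]; F <- d[5]; Lo <- d[6]
  dY <- dout
  dim(dY) <- c(B * Lo, F)
  dW <- array(0, c(k, M, F))
  dx <- if (need_dx) array(0, c(B, L, M)) else NULL
  x <- cache$x
  for (j in seq_len(k)) {
    Xj <- x[, j:(j + Lo - 1L), , drop = FALSE]
    dim(Xj) <- c(B * Lo, M)
    dW[j, , ] <- crossprod(Xj, dY)
    if (need_dx) {
      Wj <- cache$W[j, , ]
      dim(Wj) <- c(M, F)
      dx[, j:(j + Lo - 1L), ] <- dx[, j:(j + Lo - 1L), , drop = FALSE] +
        array(dY %*% t(Wj), c(B, Lo, M))
    }
  }
  list(dx = dx, dW = dW, db = colSums(dY))
}

## ---- 2-D convolution: x (B, H, W, M), W (kh, kw, M, F) -> (B, Ho, Wo, F)

conv2d_forward <- function(x, W, b) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; M <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; F <- dim(W)[4]
  if (H < kh || Wd < kw)
    stop(sprintf("input %dx%d smaller than kernel %dx%d", H, Wd, kh, kw))
  Ho <- H - kh + 1L; Wo <- Wd - kw + 1L
  Y <- matrix(rep(b, each = B * Ho * Wo), B * Ho * Wo, F)
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    Xuv <- x[, u:(u + Ho - 1L), v:(v + Wo - 1L), , drop = FALSE]
    dim(Xuv) <- c(B * Ho * Wo, M)
    Wuv <- W[u, v, , ]
    dim(Wuv) <- c(M, F)
    Y <- Y + Xuv %*% Wuv
  }
  list(out = array(Y, c(B, Ho, Wo, F)),
       cache = list(x = x, W = W, dims = c(B, H, Wd, M, kh, kw, F, Ho, Wo)))
}

conv2d_backward <- function(dout, cache, need_dx = TRUE) {
  d <- cache$dims
  B <- d[1]; H <- d[2]; Wd <- d[3]; M <- d[4]; kh <- d[5]; kw <- d[6]
  F <- d[7]; Ho <- d[8]; Wo <- d[9]
  dY <- dout
  dim(dY) <- c(B * Ho * Wo, F)
  dW <- array(0, c(kh, kw, M, F))
  dx <- if (need_dx) array(0, c(B, H, Wd, M)) else NULL
  x <- cache$x
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    Xuv <- x[, u:(u + Ho - 1L), v:(v + Wo - 1L), , drop = FALSE]
    dim(Xuv) <- c(B * Ho * Wo, M)
    dW[u, v, , ] <- crossprod(Xuv, dY)
    if (need_dx) {
      Wuv <- cache$W[u, v, , ]
      dim(Wuv) <- c(M, F)
      dx[, u:(u + Ho - 1L), v:(v + Wo - 1L), ] <-
        dx[, u:(u + Ho - 1L), v:(v + Wo - 1L), , drop = FALSE] +
        array(dY %*% t(Wuv), c(B, Ho, Wo, M))
    }
  }
  list(dx = dx, dW = dW, db = colSums(dY))
}

## ---- non-overlapping max pooling, tail truncated

maxpool1d_forward <- function(x, s) {
  d <- dim(x); B <- d[1]; L <- d[2]; M <- d[3]
  Lo <- L %/% s
  if (Lo < 1L) stop(sprintf("pool width %d exceeds input length %d", s, L))
  idx1 <- seq(1L, by = s, length.out = Lo)
  out <- x[, idx1, , drop = FALSE]
  arg <- array(1L, dim(out))
  if (s > 1L) for (o in 2:s) {
    cand <- x[, idx1 + (o - 1L), , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- o
  }
  list(out = out, cache = list(arg = arg, s = s, dims = c(B, L, M, Lo)))
}

maxpool1d_backward <- function(dout, cache) {
  d <- cache$dims; B <- d[1]; L <- d[2]; M <- d[3]; Lo <- d[4]; s <- cache$s
  dx <- array(0, c(B, L, M))
  idx1 <- seq(1L, by = s, length.out = Lo)
  for (o in seq_len(s)) {
    slab <- array(0, c(B, Lo, M))
    m <- cache$arg == o
    slab[m] <- dout[m]
    dx[, idx1 + (o - 1L), ] <- slab
  }
  dx
}

maxpool2d_forward <- function(x, ph, pw) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; M <- d[4]
  Ho <- H %/% ph; Wo <- Wd %/% pw
  if (Ho < 1L || Wo < 1L)
    stop(sprintf("pool %dx%d exceeds input %dx%d", ph, pw, H, Wd))
  hi <- seq(1L, by = ph, length.out = Ho)
  wi <- seq(1L, by = pw, length.out = Wo)
  out <- x[, hi, wi, , drop = FALSE]
  arg <- array(1L, dim(out))
  o <- 0L
  for (u in seq_len(ph)) for (v in seq_len(pw)) {
    o <- o + 1L
    if (o == 1L) next
    cand <- x[, hi + (u - 1L), wi + (v - 1L), , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- o
  }
  list(out = out, cache = list(arg = arg, ph = ph, pw = pw,
                               dims = c(B, H, Wd, M, Ho, Wo)))
}

maxpool2d_backward <- function(dout, cache) {
  d <- cache$dims; B <- d[1]; H <- d[2]; Wd <- d[3]; M <- d[4]; Ho <- d[5]; Wo <- d[6]
  ph <- cache$ph; pw <- cache$pw
  hi <- seq(1L, by = ph, length.out = Ho)
  wi <- seq(1L, by = pw, length.out = Wo)
  dx <- array(0, c(B, H, Wd, M))
  o <- 0L
  for (u in seq_len(ph)) for (v in seq_len(pw)) {
    o <- o + 1L
    slab <- array(0, c(B, Ho, Wo, M))
    m <- cache$arg == o
    slab[m] <- dout[m]
    dx[, hi + (u - 1L), wi + (v - 1L), ] <- slab
  }
  dx
}

## ---- activations and dense layer

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

## row-wise numerically stabilised softmax on a matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## dense: x (B, d_in), W (d_out, d_in), b (d_out) -> (B, d_out)
dense_forward <- function(x, W, b) {
  out <- x %*% t(W) + rep(b, each = nrow(x))
  list(out = out, cache = list(x = x, W = W))
}

dense_backward <- function(dout, cache) {
  list(dx = dout %*% cache$W,
       dW = crossprod(dout, cache$x),
       db = colSums(dout))
}

## inverted dropout; identity when rate == 0 or not training
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(out = x, cache = NULL))
  keep <- 1 - rate
  mask <- array((stats::runif(length(x)) < keep) / keep, dim(x) %||% length(x))
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## centre-crop a (B, L, M) array along L to length `target`
crop1d <- function(x, target) {
  L <- dim(x)[2]
  left <- (L - target) %/% 2L
  list(out = x[, (left + 1L):(left + target), , drop = FALSE], left = left, L = L)
}

## centre-crop a (B, H, W, M) array on both spatial axes
crop2d <- function(x, th, tw) {
  H <- dim(x)[2]; Wd <- dim(x)[3]
  top <- (H - th) %/% 2L; left <- (Wd - tw) %/% 2L
  list(out = x[, (top + 1L):(top + th), (left + 1L):(left + tw), , drop = FALSE],
       top = top, left = left, H = H, W = Wd)
}

## ---- fast reductions over (B, C, p) arrays ------------------------------

## sum over the middle axis: (B, C, p) -> (B, p)
sum_mid <- function(x) {
  d <- dim(x)
  m <- rowsum(matrix(x, d[1] * d[2], d[3]), rep(seq_len(d[1]), times = d[2]),
              reorder = TRUE)
  dimnames(m) <- NULL
  m
}

## sum over the last axis: (B, C, p) -> (B, C)
sum_last <- function(x) {
  d <- dim(x)
  matrix(rowSums(matrix(x, d[1] * d[2], d[3])), d[1], d[2])
}
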