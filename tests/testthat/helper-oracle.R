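# Independent plain-loop reference implementation of the full forward pass.
# Deliberately scalar: every convolution, pooling, crop, flatten, gate,
# softmax and dense step is an explicit loop following the documented
# conventions (valid cross-correlation, non-overlapping truncating max pool,
# centre-crop to the shortest extent, spatial-fastest column-major flatten).
# Used as the ground truth the vectorized implementation must match.

oracle_conv1d <- function(x, W, b) {
  # x: L x M matrix; W: (k, M, F); returns Lo x F
  k <- dim(W)[1]; M <- dim(W)[2]; F <- dim(W)[3]
  L <- nrow(x); Lo <- L - k + 1
  out <- matrix(0, Lo, F)
  for (f in seq_len(F)) for (t in seq_len(Lo)) {
    acc <- b[f]
    for (m in seq_len(M)) for (j in seq_len(k))
      acc <- acc + x[t + j - 1, m] * W[j, m, f]
    out[t, f] <- acc
  }
  out
}

oracle_conv2d <- function(x, W, b) {
  # x: H x Wd x M array; W: (kh, kw, M, F); returns Ho x Wo x F
  kh <- dim(W)[1]; kw <- dim(W)[2]; M <- dim(W)[3]; F <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- H - kh + 1; Wo <- Wd - kw + 1
  out <- array(0, c(Ho, Wo, F))
  for (f in seq_len(F)) for (a in seq_len(Ho)) for (bb in seq_len(Wo)) {
    acc <- b[f]
    for (m in seq_len(M)) for (u in seq_len(kh)) for (v in seq_len(kw))
      acc <- acc + x[a + u - 1, bb + v - 1, m] * W[u, v, m, f]
    out[a, bb, f] <- acc
  }
  out
}

oracle_pool1d <- function(x, s) {
  # x: L x M; non-overlapping max, tail truncated
  Lo <- nrow(x) %/% s
  out <- matrix(0, Lo, ncol(x))
  for (m in seq_len(ncol(x))) for (t in seq_len(Lo))
    out[t, m] <- max(x[((t - 1) * s + 1):(t * s), m])
  out
}

oracle_pool2d <- function(x, ph, pw) {
  Ho <- dim(x)[1] %/% ph; Wo <- dim(x)[2] %/% pw
  out <- array(0, c(Ho, Wo, dim(x)[3]))
  for (m in seq_len(dim(x)[3])) for (a in seq_len(Ho)) for (bb in seq_len(Wo))
    out[a, bb, m] <- max(x[((a - 1) * ph + 1):(a * ph),
                           ((bb - 1) * pw + 1):(bb * pw), m])
  out
}

oracle_crop1d <- function(x, target) {
  left <- (nrow(x) - target) %/% 2
  x[(left + 1):(left + target), , drop = FALSE]
}

oracle_crop2d <- function(x, th, tw) {
  top <- (dim(x)[1] - th) %/% 2
  left <- (dim(x)[2] - tw) %/% 2
  x[(top + 1):(top + th), (left + 1):(left + tw), , drop = FALSE]
}

oracle_cell1d <- function(x, cfg, pars) {
  outs <- lapply(seq_along(cfg$kernels), function(j)
    oracle_conv1d(x, pars$W[[j]], pars$b[[j]]))
  Lmin <- min(vapply(outs, nrow, 1L))
  stacked <- do.call(cbind, lapply(outs, oracle_crop1d, target = Lmin))
  oracle_pool1d(pmax(stacked, 0), cfg$pool)
}

oracle_cell2d <- function(x, cfg, pars) {
  outs <- lapply(seq_along(cfg$kernels), function(j)
    oracle_conv2d(x, pars$W[[j]], pars$b[[j]]))
  Hmin <- min(vapply(outs, function(o) dim(o)[1], 1L))
  Wmin <- min(vapply(outs, function(o) dim(o)[2], 1L))
  cropped <- lapply(outs, oracle_crop2d, th = Hmin, tw = Wmin)
  Ftot <- sum(vapply(cropped, function(o) dim(o)[3], 1L))
  stacked <- array(0, c(Hmin, Wmin, Ftot))
  f0 <- 0L
  for (o in cropped) {
    stacked[, , (f0 + 1):(f0 + dim(o)[3])] <- o
    f0 <- f0 + dim(o)[3]
  }
  ph <- cfg$pool[1]; if (is.na(ph)) ph <- Hmin
  oracle_pool2d(pmax(stacked, 0), ph, cfg$pool[2])
}

oracle_channel_view <- function(x_i, model) {
  # x_i: length-n vector -> h_i (length p)
  h <- matrix(x_i, ncol = 1)
  for (i in seq_along(model$enc$channel_cells))
    h <- oracle_cell1d(h, model$enc$channel_cells[[i]], model$params$channel[[i]])
  flat <- as.numeric(h)                 # spatial-fastest column-major flatten
  z <- model$params$proj_c$W %*% flat + model$params$proj_c$b
  pmax(as.numeric(z), 0)
}

oracle_global_view <- function(X, model) {
  # X: C x n matrix -> h_g (length p)
  h <- array(X, c(dim(X), 1))
  for (i in seq_along(model$enc$global_cells))
    h <- oracle_cell2d(h, model$enc$global_cells[[i]], model$params$global[[i]])
  flat <- as.numeric(h)
  z <- model$params$proj_g$W %*% flat + model$params$proj_g$b
  pmax(as.numeric(z), 0)
}

oracle_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

oracle_attention <- function(h_list, h_g, ap) {
  C <- length(h_list); p <- length(h_g)
  r <- numeric(C); fused <- vector("list", C); e <- numeric(C)
  for (i in seq_len(C)) {
    z <- ap$b_rc
    for (k in seq_len(p)) z <- z + ap$W_rg[k] * h_g[k] + ap$W_rc[k] * h_list[[i]][k]
    r[i] <- 1 / (1 + exp(-z))
    fused[[i]] <- (1 - r[i]) * h_g + r[i] * h_list[[i]]
    acc <- ap$b_e
    for (k in seq_len(p)) acc <- acc + ap$W_e[k] * fused[[i]][k]
    e[i] <- acc
  }
  alpha <- oracle_softmax(e)
  ctx <- numeric(p)
  for (i in seq_len(C)) ctx <- ctx + alpha[i] * fused[[i]]
  list(r = r, fused = fused, e = e, alpha = alpha, ctx = ctx)
}

oracle_forward <- function(model, X) {
  # full pass on one C x n fragment, evaluation mode
  C <- nrow(X)
  h_list <- lapply(seq_len(C), function(i) oracle_channel_view(X[i, ], model))
  h_g <- oracle_global_view(X, model)
  att <- oracle_attention(h_list, h_g, model$params$attn)
  h_alpha <- pmax(as.numeric(
    model$params$head$W_h %*% c(att$ctx, h_g) + model$params$head$b_h), 0)
  logits <- as.numeric(model$params$head$W_s %*% h_alpha + model$params$head$b_s)
  list(h_i = h_list, h_g = h_g, r = att$r, alpha = att$alpha, ctx = att$ctx,
       h_alpha = h_alpha, logits = logits, probs = oracle_softmax(logits))
}

# small encoder config for fast tests
tiny_encoder <- function(p = 4L) {
  encoder_config(
    channel_cells = list(cell_config(c(3, 5), 2, 2)),
    global_cells = list(cell_config(list(c(2, 3)), 2, c(NA, 2))),
    p = p)
}

# tiny random fragment batch
tiny_batch <- function(B, C, n, seed = 1) {
  set.seed(seed)
  array(rnorm(B * C * n), c(B, C, n))
}
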