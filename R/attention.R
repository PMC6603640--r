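#' Fusion gate between the global view and one channel view
#'
#' Computes the scalar gate `r_i = sigmoid(W_rg . h_g + W_rc . h_i + b_rc)`
#' that controls, per channel, how much channel-view versus global-view
#' information flows on. The gate is strictly in (0, 1).
#'
#' @param h_g Global-view vector (length p).
#' @param h_i Channel-view vector (length p).
#' @param params Attention parameters: list with `W_rg`, `W_rc` (length-p
#'   vectors) and scalar `b_rc` (plus `W_e`, `b_e` for the energy step).
#' @return Scalar gate in (0, 1).
#' @export
fusion_gate <- function(h_g, h_i, params) {
  if (length(h_g) != length(params$W_rg) || length(h_i) != length(params$W_rc))
    stop("view/weight dimension mismatch in fusion gate")
  sigmoid(sum(params$W_rg * h_g) + sum(params$W_rc * h_i) + params$b_rc)
}

#' Gated blend of the global and channel views
#'
#' `hbar_i = (1 - r_i) * h_g + r_i * h_i`: at `r_i = 1` only the channel view
#' passes, at `r_i = 0` only the global view.
#'
#' @param h_g Global-view vector.
#' @param h_i Channel-view vector (same length).
#' @param r_i Gate in `[0, 1]`; either a scalar (broadcast over coordinates)
#'   or a length-p vector (the elementwise-gate variant).
#' @return Fused view `hbar_i`.
#' @export
fuse_views <- function(h_g, h_i, r_i) {
  stopifnot(length(h_g) == length(h_i),
            length(r_i) == 1L || length(r_i) == length(h_i))
  (1 - r_i) * h_g + r_i * h_i
}

#' Attention energy of one fused view
#'
#' Affine score `e_i = W_e . hbar_i + b_e` (no nonlinearity).
#'
#' @param hbar_i Fused view vector.
#' @param params Attention parameters (see [fusion_gate()]).
#' @return Scalar energy.
#' @export
attention_energy <- function(hbar_i, params) {
  if (length(hbar_i) != length(params$W_e))
    stop("fused view length does not match energy weight length")
  sum(params$W_e * hbar_i) + params$b_e
}

#' Softmax contribution scores over channels
#'
#' Normalises the per-channel attention energies into contribution scores
#' `alpha = softmax(e)` (max-subtraction stabilised). Equal energies yield
#' exactly uniform scores; the scores are nonnegative and sum to one.
#'
#' @param energies Numeric vector of finite per-channel energies.
#' @return Numeric vector of scores on the simplex.
#' @export
contribution_scores <- function(energies) {
  stopifnot(length(energies) >= 1, all(is.finite(energies)))
  e <- exp(energies - max(energies))
  e / sum(e)
}

#' Attention-weighted context vector
#'
#' `c_g = sum_i alpha_i * hbar_i`, the convex combination of the fused views
#' under the contribution scores.
#'
#' @param scores Length-C score vector (typically from
#'   [contribution_scores()]).
#' @param fused List of C fused-view vectors, or a C x p matrix.
#' @return Numeric vector of length p.
#' @export
context_vector <- function(scores, fused) {
  if (is.list(fused)) fused <- do.call(rbind, fused)
  stopifnot(nrow(fused) == length(scores))
  as.numeric(crossprod(fused, scores))
}

## ---- batched attention layer (used inside the model) -------------------
## h_i: (B, C, p); h_g: (B, p). Returns gates r (B, C), fused (B, C, p),
## energies e (B, C), scores alpha (B, C), context (B, p).

attention_forward <- function(h_i, h_g, ap) {
  B <- dim(h_i)[1]; C <- dim(h_i)[2]; p <- dim(h_i)[3]
  hg_dot <- as.numeric(h_g %*% ap$W_rg)                   # (B)
  hi_mat <- matrix(h_i, B * C, p)                         # rows ordered (b, c)
  ## careful: matrix(h_i, B*C, p) flattens dims (B, C) with b fastest
  hi_dot <- matrix(hi_mat %*% ap$W_rc, B, C)
  z <- hi_dot + hg_dot + ap$b_rc
  r <- sigmoid(z)                                         # (B, C)
  rb <- array(rep(r, times = p), c(B, C, p))
  hg_b <- aperm(array(h_g, c(B, p, C)), c(1, 3, 2))        # broadcast h_g
  fused <- (1 - rb) * hg_b + rb * h_i
  e <- matrix(matrix(fused, B * C, p) %*% ap$W_e, B, C) + ap$b_e
  alpha <- softmax_rows(e)
  ab <- array(rep(alpha, times = p), c(B, C, p))
  ctx <- sum_mid(ab * fused)                              # (B, p)
  list(r = r, fused = fused, e = e, alpha = alpha, ctx = ctx,
       cache = list(h_i = h_i, h_g = h_g, r = r, fused = fused,
                    alpha = alpha, hg_b = hg_b, dims = c(B, C, p)))
}

## dctx: (B, p); returns gradients for h_i, h_g and attention params
attention_backward <- function(dctx, cache, ap) {
  d <- cache$dims; B <- d[1]; C <- d[2]; p <- d[3]
  alpha <- cache$alpha; fused <- cache$fused; r <- cache$r
  ## ctx = sum_c alpha_c * fused_c
  dctx_b <- aperm(array(dctx, c(B, p, C)), c(1, 3, 2))    # (B, C, p)
  ab <- array(rep(alpha, times = p), c(B, C, p))
  dfused <- ab * dctx_b
  dalpha <- sum_last(fused * dctx_b)                      # (B, C)
  ## softmax backward: de = alpha * (dalpha - sum(alpha * dalpha))
  s <- rowSums(alpha * dalpha)
  de <- alpha * (dalpha - s)
  ## e = fused . W_e + b_e
  de_flat <- as.numeric(matrix(de, B * C, 1))
  fused_mat <- matrix(fused, B * C, p)
  dW_e <- as.numeric(crossprod(fused_mat, de_flat))
  db_e <- sum(de)
  dfused <- dfused + array(outer(de_flat, ap$W_e), c(B, C, p))
  ## fused = (1 - r) * hg + r * h_i
  rb <- array(rep(r, times = p), c(B, C, p))
  hg_b <- cache$hg_b
  dh_i <- rb * dfused
  dhg_from_fuse <- sum_mid((1 - rb) * dfused)             # (B, p)
  dr <- sum_last((cache$h_i - hg_b) * dfused)             # (B, C)
  ## r = sigmoid(z)
  dz <- dr * r * (1 - r)
  dz_flat <- as.numeric(matrix(dz, B * C, 1))
  hi_mat <- matrix(cache$h_i, B * C, p)
  dW_rc <- as.numeric(crossprod(hi_mat, dz_flat))
  dW_rg <- as.numeric(crossprod(cache$h_g, rowSums(dz)))
  db_rc <- sum(dz)
  dh_i <- dh_i + array(outer(dz_flat, ap$W_rc), c(B, C, p))
  dh_g <- dhg_from_fuse + outer(rowSums(dz), as.numeric(ap$W_rg))
  list(dh_i = dh_i, dh_g = dh_g,
       grads = list(W_rg = dW_rg, W_rc = dW_rc, b_rc = db_rc,
                    W_e = dW_e, b_e = db_e))
}

## ---- elementwise (vector) gate variant ---------------------------------
## r_i in (0,1)^p with elementwise weights W_rg, W_rc, b_rc in R^p.

attention_forward_vec <- function(h_i, h_g, ap) {
  B <- dim(h_i)[1]; C <- dim(h_i)[2]; p <- dim(h_i)[3]
  hg_b <- aperm(array(h_g, c(B, p, C)), c(1, 3, 2))
  wb <- function(v) aperm(array(rep(v, each = B), c(B, p, C)), c(1, 3, 2))
  z <- h_i * wb(ap$W_rc) + hg_b * wb(ap$W_rg) + wb(ap$b_rc)
  r <- sigmoid(z)
  fused <- (1 - r) * hg_b + r * h_i
  e <- matrix(matrix(fused, B * C, p) %*% ap$W_e, B, C) + ap$b_e
  alpha <- softmax_rows(e)
  ab <- array(rep(alpha, times = p), c(B, C, p))
  ctx <- sum_mid(ab * fused)
  list(r = r, fused = fused, e = e, alpha = alpha, ctx = ctx,
       cache = list(h_i = h_i, h_g = h_g, r = r, fused = fused,
                    alpha = alpha, hg_b = hg_b, dims = c(B, C, p)))
}

attention_backward_vec <- function(dctx, cache, ap) {
  d <- cache$dims; B <- d[1]; C <- d[2]; p <- d[3]
  alpha <- cache$alpha; fused <- cache$fused; r <- cache$r; hg_b <- cache$hg_b
  dctx_b <- aperm(array(dctx, c(B, p, C)), c(1, 3, 2))
  ab <- array(rep(alpha, times = p), c(B, C, p))
  dfused <- ab * dctx_b
  dalpha <- sum_last(fused * dctx_b)
  s <- rowSums(alpha * dalpha)
  de <- alpha * (dalpha - s)
  de_flat <- as.numeric(matrix(de, B * C, 1))
  fused_mat <- matrix(fused, B * C, p)
  dW_e <- as.numeric(crossprod(fused_mat, de_flat))
  db_e <- sum(de)
  dfused <- dfused + array(outer(de_flat, ap$W_e), c(B, C, p))
  dh_i <- r * dfused
  dhg <- sum_mid((1 - r) * dfused)
  dr <- (cache$h_i - hg_b) * dfused
  dz <- dr * r * (1 - r)
  wb <- function(v) aperm(array(rep(v, each = B), c(B, p, C)), c(1, 3, 2))
  dW_rc <- colSums(matrix(dz * cache$h_i, B * C, p))
  dW_rg <- colSums(matrix(dz * hg_b, B * C, p))
  db_rc <- colSums(matrix(dz, B * C, p))
  dh_i <- dh_i + dz * wb(ap$W_rc)
  dh_g <- dhg + sum_mid(dz * wb(ap$W_rg))
  list(dh_i = dh_i, dh_g = dh_g,
       grads = list(W_rg = dW_rg, W_rc = dW_rc, b_rc = db_rc,
                    W_e = dW_e, b_e = db_e))
}
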