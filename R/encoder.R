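#' Multi-kernel convolution cell configuration
#'
#' One cell of the multi-view convolutional encoder: several parallel valid
#' convolutions of different kernel sizes (each with `filters` output maps),
#' ReLU, then non-overlapping max pooling. Outputs of the different kernel
#' sizes are centre-cropped to the shortest spatial extent and stacked along
#' the filter axis, so a cell with `K` kernel sizes emits `K * filters` maps.
#'
#' @param kernels For a 1-D cell, an integer vector of kernel widths; for a
#'   2-D cell, a list of `c(height, width)` pairs.
#' @param filters Output maps per kernel size.
#' @param pool Pool width (1-D) or `c(height, width)` (2-D). A 2-D pool height
#'   of `NA` means "the full remaining channel extent", collapsing the channel
#'   axis (the final global-encoder cell).
#' @return A `cell_config`.
#' @export
cell_config <- function(kernels, filters, pool) {
  two_d <- is.list(kernels)
  if (two_d) {
    stopifnot(all(vapply(kernels, length, 1L) == 2L), length(pool) == 2L)
  } else {
    stopifnot(is.numeric(kernels), all(kernels >= 1), length(pool) == 1L)
  }
  stopifnot(filters >= 1)
  structure(list(kernels = kernels, filters = as.integer(filters),
                 pool = pool, two_d = two_d),
            class = "cell_config")
}

#' Encoder configuration (channel-encoder and global-encoder cell stacks)
#'
#' @param channel_cells List of 1-D [cell_config()]s applied, with shared
#'   weights, to each channel's vector.
#' @param global_cells List of 2-D [cell_config()]s applied to the C x n
#'   channel stack.
#' @param p Dimension of both view representations.
#' @return An `encoder_config`.
#' @export
encoder_config <- function(channel_cells, global_cells, p = 128L) {
  stopifnot(length(channel_cells) >= 1, length(global_cells) >= 1, p >= 1)
  structure(list(channel_cells = channel_cells, global_cells = global_cells,
                 p = as.integer(p)),
            class = "encoder_config")
}

#' Reference encoder configuration
#'
#' The full-size configuration used for clinical-scale inputs (e.g. 23-channel
#' 256 Hz EEG): three channel cells with kernel widths (8,16,32,64)x8,
#' (3,5)x16, (3,5)x16 and pools 6,3,3; three global cells with the matching
#' 2-D kernels and a final full-height x 3 pool collapsing the channel axis.
#'
#' @param p View dimension (default 128).
#' @return An `encoder_config`.
#' @export
encoder_config_default <- function(p = 128L) {
  encoder_config(
    channel_cells = list(
      cell_config(c(8, 16, 32, 64), 8, 6),
      cell_config(c(3, 5), 16, 3),
      cell_config(c(3, 5), 16, 3)),
    global_cells = list(
      cell_config(list(c(1, 8), c(1, 16), c(1, 32), c(1, 64)), 8, c(1, 6)),
      cell_config(list(c(3, 3), c(5, 5)), 16, c(1, 3)),
      cell_config(list(c(3, 3), c(5, 5)), 16, c(NA, 3))),
    p = p)
}

#' Compact encoder configuration for short fragments / few channels
#'
#' A two-cell-per-encoder configuration sized for simulation-scale inputs
#' (e.g. 8 channels x 256 samples): channel cells (8,16)x4 pool 4 and (3,5)x8
#' pool 4; global cells (1x8,1x16)x4 pool 1x4 and (3x3)x8 with a final
#' full-height x 4 pool.
#'
#' @param p View dimension.
#' @return An `encoder_config`.
#' @export
encoder_config_small <- function(p = 32L) {
  encoder_config(
    channel_cells = list(
      cell_config(c(8, 16), 4, 4),
      cell_config(c(3, 5), 8, 4)),
    global_cells = list(
      cell_config(list(c(1, 8), c(1, 16)), 4, c(1, 4)),
      cell_config(list(c(3, 3)), 8, c(NA, 4))),
    p = p)
}

## ---- shape inference ---------------------------------------------------

cell1d_out_shape <- function(M, L, cfg) {
  Ls <- L - cfg$kernels + 1L
  if (any(Ls < 1L)) stop("input length ", L, " shorter than a kernel in cell")
  Lo <- min(Ls) %/% cfg$pool
  if (Lo < 1L) stop("pooling leaves no output in 1-D cell")
  c(M = length(cfg$kernels) * cfg$filters, L = Lo)
}

cell2d_out_shape <- function(M, H, Wd, cfg) {
  khs <- vapply(cfg$kernels, `[`, 1, 1)
  kws <- vapply(cfg$kernels, `[`, 1, 2)
  if (any(H < khs)) stop("channel extent ", H, " smaller than a kernel height")
  if (any(Wd < kws)) stop("input width ", Wd, " smaller than a kernel width")
  Ho <- min(H - khs + 1L); Wo <- min(Wd - kws + 1L)
  ph <- cfg$pool[1]; pw <- cfg$pool[2]
  if (is.na(ph)) ph <- Ho
  Ho <- Ho %/% ph; Wo <- Wo %/% pw
  if (Ho < 1L || Wo < 1L) stop("pooling leaves no output in 2-D cell")
  c(M = length(cfg$kernels) * cfg$filters, H = Ho, W = Wo)
}

## flattened feature length of each encoder for input C x n
encoder_flat_dims <- function(enc, C, n) {
  M <- 1L; L <- n
  for (cell in enc$channel_cells) {
    s <- cell1d_out_shape(M, L, cell); M <- s["M"]; L <- s["L"]
  }
  flat_c <- as.integer(M * L)
  M <- 1L; H <- C; Wd <- n
  for (cell in enc$global_cells) {
    s <- cell2d_out_shape(M, H, Wd, cell)
    M <- s["M"]; H <- s["H"]; Wd <- s["W"]
  }
  list(flat_c = flat_c, flat_g = as.integer(M * H * Wd))
}

## ---- parameter initialisation (uniform fan-in scaling: variance 1/fan_in)

glorot <- function(dims, fan_in, fan_out = NULL) {
  lim <- sqrt(3 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_cell1d <- function(cfg, M) {
  W <- list(); b <- list()
  for (j in seq_along(cfg$kernels)) {
    k <- cfg$kernels[j]
    W[[j]] <- glorot(c(k, M, cfg$filters), k * M, k * cfg$filters)
    b[[j]] <- numeric(cfg$filters)
  }
  list(W = W, b = b)
}

init_cell2d <- function(cfg, M) {
  W <- list(); b <- list()
  for (j in seq_along(cfg$kernels)) {
    kh <- cfg$kernels[[j]][1]; kw <- cfg$kernels[[j]][2]
    W[[j]] <- glorot(c(kh, kw, M, cfg$filters), kh * kw * M, kh * kw * cfg$filters)
    b[[j]] <- numeric(cfg$filters)
  }
  list(W = W, b = b)
}

## ---- multi-kernel cell forward/backward --------------------------------

cell1d_forward <- function(x, cfg, pars) {
  B <- dim(x)[1]
  convs <- lapply(seq_along(cfg$kernels), function(j)
    conv1d_forward(x, pars$W[[j]], pars$b[[j]]))
  Ls <- vapply(convs, function(cv) dim(cv$out)[2], 1L)
  Lmin <- min(Ls)
  crops <- lapply(convs, function(cv) crop1d(cv$out, Lmin))
  Ftot <- cfg$filters * length(cfg$kernels)
  stacked <- array(0, c(B, Lmin, Ftot))
  for (j in seq_along(crops))
    stacked[, , ((j - 1L) * cfg$filters + 1L):(j * cfg$filters)] <- crops[[j]]$out
  act <- relu_forward(stacked)
  pool <- maxpool1d_forward(act$out, cfg$pool)
  list(out = pool$out,
       cache = list(convs = convs, crops = crops, relu = act$cache,
                    pool = pool$cache, cfg = cfg, Lmin = Lmin, B = B))
}

cell1d_backward <- function(dout, cache, need_dx = TRUE) {
  cfg <- cache$cfg
  dact <- maxpool1d_backward(dout, cache$pool)
  dstk <- relu_backward(dact, cache$relu)
  dW <- list(); db <- list(); dx <- NULL
  for (j in seq_along(cfg$kernels)) {
    dcrop <- dstk[, , ((j - 1L) * cfg$filters + 1L):(j * cfg$filters), drop = FALSE]
    cr <- cache$crops[[j]]
    dconv <- array(0, c(cache$B, cr$L, cfg$filters))
    dconv[, (cr$left + 1L):(cr$left + cache$Lmin), ] <- dcrop
    g <- conv1d_backward(dconv, cache$convs[[j]]$cache, need_dx = need_dx)
    dW[[j]] <- g$dW; db[[j]] <- g$db
    if (need_dx) dx <- if (is.null(dx)) g$dx else dx + g$dx
  }
  list(dx = dx, dW = dW, db = db)
}

cell2d_forward <- function(x, cfg, pars) {
  B <- dim(x)[1]
  convs <- lapply(seq_along(cfg$kernels), function(j)
    conv2d_forward(x, pars$W[[j]], pars$b[[j]]))
  Hs <- vapply(convs, function(cv) dim(cv$out)[2], 1L)
  Ws <- vapply(convs, function(cv) dim(cv$out)[3], 1L)
  Hmin <- min(Hs); Wmin <- min(Ws)
  crops <- lapply(convs, function(cv) crop2d(cv$out, Hmin, Wmin))
  Ftot <- cfg$filters * length(cfg$kernels)
  stacked <- array(0, c(B, Hmin, Wmin, Ftot))
  for (j in seq_along(crops))
    stacked[, , , ((j - 1L) * cfg$filters + 1L):(j * cfg$filters)] <- crops[[j]]$out
  act <- relu_forward(stacked)
  ph <- cfg$pool[1]; pw <- cfg$pool[2]
  if (is.na(ph)) ph <- Hmin
  pool <- maxpool2d_forward(act$out, ph, pw)
  list(out = pool$out,
       cache = list(convs = convs, crops = crops, relu = act$cache,
                    pool = pool$cache, cfg = cfg, Hmin = Hmin, Wmin = Wmin, B = B))
}

cell2d_backward <- function(dout, cache, need_dx = TRUE) {
  cfg <- cache$cfg
  dact <- maxpool2d_backward(dout, cache$pool)
  dstk <- relu_backward(dact, cache$relu)
  dW <- list(); db <- list(); dx <- NULL
  for (j in seq_along(cfg$kernels)) {
    dcrop <- dstk[, , , ((j - 1L) * cfg$filters + 1L):(j * cfg$filters), drop = FALSE]
    cr <- cache$crops[[j]]
    dconv <- array(0, c(cache$B, cr$H, cr$W, cfg$filters))
    dconv[, (cr$top + 1L):(cr$top + cache$Hmin),
          (cr$left + 1L):(cr$left + cache$Wmin), ] <- dcrop
    g <- conv2d_backward(dconv, cache$convs[[j]]$cache, need_dx = need_dx)
    dW[[j]] <- g$dW; db[[j]] <- g$db
    if (need_dx) dx <- if (is.null(dx)) g$dx else dx + g$dx
  }
  list(dx = dx, dW = dW, db = db)
}

## ---- full encoder stacks ----------------------------------------------

enc1d_forward <- function(x, cells, pars) {
  caches <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    r <- cell1d_forward(x, cells[[i]], pars[[i]])
    x <- r$out; caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

enc1d_backward <- function(dout, caches) {
  grads <- vector("list", length(caches))
  for (i in rev(seq_along(caches))) {
    g <- cell1d_backward(dout, caches[[i]], need_dx = i > 1L)
    grads[[i]] <- list(dW = g$dW, db = g$db)
    dout <- g$dx
  }
  list(dx = dout, grads = grads)
}

enc2d_forward <- function(x, cells, pars) {
  caches <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    r <- cell2d_forward(x, cells[[i]], pars[[i]])
    x <- r$out; caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

enc2d_backward <- function(dout, caches) {
  grads <- vector("list", length(caches))
  for (i in rev(seq_along(caches))) {
    g <- cell2d_backward(dout, caches[[i]], need_dx = i > 1L)
    grads[[i]] <- list(dW = g$dW, db = g$db)
    dout <- g$dx
  }
  list(dx = dout, grads = grads)
}

## ---- user-facing single-input wrappers ---------------------------------

#' Apply one multi-kernel convolution cell
#'
#' Runs the convolution + ReLU + max-pool cell on a single input: a
#' `maps x length` matrix for a 1-D cell, or a `maps x height x width` array
#' for a 2-D cell.
#'
#' @param x For a 1-D cell, a numeric vector (one map) or a `length x maps`
#'   matrix; for a 2-D cell, a `height x width x maps` array.
#' @param cfg A [cell_config()].
#' @param pars Cell parameters: `list(W = <list of kernel arrays>,
#'   b = <list of bias vectors>)`. 1-D kernels have shape
#'   `(width, in_maps, filters)`; 2-D kernels `(kh, kw, in_maps, filters)`.
#' @return The cell output with the leading batch axis dropped: a
#'   `length_out x maps_out` matrix (1-D) or `h_out x w_out x maps_out` array
#'   (2-D).
#' @export
multikernel_cell <- function(x, cfg, pars) {
  if (cfg$two_d) {
    stopifnot(length(dim(x)) == 3L)
    xb <- array(x, c(1L, dim(x)))
    out <- cell2d_forward(xb, cfg, pars)$out
    array(out, dim(out)[-1])
  } else {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    xb <- array(x, c(1L, dim(x)))
    out <- cell1d_forward(xb, cfg, pars)$out
    array(out, dim(out)[-1])
  }
}

#' Encode one channel's vector into its channel-view representation
#'
#' Applies the shared-weight channel-encoder (the stacked 1-D multi-kernel
#' cells, flatten, then an affine projection with ReLU) to a single channel
#' vector, yielding the p-dimensional channel view h_i. The same parameters
#' are used for every channel index, so identical inputs give identical views.
#'
#' @param x_i Numeric vector of length n.
#' @param model A fitted or initialised [fusionatt_model()].
#' @return Numeric vector of length p.
#' @export
channel_encode <- function(x_i, model) {
  stopifnot(is.numeric(x_i))
  xb <- array(x_i, c(1L, length(x_i), 1L))
  enc <- enc1d_forward(xb, model$enc$channel_cells, model$params$channel)
  flat <- matrix(enc$out, 1L)
  proj <- dense_forward(flat, model$params$proj_c$W, model$params$proj_c$b)
  as.numeric(pmax(proj$out, 0))
}

#' Encode the full channel stack into the global-view representation
#'
#' Applies the global-encoder (stacked 2-D multi-kernel cells over the C x n
#' channel stack, flatten, affine projection with ReLU), yielding the
#' p-dimensional global view h_g.
#'
#' @param X C x n numeric matrix.
#' @param model A [fusionatt_model()].
#' @return Numeric vector of length p.
#' @export
global_encode <- function(X, model) {
  stopifnot(is.matrix(X))
  xb <- array(X, c(1L, dim(X), 1L))
  enc <- enc2d_forward(xb, model$enc$global_cells, model$params$global)
  flat <- matrix(enc$out, 1L)
  proj <- dense_forward(flat, model$params$proj_g$W, model$params$proj_g$b)
  as.numeric(pmax(proj$out, 0))
}
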