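#' Construct a FusionAtt model (or one of its simplified baselines)
#'
#' Builds the unified network: multi-view convolutional encoders, the fusional
#' attention layer, the attentional-representation head and the softmax
#' classifier, with freshly initialised parameters (uniform fan-scaled,
#' seeded). The channel-encoder weights are shared across channels by default.
#'
#' @param C Number of input channels.
#' @param n Samples (or features) per channel per fragment.
#' @param n_classes Number of classes (>= 2).
#' @param encoder An [encoder_config()]; defaults to the compact
#'   configuration with p = 32.
#' @param r Dimension of the attentional representation (default: p).
#' @param kind One of `"fusionatt"` (gated fusion attention), `"gcnn"`
#'   (global encoder only, no attention), `"mcnn"` (multi-view, unweighted
#'   channel mean, no attention), `"channelatt_local"` (attention energies
#'   from the channel views alone) or `"channelatt_global"` (energies from the
#'   channel view concatenated with the global view).
#' @param vector_gate If `TRUE`, the fusion gate is a length-p vector applied
#'   elementwise instead of a scalar per channel.
#' @param dropout Dropout rate used during training, applied to the flattened
#'   encoder outputs before projection and to the attentional representation.
#' @param per_channel_encoder If `TRUE`, each channel gets its own
#'   channel-encoder parameters instead of the default shared set.
#' @param seed Integer seed for parameter initialisation.
#' @return A `fusionatt_model` object.
#' @export
fusionatt_model <- function(C, n, n_classes,
                            encoder = encoder_config_small(32L),
                            r = encoder$p,
                            kind = c("fusionatt", "gcnn", "mcnn",
                                     "channelatt_local", "channelatt_global"),
                            vector_gate = FALSE,
                            dropout = 0.5,
                            per_channel_encoder = FALSE,
                            seed = 1L) {
  kind <- match.arg(kind)
  C <- as.integer(C); n <- as.integer(n); n_classes <- as.integer(n_classes)
  r <- as.integer(r)
  stopifnot(C >= 1, n >= 2, n_classes >= 2, r >= 1,
            dropout >= 0, dropout < 1)
  p <- encoder$p
  flat <- encoder_flat_dims(encoder, C, n)
  set.seed(as.integer(seed))
  params <- list()
  if (kind != "gcnn") {
    n_enc <- if (per_channel_encoder) C else 1L
    mk_channel <- function() {
      M <- 1L; prs <- list()
      for (i in seq_along(encoder$channel_cells)) {
        cfg <- encoder$channel_cells[[i]]
        prs[[i]] <- init_cell1d(cfg, M)
        M <- length(cfg$kernels) * cfg$filters
      }
      prs
    }
    if (per_channel_encoder) {
      params$channel_per <- lapply(seq_len(C), function(i) mk_channel())
    } else {
      params$channel <- mk_channel()
    }
    params$proj_c <- list(W = glorot(c(p, flat$flat_c), flat$flat_c, p),
                          b = numeric(p))
  }
  M <- 1L
  params$global <- list()
  for (i in seq_along(encoder$global_cells)) {
    cfg <- encoder$global_cells[[i]]
    params$global[[i]] <- init_cell2d(cfg, M)
    M <- length(cfg$kernels) * cfg$filters
  }
  params$proj_g <- list(W = glorot(c(p, flat$flat_g), flat$flat_g, p),
                        b = numeric(p))
  if (kind == "fusionatt") {
    glen <- if (vector_gate) p else 1L
    params$attn <- list(
      W_rg = as.numeric(glorot(p, p, 1)),
      W_rc = as.numeric(glorot(p, p, 1)),
      b_rc = numeric(glen),
      W_e = as.numeric(glorot(p, p, 1)),
      b_e = 0)
    if (!vector_gate) params$attn$b_rc <- 0
  } else if (kind == "channelatt_local") {
    params$attn <- list(W_e = as.numeric(glorot(p, p, 1)), b_e = 0)
  } else if (kind == "channelatt_global") {
    params$attn <- list(W_e = as.numeric(glorot(2 * p, 2 * p, 1)), b_e = 0)
  }
  head_in <- if (kind == "gcnn") p else 2L * p
  params$head <- list(
    W_h = glorot(c(r, head_in), head_in, r), b_h = numeric(r),
    W_s = glorot(c(n_classes, r), r, n_classes), b_s = numeric(n_classes))
  structure(list(C = C, n = n, n_classes = n_classes, p = p, r = r,
                 kind = kind, vector_gate = vector_gate, dropout = dropout,
                 per_channel_encoder = per_channel_encoder,
                 enc = encoder, params = params, seed = as.integer(seed)),
            class = "fusionatt_model")
}

#' @export
print.fusionatt_model <- function(x, ...) {
  np <- sum(vapply(param_paths(x$params),
                   function(p) length(get_leaf(x$params, p)), 1))
  cat(sprintf("%s model: C=%d, n=%d, p=%d, r=%d, %d classes, %d parameters\n",
              x$kind, x$C, x$n, x$p, x$r, x$n_classes, as.integer(np)))
  invisible(x)
}

## ---- batched forward pass ----------------------------------------------
## X: (B, C, n). training toggles dropout. Returns logits, probs, alpha and
## the cache needed for the backward pass.

model_forward <- function(model, X, training = FALSE) {
  B <- dim(X)[1]; C <- model$C; n <- model$n; p <- model$p
  stopifnot(dim(X)[2] == C, dim(X)[3] == n)
  kind <- model$kind
  cache <- list(B = B, training = training)

  ## channel views
  h_i <- NULL
  if (kind != "gcnn") {
    if (model$per_channel_encoder) {
      enc_out <- vector("list", C); enc_cache <- vector("list", C)
      for (i in seq_len(C)) {
        xi <- array(X[, i, , drop = FALSE], c(B, n, 1L))
        e <- enc1d_forward(xi, model$enc$channel_cells,
                           model$params$channel_per[[i]])
        enc_out[[i]] <- matrix(e$out, B)
        enc_cache[[i]] <- e$caches
      }
      ## rbind stacks channel blocks: row (c-1)*B + b, i.e. b-fastest over
      ## (b, c) — the same layout the shared path produces
      flat_c <- do.call(rbind, enc_out)
      cache$enc_c_per <- enc_cache
    } else {
      xc <- array(X, c(B * C, n, 1L))            # (b, c) with b fastest
      e <- enc1d_forward(xc, model$enc$channel_cells, model$params$channel)
      cache$enc_c <- e$caches
      flat_c <- matrix(e$out, B * C)
    }
    dc <- dropout_forward(flat_c, model$dropout, training)
    cache$drop_c <- dc$cache
    pc <- dense_forward(dc$out, model$params$proj_c$W, model$params$proj_c$b)
    cache$proj_c <- pc$cache
    rc <- relu_forward(pc$out)
    cache$relu_c <- rc$cache
    h_i <- array(rc$out, c(B, C, p))
  }

  ## global view
  xg <- array(X, c(B, C, n, 1L))
  eg <- enc2d_forward(xg, model$enc$global_cells, model$params$global)
  cache$enc_g <- eg$caches
  flat_g <- matrix(eg$out, B)
  dg <- dropout_forward(flat_g, model$dropout, training)
  cache$drop_g <- dg$cache
  pg <- dense_forward(dg$out, model$params$proj_g$W, model$params$proj_g$b)
  cache$proj_g <- pg$cache
  rg <- relu_forward(pg$out)
  cache$relu_g <- rg$cache
  h_g <- rg$out                                   # (B, p)

  ## attention / aggregation
  alpha <- NULL; r_gate <- NULL; fused <- NULL; ctx <- NULL
  if (kind == "fusionatt") {
    att <- if (model$vector_gate) attention_forward_vec(h_i, h_g, model$params$attn)
           else attention_forward(h_i, h_g, model$params$attn)
    alpha <- att$alpha; r_gate <- att$r; fused <- att$fused; ctx <- att$ctx
    cache$att <- att$cache
    head_in <- cbind(ctx, h_g)
  } else if (kind %in% c("channelatt_local", "channelatt_global")) {
    ap <- model$params$attn
    hi_mat <- matrix(h_i, B * C, p)
    if (kind == "channelatt_local") {
      e_att <- matrix(hi_mat %*% ap$W_e, B, C) + ap$b_e
    } else {
      w1 <- ap$W_e[1:p]; w2 <- ap$W_e[(p + 1):(2 * p)]
      e_att <- matrix(hi_mat %*% w1, B, C) +
        as.numeric(h_g %*% w2) + ap$b_e
    }
    alpha <- softmax_rows(e_att)
    fused <- h_i
    ab <- array(rep(alpha, times = p), c(B, C, p))
    ctx <- sum_mid(ab * h_i)
    cache$att <- list(h_i = h_i, h_g = h_g, alpha = alpha, dims = c(B, C, p))
    head_in <- cbind(ctx, h_g)
  } else if (kind == "mcnn") {
    ctx <- sum_mid(h_i) / C
    alpha <- matrix(1 / C, B, C)
    head_in <- cbind(ctx, h_g)
  } else {                                        # gcnn
    head_in <- h_g
  }
  cache$head_in <- head_in

  ## attentional representation + classifier
  hh <- dense_forward(head_in, model$params$head$W_h, model$params$head$b_h)
  cache$head_dense <- hh$cache
  ha <- relu_forward(hh$out)
  cache$relu_h <- ha$cache
  dh <- dropout_forward(ha$out, model$dropout, training)
  cache$drop_h <- dh$cache
  h_alpha <- dh$out
  lg <- dense_forward(h_alpha, model$params$head$W_s, model$params$head$b_s)
  cache$cls_dense <- lg$cache
  logits <- lg$out
  list(logits = logits, probs = softmax_rows(logits),
       h_i = h_i, h_g = h_g, r = r_gate, fused = fused, alpha = alpha,
       ctx = ctx, h_alpha = h_alpha, cache = cache)
}

## ---- backward pass ------------------------------------------------------
## dlogits: (B, K). Returns a gradient tree mirroring model$params.

model_backward <- function(model, fwd, dlogits) {
  cache <- fwd$cache
  B <- cache$B; C <- model$C; p <- model$p
  kind <- model$kind
  grads <- list()

  g_cls <- dense_backward(dlogits, cache$cls_dense)
  grads$head <- list(W_s = g_cls$dW, b_s = g_cls$db)
  dha <- dropout_backward(g_cls$dx, cache$drop_h)
  dhh <- relu_backward(dha, cache$relu_h)
  g_head <- dense_backward(dhh, cache$head_dense)
  grads$head$W_h <- g_head$dW
  grads$head$b_h <- g_head$db
  dhead_in <- g_head$dx

  dh_i <- NULL
  if (kind == "gcnn") {
    dh_g <- dhead_in
  } else {
    dctx <- dhead_in[, 1:p, drop = FALSE]
    dh_g <- dhead_in[, (p + 1):(2 * p), drop = FALSE]
    if (kind == "fusionatt") {
      ab <- if (model$vector_gate)
        attention_backward_vec(dctx, cache$att, model$params$attn)
      else attention_backward(dctx, cache$att, model$params$attn)
      dh_i <- ab$dh_i
      dh_g <- dh_g + ab$dh_g
      grads$attn <- ab$grads
    } else if (kind %in% c("channelatt_local", "channelatt_global")) {
      att <- cache$att
      alpha <- att$alpha; h_i <- att$h_i
      dctx_b <- aperm(array(dctx, c(B, p, C)), c(1, 3, 2))
      ab_ <- array(rep(alpha, times = p), c(B, C, p))
      dh_i <- ab_ * dctx_b
      dalpha <- sum_last(h_i * dctx_b)
      s <- rowSums(alpha * dalpha)
      de <- alpha * (dalpha - s)
      de_flat <- as.numeric(matrix(de, B * C, 1))
      hi_mat <- matrix(h_i, B * C, p)
      ap <- model$params$attn
      if (kind == "channelatt_local") {
        grads$attn <- list(W_e = as.numeric(crossprod(hi_mat, de_flat)),
                           b_e = sum(de))
        dh_i <- dh_i + array(outer(de_flat, ap$W_e), c(B, C, p))
      } else {
        w1 <- ap$W_e[1:p]; w2 <- ap$W_e[(p + 1):(2 * p)]
        dW1 <- as.numeric(crossprod(hi_mat, de_flat))
        dW2 <- as.numeric(crossprod(att$h_g, rowSums(de)))
        grads$attn <- list(W_e = c(dW1, dW2), b_e = sum(de))
        dh_i <- dh_i + array(outer(de_flat, w1), c(B, C, p))
        dh_g <- dh_g + outer(rowSums(de), w2)
      }
    } else if (kind == "mcnn") {
      dh_i <- aperm(array(dctx / C, c(B, p, C)), c(1, 3, 2))
    }
  }

  ## global encoder
  drg <- relu_backward(dh_g, cache$relu_g)
  g_pg <- dense_backward(drg, cache$proj_g)
  grads$proj_g <- list(W = g_pg$dW, b = g_pg$db)
  dflat_g <- dropout_backward(g_pg$dx, cache$drop_g)
  top_g <- cache$enc_g[[length(cache$enc_g)]]
  last_out_g <- c(B, dim_of_pool2(top_g$pool))
  dout_g <- array(dflat_g, last_out_g)
  eg <- enc2d_backward(dout_g, cache$enc_g)
  grads$global <- lapply(eg$grads, function(g) list(W = g$dW, b = g$db))

  ## channel encoder
  if (kind != "gcnn") {
    dflat_hi <- matrix(dh_i, B * C, p)
    drc <- relu_backward(dflat_hi, cache$relu_c)
    g_pc <- dense_backward(drc, cache$proj_c)
    grads$proj_c <- list(W = g_pc$dW, b = g_pc$db)
    dflat_c <- dropout_backward(g_pc$dx, cache$drop_c)
    if (model$per_channel_encoder) {
      grads$channel_per <- vector("list", C)
      for (i in seq_len(C)) {
        caches_i <- cache$enc_c_per[[i]]
        top_c <- caches_i[[length(caches_i)]]
        rows <- (i - 1L) * B + seq_len(B)
        dout_i <- array(dflat_c[rows, , drop = FALSE],
                        c(B, dim_of_pool1(top_c$pool)))
        ec <- enc1d_backward(dout_i, caches_i)
        grads$channel_per[[i]] <-
          lapply(ec$grads, function(g) list(W = g$dW, b = g$db))
      }
    } else {
      top_c <- cache$enc_c[[length(cache$enc_c)]]
      last_out_c <- c(B * C, dim_of_pool1(top_c$pool))
      dout_c <- array(dflat_c, last_out_c)
      ec <- enc1d_backward(dout_c, cache$enc_c)
      grads$channel <- lapply(ec$grads, function(g) list(W = g$dW, b = g$db))
    }
  }
  grads
}

## output spatial dims recorded in pooling caches (layout: spatial, maps)
dim_of_pool1 <- function(pc) c(pc$dims[4], pc$dims[3])             # (Lo, M)
dim_of_pool2 <- function(pc) c(pc$dims[5], pc$dims[6], pc$dims[4]) # (Ho, Wo, M)

## ---- loss ---------------------------------------------------------------

#' Cross-entropy loss with optional L2 penalty
#'
#' Mean categorical cross-entropy computed from logits via log-sum-exp (so a
#' predicted probability of zero cannot produce a non-finite loss), plus
#' `l2 * sum(w^2)` over the model's weight matrices and kernels (biases are
#' not penalised). For two classes this reduces to the familiar binary form
#' `-(1/M) * sum(y log yhat + (1 - y) log(1 - yhat))`.
#'
#' @param logits B x K matrix of unnormalised scores.
#' @param labels Length-B integer vector of 1-based class labels.
#' @param model Optional `fusionatt_model` whose weights enter the L2 term.
#' @param l2 L2 penalty coefficient.
#' @return Scalar loss.
#' @export
model_loss <- function(logits, labels, model = NULL, l2 = 0) {
  stopifnot(nrow(logits) == length(labels), nrow(logits) >= 1)
  mx <- apply(logits, 1, max)
  lse <- log(rowSums(exp(logits - mx))) + mx
  ce <- mean(lse - logits[cbind(seq_along(labels), labels)])
  pen <- if (l2 > 0 && !is.null(model)) l2 * l2_penalty(model$params) else 0
  ce + pen
}

## gradient of the mean cross-entropy w.r.t. logits
ce_dlogits <- function(logits, labels) {
  probs <- softmax_rows(logits)
  B <- nrow(logits)
  probs[cbind(seq_len(B), labels)] <- probs[cbind(seq_len(B), labels)] - 1
  probs / B
}

## ---- user-facing head ops ----------------------------------------------

#' Attentional representation from context and global views
#'
#' `h_alpha = ReLU(W_h [c_g (+) h_g] + b_h)`, the joint representation fed to
#' the softmax classifier ((+) is concatenation). Dropout is applied here only
#' during training, never in this evaluation-mode helper.
#'
#' @param c_g Context vector (length p).
#' @param h_g Global view (length p).
#' @param model A `fusionatt_model`.
#' @return Numeric vector of length r.
#' @export
attentional_representation <- function(c_g, h_g, model) {
  stopifnot(length(c_g) == model$p, length(h_g) == model$p)
  z <- model$params$head$W_h %*% c(c_g, h_g) + model$params$head$b_h
  as.numeric(pmax(z, 0))
}

#' Class probabilities from an attentional representation
#'
#' Applies the softmax classifier to `h_alpha`; the predicted label is the
#' argmax with lowest-index tie-break.
#'
#' @param h_alpha Attentional representation (length r).
#' @param model A `fusionatt_model`.
#' @return List with `probs` (simplex vector) and `label` (1-based).
#' @export
classify_representation <- function(h_alpha, model) {
  stopifnot(length(h_alpha) == model$r)
  z <- as.numeric(model$params$head$W_s %*% h_alpha + model$params$head$b_s)
  probs <- contribution_scores(z)     # same stabilised softmax
  list(probs = probs, label = which.max(probs))
}

#' Predict labels, probabilities and contribution scores for fragments
#'
#' Evaluation-mode forward pass (dropout off, deterministic) over a
#' `fragment_set` or a plain `(N, C, n)` array.
#'
#' @param object A `fusionatt_model`.
#' @param fragments A `fragment_set` or numeric array `(N, C, n)`.
#' @param batch_size Fragments per forward chunk.
#' @param ... Unused.
#' @return List with `probs` (N x K), `label` (length N, 1-based argmax,
#'   lowest index on ties) and `alpha` (N x C contribution scores; uniform
#'   for kinds without attention).
#' @export
predict.fusionatt_model <- function(object, fragments, batch_size = 128L, ...) {
  X <- if (inherits(fragments, "fragment_set")) fragments_to_array(fragments)
       else fragments
  N <- dim(X)[1]
  probs <- matrix(0, N, object$n_classes)
  alpha <- matrix(1 / object$C, N, object$C)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fw <- model_forward(object, X[idx, , , drop = FALSE], training = FALSE)
    probs[idx, ] <- fw$probs
    if (!is.null(fw$alpha)) {
      a <- fw$alpha
      if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
      alpha[idx, ] <- a
    }
  }
  label <- max.col(probs, ties.method = "first")
  list(probs = probs, label = label, alpha = alpha)
}

fragments_to_array <- function(fs) {
  N <- length(fs$fragments)
  d <- dim(fs$fragments[[1]])
  X <- array(0, c(N, d[1], d[2]))
  for (i in seq_len(N)) X[i, , ] <- fs$fragments[[i]]
  X
}
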