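#' Training configuration
#'
#' The optimisation protocol: Adadelta (decay constant rho = 0.95, matching
#' the reference setting) with an L2 weight-decay coefficient of 0.001 and
#' dropout rate 0.5. A plain SGD-with-momentum option is provided for
#' ablation. Early stopping monitors the validation loss.
#'
#' @param optimizer `"adadelta"` (default) or `"sgd_momentum"`.
#' @param decay_rho Adadelta decay constant (or SGD momentum coefficient).
#' @param weight_decay L2 penalty coefficient on weights (biases excluded).
#' @param dropout_rate Dropout rate during training.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping; the best-validation parameters are restored.
#' @param lr Learning-rate multiplier (Adadelta is typically run at 1).
#' @param eps Adadelta numerical stabiliser.
#' @param seed Seed for shuffling and dropout; training is deterministic for
#'   a fixed seed on a single thread.
#' @return A `train_config`.
#' @export
train_config <- function(optimizer = c("adadelta", "sgd_momentum"),
                         decay_rho = 0.95,
                         weight_decay = 0.001,
                         dropout_rate = 0.5,
                         batch_size = 64L,
                         max_epochs = 100L,
                         early_stop_patience = 10L,
                         lr = 1,
                         eps = 1e-6,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(decay_rho >= 0, decay_rho < 1, weight_decay >= 0,
            dropout_rate >= 0, dropout_rate < 1, batch_size >= 1,
            max_epochs >= 1, lr > 0)
  structure(list(optimizer = optimizer, decay_rho = decay_rho,
                 weight_decay = weight_decay, dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr = lr, eps = eps, seed = as.integer(seed)),
            class = "train_config")
}

## one optimiser step; state is an environment holding per-leaf accumulators
optim_step <- function(params, grads, tc, state) {
  for (path in state$paths) {
    key <- path_key(path)
    w <- get_leaf(params, path)
    g <- get_leaf(grads, path)
    if (tc$weight_decay > 0 && is_weight_path(path))
      g <- g + 2 * tc$weight_decay * w
    if (tc$optimizer == "adadelta") {
      Eg <- state$Eg[[key]] %||% (g * 0)
      Ed <- state$Ed[[key]] %||% (g * 0)
      Eg <- tc$decay_rho * Eg + (1 - tc$decay_rho) * g^2
      delta <- -tc$lr * sqrt(Ed + tc$eps) / sqrt(Eg + tc$eps) * g
      Ed <- tc$decay_rho * Ed + (1 - tc$decay_rho) * delta^2
      state$Eg[[key]] <- Eg
      state$Ed[[key]] <- Ed
      w <- w + delta
    } else {
      v <- state$V[[key]] %||% (g * 0)
      v <- tc$decay_rho * v - tc$lr * g
      state$V[[key]] <- v
      w <- w + v
    }
    params <- set_leaf(params, path, w)
  }
  params
}

#' Train a model end-to-end
#'
#' Minimises the cross-entropy + L2 objective over mini-batches with Adadelta
#' (or SGD with momentum), with dropout during training and early stopping on
#' the validation loss. Train and validation sets must come from disjoint
#' subjects (checked). Deterministic for a fixed seed on a single thread.
#'
#' @param model A freshly built [fusionatt_model()].
#' @param train_fs,val_fs `fragment_set`s for training and validation.
#' @param tc A [train_config()].
#' @param verbose If `TRUE`, logs one line per epoch to stderr.
#' @return The trained model, with a `history` data frame attached
#'   (`epoch`, `train_loss`, `val_loss`, `val_acc`) and `best_epoch`.
#' @export
train_model <- function(model, train_fs, val_fs, tc = train_config(),
                        verbose = FALSE) {
  if (length(intersect(unique(train_fs$subject), unique(val_fs$subject))) > 0)
    stop("train and validation sets share subjects")
  model$dropout <- tc$dropout_rate
  Xtr <- fragments_to_array(train_fs); ytr <- train_fs$label
  Xva <- fragments_to_array(val_fs);  yva <- val_fs$label
  N <- dim(Xtr)[1]
  state <- new.env(parent = emptyenv())
  state$paths <- param_paths(model$params)
  state$Eg <- list(); state$Ed <- list(); state$V <- list()
  set.seed(tc$seed)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  wait <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample.int(N)
    tr_loss <- 0; nb <- 0L
    for (start in seq(1L, N, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, N)]
      fw <- model_forward(model, Xtr[idx, , , drop = FALSE], training = TRUE)
      J <- model_loss(fw$logits, ytr[idx], model, tc$weight_decay)
      if (!is.finite(J))
        stop("non-finite loss at epoch ", epoch, ", batch starting ", start)
      dlog <- ce_dlogits(fw$logits, ytr[idx])
      grads <- model_backward(model, fw, dlog)
      model$params <- optim_step(model$params, grads, tc, state)
      tr_loss <- tr_loss + J; nb <- nb + 1L
    }
    ev <- eval_loss_acc(model, Xva, yva, tc)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val_acc %.3f",
                      epoch, tr_loss / nb, ev$loss, ev$acc))
    if (ev$loss < best$loss - 1e-8) {
      best <- list(loss = ev$loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

eval_loss_acc <- function(model, X, y, tc, chunk = 256L) {
  N <- dim(X)[1]
  loss_sum <- 0; correct <- 0L
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    fw <- model_forward(model, X[idx, , , drop = FALSE], training = FALSE)
    mx <- apply(fw$logits, 1, max)
    lse <- log(rowSums(exp(fw$logits - mx))) + mx
    loss_sum <- loss_sum + sum(lse - fw$logits[cbind(seq_along(idx), y[idx])])
    correct <- correct + sum(max.col(fw$probs, ties.method = "first") == y[idx])
  }
  list(loss = loss_sum / N + tc$weight_decay * l2_penalty(model$params),
       acc = correct / N)
}

#' Contribution-score report over consecutive fragments
#'
#' Averages the per-channel contribution scores over groups of `group`
#' consecutive fragments ("timestamps") and flags the channel with the
#' maximal mean score in each group (lowest index on ties) — the tabular
#' analogue of plotting mean scores of every few fragments with the most
#' active channel marked.
#'
#' @param model A trained `fusionatt_model`.
#' @param fs A `fragment_set`, ordered by `fragment_index`.
#' @param group Fragments per timestamp (default 5).
#' @param path Optional CSV output path.
#' @return Data frame with columns `timestamp`, `channel`, `mean_score`,
#'   `is_max`, `n_fragments`, `label` (majority label in the group). A final
#'   partial group is kept and flagged by its smaller `n_fragments`.
#' @export
export_contribution_scores <- function(model, fs, group = 5L, path = NULL) {
  stopifnot(group >= 1)
  ord <- order(fs$subject, fs$fragment_index)
  fs <- fragment_subset(fs, ord)
  pr <- predict(model, fs)
  N <- nrow(pr$alpha); C <- ncol(pr$alpha)
  gid <- (seq_len(N) - 1L) %/% group + 1L
  rows <- lapply(unique(gid), function(g) {
    sel <- gid == g
    m <- colMeans(pr$alpha[sel, , drop = FALSE])
    lab <- as.integer(names(sort(table(fs$label[sel]), decreasing = TRUE))[1])
    data.frame(timestamp = g, channel = seq_len(C), mean_score = m,
               is_max = seq_len(C) == which.max(m),
               n_fragments = sum(sel), label = lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
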