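#' Subject-independent cross-validation
#'
#' Trains one model per fold (fresh seed-derived initialisation each fold) on
#' the fold's training subjects, early-stops on its validation subjects, and
#' evaluates on its test subjects. The summary averages the per-fold metrics
#' arithmetically; the pooled test scores across folds are also returned so
#' aggregate ROC/PR curves can be exported.
#'
#' @param fs A `fragment_set`.
#' @param folds Fold list from [make_subject_folds()].
#' @param builder `function(seed)` returning a fresh [fusionatt_model()]
#'   sized for `fs`.
#' @param tc A [train_config()]; each fold trains with `tc$seed + fold_id`.
#' @param verbose Log per-epoch progress.
#' @return List with `per_fold` (data frame of fold metrics), `average`
#'   (named numeric vector), `pooled` (list: `probs`, `labels`, and a pooled
#'   `fa_metrics`), and `models` (the trained per-fold models).
#' @export
cross_validate <- function(fs, folds, builder, tc = train_config(),
                           verbose = FALSE) {
  per <- list(); pooled_probs <- list(); pooled_labels <- list()
  models <- list()
  for (fold in folds) {
    f <- fold$fold_id
    tr <- fragment_subset(fs, fs$subject %in% fold$train_subjects)
    va <- fragment_subset(fs, fs$subject %in% fold$val_subjects)
    te <- fragment_subset(fs, fs$subject %in% fold$test_subjects)
    model <- builder(tc$seed + f)
    tc_f <- tc; tc_f$seed <- tc$seed + 1000L * f
    model <- train_model(model, tr, va, tc_f, verbose = verbose)
    pr <- predict(model, te)
    m <- compute_metrics(pr$probs, te$label)
    per[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                           f1_macro = m$f1_macro,
                           auc_roc_macro = m$auc_roc_macro,
                           auc_pr_macro = m$auc_pr_macro, n_test = m$n_test)
    pooled_probs[[f]] <- pr$probs
    pooled_labels[[f]] <- te$label
    models[[f]] <- model
  }
  per <- do.call(rbind, per)
  avg <- colMeans(per[, c("accuracy", "f1_macro", "auc_roc_macro",
                          "auc_pr_macro")])
  probs_all <- do.call(rbind, pooled_probs)
  labels_all <- unlist(pooled_labels)
  list(per_fold = per, average = avg,
       pooled = list(probs = probs_all, labels = labels_all,
                     metrics = compute_metrics(probs_all, labels_all)),
       models = models)
}

#' Sensitivity sweep over a representation dimension
#'
#' Re-runs cross-validation varying one capacity hyper-parameter — the view
#' dimension `p` or the attentional-representation dimension `r` — while all
#' other settings stay at the basic configuration, and tabulates the
#' cross-validated accuracy per value.
#'
#' @param fs A `fragment_set`.
#' @param folds Fold list from [make_subject_folds()].
#' @param param `"p"` or `"r"`.
#' @param values Positive integer values to sweep.
#' @param builder `function(p, r, seed)` returning a fresh model at the given
#'   dimensions (the basic configuration supplies whichever of p/r is not
#'   swept).
#' @param base_p,base_r The basic-configuration dimensions.
#' @param tc A [train_config()].
#' @param path Optional CSV output path for the tidy table.
#' @return Data frame with columns `param`, `value`, `accuracy`, `f1_macro`,
#'   `auc_roc_macro`, `auc_pr_macro`.
#' @export
sensitivity_sweep <- function(fs, folds, param = c("p", "r"), values,
                              builder, base_p = 128L, base_r = 128L,
                              tc = train_config(), path = NULL) {
  param <- match.arg(param)
  stopifnot(all(values >= 1))
  rows <- lapply(values, function(v) {
    p <- if (param == "p") as.integer(v) else base_p
    r <- if (param == "r") as.integer(v) else base_r
    cv <- cross_validate(fs, folds, function(seed) builder(p, r, seed), tc)
    data.frame(param = param, value = v,
               accuracy = cv$average[["accuracy"]],
               f1_macro = cv$average[["f1_macro"]],
               auc_roc_macro = cv$average[["auc_roc_macro"]],
               auc_pr_macro = cv$average[["auc_pr_macro"]])
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Build a simplified comparator model
#'
#' Constructs one of the in-repo baselines sharing FusionAtt's encoders, head
#' and training protocol: `"gcnn"` (global encoder only), `"mcnn"`
#' (multi-view, unweighted mean of channel views concatenated with the global
#' view), `"channelatt_local"` (attention energies from each channel view
#' alone) or `"channelatt_global"` (energies from the channel view
#' concatenated with the global view). The two channel-attention variants are
#' approximations supporting qualitative ordering comparisons, not faithful
#' reimplementations of the original models.
#'
#' @param kind Baseline kind.
#' @param C,n,n_classes,encoder,r,dropout,seed As in [fusionatt_model()].
#' @return A `fusionatt_model` of the requested kind.
#' @export
build_baseline <- function(kind = c("gcnn", "mcnn", "channelatt_local",
                                    "channelatt_global"),
                           C, n, n_classes,
                           encoder = encoder_config_small(32L),
                           r = encoder$p, dropout = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  fusionatt_model(C, n, n_classes, encoder = encoder, r = r, kind = kind,
                  dropout = dropout, seed = seed)
}
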