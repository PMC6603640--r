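#' Simulation configuration for synthetic multi-channel signal datasets
#'
#' Describes a ground-truthed multi-channel dataset: a Gaussian (or 1/f) noise
#' background on every channel, plus class-dependent band-limited oscillatory
#' bursts confined to a known informative channel subset. Because the
#' informative channels are known by construction, attention-based channel
#' recovery can be tested against ground truth.
#'
#' Class 1 is the background class and carries no burst. Every class
#' `k >= 2` must name a non-empty set of informative channels on which its
#' burst is placed. Channel indices are 1-based.
#'
#' @param n_channels Number of channels C.
#' @param fragment_len Samples per fragment n.
#' @param sample_rate Sampling rate in Hz.
#' @param n_classes Number of classes (>= 2); class 1 is background.
#' @param informative_channels Named list mapping class index (as character,
#'   e.g. `"2"`) to an integer vector of 1-based channel indices.
#' @param burst_freq Burst frequency in Hz; either a single value used for all
#'   non-background classes or one value per class `2..n_classes`.
#' @param snr_db Per-channel burst-to-noise power ratio in decibels, measured
#'   over the burst's own support. `-Inf` yields zero-amplitude bursts.
#' @param n_subjects Number of subjects.
#' @param fragments_per_subject Fragments recorded per subject (>= 1).
#' @param subject_scale_sd Standard deviation (log scale) of the per-subject
#'   multiplicative amplitude factor `exp(N(0, sd^2))`, applied to the whole
#'   fragment (noise and burst alike, so the within-fragment SNR is preserved).
#' @param noise Noise model: `"white"` (default) or `"pink"` (1/f).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration including the seed.
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_channels = 4, fragment_len = 128, n_subjects = 2,
#'                   fragments_per_subject = 4,
#'                   informative_channels = list("2" = c(1, 2)))
sim_config <- function(n_channels = 8,
                       fragment_len = 256,
                       sample_rate = 64,
                       n_classes = 2,
                       informative_channels = list("2" = c(3, 4)),
                       burst_freq = 8,
                       snr_db = 10,
                       n_subjects = 10,
                       fragments_per_subject = 50,
                       subject_scale_sd = 0.1,
                       noise = c("white", "pink"),
                       seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_channels >= 1, fragment_len >= 2, sample_rate > 0,
            fragments_per_subject >= 1, n_subjects >= 1,
            is.finite(subject_scale_sd), subject_scale_sd >= 0)
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(burst_freq) == 1L) burst_freq <- rep(burst_freq, n_classes - 1L)
  if (length(burst_freq) != n_classes - 1L)
    stop("burst_freq must have length 1 or n_classes - 1")
  if (!is.finite(snr_db) && snr_db > 0)
    stop("snr_db = +Inf yields non-finite burst scaling")
  for (k in 2:n_classes) {
    ch <- informative_channels[[as.character(k)]]
    if (is.null(ch) || length(ch) == 0L)
      stop("class ", k, " has an empty informative channel set")
    if (any(ch < 1L | ch > n_channels))
      stop("informative channel index out of [1, ", n_channels, "] for class ", k)
  }
  structure(list(
    n_channels = as.integer(n_channels),
    fragment_len = as.integer(fragment_len),
    sample_rate = sample_rate,
    n_classes = as.integer(n_classes),
    informative_channels = informative_channels,
    burst_freq = burst_freq,
    snr_db = snr_db,
    n_subjects = as.integer(n_subjects),
    fragments_per_subject = as.integer(fragments_per_subject),
    subject_scale_sd = subject_scale_sd,
    noise = noise,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: C=%d, n=%d @ %g Hz, %d classes, %d subjects x %d fragments, SNR %g dB (%s noise)\n",
              x$n_channels, x$fragment_len, x$sample_rate, x$n_classes,
              x$n_subjects, x$fragments_per_subject, x$snr_db, x$noise))
  invisible(x)
}

## one fragment of background noise, C x n, unit variance per channel
sim_noise <- function(C, n, kind) {
  x <- matrix(stats::rnorm(C * n), C, n)
  if (kind == "pink") {
    # shape the spectrum ~ 1/sqrt(f) in amplitude, then renormalise to unit sd
    for (i in seq_len(C)) {
      sp <- stats::fft(x[i, ])
      f <- c(1, seq_len(n - 1))            # avoid dividing DC by zero
      f <- pmin(f, n - f)                  # mirror for negative frequencies
      sp <- sp / sqrt(pmax(f, 1))
      y <- Re(stats::fft(sp, inverse = TRUE)) / n
      x[i, ] <- y / stats::sd(y)
    }
  }
  x
}

## Hann-windowed sinusoid burst over a random 30-70% sub-interval,
## scaled so mean power over its support is `power`
sim_burst <- function(n, freq, rate, power) {
  len <- max(8L, round(stats::runif(1, 0.3, 0.7) * n))
  start <- sample.int(n - len + 1L, 1L)
  t <- (seq_len(len) - 1L) / rate
  phase <- stats::runif(1, 0, 2 * pi)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))  # Hann
  s <- w * sin(2 * pi * freq * t + phase)
  p <- mean(s^2)
  if (p > 0 && power > 0) s <- s * sqrt(power / p) else s <- s * 0
  out <- numeric(n)
  out[start:(start + len - 1L)] <- s
  out
}

#' Generate a labeled synthetic multi-channel dataset
#'
#' Each fragment is a C x n matrix of unit-variance channel noise; fragments of
#' a non-background class additionally carry a Hann-windowed sinusoidal burst
#' at that class's frequency, on that class's informative channels only, scaled
#' so the burst-to-noise power ratio over the burst support equals `snr_db`.
#' Each subject multiplies all of its fragments by a fixed amplitude factor
#' drawn once per subject. Labels are balanced round-robin within each subject.
#'
#' @param cfg A [sim_config()].
#' @return A `fragment_set`: list with `fragments` (list of C x n matrices),
#'   and integer vectors `label` (1-based class), `subject` and
#'   `fragment_index` (ordinal within subject), plus the `cfg`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  C <- cfg$n_channels; n <- cfg$fragment_len
  snr <- if (is.finite(cfg$snr_db)) 10^(cfg$snr_db / 10) else 0
  subj_scale <- exp(stats::rnorm(cfg$n_subjects, 0, cfg$subject_scale_sd))
  total <- cfg$n_subjects * cfg$fragments_per_subject
  fragments <- vector("list", total)
  label <- integer(total); subject <- integer(total); frag_idx <- integer(total)
  m <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (j in seq_len(cfg$fragments_per_subject)) {
      m <- m + 1L
      y <- ((j - 1L) %% cfg$n_classes) + 1L   # balanced within subject
      x <- sim_noise(C, n, cfg$noise)
      if (y >= 2L && snr > 0) {
        chans <- cfg$informative_channels[[as.character(y)]]
        for (ch in chans)
          x[ch, ] <- x[ch, ] + sim_burst(n, cfg$burst_freq[y - 1L],
                                         cfg$sample_rate, snr)
      }
      x <- x * subj_scale[s]
      if (!all(is.finite(x))) stop("non-finite sample generated")
      fragments[[m]] <- x
      label[m] <- y; subject[m] <- s; frag_idx[m] <- j
    }
  }
  structure(list(fragments = fragments, label = label, subject = subject,
                 fragment_index = frag_idx, cfg = cfg),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  d <- dim(x$fragments[[1]])
  cat(sprintf("fragment_set: %d fragments (%d x %d), %d subjects, %d classes\n",
              length(x$fragments), d[1], d[2],
              length(unique(x$subject)), length(unique(x$label))))
  invisible(x)
}

#' Subset a fragment set
#'
#' Selects fragments by integer or logical index, keeping labels, subject ids
#' and fragment ordinals aligned — the workhorse for carving a dataset into
#' the train/validation/test portions of a fold.
#'
#' @param fs A `fragment_set`.
#' @param idx Integer or logical index over fragments.
#' @return A `fragment_set` containing the selected fragments.
#' @export
#' @examples
#' fs <- generate_dataset(sim_config(n_subjects = 2, fragments_per_subject = 4))
#' train <- fragment_subset(fs, fs$subject == 1)
fragment_subset <- function(fs, idx) {
  structure(list(fragments = fs$fragments[idx], label = fs$label[idx],
                 subject = fs$subject[idx],
                 fragment_index = fs$fragment_index[idx], cfg = fs$cfg),
            class = "fragment_set")
}

#' Subject-independent cross-validation folds
#'
#' Partitions subjects into `k` disjoint test groups, then assigns whole
#' subjects from the remainder to a validation set targeting a 0.7:0.1:0.2
#' train:validation:test fragment ratio as closely as subject granularity
#' allows. No subject contributes fragments to more than one of
#' train/validation/test within a fold, and the k test sets partition the
#' subjects.
#'
#' @param fs A `fragment_set` (or any list with a `subject` vector).
#' @param k Number of folds.
#' @param seed Integer seed controlling the subject shuffle.
#' @return List of `k` fold splits, each a list with `fold_id`,
#'   `train_subjects`, `val_subjects`, `test_subjects`.
#' @export
make_subject_folds <- function(fs, k = 5L, seed = 1L) {
  subjects <- sort(unique(fs$subject))
  if (length(subjects) < k)
    stop("need at least k = ", k, " distinct subjects, got ", length(subjects))
  counts <- table(factor(fs$subject, levels = subjects))
  set.seed(seed)
  shuffled <- sample(subjects)
  test_groups <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  lapply(seq_len(k), function(f) {
    test <- sort(test_groups[[f]])
    rest <- setdiff(shuffled, test)          # keep shuffled order for val draw
    n_rest <- sum(counts[as.character(rest)])
    target_val <- n_rest * 0.1 / 0.8         # 0.1 of the whole : 0.8 non-test
    val <- character(0); acc <- 0; val_idx <- integer(0)
    for (i in seq_along(rest)) {
      ci <- counts[as.character(rest[i])]
      # take subjects while doing so moves us closer to the target
      if (abs(acc + ci - target_val) <= abs(acc - target_val) && acc < target_val) {
        val_idx <- c(val_idx, i); acc <- acc + ci
      }
    }
    if (length(val_idx) == 0L) val_idx <- 1L  # always hold out >= 1 subject
    val <- sort(rest[val_idx])
    train <- sort(setdiff(rest, val))
    list(fold_id = f, train_subjects = train, val_subjects = val,
         test_subjects = test)
  })
}
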