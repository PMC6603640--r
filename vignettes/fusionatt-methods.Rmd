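---
title: "Channel-aware fusional attention for multi-channel biosignals: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-aware fusional attention for multi-channel biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionatt)
```

## The problem

Clinical multi-channel recordings — scalp EEG for seizure detection,
polysomnography for sleep staging — carry task-relevant information on only a
subset of their sensing channels, and which subset varies across patients and
events. Hard channel selection (train on a fixed subset, discard the rest)
loses this per-situation structure. `fusionatt` implements a *soft* channel
selection network: every channel receives a continuous, learned contribution
score, and classification and channel weighting are trained jointly,
end-to-end.

## The model

A labeled fragment is a matrix $X = \{x_1, \dots, x_C\}$, $x_i \in
\mathbb{R}^n$: $C$ channels by $n$ samples (or preprocessed features).

**Multi-view convolutional encoder.** Two encoders summarize a fragment:

* the *channel-encoder* maps each channel's vector $x_i$, with one shared
  parameter set for all channels, to a channel view $h_i \in \mathbb{R}^p$;
* the *global-encoder* maps the full $C \times n$ stack to a global view
  $h_g \in \mathbb{R}^p$.

Both are stacks of *multi-kernel cells*: several parallel valid
cross-correlations of different kernel sizes (each with its own filter bank),
ReLU, then non-overlapping max pooling. Outputs of different kernel sizes have
different spatial extents; they are centre-cropped to the shortest extent and
stacked along the filter axis. After the last cell the feature maps are
flattened and an affine projection with ReLU produces the $p$-dimensional
view. The reference configuration (`encoder_config_default()`) uses channel
cells $(8,16,32,64)\times 8$ / pool 6, then $(3,5)\times 16$ / pool 3 twice;
the global cells use the matching 2-D kernels $(1\times w)$, then $3\times
3$ / $5\times 5$ kernels that mix adjacent channels, with a final
full-height $\times 3$ pool collapsing the channel axis.

**Fusional attention.** For each channel a scalar fusion gate

$$r_i = \sigma(W_{rg}^\top h_g + W_{rc}^\top h_i + b_{rc}) \in (0, 1)$$

blends the two views, $\bar h_i = (1 - r_i)\, h_g + r_i\, h_i$: at $r_i = 1$
only channel-view information passes, at $r_i = 0$ only the global view. An
affine energy $e_i = W_e^\top \bar h_i + b_e$ is normalised over channels by
a softmax into contribution scores $\alpha \in \Delta^{C-1}$, interpreted as
per-channel task relevance, and the context vector is the convex combination
$c_g = \sum_i \alpha_i \bar h_i$.

**Head and objective.** The attentional representation is $h_\alpha =
\mathrm{ReLU}(W_h [c_g \oplus h_g] + b_h) \in \mathbb{R}^r$ ($\oplus$ =
concatenation), followed by a softmax classifier. The loss is mean
categorical cross-entropy computed from logits (log-sum-exp form), plus an L2
penalty $\lambda \sum \|W\|_2^2$ over kernels and weight matrices (biases
excluded). For two classes this reduces to the familiar binary cross-entropy.
Although the binary form is the one usually printed, the categorical form is
required because the same network serves 5-class sleep staging.

## Training protocol

Training (`train_model()`) uses Adadelta with decay constant $\rho = 0.95$,
weight decay $\lambda = 0.001$ and dropout rate 0.5 — dropout is applied to
the flattened encoder outputs before projection and to $h_\alpha$, during
training only. We read the conventional "momentum 0.95" setting, which is not
an Adadelta parameter, as Adadelta's decay constant; a plain
SGD-with-momentum optimizer is available for ablation. Batch size (64) and
epoch budget (100) are configuration with documented defaults, and early
stopping on validation loss (patience 10) guards the unspecified epoch count;
the best-validation parameters are restored. Training is deterministic for a
fixed seed on a single thread. Default view dimensions are $p = r = 128$;
sensitivity to both is exposed through `sensitivity_sweep()` over the
conventional 32–512 range.

Evaluation uses subject-independent $k$-fold cross-validation
(`make_subject_folds()`, default $k = 5$): subjects are partitioned into $k$
disjoint test groups, and validation subjects are drawn from the non-test
portion targeting a 0.7:0.1:0.2 train:validation:test fragment ratio. A
"5-fold" protocol and an exact 0.7:0.1:0.2 ratio cannot both hold exactly at
subject granularity; we treat the fold structure as primary and the ratio as
best-effort, which is the only reconciliation that keeps subjects intact.
Metrics are accuracy plus macro (unweighted one-vs-rest) F1, AUC-ROC and
AUC-PR; AUCs integrate the threshold-swept curve trapezoidally, which for ROC
equals the Mann–Whitney pair statistic (tested against exhaustive pair
enumeration). Fold averaging is arithmetic over per-fold metrics; pooled
test scores are also returned for aggregate ROC/PR curves, since both
summaries are in common use.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` produces the ground-truthed data every training and
interpretation test runs on. Each fragment is unit-variance noise per channel
(white by default, optionally 1/f "pink"); each non-background class adds a
Hann-windowed sinusoidal burst at a class-specific frequency, *only on that
class's informative channels*, covering a random 30–70% sub-interval of the
fragment so that temporal pooling matters. The burst is scaled so its power
over its own support is `snr_db` decibels above the noise power. Each subject
multiplies all of its fragments by a fixed log-normal amplitude factor
(`subject_scale_sd` on the log scale) — an amplitude-only subject effect,
chosen deliberately so that ground-truth channel recovery stays unambiguous.
Labels are balanced round-robin within subjects.

Defaults mirror the seizure-detection shape: 8 channels of 256 samples at
64 Hz, two classes with channels 3–4 informative at 10 dB, 10 subjects of 50
fragments. These are the package's study conditions for the channel-recovery
and ordering experiments; the test suite and the acceptance script both use
them unchanged, with the compact `encoder_config_small(32)` encoder and a
15-epoch budget — sizes at which a full five-seed experiment runs in minutes
on one CPU.

What passing these tests shows: the architecture can learn, from data alone,
*which* channels carry class information, and its contribution scores recover
that ground truth. What they do not show: performance on real EEG morphology
(spike-wave complexes, artifacts, montage effects, non-stationary noise) —
the simulator reproduces only the statistical structure the attention
mechanism needs, not clinical waveforms.

## Numerical and design choices

* **Multi-kernel notation.** A cell specification like $(8,16,32,64)\times 8$
  is read as four parallel kernel widths with 8 filters each (32 maps). The
  notation is not self-defining; this reading matches "multi-kernel" cells
  and keeps parameter counts modest.
* **Flatten-to-$p$ projection.** The flattened dimension after the last cell
  depends on $C$ and $n$, yet the view dimension must be a constant $p$ for
  every sweep; an affine projection after flattening reconciles the two. This
  is the largest architectural inference in the package and is deliberately
  prominent here.
* **Global-encoder channel axis.** A literal sum over channels in the first
  global convolution stage would collapse the channel axis immediately, but
  the final $C \times 3$ pool requires a retained channel axis; the
  implementation keeps the axis (2-D convolution over the stack) and treats
  the summation as that convolution's inner product over input maps.
* **Scalar vs vector gate.** The gate is declared a scalar ($r_i \in
  \mathbb{R}$), so the elementwise product in the blend is scalar broadcast —
  the default. Because the blend operator hints at elementwise semantics, a
  vector-gate variant ($r_i \in (0,1)^p$, `vector_gate = TRUE`) is provided
  and tested, not silently chosen.
* **Convolution conventions.** Valid (no padding), cross-correlation
  orientation, stride 1; pooling truncates remainders; centre-cropping
  resolves multi-kernel length mismatch without padding semantics. Softmaxes
  are max-subtraction stabilised; exactly tied energies give exactly uniform
  scores; argmax ties break to the lowest index. Initialisation is seeded
  uniform fan-in/fan-out scaling.
* **Channel-encoder sharing.** One parameter set serves all channels (the
  equations use a single $\theta_c$); `per_channel_encoder = TRUE` exists
  behind a flag for the alternative reading.
* **STFT preprocessing.** `stft_features()` uses Hann-tapered frames,
  one-sided magnitudes under the orthonormal $1/\sqrt{N}$ scaling (so frame
  energy obeys Parseval, which the suite checks), optional `log1p`, flattened
  time-major. Window/hop default to $n/4$ and half-window but are
  configuration, recorded in the feature metadata — whether the original
  preprocessing was per fragment or per recording, or log-scaled, is not
  derivable, so none of these defaults is presented as anything but ours.
  A raw-waveform path is retained since the encoder equations are written on
  $x_i \in \mathbb{R}^n$ directly.
* **Fragment labeling.** A window is positive when at least 50% of it overlaps
  an annotated interval (threshold configurable; ties to the earliest
  annotation). Simulated data sidesteps the question by generating
  fragment-level labels directly.
* **Baselines.** `build_baseline()` provides gcnn (global encoder only), mcnn
  (unweighted channel mean concatenated with the global view — the merge rule
  for the multi-view CNN comparison is not derivable, so mean-then-concat is
  the documented choice), and two channel-attention variants (energies from
  $h_i$ alone, or from $[h_i \oplus h_g]$). The attention variants are
  approximations reconstructed from a brief published description; they
  support qualitative ordering tests and are not faithful reimplementations.

## Limitations

Contribution-score *orientation* is not identified by the training
objective: because the context vector is concatenated with the global view,
a head can decode the label equally well whether the informative channels
are up- or down-weighted, so on easy tasks an occasional seed converges to
an inverted or flat score profile while classifying perfectly. Empirically,
with the package's fan-in initialisation the informative channels win in the
large majority of seeds, which is why the channel-recovery property is
stated over multiple seeds rather than per run — and why single-run
contribution scores should be read with care on any dataset.

The network is trained in R with hand-written backward passes; it is sized
for method development, testing and small studies, not GPU-scale clinical
training. EDF reading supports the plain 16-bit uniform-rate format (mixed
per-channel rates are rejected explicitly). Contribution scores are an
interpretability signal, not a clinical localisation method; the grouped
report (`export_contribution_scores()`, mean scores of every 5 fragments
with the most active channel flagged) is exported for downstream inspection,
and clinical interpretation beyond that export is out of scope.
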