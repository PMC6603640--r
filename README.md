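# fusionatt

Channel-aware deep attention networks for multi-channel biomedical signals,
in R.

Multi-sensor clinical recordings — multi-channel EEG in seizure detection,
polysomnography in sleep staging — carry task-relevant activity on only a
subset of channels, and that subset varies across patients and events. Hard
channel selection (pick channels once, discard the rest) throws this
structure away. `fusionatt` implements **FusionAtt**, a unified network that
*soft-selects* channels: it learns a continuous contribution score per
channel jointly with the classifier, end-to-end.

For a fragment $X = \{x_1,\dots,x_C\}$, $x_i \in \mathbb{R}^n$:

- a shared-weight **channel-encoder** produces channel views
  $h_i \in \mathbb{R}^p$, and a **global-encoder** over the $C \times n$
  stack produces the global view $h_g \in \mathbb{R}^p$ — both are stacks of
  multi-kernel convolution cells (parallel kernel widths, ReLU,
  non-overlapping max pooling) with a final affine projection;
- a **fusion gate** $r_i = \sigma(W_{rg}^\top h_g + W_{rc}^\top h_i + b_{rc})$
  blends the views per channel, $\bar h_i = (1-r_i)h_g + r_i h_i$;
- affine energies $e_i = W_e^\top \bar h_i + b_e$ are softmax-normalised into
  **contribution scores** $\alpha \in \Delta^{C-1}$, and the **context
  vector** $c_g = \sum_i \alpha_i \bar h_i$ aggregates the fused views;
- the classifier reads $h_\alpha = \mathrm{ReLU}(W_h [c_g \oplus h_g] + b_h)$
  through a softmax, trained with categorical cross-entropy + L2 weight decay
  by Adadelta ($\rho = 0.95$, weight decay $0.001$, dropout $0.5$).

All forward and backward passes are written in vectorized base R (verified
against an independent scalar-loop reference and finite-difference
gradients). The package also provides a ground-truthed synthetic
multi-channel signal simulator, EDF/fixture readers with segmentation and
STFT preprocessing, subject-independent cross-validation with macro
accuracy/F1/AUC-ROC/AUC-PR, simplified CNN and channel-attention baselines,
and a command-line interface. See `vignettes/fusionatt-methods.Rmd` for the
model, its assumptions and every documented design choice.

## Worked example

Simulate the package's reference study conditions — 8 channels × 256 samples,
two classes, the positive class carrying 8 Hz bursts on channels 3–4 at
10 dB burst-to-noise, 10 subjects × 50 fragments — then train on a
subject-independent split and inspect what the attention learned:

```r
library(fusionatt)

fs <- generate_dataset(sim_config(seed = 1))
#> fragment_set: 500 fragments (8 x 256), 10 subjects, 2 classes

f <- make_subject_folds(fs, k = 5, seed = 1)[[1]]
train <- fragment_subset(fs, fs$subject %in% f$train_subjects)
val   <- fragment_subset(fs, fs$subject %in% f$val_subjects)
test  <- fragment_subset(fs, fs$subject %in% f$test_subjects)

model <- fusionatt_model(C = 8, n = 256, n_classes = 2,
                         encoder = encoder_config_small(32L), r = 32L,
                         seed = 1001)
#> fusionatt model: C=8, n=256, p=32, r=32, 2 classes, 14380 parameters

model <- train_model(model, train, val,
                     train_config(batch_size = 32, max_epochs = 15,
                                  seed = 2001))
pr <- predict(model, test)
compute_metrics(pr$probs, test$label)
#> n=100  accuracy 1.0000  F1(macro) 1.0000  AUC-ROC(macro) 1.0000  AUC-PR(macro) 1.0000

round(colMeans(pr$alpha[test$label == 2, ]), 3)
#> [1] 0.000 0.000 0.624 0.376 0.000 0.000 0.000 0.000
```

The held-out subjects are classified perfectly, and the mean contribution
scores on positive fragments place essentially all attention mass on
channels 3 and 4 — exactly the channels the simulator made informative. On
background fragments the scores stay near-uniform. `export_contribution_scores()`
writes the grouped per-timestamp report (mean score of every 5 consecutive
fragments per channel, most active channel flagged) used for
interpretation.

A thin command-line wrapper drives the same pipeline from YAML configs:

```sh
Rscript inst/cli/fusionatt.R simulate --config sim.yaml --out data/
Rscript inst/cli/fusionatt.R cross-validate --config run.yaml
Rscript inst/cli/fusionatt.R attention-report --checkpoint out/checkpoint \
        --data data/ --group 5 --out attention.csv
```

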