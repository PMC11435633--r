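---
title: "Graph-convolutional emotion recognition from three-channel EEG: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-convolutional emotion recognition from three-channel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dfcgn)
```

## The problem

Musical stimuli evoke measurable changes in scalp EEG: valence correlates
with frontal alpha (8–13 Hz) asymmetry, and high-frequency power (beta-2
18–22 Hz, beta-3 22–30 Hz, gamma 30–45 Hz) shifts with emotional state.
`dfcgn` implements a compact pipeline that classifies positive, negative and
neutral states from just three channels (C3, C4, Pz) sampled at 500 Hz:
windows of raw signal are treated as signals on a 3-node
functional-connectivity graph and fed to a graph-convolutional network.

The recordings such pipelines are usually built on are not publicly
distributable, so the package ships a fully seeded synthetic-session
generator that emulates the acquisition protocol, and every claim the test
suite makes is a claim about this synthetic emulation, not about human EEG.

## The synthetic sessions

`generate_session()` follows the stimulus schedule: 10 one-minute song
presentations (5 per valence, in the playing order N, P, N, P, P, N, N, P,
N, P), each followed by 10 s of silence labelled neutral, at 500 Hz. Signals
are sums of band-limited random-phase sinusoid mixtures (8 components per
band) plus white Gaussian noise, in microvolts with a 10 µV amplitude
baseline. Within each band a fraction `channel_mixing` (default 0.45) of
the power comes from a source shared by all channels; this reproduces the
inter-channel correlation (≈ 0.4–0.5) that volume conduction produces in
real recordings and without which a correlation graph would be empty. Per
class, band-by-channel weight matrices set relative band powers.

Two weight presets exist and they answer different questions:

* `class_spectrum_spec()` (default) encodes the physiology sketched above:
  positive valence gets stronger C3 alpha and suppressed beta-2/beta-3/gamma,
  negative the mirrored asymmetry with elevated high-frequency power,
  neutral a flat spectrum. The classes *overlap*: from a single 0.25-s
  window even an oracle band-power classifier reaches only ~0.87 accuracy,
  which is the realistic regime.
* `separable_spectrum_spec()` gives each class one dominant disjoint band
  (positive: alpha, negative: gamma, neutral: theta; 40× margin). This is
  the deliberately easy recovery condition used by the end-to-end tests: if
  the pipeline cannot reach ≥ 0.90 here, something is broken. Passing it
  says the machinery works, not that real EEG is this separable.

What the generator does **not** model: eye/muscle artifacts, electrode
drift, non-stationarity within a song, inter-subject anatomical variation
(all participants share the spectral templates, differing only by RNG
stream), or rating-based trial exclusion. Results on it are therefore an
upper bound on what the same pipeline would do on real data.

Seeding is hierarchical: one root seed, with per-(participant, interval)
streams derived by integer hashing, so a participant's session is identical
whether generated alone or inside a cohort and regeneration order is
irrelevant.

## Preprocessing and the sample budget

For each song only the centered 20 s is kept (offset `floor((L - keep)/2)`
samples), discarding onset/offset transients; the silences following the
first five songs supply the neutral class (50 s, half a valence class's
100 s — the retention rule that makes the published per-class counts come
out). Same-class segments are stacked along time and cut into
non-overlapping 125-sample windows.

With the default protocol the bookkeeping, reproduced exactly by
`compute_budget()` from configuration arithmetic alone, is:

* 5 songs × 20 s × 500 Hz = 50,000 stacked real samples per valence class,
  25,000 neutral;
* augmentation to 1000 windows × 125 samples = 125,000 samples per class,
  requiring 2 GAN sets of 50,000 for a valence class and 4 of 25,000 for
  neutral;
* 20 participants × 1000 windows × 3 classes = 60,000 sets, split 70/20/10
  into 42,000 / 12,000 / 6,000.

The stacking arithmetic implies 50,000 real + 2 × 50,000 generated =
150,000 samples, yet the binding downstream constraint is 1000 windows ×
125 samples; the stack is truncated to 125,000, dropping the tail. Splits
are drawn per (participant, class) stratum — `round(ratio · n)` windows to
validation and test, remainder to train — so every participant appears in
all three splits; the separate leave-one-subject-out protocol
(`loo_eval()`) covers the subject-independent question. GAN-synthesized
windows are confined to the train split by construction: `make_splits()`
swaps any GAN window drawn for validation/test with a real train window of
the same stratum, and `train_dfcgn()`/`train_gan()` raise hard errors on
any violation.

## The connectivity graph and spectral filtering

Edges are absolute Pearson correlations between channel time series
(`correlation_adjacency()`), thresholded at `tau` (default 0.3; entries
below the threshold are zeroed, a warning flags isolated nodes). The graph
is built once from pooled training-split windows and then frozen — building
it from all data would leak test statistics into the model.

With degree matrix `D` (`D_ii = Σ_j W_ij`) the unnormalized Laplacian
`L = D − W` is eigendecomposed `L = U Λ Uᵀ` (the symmetric-normalized
variant sits behind `normalized = TRUE`; the unnormalized form is the
default because it is the form the filtering is defined on). Eigenvalues
are sorted ascending and each eigenvector's largest-magnitude entry is made
positive — a deterministic sign convention, since eigenvectors are only
defined up to sign. The graph Fourier transform is `q̂ = Uᵀ q`, its inverse
`q = U q̂`, and exact spectral filtering is `y = U g(Λ) Uᵀ x`.

The trainable layers avoid the eigendecomposition entirely and use the
Chebyshev expansion on the rescaled Laplacian `L̃ = 2L/λ_max − I`:
`y = Σ_{k<K} θ_k T_k(L̃) x` with `T_0 = I`, `T_1 = L̃`,
`T_k = 2 L̃ T_{k−1} − T_{k−2}`. Order `K = 3` per layer is the default
(higher orders buy nothing on a 3-node graph, whose Laplacian has minimal
polynomial degree ≤ 3). The two filtering routes must agree for any
polynomial response of degree < K; the test suite checks this equivalence
on 500 random graphs of 3–8 nodes to 10⁻⁸, which is the module's core
correctness argument. An edgeless graph has `λ_max = 0`; the scaling falls
back to `λ_max := 2` so filtering stays defined.

## The classifier

Each 125-sample window is a graph signal: 3 nodes × 125 features. The
network is dropout (rate 0.3, input only, training only) followed by four
blocks of [Chebyshev graph convolution → feature-axis max-pool (size 2,
floor division) → Leaky-ReLU (slope 0.01)], then a flatten and a dense
softmax head. A layer's weight tensor is `[K × F_in × F_out]`: `T_k(L̃)`
mixes across nodes, the `F_in × F_out` slices mix across features, shared
over nodes. Feature widths run 125 → 62 → 31 → 15 → 7, so the head sees
3 × 7 = 21 values. Max-pooling is along time/features because a 3-node
graph admits no meaningful graph coarsening. No batch-normalization layers
are inserted; the activation choice (Leaky-ReLU) is the whole of that
design point. With dropout off the forward pass is a pure function, and the
backward pass is validated against numerical differentiation to 10⁻⁴
relative error.

Training (`train_dfcgn()`) uses Adam, learning rate 0.001, batch 16,
cross-entropy, weight decay 6 × 10⁻⁶, 200 epochs by default; inputs are
scaled by 1/sd of the training windows (stored in the model, reused at
inference). The checkpoint with the best validation accuracy is returned.
MSE loss and SGD/Adadelta/Adamax are available for ablations.

## The augmentation GAN

A 1-D convolutional pair per class. The generator maps a 64-dimensional
latent draw through a dense projection and six convolutions (five
zero-stuffing ×2 upsample + kernel-5 conv stages, one final conv to 3
channels, output cropped to 125 samples); the discriminator mirrors it with
six stride-2 convolutions and a sigmoid. Adamax, learning rate 0.001, batch
8. The reported objective is the classic two-term value
`V = E log D(x) + E log(1 − D(G(z)))` with probabilities clamped at 10⁻⁷
(`gan_value()`, logged per epoch); the generator's gradient uses the
standard non-saturating form, which optimizes the same fixed points without
the early-training vanishing gradient. Real segments are standardized by
their global sd before training and the scale is reapplied at synthesis.
Latent dimension 64 is conventional; generation operates on the same
125-sample, 3-channel unit as the classifier so shapes stay consistent, and
segments are concatenated (then truncated) to meet sample budgets.
Quality is asserted spectrally, not visually: on a single-band toy class
the generated segments' dominant-band Welch power must lie within a factor
2 of the real segments'.

## Evaluation

`compute_metrics()` reports the confusion matrix, accuracy, macro-averaged
one-vs-rest sensitivity/precision/specificity (macro because a single
number for a 3-class problem requires an averaging convention; classes
absent from the truth are excluded with a warning, a never-predicted class
contributes precision 0), Cohen's kappa `(p_o − p_e)/(1 − p_e)`, and
per-class one-vs-rest ROC curves by threshold sweep (no micro-averaging).
Every index is cross-checked against an independent naive loop
implementation in the tests.

`kfold_cv()` stratifies folds by class over the pooled train+validation
windows, never touching the test split. `loo_eval()` holds out one
participant at a time, rebuilding the graph from the remaining
participants. `add_noise_snr()` adds white Gaussian noise scaled per window
to a target SNR, and `noise_robustness()` sweeps a grid (default 20, 10, 5,
0, −5, −10 dB; accuracy at each SNR averaged over several noise draws to
damp Monte-Carlo error). On separable synthetic data accuracy is
non-increasing as SNR falls and reaches chance (1/3) by −20 dB. Baselines
(`baseline_fit()`) cover KNN, RBF-SVM and a single-hidden-layer MLP on
either 18 handcrafted statistics per window (mean, variance, skewness
`m₃/σ³`, kurtosis `m₄/σ⁴`, crest factor `max|x|/RMS`, mean power, per
channel) or raw windows, plus a plain 1-D CNN without graph mixing.

## Numerical and design choices, in one place

* Correlation flavor: absolute Pearson (sign carries no meaning for a
  nonnegative adjacency).
* Split remainders go to train — deterministic and conservative for test
  purity.
* `tau = 0.3` default: on synthetic sessions with `channel_mixing = 0.45`
  this keeps the graph connected while still exercising the sparsifier.
* Degenerate inputs: constant channels get zero correlations (warning);
  zero-variance windows get skewness/kurtosis 0 (warning); zero-power
  windows are skipped by the noise injector (warning); short signals
  produce empty window sets, not errors.
* Ties: max-pooling routes gradients to the first maximal element;
  `round()` (banker's at .5) fixes stratum counts.
* Problem sizes in the tests were chosen for a laptop-class single-CPU run:
  the recovery and robustness checks use 2 participants × 200 windows per
  class × 30 epochs, the GAN spectral check 200 windows × 30 epochs, the
  oracle-equivalence check 500 graphs. The published-scale budget
  (60,000 windows, 200 epochs) is exercised only through `compute_budget()`
  arithmetic and remains available via `run_config()` defaults.

## Known limitations

* A 3-node graph is small enough that graph convolution is close to a
  constrained dense layer; the machinery generalizes to larger montages but
  its benefit is not demonstrated here.
* The GAN asserts spectral similarity only; it is not evaluated for sample
  diversity or overfitting to the training windows.
* Synthetic stationarity makes the classification task easier than real
  EEG at equal spectral separation; headline accuracies on synthetic
  cohorts must not be read as expected performance on human recordings.
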