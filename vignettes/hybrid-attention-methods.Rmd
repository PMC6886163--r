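---
title: "Hybrid attention for multivariate sleep staging: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid attention for multivariate sleep staging: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleepatt)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical choices made
where the design was genuinely open, and the known limitations.

## The classification problem

A polysomnogram is a set of C simultaneous physiological signals with
heterogeneous sample rates. Scoring assigns each 30-second epoch one of
five stages (WAKE, REM, S1, S2, S3 — the two deepest stages merged, the
usual convention for R&K-scored corpora). Two structures carry the
information: *channel structure* (which modality is informative depends on
the stage: EEG delta power in deep sleep, EMG atonia in REM) and *temporal
structure* (stages persist and transition in characteristic patterns).
The model learns both with attention rather than hand-crafted features.

## Model

### Multi-view convolutional encoders

Each channel c has its own 1-D CNN producing a channel-view vector
$d_t^c \in \mathbb{R}^p$; the full aligned epoch matrix feeds one 2-D CNN
producing a global-view vector $s_t \in \mathbb{R}^p$. Both use three
stages of *parallel multi-scale kernel branches* — kernels 8/16/32/64 in
stage 1 — because biosignal waveforms live at several frequency scales at
once. The channel encoders use max pooling (pick out each channel's most
salient activations); the global encoder uses average pooling (retain
diffuse cross-channel information) and its final pool collapses the
channel-height axis. These are deliberate asymmetries, not accidents: the
two views are meant to specialise.

Three points were genuinely open and resolved as follows:

* **Branch paddings.** With the printed stage-1 paddings (3 and 7 for all
  four kernels) the kernel-32 and kernel-64 branches emit shorter feature
  maps than the kernel-8/16 branches and cannot be concatenated along the
  filter axis. The package uses $(K-2)/2$ — paddings 15 and 31 for those
  branches — the minimal change that makes all four branch lengths equal
  (1,920 at an input of 3,840). `build_encoder()` asserts branch-length
  equality at build time and refuses configurations that break it.
* **Reaching dimension p.** The convolutional pipeline ends in pooled
  feature maps (32 maps of length 120 at full scale), not a length-p
  vector. The package appends flatten + a learned linear projection with
  ReLU — the smallest addition consistent with $d_t^c, s_t \in \mathbb{R}^p$.
* **Nonlinearity and initialisation.** ReLU after every convolution;
  Glorot-style uniform initialisation driven by the session RNG, so a
  `set.seed()` before `build_model()` fixes the entire parameter state.

Each channel keeps an independent parameter set (`share_channel_weights`
turns sharing on, off by default): per-channel encoders are the point of
the multi-view design, since modalities differ in rate, amplitude and
rhythm.

### Channel-wise attention

For each channel the *fusional rate*
$r_t^c = \sigma(W_{rg}^\top s_t + W_{rc}^\top d_t^c + b_{rc})$ decides, in
$[0,1]$, how much the channel view (vs the global view) enters that
channel's attention energy
$e_t^c = W_{ec}^\top((1-r_t^c) \odot s_t + r_t^c \odot d_t^c) + b_{ec}$.
Softmax over channels yields $\alpha_t$, and the fused epoch vector is
the concatenation $\tilde{x}_t = s_t \oplus \sum_c \alpha_t^c d_t^c$
(length 2p). Both softmaxes in the package subtract the maximum before
exponentiating; energies of magnitude $10^4$ are handled without overflow.

### Recurrence and time-wise attention

A 2-layer bidirectional GRU (per-direction hidden size q, forward and
backward stacks independent, states concatenated) maps the fused sequence
to $h_{1:T}$. Time-wise attention reuses the same gated construction over
state pairs: $r_{t,i} = \sigma(W_{rt}^\top h_t + W_{ri}^\top h_i + b_{rt})$,
$e_{t,i} = W_{et}^\top((1-r_{t,i}) \odot h_t + r_{t,i} \odot h_i) + b_{et}$,
$\beta_t = \mathrm{softmax}(e_{t,1:T})$.

**The context-vector index.** Taken literally, a context defined as
$\sum_i \beta_{t,i} \odot h_t$ collapses to $h_t$ for *any* normalised
$\beta$ — the attention weights cancel out and the mechanism is vacuous.
The package therefore aggregates the sequence states,
$c_t = \sum_i \beta_{t,i} h_i$, the standard context-vector construction
that the rest of the design clearly intends. The literal form is kept as
`time_context(..., form = "literal")` and tested as a negative control:
the test asserts it *is* degenerate.

**Windowing.** Scores are recomputed for every query t, so time attention
is $O(T^2)$ per sequence. Overnight records (a thousand epochs) make the
full-record quadratic infeasible; sequences are processed in windows of
`window` epochs (stride = window, default 25), and T in $\beta_t$ is the
window length. The window is a config knob; the toy experiments use 5.

### Head and cost

$\hat{h}_t = f(W_h[c_t \oplus h_t] + b_h)$ with $f = \tanh$ by default
(bounded, conventional for attention heads; ReLU available), then a
softmax over the five stages. The training cost pairs the softmax output
with a **two-term** (Bernoulli-style) cross-entropy
$-[y_t^\top \log \hat{y}_t + (1-y_t)^\top \log(1-\hat{y}_t)]$, averaged
per record and then across records, so records contribute equally
regardless of length. This two-term form with a softmax output is unusual
but implemented as stated, with probabilities clipped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-7}$, before the logs;
it upper-bounds the standard categorical cross-entropy, which is available
via `loss_form = "categorical"` for comparison.

### Optimisation

Adadelta with decay $\rho = 0.95$ and $\varepsilon = 10^{-6}$. The quoted
protocol says "0.95 momentum"; Adadelta has no separate classical momentum
term, so 0.95 is read as the decay constant. (Warmer epsilons of $10^{-4}$
and $10^{-3}$ were measured on the toy task and both converged worse, so
the interpretation stands.) Weight decay enters as an L2 gradient
contribution with coefficient 0.001 on every tensor; dropout 0.5 is
applied to the fused vectors before the GRU and to $\hat{h}_t$ before the
softmax (placement is a package choice; dropout inside the GRU is not
used). Training selects the checkpoint with the best validation accuracy
and stops early after `patience` epochs without improvement.

## Differentiation

No deep-learning framework exists for R in this package's dependency
tier, so `sleepatt` ships a ~300-line reverse-mode differentiation tape
(`R/autodiff.R`): values are matrices, nodes record a backward closure,
and creation order is the topological order. Convolutions are im2col
gathers plus matrix multiplies; pooling gathers window taps (max pooling
pads with $-\infty$, average pooling counts pads in the divisor, matching
framework defaults). The tape is validated in the test suite by central
finite differences *through the entire model stack* — encoder,
attention, GRU, head, loss — with relative errors around $10^{-7}$.

## Preprocessing choices

* **Alignment.** Channels are linearly interpolated to a common length of
  `max(rate) * 30` samples: upsampling preserves information where
  downsampling would discard it, and it reproduces the full-scale count
  of 14 × 3,840 = 53,760 values per epoch. Samples sit at $k/\mathrm{rate}$,
  so integer-factor upsampling reproduces the original samples exactly and
  alignment is idempotent.
* **STFT.** The frequency-domain pathway uses 128-sample Hann windows,
  hop 128 (non-overlapping), one-sided spectra (65 bins), no boundary
  padding — the unique simple setting that yields 65 × 30 values per
  channel on a 3,840-sample epoch, i.e. 27,300 per 14-channel epoch.
  Magnitudes are used by default (`stft_log` switches to log-magnitude);
  nothing but the value count constrains this choice. Flattening is
  bin-major.
* **Normalisation.** Per-record, per-channel z-scoring before
  segmentation (`normalize = FALSE` disables). Mixed biosignal modalities
  differ in amplitude by orders of magnitude; without this the global
  encoder is dominated by the loudest channel.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the model assumes and
nothing more: a Markov-chain hypnogram over the five stages (sticky,
physiologically-ordered transitions by default; `stationary_distribution()`
exposes the implied stage mix), and per-slot signals that are sums of four
band-limited sinusoids (delta/theta/alpha/beta) whose log-amplitudes are
drawn around a (stage, channel-kind) band-power map, plus white noise.
The default map follows textbook physiology coarsely — alpha/beta-dominant
wake, theta S1/S2, delta S3, REM EMG atonia; the default montage (6 EEG
@128 Hz, 2 EOG @128, 1 EMG @64, 1 ECG @128, 4 auxiliary @64) mirrors the
heterogeneity of a 14-channel clinical montage without claiming any real
recorder's layout — both are labelled synthetic stand-ins. Per-subject
streams derive from a stable hash of (seed, subject index), so cohorts
are reproducible and order-independent.

What it does **not** emulate: artifacts, arousals, apnea events,
inter-scorer label noise, subject-specific spectra, non-stationarity
within a stage, or 1/f background spectra. Consequently, passing the
package's learning tests shows the architecture, gradients and training
loop work end-to-end on band-power-separable data; it says nothing about
clinical accuracy on real PSG, which is dominated by exactly the
structure the generator leaves out.

## Study sizes used by the checks

The bundled checks run at sizes chosen so the whole suite completes on a
single CPU while still exercising every component at full fidelity:
geometry checks use the genuine 14-channel epoch (53,760 / 27,300
values); learning checks use a 2-channel 32 Hz toy montage with one
dominant band per stage and stage-specific amplitude levels
(`toy_cohort_config()`), p = q = r = 16, attention window 5, batch 1 —
memorisation on 2 subjects × 40 epochs within 30 training epochs, and
5-fold subject-independent cross-validation on 10 subjects × 25 epochs
with up to 50 training epochs. At those sizes training accuracy reaches
≈ 0.98 and mean held-out accuracy ≈ 0.91 with fixed seeds.

## Evaluation

Five measurements: accuracy; macro-F1 (unweighted mean of per-class F1,
absent classes scoring 0); micro-F1 (pooled counts — provably equal to
accuracy for single-label multiclass, asserted in tests); and macro
one-vs-rest AUC-ROC (rank-based, midrank ties) and AUC-PR (average
precision — the stepwise sum, not trapezoids, which would be optimistic
for PR). Cross-validation is *subject-independent*: test sets partition
subjects across folds, validation subjects are `floor(0.1 n)` of the
remainder (the 0.7 : 0.1 : 0.2 convention), and no epoch of a held-out
subject ever reaches training — identity leakage is the classic error in
cross-subject sleep staging.

## Known limitations

* **Interpretability of α is weaker than hoped.** On toy cohorts with a
  single informative channel, trained channel attention concentrates
  above uniform (mean max-α ≈ 0.42 with C = 4, uniform 0.25) but does
  not reliably localise *on* the informative channel: the global view
  $s_t$ already carries the class signal, so the channel-attention path
  is not forced to. Attention heatmaps should be read as diagnostics,
  not explanations.
* **Quadratic time attention** bounds practical window lengths; contexts
  never span window boundaries.
* **Pure-R training speed** suits toy and small-cohort studies (seconds
  per window); full-scale overnight cohorts would need hours per fold
  and are out of intended scope.
* The two-term cost is implemented as printed; whether a plain
  categorical cross-entropy was intended is unknowable from the text, so
  both are provided and the printed form is the default.
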