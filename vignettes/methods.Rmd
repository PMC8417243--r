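---
title: "Graph-based seizure prediction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based seizure prediction: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

seizecast classifies fixed-length multichannel scalp-EEG windows as
**pre-ictal** (the positive class: 1 h to 5 min before an annotated seizure
onset) or **inter-ictal** (baseline, far from any seizure). This vignette
explains the model stage by stage, states its assumptions, and records the
design decisions that were genuinely open, so a reader can judge what a
passing test suite does and does not establish.

## The model

**1. Spectral reconstruction.** Each channel of a window is decomposed with
a depth-4 wavelet packet transform — the full binary tree, splitting both
the approximation and the detail branch at every level — giving 16 terminal
sub-bands that tile $[0, f_s/2]$ (8 Hz wide at 256 Hz). Band $k$'s feature
is its energy $E_k = \sum_i c_{k,i}^2$; each channel is summarized by the
relative profile $E_k / \sum_j E_j$. The transform uses periodized
(circular) extension, so it is exactly orthonormal and
$\sum_k E_k = \lVert x \rVert^2$ (Parseval) to machine precision for window
lengths divisible by $2^4$. Terminal nodes come out of the tree in
"natural" order, which is *not* frequency order (downsampling a high-pass
branch mirrors its spectrum); they are re-sorted by the binary-reflected
Gray code so band $k$ really covers $[k, k+1) \cdot f_s/32$. The package
verifies this ordering against an FFT oracle: a pure tone at each band
center must maximize that band's energy.

**2. Channel graph.** Channels become nodes of a weighted graph. Edge
weights are absolute Pearson correlations between per-channel vectors —
by default the 16-value relative energy profiles (correlation computed
*after* spectral reconstruction); a `raw_signals` mode correlates the raw
time series instead, since both readings are defensible. Signed
correlations are kept in `raw_correlations`; the adjacency takes $|r|$
because the normalized-Laplacian machinery requires nonnegative weights.
Node features $X \in \mathbb{R}^{18 \times 16}$ are the relative energy
rows. Relative (not raw) energies are used as features deliberately: they
are amplitude-scale invariant and lie in $[0,1]$, which conditions
optimization well.

**3. Graph state encoder.** Spectral graph convolution with Chebyshev
polynomial filters. With $L = I - D^{-1/2} A D^{-1/2}$ and
$\tilde{L} = 2L/\lambda_{\max} - I$ (spectrum in $[-1,1]$), a layer
computes

$$O = \sum_{k=0}^{K-1} T_k(\tilde{L})\, X\, \theta_k, \qquad
  T_k(\tilde{L})X = 2\tilde{L}\,T_{k-1}(\tilde{L})X - T_{k-2}(\tilde{L})X,$$

followed by an elementwise ReLU. Two such layers (widths 16 → 32 → 32)
are followed by a fully connected layer mapping the flattened node
representation ($18 \times 32$) to an 18-value **status code**, one value
per channel per window. The recurrence never eigendecomposes at filtering
time; the test suite proves it equal (to $10^{-9}$) to explicit spectral
filtering $U\,T_k(\Lambda)\,U^\top X$ on random graphs.

**4. Space–time predictor.** Status codes of `seq_len` consecutive windows
are consumed in chronological order by a GRU (hidden width 32, row-vector
convention, no bias terms):

$$R_t = \sigma(W_r s_t + U_r C_{t-1}), \quad
  N_t = \sigma(W_z s_t + U_z C_{t-1}),$$
$$\tilde{C}_t = \tanh(W s_t + R_t \odot (U C_{t-1})), \quad
  C_t = (1 - N_t) \odot C_{t-1} + N_t \odot \tilde{C}_t,$$

where $N_t$ is the update gate. The literature writes the candidate's
recurrent term ambiguously; we use $R_t \odot (U C_{t-1})$, the standard
GRU formulation. A one-hidden-layer MLP (32 → 16 → 2, ReLU, softmax) maps
the final state to class probabilities — "multilayer perceptron" is read
minimally as one hidden layer.

**5. Loss and training.** Cross-entropy against the one-hot label
(probability floor $10^{-12}$) plus an L2 term
$\frac{\lambda}{2}\sum w^2$ over all *weight matrices* (biases excluded),
minimized by Adam at learning rate 0.01. Gradients through the whole stack
— MLP, GRU (backpropagation through time), the fully connected layer, the
Chebyshev recurrence (its adjoint uses the symmetry of $\tilde{L}$) and
both convolution layers — are hand-derived and are checked against central
finite differences in the test suite (relative error $< 10^{-5}$).

Because the per-window graph is fixed during training, featurization
precomputes each window's $\tilde{L}$ and first-layer basis
$T_k(\tilde{L})X$; a training batch stacks $B$ sequences $\times$ $T$
windows into one tall matrix and block-diagonal sparse $\tilde{L}$, so a
batch costs a handful of large matrix products.

## Labeling and windowing

For each onset $t$, the pre-ictal interval is
$[\max(0, t - 3600), t - 300)$ seconds, truncated at the end of any
earlier seizure; an onset closer than 5 min to the recording start yields
no pre-ictal data (warned, skipped). Inter-ictal intervals are everything
at least `inter_guard` from every seizure (guard on both sides); ictal
spans belong to neither class. Pre-ictal intervals are cut into windows
with 50 % overlap, inter-ictal with none — the overlap imbalance is the
class-balancing device, since inter-ictal time dominates recordings.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| window length | 5 s (1280 samples at 256 Hz) | common for this corpus; $1280 = 2^8 \cdot 5$ comfortably supports depth 4 |
| wavelet | `db4` | a smooth, compactly supported orthogonal Daubechies member; `haar`–`db8` available |
| depth | 4 (16 bands) | 8 Hz bands at 256 Hz |
| `inter_guard` | 4 h | conservative separation of baseline from seizures; purely graphical in the source material, so configurable |
| Chebyshev order $K$ | 3 | 2-hop neighbourhoods on an 18-node graph |
| conv widths | 16 → 32 → 32 | small graph, small features; wider layers overfit windows |
| `seq_len` | 5 windows, stride 1 | 25 s of context per prediction; label = last window's |
| GRU hidden / MLP hidden | 32 / 16 | matched to the status-code width |
| learning rate / epochs / batch | 0.01 / 50 / 32 | Adam at 0.01; 50 epochs converges on the synthetic conditions |
| $\lambda$ (L2) | $5 \times 10^{-4}$ | standard weak weight decay |
| split | 70/30 stratified, sequence-blocked | all windows of a sequence on one side |

The train/test protocol, epochs and batch size have no authoritative
source values; these defaults are documented choices, with no claim of
matching any published protocol.

## The synthetic generator

The generator emulates exactly the two class contrasts the model is built
to detect:

* **Sub-band energy profile.** Band-limited components are synthesized
  directly in wavelet-packet *coefficient space*: band $b$ of channel $c$
  receives a coefficient vector of squared norm exactly
  $A^2 \frac{n}{2} w_b$, mapped to the time domain by the inverse packet
  transform. Orthonormality makes the planted relative profile recoverable
  exactly (up to additive noise). An earlier construction using pure tones
  at band centers was abandoned: depth-4 Daubechies packet filters leak
  up to 40 % of a centered tone's energy into neighbouring bands
  (a structural property of short filters, reproduced identically by
  reference implementations), which makes tone-planting unusable as a
  sharp oracle.
* **Cross-channel coupling.** Each band's coefficient vector is the
  normalized mixture $\sqrt{\rho}\,u_{\text{shared}} +
  \sqrt{1-\rho}\,u_{\text{private}}$ of unit Gaussian vectors, so the
  expected between-channel correlation rises monotonically with $\rho$;
  $\rho = 1$ gives identical channels, and the mixing never perturbs band
  energies.
* Defaults: pre-ictal concentrates energy in high bands (11–13 of 16)
  with $\rho = 0.9$; inter-ictal in low bands (2–4) with $\rho = 0.1$;
  amplitude 10 µV, white noise 1 µV. High-frequency dominance and stronger
  synchronization ahead of seizures mirror what is reported for this
  corpus; the disjoint dominant bands and the 0.9/0.1 coupling contrast
  make the two classes well separated by construction.

What it does **not** emulate: 1/f background spectra, artifacts, spikes,
nonstationarity within a window, ictal waveforms, patient heterogeneity,
or electrode-montage geometry. Consequently, a model that separates the
synthetic classes at ≥ 95 % demonstrates that the pipeline can learn
planted spectral-and-coupling contrasts end to end — it does *not*
demonstrate clinical performance on real EEG, which requires the external
corpus and is intentionally outside the test surface.

```{r synthetic-example}
library(seizecast)
cfg <- sim_config(seed = 1)                 # 18 channels, 256 Hz, 5 s
segments <- make_dataset(cfg, n_per_class = 200)
model <- train_model(segments, train_config(seed = 1))
evaluate_model(model)$metrics
```

## Numerical choices and degenerate inputs

* **Laplacian degeneracies.** Rows/columns of isolated (degree-zero) nodes
  are zeroed, so an edgeless graph has $L = 0$; $\lambda_{\max}$ is
  floor-clamped at $10^{-6}$, making $\tilde{L} = -I$ there. $\lambda_\max$
  is computed by dense symmetric eigendecomposition — the graphs are
  18 × 18, so iterative methods would be pointless.
* **Constant signals.** Pearson correlation of a constant vector is
  undefined; the package returns 0 with a warning (graph: no edge), and
  the diagonal of `raw_correlations` is pinned at 1.
* **All-zero windows.** A zero-energy channel has no defined relative
  profile; it is reported as zeros with a `zero_energy` flag rather than
  NaN.
* **Odd lengths.** The periodized transform needs even lengths at every
  level; odd inputs are wrapped by one sample, and Parseval is then only
  approximate — the documented tolerance (1e-8 relative) applies to
  lengths divisible by $2^{\text{depth}}$.
* **Metric denominators.** Any indicator with a zero denominator (e.g.
  sensitivity with no positives) is reported as missing (`NA`), never as
  0. FPR and F1 are reported on the ratio scale, the other five
  indicators as percentages.
* **Determinism.** All stochastic stages (generation, initialization,
  batch shuffling) flow through R's default Mersenne-Twister stream,
  seeded explicitly and restored afterwards; per-segment seeds are derived
  from the master seed by a fixed counter scheme. Training with the same
  seed reproduces parameters bit for bit.

## Problem sizes used by the test suite

Unit tests run on shrunken configurations (2–6 channels, 16–128 Hz): the
properties they check are size-invariant. The end-to-end classification
check runs the full study condition — 18 channels at 256 Hz, 200 segments
per class, 50 epochs, the default architecture — which completes in about
a minute on one CPU; held-out sensitivity and specificity must both reach
95 %. The EDF reader/writer is exercised by round-tripping generated
recordings, not by external downloads.

## Known limitations

* Real-data performance is unverified here by design: training on the
  public scalp-EEG corpus is stochastic, protocol-sensitive and requires
  an external download, so it is provided as a workflow (CLI `featurize` /
  `train` / `evaluate`) rather than a test gate.
* 50 %-overlapping pre-ictal windows share half their samples; the
  sequence-blocked split keeps whole sequences on one side but adjacent
  train/test sequences at a block boundary can still share samples through
  overlap. With independent synthetic segments this leakage is absent; on
  real data a per-recording split is recommended.
* The status code's "one value per channel" reading is an architectural
  convention (the fully connected layer simply has 18 outputs); no
  eigen-structure is implied.
* Alarm-level post-processing (refractory periods, firing-power
  smoothing) is out of scope; outputs are per-sequence probabilities.
* In the default `energy_vectors` graph mode, channels whose spectral
  profiles are similar (as in the synthetic data, where every channel of a
  window shares one planted profile) produce a near-complete graph in both
  classes; the class signal then travels mainly through the node features,
  with the adjacency modulating their diffusion. The `raw_signals` mode
  yields adjacencies that track the coupling level directly.
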