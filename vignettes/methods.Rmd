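---
title: "Attention-guided spatiotemporal graph networks for EEG sleep staging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided spatiotemporal graph networks for EEG sleep staging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnograph)
```

# The problem

Overnight polysomnography is scored in 30-second epochs into five AASM
stages — wake (W), three NREM depths (N1, N2, N3) and REM (R). The stages
differ both spectrally (alpha in relaxed wake, spindle-band sigma in N2,
high-amplitude delta in N3) and spatially (the topography over the
electrode montage), and they evolve slowly, so neighbouring epochs are
strongly informative about one another. `somnograph` implements an
automatic stager that treats the montage as a graph: electrodes are
nodes, channel-mixing happens along graph edges, and temporal structure
across a short window of epochs is modelled by dilated convolutions and a
joint frame-by-electrode attention block.

# From signal to network input

Each electrode's 30-s epoch is band-pass filtered into the classical
sleep bands — delta 0.5–4, theta 4–8, alpha 8–13, sigma 11–16 and beta
16–30 Hz — and each band-limited segment is summarized by its
differential entropy under a Gaussian model,
$h = \tfrac12\ln(2\pi e \sigma^2)$ nats, i.e. an affine function of
log band power. An epoch becomes an $N \times F_{de}$ matrix ($N$
electrodes, $F_{de} = 5$ bands). The classifier input for epoch $t$ is
the *temporal context* $C \in \mathbb{R}^{N\times F_{de}\times T_n}$
stacking the $k+1$ matrices at epochs $t-kd, \dots, t$, labelled with
the stage of epoch $t$.

Choices made where the method leaves them open:

* **Band edges.** The five-band split above is the standard sleep set;
  sigma overlaps alpha/beta deliberately because spindles are the key N2
  signature. The band list is fully configurable (`default_bands()`).
* **Filter.** 4th-order Butterworth run forward–backward
  (`signal::filtfilt`), so the pass band is amplitude-preserving and
  phase-free. Any stable zero-phase band-pass with the same pass/stop
  behaviour would serve.
* **Differential entropy.** The Gaussian closed form is used; for
  band-limited EEG-like signals this reduces DE estimation to a variance
  (population variance of the filtered epoch). Zero-variance input would
  diverge to $-\infty$ and instead returns a configurable floor (default
  −20 nats) with a warning.
* **Context size.** $k = 4$, $d = 1$, hence $T_n = 5$ epochs
  (2.5 minutes). Epochs with fewer than $kd$ predecessors are dropped
  rather than padded — padding would fabricate history, and dropping
  keeps epoch counts predictable (`n_contexts = n_epochs - kd`).
* **Normalization.** DE features are z-scored per recording and
  electrode-band before the network (toggleable). This removes
  inter-subject amplitude offsets, which otherwise dominate the
  first training epochs.

# The electrode graph

The *static* branch uses a fixed montage adjacency $G_p$ (0/1,
symmetric, zero diagonal). Presets connect physically neighbouring
10–20 sites: for the six-channel F/C/O montage the seven edges
F3–F4, F3–C3, F4–C4, C3–C4, C3–O1, C4–O2, O1–O2; for the two-derivation
sleep-EDF montage the single possible edge. Any montage can be supplied
as an explicit edge list. $G_p$ is degree-normalized with self-loops,
$\tilde D^{-1/2}(G_p+I)\tilde D^{-1/2}$, the usual GCN propagation
matrix (spectral radius ≤ 1); a freely trainable mask $G_m$
(initialized at zero, so training starts from the physical topology) is
added *after* normalization. A `static_norm` switch exposes the
alternatives: `"none"` (raw $G_p+G_m$, the update rule exactly as
printed for the static branch, which applies no normalization) and
`"post"` (normalize $G_p+G_m$ jointly; the mask is then part of graph
construction and is held fixed rather than trained, because the degree
terms make its gradient path awkward for no practical gain). The
default `"pre"` keeps the well-conditioned normalized base and leaves
the mask as a free perturbation.

The *dynamic* branch builds a per-sample graph from the current feature
matrix: the ordered-pair score is a rectified weighted absolute feature
difference $s_{ij} = \max(0, w^\top |x_i - x_j|)$ and each row is
softmax-normalized, giving a non-negative row-stochastic $G_d$ that is
differentiable in both $w$ and the features. Identical features give a
uniform graph; permuting electrodes permutes $G_d$ identically. By
default $G_d$ is computed per frame of the context; a `gd_agg = "mean"`
switch averages it over the $T_n$ frames of a sample.

One printed asymmetry is retained deliberately: the static branch output
passes through an activation (taken as ReLU; the Swish activation
appears only inside the attention block) while the dynamic branch has
none. The fused output is `dynamic + phi * static` with
$\phi \in [0,1]$ a fixed configuration constant, default 0.5 (the
balance is specified as a bounded weight but neither fixed nor marked
as learned; a constant keeps the ablation comparison clean).

# Module structure

Each of the nine modules (channel plan 66, 66, 66, 132, 132, 132, 264,
264, 264) is GCN → batch norm → multi-scale TCN → batch norm/ReLU →
attention → dropout (0.2). The GCN keeps the channel count; channel
increases happen inside the TCN's 1×1 bottlenecks.

The multi-scale TCN runs seven parallel branches over the frame axis:
four bottlenecked 3×1 convolutions with dilations 1, 2, 3, 4 (the
dilation values are a choice; only "different dilation factors" is
specified), one 1×1 branch for within-frame features, one bottlenecked
3×1 max-pool branch, and a residual branch. Branch outputs are
concatenated on the channel axis: each of the six transform branches
gets $\lfloor C_{out}/7\rfloor$ channels and the residual branch the
remainder (through a 1×1 projection when widths differ) — the printed
channel counts are not divisible by 7, so an exact equal split cannot
exist. A module-level residual (identity or 1×1) is added on top.
Temporal extent is always preserved: convolutions use zero "same"
padding, max-pooling shrinks its window at the edges, and there is no
temporal stride ($T_n$ is only 5).

The attention block is coordinate-attention-style: max-pool descriptors
over frames ($C \times V$) and over electrodes ($C \times T$) are
concatenated along the pooled axis, squeezed by a shared bottleneck FC
with Swish (hidden width $\lfloor C/r \rfloor$, $r = 4$; the printed
channel counts are not divisible by 4 either, so the width is floored
rather than requiring exact divisibility), batch-normalized (the
normalization sits right after the shared FC; the diagrams do not pin
its exact position), split back, expanded by two independent FCs with
sigmoids, and combined per channel as the outer product of the frame
scores (length $T$) and electrode scores (length $V$). The input is
multiplied elementwise by this map, so the output is elementwise
bounded by the input — an ablation-friendly property: with attention
disabled the module reduces exactly to GCN → TCN. The sigmoid score FCs
are initialized with bias +2 (gates open, sigmoid ≈ 0.88), the standard
open-gate initialization of gated architectures: with zero biases every
block would attenuate the signal about four-fold at the start of
training, and a stack of them starves the classifier head of gradient. The concatenation is
along the pooled axis (the alternative, channel-axis concatenation,
cannot be fully excluded from the diagrams; the pooled-axis reading
matches the stated shared-FC-then-split structure).

The head global-averages over frames and electrodes and applies a
linear softmax over the five stages. The loss is cross-entropy;
`class_weights = "balanced"` switches to inverse-frequency weighting
(off by default), which matters when N1 scarcity is extreme.

# Training

Adam, batch size 64, initial learning rate $10^{-3}$ divided by 10 at
epochs 30, 60 and 90, dropout 0.2, 120 epochs by default. One global
seed governs initialization, shuffling and the simulator. Evaluation
uses subject-wise cross-validation: each fold's test set is exactly one
subject's recordings (leave-one-subject-out when the fold count equals
the subject count). Batch-norm layers use batch statistics in training
and running averages (momentum 0.1) at evaluation.

All layers carry hand-written backward passes over base-R arrays; every
one is verified against central finite differences (relative error
below $10^{-4}$ on random small instances; probes avoid max-pool tie
points, where the finite-difference oracle itself is invalid).

# The synthetic cohort

`simulate_psg()` draws a first-order Markov hypnogram over the five
stages and synthesizes each epoch as band-limited random-phase
sinusoids weighted by stage-specific band-power profiles plus white
noise. The default transition matrix encodes sleep continuity
(self-transitions ≥ 0.85 for N2/N3, wake entering sleep through N1,
REM reachable only from N2); its stationary distribution is N2-heavy
(≈ 43%) with scarce N1 (≈ 7%), mirroring the composition of public
sleep archives. Default profiles: W alpha/beta, N1 theta, N2
sigma+theta, N3 high-amplitude delta, R low-amplitude theta/beta.

What the simulator does *not* emulate: spindle/K-complex morphology,
artifacts, non-EEG channels, scorer disagreement, or non-stationary
drift within a night. Its DE features are linearly separable almost
perfectly (an LDA on 1000 epochs exceeds 90% accuracy by a wide
margin), which is the point: passing the end-to-end learning test
demonstrates that the network and its gradients work, not that the
architecture would reach any particular accuracy on real
polysomnography. Claims at full-data scale are outside what desk-scale
synthetic runs can support.

The scaled-down study conditions used by the acceptance checks: 4
subjects × 200 epochs at 100 Hz on the six-channel montage, reduced
channel plan (16, 16, 32), 40 training epochs, train on three subjects
and test on the held-out one; the attention-on/off comparison averages
macro-F over three seeds. These sizes keep a full run in minutes on one
CPU while leaving the learning problem non-trivial (held-out, scarce
N1).

# Numerical notes and degenerate inputs

* Softmax rows are max-stabilized; cross-entropy clips probabilities at
  $10^{-12}$.
* Max-pool ties resolve to the earliest frame; argmax routing makes the
  backward pass exact at the chosen branch.
* `normalize_adjacency` of the zero graph is the identity ($\tilde A = I$).
* An all-wake record cannot be trimmed around a sleep period; the
  trimmer returns an empty, flagged range.
* A confusion matrix with an empty class row or column gets recall or
  precision 0 for that class and the class is flagged in the report.
* Two macro-F conventions exist: the unweighted mean of per-class F1
  (default, consistent with per-class F1 tables) and the harmonic mean
  of macro-precision and macro-recall; on the bundled sleep-EDF
  reference matrix they differ (89.0 vs 89.2). Both are always
  computed and reported.
* EDF output quantizes to 16 bits over a per-channel symmetric range;
  the round-trip error is bounded by half a quantization step.

# Known limitations

* Pure-R training is CPU-bound; the full nine-module plan at archive
  scale is out of reach here (and not attempted) — the full stack is
  validated by shape propagation, oracle equivalence, gradient checks
  and a sub-second forward/backward timing bound instead.
* The EDF layer covers one sampling rate across EEG channels and
  int16 samples; EDF+D (discontinuous) files are not supported.
* Hypnogram alignment assumes label sequences index epochs from the
  recording start; scorer offsets must be resolved upstream.
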