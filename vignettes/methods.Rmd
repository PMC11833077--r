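---
title: "Jacobian saliency for domain-adversarial ECG image classifiers: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jacobian saliency for domain-adversarial ECG image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Convolutional classifiers read 12-lead ECG *images* — scans of paper
printouts, or photos taken with a phone in a clinic — and emit a probability
that a given cardiac condition is present. For a clinician to trust such a
recommendation, the model must point at the waveform features that drove it,
in the clinician's own terms: the absent P waves and irregular RR intervals
of atrial fibrillation, the saw-tooth baseline of flutter, the wide QRS of a
bundle branch block. This package implements that interpretability layer and
everything needed to exercise it end to end on synthetic data with known
ground truth.

## The model

The network has four parts:

* a **feature extractor** — stacked blocks of strided convolution, batch
  normalization, Leaky ReLU (negative slope 0.01) and dropout;
* a **signal decoder** — the transposed-convolution mirror of the extractor,
  reconstructing the binary trace image; its parameters mirror the
  extractor's block for block, so the autoencoder is symmetric;
* a **label predictor** — fully connected layers on the flattened features,
  one sigmoid unit (one binary model per condition);
* a **domain classifier** — the same head shape, attached *through a
  gradient reversal layer* (GRL).

The GRL is the identity on the forward pass and multiplies the
backpropagated gradient by $-\lambda$: the domain head learns to tell
scans from photos while the extractor is pushed to *defeat* it, so the
features that survive are domain-agnostic.

Training minimizes the composite loss

$$\mathcal{L} = 60\,\mathcal{L}_{\mathrm{MSE}}
 + 2\,\mathcal{L}_{\mathrm{BCE}}^{\mathrm{label}}
 + 0.2\,\mathcal{L}_{\mathrm{BCE}}^{\mathrm{domain}},$$

with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, learning rate $4\cdot10^{-5}$
by default, batch size 25). The reversal weight follows the schedule
$\lambda = 0.85\,e^{5.5p}$, where $p$ is overall training progress
$(b + E N_B)/(N_B N_E)$ — domain adaptation is the easier task, so its
gradient is re-weighted upward as training advances. We treat $N_B$ as the
number of batches per epoch and $N_E$ as the total planned epochs, and we
let $p$ run across the two adversarial phases (2 and 3) as one sweep rather
than resetting per phase; a reset would return $\lambda$ to 0.85 just when
the extractor most needs reversal pressure.

Training proceeds in three phases: (1) extractor + decoder alone on clean
source images against their threshold-segmented traces; (2) per-condition
fine-tuning on mixed half-source/half-target batches, where source images
propagate through all heads and target images through the domain head only;
(3) domain-classifier consolidation under the same mixed regime. A
checkpoint is kept only when the label metric is the best so far, the
decoder loss the lowest so far, *and* the domain classifier accuracy lies
in [40%, 60%] — near chance, evidence the features carry no domain
signature. Early stopping halts a phase after 5 consecutive epochs in which
the training loss fell but the test metric did not improve.

Three stabilizers keep the adversarial game alive at desk scale, where the
synthetic domains are far more separable than real scan-vs-photo archives:

* **Gradient floor.** Heads emit logits and the BCE gradient is computed in
  the stable `(p − y)` form; for the domain term, `p` is clamped to
  `[0.02, 0.98]` (`adversarial_floor`). Without this, a saturated domain
  classifier emits a vanishing logit-gradient and the reversal goes dead.
* **Gated reversal.** The encoder-side reversal multiplier is zeroed on
  batches where the domain classifier is at or below chance: reversing
  past that point would train the classifier to be *anti*-correct — a
  runaway that measurably wrecked the shared features (and with them the
  label task) in ungated runs. The classifier's own un-reversed update
  always proceeds, so the game oscillates boundedly around chance — which
  is exactly the checkpoint window.
* **Fresh domain head at phase 3** (`fresh_domain_head`, on by default):
  the head saturates during phase 2; restarting it while $\lambda$ is
  already high resumes the game from an unsaturated classifier.

## The saliency map

For a trained per-condition model in eval mode, the map is the gradient of
the predicted probability with respect to every input pixel and channel —
one backward pass, no weight updates, about the cost of a forward pass. For
the *absence* map we differentiate $1 - \hat y$, the exact negation: both
maps share a magnitude; they differ in what the sign means. Because the
gradient is taken with respect to the standardized input, we divide by the
per-channel scale so the map lives in original pixel units and aligns with
the displayed image.

Channel aggregation (maximum absolute partial over the three channels;
Euclidean norm available as an option) and per-image min–max scaling onto
integers 0–255 (round half up) are our choices — the published pipeline
scales to 0–255 without fixing either detail. Max-abs preserves
single-channel sensitivity peaks that an average would dilute. Scaled
values strictly above 20 become the binary saliency mask; masked pixels are
alpha-blended in purple over the source image.

Backpropagation through every layer down to the input is authored in this
package (im2col/col2im convolutions around BLAS matrix products) and is
pinned to central finite differences at relative tolerance $10^{-3}$ in the
test suite. The finite-difference oracle is only valid where the piecewise
linear activations are locally smooth, so the tests exclude elements whose
one-sided differences disagree — a kink straddle invalidates the oracle,
not the gradient.

## Agreement scoring

Against an expert annotation mask $a$ and algorithm mask $b$ of an $i
\times j$ image,

$$C = \frac{1}{i\,j}\Bigl(i\,j - \sum_{m}\sum_{n} |a_{m,n} - b_{m,n}|\Bigr),$$

the fraction of pixels on which the two masks agree. The double sum runs
over the same $i \times j$ grid that normalizes the coefficient — the only
reading under which $C(a,a) = 1$. The colocalization rule calls an image a
true positive when $\ge 90\%$ of the network's signal features lie on
relevant clinical features, a false positive below that, a true negative
when $\ge 90\%$ avoids irrelevant features, and a false negative when
$\ge 10\%$ lands on them; an empty saliency mask is an abstention, excluded
from the counts rather than silently scored.

## The synthetic ground truth

Each record is built from Gaussian bumps (P, Q, R, S, T) on a
condition-specific parameter table, scheduled by a condition-specific RR
model, projected onto the 12 standard leads by fixed scalar weights:

* sinus bradycardia: rate drawn in 42–56 bpm; tachycardia: 106–140 bpm;
* atrial fibrillation: P removed, RR intervals log-normal (σ = 0.25, CV
  ≈ 0.25, comfortably above the 0.1 "irregularly irregular" floor), plus a
  low-amplitude 4–9 Hz fibrillatory undulation;
* atrial flutter: P and T removed, a continuous ±0.2 mV saw-tooth at
  300/min most visible in the inferior leads and V1, ventricular response
  locked at 3:1 or 4:1;
* LBBB-like: broad notched QRS (> 120 ms by construction);
* PVC: 1–2 beats fire at 55% of the base RR with a wide bizarre complex
  and discordant T, followed by a compensatory pause.

Every rule is *re-derived* from the generated signal and annotations by
`check_condition_rule()` — rate from the median RR, QRS width from
fiducials, AF irregularity from the RR coefficient of variation, the
flutter saw-tooth from the dominant periodogram frequency of the longest
inter-QRS gap — so the generator cannot vacuously certify itself.

The renderer draws standard ECG paper (1 mm minor / 5 mm major grid) at
25 mm/s and 10 mm/mV, default 0.5 mm per pixel, in a 3 × 4 panel layout
with a lead-II rhythm strip and 1 mV calibration pulses. Ink is near-black
(luminance ≈ 5 of 256), below the segmentation threshold of 10 by
construction, and the renderer records the exact set of trace pixels as a
mask. The photo-artifact simulator composites four shadows per image
(attenuation uniform on [0.3, 0.7], shapes drawn with replacement from
polygons, ellipses and half-plane "single-source" shadows, each blurred
with σ = 3·attenuation px), a random projective warp (the mask is warped
with the same homography so it stays registered), and flash saturation
whose centre always clips to 255. Shadow compositing is multiplicative, so
grid texture survives under shadow as it does in real photographs.

What the generator does *not* emulate: vectorcardiographic lead
relationships, baseline wander, muscle artifact, crumpled paper,
handwriting, or the label noise of clinical archives. Passing tests
therefore demonstrate that the machinery is correct and that the method
behaves as designed on images whose ground truth is known exactly — not
that clinical-grade accuracy transfers to hospital data.

## Desk-scale study conditions

The bundled experiments are sized for a single CPU:

* network input 48 × 128 × 3. Training datasets are rendered *directly* at
  this scale (2 mm per pixel): the trace stays one crisp sub-threshold-dark
  pixel wide, the signal mask is exact, and grid strokes are blended by
  their sub-pixel coverage, as a downscaled scan would show them. The
  alternative (`render = "pooled"`) renders at 0.5 mm/px and shrinks with
  an exact area-weighted box filter, emulating a full-resolution scan
  resized for the network — traces then soften to gray;
* three encoder blocks of 12/24/48 channels, stride 2, kernels 8/4/4 — the
  larger first kernel makes neighbouring pixels share most of their
  gradient paths, which de-speckles saliency maps — and one 64-unit hidden
  layer per head;
* the label-transfer smoke task: 200 bradycardia-vs-tachycardia records,
  85/15 development/holdout split (94/6 train/validation within
  development), 100 photo-augmented target-domain records; phases 1/2/3 run
  16/16/12 epochs, dropout off (with a few hundred gradient steps it only
  degrades the decoder);
* Adam learning rate $10^{-3}$ for this reduced task. The published
  $4\cdot10^{-5}$ remains the package default: it suits long training on
  tens of thousands of images, while the smoke task sees only a few hundred
  gradient steps and needs a proportionally larger step size.

Two generator details matter more than they look. Records start at a
random phase of the cardiac cycle: with a fixed onset, the position of the
second beat alone encodes the RR interval, and the classifier learns that
single-location shortcut (its saliency collapses to one blob). And each
record draws its own print/scan style (paper tint, grid ink, baseline
placement, grid phase): with a pixel-identical background across the
corpus, nothing ever pushes the model to distinguish trace from
stationery.

Numerical conventions: probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ before logs; a constant image channel standardizes
to zeros (scale kept at 1); an all-zero saliency map scales to all zeros;
development/holdout sizes round to nearest (11,316 ids at 85% give
9,619/1,697); the blur gate accepts a Laplacian variance exactly at the
cutoff; Laplacian variance is the population variance of the 4-neighbour
convolution over interior pixels of BT.601 luminance; degenerate
(sub-3×3) images report variance 0 and are rejected; degenerate
perspective corner draws are rejected and resampled.

## Known limitations

The Jacobian is a first-order, per-pixel quantity: maps are granular, may
highlight only part of a repeated feature, and inherit any inaccuracy of
the classifier. The method requires a memoryless network — gradients of
recurrent or stateful models do not admit this reading, and such backbones
are rejected. The synthetic domains are more separable than scan-vs-photo
archives, which is precisely why the adversarial stabilizers described
above matter here; on real corpora the domain classifier typically stays
unsaturated on its own.

The sharpest known limitation is quantitative saliency concentration at
desk scale. A clinical-grade network at full image resolution produces
pixel-granular maps that hug the trace; a three-block network at 48 × 128
cannot. Its receptive fields blur attention into blobs several pixels
wide, so a blob centred on a QRS complex unavoidably covers background
around the one-pixel trace; a rate task moreover *legitimately* attends to
where beats could occur, not only to ink — clinical maps for bradycardia
highlight the long flat periods between peaks. In our experiments the
binarized-saliency lift on signal pixels plateaus around 1.1–1.6 (holdout
median; best images near 2) and does not grow with a 4× longer training
budget, while the same maps show clear baseline-band structure by eye. We
report the lift as measured rather than tuning the pipeline's published
constants (cutoff 20, per-image min–max scaling) toward a target.
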