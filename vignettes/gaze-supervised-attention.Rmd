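---
title: "Gaze-supervised attention training: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-supervised attention training: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gazecam)
```

## The problem

Classifiers for endoscopic lesion images (for instance, NICE-type grading of
colorectal polyps under narrow-band imaging) are limited by scarce expert
annotation and by poor interpretability: a network may classify well while
attending to clinically irrelevant regions. Expert eye gaze recorded during
routine image reading is a cheap, annotation-free signal of *where the
diagnostic evidence is*. This package trains a convolutional classifier whose
internal class-activation attention is supervised by such gaze, and provides
everything needed to exercise the method end to end without an eye tracker:
a phantom-lesion generator with simulated scanpaths, gaze-map rendering,
training, and a one-vs-rest evaluation suite.

## From fixations to a gaze-attention map

A fixation at screen position $(x_c, y_c)$ is spread into a gaze area with an
isotropic Gaussian

$$G(x,y) = \frac{1}{\sqrt{2\pi}\,\sigma}
  \exp\!\left(-\frac{(x-x_c)^2+(y-y_c)^2}{2\sigma^2}\right),$$

where $\sigma$ (pixels) is the effective field-of-view radius. `render_gaze_map()`
maps screen fixations into image coordinates (the image is assumed displayed
centered at native size; the offset is overridable), drops off-image fixations
rather than clamping them (clamping would pile spurious mass on borders),
accumulates an impulse image (unit weight per fixation; duration weighting is
available but off by default, as the standard protocol does not state it), and
smooths with a separable discrete Gaussian (default $\sigma = 30$ px, 199 taps,
zero-padded borders with a reflect option). The map is then max-normalized to
$[0,1]$; an all-zero map (no in-image fixations) stays zero and is reported
with a warning, not an error. Because of the max-normalization, the $1/(\sqrt{2\pi}\sigma)$
constant in $G$ cancels; it is implemented as written for fidelity but is
immaterial.

`effective_sigma()` provides the geometric calibration behind the $\sigma$
preset: an angular error $\theta$ at viewing distance $R$ subtends a physical
arc $\pi R \theta/360$ on the screen, which converts to pixels through the
pixel density, giving
$\sigma = (\theta/360)\,\pi R\,\sqrt{H_pW_p/(HW)}$.
With a 1920×1080 display of 64×48 cm, $\theta = 1^\circ$ and $R \in [50, 80]$ cm
this evaluates to roughly 11.3–18.1 px. The default rendering preset of 30 px
deliberately over-covers this range so that residual tracker error is absorbed;
it is a parameter, not a constant.

Coordinates are 0-based with a pixel-center convention and origin at the top
left throughout.

## The attention-supervised classifier

The classifier is a standard feature extractor + global average pooling (GAP) +
linear head. The bundle contract exposes the last spatial feature map
$F \in \mathbb{R}^{h\times w\times C}$ and the head weights $W \in
\mathbb{R}^{K\times C}$; logits are $W\,\mathrm{GAP}(F)+b$. The network's
attention for class $k$ is the class-activation map

$$A_{\mathrm{raw}}(i,j) = \sum_c \max(W_{kc}, 0)\, F(i,j,c),$$

bilinearly upsampled (align-corners = false; CAM values differ across resize
conventions, so this is fixed explicitly) to the gaze map's resolution and
squashed with a sigmoid. The rectifier is applied to the class weight vector by
default; rectifying the summed map instead is available via `relu_on = "map"`.
During both training and inference the *predicted* class's weights are used
(`cam_class = "true"` is available), so no label is needed to explain a
prediction.

Training minimizes, per mini-batch,

$$\mathcal{L} = \mathrm{CE}(\mathrm{logits}, y)
  + \lambda\,\mathrm{MSE}\!\left(A_{\mathrm{model}},\ T(A_{\mathrm{human}})\right),$$

with $\lambda = 1$ by default and $\lambda = 0$ the no-gaze ablation baseline.
`attention_mse()` is the plain mean over all pixels, which keeps the term
resolution-independent and on the same scale as the cross-entropy.

### Why the supervision target is range-matched

$T$ deserves its own section because it is the one place where a seemingly
innocuous convention decides whether the method works at all. The rectified CAM
is nonnegative, so the sigmoid-activated attention lives in $[0.5, 1)$ — it
can never reach the zeros that dominate a max-normalized gaze map. If the
training loss compares $A_{\mathrm{model}}$ against $A_{\mathrm{human}}$
directly, roughly 90% of the pixels carry an *unattainable* background error of
at least $0.25$, and its gradient — the overwhelming share of the consistency
signal — only ever says "shrink the map". Empirically this collapses the
attention to the flat $0.5$ floor (we measured the flat-map loss floor at 0.202
against a best attainable 0.199 on the synthetic maps) and makes gaze
supervision *hurt* localization. The fix is to supervise toward the
range-matched target

$$T(h) = \tfrac{1}{2}(1 + h) \in [0.5, 1],$$

a monotone rescaling that puts the optimum inside the model's reachable set:
background pixels are satisfied exactly at raw CAM 0, and the entire gradient
budget goes into raising attention where the expert looked. Gaze maps
themselves keep the $[0,1]$ max-normalized contract everywhere else in the
package; the matching happens only inside the training objective.

### Optimization protocol

Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) with initial
learning rate $10^{-3}$ under cosine-annealing warm restarts: within a cycle of
length $T_i$ epochs, $\eta = \eta_{\min} + (\eta_{\max}-\eta_{\min})
(1+\cos(\pi t/T_i))/2$, with $T_0 = 10$ and cycle lengths doubling, so restarts
fall at epochs 10, 30, 70 within the default 150-epoch budget. The scheduler is
stepped per epoch. Batch sizes default to 8 (training) and 16 (validation).
There is no early stopping; after every epoch the validation accuracy is
evaluated (without augmentation, the standard practice) and the best-validation
parameters are returned. Augmentation applies one geometric transform —
horizontal/vertical flips at probability 0.5 and a right-angle rotation —
identically to the image and its gaze map; right angles avoid interpolating the
gaze map. Class weighting is off by default with inverse-frequency weights
available behind `class_weights`.

The reference backbone is a three-block strided (3×3, stride 2) convolutional
network with channels 16/32/32, mapping 64×64 RGB inputs to an 8×8×32 feature
map — small enough for CPU training and finite-difference gradient checks.
Inputs are centered ($x - 0.5$) inside the forward pass: with all-positive
inputs the first-layer gradients share signs and Adam stalls badly (an
8-sample overfit that takes ~150 steps with centering was still at chance
after 300 without). Production-scale backbones can be plugged in through the
same bundle contract, with pretrained weights as an input.

All gradients are computed in closed form (im2col convolutions, GAP head, CAM,
resize operator, sigmoid, both losses) and are verified in the test suite
against finite differences and against nested-loop forward oracles.

## Evaluation

Multiclass performance uses the one-vs-rest protocol: for class $k$,
$\mathrm{TP} = \mathrm{cm}[k,k]$ with FP/FN/TN from the row/column/complement
of a confusion matrix stored predictions-in-rows. Accuracy, precision, recall,
F1 and the Matthews correlation coefficient follow their binary definitions
per class; zero denominators yield 0 with a warning. Aggregates are unweighted
macro means by default (`average = "weighted"` is available; published reports
often do not state which is used, so both exist). Cohen's kappa,
$(p_0-p_e)/(1-p_e)$, is computed once on the full matrix. AUC is the rank
(Mann–Whitney) statistic with midrank ties, averaged one-vs-rest over classes
present; this threshold-free form is exactly equal to the all-pairs count and
is tested as such. The per-class Matthews coefficient is macro-averaged; the
generalized single-matrix form is not reported.

Attention quality is quantified by `attention_alignment()`: the attention map
is binarized at its own Otsu threshold (a fixed threshold is available) and
intersection-over-union with the ground-truth lesion mask is reported. This is
a deliberately simple, deterministic stand-in for the qualitative "does the
model look at the lesion" inspection of CAM overlays.

## The synthetic study

`synthesize_polyp_data()` emulates the *statistical structure* the
attention-consistency loss assumes — three visually distinct lesion classes,
gaze density peaked on the diagnostic region, patient-level grouping — and
deliberately not the pixel statistics of real narrow-band endoscopy. Each
64×64 phantom carries one elliptical lesion (axes 0.16–0.26 and 0.12–0.20 of
the image, random center and orientation) on a noisy mucosa-toned background
with a shared brightness jitter (shared across channels so that lesion hue
signatures survive global pooling). The class determines the texture rule, and
the rule is chosen so the label is recoverable from pixels by construction:

* class 0 — smooth pale lesion (blue-lifting tint, near-zero vessel density);
* class 1 — tubular high-granularity texture: brown stripes of wavelength
  3–5 px that depress green/blue strongly and red barely
  (vessel density 0.7–1);
* class 2 — darkened lesion with a dark, irregularly wobbled core.

The test suite holds the generator to two contracts: a fixed pixel-statistics
rule (inner-decile darkness, then high-frequency energy) must recover ≥95% of
labels, and the reference backbone must reach ≥90% test accuracy within 30
epochs on most seeds. The texture amplitudes above were calibrated against
those two contracts.

Scanpaths draw 20–60 fixations; each lands on the lesion with probability 0.8
(centroid plus isotropic Gaussian scatter of half the equivalent radius
$\sqrt{\mathrm{area}/\pi}$, redrawn while off-image) and otherwise uniformly
over the image, at ~90 Hz with plausible fixation durations. Fixations are
recorded in screen coordinates with the image centered on a simulated
1920×1080 display, exercising the same coordinate transform as real logs.
Gaze maps for the synthetic study are rendered with the smoothing width scaled
to resolution ($\sigma = 30\cdot s/512$ px at image size $s$, kernel support
≈ 6.6σ), keeping the angular extent of the field-of-view model constant; at
the native ~512 px working resolution this reduces to the 30 px / 199-tap
preset.

Patient-level splitting assigns whole patients to train/validation/test by
largest-remainder apportionment of 60/20/20, so counts are exact at the
patient level and no patient leaks across splits.

What passing tests on this generator do show: the full pipeline is internally
consistent, the losses and metrics are exactly what their formulas say, and
gaze supervision measurably improves attention-lesion alignment at matched
accuracy under controlled conditions. What they do not show: performance on
real endoscopic imagery, robustness to tracker noise beyond the Gaussian
spread model, or inter-expert gaze variability — none of which the phantom
world contains.

## Problem sizes and numerical choices

The reference experiments train the tiny backbone on ~150/50/50 images
(30 patients, 6–10 images each) for 30 epochs per arm, three seeds per arm —
about half a minute per run on one CPU. Determinism is exact: datasets and
loss histories are bit-identical given the same seed (single-threaded).
Degenerate inputs are handled explicitly: empty fixation lists give warned
all-zero maps; an all-constant attention map has no Otsu threshold and
binarizes empty; zero metric denominators give 0 with a warning; MSE with
mismatched shapes, out-of-range class indices, and empty lesion masks are
errors. Ties in argmax predictions break toward the lower class index.

## Known limitations

* The consistency loss acts through the rectified weights of one class; a
  class whose evidence is encoded purely negatively (recognized by absence)
  receives no attention gradient. Wide heads mitigate this; the range-matched
  target prevents the degenerate flat-map solution but cannot invent positive
  evidence.
* Gaze is assumed fixation-level; saccade detection from raw streams is out
  of scope.
* The phantom generator is a structural, not photometric, model of endoscopy.
* Single-threaded CPU training only; the implementation favours exactness and
  reproducibility over speed.
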