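---
title: "Bilateral symmetry evaluation for mastoid radiographs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral symmetry evaluation for mastoid radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastosym)
```

## The model

Mastoid air cells are highly variable between individuals but nearly
mirror-symmetric within one person. `mastosym` classifies mastoiditis on an
AP radiograph by processing both ears with a *single* convolutional stream
(weight sharing), and supervising the *difference* of the two resulting
feature maps with a symmetry-grade label.

One stream maps a 384×256 single-ear image through six pre-activation
residual blocks to a 12×8×3 **category feature map**: 3 channels of spatial
evidence, one per mastoiditis category (normal / mild / severe). Each block
is group-normalized, ReLU-activated, twice 3×3-convolved, and channel-gated
by a squeeze-and-excitation (SE) module; a 1×1 projection carries the
shortcut across stride or width changes. A final group-norm/ReLU/1×1
projection produces the 3 evidence channels.

The per-side classifier applies Log-Sum-Exp pooling to each channel,

$$\mathrm{LSE}_r(M) = \frac{1}{r}\,\log\!\Big(\tfrac{1}{HW}\sum_{h,w}
  e^{\,r\,M_{hw}}\Big),$$

followed by a softmax over the three pooled logits. LSE pooling
interpolates between mean pooling ($r\to 0$) and max pooling
($r\to\infty$); it always lies in $[\mathrm{mean}(M), \max(M)]$, which the
test suite checks on random grids along with the exact formula.

The **symmetry evaluation layer** computes $D = |M_R - M_L|$ element-wise.
A grade classifier pools $D$ per channel (after a learnable 1×1 channel map
by default, see below) and softmaxes over three symmetry grades: 0 (equal
categories), 1 (one-stage difference), 2 (normal vs severe). Because the
streams share weights and $|\cdot|$ is symmetric, exchanging the two input
halves exactly swaps the per-side outputs and leaves the grade prediction
unchanged — an exact identity in inference mode, not an approximation,
which is why the normalization layers are batch-independent (group norm,
never batch statistics).

Training minimizes
$$L = \mathrm{CE}_\text{right} + \mathrm{CE}_\text{left}
      + 2\,\mathrm{CE}_\text{sym},$$
i.e. the symmetry loss is added to each side's classifier loss and the two
sums are added. The factor 2 is the literal reading of that composition; a
`symmetry_weight` knob (default 1 per side) exists but is not used by any
default. Optimization is RMSprop (initial learning rate $10^{-4}$, decay
0.9, epsilon $10^{-7}$), mini-batch 4, He-initialised weights. Epoch budget
and early stopping (patience on mean validation total loss, best-epoch
weights restored) are this package's choices; nothing in the training
recipe itself prescribes a stopping rule. The single-side baseline is one
stream plus one classifier trained with plain categorical cross-entropy
under identical settings.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lse_r` | 5 | LSE sharpness (dimensionless); larger ≈ max pooling. Unstated in the recipe; 5 gives a pooled value sensitive to a localized hot region of the 12×8 map without collapsing to a single pixel. |
| `block_strides` | 1,2,2,2,2,2 | 32× total reduction fixes the 12×8 map for a 384×256 input. Stride placement is free; we downsample after the first full-resolution block. |
| `block_widths` | 16…256 | capacity schedule; free choice. |
| `se_reduction` | 8 | SE bottleneck ratio, floored at 1 unit. |
| `symmetry head` | `linear` | see below. |
| learning rate / batch | 1e-4 / 4 | fixed by the training recipe. |

**Symmetry head variants.** The difference map's channels index
*categories*, not *grades*. A parameter-free head (`direct`) pools the raw
category-difference channels, implicitly identifying channel $c$ with grade
$c$ — representable only if "difference in the severe channel" is evidence
for grade 2, which is not guaranteed. The default `linear` head inserts a
learnable 3×3 channel map (plus bias) so the three pooled channels
genuinely parameterize grades; with an all-zero difference map its logits
reduce to the bias alone. Both variants are implemented and tested;
`direct` retains the property that identical sides give exactly zero grade
evidence, which the CAM tests exploit.

## Preprocessing geometry

Crops are physical: a 180 mm × 120 mm box (rows × columns), converted to
pixels via the DICOM PixelSpacing (`round(180/row_spacing)` ×
`round(120/col_spacing)`), centred at fractional coordinates
(0.5 H, 0.25 W); the left-ear box is the *mirror reflection* of the
right-ear box about the vertical midline. Defining the left box by
reflection (rather than independently rounding a box at 0.75 W) keeps the
mirror property exact: reflecting the radiograph and re-cropping swaps the
two crops pixel-for-pixel, and a perfectly mirror-symmetric subject yields
bit-identical right and left network inputs after the left flip. Both crop
centres agree with (0.5 H, 0.25/0.75 W) within one pixel.

Order of operations: read (rescale slope/intercept, MONOCHROME1 inversion
so brighter = denser) → crop → flip left → bilinear resize to 384×256 →
per-image min–max normalization to [0, 1] → vertical concatenation (right
on top). Min–max per image is robust to vendor-specific intensity scales; a
zero-range crop normalizes to zeros with a warning rather than an error.
Boxes overhanging the image by ≤ 10% of their size are clamped inside;
larger overhangs raise a geometry error rather than silently shifting.

## The phantom generator

The generator emulates exactly the statistical structure the method
assumes, and nothing more:

* a skull-like smooth background, mirror-symmetric by construction;
* a per-subject air-cell texture (thresholded smoothed noise — "blobby"
  cells of ~5 mm grain) placed in an ellipse at the two crop centres,
  mirrored within subject up to a translation jitter
  (`asymmetry_jitter_mm`, default 1 mm);
* large between-subject variation: lucency depth is log-normal
  (`anatomy_variation` = 0.35 sd on the log scale), pneumatization
  fraction and background level also vary;
* category effects as opacity mixing: haziness levels (0.05, 0.35, 0.90)
  fill the air-cell lucency toward bone intensity, plus a bright sclerotic
  rim for severe disease so severe differs in texture as well as mean;
* additive Gaussian noise, then DICOM serialization with correct
  PixelSpacing.

With jitter and noise at zero, a grade-0 subject is *exactly* mirror
symmetric — the structural assumption the symmetry layer exploits — and
the composed right/left inputs are identical to machine precision. The
truth grade distribution is by construction the pushforward of the joint
pair distribution under $|r-l|$.

What the phantom does **not** model: real air-cell anatomy, projection
physics, lateral views, postoperative change, patient positioning error
beyond a rigid texture shift. Passing the benchmark therefore shows that
the implementation learns and that symmetry supervision helps *in the
regime the phantom encodes* (mild disease subtle per-ear but clear
relative to the contralateral side); it is not evidence about clinical
performance.

## The benchmark and its sizing

The benchmark preset renders views at 2.0 mm spacing (250×200 px), so the
physical 180×120 mm crops come out at 90×60 px and are resized to 96×64 —
a 4× downscale of the full-resolution pipeline. The benchmark stream keeps
the six-block SE-residual layout with reduced widths (8, 8, 16, 16, 24, 24)
and an immediate stride-2 first block, producing a 3×2×3 feature map.
Training runs at the standard recipe (RMSprop 1e-4, batch 4) for at most
20 epochs with patience 5 on validation loss. One replicate — 920
generated subjects split 600/120/200 by stratified sampling on the
symmetry grade, both architectures trained and evaluated — takes a few
minutes on one CPU; the acceptance suite runs three seeded replicates.
These sizes are the package's own benchmark design, chosen to make the
three-replicate comparison routine on a laptop-class machine.

In this regime both models detect severe disease essentially perfectly and
miss most mild ears on absolute grounds; the comparison between them is
carried by how well the learned features separate mild from
poorly-pneumatized normal. The bilateral model's only extra information is
the symmetry loss (per-side predictions still see one ear each), so the
expected advantage is a multi-task regularization effect — consistent in
direction, modest in size. The epoch budget matters here: the auxiliary
grade task converges much more slowly than the per-side classifiers (its
cross-entropy sits at the grade-prior entropy for roughly the first ten
epochs before dropping), so a shorter budget leaves the symmetry path
inert and the two architectures statistically indistinguishable.

## Numerical choices

* LSE pooling is computed with a max-shift; its gradient is the softmax
  weighting $e^{rM_{hw}}/\sum e^{rM}$.
* Cross-entropy floors probabilities at $10^{-12}$ inside the log.
* Group-norm epsilon is $10^{-5}$; group count is the largest divisor of
  the channel count ≤ 8 (so width-1 inputs degrade to instance norm).
* The absolute-difference backward uses `sign(M_R − M_L)`, with
  subgradient 0 at exact equality.
* Dichotomization ties (p(normal) equal to the best abnormal probability)
  resolve positive: a screening rule, favouring sensitivity. The ROC score
  is `1 − p(normal)`, the threshold-free extension of that decision.
* Stratified splitting rounds each stratum's validation share to the
  nearest subject and warns on strata smaller than 6.
* The whole backward pass is verified against central finite differences
  (worst relative error ~2×10⁻⁴ on a non-degenerate small model), and
  training is bitwise reproducible from the seed.

## Statistics

AUC is the Mann–Whitney statistic; its CI and the one-sided paired
comparison use DeLong structural components (cross-checked in the tests
against pROC, a jackknife variance oracle and a 10,000-draw sign-flip
permutation oracle). Proportion CIs are exact Clopper–Pearson Beta
quantiles (also used for accuracy, for consistency with the exact method
elsewhere). McNemar tests use the exact binomial tail for fewer than 25
discordant pairs and the continuity-corrected chi-square otherwise; both
are available in verbose mode. The two ears of one subject are treated as
independent observations throughout — the convention of the underlying
clinical analysis — and no within-subject clustering correction is applied
to DeLong variances; a conservative reader should keep that in mind when
interpreting phantom CIs.

## Known limitations

* Per-side predictions cannot consult the contralateral image at inference;
  the symmetry path acts only through shared-feature shaping during
  training.
* A postoperative (category 3) ear has no network output class; the
  pipeline excludes such subjects, and `read_label_table()` flags rather
  than drops them so exclusion counts stay auditable.
* The DICOM layer is deliberately minimal (Explicit VR little endian,
  single-frame 16-bit grayscale) — sufficient for the phantom round-trip
  and cross-checked against pydicom, not a general DICOM implementation.
* CPU-only training: practical at the benchmark scale, not at the
  full 384×256 scale with the default widths.
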