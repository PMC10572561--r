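---
title: "Translating early-uptake PET to delayed-uptake PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating early-uptake PET to delayed-uptake PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Internal dosimetry of diagnostic radiopharmaceuticals requires the tracer
distribution at several times post-injection, because cumulative activity is
obtained by integrating a time–activity curve (TAC) fitted per organ.
Acquiring a whole-body PET volume at three or more time points is costly and
burdensome for the subject.  `delaypet` implements a paired image-to-image
translation approach to this problem: a conditional adversarial network is
trained on pairs of axial slices from early-uptake and delayed-uptake
acquisitions of the same subjects, and then predicts the delayed appearance
from a single early scan.  The quantity of clinical interest downstream is
the organ-wise mean standardized uptake value (SUV~mean~) read from the
synthetic delayed volume.

## Model

**Generator.** An encoder–decoder with mirrored skip connections (U-Net
style).  All resampling is by 4×4 convolutions: stride-2 convolutions
halve the resolution on the way down, stride-2 transposed convolutions
double it on the way up; there is no pooling.  Encoder activations are
leaky rectifiers (slope 0.2), decoder activations are rectifiers, and a
final hyperbolic tangent bounds outputs in $[-1, 1]$.  Normalization
layers (batch by default, instance selectable) follow every convolution
except the first encoder block and the output block.  Weights are
initialized from a zero-mean Gaussian with standard deviation 0.02.

**Discriminator.** A patch critic: a stack of 4×4 convolutions
(`n_layers` stride-2 stages followed by two stride-1 stages) whose output
is a 2D grid of raw scores, each judging the realness of one local patch
rather than the whole image.  This preserves high-frequency detail in the
generated slices.  The critic is conditional in the pix2pix sense: it sees
the early slice channel-concatenated with either the true or the generated
delayed slice.  With the default three stride-2 stages the analytic
receptive field of one score is 70 pixels (`receptive_field()`), and the
package verifies this against a brute-force influence map.

**Adversarial losses.** Three interchangeable objectives act on the raw
patch scores (averaged over patches and batch):

- *Cross-entropy (vanilla) GAN*:
  $L_{GAN}(D,G) = \mathbb{E}_{x\sim p_d}[\log\sigma(D(x))] +
  \mathbb{E}_{\tilde x\sim p_g}[\log(1-\sigma(D(\tilde x)))]$.
  The discriminator minimizes the negative of this; the generator uses the
  literal saturating objective by default (minimizing
  $\mathbb{E}[\log(1-\sigma(D(\tilde x)))]$), with a non-saturating switch
  available.  The saturating default is deliberate: the instability of the
  cross-entropy objective in this low-style-contrast translation problem
  is part of what the loss comparison is meant to expose.
- *Least-squares GAN*:
  $L_{LSGAN}(D) = \tfrac12\mathbb{E}[D(\tilde x)^2] +
  \tfrac12\mathbb{E}[(D(x)-1)^2]$,
  $L_{LSGAN}(G) = \tfrac12\mathbb{E}[(D(\tilde x)-1)^2]$.
- *Wasserstein GAN with gradient penalty*:
  $L_{WGAN\text{-}GP}(D) = \mathbb{E}[D(\tilde x)] - \mathbb{E}[D(x)] +
  \lambda_{gp}\,\mathbb{E}[(\lVert\nabla_{\hat x}D(\hat x)\rVert_2-1)^2]$
  with $\hat x = \epsilon x + (1-\epsilon)\tilde x$,
  $\epsilon\sim U(0,1)$ per sample, and $L(G) = -\mathbb{E}[D(\tilde x)]$.
  The interpolation acts on the full conditional input; because the
  conditioning channel is identical in the real and fake inputs it passes
  through unchanged.  The critic is built without normalization layers so
  that the per-sample input gradient is well defined; the penalty's
  parameter gradients are computed by an exact double-backward pass through
  the piecewise-linear critic (activation masks are constant almost
  everywhere, so treating them as fixed is exact off a measure-zero set).
  Both facts are verified in the test suite: against finite differences,
  and against the closed form $\lambda_{gp}(\lVert w\rVert-1)^2$ for linear
  critics.

**Similarity losses.** Two options, weighted into the total objective:

- *L1*: mean absolute voxel difference, preferred over squared error for
  its lower blurring.
- *Perceptual*: $\alpha L_{content} + \beta L_{style}$ with
  $L_{content} = \sum_i \frac{w^c_i}{C_iH_iW_i}
  \lVert V_i(G(x)) - V_i(y)\rVert_2^2$ and
  $L_{style} = \sum_i w^s_i \lVert Gr(V_i(G(x))) - Gr(V_i(y))\rVert_F^2$,
  where $V_i$ is the $i$-th feature block and
  $Gr_{jk} = \sum_{h,w} F_{jhw}F_{khw} / (C_iH_iW_i)$ is the normalized
  Gram matrix.  The Gram normalization by $C_iH_iW_i$ is adopted so the
  perceptual weight is not tied to the feature dimensions.

**Total generator objective.**
$L_{total} = L_{adv}(G,D) + \lambda_{sim} L_{sim}(G)$ with the
discriminator held fixed; $\lambda_{sim}$ is $\lambda_{L1} = 200$ for the
L1 term and $\lambda_{perceptual} = 0.1$ for the perceptual term,
$\lambda_{gp} = 10$, and all content/style weights default to 1.

## The feature extractor is pluggable

The perceptual loss and the Fréchet-distance encoder are both defined
against an abstract block-structured feature extractor.  The default is a
small frozen convolutional encoder with weights drawn once from a fixed
seed (`feature_extractor()`), using fan-in-scaled initialization so
feature magnitudes stay of order one through depth.  This keeps the
package fully self-contained and deterministic with no downloads; a large
pretrained network (a deep VGG-style extractor for the perceptual loss, an
inception-style encoder for the distribution distance) can be substituted
by supplying any object with the same block interface.  Fréchet distances
are only comparable within one encoder choice, so every report records the
encoder identity string.

## Training protocol

Mini-batches of 4 slice pairs; Adam for both networks with initial
learning rate $2\times10^{-4}$, $\beta_1 = 0.5$, $\beta_2 = 0.999$; the
learning rate at epoch $e$ (counted from 0) is
$2\times10^{-4}\times0.98^{e}$, checked to $10^{-12}$ relative accuracy in
the tests.  Each step updates the discriminator first (gradient penalty
included in the critic step only), then the generator through the updated
critic, at a 1:1 ratio.  The default epoch count is 200 and is freely
configurable; when a validation set is supplied, the reported generator is
the checkpoint with the best validation PSNR.  Every source of randomness
(weight initialization, shuffling, interpolation draws) hangs off one
seed, and the whole `TrainHistory` is reproducible bit for bit; a resumed
checkpoint (which carries the random-number state) reproduces the
uninterrupted history exactly.

## Data handling

Volumes are stored on disk in SUV units (NIfTI-1, axial slices along the
last header dimension).  Normalization to $[-1, 1]$ happens in memory at
training time: one affine map per subject, fitted over the union of that
subject's early and delayed stacks.  This pair-level scope is a deliberate
design choice where slice-, volume- and dataset-level alternatives were
also defensible: it is the only scope under which the temporal uptake
change remains visible to the network (a per-volume map would renormalize
it away) while the map stays exactly invertible for SUV readout.  Slices
without signal are kept; no exclusion rule is applied.  Subject splits are
assigned at the subject level, so slices of one subject can never appear
in two splits.  With 18 subjects split 12/4/2 at 389 slices per subject
the split sizes are exactly 4668/1556/778 slices; the package always
derives slice counts from the subject-level assignment, rather than
accepting externally quoted totals, which are occasionally inconsistent
with that arithmetic (e.g. a quoted test count of 776 for a 2-subject
split).

## The kinetic phantom

Clinical paired two-time-point studies are rarely shareable, so the
package ships a digital phantom that generates paired stacks with known
ground truth.  It emulates:

- seven organ regions (brain, heart, liver, spleen, kidney, muscle/torso,
  bladder) as per-slice ellipses at anatomical axial fractions, painted in
  an explicit priority order (later organs override earlier ones where
  masks overlap), with a voxel-center containment test and 1-based
  `(slice, row, col)` indexing, slice 1 at the top of the head;
- organ kinetics as linear combinations of exponential basis terms
  $\sum_j A_j e^{-k_j t}$ ($A$ in SUV, $k$ in 1/min) — rising curves such
  as bladder filling are expressed in the same basis as
  $A(1-e^{-kt}) = A - Ae^{-kt}$.  Defaults are illustrative FDG-like
  curves: brain/heart/muscle rise to a plateau, liver/spleen/kidney decay
  slowly, and the bladder combines a decaying vascular term with a strong
  slow filling term;
- per-subject kinetic variability: each organ's amplitudes are scaled by a
  subject factor (sd 0.08), and the bladder's vascular and filling
  components are additionally scaled by two independent factors (sd 0.4).
  The independence is the point: late bladder activity is then only
  weakly predictable from the early frame, emulating the clinically
  unpredictable bladder filling that makes it the canonical failure region
  of early-to-delayed translation;
- Poisson-like counting noise (activity scaled to expected counts at 50
  counts per SUV by default, drawn, and rescaled), optional additive
  Gaussian noise, and stylized reconstruction degradations (Gaussian blur
  conserving total activity to within 1%, and a bounded correlated streak
  pattern).

It does **not** emulate sinogram-level physics: no attenuation, scatter,
randoms, detector response or real reconstruction algorithms, no
anatomical inter-subject variability, and no motion between time points
(pairs are perfectly registered by construction).  Passing the end-to-end
tests therefore shows that the implementation learns a real two-time-point
kinetic mapping under realistic noise and inter-subject kinetic spread —
not that clinical-grade image quality or clinical SUV accuracy has been
demonstrated.

## Evaluation

- **PSNR**: $10\log_{10}(R^2/\mathrm{MSE})$ computed on normalized data
  with $R = 1$ (the package convention for $[-1,1]$ intensities; a flag
  selects $R = 2$ for the conventional full dynamic range).  Identical
  images are reported at a documented 99 dB cap instead of infinity.
- **Fréchet distance**: Gaussians are fitted to the encoded features of the
  two slice sets (sample mean, sample covariance) and compared via
  $\lVert\mu_d-\mu_g\rVert^2 +
  \mathrm{Tr}(C_d + C_g - 2(C_dC_g)^{1/2})$.  The matrix square root uses
  the eigendecomposition of $C_d^{1/2}C_gC_d^{1/2}$ with eigenvalues below
  $10^{-10}$ clipped to zero; substantial negativity raises a warning.
  Test slices are pooled across subjects by default.
- **Axial profile**: per-slice PSNR of the generated stack and of the
  untranslated early stack against the delayed ground truth, with their
  difference in dB and their ratio — the "ratio" of a translation-gain
  profile is not uniquely defined, so both are reported.
- **SUV readout**: organ means are computed on denormalized stacks only
  (the normalization parameters must be consumed first), with voxel-center
  membership and no partial-volume weighting.  On noiseless phantoms the
  readout recovers the programmed TAC values to $10^{-9}$.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script exercise the full pipeline at
desk scale, a deliberate configuration of the same machinery: 10 subjects
with 24 axial 32×32 slices each (240 slice pairs; 6/2/2 subject split),
acquisition times 14 and 52 min, generator with 3 downsampling stages at
12 base channels, a 2-stage patch critic at 16 base channels, 15 epochs.
Under these conditions the least-squares adversarial loss with either
similarity term improves the median held-out PSNR over the untranslated
early baseline, the improvement concentrates in the mid-body slices, and
the bladder slices improve least — the qualitative signature expected of
early-to-delayed tracer translation.  Epoch counts, organ kinetics and
noise levels are package defaults chosen once for realism, not fitted to
any external result.

## Known limitations

- The 2D slice-wise generator ignores axial continuity; a 3D
  convolutional variant is out of scope.
- The default feature extractor is a random (if fixed) encoder: its
  Fréchet distances order image sets sensibly but are not comparable to
  values computed with pretrained inception features.
- The phantom's geometric simplicity (elliptical organs, shared anatomy
  across subjects) makes the translation task easier than clinical data;
  SUV error magnitudes on the phantom should not be read as clinical
  accuracy estimates.
- Unpaired or semi-supervised translation, tumor kinetics, and dosimetry
  integration (S-values, cumulative activity) are out of scope.
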