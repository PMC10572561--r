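Package: delaypet
Title: Paired Image-to-Image Translation of Early- to Delayed-Uptake PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains a conditional adversarial translation model that maps an
    early-uptake positron emission tomography (PET) image to a synthetic
    delayed-uptake image, for organ-wise standardized uptake value (SUV)
    estimation from a single early scan.  Provides a U-Net style generator and
    patch-based discriminator built on a self-contained reverse-mode
    differentiation core, six adversarial/similarity loss combinations
    (vanilla GAN, least-squares GAN and Wasserstein GAN with gradient penalty,
    each paired with an L1 or perceptual similarity term), Frechet-distance
    and peak signal-to-noise ratio evaluation, organ-wise SUV readout, and a
    kinetic digital phantom that simulates paired two-time-point whole-body
    tracer studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
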