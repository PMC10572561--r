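# delaypet

Paired image-to-image translation of early-uptake PET into synthetic
delayed-uptake PET, for organ-wise SUV estimation from a single early scan.

## The problem

Internal dosimetry of radiopharmaceuticals needs the tracer distribution at
several times post-injection: cumulative organ activity comes from
integrating a time–activity curve fitted through multiple acquisitions.
Scanning a subject three or four times after one injection is expensive and
burdensome. `delaypet` trains a conditional adversarial network on paired
axial slices of early- and delayed-uptake acquisitions, then predicts the
delayed appearance — and the organ-wise mean standardized uptake value
(SUV_mean) — from the early scan alone. It is aimed at researchers in
quantitative PET / molecular imaging methodology who want a transparent,
fully self-contained R implementation to experiment with.

## The model

A U-Net-style generator G (4×4 stride-2 convolutions down, transposed
convolutions up, mirrored skips, tanh output in [−1, 1]) is trained against
a conditional PatchGAN discriminator D that scores local patches of
(early, delayed) slice pairs. Six objectives are available — every
combination of an adversarial term

- vanilla GAN: binary cross-entropy of sigmoid-transformed patch scores,
- LSGAN: ½E[D(x̃)²] + ½E[(D(x)−1)²] for D, ½E[(D(x̃)−1)²] for G,
- WGAN-GP: E[D(x̃)] − E[D(x)] + λ_gp E[(‖∇_x̂ D(x̂)‖₂ − 1)²],

with a similarity term

- L1: mean absolute voxel difference (λ_L1 = 200), or
- perceptual: α·content + β·style over a pluggable feature extractor, with
  normalized Gram-matrix style representations (λ_perceptual = 0.1),

giving the generator objective `L_total = L_adv + λ_sim · L_sim`.
Training uses mini-batches of 4, Adam (lr 2e-4, β₁ = 0.5, β₂ = 0.999) and
a 0.98^epoch learning-rate decay. Everything — including the WGAN-GP
double-backward — is implemented in R on a small reverse-mode
differentiation core and verified against finite differences and closed
forms. Evaluation provides the Fréchet distance between encoded feature
distributions, per-slice PSNR (R = 1 on normalized data), the axial
PSNR-improvement profile, and organ-wise SUV_mean error tables.

A kinetic digital phantom (`phantom_study()`) generates paired two-time-point
whole-body studies with seven organs whose activities follow exponential
time–activity curves, Poisson-like noise, per-subject kinetic variability
(strongest for the bladder, whose filling is clinically unpredictable), and
optional reconstruction-style degradations — so the whole pipeline runs and
is tested without any clinical data.

## Worked example

```r
library(delaypet)

study <- phantom_study(n_subjects = 10, seed = 11)   # 24 slices of 32x32, 14/52 min
ids   <- vapply(study$subjects, `[[`, "", "id")
split <- split_subjects(ids, c(6, 2, 2), seed = 11)

tr <- as_paired_samples(study, split$subject_id[split$split == "train"])
va <- as_paired_samples(study, split$subject_id[split$split == "val"])

m <- pet_translator(tr, loss = "lsgan+l1",
                    generator = generator_spec(c(32, 32), n_down = 3, base_channels = 12),
                    discriminator = discriminator_spec(n_layers = 2, base_channels = 16),
                    control = train_control(epochs = 15, seed = 11), val = va)
print(m)
#> <pet_translator> lsgan + l1, 15 epochs on 32x32 slices
#>   final losses: D 0.0444, G 8.4788 (adv 0.4238, sim 0.04027)
#>   best validation PSNR 24.82 dB at epoch 14

rep <- evaluate_study(m, study, split$subject_id[split$split == "test"])
print(rep)
#> <eval_report> 2 subject(s): S03, S06
#>   FID (encoder convenc-b2-c8-seed1234): generated 0.003, early baseline 0.015
#>   median PSNR: generated 27.89 dB, early baseline 23.83 dB
#>   mean organ SUV_mean absolute errors:
#>     bladder  3.199
#>     brain    0.580
#>     heart    1.059
#>     kidney   0.192
#>     liver    0.153
#>     muscle   0.076
#>     spleen   0.130
```

Reading this output: after 15 epochs the synthetic delayed slices are
closer to the true delayed slices than the untranslated early slices are
(median 27.9 dB vs 23.8 dB; Fréchet distance 0.003 vs the 0.015 baseline,
under the package's deterministic encoder). SUV_mean errors are small for
muscle, spleen, liver and kidney and largest for the bladder — the organ
whose activity changes most, and least predictably, between the two time
points. The regional breakdown (`rep$axial_profile`) shows the PSNR gain
concentrated in mid-body slices (+5.5 dB median) with almost none on
bladder slices (+0.5 dB).

`predict(m, study)` returns synthetic delayed volumes in SUV units;
`translate()` does the same for a single `image_stack` with its
normalization parameters. A thin command-line wrapper
(`inst/cli/delaypet`) exposes `simulate` / `train` / `evaluate`
subcommands driven by one YAML config per experiment.

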