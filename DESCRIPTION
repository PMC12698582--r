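Package: octabridge
Title: Brownian-Bridge Diffusion Translation of OCT to OCTA with Vascular
    Biomarker Quantification
Version: 0.1.0
Authors@R: person("octabridge", "maintainers", email = "octabridge@example.org",
    role = c("aut", "cre"))
Description: Implements a Brownian-bridge diffusion model (BBDM) for
    image-to-image translation between structural optical coherence
    tomography (OCT) images and OCT angiography (OCTA) projection maps,
    together with the evaluation apparatus used to judge translated
    angiograms: vascular biomarkers (blood vessel density, caliber,
    tortuosity and vessel perimeter index) computed from segmented and
    skeletonized vessel masks, perceptual image-quality metrics (SSIM,
    PCQI, Frechet distance with a pluggable embedding), an automated
    patch-based vascular hallucination score, and Welch two-tailed t-test
    cohort comparisons.  A seeded generator of paired pseudo-OCT/OCTA
    images with analytic vessel ground truth supports end-to-end testing
    at desk scale, including a conditional-DDPM ablation baseline and a
    small trainable U-Net denoiser with its own reverse-mode gradients
    (no external deep-learning runtime required).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
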