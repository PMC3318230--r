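Package: nlmdct
Title: Nonlocal-Means Denoising of Magnitude MR Images in a DCT Patch Subspace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based nonlocal-means (NLM) denoising for 2-D magnitude
    magnetic resonance images, including a variant that measures patch
    similarity in a low-dimensional subspace of zigzag-ordered 2-D discrete
    cosine transform (DCT) coefficients, and Rician-unbiased versions of both
    filters. Ships a Rician noise simulator with the percent-of-brightest-
    tissue noise-level convention, background-based noise estimation, PSNR/MSE
    evaluation with residual images, a deterministic piecewise-constant brain
    phantom generator, and harnesses for subspace-dimension sweeps and PSNR
    benchmark tables. Reads and writes PGM, PNG, TIFF and single slices of
    NIfTI-1 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    png,
    tiff,
    RNifti,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
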