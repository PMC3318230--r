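# nlmdct

Nonlocal-means denoising of 2-D magnitude MR images, with patch similarity
measured in a low-dimensional DCT subspace and with Rician bias correction.

## The problem

Magnitude MR images carry Rician noise: the complex scanner signal picks up
independent Gaussian noise `N(0, σ)` in its real and imaginary channels, and
the magnitude operation folds that into a signal-dependent, non-zero-mean
corruption with `E(v²) = u² + 2σ²`. Plain smoothing blurs tissue boundaries;
the nonlocal-means (NLM) filter instead averages pixels whose surrounding
*patches* look alike,

    û(i)  = Σ_{j ∈ S_i} w(i,j) v(j),
    w(i,j) = exp( −‖p(N_i) − p(N_j)‖² / h² ) / Z(i),

with `p(N_i)` the `r × r` patch around pixel `i`, `S_i` an `S × S` search
window, and `Z(i)` normalizing the weights to sum to one.

Two refinements are implemented on top, separately and combined:

* **DCT-subspace weights (NLM-DCT).** Patch distances are computed on the
  first `d` zigzag-ordered coefficients of the orthonormal 2-D discrete
  cosine transform of each patch. Image energy compacts into the
  low-frequency coefficients while white noise spreads evenly over all
  `M = r²` of them, so truncation discards mostly noise and the weights get
  more reliable — increasingly so at high noise. By Parseval, `d = M`
  reproduces plain NLM exactly.
* **Rician unbiasing (UNLM, UNLM-DCT).** Each filtered value is corrected by
  `sqrt(max(û² − 2σ², 0))`, removing the `2σ²` bias of the squared magnitude
  and returning to intensity units.

The package is for researchers evaluating patch-based MR denoising: it
bundles the four filters (`nlm`, `nlm-dct`, `unlm`, `unlm-dct`), a Rician
noise simulator using the percent-of-brightest-tissue level convention, a
background noise estimator, PSNR/MSE/residual metrics, a deterministic
brain-like phantom generator, harnesses for subspace-dimension sweeps and
PSNR benchmark tables, image I/O (PGM/PNG/TIFF/NIfTI slices), and a small
CLI.

## Worked example

```r
library(nlmdct)

spec  <- phantom_spec(128, 128, preset = "T1")   # brain-like phantom, t = 150
clean <- make_phantom(spec)
sigma <- sigma_from_level(9, 150)                # 9% of t  ->  sigma = 13.5
noisy <- add_rician(clean, sigma, seed = 1)

params <- filter_params("unlm-dct", h = 3 * sigma, d = default_d(5),
                        sigma = sigma)
params
#> <filter_params> method=unlm-dct  h=40.5  d=10/25  r=5  S=11  sigma=13.5

res <- nlm_denoise(noisy, params)

psnr(clean, noisy, noisy)          # 21.44 dB  (baseline)
psnr(clean, res$denoised, noisy)   # 28.76 dB  (after filtering)

estimate_sigma_background(noisy, background_mask(spec))
#> 13.591                           # recovers the injected 13.5
```

The filter raised PSNR by ~7.3 dB at this noise level; the background
estimator recovered `σ` within 0.7%. `res$residual` (`noisy − denoised`)
should look like pure noise — anatomy visible in it means the filter removed
real structure. `sweep_d()` traces PSNR against the subspace dimension `d`
(the curve has a knee below the full dimension at strong noise), and
`benchmark_table()` builds a per-level, per-method best-`h` PSNR table with
one shared noise realization per level so the comparisons are paired.

Tuned bandwidths reported as `base^exponent` can be evaluated with
`h_from_power(3, 4.38)` → `122.9677`; `h` itself is always passed as a
literal number.

A thin command-line wrapper ships at `inst/cli/nlmdct`
(subcommands `phantom`, `addnoise`, `denoise`, `evaluate`, `sweep-d`,
`benchmark`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nlmdct", package = "nlmdct"))')
Rscript $CLI phantom --preset T1 --height 64 --width 64 --out clean.pgm
Rscript $CLI addnoise --input clean.pgm --level 6 --t 150 --seed 9 --out noisy.pgm
Rscript $CLI denoise --input noisy.pgm --method unlm-dct --h 27 --d 10 \
        --sigma 9 --clean clean.pgm --out den.pgm --metrics-out m.csv
```

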