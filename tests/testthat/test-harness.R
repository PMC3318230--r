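test_that("default_d cuts the zigzag at whole anti-diagonals", {
  expect_equal(default_d(5), 10L)          # diagonals 0..3: 1+2+3+4
  expect_equal(default_d(5, 1), 25L)
  expect_equal(default_d(3, 0.25), 3L)     # first two diagonals cover 2.25
  expect_equal(default_d(7, 1e-9), 1L)
  expect_error(default_d(5, 0), "fraction")
  expect_error(default_d(5, 1.5), "fraction")
})

test_that("h_from_power evaluates the base^exponent reporting notation", {
  expect_equal(round(h_from_power(3, 4.38), 4), 122.9677)
  expect_equal(h_from_power(3, 4), 81)
  expect_equal(h_from_power(10, 0), 1)
  expect_error(h_from_power(-2, 3), "positive")
})

test_that("run_denoise validates noise configuration", {
  img <- test_phantom(32)
  noisy <- add_rician(img, 4.5, seed = 1)
  expect_error(run_denoise(noisy, method = "unlm", h = 50), "sigma")
  expect_error(run_denoise(noisy, method = "unlm", h = 50, sigma = 4.5,
                           level = 3, t = 150), "not both")
  expect_error(run_denoise(noisy, method = "unlm", h = 50, level = 3),
               "together")
  # (level, t) resolves sigma = 4.5 for the unbiased method
  res <- run_denoise(noisy, method = "unlm", h = 50, level = 3, t = 150)
  expect_equal(res$params$sigma, 4.5)
})

test_that("run_denoise writes outputs and a metrics row", {
  clean <- test_phantom(32)
  noisy <- add_rician(clean, 4.5, seed = 2)
  out <- tempfile(fileext = ".pgm")
  rout <- tempfile(fileext = ".pgm")
  mout <- tempfile(fileext = ".csv")
  res <- run_denoise(noisy, method = "nlm", h = 30, clean = clean,
                     seed = 2, out = out, residual_out = rout,
                     metrics_out = mout)
  expect_true(file.exists(out) && file.exists(rout) && file.exists(mout))
  m <- read.csv(mout)
  expect_named(m, c("image", "level_percent", "method", "h", "d", "mse",
                    "psnr_db", "seed"))
  expect_equal(m$psnr_db, psnr(clean, res$denoised, noisy))
  expect_equal(read_image(out), round(res$denoised))
  unlink(c(out, rout, mout))
})

test_that("the DCT filter at d = M reproduces plain NLM through the harness", {
  clean <- test_phantom(32)
  noisy <- add_rician(clean, 4.5, seed = 3)
  a <- run_denoise(noisy, method = "nlm", h = 60)
  b <- run_denoise(noisy, method = "nlm-dct", h = 60, d = 25)
  expect_equal(b$denoised, a$denoised, tolerance = 1e-9)

  sw <- sweep_d(clean, noisy, d_values = 25, h = 60, method = "nlm-dct")
  expect_equal(sw$psnr_db, psnr(clean, a$denoised, noisy),
               tolerance = 1e-9)
})

test_that("sweep_d returns the per-d best and flags the argmax", {
  clean <- test_phantom(48)
  sigma <- sigma_from_level(9, 150)
  noisy <- add_rician(clean, sigma, seed = 4)
  sw <- sweep_d(clean, noisy, d_values = c(1, 6, 25),
                h = c(2, 4) * sigma, method = "unlm-dct", sigma = sigma)
  expect_equal(sw$d, c(1, 6, 25))
  d_opt <- attr(sw, "d_opt")
  expect_true(d_opt %in% sw$d)
  expect_true(all(max(sw$psnr_db) >= sw$psnr_db))
  expect_equal(sw$psnr_db[sw$d == d_opt], max(sw$psnr_db))
})

test_that("benchmark_table emits paired noisy and best-h rows, reproducibly", {
  clean <- test_phantom(48)
  tab <- benchmark_table(list(T1 = list(image = clean, t = 150)),
                         levels = c(3, 9), methods = c("nlm", "unlm"),
                         h_factors = c(3, 6), seed = 5)
  expect_named(tab, c("image", "level_percent", "method", "h", "d", "mse",
                      "psnr_db", "seed"))
  # one noisy row per level, before the method rows
  expect_equal(sum(tab$method == "noisy"), 2L)
  for (lev in c(3, 9)) {
    sub <- tab[tab$level_percent == lev, ]
    expect_true("noisy" %in% sub$method)
    # paired: all rows of a level share one noise realization (same seed)
    expect_equal(length(unique(sub$seed)), 1L)
    # tuned h comes from the declared grid
    sigma <- sigma_from_level(lev, 150)
    expect_true(all(sub$h[sub$method != "noisy"] %in% (c(3, 6) * sigma)))
  }
  tab2 <- benchmark_table(list(T1 = list(image = clean, t = 150)),
                          levels = c(3, 9), methods = c("nlm", "unlm"),
                          h_factors = c(3, 6), seed = 5)
  expect_identical(tab, tab2)

  csv <- tempfile(fileext = ".csv")
  benchmark_table(list(T1 = list(image = clean, t = 150)), levels = 9,
                  methods = "nlm", h_factors = 4, seed = 5, csv = csv)
  expect_true(file.exists(csv))
  unlink(csv)
})

test_that("the command-line entry point script is shipped", {
  path <- system.file("cli", "nlmdct", package = "nlmdct")
  expect_true(nzchar(path))
  first <- readLines(path, n = 1)
  expect_match(first, "Rscript")
})
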