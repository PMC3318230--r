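test_that("weights are a normalized convex family at every center", {
  img <- pad_reflect(random_image(12, 12, seed = 5), 7)
  p <- filter_params("nlm", h = 0.4, r = 3, S = 5)
  pd <- filter_params("nlm-dct", h = 0.4, d = 4, r = 3, S = 5)
  for (center in list(c(9, 9), c(8, 12), c(12, 8))) {
    for (wf in list(weights_full(img, center, p),
                    weights_dct(img, center, pd))) {
      expect_equal(sum(wf$weights), 1, tolerance = 1e-12)
      expect_true(all(wf$weights >= 0 & wf$weights <= 1))
      expect_equal(nrow(wf$indices), 25L)
      expect_gt(wf$normalizer, 0)
    }
  }
})

test_that("constant images give uniform weights, any h and d", {
  img <- matrix(3, 20, 20)
  for (p in list(filter_params("nlm", h = 0.1, r = 3, S = 5),
                 filter_params("nlm", h = 1e12, r = 3, S = 5),
                 filter_params("nlm-dct", h = 2, d = 1, r = 3, S = 5))) {
    wf <- if (p$method == "nlm") weights_full(img, c(10, 10), p)
          else weights_dct(img, c(10, 10), p)
    expect_equal(wf$weights, rep(1 / 25, 25), tolerance = 1e-12)
  }
})

test_that("very large h flattens the weights to 1/S^2", {
  img <- pad_reflect(random_image(10, 10, seed = 6, lo = 0, hi = 100), 7)
  p <- filter_params("nlm", h = 1e12, r = 3, S = 5)
  wf <- weights_full(img, c(10, 10), p)
  expect_equal(wf$weights, rep(1 / 25, 25), tolerance = 1e-9)
})

test_that("DCT weights with d = M equal the full-space weights", {
  img <- pad_reflect(random_image(14, 14, seed = 7, lo = 0, hi = 10), 7)
  p <- filter_params("nlm", h = 8, r = 5, S = 7)
  pd <- filter_params("nlm-dct", h = 8, d = 25, r = 5, S = 7)
  for (center in list(c(10, 10), c(12, 15))) {
    expect_equal(weights_dct(img, center, pd)$weights,
                 weights_full(img, center, p)$weights,
                 tolerance = 1e-9)
  }
})

test_that("patches sharing the DC coefficient are indistinguishable at d = 1", {
  # two tissue blocks with equal mean but different zero-mean pattern
  img <- matrix(5, 15, 15)
  img[7:9, 3:5] <- 5 + matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 0), 3, 3)
  padded <- pad_reflect(img, 4)
  pd <- filter_params("nlm-dct", h = 0.5, d = 1, r = 3, S = 5)
  wf <- weights_dct(padded, c(12, 8), pd)
  # the patterned patch center sits at (12, 8); its neighbors with equal
  # patch mean carry the same weight as the self-weight
  self <- wf$weights[which(wf$indices[, 1] == 12 & wf$indices[, 2] == 8)]
  flat <- wf$weights[which(wf$indices[, 1] == 14 & wf$indices[, 2] == 8)]
  expect_equal(self, flat, tolerance = 1e-12)
})

test_that("constant images are exact fixed points and outputs stay in window range", {
  const <- matrix(42, 16, 16)
  for (m in c("nlm", "nlm-dct")) {
    p <- filter_params(m, h = 3, r = 3, S = 5)
    expect_equal(nlm_denoise(const, p)$denoised, const)
  }
  img <- random_image(16, 16, seed = 8, lo = 0, hi = 50)
  for (m in c("nlm", "nlm-dct")) {
    p <- filter_params(m, h = 20, r = 3, S = 5)
    out <- nlm_denoise(img, p)$denoised
    expect_true(all(out >= min(img) - 1e-12))
    expect_true(all(out <= max(img) + 1e-12))
  }
})

test_that("residual plus denoised reconstructs the input exactly", {
  img <- random_image(12, 12, seed = 9, lo = 0, hi = 30)
  res <- nlm_denoise(img, filter_params("unlm", h = 10, sigma = 2,
                                        r = 3, S = 5))
  expect_identical(res$residual + res$denoised, img)
  expect_true(all(is.finite(res$denoised)))
  expect_true(all(res$denoised >= 0))
})

test_that("unbias subtracts the Rician floor with clamping", {
  expect_equal(unbias(0, 5), 0)
  expect_equal(unbias(5, 10), 0)
  expect_equal(unbias(10, 1), sqrt(98))
  x <- matrix(c(0, 1, 7, 100), 2, 2)
  expect_equal(unbias(x, 0), x)
  # monotone nondecreasing in the filtered value
  v <- unbias(seq(0, 20, by = 0.5), 3)
  expect_true(all(diff(v) >= 0))
  expect_error(unbias(3, -1), "nonnegative")
})

test_that("filter input validation rejects bad configurations", {
  img <- matrix(1, 8, 8)
  expect_error(filter_params("nlm", h = 0), "positive")
  expect_error(filter_params("nlm-dct", h = 1, d = 26), "\\[1, 25\\]")
  expect_error(filter_params("unlm", h = 1), "sigma")
  expect_error(filter_params("nlm", h = 1, r = 4), "odd")
  expect_error(filter_params("nlm", h = 1, r = 7, S = 5), "at least")
  expect_error(nlm_denoise(img - 2, filter_params("nlm", h = 1, r = 3,
                                                  S = 3)),
               "nonnegative")
})

test_that("weight_map arranges window weights as an image", {
  const <- matrix(2, 20, 20)
  p <- filter_params("nlm", h = 1, r = 3, S = 5)
  m <- weight_map(const, c(10, 10), p)
  expect_equal(m, matrix(1 / 25, 5, 5), tolerance = 1e-12)

  img <- pad_reflect(random_image(12, 12, seed = 10), 4)
  for (method in c("nlm", "nlm-dct")) {
    p <- filter_params(method, h = 0.3, d = 4, r = 3, S = 5)
    m <- weight_map(img, c(9, 9), p)
    expect_equal(sum(m), 1, tolerance = 1e-12)
    # the center has zero self-distance, hence the maximal weight
    expect_equal(max(m), m[3, 3])
    lg <- weight_map(img, c(9, 9), p, log_scale = TRUE)
    expect_equal(lg, log10(m))
  }
})

test_that("the max-neighbor center weight option changes only the self-weight rule", {
  img <- random_image(12, 12, seed = 11, lo = 0, hi = 10)
  base <- nlm_denoise(img, filter_params("nlm", h = 5, r = 3, S = 5))
  alt <- nlm_denoise(img, filter_params("nlm", h = 5, r = 3, S = 5,
                                        center_weight = "max-neighbor"))
  # less self-anchoring: output differs but remains in the window hull
  expect_false(isTRUE(all.equal(base$denoised, alt$denoised)))
  expect_true(all(alt$denoised >= min(img) - 1e-12 &
                  alt$denoised <= max(img) + 1e-12))
})

test_that("denoising improves PSNR across the noise-level range", {
  ph <- test_phantom(64)
  for (lev in c(3, 9, 18)) {
    sigma <- sigma_from_level(lev, 150)
    noisy <- add_rician(ph, sigma, seed = 20 + lev)
    p <- filter_params("unlm-dct", h = 3 * sigma, d = 10, sigma = sigma)
    out <- nlm_denoise(noisy, p)$denoised
    expect_gt(psnr(ph, out, noisy), psnr(ph, noisy, noisy))
  }
})
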