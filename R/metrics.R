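#' Mean squared error between two images
#'
#' `(1/Q) * sum((u - uhat)^2)` over all `Q` pixels.
#'
#' @param reference,estimate Numeric matrices of identical dimensions.
#' @return A nonnegative number, in squared intensity units.
#' @export
mse <- function(reference, estimate) {
  reference <- as_image(reference)
  estimate <- as_image(estimate)
  if (!identical(dim(reference), dim(estimate))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  mean((reference - estimate)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `PSNR = 10 log10(Max^2 / MSE)` with `MSE` taken between the clean image
#' and the estimate. By default `Max` is the maximum over the union of the
#' clean and noisy images — the convention used when benchmarking filters
#' on simulated data, where the noisy image can exceed the clean dynamic
#' range — rather than a fixed bit-depth peak. Supply `max_value` to use a
#' fixed peak (e.g. 255) for cross-tool comparison.
#'
#' A perfect estimate (`MSE = 0`) returns `Inf` rather than raising, so
#' sweep tables never fail on degenerate fixtures.
#'
#' @param clean Clean reference image.
#' @param estimate Image under evaluation (denoised or noisy).
#' @param noisy The noisy observation, used only to widen `Max`; ignored
#'   when `max_value` is given.
#' @param max_value Optional fixed peak value (`> 0`).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(clean, estimate, noisy = NULL, max_value = NULL) {
  clean <- as_image(clean)
  estimate <- as_image(estimate)
  if (!identical(dim(clean), dim(estimate))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  if (is.null(max_value)) {
    mx <- max(clean)
    if (!is.null(noisy)) {
      noisy <- as_image(noisy)
      if (!identical(dim(noisy), dim(clean))) {
        stop("noisy image dimensions must match the clean image",
             call. = FALSE)
      }
      mx <- max(mx, max(noisy))
    }
  } else {
    mx <- max_value
  }
  if (length(mx) != 1L || !is.finite(mx) || mx <= 0) {
    stop("Max must be a positive number", call. = FALSE)
  }
  err <- mse(clean, estimate)
  if (err == 0) return(Inf)
  10 * log10(mx^2 / err)
}

#' Residual image
#'
#' `noisy - denoised`, signed. On a well-behaved filter the residual looks
#' like pure noise; anatomical structure visible in it indicates
#' over-smoothing (real detail removed along with the noise).
#'
#' @param noisy,denoised Numeric matrices of identical dimensions.
#' @return The signed residual matrix.
#' @export
residual <- function(noisy, denoised) {
  noisy <- as_image(noisy)
  denoised <- as_image(denoised)
  if (!identical(dim(noisy), dim(denoised))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  noisy - denoised
}
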