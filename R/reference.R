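#' Direct per-pixel reference implementation of the filters
#'
#' A deliberately naive evaluation of the estimator definitions — an
#' explicit loop over pixels and window members, extracting both patches
#' and summing their squared differences (or DCT-subspace coefficient
#' differences) term by term. It shares no computation strategy with the
#' vectorized [nlm_denoise()] and exists as its correctness oracle; it is
#' orders of magnitude slower and only meant for small images.
#'
#' @inheritParams nlm_denoise
#' @return The denoised image as a numeric matrix.
#' @export
nlm_reference <- function(noisy, params) {
  noisy <- as_image(noisy, nonnegative = TRUE)
  r <- params$r
  S <- params$S
  f <- (S - 1L) %/% 2L
  pad <- f + (r - 1L) %/% 2L
  vp <- pad_reflect(noisy, pad)
  use_dct <- params$method %in% c("nlm-dct", "unlm-dct")
  h2 <- params$h^2
  H <- nrow(noisy)
  W <- ncol(noisy)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      center <- c(i + pad, j + pad)
      pi_ <- extract_patch(vp, center, r)
      if (use_dct) ci_ <- patch_to_coeffs(pi_)
      num <- 0
      Z <- 0
      for (oy in -f:f) {
        for (ox in -f:f) {
          q <- c(center[1L] + oy, center[2L] + ox)
          pj <- extract_patch(vp, q, r)
          D2 <- if (use_dct) {
            subspace_distance(ci_, patch_to_coeffs(pj), params$d)
          } else {
            sum((pi_ - pj)^2)
          }
          w <- exp(-D2 / h2)
          num <- num + w * vp[q[1L], q[2L]]
          Z <- Z + w
        }
      }
      out[i, j] <- num / Z
    }
  }
  if (params$method %in% c("unlm", "unlm-dct")) {
    out <- unbias(out, params$sigma)
  }
  out
}
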