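#' Denoise a magnitude MR image with the nonlocal-means family
#'
#' Estimates every pixel as a convex combination of the pixels in its
#' `S x S` search window, with weights
#' `w(i, j) = exp(-D2(i, j) / h^2) / Z(i)`,
#' where `D2` is either the squared Euclidean distance between the `r x r`
#' patches around `i` and `j` (methods `"nlm"`, `"unlm"`) or the squared
#' distance between their first `d` zigzag-ordered DCT coefficients
#' (`"nlm-dct"`, `"unlm-dct"`). The unbiased methods then remove the Rician
#' bias of the magnitude image by
#' `sqrt(max(uhat^2 - 2 sigma^2, 0))` at every pixel.
#'
#' The image is mirror-padded by `(S - 1)/2 + (r - 1)/2` so each pixel has a
#' full window and full patches; weights are normalized over the full window
#' including the pixel itself.
#'
#' @param noisy Nonnegative numeric matrix (the observed magnitude image).
#' @param params A [filter_params()] object.
#' @return A `"denoise_result"`: list with `denoised`, `residual`
#'   (`noisy - denoised`), and `params`. `metrics` is filled by
#'   [run_denoise()] when a clean reference is available.
#' @seealso [nlm_reference()] for the direct per-pixel definition this
#'   implementation is tested against.
#' @export
nlm_denoise <- function(noisy, params) {
  noisy <- as_image(noisy, nonnegative = TRUE)
  if (!inherits(params, "filter_params")) {
    stop("params must be created with filter_params()", call. = FALSE)
  }
  r <- params$r
  S <- params$S
  f <- (S - 1L) %/% 2L
  g <- (r - 1L) %/% 2L
  pad <- f + g
  H <- nrow(noisy)
  W <- ncol(noisy)
  vp <- pad_reflect(noisy, pad)

  use_dct <- params$method %in% c("nlm-dct", "unlm-dct")
  # Feature planes over every candidate window center: plane [a, b] holds
  # feature k of the patch centered at padded position (g + a, g + b).
  FH <- H + 2L * f
  FW <- W + 2L * f
  rows <- seq_len(FH)
  cols <- seq_len(FW)
  if (use_dct) {
    B <- dct_matrix(r)
    zz <- zigzag_order(r)
    nfeat <- params$d
    feats <- vector("list", nfeat)
    for (k in seq_len(nfeat)) {
      basis <- outer(B[zz[k, 1L] + 1L, ], B[zz[k, 2L] + 1L, ])
      Fk <- matrix(0, FH, FW)
      for (x in 0:(r - 1L)) {
        for (y in 0:(r - 1L)) {
          Fk <- Fk + basis[x + 1L, y + 1L] * vp[rows + x, cols + y]
        }
      }
      feats[[k]] <- Fk
    }
  } else {
    nfeat <- r * r
    feats <- vector("list", nfeat)
    k <- 0L
    for (x in 0:(r - 1L)) {
      for (y in 0:(r - 1L)) {
        k <- k + 1L
        feats[[k]] <- vp[rows + x, cols + y]
      }
    }
  }

  ci <- (f + 1L):(f + H)
  cj <- (f + 1L):(f + W)
  center_feats <- lapply(feats, function(Fk) Fk[ci, cj, drop = FALSE])
  crow <- (pad + 1L):(pad + H)
  ccol <- (pad + 1L):(pad + W)

  h2 <- params$h^2
  num <- matrix(0, H, W)
  Z <- matrix(0, H, W)
  max_neighbor <- params$center_weight == "max-neighbor"
  wmax <- if (max_neighbor) matrix(0, H, W)
  for (oy in -f:f) {
    for (ox in -f:f) {
      if (max_neighbor && oy == 0L && ox == 0L) next
      d2 <- matrix(0, H, W)
      si <- ci + oy
      sj <- cj + ox
      for (k in seq_len(nfeat)) {
        dk <- center_feats[[k]] - feats[[k]][si, sj]
        d2 <- d2 + dk * dk
      }
      w <- exp(-d2 / h2)
      num <- num + w * vp[crow + oy, ccol + ox]
      Z <- Z + w
      if (max_neighbor) wmax <- pmax(wmax, w)
    }
  }
  if (max_neighbor) {
    # center pixel takes the largest neighbor weight (1 if all underflowed)
    w0 <- ifelse(wmax > 0, wmax, 1)
    num <- num + w0 * noisy
    Z <- Z + w0
  }
  uhat <- num / Z
  if (params$method %in% c("unlm", "unlm-dct")) {
    uhat <- unbias(uhat, params$sigma)
  }
  structure(
    list(denoised = uhat, residual = noisy - uhat, params = params,
         metrics = NULL),
    class = "denoise_result"
  )
}

#' @export
print.denoise_result <- function(x, ...) {
  cat("<denoise_result> ", nrow(x$denoised), "x", ncol(x$denoised),
      " image, method=", x$params$method, "\n", sep = "")
  if (!is.null(x$metrics)) {
    cat("  mse=", format(x$metrics$mse),
        "  psnr=", format(x$metrics$psnr), " dB\n", sep = "")
  }
  invisible(x)
}

#' Rician bias correction of a filtered magnitude value
#'
#' The squared magnitude of a Rician-noisy image is biased upward by
#' `2 sigma^2` independently of the signal. The correction squares the
#' filtered value, subtracts `2 sigma^2`, clamps at zero, and takes the
#' square root so the result is again in intensity units.
#'
#' @param x Filtered nonnegative value(s) (vector or matrix).
#' @param sigma Nonnegative noise standard deviation.
#' @return Corrected value(s), same shape as `x`; zero wherever
#'   `x^2 <= 2 sigma^2`.
#' @export
unbias <- function(x, sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("sigma must be a single nonnegative number", call. = FALSE)
  }
  sqrt(pmax(x * x - 2 * sigma^2, 0))
}

# shared per-center weight computation over an already padded image
weight_field <- function(image, center, params, use_dct) {
  image <- as_image(image)
  idx <- window_indices(center, params$S, image)
  n <- nrow(idx)
  pi_ <- extract_patch(image, center, params$r)
  d2 <- numeric(n)
  if (use_dct) {
    ci_ <- patch_to_coeffs(pi_)
    for (k in seq_len(n)) {
      pj <- extract_patch(image, idx[k, ], params$r)
      d2[k] <- subspace_distance(ci_, patch_to_coeffs(pj), params$d)
    }
  } else {
    for (k in seq_len(n)) {
      pj <- extract_patch(image, idx[k, ], params$r)
      d2[k] <- sum((pi_ - pj)^2)
    }
  }
  wraw <- exp(-d2 / params$h^2)
  Z <- sum(wraw)
  structure(
    list(center = center, indices = idx, weights = wraw / Z,
         normalizer = Z),
    class = "weight_field"
  )
}

#' Similarity weights at one pixel, full patch space
#'
#' Direct evaluation of the weight formula at a single window center:
#' unnormalized weight `exp(-||p(N_i) - p(N_j)||^2 / h^2)` over the plain
#' squared Euclidean patch distance, normalized so the window sums to one
#' (the center `j = i` is included with self-distance zero).
#'
#' @param image Padded image (see [pad_reflect()]).
#' @param center `c(row, col)` of the window center in the padded image.
#' @param params [filter_params()].
#' @return A `"weight_field"`: list with `center`, `indices` (`S^2 x 2`),
#'   `weights` (summing to 1), and `normalizer` `Z(i)`.
#' @export
weights_full <- function(image, center, params) {
  weight_field(image, center, params, use_dct = FALSE)
}

#' Similarity weights at one pixel, DCT subspace
#'
#' As [weights_full()] but with the squared distance computed over the
#' first `d` zigzag-ordered DCT coefficients of each patch. With `d = r^2`
#' the weights equal the full-space weights (Parseval).
#'
#' @inheritParams weights_full
#' @return A `"weight_field"`; see [weights_full()].
#' @export
weights_dct <- function(image, center, params) {
  weight_field(image, center, params, use_dct = TRUE)
}

#' Weight map of a search window, as an image
#'
#' Arranges the normalized similarity weights of the window around `center`
#' into an `S x S` image for visual inspection (how many window pixels the
#' filter considers similar, and where). The method in `params` selects
#' full-space or DCT-subspace weights.
#'
#' @inheritParams weights_full
#' @param log_scale Return `log10` of the weights (weight maps span many
#'   decades, so displays normally use a logarithmic scale).
#' @return An `S x S` numeric matrix; without `log_scale` it sums to 1.
#' @export
weight_map <- function(image, center, params, log_scale = FALSE) {
  use_dct <- params$method %in% c("nlm-dct", "unlm-dct")
  wf <- weight_field(image, center, params, use_dct = use_dct)
  m <- matrix(wf$weights, params$S, params$S, byrow = TRUE)
  if (log_scale) log10(m) else m
}
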