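#' Run one denoising job end to end
#'
#' Thin experiment wrapper around [nlm_denoise()]: resolves the noise
#' standard deviation (either a literal `sigma` or a `(level, t)`
#' percent-of-brightest-tissue pair — exactly one of the two for the
#' unbiased methods), runs the filter, computes metrics against a clean
#' reference when one is given, and optionally writes the denoised image,
#' the residual, and a metrics CSV row.
#'
#' @param input Noisy image: numeric matrix or a path readable by
#'   [read_image()].
#' @param method,h,d,r,S,center_weight Passed to [filter_params()].
#' @param sigma Literal noise standard deviation.
#' @param level,t Noise level in percent of the brightest tissue `t`;
#'   alternative to `sigma`.
#' @param clean Optional clean reference (matrix or path) for metrics.
#' @param seed Recorded in the metrics row (the filter itself is
#'   deterministic; the seed documents the noise realization used
#'   upstream).
#' @param out,residual_out,metrics_out Optional output paths for the
#'   denoised image, the residual image (written shifted into the
#'   nonnegative range for PGM), and a one-row metrics CSV.
#' @param slice Slice index forwarded to [read_image()] for NIfTI input.
#' @param verbose Log the resolved configuration with `message()`.
#' @return A `"denoise_result"`; `$metrics` is a one-row data frame when
#'   `clean` was given.
#' @export
run_denoise <- function(input, method, h, d = NULL, r = 5L, S = 11L,
                        sigma = NULL, level = NULL, t = NULL,
                        clean = NULL, seed = NA_integer_,
                        out = NULL, residual_out = NULL,
                        metrics_out = NULL, slice = NULL,
                        center_weight = "self", verbose = FALSE) {
  if (!is.null(level) || !is.null(t)) {
    if (is.null(level) || is.null(t)) {
      stop("level and t must be supplied together", call. = FALSE)
    }
    if (!is.null(sigma)) {
      stop("supply either sigma or (level, t), not both", call. = FALSE)
    }
    sigma <- sigma_from_level(level, t)
  }
  noisy <- if (is.character(input)) read_image(input, slice = slice)
           else as_image(input, nonnegative = TRUE)
  params <- filter_params(method = method, h = h, d = d, sigma = sigma,
                          r = r, S = S, center_weight = center_weight)
  if (verbose) {
    message("denoise: method=", params$method, " h=", format(params$h),
            " d=", params$d, " r=", params$r, " S=", params$S,
            " sigma=", if (is.null(params$sigma)) "-" else
              format(params$sigma),
            " seed=", seed, " input=", nrow(noisy), "x", ncol(noisy))
  }
  res <- nlm_denoise(noisy, params)
  if (!is.null(clean)) {
    clean_img <- if (is.character(clean)) read_image(clean, slice = slice)
                 else as_image(clean)
    res$metrics <- data.frame(
      image = if (is.character(input)) basename(input) else "matrix",
      level_percent = if (is.null(level)) NA_real_ else level,
      method = params$method,
      h = params$h,
      d = params$d,
      mse = mse(clean_img, res$denoised),
      psnr_db = psnr(clean_img, res$denoised, noisy = noisy),
      seed = seed,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(out)) write_image(res$denoised, out)
  if (!is.null(residual_out)) {
    write_image(res$residual - min(res$residual), residual_out)
  }
  if (!is.null(metrics_out)) {
    if (is.null(res$metrics)) {
      stop("metrics output requested but no clean reference given",
           call. = FALSE)
    }
    utils::write.csv(res$metrics, metrics_out, row.names = FALSE)
  }
  res
}

#' Sweep the DCT subspace dimension against PSNR
#'
#' Filters one fixed noisy realization for every requested subspace
#' dimension `d` (tuning `h` over a grid per `d` when a grid is given) and
#' records the PSNR against the clean reference. The PSNR-versus-`d` curve
#' typically rises steeply, passes a knee at the optimum `d_opt`, and then
#' flattens or declines; at strong noise `d_opt` sits well below the full
#' dimension `M`.
#'
#' @param clean Clean reference image.
#' @param noisy A single noisy realization of `clean` (shared across the
#'   whole sweep so comparisons are paired).
#' @param d_values Integer vector of subspace dimensions to try.
#' @param h Numeric vector: the `h` grid searched per `d` (a scalar fixes
#'   `h`).
#' @param method `"nlm-dct"` or `"unlm-dct"`.
#' @param sigma Noise standard deviation (required for `"unlm-dct"`).
#' @param r,S Patch / search geometry.
#' @return A data frame with columns `d`, `h` (the best `h` for that `d`),
#'   `psnr_db`, ordered as `d_values`; attribute `"d_opt"` holds the
#'   argmax-PSNR dimension.
#' @export
sweep_d <- function(clean, noisy, d_values, h, method = "unlm-dct",
                    sigma = NULL, r = 5L, S = 11L) {
  clean <- as_image(clean)
  noisy <- as_image(noisy, nonnegative = TRUE)
  if (!method %in% c("nlm-dct", "unlm-dct")) {
    stop("sweep_d applies to the DCT methods", call. = FALSE)
  }
  rows <- lapply(d_values, function(d) {
    best <- NULL
    for (hh in h) {
      p <- filter_params(method, h = hh, d = d, sigma = sigma, r = r,
                         S = S)
      res <- nlm_denoise(noisy, p)
      ps <- psnr(clean, res$denoised, noisy = noisy)
      if (is.null(best) || ps > best$psnr_db) {
        best <- data.frame(d = d, h = hh, psnr_db = ps)
      }
    }
    best
  })
  out <- do.call(rbind, rows)
  attr(out, "d_opt") <- out$d[which.max(out$psnr_db)]
  out
}

#' PSNR benchmark table over images, noise levels, and methods
#'
#' For every image and noise level, draws one Rician realization (shared
#' by all methods at that level, so comparisons are paired), records the
#' noisy-image PSNR, then runs every method with `h` tuned exhaustively
#' over `h_factors * sigma` (and, for the DCT methods, `d` over
#' `d_values`), keeping the best-PSNR cell.
#'
#' @param images Named list; each element is `list(image = matrix or
#'   path, t = brightest-tissue value)`.
#' @param levels Noise levels in percent of `t`.
#' @param methods Subset of `c("nlm", "nlm-dct", "unlm", "unlm-dct")`.
#' @param h_factors Multipliers of `sigma` forming the `h` grid.
#' @param d_values Subspace dimensions tried for the DCT methods
#'   (default: [default_d()] of `r`).
#' @param r,S Patch / search geometry.
#' @param seed Base seed; the realization for image `i`, level `l` uses
#'   `seed + 1000*i + l` so rows are independent but reproducible.
#' @param csv Optional path: write the table as CSV.
#' @return A data frame with columns `image`, `level_percent`, `method`,
#'   `h`, `d`, `mse`, `psnr_db`, `seed`, including a `"noisy"` row per
#'   image and level.
#' @export
benchmark_table <- function(images, levels,
                            methods = c("nlm", "unlm", "unlm-dct"),
                            h_factors = c(5, 8, 12, 16, 20),
                            d_values = NULL, r = 5L, S = 11L, seed = 1L,
                            csv = NULL) {
  if (is.null(names(images))) {
    names(images) <- paste0("image", seq_along(images))
  }
  if (is.null(d_values)) d_values <- default_d(r)
  rows <- list()
  for (i in seq_along(images)) {
    entry <- images[[i]]
    clean <- if (is.character(entry$image)) read_image(entry$image)
             else as_image(entry$image)
    t <- entry$t
    for (l in seq_along(levels)) {
      level <- levels[l]
      sigma <- sigma_from_level(level, t)
      s <- seed + 1000L * i + l
      noisy <- add_rician(clean, sigma, seed = s)
      rows[[length(rows) + 1L]] <- data.frame(
        image = names(images)[i], level_percent = level,
        method = "noisy", h = NA_real_, d = NA_integer_,
        mse = mse(clean, noisy),
        psnr_db = psnr(clean, noisy, noisy = noisy), seed = s,
        stringsAsFactors = FALSE
      )
      for (method in methods) {
        dct <- method %in% c("nlm-dct", "unlm-dct")
        dgrid <- if (dct) d_values else NA_integer_
        best <- NULL
        for (d in dgrid) {
          for (hf in h_factors) {
            p <- filter_params(method, h = hf * sigma,
                               d = if (dct) d else NULL,
                               sigma = sigma, r = r, S = S)
            res <- nlm_denoise(noisy, p)
            cell <- data.frame(
              image = names(images)[i], level_percent = level,
              method = method, h = p$h, d = p$d,
              mse = mse(clean, res$denoised),
              psnr_db = psnr(clean, res$denoised, noisy = noisy),
              seed = s, stringsAsFactors = FALSE
            )
            if (is.null(best) || cell$psnr_db > best$psnr_db) best <- cell
          }
        }
        rows[[length(rows) + 1L]] <- best
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
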