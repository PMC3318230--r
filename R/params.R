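#' Filter parameters for the nonlocal-means family
#'
#' Bundles and validates everything a filter run needs: the method, the
#' smoothing bandwidth `h`, the DCT subspace dimension `d`, the noise
#' standard deviation `sigma` (required by the unbiased methods), and the
#' patch / search-window geometry.
#'
#' The squared patch distance in the weight kernel is *not* divided by the
#' patch size `M = r^2`, so useful `h` values are large relative to the
#' intensity scale (tens to hundreds for 8-bit-range images); see
#' [h_from_power()] for the `base^exponent` notation often used to report
#' tuned values.
#'
#' @param method One of `"nlm"`, `"nlm-dct"`, `"unlm"`, `"unlm-dct"`.
#'   The `-dct` variants measure patch similarity on the first `d`
#'   zigzag-ordered DCT coefficients; the `u`-variants apply the Rician
#'   bias correction after averaging.
#' @param h Positive smoothing bandwidth, in intensity units.
#' @param d Subspace dimension in `[1, r^2]`; defaults to
#'   [default_d()]`(r)` (25% of the coefficients) for the DCT methods and
#'   to `r^2` otherwise.
#' @param sigma Noise standard deviation, intensity units. Mandatory for
#'   `"unlm"` and `"unlm-dct"`.
#' @param r Odd patch side length (default 5).
#' @param S Odd search-window side length (default 11); must be `>= r`.
#' @param center_weight `"self"` keeps the self-weight `exp(0) = 1` exactly
#'   as the weight formula reads (the default); `"max-neighbor"` replaces it
#'   by the largest off-center weight, a common heuristic that is off by
#'   default because the estimator is defined without it.
#' @return An object of class `"filter_params"`.
#' @export
filter_params <- function(method = c("nlm", "nlm-dct", "unlm", "unlm-dct"),
                          h,
                          d = NULL,
                          sigma = NULL,
                          r = 5L,
                          S = 11L,
                          center_weight = c("self", "max-neighbor")) {
  method <- match.arg(tolower(method[1L]),
                      c("nlm", "nlm-dct", "unlm", "unlm-dct"))
  center_weight <- match.arg(center_weight)
  r <- check_odd(r, "r")
  S <- check_odd(S, "S")
  if (S < r) stop("search window S must be at least the patch size r",
                  call. = FALSE)
  if (length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("h must be a single positive number", call. = FALSE)
  }
  M <- r * r
  if (is.null(d)) {
    d <- if (method %in% c("nlm-dct", "unlm-dct")) default_d(r) else M
  }
  if (length(d) != 1L || is.na(d) || d != round(d) || d < 1 || d > M) {
    stop("d must be an integer in [1, ", M, "]", call. = FALSE)
  }
  unbiased <- method %in% c("unlm", "unlm-dct")
  if (unbiased) {
    if (is.null(sigma)) {
      stop("sigma must be supplied for the unbiased methods (", method, ")",
           call. = FALSE)
    }
    if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
      stop("sigma must be a single nonnegative number", call. = FALSE)
    }
  }
  structure(
    list(method = method, h = as.numeric(h), d = as.integer(d),
         sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
         r = r, S = S, M = M, center_weight = center_weight),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat("<filter_params> method=", x$method,
      "  h=", format(x$h), "  d=", x$d, "/", x$M,
      "  r=", x$r, "  S=", x$S,
      if (!is.null(x$sigma)) paste0("  sigma=", format(x$sigma)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Default DCT subspace dimension
#'
#' The recommended data-free choice keeps the low-frequency quarter of the
#' zigzag-ordered coefficients, cut at an anti-diagonal boundary: the
#' smallest number of complete anti-diagonals of the `r x r` coefficient
#' grid whose coefficient count reaches `fraction * r^2`. Cutting at a
#' whole anti-diagonal makes the subspace independent of the zigzag
#' traversal direction. For the standard 5 x 5 patch at 25% this selects
#' the first four anti-diagonals, `d = 1 + 2 + 3 + 4 = 10`.
#'
#' @param r Odd patch side length.
#' @param fraction Fraction of coefficients to cover, in `(0, 1]`.
#' @return An integer subspace dimension in `[1, r^2]`.
#' @export
default_d <- function(r, fraction = 0.25) {
  r <- check_odd(r, "r")
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  M <- r * r
  target <- fraction * M
  # anti-diagonal s of an r x r grid holds r - |s - (r - 1)| entries
  count <- 0L
  for (s in 0:(2L * r - 2L)) {
    count <- count + (r - abs(s - (r - 1L)))
    if (count >= target) break
  }
  min(max(count, 1L), M)
}

#' Evaluate base^exponent notation for h
#'
#' Tuned smoothing bandwidths are often reported as `base^exponent` (for
#' example `3^4.38 = 122.9677`). This helper evaluates that notation so the
#' programmatic interface only ever takes literal numbers.
#'
#' @param base,exponent Numeric scalars.
#' @return `base^exponent` as a plain number.
#' @export
h_from_power <- function(base, exponent) {
  if (!is.finite(base) || base <= 0) stop("base must be positive",
                                          call. = FALSE)
  base^exponent
}
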