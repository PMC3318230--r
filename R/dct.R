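#' Orthonormal DCT-II basis matrix
#'
#' Row `m + 1` holds the length-`r` type-II DCT basis vector of frequency
#' `m`: `alpha(m) * cos(pi * (2x + 1) * m / (2r))` with `alpha(0) =
#' sqrt(1/r)` and `alpha(m) = sqrt(2/r)` otherwise, so the matrix is
#' orthogonal and the 2-D transform below satisfies Parseval exactly (up to
#' floating point).
#'
#' @param r Side length.
#' @return An `r x r` orthogonal matrix.
#' @keywords internal
dct_matrix <- function(r) {
  m <- 0:(r - 1L)
  x <- 0:(r - 1L)
  B <- sqrt(2 / r) * cos(outer(m, 2 * x + 1) * pi / (2 * r))
  B[1L, ] <- sqrt(1 / r)
  B
}

#' Orthonormal 2-D discrete cosine transform of a square patch
#'
#' `C(m, n) = alpha(m) alpha(n) sum_{x,y} p(x, y) cos(pi (2x+1) m / 2r)
#' cos(pi (2y+1) n / 2r)`. With the orthonormal scaling the sum of squared
#' coefficients equals the sum of squared pixels, which is what makes the
#' full-dimension DCT patch distance coincide with the Euclidean patch
#' distance.
#'
#' @param patch Square numeric matrix (`p(x, y)`; rows index `x`).
#' @return The `r x r` coefficient matrix `C(m, n)` (rows index `m`).
#' @export
dct2 <- function(patch) {
  patch <- as_image(patch)
  if (nrow(patch) != ncol(patch)) {
    stop("patch must be square", call. = FALSE)
  }
  B <- dct_matrix(nrow(patch))
  B %*% patch %*% t(B)
}

#' Inverse orthonormal 2-D DCT
#'
#' Exact inverse of [dct2()] up to floating tolerance.
#'
#' @param coeffs Square coefficient matrix.
#' @return The reconstructed patch.
#' @export
idct2 <- function(coeffs) {
  coeffs <- as_image(coeffs)
  if (nrow(coeffs) != ncol(coeffs)) {
    stop("coefficient matrix must be square", call. = FALSE)
  }
  B <- dct_matrix(nrow(coeffs))
  t(B) %*% coeffs %*% B
}

# Anti-diagonal (zigzag) traversal of an nr x nc grid, JPEG convention:
# start at (0,0), first step to (0,1); odd anti-diagonals are walked with the
# row index increasing, even ones with it decreasing. Returns 0-based (m, n).
zigzag_rect <- function(nr, nc) {
  out <- matrix(0L, nr * nc, 2L)
  k <- 0L
  for (s in 0:(nr + nc - 2L)) {
    ms <- max(0L, s - nc + 1L):min(s, nr - 1L)
    if (s %% 2L == 0L) ms <- rev(ms)
    for (m in ms) {
      k <- k + 1L
      out[k, ] <- c(m, s - m)
    }
  }
  colnames(out) <- c("m", "n")
  out
}

#' Zigzag scan order for an r x r coefficient grid
#'
#' JPEG-style traversal of the anti-diagonals `m + n = const` in order of
#' increasing spatial frequency, alternating direction, beginning with the
#' step from `(0, 0)` to `(0, 1)`. Selecting the first `d` entries of this
#' order keeps the `d` lowest-frequency coefficients, where the DCT of
#' natural image patches concentrates its energy.
#'
#' @param r Side length (`r >= 1`).
#' @return An `r^2 x 2` integer matrix of 0-based frequency pairs `(m, n)`;
#'   row 1 is the DC coefficient `(0, 0)`.
#' @export
zigzag_order <- function(r) {
  if (length(r) != 1L || is.na(r) || r < 1 || r != round(r)) {
    stop("r must be a positive integer", call. = FALSE)
  }
  zigzag_rect(as.integer(r), as.integer(r))
}

#' Zigzag-ordered DCT coefficient vector of a patch
#'
#' Applies [dct2()] and flattens the coefficient matrix in [zigzag_order()],
#' so entry 1 is the DC coefficient and entries are ordered roughly by
#' increasing spatial frequency.
#'
#' @param patch Square numeric matrix.
#' @return Numeric vector of length `r^2`.
#' @export
patch_to_coeffs <- function(patch) {
  C <- dct2(patch)
  zz <- zigzag_order(nrow(C))
  C[cbind(zz[, 1L] + 1L, zz[, 2L] + 1L)]
}

#' Squared distance between two patches in the leading DCT subspace
#'
#' `sum_{k=1}^{d} (a_k - b_k)^2` over zigzag-ordered coefficient vectors.
#' With `d = M` (all coefficients) this equals the squared Euclidean
#' distance between the raw patches, by Parseval.
#'
#' @param a,b Coefficient vectors of equal length (from
#'   [patch_to_coeffs()]).
#' @param d Number of leading coefficients to use, in `[1, length(a)]`.
#' @return A nonnegative number.
#' @export
subspace_distance <- function(a, b, d) {
  if (length(a) != length(b)) {
    stop("coefficient vectors must have equal length", call. = FALSE)
  }
  if (length(d) != 1L || is.na(d) || d != round(d) || d < 1 ||
      d > length(a)) {
    stop("d must be an integer in [1, ", length(a), "]", call. = FALSE)
  }
  delta <- a[seq_len(d)] - b[seq_len(d)]
  sum(delta * delta)
}

#' Reconstruct an image from its leading zigzag DCT coefficients
#'
#' Treats the whole image as one block: transforms it with a separable
#' orthonormal DCT, keeps the first `round(fraction * Q)` coefficients in
#' zigzag order (where `Q` is the pixel count), zeroes the rest, and
#' inverse-transforms. A demonstration of the energy-compaction property
#' that motivates computing patch similarity in the low-frequency subspace.
#'
#' @param image Numeric matrix (need not be square).
#' @param fraction Fraction of coefficients to keep, in `(0, 1]`.
#' @return The reconstructed image, same dimensions as the input.
#' @export
reconstruct_topk <- function(image, fraction) {
  image <- as_image(image)
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  nr <- nrow(image)
  nc <- ncol(image)
  Br <- dct_matrix(nr)
  Bc <- dct_matrix(nc)
  C <- Br %*% image %*% t(Bc)
  keep <- as.integer(round(fraction * nr * nc))
  zz <- zigzag_rect(nr, nc)
  if (keep < nrow(zz)) {
    drop_idx <- zz[seq.int(keep + 1L, nrow(zz)), , drop = FALSE]
    C[cbind(drop_idx[, 1L] + 1L, drop_idx[, 2L] + 1L)] <- 0
  }
  t(Br) %*% C %*% Bc
}
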