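#' Validate and coerce a 2-D image
#'
#' Images are plain numeric matrices in double precision, indexed
#' `[row, col]` with the top-left pixel at `[1, 1]`. Magnitude MR images are
#' nonnegative; use `nonnegative = TRUE` to enforce that on load.
#'
#' @param x A numeric matrix (or data frame coercible to one).
#' @param nonnegative Require all values to be `>= 0`.
#' @return A double-precision numeric matrix.
#' @export
as_image <- function(x, nonnegative = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    stop("image values must all be finite", call. = FALSE)
  }
  if (nonnegative && any(x < 0)) {
    stop("magnitude image must be nonnegative", call. = FALSE)
  }
  x
}

# Reflective index fold: maps any integer position k onto [1, n] by mirror
# reflection about the edges without repeating the edge pixel (period 2n - 2).
reflect_index <- function(k, n) {
  if (n == 1L) return(rep.int(1L, length(k)))
  p <- 2L * n - 2L
  k0 <- (k - 1L) %% p
  ifelse(k0 < n, k0 + 1L, p - k0 + 1L)
}

#' Pad an image by mirror reflection
#'
#' Extends the image by `margin` pixels on every side using mirror reflection
#' that does not repeat the edge pixel (a 1 x 3 row `1 2 3` padded by 1
#' becomes `2 1 2 3 2`). Used so every pixel of the original image has a full
#' search window and full similarity patches, keeping the weight
#' normalization uniform across the image.
#'
#' @param image Numeric matrix.
#' @param margin Nonnegative integer number of pixels to add per side; must
#'   not exceed the smaller image dimension.
#' @return A `(nrow + 2 margin) x (ncol + 2 margin)` matrix whose interior
#'   equals `image` exactly.
#' @export
pad_reflect <- function(image, margin) {
  image <- as_image(image)
  if (length(margin) != 1L || is.na(margin) || margin < 0 ||
      margin != round(margin)) {
    stop("margin must be a single nonnegative integer", call. = FALSE)
  }
  margin <- as.integer(margin)
  if (margin == 0L) return(image)
  h <- nrow(image)
  w <- ncol(image)
  if (margin > min(h, w)) {
    stop("margin (", margin, ") exceeds the smaller image dimension (",
         min(h, w), ")", call. = FALSE)
  }
  ridx <- reflect_index(seq.int(1L - margin, h + margin), h)
  cidx <- reflect_index(seq.int(1L - margin, w + margin), w)
  image[ridx, cidx, drop = FALSE]
}

#' Extract a square patch around a pixel
#'
#' Returns the `r x r` neighborhood of intensities centered on `center`.
#' The caller is expected to have padded the image (see [pad_reflect()]);
#' a window that would leave the image raises an error rather than being
#' truncated.
#'
#' @param image Numeric matrix (normally already padded).
#' @param center Integer `c(row, col)`, 1-based.
#' @param r Odd positive patch side length in pixels.
#' @return An `r x r` numeric matrix.
#' @export
extract_patch <- function(image, center, r) {
  image <- as_image(image)
  check_odd(r, "r")
  center <- as.integer(center)
  if (length(center) != 2L || any(is.na(center))) {
    stop("center must be an integer (row, col) pair", call. = FALSE)
  }
  g <- (r - 1L) %/% 2L
  rows <- (center[1L] - g):(center[1L] + g)
  cols <- (center[2L] - g):(center[2L] + g)
  if (rows[1L] < 1L || cols[1L] < 1L ||
      rows[r] > nrow(image) || cols[r] > ncol(image)) {
    stop("patch window exceeds image bounds; pad the image first",
         call. = FALSE)
  }
  image[rows, cols, drop = FALSE]
}

#' Enumerate the search window around a pixel
#'
#' Returns the `S^2` pixel coordinates of the square search window centered
#' on `center`, in row-major order (rows outer, columns inner); the center
#' itself is included exactly once.
#'
#' @param center Integer `c(row, col)`, 1-based.
#' @param S Odd positive search-window side length.
#' @param image Image the window must fit inside (normally padded).
#' @return An `S^2 x 2` integer matrix with columns `row`, `col`.
#' @export
window_indices <- function(center, S, image) {
  image <- as_image(image)
  check_odd(S, "S")
  center <- as.integer(center)
  f <- (S - 1L) %/% 2L
  rows <- (center[1L] - f):(center[1L] + f)
  cols <- (center[2L] - f):(center[2L] + f)
  if (rows[1L] < 1L || cols[1L] < 1L ||
      rows[S] > nrow(image) || cols[S] > ncol(image)) {
    stop("search window exceeds image bounds; pad the image first",
         call. = FALSE)
  }
  cbind(row = rep(rows, each = S), col = rep(cols, times = S))
}

check_odd <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != round(x) ||
      as.integer(x) %% 2L != 1L) {
    stop(name, " must be a single odd positive integer", call. = FALSE)
  }
  invisible(as.integer(x))
}
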