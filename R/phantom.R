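#' Specification of a piecewise-constant brain-like phantom
#'
#' A deterministic stand-in for simulated brain slices: a handful of
#' analytic shapes (ellipses and axis-aligned rectangles) painted in order
#' onto a zero background. Shape centers and radii are given as fractions
#' of the canvas so the same anatomy renders at any size. The brightest
#' declared intensity is `t`, matching the percent-of-`t` noise-level
#' convention of [sigma_from_level()]; the background is exactly zero so
#' background noise estimation has ground truth.
#'
#' Presets mirror typical brightest-tissue values of the standard simulated
#' contrasts: `"T1"` (`t = 150`), `"T2"` (`t = 250`), `"PD"` (`t = 255`).
#'
#' @param height,width Canvas size in pixels (default 181 x 217, the
#'   canonical simulated-slice dimensions).
#' @param preset One of `"T1"`, `"T2"`, `"PD"`; sets `t` unless `t` is
#'   given.
#' @param t Brightest-tissue intensity; overrides the preset.
#' @param shapes Optional list of shapes from [phantom_shape()]; defaults
#'   to a brain-like arrangement (skull rim at `t`, gray/white matter,
#'   ventricles, a brainstem blob and a bright band for edge content).
#' @return A `"phantom_spec"` object.
#' @export
phantom_spec <- function(height = 181L, width = 217L,
                         preset = c("T1", "T2", "PD"), t = NULL,
                         shapes = NULL) {
  preset <- match.arg(preset)
  if (is.null(t)) t <- c(T1 = 150, T2 = 250, PD = 255)[[preset]]
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("t must be a single positive number", call. = FALSE)
  }
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 1L || width < 1L) {
    stop("canvas dimensions must be positive", call. = FALSE)
  }
  if (is.null(shapes)) shapes <- brain_shapes(t)
  for (s in shapes) validate_shape(s)
  if (length(shapes) > 0L) {
    vmax <- max(vapply(shapes, `[[`, numeric(1), "value"))
    if (abs(vmax - t) > 1e-12) {
      stop("the brightest declared shape intensity (", vmax,
           ") must equal t (", t, ")", call. = FALSE)
    }
  }
  structure(list(height = height, width = width, t = t, shapes = shapes),
            class = "phantom_spec")
}

#' Analytic phantom shape
#'
#' @param type `"ellipse"` (filled, inequality
#'   `((row-cy)/ry)^2 + ((col-cx)/rx)^2 <= 1`) or `"rect"` (axis-aligned).
#' @param cy,cx Center as fractions of height and width in `[0, 1]`.
#' @param ry,rx Half-axes (ellipse) or half-sides (rect) as fractions of
#'   height and width.
#' @param value Intensity painted inside the shape.
#' @return A shape descriptor list.
#' @export
phantom_shape <- function(type = c("ellipse", "rect"), cy, cx, ry, rx,
                          value) {
  type <- match.arg(type)
  s <- list(type = type, cy = cy, cx = cx, ry = ry, rx = rx,
            value = value)
  validate_shape(s)
  s
}

validate_shape <- function(s) {
  need <- c("type", "cy", "cx", "ry", "rx", "value")
  if (!is.list(s) || !all(need %in% names(s))) {
    stop("each shape needs fields ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  num <- unlist(s[c("cy", "cx", "ry", "rx", "value")])
  if (any(!is.finite(num)) || s$ry <= 0 || s$rx <= 0 || s$value < 0) {
    stop("shape parameters must be finite, radii positive, value >= 0",
         call. = FALSE)
  }
  if (s$cy - s$ry < -1e-9 || s$cy + s$ry > 1 + 1e-9 ||
      s$cx - s$rx < -1e-9 || s$cx + s$rx > 1 + 1e-9) {
    stop("shape extends outside the canvas", call. = FALSE)
  }
  invisible(TRUE)
}

# Default brain-like arrangement; brightest shape (scalp/fat rim) is t.
# Deliberately rich in edges and fine structure: a phantom made only of
# large flat regions is trivially self-similar, every patch-based filter
# saturates on it, and method comparisons degenerate. Gyri-like blobs along
# the cortical shell, thin bands and small lesions keep patch similarity
# nontrivial, as on real brain slices.
brain_shapes <- function(t) {
  shells <- list(
    phantom_shape("ellipse", cy = 0.50, cx = 0.50, ry = 0.46, rx = 0.40,
                  value = t),            # scalp/fat rim, brightest tissue
    phantom_shape("ellipse", cy = 0.50, cx = 0.50, ry = 0.42, rx = 0.36,
                  value = 0.12 * t),     # skull, dark
    phantom_shape("ellipse", cy = 0.50, cx = 0.50, ry = 0.38, rx = 0.32,
                  value = 0.45 * t),     # gray matter shell
    phantom_shape("ellipse", cy = 0.50, cx = 0.50, ry = 0.29, rx = 0.23,
                  value = 0.65 * t)      # white matter core
  )
  # gyri/sulci: alternating blobs straddling the gray/white boundary
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  gyri <- lapply(seq_along(ang), function(k) {
    a <- ang[k]
    phantom_shape("ellipse",
                  cy = 0.50 + 0.335 * sin(a), cx = 0.50 + 0.275 * cos(a),
                  ry = 0.035, rx = 0.030,
                  value = if (k %% 2L == 0L) 0.65 * t else 0.45 * t)
  })
  deep <- list(
    phantom_shape("ellipse", cy = 0.42, cx = 0.42, ry = 0.10, rx = 0.055,
                  value = 0.20 * t),     # left ventricle
    phantom_shape("ellipse", cy = 0.42, cx = 0.58, ry = 0.10, rx = 0.055,
                  value = 0.20 * t),     # right ventricle
    phantom_shape("rect",    cy = 0.50, cx = 0.50, ry = 0.13, rx = 0.012,
                  value = 0.30 * t),     # interhemispheric fissure
    phantom_shape("ellipse", cy = 0.30, cx = 0.50, ry = 0.030, rx = 0.085,
                  value = 0.80 * t),     # corpus-callosum-like band
    phantom_shape("ellipse", cy = 0.56, cx = 0.44, ry = 0.035, rx = 0.030,
                  value = 0.55 * t),     # left thalamus blob
    phantom_shape("ellipse", cy = 0.56, cx = 0.56, ry = 0.035, rx = 0.030,
                  value = 0.55 * t),     # right thalamus blob
    phantom_shape("ellipse", cy = 0.68, cx = 0.50, ry = 0.055, rx = 0.085,
                  value = 0.50 * t),     # brainstem-like blob
    phantom_shape("rect",    cy = 0.63, cx = 0.36, ry = 0.025, rx = 0.020,
                  value = 0.90 * t),     # small bright lesion
    phantom_shape("rect",    cy = 0.37, cx = 0.63, ry = 0.018, rx = 0.028,
                  value = 0.30 * t),     # small dark lesion
    phantom_shape("ellipse", cy = 0.23, cx = 0.41, ry = 0.016, rx = 0.016,
                  value = 0.85 * t),     # punctate structure
    phantom_shape("ellipse", cy = 0.23, cx = 0.59, ry = 0.016, rx = 0.016,
                  value = 0.85 * t)      # punctate structure
  )
  c(shells, gyri, deep)
}

paint_masks <- function(spec) {
  H <- spec$height
  W <- spec$width
  # pixel centers in fractional canvas coordinates
  ry <- if (H > 1L) (seq_len(H) - 1) / (H - 1) else 0.5
  rx <- if (W > 1L) (seq_len(W) - 1) / (W - 1) else 0.5
  Y <- matrix(ry, H, W)
  X <- matrix(rx, H, W, byrow = TRUE)
  lapply(spec$shapes, function(s) {
    if (s$type == "ellipse") {
      ((Y - s$cy) / s$ry)^2 + ((X - s$cx) / s$rx)^2 <= 1
    } else {
      (abs(Y - s$cy) <= s$ry) & (abs(X - s$cx) <= s$rx)
    }
  })
}

#' Render a phantom specification to an image
#'
#' Paints the shapes in declaration order (later shapes overwrite earlier
#' ones) on a zero background. Fully deterministic: the same spec always
#' renders bit-identically.
#'
#' @param spec A [phantom_spec()].
#' @return A `height x width` numeric matrix whose set of values is a
#'   subset of `{0}` and the declared shape intensities.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- matrix(0, spec$height, spec$width)
  masks <- paint_masks(spec)
  for (k in seq_along(masks)) {
    img[masks[[k]]] <- spec$shapes[[k]]$value
  }
  img
}

#' Exact background mask of a phantom
#'
#' `TRUE` exactly where no shape painted the canvas — the pixels that are
#' signal-free by construction, suitable as ground truth for
#' [estimate_sigma_background()].
#'
#' @param spec A [phantom_spec()].
#' @return A logical `height x width` matrix.
#' @export
background_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  painted <- Reduce(`|`, paint_masks(spec),
                    matrix(FALSE, spec$height, spec$width))
  !painted
}
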