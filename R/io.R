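#' Read a 2-D grayscale image
#'
#' Supported formats, dispatched on the file extension (or forced with
#' `format`): plain/binary PGM (`P2`/`P5`), PNG, grayscale TIFF, and
#' NIfTI-1 (a single slice of a volume, selected with `slice`). Values are
#' promoted to double precision; PGM and TIFF integer depths are preserved
#' without rescaling, PNG values (which the reader returns in `[0, 1]`)
#' are rescaled to the 8-bit range.
#'
#' @param path File path.
#' @param format Optional override: `"pgm"`, `"png"`, `"tiff"`, `"nifti"`.
#' @param slice Slice index along the third dimension, required for 3-D
#'   NIfTI volumes.
#' @return A nonnegative numeric matrix.
#' @export
read_image <- function(path, format = NULL, slice = NULL) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  fmt <- if (is.null(format)) guess_format(path) else tolower(format)
  img <- switch(fmt,
    pgm = read_pgm(path),
    png = {
      need_ns("png")
      x <- png::readPNG(path)
      collapse_gray(x, path) * 255
    },
    tiff = {
      need_ns("tiff")
      x <- tiff::readTIFF(path, as.is = TRUE)
      collapse_gray(x, path)
    },
    nifti = {
      need_ns("RNifti")
      x <- as.array(RNifti::readNifti(path))
      x <- drop(x)
      if (length(dim(x)) == 3L) {
        if (is.null(slice)) {
          stop("NIfTI volume is 3-D; a slice index is required: ", path,
               call. = FALSE)
        }
        if (slice < 1L || slice > dim(x)[3L]) {
          stop("slice ", slice, " out of range [1, ", dim(x)[3L], "]: ",
               path, call. = FALSE)
        }
        x <- x[, , slice]
      } else if (length(dim(x)) != 2L) {
        stop("unsupported NIfTI dimensionality: ", path, call. = FALSE)
      }
      matrix(as.numeric(x), nrow(x), ncol(x))
    },
    stop("unsupported image format '", fmt, "': ", path, call. = FALSE)
  )
  img <- as_image(img)
  if (any(img < 0)) {
    stop("image contains negative values, not a magnitude image: ", path,
         call. = FALSE)
  }
  img
}

#' Write a 2-D grayscale image
#'
#' PGM is written losslessly (`P2` plain text by default, maxval chosen
#' from the data); PNG and TIFF are written as floating point scaled by
#' `max_value` (default: the 8-bit range, or the data maximum if larger).
#'
#' @param image Numeric matrix.
#' @param path Output path; the extension selects the format unless
#'   `format` is given.
#' @param format Optional override: `"pgm"`, `"png"`, `"tiff"`.
#' @param binary For PGM: write binary `P5` instead of plain `P2`.
#' @param max_value Peak value used to scale PNG/TIFF output.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL, binary = FALSE,
                        max_value = NULL) {
  image <- as_image(image, nonnegative = TRUE)
  fmt <- if (is.null(format)) guess_format(path) else tolower(format)
  switch(fmt,
    pgm = write_pgm(image, path, binary = binary),
    png = {
      need_ns("png")
      mx <- if (is.null(max_value)) max(255, max(image)) else max_value
      png::writePNG(pmin(image / mx, 1), path)
    },
    tiff = {
      need_ns("tiff")
      mx <- if (is.null(max_value)) max(255, max(image)) else max_value
      tiff::writeTIFF(pmin(image / mx, 1), path, bits.per.sample = 16L)
    },
    stop("unsupported output format '", fmt, "'", call. = FALSE)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(ext,
    pgm = "pgm",
    png = "png",
    tif = ,
    tiff = "tiff",
    nii = "nifti",
    stop("cannot infer image format from extension of ", path,
         call. = FALSE)
  )
}

need_ns <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this format", call. = FALSE)
  }
}

collapse_gray <- function(x, path) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] == 1L) {
      x <- x[, , 1L]
    } else {
      stop("multi-channel image; grayscale required: ", path,
           call. = FALSE)
    }
  }
  x
}

# -- PGM (netpbm P2 plain / P5 binary), maxval <= 65535 ----------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (magic '", magic, "'): ", path, call. = FALSE)
  }
  head <- pgm_header_tokens(con, 3L)
  w <- head[1L]
  h <- head[2L]
  maxval <- head[3L]
  if (w < 1L || h < 1L || maxval < 1L || maxval > 65535L) {
    stop("invalid PGM header in ", path, call. = FALSE)
  }
  n <- w * h
  vals <- if (magic == "P2") {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
    if (length(v) != n) stop("truncated PGM data in ", path, call. = FALSE)
    v
  } else {
    if (maxval < 256L) {
      v <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    } else {
      v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                   endian = "big")
    }
    if (length(v) != n) stop("truncated PGM data in ", path, call. = FALSE)
    v
  }
  if (any(vals < 0L | vals > maxval)) {
    stop("PGM sample outside [0, maxval] in ", path, call. = FALSE)
  }
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}

# read `n` whitespace-separated header integers, honoring '#' comments
pgm_header_tokens <- function(con, n) {
  out <- integer(0)
  tok <- character(0)
  in_comment <- FALSE
  while (length(out) < n) {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    c <- rawToChar(ch)
    if (in_comment) {
      if (c %in% c("\n", "\r")) in_comment <- FALSE
      next
    }
    if (c == "#") {
      in_comment <- TRUE
      next
    }
    if (grepl("[0-9]", c)) {
      tok <- c(tok, c)
    } else if (length(tok) > 0L) {
      out <- c(out, as.integer(paste(tok, collapse = "")))
      tok <- character(0)
    }
  }
  out
}

write_pgm <- function(image, path, binary = FALSE) {
  vals <- round(image)
  maxval <- max(1L, as.integer(max(vals)))
  if (maxval > 65535L) {
    stop("PGM supports maxval up to 65535; rescale first", call. = FALSE)
  }
  h <- nrow(vals)
  w <- ncol(vals)
  v <- as.integer(t(vals))  # row-major
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(w, h), as.character(maxval)), con)
    if (maxval < 256L) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(v, con, size = 2L, endian = "big")
    }
  } else {
    rows <- apply(matrix(v, nrow = h, byrow = TRUE), 1L, paste,
                  collapse = " ")
    writeLines(c("P2", paste(w, h), as.character(maxval), rows), path)
  }
  invisible(path)
}
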