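#' 8-bit grayscale image
#'
#' The whole pipeline operates on plain integer matrices holding intensities
#' in `[0, 255]`, row 1 at the top of the image and column index increasing
#' rightward. `gray_image()` validates a matrix and stamps it with the
#' `"gray_image"` class; every exported function also accepts a bare numeric
#' matrix of integral values and coerces it on entry.
#'
#' @param x numeric or integer matrix with all values integral and in
#'   `[0, 255]`.
#' @return An integer matrix of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(128L, 4, 6))
#' dim(img)
#' @export
gray_image <- function(x) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("image must have positive dimensions")
  if (anyNA(x)) stop("image contains missing values")
  if (any(x < 0) || any(x > 255)) stop("intensities must lie in [0, 255]")
  if (is.double(x) && any(x != floor(x))) {
    stop("intensities must be integral; round explicitly before construction")
  }
  storage.mode(x) <- "integer"
  class(x) <- c("gray_image", class(matrix()))
  x
}

#' @rdname gray_image
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
as_gray_image <- function(x) {
  if (is_gray_image(x)) return(x)
  gray_image(x)
}

# round-half-up: reproducible across platforms, unlike banker's round()
round_half_up <- function(x) floor(x + 0.5)

# clip to the 8-bit range and round half-up; returns an integer matrix
clip8 <- function(x) {
  x <- round_half_up(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

check_congruent <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("images must have identical dimensions")
  }
  invisible(TRUE)
}

#' Read a raster image as 8-bit grayscale
#'
#' Reads a PNG or TIFF file and normalizes it to the 8-bit grayscale domain
#' the defect-removal algorithm assumes. RGB(A) input is collapsed with the
#' Rec. 601 luma weights (0.299, 0.587, 0.114) before rounding. Inputs with
#' more than 8 bits per sample are mapped to `[0, 255]` according to `mode`:
#' `"rescale-minmax"` linearly maps the observed `[min, max]` onto
#' `[0, 255]` (a constant image maps to 0), `"8bit-passthrough"` assumes the
#' stored values already use at most 8 bits and refuses otherwise. DICOM
#' window/level transformations are not applied; convert DICOM exports to
#' PNG/TIFF upstream.
#'
#' @param path path to a single-frame PNG or TIFF file.
#' @param mode bit-depth policy for deeper-than-8-bit input, see Details.
#' @return A [gray_image].
#' @export
load_image <- function(path, mode = c("rescale-minmax", "8bit-passthrough")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, all = TRUE)
      if (length(x) > 1L) stop("multi-frame TIFF input is unsupported")
      x[[1L]]
    },
    stop("unsupported image format: '.", ext, "'")
  )
  # readers return [0,1] doubles; 8-bit samples sit exactly on the /255 grid
  is8bit <- max(abs(raw * 255 - round(raw * 255))) < 1e-6
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3L]
    raw <- if (nc >= 3L) {
      0.299 * raw[, , 1L] + 0.587 * raw[, , 2L] + 0.114 * raw[, , 3L]
    } else {
      raw[, , 1L] # gray+alpha: drop alpha
    }
  }
  if (is8bit) {
    return(gray_image(clip8(raw * 255)))
  }
  # deeper than 8 bits per sample
  if (mode == "8bit-passthrough") {
    stop("input exceeds 8 bits per sample; use mode = 'rescale-minmax'")
  }
  lo <- min(raw)
  hi <- max(raw)
  if (hi == lo) {
    out <- matrix(0L, nrow(raw), ncol(raw))
  } else {
    out <- clip8((raw - lo) / (hi - lo) * 255)
  }
  gray_image(out)
}

#' Write an 8-bit grayscale image losslessly
#'
#' PNG and TIFF output round-trips bit-exactly through [load_image()].
#'
#' @param img a [gray_image] (or coercible matrix).
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @export
save_image <- function(img, path) {
  img <- as_gray_image(img)
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  x <- unclass(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, target = path),
    tif = ,
    tiff = tiff::writeTIFF(x, where = path, bits.per.sample = 8L),
    stop("unsupported image format: '.", ext, "'")
  )
  invisible(path)
}
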