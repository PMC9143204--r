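#' Per-row column intervals of a detected defect core
#'
#' The defect core is the part of the image where the detector fault
#' destroyed information outright: intensity strictly above the core
#' threshold (default 220) or exactly zero. It is stored as one half-open
#' column interval `[left, right)` per affected row; rows without
#' qualifying pixels carry no interval until [connect_core_segments()]
#' bridges them.
#'
#' @param rows data frame with integer columns `row`, `left`, `right`
#'   (1-based, half-open, `left < right`), at most one interval per row.
#' @param connected logical; TRUE once the rows form a single contiguous
#'   vertical block.
#' @param dim dimensions of the source image, used for validation.
#' @return An object of class `defect_core`.
#' @export
defect_core <- function(rows, connected = FALSE, dim = NULL) {
  stopifnot(is.data.frame(rows), all(c("row", "left", "right") %in% names(rows)))
  rows <- rows[order(rows$row), , drop = FALSE]
  if (anyDuplicated(rows$row)) stop("at most one interval per row")
  if (nrow(rows) && any(rows$left >= rows$right)) stop("intervals must be non-empty")
  if (!is.null(dim) && nrow(rows)) {
    if (any(rows$row < 1L) || any(rows$row > dim[1]) ||
        any(rows$left < 1L) || any(rows$right > dim[2] + 1L)) {
      stop("core intervals lie outside the image")
    }
  }
  rownames(rows) <- NULL
  rows$row <- as.integer(rows$row)
  rows$left <- as.integer(rows$left)
  rows$right <- as.integer(rows$right)
  structure(list(rows = rows, connected = isTRUE(connected), dim = dim),
            class = "defect_core")
}

#' @rdname defect_core
#' @export
core_is_empty <- function(core) nrow(core$rows) == 0L

#' @rdname defect_core
#' @description `core_span()` returns the overall half-open column span of
#'   all intervals and `core_raster()` rasterizes the core to a logical
#'   matrix.
#' @param core a `defect_core`.
#' @export
core_span <- function(core) {
  if (core_is_empty(core)) stop("empty defect core")
  c(min(core$rows$left), max(core$rows$right))
}

#' @rdname defect_core
#' @export
core_raster <- function(core, dim = core$dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  r <- core$rows
  for (i in seq_len(nrow(r))) m[r$row[i], r$left[i]:(r$right[i] - 1L)] <- TRUE
  m
}

#' Locate the breast contour by border-to-center scanning
#'
#' For each row, the scan moves inward from the left and right image
#' borders until a pixel exceeds `low_thresh`; the breast run of that row is
#' the contiguous column interval between the two first hits. Rows in which
#' no pixel exceeds the threshold get an empty run, so an all-black image
#' yields an empty mask.
#'
#' @param img a [gray_image].
#' @param low_thresh intensities at or below this value count as background
#'   black (default 5).
#' @param side which vertical image edge the breast abuts; `"auto"` compares
#'   the mean intensity of the first and last column. Recorded as an
#'   attribute for downstream reporting; the scan itself is symmetric.
#' @return A logical matrix congruent with `img`, TRUE inside the breast;
#'   attribute `side` records the abutting edge.
#' @export
find_breast_contour <- function(img, low_thresh = 5L, side = c("auto", "left", "right")) {
  side <- match.arg(side)
  img <- as_gray_image(img)
  if (low_thresh < 0 || low_thresh > 255) stop("low_thresh must lie in [0, 255]")
  x <- unclass(img)
  bright <- x > low_thresh
  h <- nrow(x)
  w <- ncol(x)
  mask <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    v <- bright[r, ]
    l <- match(TRUE, v)
    if (is.na(l)) next
    rr <- w + 1L - match(TRUE, rev(v))
    mask[r, l:rr] <- TRUE
  }
  if (side == "auto") {
    side <- if (mean(x[, 1]) >= mean(x[, w])) "left" else "right"
  }
  attr(mask, "side") <- side
  mask
}

#' Detect the defect core
#'
#' Core pixels are those inside the breast mask whose intensity is strictly
#' greater than `hi_thresh` or exactly zero. Per row, when several disjoint
#' runs of core pixels occur (stray bright specks), the run whose center is
#' nearest the median core column over all rows is kept: the band defect is
#' a single vertical structure.
#'
#' @param img a [gray_image].
#' @param mask logical breast mask congruent with `img`.
#' @param hi_thresh core intensity threshold; pixels must exceed it strictly
#'   (default 220).
#' @return A [defect_core] with `connected = FALSE`; empty when no pixel
#'   qualifies.
#' @export
detect_defect_core <- function(img, mask, hi_thresh = 220L) {
  img <- as_gray_image(img)
  check_congruent(img, mask)
  x <- unclass(img)
  qual <- mask & (x > hi_thresh | x == 0L)
  h <- nrow(x)
  runs_per_row <- vector("list", h)
  for (r in seq_len(h)) {
    v <- qual[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs_per_row[[r]] <- cbind(start = starts[keep], end = ends[keep])
  }
  present <- which(!vapply(runs_per_row, is.null, logical(1)))
  if (!length(present)) {
    return(defect_core(data.frame(row = integer(), left = integer(),
                                  right = integer()), dim = dim(img)))
  }
  # first pass: longest run per row fixes a provisional band axis
  centers <- vapply(present, function(r) {
    runs <- runs_per_row[[r]]
    i <- which.max(runs[, "end"] - runs[, "start"])
    (runs[i, "start"] + runs[i, "end"]) / 2
  }, numeric(1))
  axis <- stats::median(centers)
  # second pass: per row keep the run nearest the axis
  sel <- t(vapply(present, function(r) {
    runs <- runs_per_row[[r]]
    d <- abs((runs[, "start"] + runs[, "end"]) / 2 - axis)
    i <- which.min(d)
    c(runs[i, "start"], runs[i, "end"])
  }, numeric(2)))
  defect_core(data.frame(row = present, left = as.integer(sel[, 1]),
                         right = as.integer(sel[, 2] + 1L)),
              dim = dim(img))
}

#' Bridge gaps in the defect core with straight lines
#'
#' The core of a band defect need not be present in every horizontal
#' section (the band's brightness can dip below the core threshold in the
#' middle). Rows between the topmost and bottommost detected intervals that
#' lack one get left and right bounds filled in by linear interpolation, in
#' row index, between the nearest bounded rows above and below, rounded
#' half-up to whole columns. The result is a single vertically contiguous
#' band; the operation never shrinks an existing interval and is idempotent.
#'
#' @param core a non-empty [defect_core].
#' @return The connected [defect_core].
#' @export
connect_core_segments <- function(core) {
  stopifnot(inherits(core, "defect_core"))
  if (core_is_empty(core)) stop("cannot connect an empty defect core")
  r <- core$rows
  all_rows <- seq(min(r$row), max(r$row))
  missing <- setdiff(all_rows, r$row)
  if (length(missing)) {
    li <- stats::approx(r$row, r$left, xout = missing)$y
    ri <- stats::approx(r$row, r$right, xout = missing)$y
    add <- data.frame(row = missing,
                      left = as.integer(round_half_up(li)),
                      right = as.integer(round_half_up(ri)))
    r <- rbind(r, add)
  }
  defect_core(r, connected = TRUE, dim = core$dim)
}
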