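#' Tile the defect flanks with curvilinear quadrilaterals
#'
#' The areas left and right of the connected core are covered with
#' quadrilaterals of nominal size `tile` x `tile` pixels that follow the
#' core's (generally arcuate) edge: tiles proceed outward from the core in
#' `tile`-column layers and downward in `tile`-row blocks, each row of a
#' tile clipped to the breast mask, so tiles near the contour can be
#' shorter than `tile` pixels vertically. Tiles are pairwise disjoint and
#' jointly cover the flank band out to `layers` layers per side.
#'
#' @param core a connected [defect_core].
#' @param mask logical breast mask.
#' @param tile nominal tile size in pixels (default 100).
#' @param layers number of tile layers per side (default 4).
#' @return List of `flank_region` objects, each a list with `side`
#'   (`"left"`/`"right"`), `layer`, `block` (row-block index) and `bounds`
#'   (data frame `row`, `left`, `right`, half-open column intervals).
#' @export
tile_flanks <- function(core, mask, tile = 100L, layers = 4L) {
  stopifnot(inherits(core, "defect_core"))
  if (core_is_empty(core)) stop("cannot tile the flanks of an empty core")
  if (!core$connected) stop("core must be connected before tiling")
  r <- core$rows
  # per-row breast run bounds
  run <- mask_runs(mask)
  blocks <- split(seq_len(nrow(r)), (seq_len(nrow(r)) - 1L) %/% tile)
  out <- list()
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    for (side in c("left", "right")) {
      for (k in seq_len(layers)) {
        bounds <- lapply(idx, function(i) {
          row <- r$row[i]
          if (is.na(run$first[row])) return(NULL)
          if (side == "right") {
            a <- r$right[i] + (k - 1L) * tile
            z <- min(a + tile, run$last[row] + 1L)
            a <- max(a, r$right[i], run$first[row])
          } else {
            z <- r$left[i] - (k - 1L) * tile
            a <- max(z - tile, run$first[row])
            z <- min(z, r$left[i], run$last[row] + 1L)
          }
          if (a >= z) return(NULL)
          data.frame(row = row, left = a, right = z)
        })
        bounds <- do.call(rbind, bounds)
        if (is.null(bounds) || !nrow(bounds)) next
        out[[length(out) + 1L]] <- structure(
          list(side = side, layer = k, block = b, bounds = bounds),
          class = "flank_region")
      }
    }
  }
  out
}

# first/last in-mask column per row (NA where the row is empty)
mask_runs <- function(mask) {
  h <- nrow(mask)
  first <- rep(NA_integer_, h)
  last <- rep(NA_integer_, h)
  for (row in seq_len(h)) {
    v <- mask[row, ]
    if (!any(v)) next
    first[row] <- match(TRUE, v)
    last[row] <- ncol(mask) + 1L - match(TRUE, rev(v))
  }
  list(first = first, last = last)
}

# column means of the image restricted to a flank region (and optionally a
# paired region across the core); returns cols, means, and a side label
region_column_means <- function(x, region) {
  b <- region$bounds
  cols <- sort(unique(unlist(lapply(seq_len(nrow(b)),
                                    function(i) b$left[i]:(b$right[i] - 1L)))))
  sums <- stats::setNames(numeric(length(cols)), cols)
  cnts <- stats::setNames(numeric(length(cols)), cols)
  for (i in seq_len(nrow(b))) {
    cc <- b$left[i]:(b$right[i] - 1L)
    key <- as.character(cc)
    sums[key] <- sums[key] + x[b$row[i], cc]
    cnts[key] <- cnts[key] + 1
  }
  list(cols = cols, means = unname(sums / cnts))
}

#' Column-mean profile and straight-line baseline of a flank region
#'
#' Computes the average intensity of every image column within the region,
#' then the straight line that the ramp-flattening step corrects toward:
#' the line through the minimum column mean on the illuminated (bright)
#' side and the maximum column mean on the darkened side. When the region
#' lies wholly on one side of the core, the anchor for the missing side is
#' taken from `paired`, the mirror region across the core; with no paired
#' region the line runs through the region's own extreme column means.
#'
#' @param img a [gray_image].
#' @param region a `flank_region` from [tile_flanks()].
#' @param bright_side which side of the core is illuminated, `"left"` or
#'   `"right"`.
#' @param paired optional mirror `flank_region` on the opposite side.
#' @return An object of class `column_profile`: list with `cols` (absolute
#'   column indices covered, region first then paired), `means`, `baseline`
#'   (affine in column index) and `region_cols` (columns belonging to
#'   `region` itself).
#' @export
column_baseline <- function(img, region, bright_side = c("left", "right"),
                            paired = NULL) {
  bright_side <- match.arg(bright_side)
  img <- as_gray_image(img)
  if (is.null(region$bounds) || !nrow(region$bounds)) stop("empty flank region")
  x <- unclass(img) * 1.0
  own <- region_column_means(x, region)
  if (!is.null(paired)) {
    oth <- region_column_means(x, paired)
    bright <- if (region$side == bright_side) own else oth
    dark <- if (region$side == bright_side) oth else own
    cb <- bright$cols[which.min(bright$means)]
    vb <- min(bright$means)
    cd <- dark$cols[which.max(dark$means)]
    vd <- max(dark$means)
    cols <- c(own$cols, oth$cols)
    means <- c(own$means, oth$means)
  } else {
    cb <- own$cols[which.min(own$means)]
    vb <- min(own$means)
    cd <- own$cols[which.max(own$means)]
    vd <- max(own$means)
    cols <- own$cols
    means <- own$means
  }
  baseline <- if (cd == cb) rep(vb, length(cols)) else {
    vb + (vd - vb) * (cols - cb) / (cd - cb)
  }
  structure(list(cols = cols, means = means, baseline = baseline,
                 region_cols = own$cols),
            class = "column_profile")
}

#' Flatten the intensity ramp within one flank region
#'
#' For every column of the region, the difference between its column mean
#' and the straight-line baseline is subtracted from each pixel of that
#' column (clipped to `[0, 255]`), so that post-correction column means
#' equal the baseline up to rounding wherever no clipping occurred. Pixels
#' outside the region are untouched.
#'
#' @param img a [gray_image].
#' @param region the `flank_region` the profile was computed for.
#' @param profile a `column_profile` from [column_baseline()].
#' @return The corrected [gray_image].
#' @export
flatten_ramp <- function(img, region, profile) {
  img <- as_gray_image(img)
  stopifnot(inherits(profile, "column_profile"))
  x <- unclass(img) * 1.0
  delta <- stats::setNames(profile$means - profile$baseline, profile$cols)
  b <- region$bounds
  for (i in seq_len(nrow(b))) {
    cc <- b$left[i]:(b$right[i] - 1L)
    x[b$row[i], cc] <- x[b$row[i], cc] - delta[as.character(cc)]
  }
  out <- gray_image(clip8(x))
  for (a in c("breast_mask", "streak_truth", "background")) {
    if (!is.null(attr(img, a))) attr(out, a) <- attr(img, a)
  }
  out
}

#' Flatten the full ramp around a defect core
#'
#' Convenience driver for the baseline correction: tiles both flanks,
#' decides which side is illuminated (larger mean intensity in the tile
#' layer adjacent to the core), pairs each tile with its mirror across the
#' core, and applies [column_baseline()] + [flatten_ramp()] tile by tile.
#'
#' @inheritParams tile_flanks
#' @param img a [gray_image].
#' @return The ramp-flattened [gray_image].
#' @export
correct_ramp <- function(img, core, mask, tile = 100L, layers = 4L) {
  img <- as_gray_image(img)
  regions <- tile_flanks(core, mask, tile = tile, layers = layers)
  if (!length(regions)) return(img)
  x <- unclass(img)
  layer1 <- Filter(function(r) r$layer == 1L, regions)
  side_mean <- function(s) {
    b <- do.call(rbind, lapply(Filter(function(r) r$side == s, layer1),
                               `[[`, "bounds"))
    if (is.null(b) || !nrow(b)) return(NA_real_)
    mean(unlist(lapply(seq_len(nrow(b)),
                       function(i) x[b$row[i], b$left[i]:(b$right[i] - 1L)])))
  }
  ml <- side_mean("left")
  mr <- side_mean("right")
  bright_side <- if (isTRUE(ml >= mr) || is.na(mr)) "left" else "right"

  key <- function(r) paste(r$block, r$layer)
  lefts <- Filter(function(r) r$side == "left", regions)
  rights <- Filter(function(r) r$side == "right", regions)
  rkeys <- vapply(rights, key, character(1))
  out <- img
  done <- character(0)
  for (rg in lefts) {
    mate <- rights[match(key(rg), rkeys)][[1]]
    prof <- column_baseline(out, rg, bright_side, paired = mate)
    out <- flatten_ramp(out, rg, prof)
    if (!is.null(mate)) {
      prof2 <- column_baseline(out, mate, bright_side, paired = rg)
      out <- flatten_ramp(out, mate, prof2)
      done <- c(done, key(mate))
    }
  }
  for (rg in rights[!rkeys %in% done]) {
    prof <- column_baseline(out, rg, bright_side, paired = NULL)
    out <- flatten_ramp(out, rg, prof)
  }
  out
}

#' Per-side intensity statistics across the defect
#'
#' Partitions the in-mask, non-core pixels by the core's overall column
#' span and computes each side's histogram mode (smallest intensity
#' achieving the maximum count) and population standard deviation. Side A
#' is the side with the larger standard deviation — the high-contrast,
#' uncorrupted side — and side B the lower-contrast one; ties label the
#' left side A.
#'
#' @param img a [gray_image].
#' @param mask logical breast mask.
#' @param core a connected, non-empty [defect_core].
#' @return An object of class `contrast_stats`: list with `modeA`, `modeB`,
#'   `stdA`, `stdB` and `side_a` (`"left"`/`"right"`).
#' @export
side_stats <- function(img, mask, core) {
  img <- as_gray_image(img)
  check_congruent(img, mask)
  span <- core_span(core)
  x <- unclass(img)
  cols <- matrix(seq_len(ncol(x)), nrow(x), ncol(x), byrow = TRUE)
  left_sel <- mask & cols < span[1]
  right_sel <- mask & cols >= span[2]
  if (!any(left_sel) || !any(right_sel)) {
    stop("a side of the defect contains no in-mask pixels")
  }
  stat1 <- function(v) {
    tab <- tabulate(v + 1L, nbins = 256L)
    list(mode = which.max(tab) - 1L, # which.max returns the first maximum
         std = sqrt(mean((v - mean(v))^2)))
  }
  sl <- stat1(x[left_sel])
  sr <- stat1(x[right_sel])
  if (sl$std >= sr$std) {
    structure(list(modeA = sl$mode, modeB = sr$mode,
                   stdA = sl$std, stdB = sr$std, side_a = "left"),
              class = "contrast_stats")
  } else {
    structure(list(modeA = sr$mode, modeB = sl$mode,
                   stdA = sr$std, stdB = sl$std, side_a = "right"),
              class = "contrast_stats")
  }
}

#' @rdname side_stats
#' @param modeA,modeB,stdA,stdB components for direct construction.
#' @param side_a which physical side carries label A.
#' @export
contrast_stats <- function(modeA, modeB, stdA, stdB, side_a = "left") {
  stopifnot(stdA >= 0, stdB >= 0)
  structure(list(modeA = modeA, modeB = modeB, stdA = stdA, stdB = stdB,
                 side_a = side_a),
            class = "contrast_stats")
}

#' Adaptive CLAHE clip limit from the two flank standard deviations
#'
#' The clip limit used to equalize the low-contrast side is set by the
#' empirical linear model
#' `clip_limit = 1.11 - 0.023 * (stdB - stdA)`,
#' where `stdA` and `stdB` are the pixel-brightness standard deviations of
#' the high- and low-contrast sides of the defect. Since the linear form
#' can turn non-positive for large contrast gaps and CLAHE requires a
#' positive clip limit, the value is floored at `floor`.
#'
#' @param stats a `contrast_stats` object.
#' @param floor smallest admissible clip limit (default 0.1).
#' @return The clip limit, a positive scalar.
#' @export
adaptive_clip_limit <- function(stats, floor = 0.1) {
  stopifnot(inherits(stats, "contrast_stats"))
  max(1.11 - 0.023 * (stats$stdB - stats$stdA), floor)
}

# CLAHE on an 8-bit matrix: pad by edge replication to a multiple of the
# tile grid (EBImage requires exact divisibility), equalize, crop back.
clahe8 <- function(x, clip_limit, grid = 8L) {
  h <- nrow(x)
  w <- ncol(x)
  nx <- max(1L, min(grid, w %/% 2L))
  ny <- max(1L, min(grid, h %/% 2L))
  if (nx < 2L || ny < 2L) return(x) # window too small to equalize locally
  ph <- ceiling(h / ny) * ny
  pw <- ceiling(w / nx) * nx
  xp <- x[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w)), drop = FALSE]
  y <- EBImage::clahe(EBImage::Image(xp / 255), nx = nx, ny = ny,
                      bins = 256L, limit = clip_limit)
  clip8(as.matrix(y)[seq_len(h), seq_len(w), drop = FALSE] * 255)
}

#' Equalize the low-contrast side of the defect with CLAHE
#'
#' Applies contrast-limited adaptive histogram equalization (8x8 tile grid
#' by default) to the bounding box of the low-contrast side B and blends
#' the result back with a linear feather over `feather` columns starting at
#' the core boundary, so no visible seam is created. Pixels on the
#' high-contrast side and outside the breast mask are bit-identical to the
#' input. A degenerate side (at most one pixel, or constant intensity) is
#' returned unchanged with a warning.
#'
#' @param img a [gray_image].
#' @param mask logical breast mask.
#' @param core a connected [defect_core].
#' @param clip_limit positive CLAHE clip limit, typically from
#'   [adaptive_clip_limit()].
#' @param grid tiles per axis of the CLAHE grid (default 8).
#' @param feather width (columns) of the linear blending ramp at the core
#'   boundary (default 20).
#' @param stats optional precomputed `contrast_stats`; recomputed when
#'   missing.
#' @return The equalized [gray_image].
#' @export
equalize_low_contrast_side <- function(img, mask, core, clip_limit,
                                       grid = 8L, feather = 20L,
                                       stats = NULL) {
  img <- as_gray_image(img)
  if (clip_limit <= 0) stop("clip_limit must be positive")
  if (is.null(stats)) stats <- side_stats(img, mask, core)
  span <- core_span(core)
  x <- unclass(img)
  cols <- matrix(seq_len(ncol(x)), nrow(x), ncol(x), byrow = TRUE)
  b_left <- stats$side_a == "right"
  sel <- if (b_left) mask & cols < span[1] else mask & cols >= span[2]
  if (sum(sel) <= 1L) {
    warning("degenerate low-contrast side; returning input unchanged")
    return(img)
  }
  if (stats$stdB == 0) {
    warning("low-contrast side is constant; nothing to equalize")
    return(img)
  }
  rr <- range(which(rowSums(sel) > 0))
  cr <- range(which(colSums(sel) > 0))
  sub <- x[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  eq <- clahe8(sub, clip_limit, grid)
  # feather: weight 0 at the core-adjacent edge of the box, 1 beyond it
  nc <- ncol(sub)
  dist <- if (b_left) (nc:1) else (1:nc)
  wgt <- pmin(dist / max(1L, feather), 1)
  wmat <- matrix(wgt, nrow(sub), nc, byrow = TRUE)
  blend <- clip8(wmat * eq + (1 - wmat) * sub)
  out <- x
  subsel <- sel[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  region <- out[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  region[subsel] <- blend[subsel]
  out[rr[1]:rr[2], cr[1]:cr[2]] <- region
  res <- gray_image(out)
  for (a in c("breast_mask", "streak_truth", "background")) {
    if (!is.null(attr(img, a))) attr(res, a) <- attr(img, a)
  }
  res
}
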