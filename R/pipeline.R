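#' Configuration of the full defect-removal pipeline
#'
#' Collects every tunable of the pipeline with the algorithm's standard
#' values: core threshold 220, contour threshold 5, 100-pixel flank tiles,
#' 8x8 CLAHE grid, streak-mask clip limit 20 and binarization threshold
#' 170.
#'
#' @param low_thresh breast-contour background threshold.
#' @param hi_thresh defect-core intensity threshold (strict).
#' @param tile flank tile size in pixels.
#' @param layers flank tile layers per side.
#' @param grid CLAHE tiles per axis.
#' @param clip_floor smallest admissible adaptive clip limit.
#' @param feather seam feather width (columns) for side equalization.
#' @param degree interpolation polynomial degree.
#' @param flank_k flank columns averaged per interpolation anchor.
#' @param margin streak-mask margin beyond the core (columns).
#' @param mask_clip CLAHE clip limit of the streak-mask boost.
#' @param mask_threshold streak binarization threshold.
#' @param restorer background restorer, see [restorers].
#' @param verbose log each stage to the console.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(low_thresh = 5L, hi_thresh = 220L, tile = 100L,
                            layers = 4L, grid = 8L, clip_floor = 0.1,
                            feather = 20L, degree = 1L, flank_k = 3L,
                            margin = 50L, mask_clip = 20,
                            mask_threshold = streak_threshold(),
                            restorer = restorer_biharmonic(),
                            verbose = FALSE) {
  structure(list(low_thresh = low_thresh, hi_thresh = hi_thresh, tile = tile,
                 layers = layers, grid = grid, clip_floor = clip_floor,
                 feather = feather, degree = degree, flank_k = flank_k,
                 margin = margin, mask_clip = mask_clip,
                 mask_threshold = mask_threshold, restorer = restorer,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the complete band-defect removal pipeline
#'
#' Executes the full chain: breast-contour extraction, defect-core
#' detection and connection, per-column ramp flattening of the flanks,
#' CLAHE equalization of the low-contrast side with the adaptive clip
#' limit, per-row interpolation of the core, background inpainting, streak
#' mask extraction and the final overlay. When no core is found the
#' restoration stages are bypassed: the defect axis is taken at the median
#' in-breast column, the low-contrast side is still equalized, and the
#' composite equals that equalized image with an empty streak mask.
#'
#' @param img a [gray_image] (or coercible matrix).
#' @param config a [pipeline_config].
#' @return An object of class `restoration_bundle`: list with elements
#'   `interpolated`, `background`, `mask` (streak mask), `composite`,
#'   `corrected` (ramp-flattened, equalized input), `core`, `breast_mask`,
#'   `stats` (contrast statistics) and `clip_limit`.
#' @export
restore_pipeline <- function(img, config = pipeline_config()) {
  img <- as_gray_image(img)
  say <- function(...) if (isTRUE(config$verbose)) message("[deband] ", ...)

  say("breast contour")
  bmask <- find_breast_contour(img, low_thresh = config$low_thresh)
  say("defect core")
  core <- detect_defect_core(img, bmask, hi_thresh = config$hi_thresh)

  if (core_is_empty(core)) {
    say("no defect core found; equalization-only bypass")
    in_cols <- which(colSums(bmask) > 0)
    if (!length(in_cols)) {
      empty_mask <- matrix(FALSE, nrow(img), ncol(img))
      return(bundle(img, img, empty_mask, img, img, core, bmask, NULL, NA_real_))
    }
    med <- as.integer(round_half_up(stats::median(in_cols)))
    rows_in <- which(rowSums(bmask) > 0)
    axis <- defect_core(data.frame(row = rows_in, left = med, right = med + 1L),
                        connected = TRUE, dim = dim(img))
    st <- side_stats(img, bmask, axis)
    clip <- adaptive_clip_limit(st, floor = config$clip_floor)
    eq <- equalize_low_contrast_side(img, bmask, axis, clip,
                                     grid = config$grid,
                                     feather = config$feather, stats = st)
    empty_mask <- matrix(FALSE, nrow(img), ncol(img))
    return(bundle(eq, eq, empty_mask, eq, eq, core, bmask, st, clip))
  }

  core <- connect_core_segments(core)
  say("ramp flattening (", nrow(core$rows), " core rows)")
  corrected <- correct_ramp(img, core, bmask,
                            tile = config$tile, layers = config$layers)
  say("side statistics and adaptive clip limit")
  st <- side_stats(corrected, bmask, core)
  clip <- adaptive_clip_limit(st, floor = config$clip_floor)
  say(sprintf("clip limit %.3f (stdA %.2f, stdB %.2f)", clip, st$stdA, st$stdB))
  eq <- equalize_low_contrast_side(corrected, bmask, core, clip,
                                   grid = config$grid,
                                   feather = config$feather, stats = st)
  say("core interpolation")
  interp <- interpolate_core(eq, core, degree = config$degree,
                             flank_k = config$flank_k)
  say("background restoration")
  bg <- restore_background(eq, core, restorer = config$restorer)
  say("streak mask")
  smask <- streak_mask(interp, core, margin = config$margin,
                       mask_clip = config$mask_clip,
                       threshold = config$mask_threshold, grid = config$grid)
  # fuse only inside the core: outside it interpolated == equalized anyway,
  # but restricting keeps the composite's provenance explicit
  fuse <- smask & core_raster(core, dim(img))
  say("overlay")
  composite <- overlay_streaks(bg, interp, fuse)
  bundle(interp, bg, smask, composite, eq, core, bmask, st, clip)
}

bundle <- function(interpolated, background, mask, composite, corrected,
                   core, breast_mask, stats, clip_limit) {
  structure(list(interpolated = interpolated, background = background,
                 mask = mask, composite = composite, corrected = corrected,
                 core = core, breast_mask = breast_mask, stats = stats,
                 clip_limit = clip_limit),
            class = "restoration_bundle")
}

#' @export
print.restoration_bundle <- function(x, ...) {
  d <- dim(x$composite)
  cat("<restoration_bundle> ", d[1], "x", d[2], " image\n", sep = "")
  if (core_is_empty(x$core)) {
    cat("  no defect core detected (equalization-only bypass)\n")
  } else {
    sp <- core_span(x$core)
    cat("  core: rows ", min(x$core$rows$row), "-", max(x$core$rows$row),
        ", columns [", sp[1], ", ", sp[2], ")\n", sep = "")
  }
  if (!is.null(x$stats)) {
    cat(sprintf("  stdA %.2f, stdB %.2f -> clip limit %.3f\n",
                x$stats$stdA, x$stats$stdB, x$clip_limit))
  }
  cat("  streak mask covers ", sum(x$mask), " pixels\n", sep = "")
  invisible(x)
}
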