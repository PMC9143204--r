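#' First-order radiomics descriptors of an image region
#'
#' The 18 standard first-order (histogram) radiomics features over the
#' in-mask pixels: energy, total energy, entropy, minimum, 10th percentile,
#' 90th percentile, maximum, mean, median, interquartile range, range, mean
#' absolute deviation, robust mean absolute deviation (over the 10th–90th
#' percentile subset), root mean squared, skewness, kurtosis (not excess),
#' variance (population) and uniformity. Entropy and uniformity use
#' fixed-bin-width discretization anchored at the region minimum
#' (`bin_width` intensity units, default 25). Pixels have unit area, so
#' total energy equals energy. For a constant region, skewness and
#' kurtosis are reported as 0.
#'
#' @param img a [gray_image].
#' @param mask logical matrix selecting the region (non-empty).
#' @param bin_width histogram bin width for entropy/uniformity.
#' @return Named numeric vector of length 18.
#' @export
first_order_features <- function(img, mask, bin_width = 25) {
  img <- as_gray_image(img)
  check_congruent(img, mask)
  if (!any(mask)) stop("empty mask")
  x <- as.numeric(unclass(img)[mask])
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  bins <- floor((x - min(x)) / bin_width)
  p <- tabulate(bins + 1L, nbins = max(bins) + 1L) / n
  p <- p[p > 0]
  c(energy = sum(x^2),
    total_energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    p10 = q[1],
    p90 = q[5],
    maximum = max(x),
    mean = m,
    median = q[3],
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - m)),
    rmad = if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    rms = sqrt(mean(x^2)),
    skewness = if (v > 0) mean((x - m)^3) / v^1.5 else 0,
    kurtosis = if (v > 0) mean((x - m)^4) / v^2 else 0,
    variance = v,
    uniformity = sum(p^2))
}

#' Names of the first-order feature set
#' @return Character vector of the 18 feature names.
#' @export
first_order_feature_names <- function() {
  c("energy", "total_energy", "entropy", "minimum", "p10", "p90", "maximum",
    "mean", "median", "iqr", "range", "mad", "rmad", "rms", "skewness",
    "kurtosis", "variance", "uniformity")
}

#' Feature table across processing groups
#'
#' Computes, for each group of images (e.g. originals and the variants
#' produced by different restoration methods), the first-order features of
#' every image, optionally augmented by texture features from a pluggable
#' extractor. Groups must hold equally many images so the downstream
#' balanced tests apply.
#'
#' @param images_by_group named list of lists of [gray_image]s; the group
#'   of pristine originals should be named `"original"`.
#' @param mask logical region mask, a single matrix applied to all images,
#'   or a list of masks parallel to the images of each group. `NULL` uses
#'   each image's own `breast_mask` attribute.
#' @param extractor optional `function(img, mask)` returning a named
#'   numeric vector of texture features; its names are reported with
#'   feature class `"texture"`.
#' @param bin_width passed to [first_order_features()].
#' @return An object of class `feature_table`: list with `groups`,
#'   `features` (feature -> group -> numeric vector) and `feature_class`
#'   (named `"first-order"`/`"texture"`).
#' @export
build_feature_table <- function(images_by_group, mask = NULL,
                                extractor = NULL, bin_width = 25) {
  stopifnot(is.list(images_by_group), length(images_by_group) >= 2L,
            !is.null(names(images_by_group)))
  sizes <- lengths(images_by_group)
  if (length(unique(sizes)) != 1L) stop("groups must hold equal image counts")
  get_mask <- function(im) {
    if (!is.null(mask)) return(mask)
    bm <- attr(im, "breast_mask")
    if (is.null(bm)) stop("no mask supplied and image carries no breast_mask")
    bm
  }
  one <- function(im) {
    fo <- first_order_features(im, get_mask(im), bin_width = bin_width)
    if (!is.null(extractor)) {
      tx <- extractor(im, get_mask(im))
      fo <- c(fo, tx)
    }
    fo
  }
  per_group <- lapply(images_by_group, function(gr) {
    vals <- vapply(gr, one, one(gr[[1]]))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    vals
  })
  fnames <- rownames(per_group[[1]])
  features <- stats::setNames(lapply(fnames, function(f) {
    lapply(per_group, function(m) unname(m[f, ]))
  }), fnames)
  fclass <- ifelse(fnames %in% first_order_feature_names(),
                   "first-order", "texture")
  structure(list(groups = names(images_by_group), features = features,
                 feature_class = stats::setNames(fclass, fnames)),
            class = "feature_table")
}
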