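#' Background restorers
#'
#' A background restorer reconstructs plausible tissue inside the defect
#' core. It is a pluggable contract: a function `f(img, hole)` taking a
#' [gray_image] and a logical hole mask, returning a congruent
#' [gray_image] that is identical to the input outside the hole.
#' [restore_background()] enforces the contract at run time, so any
#' hole-filling procedure — including an external neural inpainter — can be
#' dropped in.
#'
#' `restorer_biharmonic()` is the default: biharmonic inpainting, the
#' classical workhorse for smooth hole filling. The fill minimizes the
#' squared discrete Laplacian over the hole, which continues both the
#' intensity and its gradient across the hole boundary; the sparse normal
#' equations are solved exactly on a window two pixels wider than the hole
#' (outside of which the solution does not depend on the data).
#'
#' `restorer_diffusion()` is harmonic (Laplace) inpainting: hole pixels
#' solve the discrete Laplace equation with Dirichlet data from the
#' surrounding ring, i.e. each filled pixel is the average of its
#' 4-neighbors. Cheaper and flatter than the biharmonic fill. Both
#' reconstruct a smooth background but, by design, no texture or streaks —
#' those are re-imposed by the streak-mask overlay.
#'
#' `restorer_coarse_fine()` wraps any base restorer in a coarse-to-fine
#' scheme for very large holes: the image is block-averaged down by
#' `factor`, inpainted at coarse scale, and the fill is bilinearly
#' upsampled into the hole.
#'
#' @param factor integer downsampling factor for the coarse pass.
#' @param base restorer used at the coarse scale.
#' @return A restorer function with signature `function(img, hole)`.
#' @name restorers
NULL

#' @rdname restorers
#' @export
restorer_biharmonic <- function() {
  function(img, hole) {
    img <- as_gray_image(img)
    if (!any(hole)) return(img)
    x <- unclass(img) * 1.0
    hidx <- which(hole, arr.ind = TRUE)
    r0 <- max(1L, min(hidx[, 1]) - 2L)
    r1 <- min(nrow(x), max(hidx[, 1]) + 2L)
    c0 <- max(1L, min(hidx[, 2]) - 2L)
    c1 <- min(ncol(x), max(hidx[, 2]) + 2L)
    sub <- x[r0:r1, c0:c1, drop = FALSE]
    hsub <- hole[r0:r1, c0:c1, drop = FALSE]
    h <- nrow(sub)
    w <- ncol(sub)
    n <- h * w
    idx <- seq_len(n)
    rs <- ((idx - 1L) %% h) + 1L
    cs <- ((idx - 1L) %/% h) + 1L
    ti <- tj <- integer(0)
    tv <- numeric(0)
    deg <- numeric(n)
    for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- rs + off[1]
      nc <- cs + off[2]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      deg[ok] <- deg[ok] + 1
      ti <- c(ti, idx[ok])
      tj <- c(tj, (nc[ok] - 1L) * h + nr[ok])
      tv <- c(tv, rep(-1, sum(ok)))
    }
    L <- Matrix::sparseMatrix(i = c(idx, ti), j = c(idx, tj),
                              x = c(deg, tv), dims = c(n, n))
    hv <- which(hsub)
    A <- L[, hv, drop = FALSE]
    B <- L[, -hv, drop = FALSE]
    rhs <- -(Matrix::t(A) %*% (B %*% sub[-hv]))
    sol <- as.numeric(Matrix::solve(Matrix::t(A) %*% A, rhs))
    sub[hv] <- sol
    x[r0:r1, c0:c1] <- sub
    out <- clip8(x)
    out[!hole] <- unclass(img)[!hole]
    gray_image(out)
  }
}

#' @rdname restorers
#' @export
restorer_diffusion <- function() {
  function(img, hole) {
    img <- as_gray_image(img)
    x <- unclass(img) * 1.0
    if (!any(hole)) return(img)
    h <- nrow(x)
    w <- ncol(x)
    idx <- which(hole)
    id <- matrix(0L, h, w)
    id[idx] <- seq_along(idx)
    n <- length(idx)
    rs <- ((idx - 1L) %% h) + 1L
    cs <- ((idx - 1L) %/% h) + 1L
    ti <- integer(0); tj <- integer(0); tv <- numeric(0)
    b <- numeric(n)
    deg <- numeric(n)
    for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- rs + off[1]
      nc <- cs + off[2]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      deg[ok] <- deg[ok] + 1
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      inhole <- id[nidx] > 0L
      ii <- which(ok)[inhole]
      ti <- c(ti, ii)
      tj <- c(tj, id[nidx[inhole]])
      tv <- c(tv, rep(-1, length(ii)))
      kk <- which(ok)[!inhole]
      b[kk] <- b[kk] + x[nidx[!inhole]]
    }
    A <- Matrix::sparseMatrix(i = c(seq_len(n), ti), j = c(seq_len(n), tj),
                              x = c(deg, tv), dims = c(n, n))
    sol <- as.numeric(Matrix::solve(A, b))
    x[idx] <- sol
    out <- gray_image(clip8(x))
    out[!hole] <- img[!hole] # rounding must not touch known pixels
    gray_image(unclass(out))
  }
}

#' @rdname restorers
#' @export
restorer_coarse_fine <- function(factor = 4L, base = restorer_diffusion()) {
  force(factor); force(base)
  function(img, hole) {
    img <- as_gray_image(img)
    if (!any(hole)) return(img)
    h <- nrow(img)
    w <- ncol(img)
    hc <- max(1L, h %/% factor)
    wc <- max(1L, w %/% factor)
    small <- clip8(as.matrix(EBImage::resize(EBImage::Image(unclass(img) / 255),
                                             w = hc, h = wc)) * 255)
    hole_small <- as.matrix(EBImage::resize(EBImage::Image(hole * 1.0),
                                            w = hc, h = wc)) > 0
    filled <- base(gray_image(small), hole_small)
    up <- as.matrix(EBImage::resize(EBImage::Image(unclass(filled) / 255),
                                    w = h, h = w)) * 255
    x <- unclass(img) * 1.0
    x[hole] <- up[hole]
    out <- clip8(x)
    out[!hole] <- unclass(img)[!hole]
    gray_image(out)
  }
}

#' Restore the defect background with a pluggable hole filler
#'
#' Replaces the core pixels by the restorer's output after validating the
#' restorer contract: congruent dimensions and bit-identical pixels outside
#' the hole.
#'
#' @param img a [gray_image].
#' @param core a [defect_core] (possibly empty, in which case the input is
#'   returned unchanged).
#' @param restorer a restorer function, see [restorers]; default
#'   [restorer_biharmonic()].
#' @return The background-restored [gray_image].
#' @export
restore_background <- function(img, core, restorer = restorer_biharmonic()) {
  img <- as_gray_image(img)
  if (core_is_empty(core)) return(img)
  hole <- core_raster(core, dim(img))
  out <- restorer(img, hole)
  if (!is.matrix(out) || !identical(dim(out)[1:2], dim(img)[1:2])) {
    stop("restorer contract violation: output shape differs from input")
  }
  out <- as_gray_image(out)
  if (!identical(unclass(out)[!hole], unclass(img)[!hole])) {
    stop("restorer contract violation: pixels outside the hole were modified")
  }
  for (a in c("breast_mask", "streak_truth", "background")) {
    if (!is.null(attr(img, a))) attr(out, a) <- attr(img, a)
  }
  out
}
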