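#' 3D image stack with physical voxel spacing
#'
#' @param voxels 3D numeric array of non-negative intensities
#'   (x, y, z order).
#' @param spacing per-axis physical voxel size in micrometres (length 3);
#'   confocal stacks are typically anisotropic (coarser in z).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive on all axes")
  if (any(!is.finite(voxels)) || any(voxels < 0)) {
    stop("intensities must be finite and non-negative")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Image stack %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' Read / write an image stack as multi-page TIFF with a spacing sidecar
#'
#' The stack is stored as one 2D page per z-plane; voxel spacing (absent
#' from plain TIFF tags) travels in a JSON sidecar `<file>.json`.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  v <- v / max(max(v), 1e-12)
  # tiff pages are row x col = y x x; store transposed planes
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(spacing_um = stack$spacing, scale = max(stack$voxels)),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  v <- vapply(pages, t, matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  sidecar <- paste0(path, ".json")
  spacing <- c(1, 1, 1)
  scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$spacing_um)) spacing <- as.numeric(meta$spacing_um)
    if (!is.null(meta$scale)) scale <- as.numeric(meta$scale)
  }
  image_stack(v * scale, spacing)
}

#' Preprocess a stack for segmentation
#'
#' Despeckles with a 3x3x3 median filter, subtracts a background level (a
#' low intensity quantile), smooths with an anisotropy-aware Gaussian
#' (sigma given in micrometres, converted to voxels per axis), and rescales
#' intensities to `[0, 1]`. A constant stack passes through unchanged
#' (rescaled), with a warning for the all-zero case.
#'
#' @param stack an [image_stack()].
#' @param smooth_um Gaussian smoothing SD in micrometres (default 1).
#' @param background_quantile intensity quantile subtracted as background
#'   (default 0.2).
#' @param despeckle apply the median filter first (default TRUE).
#' @return the preprocessed [image_stack()], intensities in `[0, 1]`.
#' @export
preprocess_stack <- function(stack, smooth_um = 1, background_quantile = 0.2,
                             despeckle = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  rng <- range(v)
  if (rng[2] == rng[1]) {
    if (rng[2] == 0) warning("all-zero stack: passing through")
    out <- array(if (rng[2] > 0) 1 else 0, d)
    return(image_stack(out, stack$spacing))
  }
  x <- as.numeric(v)
  if (despeckle) x <- .median_filter_3d(x, d)
  bg <- stats::quantile(x, background_quantile, names = FALSE)
  x <- pmax(x - bg, 0)
  if (smooth_um > 0) {
    x <- .gaussian_blur_3d(x, d, smooth_um / stack$spacing)
  }
  mx <- max(x)
  if (mx > 0) x <- x / mx
  image_stack(array(x, d), stack$spacing)
}

#' Watershed segmentation of fibres in a preprocessed stack
#'
#' Seeds are the connected plateaus of the superlevel set
#' `{intensity >= seed_threshold}` (the regions containing the local
#' intensity maxima; connected thresholding is robust where voxel noise
#' fragments strict maxima). Segments grow from the seeds by priority-flood
#' watershed over the foreground mask `{intensity >= fg_threshold}`, always
#' expanding through the brightest unassigned voxel, so boundaries between
#' touching fibres fall along their intensity valleys. Labels partition the
#' foreground; background is 0.
#'
#' @param stack a preprocessed [image_stack()] with intensities in `[0, 1]`.
#' @param seed_threshold relative intensity above which voxels seed a
#'   segment (default 0.5).
#' @param fg_threshold relative intensity above which voxels belong to the
#'   foreground (default 0.2).
#' @param connectivity voxel neighbourhood, 6 or 26 (default 26).
#' @return integer label array (same dimensions as the stack); attribute
#'   `"n_segments"` gives the segment count. Zero segments (with a warning)
#'   when no seeds are found.
#' @export
segment_watershed <- function(stack, seed_threshold = 0.5,
                              fg_threshold = 0.2, connectivity = 26L) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  x <- as.numeric(v)
  seeds_mask <- x >= seed_threshold
  if (!any(seeds_mask)) {
    warning("no seeds above seed_threshold: zero segments")
    out <- array(0L, d)
    attr(out, "n_segments") <- 0L
    return(out)
  }
  seeds <- .label_components_3d(seeds_mask, d, as.integer(connectivity))
  mask <- x >= fg_threshold
  labels <- .watershed_3d(x, seeds, mask, d, as.integer(connectivity))
  out <- array(labels, d)
  attr(out, "n_segments") <- length(unique(labels[labels > 0L]))
  out
}

#' Filter segments by voxel-count size
#'
#' Removes segments outside `[min_size, max_size]`; undersized segments are
#' typically incomplete fibre fragments, oversized ones merged multi-fibre
#' blobs.
#'
#' @param labels integer label array from [segment_watershed()].
#' @param min_size,max_size inclusive voxel-count bounds.
#' @return label array with out-of-bounds segments zeroed; attributes
#'   `"removed_small"` and `"removed_large"` count removals per bound.
#' @export
filter_by_size <- function(labels, min_size = 1L, max_size = Inf) {
  if (min_size > max_size) stop("min_size must not exceed max_size")
  d <- dim(labels)
  tab <- tabulate(labels[labels > 0L])
  small <- which(tab > 0 & tab < min_size)
  large <- which(tab > max_size)
  drop <- labels %in% c(small, large)
  labels[drop] <- 0L
  out <- array(as.integer(labels), d)
  attr(out, "removed_small") <- length(small)
  attr(out, "removed_large") <- length(large)
  attr(out, "n_segments") <- sum(tab >= min_size & tab <= max_size)
  out
}

#' Measure centroid, size and principal-axis orientation per segment
#'
#' For each labelled segment, computes the centroid (physical units), the
#' voxel count, the dominant principal direction of the (unweighted) voxel
#' coordinate cloud in micrometres, and the elongation (square root of the
#' ratio of the largest to the middle eigenvalue of the coordinate
#' covariance). The axis sign is canonicalized to a positive longitudinal
#' component (flipped posterior-positive downstream). Segments that cannot
#' carry an orientation (single voxel) or that do not look like single
#' fibres (elongation below `min_elongation`) are flagged.
#'
#' @param labels integer label array.
#' @param stack the [image_stack()] the labels came from (for spacing).
#' @param min_elongation flag threshold on elongation (default 2).
#' @return data.frame with columns `label`, `size`, `cx`, `cy`, `cz` (um),
#'   `ax`, `ay`, `az` (unit axis), `elongation`, `flagged`.
#' @export
measure_segments <- function(labels, stack, min_elongation = 2) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0) stop("no segments to measure")
  sp <- stack$spacing
  out <- vector("list", length(ids))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  # voxel -> physical coordinates (voxel centres)
  coord <- cbind(
    ((idx - 1L) %% d[1]) * sp[1],
    (((idx - 1L) %/% d[1]) %% d[2]) * sp[2],
    ((idx - 1L) %/% (d[1] * d[2])) * sp[3]
  )
  for (s in seq_along(ids)) {
    pts <- coord[lab == ids[s], , drop = FALSE]
    n <- nrow(pts)
    ctr <- colMeans(pts)
    if (n == 1L) {
      out[[s]] <- data.frame(
        label = ids[s], size = 1L, cx = ctr[1], cy = ctr[2], cz = ctr[3],
        ax = NA_real_, ay = NA_real_, az = NA_real_,
        elongation = NA_real_, flagged = TRUE
      )
      next
    }
    cv <- stats::cov(pts)
    eg <- eigen(cv, symmetric = TRUE)
    axis <- eg$vectors[, 1]
    if (axis[1] < 0) axis <- -axis
    ev <- pmax(eg$values, 0)
    elong <- if (ev[2] > 0) sqrt(ev[1] / ev[2]) else Inf
    out[[s]] <- data.frame(
      label = ids[s], size = n, cx = ctr[1], cy = ctr[2], cz = ctr[3],
      ax = axis[1], ay = axis[2], az = axis[3],
      elongation = elong, flagged = is.finite(elong) && elong < min_elongation
    )
  }
  do.call(rbind, out)
}
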