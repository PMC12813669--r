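#' Random non-overlapping fibre layout for rendering
#'
#' Places straight fibres (finite cylinders) with random posterior-pointing
#' orientations inside a voxel grid, rejecting placements that come closer
#' than `2 * radius_um + min_gap_um` to an accepted fibre.
#'
#' @param n number of fibres (default 20).
#' @param dim voxel grid dimensions (x, y, z).
#' @param spacing voxel spacing in micrometres.
#' @param length_um,radius_um cylinder geometry.
#' @param max_theta maximum angle to the x axis in degrees (default 40).
#' @param min_gap_um minimum surface gap between fibres (default 2).
#' @param seed optional seed.
#' @return data.frame with columns `cx`, `cy`, `cz` (centre, um), `ax`,
#'   `ay`, `az` (unit axis), `length_um`, `radius_um`.
#' @export
random_fibre_layout <- function(n = 20L, dim = c(96L, 72L, 48L),
                                spacing = c(1, 1, 2), length_um = 30,
                                radius_um = 2.5, max_theta = 40,
                                min_gap_um = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ext <- (dim - 1) * spacing
  margin <- length_um / 2 + radius_um + 1
  if (any(ext <= 2 * margin)) stop("grid too small for the fibre length")
  placed <- matrix(NA_real_, 0, 6)  # p1, p2 endpoints
  rows <- list()
  tries <- 0L
  while (nrow(placed) < n && tries < 20000L) {
    tries <- tries + 1L
    ctr <- stats::runif(3, margin, ext - margin)
    cth <- stats::runif(1, cos(max_theta / .DEG), 1)
    sth <- sqrt(1 - cth^2)
    az <- stats::runif(1, -pi, pi)
    a <- c(cth, sth * cos(az), sth * sin(az))
    p1 <- ctr - a * length_um / 2
    p2 <- ctr + a * length_um / 2
    ok <- TRUE
    if (nrow(placed) > 0) {
      for (r in seq_len(nrow(placed))) {
        dmin <- .segment_distance(p1, p2, placed[r, 1:3], placed[r, 4:6])
        if (dmin < 2 * radius_um + min_gap_um) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      placed <- rbind(placed, c(p1, p2))
      rows[[length(rows) + 1L]] <- data.frame(
        cx = ctr[1], cy = ctr[2], cz = ctr[3],
        ax = a[1], ay = a[2], az = a[3],
        length_um = length_um, radius_um = radius_um
      )
    }
  }
  if (length(rows) < n) {
    warning(sprintf("placed only %d of %d fibres", length(rows), n))
  }
  do.call(rbind, rows)
}

#' Render fibres into a synthetic image stack with ground truth
#'
#' Each fibre is rendered as a finite cylinder with a per-fibre random
#' plateau intensity (emulating the random expression-level variation that
#' makes individual fibres separable), then the stack gets a Gaussian blur
#' and additive Gaussian noise. A ground-truth label volume is returned
#' alongside; where cylinders overlap, the brighter fibre claims the voxel
#' and the overlap is flagged.
#'
#' @param geom fibre geometry as from [random_fibre_layout()]; an
#'   `intensity` column is honoured, otherwise plateaus are drawn uniform
#'   on `intensity_range`.
#' @param dim voxel grid dimensions (x, y, z).
#' @param spacing voxel spacing in micrometres.
#' @param intensity_range plateau range (default `c(0.5, 1)`).
#' @param blur_um Gaussian blur SD in micrometres (default 0.8).
#' @param noise_sd additive Gaussian noise SD (default 0.03).
#' @param background constant background level (default 0.02).
#' @param seed optional seed.
#' @return list with `stack` (an [image_stack()]), `truth` (integer label
#'   array, row index into `geom`), and `n_overlap_voxels`.
#' @export
render_stack <- function(geom, dim = c(96L, 72L, 48L), spacing = c(1, 1, 2),
                         intensity_range = c(0.5, 1), blur_um = 0.8,
                         noise_sd = 0.03, background = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(geom) >= 1)
  if (is.null(geom$intensity)) {
    geom$intensity <- stats::runif(nrow(geom), intensity_range[1],
                                   intensity_range[2])
  }
  vol <- array(0, dim)
  truth <- array(0L, dim)
  bright <- array(0, dim)
  n_overlap <- 0L
  ax_um <- list(
    (seq_len(dim[1]) - 1) * spacing[1],
    (seq_len(dim[2]) - 1) * spacing[2],
    (seq_len(dim[3]) - 1) * spacing[3]
  )
  for (f in seq_len(nrow(geom))) {
    ctr <- c(geom$cx[f], geom$cy[f], geom$cz[f])
    a <- c(geom$ax[f], geom$ay[f], geom$az[f])
    half <- geom$length_um[f] / 2
    r <- geom$radius_um[f]
    # bounding box of the capped cylinder
    lo <- ctr - abs(a) * half - r
    hi <- ctr + abs(a) * half + r
    ib <- lapply(1:3, function(d) {
      which(ax_um[[d]] >= lo[d] - spacing[d] & ax_um[[d]] <= hi[d] + spacing[d])
    })
    if (any(lengths(ib) == 0)) next
    g <- expand.grid(i = ib[[1]], j = ib[[2]], k = ib[[3]])
    px <- ax_um[[1]][g$i] - ctr[1]
    py <- ax_um[[2]][g$j] - ctr[2]
    pz <- ax_um[[3]][g$k] - ctr[3]
    t_ax <- px * a[1] + py * a[2] + pz * a[3]
    tc <- pmin(pmax(t_ax, -half), half)
    d2 <- (px - tc * a[1])^2 + (py - tc * a[2])^2 + (pz - tc * a[3])^2
    inside <- d2 <= r^2 & abs(t_ax) <= half + r
    if (!any(inside)) next
    lin <- g$i[inside] + dim[1] * (g$j[inside] - 1L) +
      dim[1] * dim[2] * (g$k[inside] - 1L)
    inten <- geom$intensity[f]
    taken <- truth[lin] != 0L
    n_overlap <- n_overlap + sum(taken)
    win <- !taken | bright[lin] < inten
    truth[lin[win]] <- f
    bright[lin[win]] <- inten
    vol[lin] <- pmax(vol[lin], inten)
  }
  if (n_overlap > 0) {
    warning(sprintf(
      "%d voxels shared by overlapping fibres (brighter fibre kept)",
      n_overlap
    ))
  }
  x <- as.numeric(vol) + background
  if (blur_um > 0) x <- .gaussian_blur_3d(x, dim, blur_um / spacing)
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  x <- pmax(x, 0)
  list(
    stack = image_stack(array(x, dim), spacing),
    truth = truth,
    n_overlap_voxels = n_overlap
  )
}
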