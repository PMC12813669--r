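#' Fit a smooth notochord centreline through ordered annotation points
#'
#' Fits a cubic (smoothing) spline to each raw coordinate against cumulative
#' chord length and resamples the curve at uniform arc-length steps. The
#' resulting centreline is the anatomical reference axis for the digitally
#' straightened coordinate system.
#'
#' @param annotated_points numeric matrix (n x 3) of ordered 3D points in
#'   raw image units (micrometres), running head to tail. At least 4 points.
#' @param smoothing smoothing parameter in `[0, 1]` passed to
#'   [stats::smooth.spline()] as `spar`; `0` (default) interpolates the
#'   annotations exactly with a natural cubic spline. The default keeps the
#'   residual to the annotations below one voxel for typical annotation
#'   densities.
#' @param n_out number of uniformly spaced arc-length samples in the result
#'   (default 512).
#'
#' @return An object of class `notochord_centreline`: a list with `points`
#'   (n_out x 3 matrix), `arc_length` (cumulative arc length per point, same
#'   units as the input), `total_length`, and internal spline accessors used
#'   by [straighten()].
#' @seealso [build_frames()], [straighten()]
#' @export
fit_centreline <- function(annotated_points, smoothing = 0, n_out = 512L) {
  pts <- as.matrix(annotated_points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("annotated_points must have 3 columns (x, y, z)")
  n <- nrow(pts)
  if (n < 4L) stop("at least 4 annotation points are required")
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen == 0)) stop("consecutive annotation points must not coincide")
  if (.polyline_self_intersects(pts, seglen)) {
    stop("annotation polyline self-intersects")
  }
  tt <- c(0, cumsum(seglen))
  polyline_length <- tt[n]

  fx <- .coord_spline(tt, pts[, 1], smoothing)
  fy <- .coord_spline(tt, pts[, 2], smoothing)
  fz <- .coord_spline(tt, pts[, 3], smoothing)

  # dense sampling for the arc-length reparameterization
  n_dense <- max(2000L, 50L * n)
  td <- seq(0, polyline_length, length.out = n_dense)
  dense <- cbind(fx$f(td), fy$f(td), fz$f(td))
  ds <- sqrt(rowSums(diff(dense)^2))
  sd_cum <- c(0, cumsum(ds))
  total <- sd_cum[n_dense]

  s_out <- seq(0, total, length.out = n_out)
  t_out <- stats::approx(sd_cum, td, xout = s_out, ties = "ordered")$y
  out <- cbind(fx$f(t_out), fy$f(t_out), fz$f(t_out))
  colnames(out) <- c("x", "y", "z")

  structure(
    list(
      points = out,
      arc_length = s_out,
      total_length = total,
      t_of_s = stats::approxfun(sd_cum, td),
      splines = list(x = fx, y = fy, z = fz),
      smoothing = smoothing
    ),
    class = "notochord_centreline"
  )
}

# cubic spline accessor for one coordinate: f(t) and derivative df(t)
.coord_spline <- function(tt, v, smoothing) {
  if (smoothing <= 0) {
    f <- stats::splinefun(tt, v, method = "natural")
    list(f = function(t) f(t), df = function(t) f(t, deriv = 1L))
  } else {
    ss <- stats::smooth.spline(tt, v, spar = smoothing)
    list(
      f = function(t) stats::predict(ss, t)$y,
      df = function(t) stats::predict(ss, t, deriv = 1L)$y
    )
  }
}

# coarse self-intersection check: non-adjacent segments of the annotation
# polyline must stay farther apart than a small fraction of its length
.polyline_self_intersects <- function(pts, seglen) {
  n <- nrow(pts) - 1L
  if (n < 3L) return(FALSE)
  tol <- 1e-6 * sum(seglen)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      d <- .segment_distance(
        pts[i, ], pts[i + 1L, ],
        pts[j, ], pts[j + 1L, ]
      )
      if (d < tol) return(TRUE)
    }
  }
  FALSE
}

# minimum distance between 3D segments [p1,p2] and [q1,q2]
.segment_distance <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * cc - b * b
  if (den > 1e-14 * a * cc) {
    s <- (b * e - cc * d) / den
    t <- (a * e - b * d) / den
  } else {  # near-parallel
    s <- 0; t <- if (cc > 0) e / cc else 0
  }
  s <- min(max(s, 0), 1)
  t <- min(max(t, 0), 1)
  # re-clamp each against the other
  t <- min(max((b * s + e) / max(cc, 1e-300), 0), 1)
  s <- min(max((b * t - d) / max(a, 1e-300), 0), 1)
  sqrt(sum((p1 + s * u - (q1 + t * v))^2))
}

#' @export
print.notochord_centreline <- function(x, ...) {
  cat("Notochord centreline\n")
  cat(sprintf("  samples:      %d (uniform arc-length steps)\n", nrow(x$points)))
  cat(sprintf("  total length: %.2f (raw units)\n", x$total_length))
  cat(sprintf("  smoothing:    %g\n", x$smoothing))
  invisible(x)
}

#' Build rotation-minimizing orthonormal frames along a centreline
#'
#' Transports an initial (dorsal, lateral) pair along the centreline with the
#' double-reflection rotation-minimizing-frame method, so the transverse frame
#' follows body curvature without introducing spurious twist. This realizes
#' the correction for embedding misalignment, body curvature and torsion.
#'
#' @param centreline a [fit_centreline()] result.
#' @param dorsal_hint 3D direction (raw coordinates) indicating dorsal at the
#'   anterior end; must not be parallel to the first tangent.
#'
#' @return An object of class `straightened_frame`: the centreline plus
#'   per-sample orthonormal triads `tangent`, `ydir` (dorsal), `zdir`
#'   (lateral, `zdir = tangent x ydir`, right-handed).
#' @export
build_frames <- function(centreline, dorsal_hint = c(0, 1, 0)) {
  stopifnot(inherits(centreline, "notochord_centreline"))
  P <- centreline$points
  n <- nrow(P)
  dP <- diff(P)
  steps <- sqrt(rowSums(dP^2))
  if (any(steps == 0)) stop("degenerate (zero-length) centreline step")

  # tangents from the analytic spline derivative at each arc-length sample
  tt <- centreline$t_of_s(centreline$arc_length)
  Tm <- cbind(
    centreline$splines$x$df(tt),
    centreline$splines$y$df(tt),
    centreline$splines$z$df(tt)
  )
  Tm <- Tm / sqrt(rowSums(Tm^2))

  h <- as.numeric(dorsal_hint)
  h <- h / sqrt(sum(h^2))
  y0 <- h - sum(h * Tm[1, ]) * Tm[1, ]
  ny0 <- sqrt(sum(y0^2))
  if (ny0 < 1e-9) stop("dorsal_hint is parallel to the first tangent")
  y0 <- y0 / ny0

  Y <- matrix(0, n, 3)
  Y[1, ] <- y0
  for (i in seq_len(n - 1L)) {
    # double-reflection step (Wang et al. rotation-minimizing frames)
    v1 <- P[i + 1L, ] - P[i, ]
    c1 <- sum(v1 * v1)
    yL <- Y[i, ] - (2 / c1) * sum(v1 * Y[i, ]) * v1
    tL <- Tm[i, ] - (2 / c1) * sum(v1 * Tm[i, ]) * v1
    v2 <- Tm[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    yN <- if (c2 < 1e-300) yL else yL - (2 / c2) * sum(v2 * yL) * v2
    # keep orthonormal against accumulated rounding
    yN <- yN - sum(yN * Tm[i + 1L, ]) * Tm[i + 1L, ]
    Y[i + 1L, ] <- yN / sqrt(sum(yN^2))
  }
  Z <- .cross3(Tm, Y)

  structure(
    list(centreline = centreline, tangent = Tm, ydir = Y, zdir = Z),
    class = "straightened_frame"
  )
}

.cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' @export
print.straightened_frame <- function(x, ...) {
  cat("Straightened notochord frame\n")
  print(x$centreline)
  cat(sprintf("  frames:       %d rotation-minimizing triads\n", nrow(x$tangent)))
  invisible(x)
}

#' Map raw 3D points into the straightened notochord coordinate system
#'
#' Orthogonally projects each raw point onto the centreline; `x` is the arc
#' length of the foot point, `y`/`z` the offsets along the local dorsal and
#' lateral frame directions. The transverse radial distance
#' `sqrt(y^2 + z^2)` equals the raw orthogonal distance to the centreline.
#'
#' @param points numeric matrix (n x 3) of raw coordinates, or a length-3
#'   vector for a single point.
#' @param frame a [build_frames()] result.
#'
#' @return data.frame with columns `x`, `y`, `z` (straightened coordinates,
#'   raw units) and `ambiguous` (logical; `TRUE` where the nearest-foot
#'   projection was not unique and the record should be excluded downstream).
#' @export
straighten <- function(points, frame) {
  stopifnot(inherits(frame, "straightened_frame"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  cl <- frame$centreline
  P <- cl$points
  n <- nrow(P)
  s_grid <- cl$arc_length
  out <- matrix(NA_real_, nrow(points), 3)
  amb <- logical(nrow(points))

  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    d2 <- (P[, 1] - p[1])^2 + (P[, 2] - p[2])^2 + (P[, 3] - p[3])^2
    i0 <- which.min(d2)
    # ambiguity: another near-minimal sample far away in arc length
    dmin <- sqrt(d2[i0])
    near <- which(sqrt(d2) <= dmin * (1 + 1e-3) + 1e-12)
    if (any(abs(s_grid[near] - s_grid[i0]) > 0.05 * cl$total_length)) {
      amb[k] <- TRUE
    }
    # refine the foot on the smooth curve around the nearest sample
    t_lo <- cl$t_of_s(s_grid[max(i0 - 1L, 1L)])
    t_hi <- cl$t_of_s(s_grid[min(i0 + 1L, n)])
    obj <- function(t) {
      sum((c(cl$splines$x$f(t), cl$splines$y$f(t), cl$splines$z$f(t)) - p)^2)
    }
    t_star <- if (t_hi > t_lo) {
      stats::optimize(obj, c(t_lo, t_hi), tol = 1e-12)$minimum
    } else {
      t_lo
    }
    foot <- c(
      cl$splines$x$f(t_star), cl$splines$y$f(t_star), cl$splines$z$f(t_star)
    )
    tri <- .frame_at(frame, t_star)
    r <- p - foot
    # remove any residual tangential component so radial distance is exact
    r_perp <- r - sum(r * tri$tangent) * tri$tangent
    s_star <- .arc_of_t(cl, t_star)
    out[k, ] <- c(
      s_star + sum(r * tri$tangent),
      sum(r_perp * tri$ydir),
      sum(r_perp * tri$zdir)
    )
  }
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3], ambiguous = amb)
}

# arc length at spline parameter t (inverse of t_of_s, by interpolation)
.arc_of_t <- function(cl, t_star) {
  tt <- cl$t_of_s(cl$arc_length)
  stats::approx(tt, cl$arc_length, xout = t_star, rule = 2, ties = "ordered")$y
}

# local orthonormal triad at spline parameter t: exact tangent from the
# spline derivative, dorsal/lateral interpolated from the transported frames
# and re-orthonormalized
.frame_at <- function(frame, t_star) {
  cl <- frame$centreline
  tg <- c(
    cl$splines$x$df(t_star), cl$splines$y$df(t_star), cl$splines$z$df(t_star)
  )
  tg <- tg / sqrt(sum(tg^2))
  s_star <- .arc_of_t(cl, t_star)
  i <- findInterval(s_star, cl$arc_length, all.inside = TRUE)
  w <- (s_star - cl$arc_length[i]) /
    (cl$arc_length[i + 1L] - cl$arc_length[i])
  y <- (1 - w) * frame$ydir[i, ] + w * frame$ydir[i + 1L, ]
  y <- y - sum(y * tg) * tg
  y <- y / sqrt(sum(y^2))
  z <- as.numeric(.cross3(tg, y))
  list(tangent = tg, ydir = y, zdir = z)
}

#' Local straightening triad at a given arc-length position
#'
#' @param frame a [build_frames()] result.
#' @param x arc-length position along the centreline (raw units).
#' @return list with unit vectors `tangent`, `ydir`, `zdir`.
#' @export
foot_frame <- function(frame, x) {
  stopifnot(inherits(frame, "straightened_frame"))
  .frame_at(frame, frame$centreline$t_of_s(x))
}

#' Express a raw direction vector in the straightened coordinate system
#'
#' Projects a raw 3D direction onto the local (tangent, dorsal, lateral)
#' triad at the fibre's foot point, normalizes it, and flips its sign where
#' needed so the longitudinal component points posteriorly (`v_x > 0`).
#'
#' @param raw_vector nonzero 3D direction in raw coordinates.
#' @param foot_frame local triad as returned by [foot_frame()].
#' @return named numeric vector `c(vx, vy, vz)` with unit norm and `vx > 0`;
#'   carries attribute `flagged = TRUE` if the vector is orthogonal to the
#'   tangent (posterior direction undefined).
#' @export
straighten_direction <- function(raw_vector, foot_frame) {
  v <- as.numeric(raw_vector)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("raw_vector must be nonzero")
  u <- c(
    sum(v * foot_frame$tangent),
    sum(v * foot_frame$ydir),
    sum(v * foot_frame$zdir)
  ) / nv
  flagged <- abs(u[1]) < 1e-9
  if (!flagged && u[1] < 0) u <- -u
  u <- u / sqrt(sum(u^2))
  names(u) <- c("vx", "vy", "vz")
  if (flagged) attr(u, "flagged") <- TRUE
  u
}
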