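.DEG <- 180 / pi

#' Fibre orientation angles from a unit direction vector
#'
#' Computes, in degrees, the frontal projection angle (azimuth)
#' `alpha = arctan(vz/vx)`, the sagittal projection angle
#' `phi = arctan(vy/vx)`, the elevation `beta = arcsin(vy)`, and the angle to
#' the straightened notochord axis
#' `theta = arctan(sqrt(vz^2 + vy^2)/vx)`, with `theta >= 0`. Signs follow
#' the anatomical convention: `alpha > 0` for laterally pointing fibres
#' (`vz > 0`), `phi > 0` for dorsally pointing fibres (`vy > 0`).
#'
#' @param v unit direction vector `c(vx, vy, vz)` with `vx > 0`
#'   (posterior-pointing), or an n x 3 matrix of such vectors.
#' @return data.frame with columns `alpha`, `phi`, `beta`, `theta` (degrees).
#' @export
compute_angles <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- as.matrix(v)
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("v must be a unit vector (||v|| = 1)")
  if (any(v[, 1] <= 0)) stop("v must point posteriorly (vx > 0)")
  data.frame(
    alpha = atan(v[, 3] / v[, 1]) * .DEG,
    phi   = atan(v[, 2] / v[, 1]) * .DEG,
    beta  = asin(pmin(pmax(v[, 2], -1), 1)) * .DEG,
    theta = atan(sqrt(v[, 3]^2 + v[, 2]^2) / v[, 1]) * .DEG
  )
}

#' Reconstruct the unit direction vector from projection angles
#'
#' The pair (alpha, phi) fully defines a posterior-pointing orientation:
#' `v` is proportional to `(1, tan(phi), tan(alpha))`, normalized.
#'
#' @param alpha,phi projection angles in degrees.
#' @return n x 3 matrix with columns `vx`, `vy`, `vz`.
#' @export
vector_from_angles <- function(alpha, phi) {
  ta <- tan(alpha / .DEG)
  tp <- tan(phi / .DEG)
  v <- cbind(vx = 1, vy = tp, vz = ta)
  v / sqrt(rowSums(v^2))
}

#' Mirror left-side fibre records to the right side
#'
#' Under the bilateral-symmetry assumption, records with `z < 0` are
#' reflected across the median plane: `z`, `vz` and `alpha` change sign and
#' `side` becomes `"right"`; `phi`, `beta` and `theta` are unchanged.
#' Records already on the right pass through; the operation is idempotent.
#'
#' @param fibres fibre table (data.frame) with at least columns `z`, `vz`,
#'   `alpha`; columns `side` updated if present.
#' @return the mirrored fibre table.
#' @export
mirror_to_right <- function(fibres) {
  left <- fibres$z < 0
  fibres$z[left] <- -fibres$z[left]
  if (!is.null(fibres$vz)) fibres$vz[left] <- -fibres$vz[left]
  if (!is.null(fibres$alpha)) fibres$alpha[left] <- -fibres$alpha[left]
  if (!is.null(fibres$side)) fibres$side[left] <- "right"
  fibres
}

#' Normalize a longitudinal coordinate to the axial-muscle span
#'
#' Linear map taking the anterior-most fluorescent muscle position to 0 and
#' the posterior-most to 1.
#'
#' @param x arc-length coordinate(s).
#' @param x_anterior,x_posterior anterior- and posterior-most extents;
#'   `x_posterior > x_anterior` required.
#' @return normalized coordinate(s).
#' @export
normalize_x <- function(x, x_anterior, x_posterior) {
  span <- x_posterior - x_anterior
  if (!is.finite(span) || span <= 0) {
    stop("x_posterior must exceed x_anterior")
  }
  (x - x_anterior) / span
}

#' Axial muscle length along the straightened axis
#'
#' Distance between the anterior- and posterior-most axial muscle tissue,
#' used as the length proxy for developmental stage.
#'
#' @param x longitudinal coordinates of muscle tissue (fibre centroids or
#'   mask extents), in micrometres.
#' @return length in the same units; warns on a degenerate single-point
#'   input (length 0).
#' @export
axial_muscle_length <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no muscle coordinates supplied")
  len <- max(x) - min(x)
  if (len == 0) warning("degenerate extent: single longitudinal position")
  len
}

#' Remove implausible fibre orientations
#'
#' Fibres are deemed segmentation outliers, unlikely to represent single
#' fibres, if `|alpha|`, `|beta|` or `theta` exceeds the limit (strictly);
#' records exactly at the limit are kept.
#'
#' @param fibres fibre table with columns `alpha`, `beta`, `theta` (degrees).
#' @param limit angular limit in degrees (default 45).
#' @return list with elements `kept`, `removed` (fibre tables) and `counts`
#'   (named removals per criterion; a record can trip several).
#' @export
filter_outliers <- function(fibres, limit = 45) {
  bad_alpha <- abs(fibres$alpha) > limit
  bad_beta <- abs(fibres$beta) > limit
  bad_theta <- fibres$theta > limit
  bad <- bad_alpha | bad_beta | bad_theta
  list(
    kept = fibres[!bad, , drop = FALSE],
    removed = fibres[bad, , drop = FALSE],
    counts = c(
      alpha = sum(bad_alpha),
      beta = sum(bad_beta),
      theta = sum(bad_theta),
      total = sum(bad)
    )
  )
}

#' Assign fibres to the epaxial or hypaxial compartment
#'
#' The horizontal septum is taken at `y = septum_y` in the straightened
#' frame (default 0, the notochord centre): dorsal fibres (`y > septum_y`)
#' are epaxial, ventral fibres hypaxial.
#'
#' @param fibres fibre table with column `y`.
#' @param septum_y dorsoventral position of the horizontal septum.
#' @return the fibre table with a `compartment` column.
#' @export
assign_compartment <- function(fibres, septum_y = 0) {
  fibres$compartment <- ifelse(fibres$y > septum_y, "epaxial", "hypaxial")
  fibres
}
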