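#' Per-fibre angular residuals from a fitted helix model
#'
#' Computes `dalpha = alpha - alpha_m` and `dphi = phi - phi_m` for each
#' fibre at its own position, together with its radial coordinates
#' (`R`, `zeta`) about the fitted centre at the fibre's longitudinal
#' position. Fibres at the fitted centre (`R ~ 0`) have undefined `zeta`;
#' they are excluded from direction-indexed curves but kept in scalar
#' summaries.
#'
#' @param fibres fibre table with columns `x_norm`, `y`, `z`, `alpha`,
#'   `phi`, and optionally `fish_id`, `compartment`.
#' @param fit a [fit_helix()] result (or [helix_params()] for known truth).
#' @return data.frame of class `residual_profile` with columns `x_norm`,
#'   `R`, `zeta` (degrees), `dalpha`, `dphi` plus any grouping columns
#'   present in the input.
#' @export
helix_residuals <- function(fibres, fit) {
  params <- if (inherits(fit, "helix_fit")) fit$params else fit
  stopifnot(inherits(params, "helix_params"))
  pred <- predict_angles(fibres$y, fibres$z, fibres$x_norm, params)
  rc <- radial_coords(
    fibres$y, fibres$z,
    .polyval(params$yc, fibres$x_norm),
    .polyval(params$zc, fibres$x_norm)
  )
  out <- data.frame(
    x_norm = fibres$x_norm,
    R = rc$R,
    zeta = rc$zeta,
    dalpha = fibres$alpha - pred$alpha_m,
    dphi = fibres$phi - pred$phi_m
  )
  for (col in c("fish_id", "compartment", "side")) {
    if (!is.null(fibres[[col]])) out[[col]] <- fibres[[col]]
  }
  class(out) <- c("residual_profile", "data.frame")
  out
}

#' @rdname helix_residuals
#' @param object a [fit_helix()] result.
#' @param ... unused.
#' @export
residuals.helix_fit <- function(object, ...) {
  helix_residuals(object$data, object)
}

#' Circular moving average of values indexed by an angle
#'
#' At each query angle, averages all values whose angular coordinate lies
#' within half a window of it, with wrap-around at +/-180 degrees and
#' inclusive window endpoints. Query angles whose window holds no data give
#' `NA` (gaps are not interpolated). The curve is 360-degree periodic; it
#' commutes with adding a constant and never amplifies a sinusoid (for a
#' 90-degree window the gain on `sin(zeta)` is `sin(45 deg)/(pi/4) ~ 0.9003`).
#'
#' @param zeta angular coordinates in degrees.
#' @param values values to average (same length).
#' @param window full window width in degrees, in `(0, 360]` (default 90,
#'   i.e. +/-45 around each query angle).
#' @param grid query angles in degrees (default 1-degree steps over
#'   `(-180, 180]`).
#' @return data.frame with `zeta` (query angle), `avg` and `n` (points in
#'   the window).
#' @export
circular_moving_average <- function(zeta, values, window = 90,
                                    grid = seq(-179, 180, by = 1)) {
  if (!(window > 0 && window <= 360)) stop("window must be in (0, 360]")
  ok <- is.finite(zeta) & is.finite(values)
  zeta <- zeta[ok]
  values <- values[ok]
  if (length(zeta) == 0) stop("no finite (zeta, value) pairs")
  half <- window / 2
  # circular distance |zeta - q| on the wheel
  d <- abs(outer(zeta, grid, `-`)) %% 360
  d <- pmin(d, 360 - d)
  inwin <- d <= half + 1e-9
  n <- colSums(inwin)
  avg <- colSums(inwin * values) / n
  avg[n == 0] <- NA_real_
  data.frame(zeta = grid, avg = avg, n = n)
}

#' Mean absolute residuals per group with normal-approximation CIs
#'
#' Summarizes the magnitude of helix-fit errors per fish, compartment and
#' projection angle: the mean of `|residual|` with a 95% confidence
#' interval `mean +/- 1.96 * SD / sqrt(n)` across fibres. Groups with fewer
#' than two fibres get the mean only (CI flagged unavailable as `NA`).
#'
#' @param profile a [helix_residuals()] result (or any data.frame with
#'   `dalpha`, `dphi` and the grouping columns).
#' @param by character vector of grouping columns present in `profile`
#'   (default those of `fish_id`, `compartment` that exist).
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per group x angle: grouping columns,
#'   `angle` (`"alpha"` or `"phi"`), `n`, `mean_abs`, `sd_abs`, `ci_lo`,
#'   `ci_hi`.
#' @export
mean_absolute_residuals <- function(profile, by = NULL, level = 0.95) {
  if (is.null(by)) by <- intersect(c("fish_id", "compartment"), names(profile))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  long <- rbind(
    data.frame(profile[by], angle = "alpha", value = abs(profile$dalpha)),
    data.frame(profile[by], angle = "phi", value = abs(profile$dphi))
  )
  agg <- stats::aggregate(
    long$value, by = as.list(long[c(by, "angle")]),
    FUN = function(v) c(n = length(v), m = mean(v), s = stats::sd(v))
  )
  stats_m <- agg$x
  agg$x <- NULL
  agg$n <- stats_m[, "n"]
  agg$mean_abs <- stats_m[, "m"]
  agg$sd_abs <- stats_m[, "s"]
  se <- agg$sd_abs / sqrt(agg$n)
  agg$ci_lo <- ifelse(agg$n >= 2, agg$mean_abs - zq * se, NA_real_)
  agg$ci_hi <- ifelse(agg$n >= 2, agg$mean_abs + zq * se, NA_real_)
  agg[order(agg$angle), , drop = FALSE]
}

#' Polar residual diagnostics for a helix fit
#'
#' Plots per-fibre residuals against the direction `zeta` around the fitted
#' helix centre, with the circular moving-average curve, for both
#' projection angles. Systematic direction-related structure (e.g. the
#' two-lobed pattern of an elliptical cross-section) shows up as departures
#' of the curve from zero.
#'
#' @param x a [helix_residuals()] result.
#' @param window moving-average window in degrees (default 90).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a list with the two moving-average curves.
#' @export
plot.residual_profile <- function(x, window = 90, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  curves <- list()
  for (ang in c("dalpha", "dphi")) {
    ma <- circular_moving_average(x$zeta, x[[ang]], window = window)
    curves[[ang]] <- ma
    graphics::plot(
      x$zeta, x[[ang]], pch = 16, cex = 0.3, col = "grey60",
      xlab = expression(zeta ~ "(deg)"),
      ylab = sprintf("%s residual (deg)",
                     if (ang == "dalpha") "frontal" else "sagittal"),
      main = if (ang == "dalpha") expression(Delta * alpha)
             else expression(Delta * phi),
      ...
    )
    graphics::abline(h = 0, col = "orange", lwd = 2)
    graphics::lines(ma$zeta, ma$avg, col = "blue", lwd = 2)
  }
  invisible(curves)
}
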