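#' Evaluate a fitted helix model along the body with confidence bands
#'
#' Evaluates the centre polynomials and slope on a grid of normalized
#' longitudinal positions and propagates coefficient uncertainty through the
#' polynomial evaluation: `var(y_c(x)) = m(x)' Cov m(x)` with `m(x)` the
#' monomial vector, and likewise for `z_c` and `c`. The pitch confidence
#' interval uses a first-order delta method through `2*pi / |c|`. Bands are
#' `estimate +/- z * SE` at the requested level.
#'
#' @param fit a [fit_helix()] result.
#' @param x_norm evaluation grid on `[0, 1]` (default 101 points).
#' @param level confidence level (default 0.95).
#' @return data.frame of class `helix_evaluation` with columns `x_norm`,
#'   `y_c`, `y_c_se`, `y_c_lo`, `y_c_hi`, the same for `z_c`, `slope` and
#'   its SE, `pitch`, `pitch_se`, `pitch_lo`, `pitch_hi`, `chirality`, and
#'   `pitch_unbounded` (TRUE where the slope is not distinguishable from 0
#'   at the requested level, so the pitch CI is unbounded; `pitch_lo`/`hi`
#'   are NA there).
#' @export
evaluate_fit <- function(fit, x_norm = seq(0, 1, length.out = 101),
                         level = 0.95) {
  stopifnot(inherits(fit, "helix_fit"))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ords <- fit$orders
  iy <- seq_len(ords[1] + 1)
  iz <- max(iy) + seq_len(ords[2] + 1)
  ic <- max(iz) + seq_len(ords[3] + 1)

  My <- .monomials(x_norm, ords[1])
  Mz <- .monomials(x_norm, ords[2])
  Mc <- .monomials(x_norm, ords[3])

  yc <- drop(My %*% fit$params$yc)
  zc <- drop(Mz %*% fit$params$zc)
  cx <- drop(Mc %*% fit$params$c)

  vband <- function(M, V) pmax(rowSums((M %*% V) * M), 0)
  yc_se <- sqrt(vband(My, fit$vcov[iy, iy, drop = FALSE]))
  zc_se <- sqrt(vband(Mz, fit$vcov[iz, iz, drop = FALSE]))
  c_se <- sqrt(vband(Mc, fit$vcov[ic, ic, drop = FALSE]))

  pitch <- 2 * pi / abs(cx)
  # delta method: d pitch / d c = -2*pi * sign(c) / c^2
  pitch_se <- 2 * pi * c_se / cx^2
  unbounded <- abs(cx) <= zq * c_se | abs(cx) < 1e-8
  pitch_lo <- ifelse(unbounded, NA_real_, pitch - zq * pitch_se)
  pitch_hi <- ifelse(unbounded, NA_real_, pitch + zq * pitch_se)

  out <- data.frame(
    x_norm = x_norm,
    y_c = yc, y_c_se = yc_se,
    y_c_lo = yc - zq * yc_se, y_c_hi = yc + zq * yc_se,
    z_c = zc, z_c_se = zc_se,
    z_c_lo = zc - zq * zc_se, z_c_hi = zc + zq * zc_se,
    slope = cx, slope_se = c_se,
    pitch = pitch, pitch_se = pitch_se,
    pitch_lo = pitch_lo, pitch_hi = pitch_hi,
    chirality = sign(cx),
    pitch_unbounded = unbounded
  )
  class(out) <- c("helix_evaluation", "data.frame")
  attr(out, "level") <- level
  out
}

#' Confidence intervals for helix centre and pitch at given positions
#'
#' Thin wrapper around [evaluate_fit()] in the shape [stats::confint()]
#' users expect.
#'
#' @param object a [fit_helix()] result.
#' @param parm positions `x_norm` at which to report (default
#'   `c(0.3, 0.5, 0.7)`).
#' @param level confidence level.
#' @param ... unused.
#' @return data.frame with one row per position and parameter.
#' @export
confint.helix_fit <- function(object, parm = c(0.3, 0.5, 0.7),
                              level = 0.95, ...) {
  ev <- evaluate_fit(object, x_norm = parm, level = level)
  data.frame(
    x_norm = rep(ev$x_norm, 3L),
    parameter = rep(c("y_c", "z_c", "pitch"), each = nrow(ev)),
    estimate = c(ev$y_c, ev$z_c, ev$pitch),
    lower = c(ev$y_c_lo, ev$z_c_lo, ev$pitch_lo),
    upper = c(ev$y_c_hi, ev$z_c_hi, ev$pitch_hi)
  )
}

#' Plot a fitted helix model
#'
#' Two-panel base-graphics display: the transverse fibre field with measured
#' and model-predicted orientation vectors in a chosen longitudinal window,
#' and the pitch profile with its confidence band along the body.
#'
#' @param x a [fit_helix()] result.
#' @param window longitudinal window (normalized) for the vector panel.
#' @param arrow_scale length scale for orientation arrows.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the [evaluate_fit()] grid used for the pitch panel.
#' @export
plot.helix_fit <- function(x, window = c(0.4, 0.8), arrow_scale = 0.05, ...) {
  d <- x$data
  sel <- d$x_norm >= window[1] & d$x_norm <= window[2]
  d <- d[sel, , drop = FALSE]
  pred <- predict(x, d)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))

  graphics::plot(
    d$z, d$y, asp = 1, pch = 16, cex = 0.4, col = "grey40",
    xlab = "z (lateral, normalized)", ylab = "y (dorsal, normalized)",
    main = sprintf("fibre field, x in [%.2f, %.2f]", window[1], window[2]),
    ...
  )
  ta <- tan(d$alpha / .DEG)
  tp <- tan(d$phi / .DEG)
  graphics::arrows(d$z, d$y, d$z + arrow_scale * ta, d$y + arrow_scale * tp,
                   length = 0.02, col = "black")
  tam <- tan(pred$alpha_m / .DEG)
  tpm <- tan(pred$phi_m / .DEG)
  graphics::arrows(d$z, d$y, d$z + arrow_scale * tam, d$y + arrow_scale * tpm,
                   length = 0.02, col = "forestgreen")
  mid <- evaluate_fit(x, mean(window))
  graphics::points(mid$z_c, mid$y_c, pch = 3, cex = 2, col = "red")

  ev <- evaluate_fit(x)
  ok <- !ev$pitch_unbounded
  graphics::plot(
    ev$x_norm, ev$pitch, type = "n",
    ylim = range(c(ev$pitch_lo[ok], ev$pitch_hi[ok], ev$pitch[ok]),
                 finite = TRUE),
    xlab = "normalized x", ylab = "pitch (body lengths / turn)",
    main = "helix pitch"
  )
  graphics::polygon(
    c(ev$x_norm[ok], rev(ev$x_norm[ok])),
    c(ev$pitch_lo[ok], rev(ev$pitch_hi[ok])),
    col = grDevices::adjustcolor("steelblue", 0.3), border = NA
  )
  graphics::lines(ev$x_norm, ev$pitch, col = "steelblue", lwd = 2)
  invisible(ev)
}
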