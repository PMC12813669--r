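# evaluate a polynomial with ascending-power coefficients at x
.polyval <- function(coeffs, x) {
  r <- 0
  for (k in rev(coeffs)) r <- r * x + k
  r
}

# monomial design matrix 1, x, x^2, ... up to the given order
.monomials <- function(x, order) {
  outer(x, 0:order, `^`)
}

#' Helix model parameters
#'
#' Container for the concentric circular-helix model: the transverse helix
#' centre coordinates vary along the body as 4th-order polynomials of the
#' normalized longitudinal position, and the slope `c` (the proportionality
#' between the tangent of a projection angle and the displacement from the
#' centre; `|c| = 2*pi / pitch`) as a 3rd-order polynomial.
#'
#' @param yc,zc polynomial coefficients (ascending powers) of the
#'   dorsoventral and mediolateral centre coordinates `y_c(x)`, `z_c(x)`,
#'   in normalized units.
#' @param c_ polynomial coefficients of the slope `c(x)`, units of
#'   1 / normalized length; its sign encodes chirality.
#' @param compartment optional `"epaxial"` or `"hypaxial"` label.
#' @return object of class `helix_params`.
#' @export
helix_params <- function(yc, zc, c_, compartment = NULL) {
  structure(
    list(
      yc = as.numeric(yc), zc = as.numeric(zc), c = as.numeric(c_),
      compartment = compartment
    ),
    class = "helix_params"
  )
}

#' Radial coordinates of a fibre about the helix centre
#'
#' @param y,z transverse fibre coordinates (normalized units).
#' @param y_c,z_c helix centre at the fibre's longitudinal position.
#' @return data.frame with `R` (radial distance) and `zeta` (angle around
#'   the cross-sectional circle, degrees in (-180, 180], `zeta = 0` at the
#'   dorsal direction from the centre, `zeta = 90` lateral). `zeta` is `NA`
#'   (undefined) where `R = 0`.
#' @export
radial_coords <- function(y, z, y_c, z_c) {
  dy <- y - y_c
  dz <- z - z_c
  R <- sqrt(dy^2 + dz^2)
  zeta <- atan2(dz, dy) * .DEG
  zeta[R == 0] <- NA_real_
  data.frame(R = R, zeta = zeta)
}

#' Model-predicted projection angles at given fibre positions
#'
#' For a fibre at transverse position `(y, z)` and normalized longitudinal
#' position `x_norm`, the concentric-helix model with constant pitch across
#' radii predicts `tan(alpha_m) = -c(x) * (y - y_c(x))` and
#' `tan(phi_m) = c(x) * (z - z_c(x))`.
#'
#' @param y,z transverse coordinates (normalized units).
#' @param x_norm normalized longitudinal positions.
#' @param params a [helix_params()] object.
#' @return data.frame with `alpha_m`, `phi_m` in degrees.
#' @export
predict_angles <- function(y, z, x_norm, params) {
  stopifnot(inherits(params, "helix_params"))
  ycx <- .polyval(params$yc, x_norm)
  zcx <- .polyval(params$zc, x_norm)
  cx <- .polyval(params$c, x_norm)
  data.frame(
    alpha_m = atan(-cx * (y - ycx)) * .DEG,
    phi_m = atan(cx * (z - zcx)) * .DEG
  )
}

#' Helix pitch from the slope parameter
#'
#' The pitch is the normalized body length advanced per full helix turn:
#' `pitch = 2*pi / |c|`. Chirality is reported separately as the sign of
#' `c`. A zero slope (longitudinal fibres) gives infinite pitch.
#'
#' @param c_ slope value(s), units 1 / normalized length.
#' @return numeric vector of pitches with attribute `chirality`
#'   (`sign(c_)`); `Inf` where `c_ = 0` (flagged by a warning).
#' @export
pitch_from_slope <- function(c_) {
  if (any(c_ == 0)) {
    warning("zero slope: longitudinal fibres, pitch is infinite")
  }
  p <- 2 * pi / abs(c_)
  attr(p, "chirality") <- sign(c_)
  p
}

#' Completed helix turns over a longitudinal span
#'
#' Integrates the local turn rate `|c(x)| / (2*pi)` over the span; with a
#' constant pitch `p` over a unit span this equals `1/p` (e.g. pitch 0.25
#' means four turns are completed within the axial muscles).
#'
#' @param object a [helix_params()] object or a fitted [fit_helix()] model.
#' @param span normalized interval to integrate over (default `c(0, 1)`).
#' @return number of completed turns.
#' @export
completed_turns <- function(object, span = c(0, 1)) {
  params <- if (inherits(object, "helix_fit")) object$params else object
  stopifnot(inherits(params, "helix_params"))
  stats::integrate(
    function(x) abs(.polyval(params$c, x)) / (2 * pi),
    span[1], span[2], rel.tol = 1e-10
  )$value
}

# residual function and analytic Jacobian for the stacked
# (alpha, phi) degree-scale least-squares problem
.helix_resid_fn <- function(y, z, x, alpha, phi, orders) {
  iy <- seq_len(orders[1] + 1)
  iz <- max(iy) + seq_len(orders[2] + 1)
  ic <- max(iz) + seq_len(orders[3] + 1)
  function(p) {
    ycx <- .polyval(p[iy], x)
    zcx <- .polyval(p[iz], x)
    cx <- .polyval(p[ic], x)
    c(
      alpha - atan(-cx * (y - ycx)) * .DEG,
      phi - atan(cx * (z - zcx)) * .DEG
    )
  }
}

.helix_jac_fn <- function(y, z, x, alpha, phi, orders) {
  My <- .monomials(x, orders[1])
  Mz <- .monomials(x, orders[2])
  Mc <- .monomials(x, orders[3])
  Zy <- matrix(0, length(x), ncol(My))
  Zz <- matrix(0, length(x), ncol(Mz))
  iy <- seq_len(orders[1] + 1)
  iz <- max(iy) + seq_len(orders[2] + 1)
  ic <- max(iz) + seq_len(orders[3] + 1)
  function(p) {
    ycx <- .polyval(p[iy], x)
    zcx <- .polyval(p[iz], x)
    cx <- .polyval(p[ic], x)
    a <- -cx * (y - ycx)
    b <- cx * (z - zcx)
    da <- .DEG / (1 + a^2)
    db <- .DEG / (1 + b^2)
    # residual = observed - model, so the Jacobian is -d(model)/dp
    rbind(
      cbind(-da * cx * My, Zz, da * (y - ycx) * Mc),
      cbind(Zy, db * cx * Mz, -db * (z - zcx) * Mc)
    )
  }
}

#' Fit the concentric circular-helix model to a fibre field
#'
#' Minimizes the summed squared angular residual
#' `sum((alpha - alpha_m)^2 + (phi - phi_m)^2)` (degrees) over the
#' polynomial coefficients of the helix centre `y_c(x)`, `z_c(x)` and slope
#' `c(x)` by Levenberg-Marquardt nonlinear least squares with an analytic
#' Jacobian. The model is fitted per compartment on the full fibre set of
#' one fish, using right-side (mirrored) data.
#'
#' @param fibres fibre table with columns `x_norm` (in `[0, 1]`), `y`, `z`
#'   (normalized transverse coordinates), `alpha`, `phi` (degrees), and
#'   optionally `compartment`.
#' @param compartment if given, subset `fibres` to this compartment
#'   (`"epaxial"` or `"hypaxial"`).
#' @param init optional [helix_params()] starting values. By default the
#'   centre constants start at the compartment centroid and the slope
#'   constant at the sign-aware least-squares slope of `tan(alpha)` against
#'   `-(y - y_c)` over the middle third of the body.
#' @param orders polynomial orders for `(y_c, z_c, c)`; default `c(4, 4, 3)`
#'   giving 14 coefficients.
#' @param control a [minpack.lm::nls.lm.control()] list; defaults to
#'   `ftol = 1e-10`, at most 10000 function evaluations.
#'
#' @return object of class `helix_fit`: a list with `params`
#'   ([helix_params()]), `coefficients`, `vcov` (Gauss-Newton covariance of
#'   the coefficients, scaled by the residual variance), `sigma` (residual
#'   SD, degrees), `sse` (summed squared angular residual, deg^2),
#'   `n_fibres`, `df_residual`, `orders`, `compartment`, `converged`,
#'   `ill_defined` (TRUE when the design is rank deficient, e.g. for an
#'   all-longitudinal field where the helix centre is unidentifiable), and
#'   the fitted `data`.
#' @seealso [evaluate_fit()], [residuals.helix_fit()], [standardized_pitch()]
#' @export
fit_helix <- function(fibres, compartment = NULL, init = NULL,
                      orders = c(4, 4, 3), control = NULL) {
  if (!is.null(compartment) && !is.null(fibres$compartment)) {
    fibres <- fibres[fibres$compartment == compartment, , drop = FALSE]
  } else if (!is.null(fibres$compartment) && is.null(compartment)) {
    u <- unique(fibres$compartment)
    if (length(u) > 1) {
      stop("fibres span several compartments; pass `compartment`")
    }
    compartment <- u
  }
  req <- c("x_norm", "y", "z", "alpha", "phi")
  miss <- setdiff(req, names(fibres))
  if (length(miss)) stop("missing fibre columns: ", paste(miss, collapse = ", "))
  npar <- sum(orders) + 3L
  n <- nrow(fibres)
  if (n < npar) {
    stop(sprintf("need at least %d fibres to fit %d coefficients", npar, npar))
  }
  if (any(fibres$x_norm < -1e-9 | fibres$x_norm > 1 + 1e-9)) {
    stop("x_norm must lie in [0, 1]")
  }

  x <- fibres$x_norm
  y <- fibres$y
  z <- fibres$z
  alpha <- fibres$alpha
  phi <- fibres$phi

  p0 <- .helix_init(x, y, z, alpha, init, orders)
  fn <- .helix_resid_fn(y, z, x, alpha, phi, orders)
  jac <- .helix_jac_fn(y, z, x, alpha, phi, orders)
  ctrl <- do.call(
    minpack.lm::nls.lm.control,
    if (is.null(control)) list(ftol = 1e-10, maxfev = 10000, maxiter = 1000)
    else control
  )
  fit <- minpack.lm::nls.lm(par = p0, fn = fn, jac = jac, control = ctrl)
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning(sprintf(
      "helix fit did not converge (info = %d: %s)", fit$info, fit$message
    ))
  }

  p <- fit$par
  iy <- seq_len(orders[1] + 1)
  iz <- max(iy) + seq_len(orders[2] + 1)
  ic <- max(iz) + seq_len(orders[3] + 1)
  names(p) <- c(
    paste0("yc_", 0:orders[1]),
    paste0("zc_", 0:orders[2]),
    paste0("c_", 0:orders[3])
  )

  sse <- fit$deviance
  dfres <- 2L * n - npar
  sigma2 <- sse / dfres
  J <- jac(fit$par)
  JtJ <- crossprod(J)
  rank <- qr(J)$rank
  ill <- rank < npar
  vc <- tryCatch(
    sigma2 * solve(JtJ),
    error = function(e) {
      ill <<- TRUE
      sigma2 * MASS::ginv(JtJ)
    }
  )
  dimnames(vc) <- list(names(p), names(p))
  if (ill) {
    warning(
      "rank-deficient design: helix centre/slope ill-defined ",
      "(e.g. near-longitudinal fibre field); covariance from pseudo-inverse"
    )
  }

  structure(
    list(
      params = helix_params(p[iy], p[iz], p[ic], compartment),
      coefficients = p,
      vcov = vc,
      sigma = sqrt(sigma2),
      sse = sse,
      n_fibres = n,
      df_residual = dfres,
      orders = orders,
      compartment = compartment,
      converged = converged,
      ill_defined = ill,
      niter = fit$niter,
      data = fibres[, req],
      call = match.call()
    ),
    class = "helix_fit"
  )
}

# starting values: centre constants at the fibre centroid, slope constant
# from the pooled tan(alpha) regression over the middle third of the body
.helix_init <- function(x, y, z, alpha, init, orders) {
  if (!is.null(init)) {
    stopifnot(inherits(init, "helix_params"))
    pad <- function(v, len) c(v, rep(0, len))[seq_len(len)]
    return(c(
      pad(init$yc, orders[1] + 1),
      pad(init$zc, orders[2] + 1),
      pad(init$c, orders[3] + 1)
    ))
  }
  yc0 <- mean(y)
  zc0 <- mean(z)
  mid <- x >= 1 / 3 & x <= 2 / 3
  if (sum(mid) < 10) mid <- rep(TRUE, length(x))
  u <- -(y[mid] - yc0)
  ta <- tan(alpha[mid] / .DEG)
  c0 <- if (sum(u^2) > 0) sum(u * ta) / sum(u^2) else 0
  if (!is.finite(c0) || abs(c0) < 1e-3) c0 <- sign(c0 + 1e-12) * 1
  c(
    yc0, rep(0, orders[1]),
    zc0, rep(0, orders[2]),
    c0, rep(0, orders[3])
  )
}

#' @export
coef.helix_fit <- function(object, ...) object$coefficients

#' @export
vcov.helix_fit <- function(object, ...) object$vcov

#' @export
print.helix_fit <- function(x, digits = 4, ...) {
  cat("Concentric circular-helix model fit\n")
  if (!is.null(x$compartment)) cat("  compartment:", x$compartment, "\n")
  cat(sprintf("  fibres: %d   residual SD: %.3f deg   SSE: %.1f deg^2\n",
              x$n_fibres, x$sigma, x$sse))
  mid <- evaluate_fit(x, 0.5)
  cat(sprintf(
    "  at x = 0.5: centre (y_c, z_c) = (%.*f, %.*f), pitch = %.*f %s\n",
    digits, mid$y_c, digits, mid$z_c, digits, mid$pitch,
    if (mid$chirality >= 0) "(right-handed, c > 0)" else "(left-handed, c < 0)"
  ))
  if (x$ill_defined) cat("  NOTE: rank-deficient design, parameters ill-defined\n")
  if (!x$converged) cat("  NOTE: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.helix_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  structure(
    list(
      coefficients = tab,
      sigma = object$sigma,
      sse = object$sse,
      n_fibres = object$n_fibres,
      df_residual = object$df_residual,
      compartment = object$compartment,
      converged = object$converged,
      ill_defined = object$ill_defined,
      evaluation = evaluate_fit(object, seq(0.1, 0.9, by = 0.2))
    ),
    class = "summary.helix_fit"
  )
}

#' @export
print.summary.helix_fit <- function(x, ...) {
  cat("Concentric circular-helix model fit\n")
  if (!is.null(x$compartment)) cat("  compartment:", x$compartment, "\n")
  cat(sprintf("  fibres: %d   residual SD: %.3f deg (df = %d)\n",
              x$n_fibres, x$sigma, x$df_residual))
  cat("\nCoefficients (polynomials in normalized x):\n")
  stats::printCoefmat(x$coefficients)
  cat("\nCentre and pitch along the body (95% CI):\n")
  ev <- x$evaluation
  print(
    data.frame(
      x_norm = ev$x_norm,
      y_c = sprintf("%.4f [%.4f, %.4f]", ev$y_c, ev$y_c_lo, ev$y_c_hi),
      z_c = sprintf("%.4f [%.4f, %.4f]", ev$z_c, ev$z_c_lo, ev$z_c_hi),
      pitch = ifelse(
        ev$pitch_unbounded,
        sprintf("%.3f [unbounded]", ev$pitch),
        sprintf("%.3f [%.3f, %.3f]", ev$pitch, ev$pitch_lo, ev$pitch_hi)
      )
    ),
    row.names = FALSE
  )
  invisible(x)
}

#' Predicted projection angles for fibres under a fitted helix model
#'
#' @param object a [fit_helix()] result.
#' @param newdata data.frame with columns `y`, `z`, `x_norm`; defaults to
#'   the fitted data.
#' @param ... unused.
#' @return data.frame with `alpha_m`, `phi_m` (degrees).
#' @export
predict.helix_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  predict_angles(newdata$y, newdata$z, newdata$x_norm, object$params)
}
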