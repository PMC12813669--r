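# the concentric circular-helix model: geometry, fitting, confidence bands

test_that("radial coordinates follow the dorsal-zero convention", {
  rc <- radial_coords(1.5, 0.2, 0.5, 0.2)
  expect_equal(rc$R, 1)
  expect_equal(rc$zeta, 0)
  rc <- radial_coords(0.5, 0.7, 0.5, 0.2)
  expect_equal(rc$R, 0.5)
  expect_equal(rc$zeta, 90)
  rc <- radial_coords(-3, 4, 0, 0)
  expect_equal(rc$R, 5)
  expect_equal(rc$zeta, 126.86989764584402, tolerance = 1e-10)
  rc <- radial_coords(0.1, 0.2, 0.1, 0.2)
  expect_true(is.na(rc$zeta))
})

test_that("predicted angles vanish at the centre and match direct evaluation", {
  p <- helix_params(0.1, 0.05, 8 * pi)
  at_centre <- predict_angles(0.1, 0.05, 0.5, p)
  expect_equal(at_centre$alpha_m, 0)
  expect_equal(at_centre$phi_m, 0)
  off <- predict_angles(0.11, 0.05, 0.5, p)
  expect_equal(off$alpha_m, -14.107802371590129, tolerance = 1e-9)
  expect_equal(off$phi_m, 0)
})

test_that("predicted angles equal finite-difference tangents of parametric helices", {
  sw <- angle_oracle_sweep(n = 200, seed = 3)
  expect_lt(max(sw$err_rad), 1e-6)
})

test_that("pitch is 2*pi over the slope magnitude, with chirality in the sign", {
  expect_equal(as.numeric(pitch_from_slope(2 * pi)), 1)
  expect_equal(as.numeric(pitch_from_slope(8 * pi)), 0.25)
  p <- pitch_from_slope(-4 * pi)
  expect_equal(as.numeric(p), 0.5)
  expect_equal(attr(p, "chirality"), -1)
  expect_warning(pinf <- pitch_from_slope(0), "infinite")
  expect_true(is.infinite(pinf[1]))
})

test_that("completed turns integrate the local turn rate", {
  expect_equal(completed_turns(helix_params(0, 0, 2 * pi / 0.25)), 4,
               tolerance = 1e-8)
  # opposite chirality makes the same number of turns
  expect_equal(completed_turns(helix_params(0, 0, -2 * pi / 0.25)), 4,
               tolerance = 1e-8)
})

test_that("noise-free synthetic fields are recovered essentially exactly", {
  fib <- generate_field(field_spec(n_fibres = 800, yc = 0.15, zc = 0.05,
                                   c_ = 8 * pi, noise_sd = 0, seed = 11))
  fit <- fit_helix(fib)
  ev <- evaluate_fit(fit, c(0.2, 0.5, 0.8))
  expect_lt(max(abs(ev$y_c - 0.15)), 1e-4)
  expect_lt(max(abs(ev$z_c - 0.05)), 1e-4)
  expect_lt(max(abs(ev$pitch - 0.25) / 0.25), 0.001)
})

test_that("noisy fields are recovered within the stated tolerances", {
  fib <- generate_field(field_spec(n_fibres = 800, yc = 0.15, zc = 0.05,
                                   c_ = 8 * pi, noise_sd = 3, seed = 12))
  fit <- fit_helix(fib)
  ev <- evaluate_fit(fit, 0.5)
  expect_lt(abs(ev$y_c - 0.15), 0.01)
  expect_lt(abs(ev$z_c - 0.05), 0.01)
  expect_lt(abs(ev$pitch - 0.25) / 0.25, 0.05)
})

test_that("the fit is invariant to fibre ordering", {
  fib <- generate_field(field_spec(n_fibres = 300, noise_sd = 3, seed = 4))
  f1 <- fit_helix(fib)
  f2 <- fit_helix(fib[sample(nrow(fib)), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("translating the field shifts the centre constants and keeps c", {
  fib <- generate_field(field_spec(n_fibres = 400, yc = 0.1, zc = 0.02,
                                   c_ = 6 * pi, noise_sd = 0, seed = 5))
  f0 <- fit_helix(fib)
  fib2 <- fib
  fib2$y <- fib2$y + 0.07
  fib2$z <- fib2$z - 0.03
  f1 <- fit_helix(fib2)
  expect_equal(coef(f1)[["yc_0"]], coef(f0)[["yc_0"]] + 0.07,
               tolerance = 1e-6)
  expect_equal(coef(f1)[["zc_0"]], coef(f0)[["zc_0"]] - 0.03,
               tolerance = 1e-6)
  expect_equal(coef(f1)[grep("^c_", names(coef(f1)))],
               coef(f0)[grep("^c_", names(coef(f0)))], tolerance = 1e-6)
})

test_that("the constant-pitch identity tan(theta_m) / R = |c| holds across radii", {
  p <- helix_params(0.1, 0.05, 5)
  d <- pi / 180
  for (R in c(0.01, 0.05, 0.12)) {
    for (zeta in c(-2, 0.3, 1.7)) {
      y <- 0.1 + R * cos(zeta)
      z <- 0.05 + R * sin(zeta)
      pa <- predict_angles(y, z, 0.5, p)
      tan_theta <- sqrt(tan(pa$alpha_m * d)^2 + tan(pa$phi_m * d)^2)
      expect_equal(tan_theta / R, 5, tolerance = 1e-9)
    }
  }
})

test_that("an all-longitudinal field is flagged ill-defined with unbounded pitch", {
  set.seed(8)
  n <- 200
  fib <- data.frame(
    x_norm = runif(n), y = runif(n, 0, 0.2), z = runif(n, -0.1, 0.1),
    alpha = 0, phi = 0
  )
  fit <- suppressWarnings(fit_helix(fib, compartment = "epaxial"))
  ev <- evaluate_fit(fit, 0.5)
  expect_true(fit$ill_defined || ev$pitch_unbounded)
  expect_true(ev$pitch_unbounded)
})

test_that("confidence bands propagate coefficient covariance linearly", {
  fib <- generate_field(field_spec(n_fibres = 400, noise_sd = 3, seed = 6))
  fit <- fit_helix(fib)
  ev <- evaluate_fit(fit, c(0.25, 0.5, 0.75))
  # zero covariance -> zero-width bands
  fit0 <- fit
  fit0$vcov[] <- 0
  ev0 <- evaluate_fit(fit0, c(0.25, 0.5, 0.75))
  expect_true(all(ev0$y_c_se == 0 & ev0$z_c_se == 0))
  expect_equal(ev0$y_c_lo, ev0$y_c_hi)
  # scaling the covariance by 4 doubles the centre band half-widths
  fit4 <- fit
  fit4$vcov <- 4 * fit$vcov
  ev4 <- evaluate_fit(fit4, c(0.25, 0.5, 0.75))
  expect_equal(ev4$y_c_se, 2 * ev$y_c_se, tolerance = 1e-12)
  expect_equal(ev4$z_c_hi - ev4$z_c_lo, 2 * (ev$z_c_hi - ev$z_c_lo),
               tolerance = 1e-12)
  # delta method through 2*pi/|c|
  expect_equal(ev$pitch_se, 2 * pi * ev$slope_se / ev$slope^2,
               tolerance = 1e-12)
})

test_that("constant-model centre SE matches the closed-form SE of a mean", {
  # small-angle regime: the yc column of the Jacobian is constant, so the
  # centre estimate behaves like a mean with SE = sigma / (deg * |c| * sqrt(n))
  n <- 2000
  fib <- generate_field(field_spec(n_fibres = n, yc = 0, zc = 0, c_ = 0.5,
                                   noise_sd = 1, seed = 9))
  fit <- fit_helix(fib, orders = c(0, 0, 0))
  ev <- evaluate_fit(fit, 0.5)
  closed <- fit$sigma / ((180 / pi) * abs(ev$slope) * sqrt(n))
  expect_equal(ev$y_c_se, closed, tolerance = 0.02)
  expect_equal(ev$z_c_se, closed, tolerance = 0.02)
})
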