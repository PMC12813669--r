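# residual diagnostics: per-fibre errors, circular moving average, summaries

test_that("residuals vanish under the generating parameters", {
  fib <- generate_field(field_spec(n_fibres = 300, noise_sd = 0, seed = 2))
  res <- helix_residuals(fib, attr(fib, "truth"))
  expect_lt(max(abs(res$dalpha), abs(res$dphi)), 1e-6)
})

test_that("a constant angular offset appears as a constant residual", {
  fib <- generate_field(field_spec(n_fibres = 300, noise_sd = 0, seed = 2))
  fib$alpha <- fib$alpha + 2
  res <- helix_residuals(fib, attr(fib, "truth"))
  expect_equal(res$dalpha, rep(2, nrow(fib)), tolerance = 1e-9)
  expect_lt(max(abs(res$dphi)), 1e-9)
})

test_that("residuals of a fitted model are centred and ordering-stable", {
  fib <- generate_field(field_spec(n_fibres = 500, noise_sd = 3, seed = 7))
  fit <- fit_helix(fib)
  res <- residuals(fit)
  expect_equal(nrow(res), nrow(fib))
  expect_lt(abs(mean(res$dalpha)), 0.5)
  expect_lt(abs(mean(res$dphi)), 0.5)
})

test_that("circular moving average reproduces constants and attenuates sin", {
  zeta <- seq(-179, 180, by = 1)
  ma <- circular_moving_average(zeta, rep(2, length(zeta)), window = 90)
  expect_equal(ma$avg, rep(2, nrow(ma)), tolerance = 1e-12)
  # sin(zeta) under a 90-degree window: amplitude sin(45 deg)/(pi/4)
  expect_equal(ma_attenuation(), 0.90031631615710606, tolerance = 1e-3)
})

test_that("moving average gain never exceeds one and commutes with constants", {
  set.seed(3)
  zeta <- runif(4000, -180, 180)
  for (k in 1:3) {
    ph <- runif(1, 0, 2 * pi)
    v <- sin(k * zeta * pi / 180 + ph)
    ma <- circular_moving_average(zeta, v, window = 90)
    expect_lt(max(abs(ma$avg), na.rm = TRUE), 1 + 1e-9)
    ma_c <- circular_moving_average(zeta, v + 5, window = 90)
    expect_equal(ma_c$avg, ma$avg + 5, tolerance = 1e-9)
  }
})

test_that("a single observation fills only its own window", {
  ma <- circular_moving_average(10, 3.5, window = 90,
                                grid = seq(-179, 180, by = 1))
  inside <- abs(((ma$zeta - 10 + 180) %% 360) - 180) <= 45
  expect_true(all(ma$avg[inside] == 3.5))
  expect_true(all(is.na(ma$avg[!inside])))
  expect_error(circular_moving_average(10, 3.5, window = 0), "window")
})

test_that("group summaries of absolute residuals match closed forms", {
  prof <- data.frame(
    fish_id = "f1", compartment = "epaxial",
    dalpha = c(3, -3), dphi = c(0, 4)
  )
  s <- mean_absolute_residuals(prof)
  a <- s[s$angle == "alpha", ]
  expect_equal(a$mean_abs, 3)
  expect_equal(a$sd_abs, 0)
  expect_equal(a$ci_hi - a$ci_lo, 0)
  p <- s[s$angle == "phi", ]
  expect_equal(p$mean_abs, 2)
  expect_equal(p$sd_abs, 2 * sqrt(2), tolerance = 1e-12)
  # CI half-width 1.96 * (2.828 / sqrt(2)) = 3.92
  expect_equal(p$ci_hi - p$mean_abs, stats::qnorm(0.975) * 2,
               tolerance = 1e-9)
  # n < 2: mean only
  s1 <- mean_absolute_residuals(data.frame(
    fish_id = "f2", compartment = "epaxial", dalpha = 1.5, dphi = 0.5
  ))
  expect_true(all(is.na(s1$ci_lo)))
})

test_that("the mean of |N(0, 5)| approaches the half-normal mean", {
  set.seed(10)
  prof <- data.frame(fish_id = "f", compartment = "epaxial",
                     dalpha = rnorm(10000, 0, 5), dphi = 0)
  s <- mean_absolute_residuals(prof)
  m <- s$mean_abs[s$angle == "alpha"]
  expect_equal(m, 5 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("absolute residuals are invariant under septum mirroring", {
  fib <- generate_field(field_spec(n_fibres = 400, noise_sd = 3, seed = 13))
  res <- helix_residuals(fib, attr(fib, "truth"))
  mir <- mirror_septum(fib)
  tr <- attr(fib, "truth")
  tr_m <- helix_params(-tr$yc, tr$zc, -tr$c, "hypaxial")
  res_m <- helix_residuals(mir, tr_m)
  expect_equal(abs(res_m$dalpha), abs(res$dalpha), tolerance = 1e-9)
  expect_equal(abs(res_m$dphi), abs(res$dphi), tolerance = 1e-9)
})

test_that("per-fish mean absolute residuals show no trend with length", {
  # constant noise across simulated sizes: the residual-vs-length slope CI
  # must cover zero
  set.seed(21)
  lens <- seq(2.3, 3.1, length.out = 8)
  means <- vapply(seq_along(lens), function(i) {
    fib <- generate_field(field_spec(n_fibres = 250, noise_sd = 3,
                                     seed = 100 + i))
    fit <- fit_helix(fib)
    mean(abs(residuals(fit)$dalpha))
  }, numeric(1))
  sl <- summary(stats::lm(means ~ lens))$coefficients["lens", ]
  ci <- sl["Estimate"] + c(-1, 1) * stats::qt(0.975, 6) * sl["Std. Error"]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})
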