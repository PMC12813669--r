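# synthetic-data generator: round trips, reproducibility, chirality,
# ellipticity and tail tapering

test_that("noise-free circular fields satisfy the model exactly", {
  fib <- generate_field(field_spec(n_fibres = 500, noise_sd = 0,
                                   ellipticity = 1, seed = 1))
  pred <- predict_angles(fib$y, fib$z, fib$x_norm, attr(fib, "truth"))
  expect_lt(max(abs(fib$alpha - pred$alpha_m)), 1e-9)
  expect_lt(max(abs(fib$phi - pred$phi_m)), 1e-9)
  expect_true(all(fib$vx > 0))
  expect_true(all(fib$side == "right"))
  # unit direction vectors
  expect_lt(max(abs(fib$vx^2 + fib$vy^2 + fib$vz^2 - 1)), 1e-9)
})

test_that("generation is reproducible from the seed", {
  a <- generate_field(field_spec(n_fibres = 100, seed = 42))
  b <- generate_field(field_spec(n_fibres = 100, seed = 42))
  expect_identical(a, b)
  c_ <- generate_field(field_spec(n_fibres = 100, seed = 43))
  expect_false(isTRUE(all.equal(a$alpha, c_$alpha)))
  expect_equal(nrow(generate_field(field_spec(n_fibres = 0))), 0)
})

test_that("epaxial and mirrored fields fit opposite chirality", {
  st <- chirality_study(n_rep = 3, n_fibres = 200, seed = 2)
  expect_true(all(st$opposite))
  expect_true(all(st$sign_epaxial == 1))
  # the hypaxial default spec itself generates left-handed fields
  hyp <- generate_field(field_spec(n_fibres = 300,
                                   compartment = "hypaxial", noise_sd = 3,
                                   seed = 3))
  f <- fit_helix(hyp)
  expect_lt(evaluate_fit(f, 0.5)$slope, 0)
})

test_that("ellipticity produces growing two-lobed sagittal residual structure", {
  st <- ellipticity_study(ratios = c(1, 1.15, 1.3), n_fibres = 1500,
                          noise_sd = 3, seed = 5)
  expect_true(all(diff(st$amplitude) > 0))
  expect_true(all(diff(st$first_harmonic) > 0))
  expect_true(st$lobe_sign_flip[st$ratio == 1.3])
})

test_that("a slope tapering to zero posteriorly gives unbounded tail pitch CIs", {
  # c(x) = 8*pi*(1 - x)^3: near-longitudinal fibres towards the tail
  cpoly <- 8 * pi * c(1, -3, 3, -1)
  fib <- generate_field(field_spec(n_fibres = 800, c_ = cpoly, noise_sd = 3,
                                   seed = 6))
  fit <- fit_helix(fib)
  ev <- evaluate_fit(fit, c(0.3, 0.95))
  expect_false(ev$pitch_unbounded[1])
  expect_true(ev$pitch_unbounded[2])
})

test_that("cohorts realize the designed pitch structure", {
  co <- generate_cohort(cohort_spec(n_fish = 4, n_fibres = 50,
                                    intercept_sd = 0, length_effect = 0,
                                    seed = 7))
  tr <- co$truth
  # zero effects and zero intercept SD: all fish share the same truth
  sp <- split(tr$pitch_true, tr$location)
  expect_true(all(vapply(sp, function(v) diff(range(v)) < 1e-12, TRUE)))
  # the 30-vs-70 contrast is realized exactly
  expect_equal(
    tr$pitch_true[tr$location == 0.7] - tr$pitch_true[tr$location == 0.3],
    rep(0.5, 4), tolerance = 1e-10
  )
  expect_true(all(co$meta$length_mm >= 2.3 & co$meta$length_mm <= 3.1))
  expect_true(all(co$meta$age_dpf >= 2 & co$meta$age_dpf <= 13))
})

test_that("simulating from a fit reproduces its parameter scale", {
  fib <- generate_field(field_spec(n_fibres = 400, noise_sd = 3, seed = 8))
  fit <- fit_helix(fib)
  sims <- simulate(fit, nsim = 2, seed = 9, n_fibres = 300)
  expect_length(sims, 2)
  refit <- fit_helix(sims[[1]])
  expect_lt(abs(evaluate_fit(refit, 0.5)$pitch -
                  evaluate_fit(fit, 0.5)$pitch), 0.05)
})
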