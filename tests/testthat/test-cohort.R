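# standardized pitch extraction and the weighted mixed-effects trend model

make_table <- function(n_fish = 8, loc_eff = 0.5, len_eff = 0,
                       int_sd = 0.05, noise_sd = 0.01, se = 0.01,
                       seed = 1) {
  set.seed(seed)
  locs <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  lens <- runif(n_fish, 2.3, 3.1)
  ints <- rnorm(n_fish, 0, int_sd)
  do.call(rbind, lapply(seq_len(n_fish), function(i) {
    mu <- 0.6 + loc_eff * (locs - 0.3) / 0.4 + len_eff * lens[i] + ints[i]
    data.frame(
      fish_id = sprintf("f%02d", i), age_dpf = NA, length_mm = lens[i],
      compartment = "epaxial", location = locs,
      pitch = mu + rnorm(length(locs), 0, noise_sd),
      pitch_se = se, weight = 1 / se^2
    )
  }))
}

test_that("pitch SEs are the 95% CI width over 2 * 1.96", {
  fib <- generate_field(field_spec(n_fibres = 500, noise_sd = 3, seed = 31))
  fit <- fit_helix(fib)
  tab <- standardized_pitch(fit, fish_id = "f1", length_mm = 2.8)
  ev <- evaluate_fit(fit, tab$location)
  expect_equal(tab$pitch_se, (ev$pitch_hi - ev$pitch_lo) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(tab$weight, 1 / tab$pitch_se^2)
  # worked example: CI (0.2, 0.6) converts to SE 0.10204
  expect_equal((0.6 - 0.2) / (2 * qnorm(0.975)), 0.1020442, tolerance = 1e-4)
})

test_that("locations with unbounded pitch CIs are excluded", {
  set.seed(8)
  n <- 200
  fib <- data.frame(
    x_norm = runif(n), y = runif(n, 0, 0.2), z = runif(n, -0.1, 0.1),
    alpha = rnorm(n, 0, 0.01), phi = rnorm(n, 0, 0.01)
  )
  fit <- suppressWarnings(fit_helix(fib, compartment = "epaxial"))
  tab <- standardized_pitch(fit, fish_id = "f1")
  excl <- attr(tab, "excluded")
  expect_true(length(excl) > 0)
  expect_equal(sort(c(tab$location, excl)), c(0.3, 0.4, 0.5, 0.6, 0.7))
})

test_that("zero noise and zero intercept SD recover coefficients exactly", {
  tab <- make_table(n_fish = 6, loc_eff = 0.5, len_eff = 0.1, int_sd = 0,
                    noise_sd = 0, seed = 2)
  tr <- fit_pitch_trend(tab)
  cf <- coef(tr)
  expect_equal(unname(cf["length_mm"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(cf["location_f0.7"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(cf["location_f0.5"]), 0.25, tolerance = 1e-6)
})

test_that("equal weights match the unweighted mixed fit", {
  tab <- make_table(n_fish = 8, noise_sd = 0.02, seed = 3)
  tr <- fit_pitch_trend(tab)
  d <- data.frame(
    pitch = tab$pitch, length_mm = tab$length_mm,
    fish_id = factor(tab$fish_id),
    location_f = factor(tab$location)
  )
  un <- nlme::lme(pitch ~ length_mm + location_f, random = ~ 1 | fish_id,
                  data = d, method = "REML")
  expect_equal(unname(coef(tr)), unname(nlme::fixef(un)), tolerance = 1e-8)
})

test_that("rescaling all SEs leaves the point estimates unchanged", {
  tab <- make_table(n_fish = 8, noise_sd = 0.02, seed = 4)
  tr1 <- fit_pitch_trend(tab)
  tab2 <- tab
  tab2$pitch_se <- 2 * tab2$pitch_se
  tab2$weight <- 1 / tab2$pitch_se^2
  tr2 <- fit_pitch_trend(tab2)
  expect_equal(coef(tr1), coef(tr2), tolerance = 1e-8)
})

test_that("degenerate cohorts are rejected", {
  tab <- make_table(n_fish = 1, seed = 5)
  expect_error(fit_pitch_trend(tab), "more than one fish")
  expect_warning(fit_pitch_trend(make_table(n_fish = 3, seed = 6)),
                 "fewer than 5")
})

test_that("a full synthetic cohort recovers the location contrast", {
  co <- generate_cohort(cohort_spec(n_fish = 8, n_fibres = 300, seed = 17))
  rows <- lapply(names(co$fields), function(k) {
    fib <- co$fields[[k]]
    fit <- fit_helix(fib)
    m <- co$meta[co$meta$fish_id == fib$fish_id[1], ]
    standardized_pitch(fit, fish_id = fib$fish_id[1],
                       age_dpf = m$age_dpf, length_mm = m$length_mm)
  })
  tr <- fit_pitch_trend(do.call(rbind, rows), compartment = "epaxial")
  cf <- tr$coefficients
  row <- cf[cf$term == "location_f0.7", ]
  expect_lt(abs(row$estimate - 0.5), 5 * row$se)
  expect_true(all(c("df", "t", "p") %in% names(cf)))
})

test_that("parameters-vs-length tables have the documented long format", {
  fib <- generate_field(field_spec(n_fibres = 400, noise_sd = 3, seed = 41))
  fit <- fit_helix(fib)
  tab <- summarize_parameters_vs_length(
    list(fit), meta = data.frame(fish_id = "f1", length_mm = 2.9)
  )
  expect_equal(nrow(tab), 9)  # 3 locations x 3 parameters
  expect_setequal(unique(tab$parameter), c("y_c", "z_c", "pitch"))
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
  empty <- summarize_parameters_vs_length(list(), meta = NULL)
  expect_equal(nrow(empty), 0)
})

test_that("across-fish spread is consistent with the propagated SEs", {
  # identical true parameters: the inverse-variance heterogeneity statistic
  # for pitch at mid-body should not reject homogeneity
  fits <- lapply(1:5, function(i) {
    fit_helix(generate_field(field_spec(n_fibres = 400, noise_sd = 3,
                                        seed = 200 + i)))
  })
  tab <- summarize_parameters_vs_length(
    fits, meta = data.frame(fish_id = sprintf("f%d", 1:5),
                            length_mm = seq(2.3, 3.1, length.out = 5)),
    locations = 0.5
  )
  p <- tab[tab$parameter == "pitch", ]
  w <- 1 / p$se^2
  q <- sum(w * (p$estimate - sum(w * p$estimate) / sum(w))^2)
  expect_gt(stats::pchisq(q, df = nrow(p) - 1, lower.tail = FALSE), 0.01)
})
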