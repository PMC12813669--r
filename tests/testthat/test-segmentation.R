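# the 3D segmentation chain: preprocessing, watershed, size filter, moments

# voxelized straight tube along `axis`, for constructing fixtures
make_tube <- function(dim, spacing, p0, axis, radius, length,
                      intensity = 1) {
  vol <- array(0, dim)
  ax <- lapply(1:3, function(d) (seq_len(dim[d]) - 1) * spacing[d])
  g <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                   k = seq_len(dim[3]))
  px <- ax[[1]][g$i] - p0[1]
  py <- ax[[2]][g$j] - p0[2]
  pz <- ax[[3]][g$k] - p0[3]
  t <- px * axis[1] + py * axis[2] + pz * axis[3]
  tc <- pmin(pmax(t, 0), length)
  d2 <- (px - tc * axis[1])^2 + (py - tc * axis[2])^2 + (pz - tc * axis[3])^2
  vol[d2 <= radius^2 & t >= 0 & t <= length] <- intensity
  vol
}

test_that("preprocessing leaves structureless stacks alone", {
  const <- image_stack(array(0.7, c(10, 10, 5)))
  out <- preprocess_stack(const)
  expect_true(all(out$voxels == out$voxels[1]))
  expect_warning(preprocess_stack(image_stack(array(0, c(6, 6, 3)))),
                 "all-zero")
})

test_that("preprocessing raises tube contrast over noisy background", {
  set.seed(1)
  dim <- c(40, 24, 16)
  tube <- make_tube(dim, c(1, 1, 2), c(5, 12, 14), c(1, 0, 0), 3, 30)
  noisy <- pmax(tube + array(rnorm(prod(dim), 0, 0.1), dim), 0)
  pre <- preprocess_stack(image_stack(noisy, c(1, 1, 2)))
  inside <- tube > 0
  expect_gt(mean(pre$voxels[inside]), mean(pre$voxels[!inside]))
})

test_that("a single hot voxel is despeckled", {
  dim <- c(40, 24, 16)
  tube <- make_tube(dim, c(1, 1, 2), c(5, 12, 14), c(1, 0, 0), 3, 30,
                    intensity = 0.5)
  tube[35, 5, 3] <- 10
  pre <- preprocess_stack(image_stack(tube, c(1, 1, 2)))
  plateau <- stats::median(pre$voxels[make_tube(dim, c(1, 1, 2), c(5, 12, 14),
                                                c(1, 0, 0), 2, 28) > 0])
  expect_lt(pre$voxels[35, 5, 3], 3 * plateau)
})

test_that("watershed separates two parallel tubes of distinct brightness", {
  dim <- c(48, 30, 16)
  sp <- c(1, 1, 2)
  t1 <- make_tube(dim, sp, c(6, 9, 14), c(1, 0, 0), 3, 34, intensity = 0.9)
  t2 <- make_tube(dim, sp, c(6, 20, 14), c(1, 0, 0), 3, 34, intensity = 0.6)
  stack <- image_stack(t1 + t2, sp)
  pre <- preprocess_stack(stack, smooth_um = 0.6,
                          background_quantile = 0.05)
  labels <- segment_watershed(pre, seed_threshold = 0.4, fg_threshold = 0.15)
  expect_equal(attr(labels, "n_segments"), 2L)
  for (tube in list(t1, t2)) {
    labs <- labels[tube > 0]
    main <- as.integer(names(which.max(table(labs[labs > 0]))))
    expect_gt(mean(labs == main), 0.8)
  }
})

test_that("a single tube gives one segment and an empty stack none", {
  dim <- c(40, 24, 16)
  sp <- c(1, 1, 2)
  tube <- make_tube(dim, sp, c(5, 12, 14), c(1, 0, 0), 3, 30)
  pre <- preprocess_stack(image_stack(tube, sp))
  labels <- segment_watershed(pre)
  expect_equal(attr(labels, "n_segments"), 1L)
  expect_warning(
    empty <- segment_watershed(image_stack(array(0, dim), sp)),
    "no seeds"
  )
  expect_equal(attr(empty, "n_segments"), 0L)
})

test_that("size filtering removes out-of-bounds segments and is monotone", {
  labels <- array(0L, c(10, 10, 4))
  labels[1:2, 1, 1] <- 1L          # 2 voxels
  labels[1:5, 3:6, 1:3] <- 2L      # 60 voxels
  labels[6:10, 8:10, 1:4] <- 3L    # 60 voxels
  f <- filter_by_size(labels, min_size = 50, max_size = 1000)
  expect_equal(attr(f, "removed_small"), 1L)
  expect_equal(sort(unique(as.vector(f[f > 0]))), c(2L, 3L))
  # identity when all within bounds
  f2 <- filter_by_size(labels, 1, Inf)
  expect_equal(as.vector(f2), as.vector(labels))
  # merged oversized blob removed
  f3 <- filter_by_size(labels, 1, 50)
  expect_equal(attr(f3, "removed_large"), 2L)
  # monotone: shrinking the window never adds segments
  n_wide <- attr(filter_by_size(labels, 1, 100), "n_segments")
  n_narrow <- attr(filter_by_size(labels, 10, 60), "n_segments")
  expect_lte(n_narrow, n_wide)
  expect_error(filter_by_size(labels, 10, 5), "exceed")
})

test_that("segment moments recover orientation and flag non-fibres", {
  dim <- c(48, 32, 24)
  sp <- c(1, 1, 2)
  along_x <- make_tube(dim, sp, c(6, 16, 22), c(1, 0, 0), 2.5, 32)
  lab <- array(as.integer(along_x > 0), dim)
  m <- measure_segments(lab, image_stack(along_x, sp))
  expect_lt(acos(abs(m$ax)) * 180 / pi, 2)

  a30 <- c(cos(pi / 6), 0, sin(pi / 6))
  oblique <- make_tube(dim, sp, c(6, 16, 12), a30, 2.5, 32)
  lab2 <- array(as.integer(oblique > 0), dim)
  m2 <- measure_segments(lab2, image_stack(oblique, sp))
  dt <- abs(m2$ax * a30[1] + m2$ay * a30[2] + m2$az * a30[3])
  expect_lt(acos(pmin(dt, 1)) * 180 / pi, 2)
  expect_gt(m2$elongation, 2)
  expect_false(m2$flagged)

  # spherical blob: isotropic, flagged non-fibre
  ax <- lapply(1:3, function(d) (seq_len(dim[d]) - 1) * sp[d])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  ball <- array(as.integer(
    (g$x - 20)^2 + (g$y - 16)^2 + (g$z - 20)^2 <= 8^2
  ), dim)
  m3 <- measure_segments(ball, image_stack(ball + 0, sp))
  expect_lt(m3$elongation, 1.2)
  expect_true(m3$flagged)
})

test_that("principal-axis recovery stays within 3 degrees over random tubes", {
  set.seed(9)
  errs <- vapply(1:100, function(i) {
    cth <- runif(1, cos(40 * pi / 180), 1)
    sth <- sqrt(1 - cth^2)
    ph <- runif(1, -pi, pi)
    a <- c(cth, sth * cos(ph), sth * sin(ph))
    dim <- c(40, 30, 20)
    sp <- c(1, 1, 2)
    tube <- make_tube(dim, sp, c(4, 15, 18) , a, 2.5, 28)
    lab <- array(as.integer(tube > 0), dim)
    m <- measure_segments(lab, image_stack(tube, sp))
    dt <- abs(m$ax * a[1] + m$ay * a[2] + m$az * a[3])
    acos(min(dt, 1)) * 180 / pi
  }, numeric(1))
  expect_lt(stats::median(errs), 3)
})

test_that("rendered fixtures are segmented end to end", {
  b <- segmentation_benchmark(n_fibres = 10, seed = 12)
  expect_gte(b$n_recovered, 9)
  expect_lt(b$median_axis_err_deg, 3)
})

test_that("overlapping fibres are resolved to the brighter one and flagged", {
  geom <- data.frame(
    cx = c(30, 34), cy = c(20, 20), cz = c(20, 20),
    ax = 1, ay = 0, az = 0, length_um = 24, radius_um = 3,
    intensity = c(0.9, 0.5)
  )
  expect_warning(
    r <- render_stack(geom, dim = c(64L, 40L, 20L), noise_sd = 0,
                      blur_um = 0, seed = 1),
    "overlapping"
  )
  expect_gt(r$n_overlap_voxels, 0)
  shared <- r$truth[r$truth > 0]
  expect_true(all(sort(unique(shared)) == c(1L, 2L)))
})
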