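# Simulation studies that exercise the whole pipeline against known ground
# truth. These back the package's validation claims (parameter recovery,
# chirality, CI calibration, cohort-trend recovery, segmentation accuracy).

#' Projection-angle oracle sweep against finite-difference helix tangents
#'
#' Samples parametric circular helices over a range of radii, pitches and
#' phase angles, differentiates the helix position numerically, and compares
#' the projection angles of the numeric tangent with [predict_angles()].
#' The two must agree: the model's angle equations are exactly the
#' projection angles of a constant-pitch circular helix.
#'
#' @param n number of sampled (R, pitch, zeta) combinations (default 1000).
#' @param step finite-difference step on the longitudinal coordinate
#'   (default 1e-6).
#' @param seed seed for the sweep sample.
#' @return data.frame with the sampled configurations and `err_rad`, the
#'   angular discrepancy in radians (max over alpha and phi).
#' @export
angle_oracle_sweep <- function(n = 1000L, step = 1e-6, seed = 1L) {
  set.seed(seed)
  R <- stats::runif(n, 0.005, 0.15)
  pitch <- stats::runif(n, 0.1, 1.5)
  chir <- sample(c(-1, 1), n, replace = TRUE)
  zeta0 <- stats::runif(n, -pi, pi)
  x0 <- stats::runif(n, 0.1, 0.9)
  yc <- 0.1
  zc <- 0.05
  err <- numeric(n)
  for (i in seq_len(n)) {
    cc <- chir[i] * 2 * pi / pitch[i]
    pos <- function(x) {
      zeta <- zeta0[i] - cc * (x - x0[i])
      c(x, yc + R[i] * cos(zeta), zc + R[i] * sin(zeta))
    }
    d <- (pos(x0[i] + step) - pos(x0[i] - step)) / (2 * step)
    v <- d / sqrt(sum(d^2))
    ang <- compute_angles(v)
    p <- pos(x0[i])
    m <- predict_angles(p[2], p[3], x0[i], helix_params(yc, zc, cc))
    err[i] <- max(abs(ang$alpha - m$alpha_m), abs(ang$phi - m$phi_m)) / .DEG
  }
  data.frame(R = R, pitch = pitch, chirality = chir, zeta0 = zeta0,
             x0 = x0, err_rad = err)
}

#' Parameter-recovery study on noisy synthetic fields
#'
#' Repeatedly generates a fibre field with known constant helix parameters
#' plus Gaussian angular noise, fits the full polynomial model, and records
#' the recovery error and confidence-interval coverage of the centre and
#' pitch at a reference position.
#'
#' @param n_rep replicates (default 100).
#' @param n_fibres fibres per field (default 800).
#' @param noise_sd angular noise SD in degrees (default 3).
#' @param yc,zc,c_ true constant parameters (defaults 0.15, 0.05, `8*pi`).
#' @param x_eval position at which recovery is assessed (default 0.5).
#' @param seed base seed; replicate seeds fan out from it.
#' @return data.frame per replicate: `yc_err`, `zc_err` (absolute,
#'   normalized units), `pitch_err_pct`, and logical coverage indicators
#'   `cover_yc`, `cover_zc`, `cover_pitch` for the 95% intervals.
#' @export
recovery_study <- function(n_rep = 100L, n_fibres = 800L, noise_sd = 3,
                           yc = 0.15, zc = 0.05, c_ = 8 * pi,
                           x_eval = 0.5, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  true_pitch <- 2 * pi / abs(c_)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    fib <- generate_field(field_spec(
      n_fibres = n_fibres, yc = yc, zc = zc, c_ = c_,
      noise_sd = noise_sd, seed = seeds[r]
    ))
    fit <- fit_helix(fib)
    ev <- evaluate_fit(fit, x_eval)
    out[[r]] <- data.frame(
      yc_err = abs(ev$y_c - yc),
      zc_err = abs(ev$z_c - zc),
      pitch_err_pct = 100 * abs(ev$pitch - true_pitch) / true_pitch,
      cover_yc = ev$y_c_lo <= yc & yc <= ev$y_c_hi,
      cover_zc = ev$z_c_lo <= zc & zc <= ev$z_c_hi,
      cover_pitch = !ev$pitch_unbounded &
        ev$pitch_lo <= true_pitch & true_pitch <= ev$pitch_hi
    )
  }
  do.call(rbind, out)
}

#' Chirality study: mirrored fields must fit opposite-sign slopes
#'
#' Generates an epaxial field, reflects it across the horizontal septum
#' (`y -> -y`, `phi -> -phi`, hypaxial-like), fits both, and records the
#' fitted slope signs at mid-body.
#'
#' @param n_rep replicates (default 100).
#' @param n_fibres fibres per field (default 200).
#' @param noise_sd angular noise SD in degrees (default 3).
#' @param seed base seed.
#' @return data.frame per replicate with `sign_epaxial`, `sign_mirrored`,
#'   `opposite` (logical).
#' @export
chirality_study <- function(n_rep = 100L, n_fibres = 200L, noise_sd = 3,
                            seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    epa <- generate_field(field_spec(
      n_fibres = n_fibres, compartment = "epaxial",
      noise_sd = noise_sd, seed = seeds[r]
    ))
    hyp <- mirror_septum(epa)
    f1 <- fit_helix(epa)
    f2 <- fit_helix(hyp)
    s1 <- sign(evaluate_fit(f1, 0.5)$slope)
    s2 <- sign(evaluate_fit(f2, 0.5)$slope)
    out[[r]] <- data.frame(
      sign_epaxial = s1, sign_mirrored = s2, opposite = s1 == -s2
    )
  }
  do.call(rbind, out)
}

#' Reflect a fibre field across the horizontal septum
#'
#' Maps an epaxial field onto its hypaxial mirror image: `y`, `vy`, `phi`
#' and `beta` change sign; `alpha` and `theta` are preserved. The helical
#' chirality of the reflected field is opposite.
#'
#' @param fibres fibre table.
#' @return the reflected fibre table, compartment labels swapped.
#' @export
mirror_septum <- function(fibres) {
  fibres$y <- -fibres$y
  if (!is.null(fibres$y_um)) fibres$y_um <- -fibres$y_um
  if (!is.null(fibres$vy)) fibres$vy <- -fibres$vy
  if (!is.null(fibres$phi)) fibres$phi <- -fibres$phi
  if (!is.null(fibres$beta)) fibres$beta <- -fibres$beta
  if (!is.null(fibres$compartment)) {
    fibres$compartment <- ifelse(
      fibres$compartment == "epaxial", "hypaxial", "epaxial"
    )
  }
  fibres
}

#' Ellipticity study: direction-structured sagittal residuals
#'
#' Generates fields whose cross-sections are stretched by increasing axis
#' ratios, fits the circular-helix model, and measures the structure of the
#' sagittal residual against the direction `zeta` around the fitted centre:
#' the full moving-average amplitude `(max - min) / 2` and the amplitude of
#' the first circular harmonic. An elliptical cross-section shows up as a
#' two-lobed pattern: one positive lobe along the stretched axis and an
#' opposite-sign lobe in the opposite quadrant (the curve flips sign half a
#' turn from its maximum).
#'
#' @param ratios axis ratios to scan (default `c(1, 1.15, 1.3)`).
#' @param n_fibres fibres per field (default 2000).
#' @param noise_sd angular noise SD in degrees (default 3).
#' @param window moving-average window in degrees (default 90).
#' @param seed base seed (same fibre placements across ratios).
#' @return data.frame per ratio: `amplitude` (moving-average half-range),
#'   `first_harmonic` (amplitude of the `zeta` component), and
#'   `lobe_sign_flip` (TRUE if the curve changes sign half a turn from its
#'   maximum, the opposite-quadrant signature).
#' @export
ellipticity_study <- function(ratios = c(1, 1.15, 1.3), n_fibres = 2000L,
                              noise_sd = 3, window = 90, seed = 1L) {
  out <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    fib <- generate_field(field_spec(
      n_fibres = n_fibres, ellipticity = ratios[i], ell_angle = 45,
      noise_sd = noise_sd, seed = seed
    ))
    fit <- fit_helix(fib)
    res <- residuals(fit)
    ma <- circular_moving_average(res$zeta, res$dphi, window = window)
    ok <- is.finite(ma$avg)
    amp <- (max(ma$avg[ok]) - min(ma$avg[ok])) / 2
    zr <- ma$zeta[ok] / .DEG
    a1 <- 2 * mean(ma$avg[ok] * sin(zr))
    b1 <- 2 * mean(ma$avg[ok] * cos(zr))
    # value half a turn from the curve maximum: the opposite-quadrant lobe
    zmax <- ma$zeta[ok][which.max(ma$avg[ok])]
    zq <- ((zmax + 180 + 180) %% 360) - 180
    vq <- ma$avg[ok][which.min(abs(ma$zeta[ok] - zq))]
    out[[i]] <- data.frame(
      ratio = ratios[i],
      amplitude = amp,
      first_harmonic = sqrt(a1^2 + b1^2),
      lobe_sign_flip = sign(vq) != sign(max(ma$avg[ok]))
    )
  }
  do.call(rbind, out)
}

#' Cohort pitch-trend recovery study
#'
#' Repeatedly generates a full synthetic cohort, runs every fish through
#' the helix fit and standardized-pitch extraction, fits the weighted
#' mixed-effects trend model, and checks whether its 30%-vs-70% location
#' contrast covers the cohort's realized true contrast.
#'
#' @param n_rep replicates (default 100).
#' @param spec a [cohort_spec()] template; its seed is replaced per
#'   replicate.
#' @param seed base seed.
#' @return data.frame per replicate: `estimate`, `se`, `true_contrast`
#'   (cohort-mean realized contrast), `covered` (95% CI covers the truth).
#' @export
cohort_recovery_study <- function(n_rep = 100L, spec = cohort_spec(),
                                  seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    spec$seed <- seeds[r]
    co <- generate_cohort(spec)
    rows <- vector("list", length(co$fields))
    for (k in seq_along(co$fields)) {
      fib <- co$fields[[k]]
      fit <- fit_helix(fib)
      m <- co$meta[co$meta$fish_id == fib$fish_id[1], ]
      rows[[k]] <- standardized_pitch(
        fit, fish_id = fib$fish_id[1],
        age_dpf = m$age_dpf, length_mm = m$length_mm
      )
    }
    tab <- do.call(rbind, rows)
    trend <- fit_pitch_trend(tab, compartment = spec$compartments[1])
    cf <- trend$coefficients
    row <- cf[cf$term == "location_f0.7", ]
    tr <- co$truth[co$truth$compartment == spec$compartments[1], ]
    true_contrast <- mean(
      tr$pitch_true[tr$location == 0.7] - tr$pitch_true[tr$location == 0.3]
    )
    zq <- stats::qnorm(0.975)
    out[[r]] <- data.frame(
      estimate = row$estimate, se = row$se, true_contrast = true_contrast,
      covered = row$estimate - zq * row$se <= true_contrast &
        true_contrast <= row$estimate + zq * row$se
    )
  }
  do.call(rbind, out)
}

#' End-to-end segmentation benchmark on a rendered fixture
#'
#' Renders non-overlapping fibres with known geometry, runs the
#' preprocessing / watershed / size-filter / measurement chain, matches the
#' recovered segments to the ground-truth labels by voxel overlap, and
#' reports the per-fibre principal-axis error.
#'
#' @param n_fibres rendered fibres (default 20).
#' @param dim,spacing voxel grid (defaults `c(96, 72, 48)`,
#'   `c(1, 1, 2)` micrometres).
#' @param noise_sd render noise SD (default 0.03).
#' @param seed seed for layout, intensities and noise.
#' @param min_size,max_size size-filter bounds in voxels.
#' @return list with `n_rendered`, `n_recovered`, `axis_err_deg`
#'   (per-recovered-fibre), `median_axis_err_deg`, and the measured
#'   segment table.
#' @export
segmentation_benchmark <- function(n_fibres = 20L, dim = c(96L, 72L, 48L),
                                   spacing = c(1, 1, 2), noise_sd = 0.03,
                                   seed = 1L, min_size = 60L,
                                   max_size = 3000L) {
  geom <- random_fibre_layout(n_fibres, dim = dim, spacing = spacing,
                              seed = seed)
  rend <- render_stack(geom, dim = dim, spacing = spacing,
                       noise_sd = noise_sd, seed = seed + 1L)
  pre <- preprocess_stack(rend$stack)
  labels <- segment_watershed(pre, seed_threshold = 0.4, fg_threshold = 0.15)
  labels <- filter_by_size(labels, min_size, max_size)
  seg <- measure_segments(labels, pre)

  # match each true fibre to the segment holding most of its voxels
  err <- rep(NA_real_, nrow(geom))
  used <- integer(0)
  for (f in seq_len(nrow(geom))) {
    lab_f <- labels[rend$truth == f]
    lab_f <- lab_f[lab_f > 0L]
    if (length(lab_f) == 0) next
    tt <- table(lab_f)
    best <- as.integer(names(tt)[which.max(tt)])
    # majority of the true fibre must be captured, uniquely
    if (max(tt) < 0.5 * sum(rend$truth == f) || best %in% used) next
    used <- c(used, best)
    s <- seg[seg$label == best, ]
    if (is.na(s$ax[1])) next
    tru <- c(geom$ax[f], geom$ay[f], geom$az[f])
    dt <- abs(s$ax[1] * tru[1] + s$ay[1] * tru[2] + s$az[1] * tru[3])
    err[f] <- acos(pmin(dt, 1)) * .DEG
  }
  recovered <- sum(!is.na(err))
  list(
    n_rendered = nrow(geom),
    n_recovered = recovered,
    axis_err_deg = err[!is.na(err)],
    median_axis_err_deg = stats::median(err, na.rm = TRUE),
    segments = seg
  )
}

#' Moving-average attenuation on a dense sinusoidal residual
#'
#' A pure `sin(zeta)` residual sampled densely and smoothed with a
#' `window`-degree circular moving average keeps its shape but is
#' attenuated by the window integral `sin(window/2) / (window/2)` (0.9003
#' for the 90-degree window).
#'
#' @param window window in degrees (default 90).
#' @param step data grid step in degrees (default 0.02).
#' @return fitted amplitude of the smoothed curve (half its range).
#' @export
ma_attenuation <- function(window = 90, step = 0.02) {
  zeta <- seq(-180 + step, 180, by = step)
  ma <- circular_moving_average(zeta, sin(zeta / .DEG), window = window)
  (max(ma$avg) - min(ma$avg)) / 2
}
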