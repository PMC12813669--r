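#' Pitch estimates at standardized body locations
#'
#' Extracts helix pitch and its standard error from a fitted helix model at
#' standardized normalized locations along the body (default 30-70%). The
#' 95% confidence intervals from [evaluate_fit()] are converted to standard
#' errors as `(upper - lower) / (2 * 1.96)`; locations with an unbounded
#' pitch CI (slope indistinguishable from zero) are excluded and reported
#' via the `"excluded"` attribute.
#'
#' @param fit a [fit_helix()] result.
#' @param locations normalized positions (default
#'   `c(0.30, 0.40, 0.50, 0.60, 0.70)`).
#' @param fish_id,age_dpf,length_mm cohort metadata attached to each row.
#' @return data.frame with columns `fish_id`, `age_dpf`, `length_mm`,
#'   `compartment`, `location`, `pitch`, `pitch_se`, `weight`
#'   (`1 / pitch_se^2`).
#' @export
standardized_pitch <- function(fit, locations = c(0.3, 0.4, 0.5, 0.6, 0.7),
                               fish_id = NA, age_dpf = NA, length_mm = NA) {
  stopifnot(inherits(fit, "helix_fit"))
  ev <- evaluate_fit(fit, x_norm = locations, level = 0.95)
  se <- (ev$pitch_hi - ev$pitch_lo) / (2 * stats::qnorm(0.975))
  keep <- !ev$pitch_unbounded & is.finite(se) & se > 0
  nk <- sum(keep)
  out <- data.frame(
    fish_id = rep(fish_id, nk),
    age_dpf = rep(age_dpf, nk),
    length_mm = rep(length_mm, nk),
    compartment = rep(
      if (is.null(fit$compartment)) NA_character_ else fit$compartment, nk
    ),
    location = locations[keep],
    pitch = ev$pitch[keep],
    pitch_se = se[keep],
    weight = 1 / se[keep]^2
  )
  attr(out, "excluded") <- locations[!keep]
  out
}

#' Pitch-trend mixed model across a cohort
#'
#' Models helix pitch as a function of axial muscle length (continuous, mm)
#' and standardized body location, with a random intercept per fish and
#' inverse-variance observation weights derived from the per-location pitch
#' standard errors. Location enters as a categorical factor with the
#' anterior-most level (30%) as reference, so the reported location
#' coefficients are contrasts against 30% (a continuous-location variant is
#' available via `location_continuous = TRUE`).
#'
#' @param table cohort table as stacked [standardized_pitch()] rows.
#' @param compartment if given, restrict to one compartment.
#' @param location_continuous treat location as a continuous covariate.
#' @param known_se treat the pitch standard errors as known measurement
#'   SDs by fixing the residual scale at 1 (meta-analytic weighting;
#'   default). With `FALSE` the SEs act only as relative weights and a free
#'   residual scale is estimated, which makes the fixed-effect standard
#'   errors anticonservative here because the smooth within-fish error
#'   correlation deflates the estimated scale.
#' @return object of class `pitch_trend`: list with the fitted
#'   [nlme::lme()] model, a `coefficients` table (estimate, SE, df, t, p),
#'   `n_obs` and `n_fish`.
#' @export
fit_pitch_trend <- function(table, compartment = NULL,
                            location_continuous = FALSE, known_se = TRUE) {
  if (!is.null(compartment)) {
    table <- table[table$compartment == compartment, , drop = FALSE]
  }
  table <- table[is.finite(table$pitch) & is.finite(table$pitch_se), ,
                 drop = FALSE]
  n_fish <- length(unique(table$fish_id))
  if (n_fish < 2) stop("pitch trend model needs more than one fish")
  if (n_fish < 5) warning("fewer than 5 fish: trend estimates are fragile")
  locs_per_fish <- tapply(table$location, table$fish_id,
                          function(l) length(unique(l)))
  if (any(locs_per_fish < 2)) {
    warning("some fish contribute fewer than 2 locations")
  }

  d <- data.frame(
    pitch = table$pitch,
    length_mm = table$length_mm,
    fish_id = factor(table$fish_id),
    se2 = table$pitch_se^2
  )
  d$location_f <- if (location_continuous) {
    table$location
  } else {
    factor(table$location, levels = sort(unique(table$location)))
  }

  model <- nlme::lme(
    fixed = pitch ~ length_mm + location_f,
    random = ~ 1 | fish_id,
    weights = nlme::varFixed(~se2),
    data = d,
    method = "REML",
    control = if (known_se) nlme::lmeControl(sigma = 1)
              else nlme::lmeControl()
  )
  tt <- summary(model)$tTable
  coefs <- data.frame(
    term = rownames(tt),
    estimate = tt[, "Value"],
    se = tt[, "Std.Error"],
    df = tt[, "DF"],
    t = tt[, "t-value"],
    p = tt[, "p-value"],
    row.names = NULL
  )
  structure(
    list(
      model = model,
      coefficients = coefs,
      n_obs = nrow(d),
      n_fish = n_fish,
      compartment = compartment,
      location_continuous = location_continuous
    ),
    class = "pitch_trend"
  )
}

#' @export
print.pitch_trend <- function(x, ...) {
  cat("Helix pitch trend (inverse-variance-weighted linear mixed model)\n")
  if (!is.null(x$compartment)) cat("  compartment:", x$compartment, "\n")
  cat(sprintf("  %d observations, %d fish (random intercept per fish)\n",
              x$n_obs, x$n_fish))
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, 4)
  cf$se <- signif(cf$se, 3)
  cf$t <- round(cf$t, 2)
  cf$p <- signif(cf$p, 3)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pitch_trend <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Helix parameters across fish as a function of length
#'
#' Long-format table of centre coordinates and pitch with confidence
#' intervals at chosen locations, per fish and compartment, for plotting
#' parameters against fish length.
#'
#' @param fits list of [fit_helix()] results.
#' @param meta data.frame with one row per element of `fits`: columns
#'   `fish_id`, `length_mm` (and optionally `age_dpf`).
#' @param locations normalized positions (default `c(0.3, 0.5, 0.7)`).
#' @param level confidence level.
#' @return data.frame with columns `fish_id`, `length_mm`, `age_dpf`,
#'   `compartment`, `location`, `parameter` (`"y_c"`, `"z_c"`, `"pitch"`),
#'   `estimate`, `se`, `lower`, `upper`. Empty input gives an empty table.
#' @export
summarize_parameters_vs_length <- function(fits, meta,
                                           locations = c(0.3, 0.5, 0.7),
                                           level = 0.95) {
  cols <- c("fish_id", "length_mm", "age_dpf", "compartment", "location",
            "parameter", "estimate", "se", "lower", "upper")
  if (length(fits) == 0) {
    out <- as.data.frame(
      stats::setNames(rep(list(numeric(0)), length(cols)), cols)
    )
    return(out)
  }
  rows <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    ev <- evaluate_fit(fit, x_norm = locations, level = level)
    rows[[i]] <- data.frame(
      fish_id = meta$fish_id[i],
      length_mm = meta$length_mm[i],
      age_dpf = if (is.null(meta$age_dpf)) NA else meta$age_dpf[i],
      compartment = if (is.null(fit$compartment)) NA_character_
                    else fit$compartment,
      location = rep(locations, 3L),
      parameter = rep(c("y_c", "z_c", "pitch"), each = length(locations)),
      estimate = c(ev$y_c, ev$z_c, ev$pitch),
      se = c(ev$y_c_se, ev$z_c_se, ev$pitch_se),
      lower = c(ev$y_c_lo, ev$z_c_lo, ev$pitch_lo),
      upper = c(ev$y_c_hi, ev$z_c_hi, ev$pitch_hi)
    )
  }
  do.call(rbind, rows)
}
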