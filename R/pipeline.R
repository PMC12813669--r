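#' Default pipeline configuration
#'
#' All thresholds and stage toggles for [run_pipeline()], overridable by a
#' (partial) list or YAML file. Every run writes its resolved configuration
#' beside the outputs so results are reproducible bit-identically from the
#' run directory alone.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    run_dir = "fibrehelix-run",
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      cohort = FALSE,
      n_fish = 18L,
      n_fibres = 542L,
      noise_sd = 3,
      compartments = c("epaxial", "hypaxial")
    ),
    input = list(
      fibre_csv = NULL,       # pre-segmented fibre table (skips simulate)
      stack_tiff = NULL,      # raw stack (enables the segmentation stage)
      centreline_csv = NULL   # ordered notochord points, micrometres
    ),
    segment = list(
      smooth_um = 1, background_quantile = 0.2,
      seed_threshold = 0.4, fg_threshold = 0.15,
      min_size = 60L, max_size = 5000L
    ),
    angles = list(outlier_limit = 45, septum_y = 0),
    fit = list(orders = c(4, 4, 3), grid = 101L),
    residuals = list(window = 90),
    cohort = list(locations = c(0.3, 0.4, 0.5, 0.6, 0.7))
  )
}

# deep-merge user values over defaults
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Write a fibre table in the standard CSV layout
#'
#' Columns: `fish_id`, `x` (micrometres), `x_norm`, `y`, `z` (normalized
#' units, the coordinates the helix fit consumes), `y_um`, `z_um`, unit
#' direction vector `vx`/`vy`/`vz`, angles `alpha`/`phi`/`beta`/`theta`
#' (degrees), `size_voxels`, `compartment`, `side`.
#'
#' @param fibres fibre table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fibre_csv <- function(fibres, path) {
  cols <- c("fish_id", "x_um", "x_norm", "y", "z", "y_um", "z_um",
            "vx", "vy", "vz", "alpha", "phi", "beta", "theta",
            "size_voxels", "compartment", "side")
  out <- fibres[, intersect(cols, names(fibres)), drop = FALSE]
  names(out)[names(out) == "x_um"] <- "x"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fibre_csv
#' @export
read_fibre_csv <- function(path) {
  d <- utils::read.csv(path)
  names(d)[names(d) == "x"] <- "x_um"
  d
}

# fit JSON report: coefficients, covariance, grid evaluations with CIs
.write_fit_json <- function(fit, path, grid = 101L) {
  ev <- evaluate_fit(fit, seq(0, 1, length.out = grid))
  jsonlite::write_json(
    list(
      compartment = fit$compartment,
      coefficients = as.list(coef(fit)),
      covariance = unclass(fit$vcov),
      n_fibres = fit$n_fibres,
      sse = fit$sse,
      sigma = fit$sigma,
      converged = fit$converged,
      ill_defined = fit$ill_defined,
      evaluation = as.data.frame(ev)
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Run the fibre-architecture pipeline end to end
#'
#' Executes the configured stages: synthetic-data generation (or reading a
#' fibre table / segmenting a stack against a notochord centreline), angle
#' computation with mirroring and outlier filtering, the per-compartment
#' helix fit, residual diagnostics, and - for cohorts - standardized pitch
#' extraction and the weighted mixed-effects pitch trend. Every artefact is
#' written into the run directory together with the resolved configuration
#' and a stage log; re-running the same configuration and seed reproduces
#' the outputs bit-identically.
#'
#' @param config a (partial) configuration list or path to a YAML file;
#'   merged over [default_config()].
#' @return the run directory path, invisibly; artefacts on disk.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  dir.create(cfg$run_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$run_dir, "config.yaml"))
  logf <- file.path(cfg$run_dir, "run.log")
  log <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logf, append = TRUE)
  }
  set.seed(cfg$seed)
  log("pipeline start (seed %d)", cfg$seed)

  # --- acquire fibre tables -------------------------------------------------
  if (!is.null(cfg$input$fibre_csv)) {
    if (!file.exists(cfg$input$fibre_csv)) {
      stop("missing input: ", cfg$input$fibre_csv)
    }
    fib_in <- read_fibre_csv(cfg$input$fibre_csv)
    fields <- split(fib_in, interaction(fib_in$fish_id, fib_in$compartment,
                                        drop = TRUE))
    meta <- NULL
    log("read fibre table: %s", cfg$input$fibre_csv)
  } else if (!is.null(cfg$input$stack_tiff)) {
    for (p in c(cfg$input$stack_tiff, cfg$input$centreline_csv)) {
      if (is.null(p) || !file.exists(p)) stop("missing input: ", p)
    }
    fields <- list(fish01 = .segment_and_straighten(cfg, log))
    meta <- NULL
  } else if (isTRUE(cfg$simulate$enabled)) {
    if (isTRUE(cfg$simulate$cohort)) {
      co <- generate_cohort(cohort_spec(
        n_fish = cfg$simulate$n_fish, n_fibres = cfg$simulate$n_fibres,
        noise_sd = cfg$simulate$noise_sd,
        compartments = cfg$simulate$compartments, seed = cfg$seed
      ), locations = cfg$cohort$locations)
      fields <- co$fields
      meta <- co$meta
      utils::write.csv(co$truth, file.path(cfg$run_dir, "truth.csv"),
                       row.names = FALSE)
      log("simulated cohort: %d fish", cfg$simulate$n_fish)
    } else {
      fields <- list()
      for (comp in cfg$simulate$compartments) {
        fields[[paste0("fish01.", comp)]] <- generate_field(field_spec(
          n_fibres = cfg$simulate$n_fibres, compartment = comp,
          noise_sd = cfg$simulate$noise_sd, fish_id = "fish01",
          seed = cfg$seed
        ))
      }
      meta <- NULL
      log("simulated single fish (%d fibres per compartment)",
          cfg$simulate$n_fibres)
    }
  } else {
    stop("no inputs: enable simulate or provide input paths")
  }

  # --- filter, fit, residuals ----------------------------------------------
  pitch_rows <- list()
  for (key in names(fields)) {
    fib <- fields[[key]]
    fib <- mirror_to_right(fib)
    flt <- filter_outliers(fib, cfg$angles$outlier_limit)
    log("%s: %d fibres, %d removed as outliers", key, nrow(fib),
        flt$counts["total"])
    fib <- flt$kept
    write_fibre_csv(fib, file.path(cfg$run_dir, paste0("fibres_", key, ".csv")))
    if (nrow(fib) < sum(cfg$fit$orders) + 3) {
      log("%s: too few fibres to fit, skipped", key)
      next
    }
    fit <- fit_helix(fib, orders = cfg$fit$orders)
    .write_fit_json(fit, file.path(cfg$run_dir, paste0("fit_", key, ".json")),
                    grid = cfg$fit$grid)
    res <- residuals(fit)
    utils::write.csv(res, file.path(cfg$run_dir,
                                    paste0("residuals_", key, ".csv")),
                     row.names = FALSE)
    if (!is.null(meta)) {
      fish <- fib$fish_id[1]
      m <- meta[meta$fish_id == fish, ]
      pitch_rows[[key]] <- standardized_pitch(
        fit, locations = cfg$cohort$locations,
        fish_id = fish, age_dpf = m$age_dpf, length_mm = m$length_mm
      )
    }
  }

  # --- cohort statistics ----------------------------------------------------
  if (length(pitch_rows) > 0) {
    tab <- do.call(rbind, pitch_rows)
    utils::write.csv(tab, file.path(cfg$run_dir, "cohort_pitch.csv"),
                     row.names = FALSE)
    for (comp in unique(tab$compartment)) {
      trend <- fit_pitch_trend(tab, compartment = comp)
      jsonlite::write_json(
        list(
          compartment = comp,
          coefficients = trend$coefficients,
          n_obs = trend$n_obs,
          n_fish = trend$n_fish
        ),
        file.path(cfg$run_dir, paste0("pitch_trend_", comp, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      log("pitch trend (%s): %d obs, %d fish", comp, trend$n_obs,
          trend$n_fish)
    }
  }
  log("pipeline done")
  invisible(cfg$run_dir)
}

# microscopy path: segment the stack, straighten against the annotated
# notochord centreline, and derive the fibre table
.segment_and_straighten <- function(cfg, log) {
  stack <- read_stack(cfg$input$stack_tiff)
  pre <- preprocess_stack(
    stack, smooth_um = cfg$segment$smooth_um,
    background_quantile = cfg$segment$background_quantile
  )
  labels <- segment_watershed(
    pre, seed_threshold = cfg$segment$seed_threshold,
    fg_threshold = cfg$segment$fg_threshold
  )
  labels <- filter_by_size(labels, cfg$segment$min_size, cfg$segment$max_size)
  seg <- measure_segments(labels, pre)
  seg <- seg[!seg$flagged, , drop = FALSE]
  log("segmentation: %d fibre candidates", nrow(seg))

  ann <- utils::read.csv(cfg$input$centreline_csv)
  cl <- fit_centreline(as.matrix(ann[, c("x", "y", "z")]))
  frame <- build_frames(cl)
  st <- straighten(as.matrix(seg[, c("cx", "cy", "cz")]), frame)
  keep <- !st$ambiguous
  seg <- seg[keep, , drop = FALSE]
  st <- st[keep, , drop = FALSE]
  v <- t(vapply(seq_len(nrow(seg)), function(i) {
    straighten_direction(
      c(seg$ax[i], seg$ay[i], seg$az[i]),
      foot_frame(frame, st$x[i])
    )
  }, numeric(3)))
  ang <- compute_angles(v)
  span <- range(st$x)
  scale <- span[2] - span[1]
  data.frame(
    fish_id = "fish01",
    x_norm = normalize_x(st$x, span[1], span[2]),
    y = st$y / scale, z = st$z / scale,
    x_um = st$x, y_um = st$y, z_um = st$z,
    vx = v[, 1], vy = v[, 2], vz = v[, 3],
    alpha = ang$alpha, phi = ang$phi, beta = ang$beta, theta = ang$theta,
    size_voxels = seg$size,
    compartment = ifelse(st$y > cfg$angles$septum_y, "epaxial", "hypaxial"),
    side = ifelse(st$z >= 0, "right", "left")
  )
}
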