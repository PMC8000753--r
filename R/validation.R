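#' Comparison series for model-vs-experiment agreement
#'
#' Pairs an empirical force line with a model line on a shared displacement
#' grid.
#'
#' @param x Displacement grid, mm (length >= 2).
#' @param y_emp Empirical forces, N.
#' @param y_model Model forces, N.
#' @return Object of class `comparison_series`.
#' @export
comparison_series <- function(x, y_emp, y_model) {
  if (length(x) < 2L || length(y_emp) != length(x) || length(y_model) != length(x)) {
    stop("x, y_emp and y_model must share one grid of length >= 2")
  }
  stopifnot(all(is.finite(x)), all(is.finite(y_emp)), all(is.finite(y_model)))
  structure(list(x = x, y_emp = y_emp, y_model = y_model,
                 y_emp_mean = mean(y_emp)),
            class = "comparison_series")
}

#' Fraction of variance unexplained
#'
#' `FVU = sum((y_i - yhat_i)^2) / sum((y_i - ybar)^2)`: 0 for a perfect
#' model, 1 for the constant mean model. Errors on a constant empirical
#' series (zero total sum of squares).
#'
#' @param series A [comparison_series()].
#' @return Non-negative scalar.
#' @export
fvu <- function(series) {
  stopifnot(inherits(series, "comparison_series"))
  ss_tot <- sum((series$y_emp - series$y_emp_mean)^2)
  if (ss_tot == 0) stop("zero total sum of squares: constant empirical series")
  sum((series$y_emp - series$y_model)^2) / ss_tot
}

#' Default pipeline configuration
#'
#' The study conditions of the synthetic replication: prototype scaffold
#' geometry, reference bone constants, the region-II regression parameters as
#' the empirical generative truth, the reference marrow-fraction schedule of
#' the embedding levels (1.5 / 2.0 / 2.5 mm), and a quarter-cylinder FE
#' domain (radius 2 mm, height 4 mm, 0.1 mm elements) swept over five
#' embedding levels. Any element can be overridden via `modifyList()`
#' semantics in [run_pipeline()].
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 42L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    geometry = list(spike_height = 5, base_diameter = 0.5, apex_diameter = 0.1,
                    inter_spike_gap = 0.35, n_rings = 1L, embed_depth_max = 3),
    bone = list(E1 = 608, E2 = 771, G1 = 260, G2 = 269,
                nu1 = 0.17, nu2 = 0.15, sigma_c = 25),
    constants = list(rho_T = 1.90, rho_w = 1.00, modulus_coefficient = 315),
    curves = list(slope_a_true = 376.49, intercept_b_true = 209.46,
                  region1_span = 0.5, region2_span = 2.0, region3_span = 0.5,
                  noise_sd = 15, n_replicates = 10L, sampling_step = 0.01,
                  seed = seed + 1L),
    volume = list(shape = c(160L, 160L, 208L), voxel_size = 17.5,
                  target_marrow_fraction = 0.67, correlation_length = 350,
                  intensity_bone = 180, intensity_soft = 60, noise_sd = 8,
                  seed = seed + 2L),
    densification = list(levels = c(1.5, 2.0, 2.5),
                         phi_reference = c(0.582, 0.491, 0.403),
                         zone_radius = 0.45, zone_thickness = 1.0,
                         roi_size = 0.6, roi_depth = 0.8,
                         seed = seed + 3L),
    fe = list(domain_radius = 2.0, domain_height = 4.0, element_size = 0.1,
              levels = c(1.25, 1.5, 2.0, 2.5, 3.0),
              delta = 0.01, insert_thickness = 0.5)
  )
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full synthetic validation pipeline
#'
#' Executes the two-step validation loop end to end:
#' \enumerate{
#'   \item synthetic replicate embedding curves -> region-II mean line and
#'     regression;
#'   \item initial FE sweep over the embedding levels -> model force line ->
#'     `fvu_initial` against the empirical mean line;
#'   \item synthetic micro-CT volume, periapical densification per level,
#'     segmentation and densitometry -> per-level marrow fraction, density
#'     and longitudinal modulus;
#'   \item FE re-simulation with the densified-bone insert (insert modulus
#'     from the measured chain, extrapolated linearly in marrow fraction to
#'     un-measured levels) -> `fvu_modified`.
#' }
#' The model line is interpolated onto the region-II displacement grid
#' restricted to the swept level range. Any stage failure aborts with the
#' stage name; results computed so far are returned in the error's `partial`
#' field.
#'
#' @param config Overrides merged onto [default_pipeline_config()].
#' @param output_dir Optional directory; stage artefacts (curves CSV,
#'   densitometry CSV/JSON, report JSON) are written as they are produced.
#' @return Object of class `validation_report`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  cfg <- deep_merge(default_pipeline_config(), config)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  state <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("pipeline stage '%s' failed: %s",
                                 name, conditionMessage(e)))
      err$partial <- state
      stop(err)
    })
  }

  layout <- stage("geometry", build_spike_layout(do.call(scaffold_params, cfg$geometry)))
  bone <- do.call(elastic_constants, cfg$bone)
  constants <- do.call(density_constants, cfg$constants)

  # 1. empirical side: replicate curves -> region II -> regression
  emp <- stage("curves", {
    curves <- generate_force_curves(do.call(curve_spec, cfg$curves))
    if (!is.null(output_dir)) {
      write_force_curves(curves, file.path(output_dir, "force_curves.csv"))
    }
    ml <- mean_curve(curves)
    seg2 <- detect_regions(ml)
    list(curves = curves, meanline = ml, segmentation = seg2,
         fit = fit_region2(ml, seg2))
  })
  state$region_fit <- emp$fit

  # 2. initial FE sweep
  sweep_levels <- cfg$fe$levels
  run_sweep <- function(insert_E2 = NULL) {
    vapply(seq_along(sweep_levels), function(i) {
      mesh <- build_mesh(cfg$fe$domain_radius, cfg$fe$domain_height, layout,
                         sweep_levels[i], cfg$fe$element_size)
      insert <- NULL
      if (!is.null(insert_E2)) {
        mesh <- add_densified_insert(mesh, cfg$fe$insert_thickness)
        ratio <- insert_E2[i] / bone$E2
        insert <- elastic_constants(E1 = bone$E1 * ratio, E2 = insert_E2[i],
                                    G1 = bone$G1 * ratio, G2 = bone$G2 * ratio,
                                    nu1 = bone$nu1, nu2 = bone$nu2,
                                    sigma_c = bone$sigma_c)
      }
      res <- solve_embedding(assemble_system(mesh, bone, insert), mesh,
                             cfg$fe$delta)
      embedding_force(res, bone)$force_N
    }, 0)
  }
  forces_initial <- stage("fe_initial", run_sweep())
  state$model_forces_initial <- forces_initial

  model_vs_empirical <- function(forces) {
    ml <- emp$meanline
    keep <- ml$displacement_mm >= emp$segmentation$b1 &
      ml$displacement_mm <= emp$segmentation$b2 &
      ml$displacement_mm >= min(sweep_levels) &
      ml$displacement_mm <= max(sweep_levels)
    x <- ml$displacement_mm[keep]
    comparison_series(x, ml$mean_N[keep],
                      approx(sweep_levels, forces, xout = x)$y)
  }
  fvu_initial <- stage("fvu_initial", fvu(model_vs_empirical(forces_initial)))
  state$fvu_initial <- fvu_initial

  # 3. micro-CT densitometry of the progressively embedded synthetic specimen
  dens <- stage("densitometry", {
    gen <- generate_trabecular_volume(do.call(volume_spec, cfg$volume))
    dcfg <- cfg$densification
    rows <- lapply(seq_along(dcfg$levels), function(i) {
      lev <- dcfg$levels[i]
      densified <- apply_densification(gen$volume, gen$bone_mask, layout,
                                       embed_depth = lev,
                                       zone_thickness = dcfg$zone_thickness,
                                       target_phi = dcfg$phi_reference[i],
                                       zone_radius = dcfg$zone_radius,
                                       seed = dcfg$seed + i)
      seg <- segment_bone(densified$volume, method = "otsu")
      seg <- remove_noise_objects(seg)
      seg <- classify_pores(seg)
      rois <- periapical_rois(layout, densified$volume, lev,
                              roi_size = dcfg$roi_size,
                              roi_depth = dcfg$roi_depth)
      rep_i <- density_report(seg, rois, constants)
      pooled_phi <- mean(rep_i$phi)
      rho <- bone_density(pooled_phi, constants)
      data.frame(level_mm = lev, phi = pooled_phi, rho_b_g_cm3 = rho,
                 E2_MPa = longitudinal_modulus(rho, constants))
    })
    tab <- do.call(rbind, rows)
    if (!is.null(output_dir)) {
      write.csv(tab, file.path(output_dir, "densitometry_by_level.csv"),
                row.names = FALSE)
    }
    tab
  })
  state$density_table <- dens

  # insert modulus per swept level: measured chain, linear in phi vs level
  insert_E2 <- stage("insert_moduli", {
    phi_fit <- lm(phi ~ level_mm, data = dens)
    phi_at <- pmin(pmax(predict(phi_fit,
                                newdata = data.frame(level_mm = sweep_levels)),
                        0), 1)
    pos <- match(dens$level_mm, sweep_levels)
    phi_at[pos[!is.na(pos)]] <- dens$phi[!is.na(pos)]
    longitudinal_modulus(bone_density(phi_at, constants), constants)
  })
  state$insert_E2 <- insert_E2

  # 4. re-simulation with the densified insert
  forces_modified <- stage("fe_modified", run_sweep(insert_E2))
  state$model_forces_modified <- forces_modified
  fvu_modified <- stage("fvu_modified", fvu(model_vs_empirical(forces_modified)))

  report <- structure(list(
    fvu_initial = fvu_initial,
    fvu_modified = fvu_modified,
    region_fit = unclass(emp$fit),
    levels_mm = sweep_levels,
    model_forces_initial_N = forces_initial,
    model_forces_modified_N = forces_modified,
    empirical_forces_at_levels_N = approx(emp$meanline$displacement_mm,
                                          emp$meanline$mean_N,
                                          xout = sweep_levels, rule = 2)$y,
    density_table = dens,
    insert_E2_MPa = insert_E2,
    provenance = list(seed = cfg$seed,
                      config_hash = rlang::hash(cfg),
                      config = cfg)
  ), class = "validation_report")
  if (!is.null(output_dir)) {
    write_validation_report(report, file.path(output_dir, "validation_report.json"))
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation report: FVU initial %.4f -> modified %.4f\n",
              x$fvu_initial, x$fvu_modified))
  cat(sprintf("region II fit: a = %.2f N/mm, b = %.2f N, R^2 = %.4f\n",
              x$region_fit$a, x$region_fit$b, x$region_fit$r_squared))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' Deterministic for identical seeds/config (no timestamps).
#'
#' @param report A `validation_report`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
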