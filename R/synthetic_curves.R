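#' Specification of synthetic embedding force-distance curves
#'
#' Replicate quasi-static embedding traces with the three-region shape seen in
#' press-fit tests: region I, a concave-up quadratic onset while the spikes
#' enter the intertrabecular space; region II, a linear elastic load-transfer
#' rise `a * x + b`; region III, sawtooth force drops from trabecular
#' destruction superposed on a reduced mean slope. Regions join continuously
#' in the noiseless limit. Defaults follow the reference region-II regression
#' (a = 376.49 N/mm, b = 209.46 N) with 10 replicates to a 3 mm total span.
#'
#' @param slope_a_true Region-II slope, N/mm.
#' @param intercept_b_true Region-II intercept (at zero displacement), N.
#' @param region1_span,region2_span,region3_span Region extents, mm.
#' @param noise_sd Additive Gaussian force noise SD, N.
#' @param n_replicates Number of replicate curves.
#' @param sampling_step Displacement grid step, mm.
#' @param saw_amplitude Region-III drop amplitude, N.
#' @param saw_period Region-III drop period, mm.
#' @param slope3_factor Region-III mean slope as a fraction of `slope_a_true`.
#' @param seed Integer seed.
#' @return Object of class `curve_spec`.
#' @export
curve_spec <- function(slope_a_true = 376.49,
                       intercept_b_true = 209.46,
                       region1_span = 0.5, region2_span = 2.0, region3_span = 0.5,
                       noise_sd = 15,
                       n_replicates = 10L,
                       sampling_step = 0.01,
                       saw_amplitude = 30, saw_period = 0.1,
                       slope3_factor = 0.5,
                       seed = 1L) {
  spans <- c(region1_span, region2_span, region3_span)
  if (any(spans <= 0)) stop("region spans must be positive")
  if (slope_a_true <= 0) stop("slope_a_true must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_replicates < 1L) stop("need at least one replicate")
  stopifnot(sampling_step > 0, saw_amplitude >= 0, saw_period > 0,
            slope3_factor >= 0)
  structure(list(slope_a_true = slope_a_true,
                 intercept_b_true = intercept_b_true,
                 region1_span = region1_span, region2_span = region2_span,
                 region3_span = region3_span,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 sampling_step = sampling_step,
                 saw_amplitude = saw_amplitude, saw_period = saw_period,
                 slope3_factor = slope3_factor,
                 seed = as.integer(seed)),
            class = "curve_spec")
}

# Noiseless generative mean of the three-region curve at displacements x.
curve_mean_force <- function(spec, x) {
  x1 <- spec$region1_span
  x2 <- spec$region1_span + spec$region2_span
  a <- spec$slope_a_true
  b <- spec$intercept_b_true
  c1 <- (a * x1 + b) / x1^2 # quadratic onset meeting the line at x1
  f <- numeric(length(x))
  r1 <- x <= x1
  r2 <- x > x1 & x <= x2
  r3 <- x > x2
  f[r1] <- c1 * x[r1]^2
  f[r2] <- a * x[r2] + b
  t3 <- x[r3] - x2
  f[r3] <- (a * x2 + b) + spec$slope3_factor * a * t3 +
    spec$saw_amplitude * ((t3 / spec$saw_period) %% 1)
  f
}

#' Generate replicate force-distance curves
#'
#' @param spec A [curve_spec()].
#' @return A data.frame of class `force_curves` with columns
#'   `displacement_mm`, `force_N`, `replicate`, on a shared strictly
#'   increasing displacement grid.
#' @export
generate_force_curves <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  set.seed(spec$seed)
  x <- seq(0, spec$region1_span + spec$region2_span + spec$region3_span,
           by = spec$sampling_step)
  mean_f <- curve_mean_force(spec, x)
  out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    noise <- if (spec$noise_sd > 0) rnorm(length(x), 0, spec$noise_sd) else 0
    data.frame(displacement_mm = x, force_N = mean_f + noise, replicate = r)
  }))
  class(out) <- c("force_curves", "data.frame")
  out
}

#' Write force curves as CSV
#'
#' Header `displacement_mm,force_N,replicate`, the interchange format of the
#' curve-analysis stage.
#'
#' @param curves A `force_curves` data.frame.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_force_curves <- function(curves, path) {
  stopifnot(all(c("displacement_mm", "force_N", "replicate") %in% names(curves)))
  write.csv(curves[, c("displacement_mm", "force_N", "replicate")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read force curves from CSV
#'
#' @param path File with columns `displacement_mm,force_N,replicate`.
#' @return A `force_curves` data.frame.
#' @export
read_force_curves <- function(path) {
  out <- read.csv(path)
  stopifnot(all(c("displacement_mm", "force_N", "replicate") %in% names(out)))
  class(out) <- c("force_curves", "data.frame")
  out
}
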