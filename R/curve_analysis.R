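#' Detect the three regions of an embedding force-distance curve
#'
#' Embedding traces show a concave onset (region I), a linear elastic
#' load-transfer phase (region II) and a post-yield phase with force drops
#' (region III). Region II is found as the longest contiguous span whose
#' rolling-window local slope stays within `slope_tol` (relative) of the
#' span's median slope; the window median is iterated to a fixed point. The
#' boundaries are then refined pointwise: the region-II line is fitted and
#' extended while residuals stay within 3 residual-SDs (or an absolute
#' epsilon for noiseless data), which recovers the true breakpoints to about
#' one grid step when there is no noise.
#'
#' @param curve data.frame with `displacement_mm` and `force_N` columns
#'   (a single replicate, or a mean line from [mean_curve()]).
#' @param window Rolling window span for local slopes, mm.
#' @param slope_tol Relative slope-stability tolerance.
#' @return Object of class `region_segmentation`: list with `b1`, `b2`
#'   (displacement boundaries, mm) and `slope_median` (N/mm).
#' @export
detect_regions <- function(curve, window = 0.2, slope_tol = 0.15) {
  x <- curve$displacement_mm
  y <- if ("force_N" %in% names(curve)) curve$force_N else curve$mean_N
  stopifnot(length(x) == length(y), all(diff(x) > 0), all(is.finite(y)))
  step <- median(diff(x))
  hw <- max(1L, round(window / step / 2))
  n <- length(x)
  if (n < 6L * hw + 3L) stop("curve shorter than 3 rolling windows")
  centers <- (hw + 1L):(n - hw)
  slopes <- vapply(centers, function(i) {
    ii <- (i - hw):(i + hw)
    xs <- x[ii] - x[i]
    sum(xs * (y[ii] - mean(y[ii]))) / sum(xs^2)
  }, 0)

  run <- seq_along(centers)
  for (iter in 1:10) {
    m <- median(slopes[run])
    ok <- if (is.infinite(slope_tol)) rep(TRUE, length(slopes)) else
      abs(slopes - m) <= slope_tol * abs(m)
    if (!any(ok)) stop("no slope-stable span found")
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- which(r$values)[which.max(r$lengths[r$values])]
    new_run <- starts[best]:ends[best]
    if (identical(new_run, run)) break
    run <- new_run
  }
  i_lo <- centers[run[1]]
  i_hi <- centers[run[length(run)]]

  # refine boundaries pointwise: fit the region-II line on the inner half of
  # the current span (its core, which boundary contamination cannot reach),
  # then take the maximal contiguous run around the core whose residuals stay
  # within 3 robust SDs of that line; iterate to a fixed point
  ab <- NULL
  n_iter <- if (is.infinite(slope_tol)) 0L else 5L # vacuous constraint: keep span
  if (n_iter == 0L) {
    core <- i_lo:i_hi
    ab <- coef(lm(y[core] ~ x[core]))
  }
  for (iter in seq_len(n_iter)) {
    quarter <- (i_hi - i_lo) %/% 4L
    core <- (i_lo + quarter):(i_hi - quarter)
    fit <- lm(y[core] ~ x[core])
    ab <- coef(fit)
    sigma <- stats::mad(fit$residuals)
    tol <- max(3 * sigma, 1e-7 * max(abs(y)), .Machine$double.eps)
    resid_ok <- abs(y - (ab[1] + ab[2] * x)) <= tol
    mid <- (core[1] + core[length(core)]) %/% 2L
    # stop only on two consecutive violations so one noise outlier inside
    # region II cannot truncate it; trim the final boundary back to a point
    # that itself fits the line
    new_lo <- mid
    new_hi <- mid
    while (new_lo > 1L &&
           (resid_ok[new_lo - 1L] || (new_lo > 2L && resid_ok[new_lo - 2L]))) {
      new_lo <- new_lo - 1L
    }
    while (new_hi < n &&
           (resid_ok[new_hi + 1L] || (new_hi < n - 1L && resid_ok[new_hi + 2L]))) {
      new_hi <- new_hi + 1L
    }
    while (new_lo < mid && !resid_ok[new_lo]) new_lo <- new_lo + 1L
    while (new_hi > mid && !resid_ok[new_hi]) new_hi <- new_hi - 1L
    if (new_lo == i_lo && new_hi == i_hi) break
    i_lo <- new_lo
    i_hi <- new_hi
  }

  structure(list(b1 = x[i_lo], b2 = x[i_hi], slope_median = unname(ab[2]),
                 window = window, slope_tol = slope_tol),
            class = "region_segmentation")
}

#' Pointwise mean and SD band of replicate curves
#'
#' Each replicate is linearly interpolated onto the common grid; the band is
#' the pointwise mean with the sample standard deviation (n - 1 denominator).
#'
#' @param curves A `force_curves` data.frame (>= 2 replicates).
#' @param grid Displacement grid, mm; defaults to the grid of the first
#'   replicate restricted to the span shared by all replicates.
#' @return data.frame with `displacement_mm`, `mean_N`, `sd_N`, `n`.
#' @export
mean_curve <- function(curves, grid = NULL) {
  reps <- split(curves, curves$replicate)
  if (length(reps) < 2L) stop("need at least 2 replicate curves")
  lo <- max(vapply(reps, function(r) min(r$displacement_mm), 0))
  hi <- min(vapply(reps, function(r) max(r$displacement_mm), 0))
  if (is.null(grid)) {
    g0 <- reps[[1]]$displacement_mm
    grid <- g0[g0 >= lo & g0 <= hi]
  }
  if (any(grid < lo) || any(grid > hi)) {
    stop("grid extends outside the span of at least one curve")
  }
  mat <- vapply(reps, function(r) {
    approx(r$displacement_mm, r$force_N, xout = grid)$y
  }, numeric(length(grid)))
  data.frame(displacement_mm = grid,
             mean_N = rowMeans(mat),
             sd_N = apply(mat, 1L, sd),
             n = length(reps))
}

#' Ordinary least-squares fit of the region-II mean line
#'
#' `force = a * displacement + b` over the detected region II;
#' `R^2 = 1 - SS_res / SS_tot`. A constant force trace (zero total sum of
#' squares) yields `r_squared = 0` with a warning.
#'
#' @param meanline data.frame from [mean_curve()] (or any curve with
#'   `displacement_mm` and `mean_N`/`force_N`).
#' @param segmentation A `region_segmentation` from [detect_regions()].
#' @return Object of class `region_fit`: list with `a` (N/mm), `b` (N),
#'   `r_squared`, `n_points`, `b1`, `b2`.
#' @export
fit_region2 <- function(meanline, segmentation) {
  stopifnot(inherits(segmentation, "region_segmentation"))
  x <- meanline$displacement_mm
  y <- if ("mean_N" %in% names(meanline)) meanline$mean_N else meanline$force_N
  keep <- x >= segmentation$b1 & x <= segmentation$b2
  if (sum(keep) < 3L) stop("region II contains fewer than 3 grid points")
  x <- x[keep]; y <- y[keep]
  if (var(x) == 0) stop("degenerate region: constant displacement")
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("zero total sum of squares; reporting r_squared = 0")
    r2 <- 0
  } else {
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
  }
  structure(list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 r_squared = r2, n_points = length(x),
                 b1 = segmentation$b1, b2 = segmentation$b2),
            class = "region_fit")
}

#' @export
print.region_fit <- function(x, ...) {
  cat(sprintf("region II fit: a = %.2f N/mm, b = %.2f N, R^2 = %.4f (%d points, %.2f-%.2f mm)\n",
              x$a, x$b, x$r_squared, x$n_points, x$b1, x$b2))
  invisible(x)
}

#' Write a region-II fit report as JSON
#'
#' @param fit A `region_fit`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_region_fit <- function(fit, path) {
  stopifnot(inherits(fit, "region_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
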