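test_that("region boundaries of a noiseless curve are recovered to one grid step", {
  cur <- generate_force_curves(curve_spec(noise_sd = 0, n_replicates = 1L,
                                          seed = 1))
  seg <- detect_regions(cur)
  expect_lt(abs(seg$b1 - 0.5), 0.01 + 1e-12)
  expect_lt(abs(seg$b2 - 2.5), 0.01 + 1e-12)
})

test_that("a purely linear curve is all region II", {
  x <- seq(0, 3, 0.01)
  lin <- data.frame(displacement_mm = x, force_N = 376.49 * x + 209.46)
  seg <- detect_regions(lin)
  expect_equal(seg$b1, 0)
  expect_equal(seg$b2, 3)
  # vacuous slope constraint: the window-trimmed span survives
  cur <- generate_force_curves(curve_spec(noise_sd = 0, n_replicates = 1L,
                                          seed = 1))
  seg_inf <- detect_regions(cur, slope_tol = Inf)
  expect_lte(seg_inf$b1, 0.1 + 1e-12)
  expect_gte(seg_inf$b2, 2.9 - 1e-12)
})

test_that("too-short curves are rejected", {
  x <- seq(0, 0.3, 0.01)
  expect_error(detect_regions(data.frame(displacement_mm = x,
                                         force_N = x)), "3 rolling windows")
})

test_that("mean curve and SD band follow the sample conventions", {
  x <- seq(0, 1, 0.1)
  base <- data.frame(displacement_mm = x, force_N = 100 * x, replicate = 1L)
  identical10 <- do.call(rbind, lapply(1:10, function(r) {
    b <- base; b$replicate <- r; b
  }))
  ml <- mean_curve(identical10)
  expect_equal(ml$mean_N, 100 * x)
  expect_equal(ml$sd_N, rep(0, length(x)))
  # two curves offset +10 / -10: mean midway, sample SD = 10 * sqrt(2)
  two <- rbind(transform(base, force_N = force_N + 10, replicate = 1L),
               transform(base, force_N = force_N - 10, replicate = 2L))
  ml2 <- mean_curve(two)
  expect_equal(ml2$mean_N, 100 * x)
  expect_equal(ml2$sd_N, rep(14.1421356, length(x)), tolerance = 1e-7)
  expect_error(mean_curve(base), "at least 2")
  expect_error(mean_curve(two, grid = seq(-1, 1, 0.1)), "outside")
})

test_that("mean curve commutes with affine force rescaling", {
  cur <- generate_force_curves(curve_spec(n_replicates = 4L, seed = 7))
  ml <- mean_curve(cur)
  cur2 <- cur
  cur2$force_N <- 2.5 * cur$force_N + 40
  ml2 <- mean_curve(cur2)
  expect_equal(ml2$mean_N, 2.5 * ml$mean_N + 40, tolerance = 1e-9)
  expect_equal(ml2$sd_N, 2.5 * ml$sd_N, tolerance = 1e-9)
})

test_that("region-II regression recovers an exact line and flags degeneracy", {
  x <- seq(0, 3, 0.01)
  lin <- data.frame(displacement_mm = x, force_N = 376.49 * x + 209.46)
  fit <- fit_region2(lin, detect_regions(lin))
  expect_equal(fit$a, 376.49, tolerance = 1e-9)
  expect_equal(fit$b, 209.46, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  const <- data.frame(displacement_mm = x, force_N = rep(5, length(x)))
  seg <- structure(list(b1 = 0, b2 = 3), class = "region_segmentation")
  expect_warning(fitc <- fit_region2(const, seg), "zero total sum of squares")
  expect_equal(fitc$r_squared, 0)
})

test_that("regression residuals are orthogonal to displacement", {
  ml <- mean_curve(generate_force_curves(curve_spec(seed = 11)))
  seg <- detect_regions(ml)
  fit <- fit_region2(ml, seg)
  keep <- ml$displacement_mm >= seg$b1 & ml$displacement_mm <= seg$b2
  x <- ml$displacement_mm[keep]
  res <- ml$mean_N[keep] - (fit$a * x + fit$b)
  scale <- sqrt(sum(x^2)) * sqrt(sum(res^2)) + .Machine$double.eps
  expect_lt(abs(sum(res * x)) / scale, 1e-6)
})
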