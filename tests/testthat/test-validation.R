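test_that("FVU satisfies its defining identities", {
  x <- 1:5
  y <- c(2, 4, 5, 4, 6)
  expect_equal(fvu(comparison_series(x, y, y)), 0)
  expect_equal(fvu(comparison_series(x, y, rep(mean(y), 5))), 1)
  # hand-computed: residuals (0,0,1); deviations (-1,0,1)
  expect_equal(fvu(comparison_series(1:3, c(1, 2, 3), c(1, 2, 4))), 0.5)
  expect_error(fvu(comparison_series(1:3, c(2, 2, 2), c(1, 2, 3))),
               "zero total sum of squares")
  expect_error(comparison_series(1:3, 1:2, 1:3), "one grid")
})

test_that("FVU is invariant under a common affine rescaling", {
  set.seed(1)
  x <- seq(0, 1, length.out = 20)
  y <- 3 * x + rnorm(20)
  m <- 3 * x
  v0 <- fvu(comparison_series(x, y, m))
  v1 <- fvu(comparison_series(x, 5 * y - 7, 5 * m - 7))
  expect_equal(v1, v0, tolerance = 1e-12)
})

# scaled-down study conditions: single spike, coarse voxels, small FE domain
tiny_config <- function(seed = 42L) {
  list(seed = seed,
       geometry = list(n_rings = 0L),
       volume = list(shape = c(64L, 64L, 112L), voxel_size = 35,
                     target_marrow_fraction = 0.67, seed = seed + 2L),
       densification = list(zone_radius = 0.4, zone_thickness = 0.8,
                            roi_size = 0.5, roi_depth = 0.6),
       fe = list(domain_radius = 1.0, domain_height = 3.5,
                 element_size = 0.1, insert_thickness = 0.4,
                 levels = c(1.25, 1.5, 2.0, 2.5, 3.0)))
}

test_that("the pipeline runs end to end, deterministically, writing artefacts", {
  dir <- tempfile("pipe")
  rep1 <- run_pipeline(tiny_config(), output_dir = dir)
  expect_s3_class(rep1, "validation_report")
  expect_true(all(c("force_curves.csv", "densitometry_by_level.csv",
                    "validation_report.json") %in% list.files(dir)))
  expect_true(rep1$fvu_initial >= 0 && rep1$fvu_modified >= 0)
  expect_equal(nrow(rep1$density_table), 3L)
  # the measured densification deepens with the embedding level
  expect_true(all(diff(rep1$density_table$phi) < 0))
  expect_true(all(diff(rep1$density_table$E2_MPa) > 0))
  rep2 <- run_pipeline(tiny_config())
  rep2$provenance$config <- rep1$provenance$config
  expect_equal(rep1[names(rep1) != "provenance"],
               rep2[names(rep2) != "provenance"], tolerance = 1e-12)
  expect_equal(rep1$provenance$config_hash, rep2$provenance$config_hash)
  # JSON report is byte-identical across reruns
  f2 <- tempfile(fileext = ".json")
  write_validation_report(rep2, f2)
  expect_identical(readLines(file.path(dir, "validation_report.json")),
                   readLines(f2))
})

test_that("a failing stage reports its name", {
  bad <- tiny_config()
  bad$fe$element_size <- 0.3 # cannot resolve the apex footprints
  err <- tryCatch(run_pipeline(bad), error = function(e) e)
  expect_match(conditionMessage(err), "pipeline stage 'fe_initial' failed")
})
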