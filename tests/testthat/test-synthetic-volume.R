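test_that("generated marrow fraction matches the dial across seeds", {
  for (s in 1:5) {
    g <- generate_trabecular_volume(
      small_volume_spec(target_marrow_fraction = 0.582, seed = s))
    expect_lt(abs(mean(!g$bone_mask) - 0.582), 0.01)
  }
  g2 <- generate_trabecular_volume(
    small_volume_spec(target_marrow_fraction = 0.3, seed = 1))
  expect_lt(abs(mean(!g2$bone_mask) - 0.3), 0.01)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_trabecular_volume(small_volume_spec(seed = 9, n_speckles = 5L))
  b <- generate_trabecular_volume(small_volume_spec(seed = 9, n_speckles = 5L))
  expect_identical(a$bone_mask, b$bone_mask)
  expect_identical(a$volume$voxels, b$volume$voxels)
  c <- generate_trabecular_volume(small_volume_spec(seed = 10, n_speckles = 5L))
  expect_false(identical(a$bone_mask, c$bone_mask))
})

test_that("speckles are isolated single soft voxels inside bone", {
  g <- generate_trabecular_volume(
    volume_spec(shape = c(64L, 64L, 64L), n_speckles = 50L, noise_sd = 0,
                seed = 3))
  expect_length(g$planted$speckles, 50L)
  expect_true(all(!g$bone_mask[g$planted$speckles]))
  labels <- label_components(!g$bone_mask, connectivity = 26L)
  sizes <- tabulate(labels, attr(labels, "n_components"))
  expect_true(all(sizes[labels[g$planted$speckles]] == 1L))
  expect_equal(length(unique(labels[g$planted$speckles])), 50L)
})

test_that("planted canals and lacunae are separate pore components", {
  g <- generate_trabecular_volume(
    volume_spec(shape = c(96L, 96L, 96L), n_canals = 3L, n_lacunae = 15L,
                noise_sd = 0, seed = 5))
  labels <- label_components(!g$bone_mask, connectivity = 26L)
  sizes <- tabulate(labels, attr(labels, "n_components"))
  can <- g$planted$canals
  can_labels <- labels[cbind(can$x, can$y, can$z_mid)]
  expect_equal(length(unique(can_labels)), 3L)
  expect_true(all(sizes[can_labels] > 150L))
  lac <- g$planted$lacunae
  lac_labels <- labels[cbind(lac$x, lac$y, lac$z)]
  expect_equal(length(unique(lac_labels)), 15L)
  expect_true(all(sizes[lac_labels] > 1L & sizes[lac_labels] <= 150L))
  expect_equal(length(intersect(can_labels, lac_labels)), 0L)
})

test_that("volume spec validation rejects bad inputs", {
  expect_error(volume_spec(target_marrow_fraction = 0), "strictly inside")
  expect_error(volume_spec(target_marrow_fraction = 1.2), "strictly inside")
  expect_error(volume_spec(shape = c(8, 48, 48)), "at least 16")
  expect_error(volume_spec(intensity_bone = 50, intensity_soft = 60),
               "intensity_bone")
  expect_error(volume_spec(n_canals = -1), "non-negative")
})

test_that("densification reduces the zone marrow fraction and nothing else", {
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  g <- generate_trabecular_volume(
    volume_spec(shape = c(64L, 64L, 96L), target_marrow_fraction = 0.6,
                noise_sd = 0, seed = 4))
  # identity at delta 0
  out0 <- apply_densification(g$volume, g$bone_mask, lay, embed_depth = 0.6,
                              zone_thickness = 0.5, delta_phi = 0)
  expect_identical(out0$mask, g$bone_mask)
  expect_identical(out0$volume$voxels, g$volume$voxels)

  out <- apply_densification(g$volume, g$bone_mask, lay, embed_depth = 0.6,
                             zone_thickness = 0.5, delta_phi = 0.1,
                             zone_radius = 0.3)
  zr <- out$zone_report
  expect_lt(abs(zr$phi_before - zr$phi_after - 0.1), 1 / zr$n_zone[1])
  # recount directly in the zone
  d <- dim(g$bone_mask)
  vs <- g$volume$voxel_size
  changed <- which(out$mask != g$bone_mask)
  expect_equal(length(changed), round(0.1 * zr$n_zone[1]))
  xyz <- arrayInd(changed, d)
  r_vox <- 0.3 * 1000 / vs
  cc <- round((d[1] + 1) / 2) # zone centre voxel of the axis spike
  expect_true(all((xyz[, 1] - cc)^2 + (xyz[, 2] - cc)^2 <= r_vox^2 + 1e-9))
  z1 <- ceiling(0.6 * 1000 / vs + 1e-9)
  z2 <- ceiling(1.1 * 1000 / vs + 1e-9)
  expect_true(all(xyz[, 3] >= z1 & xyz[, 3] <= z2))
  # only soft -> bone flips
  expect_true(all(out$mask[changed] & !g$bone_mask[changed]))
})

test_that("densification to a target fraction reaches it per zone", {
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  g <- generate_trabecular_volume(
    volume_spec(shape = c(64L, 64L, 96L), target_marrow_fraction = 0.65,
                noise_sd = 0, seed = 8))
  out <- apply_densification(g$volume, g$bone_mask, lay, embed_depth = 0.6,
                             zone_thickness = 0.5, target_phi = 0.45,
                             zone_radius = 0.3)
  expect_equal(out$zone_report$phi_after, 0.45,
               tolerance = 1 / out$zone_report$n_zone[1] + 1e-12)
  expect_error(apply_densification(g$volume, g$bone_mask, lay, 0.6, 0.5,
                                   delta_phi = 0.1, target_phi = 0.4),
               "exactly one")
  expect_error(apply_densification(g$volume, g$bone_mask, lay, 0.6, 0.5,
                                   delta_phi = 0.9),
               "exceeds")
})

test_that("densification zones outside the volume are rejected", {
  lay <- build_spike_layout(scaffold_params(n_rings = 1L))
  g <- generate_trabecular_volume(small_volume_spec(seed = 2))
  expect_error(apply_densification(g$volume, g$bone_mask, lay,
                                   embed_depth = 0.7, zone_thickness = 0.5,
                                   delta_phi = 0.05),
               "outside the volume")
})

test_that("volumes round-trip through NIfTI and TIFF", {
  g <- generate_trabecular_volume(small_volume_spec(seed = 6))
  nii <- tempfile(fileext = ".nii.gz")
  write_ct_volume(g$volume, nii)
  back <- read_ct_volume(nii)
  expect_equal(back$voxels, g$volume$voxels, tolerance = 1e-6)
  expect_equal(back$voxel_size, 17.5, tolerance = 1e-6)
  tif <- tempfile(fileext = ".tif")
  write_tiff_stack(g$volume, tif)
  back2 <- read_tiff_stack(tif, voxel_size = 17.5)
  rescaled <- (g$volume$voxels - min(g$volume$voxels)) /
    diff(range(g$volume$voxels))
  expect_equal(back2$voxels, rescaled, tolerance = 1 / 65535)
})
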