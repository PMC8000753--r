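test_that("fixed-threshold segmentation splits simple volumes as expected", {
  vol <- ct_volume(array(150, c(16, 16, 16)), 17.5)
  expect_warning(seg <- segment_bone(vol, method = "fixed", threshold = 100),
                 "bone fraction")
  expect_true(all(seg$bone_mask))
  expect_equal(marrow_fraction(seg), 0)

  half <- array(rep(c(60, 180), each = 8 * 16 * 16 / 16), c(16, 16, 16))
  half <- array(60, c(16, 16, 16))
  half[9:16, , ] <- 180
  seg2 <- segment_bone(ct_volume(half, 17.5), method = "fixed", threshold = 120)
  expect_equal(mean(!seg2$bone_mask), 0.5)
})

test_that("Otsu segmentation recovers the ground-truth bone mask", {
  g <- generate_trabecular_volume(
    volume_spec(shape = c(64L, 64L, 64L), noise_sd = 8, seed = 13))
  seg <- segment_bone(g$volume, method = "otsu")
  expect_gt(mean(seg$bone_mask == g$bone_mask), 0.99)
  expect_gt(seg$threshold, 60)
  expect_lt(seg$threshold, 180)
})

test_that("single-voxel noise removal is exact and idempotent", {
  g <- generate_trabecular_volume(
    volume_spec(shape = c(64L, 64L, 64L), n_speckles = 50L, n_lacunae = 10L,
                noise_sd = 0, seed = 3))
  seg <- segment_bone(g$volume, method = "fixed", threshold = 120)
  seg1 <- remove_noise_objects(seg)
  expect_equal(seg1$n_noise_removed, 50L)
  expect_true(all(seg1$bone_mask[g$planted$speckles]))
  # larger pores untouched
  lac <- g$planted$lacunae
  expect_true(all(!seg1$bone_mask[cbind(lac$x, lac$y, lac$z)]))
  seg2 <- remove_noise_objects(seg1)
  expect_identical(seg2$bone_mask, seg1$bone_mask)
  expect_equal(length(seg2$pore_sizes), length(seg1$pore_sizes))
})

test_that("pore classification applies the size rule", {
  # one 10-voxel blob and one 5000-voxel tube in a bone block
  m <- array(TRUE, c(30, 30, 80))
  m[5:14, 10, 10] <- FALSE       # 10-voxel blob
  m[21:23, 21:25, 6:72] <- FALSE # 3*5*67 = 1005-voxel tube
  vol <- ct_volume(array(ifelse(m, 180, 60), dim(m)), 17.5)
  seg <- segment_bone(vol, method = "fixed", threshold = 120)
  seg <- remove_noise_objects(seg)
  seg <- classify_pores(seg, lacuna_max_voxels = 100L)
  expect_equal(sort(as.character(seg$classes)), c("canal", "lacuna"))
  expect_equal(as.character(seg$classes[seg$pore_sizes == 10L]), "lacuna")
  expect_error(classify_pores(seg, lacuna_max_voxels = 1L), "exceed")
})

test_that("marrow fraction discards the first and last ROI slices", {
  m <- array(TRUE, c(10, 10, 8))
  m[, , c(1, 8)] <- FALSE        # soft end slices must not contribute
  m[1:5, , 2:7] <- FALSE         # interior half soft
  vol <- ct_volume(array(ifelse(m, 200, 50), dim(m)), 17.5)
  seg <- segment_bone(vol, method = "fixed", threshold = 120)
  expect_equal(marrow_fraction(seg), 0.5)
  expect_equal(marrow_fraction(seg, list(x = c(1, 10), y = c(1, 10),
                                         z = c(1, 8))), 0.5)
  expect_error(marrow_fraction(seg, list(x = c(1, 10), y = c(1, 10),
                                         z = c(3, 4))), "3 slices")
  expect_error(marrow_fraction(seg, list(x = c(0, 10), y = c(1, 10),
                                         z = c(1, 8))), "inside the volume")
})

test_that("measured marrow fraction matches the generator ground truth", {
  g <- generate_trabecular_volume(
    volume_spec(shape = c(64L, 64L, 64L), target_marrow_fraction = 0.582,
                noise_sd = 8, seed = 21))
  seg <- segment_bone(g$volume)
  expect_lt(abs(marrow_fraction(seg) - 0.582), 0.02)
})

test_that("density chain reproduces the reference table values", {
  k <- density_constants()
  expect_equal(bone_density(0.582, k), 1.3762, tolerance = 1e-12)
  expect_equal(round(longitudinal_modulus(bone_density(0.582, k), k)), 821)
  expect_equal(round(bone_density(0.491, k), 2), 1.46)
  expect_equal(longitudinal_modulus(bone_density(0.491, k), k), 976.5,
               tolerance = 1e-3)
  expect_equal(bone_density(1, k), 1.00)
  expect_equal(bone_density(0, k), 1.90)
  expect_equal(longitudinal_modulus(1, k), 315)
  expect_error(bone_density(1.2, k), "phi")
  expect_error(longitudinal_modulus(-1, k), "positive")
})

test_that("the density-modulus chain is monotone in the marrow fraction", {
  k <- density_constants()
  phis <- seq(0, 1, 0.05)
  rhos <- bone_density(phis, k)
  mods <- longitudinal_modulus(rhos, k)
  expect_true(all(diff(rhos) < 0))
  expect_true(all(diff(mods) < 0))
  expect_true(all(rhos >= k$rho_w & rhos <= k$rho_T))
})

test_that("periapical ROIs sit under each apex and stay disjoint", {
  lay <- build_spike_layout(scaffold_params(n_rings = 1L))
  g <- generate_trabecular_volume(
    volume_spec(shape = c(160L, 160L, 96L), noise_sd = 0, seed = 2))
  rois <- periapical_rois(lay, g$volume, embed_depth = 0.5, roi_size = 0.4)
  expect_length(rois, nrow(lay$spikes))
  boxes <- do.call(rbind, lapply(rois, function(r) c(r$x, r$y)))
  for (i in seq_len(nrow(boxes) - 1)) {
    for (j in (i + 1):nrow(boxes)) {
      overlap_x <- boxes[i, 1] <= boxes[j, 2] && boxes[j, 1] <= boxes[i, 2]
      overlap_y <- boxes[i, 3] <= boxes[j, 4] && boxes[j, 3] <= boxes[i, 4]
      expect_false(overlap_x && overlap_y)
    }
  }
  expect_error(periapical_rois(lay, g$volume, embed_depth = 1.5,
                               roi_size = 0.4), "clipped")
})

test_that("density report rounds for presentation but not in the chain", {
  g <- generate_trabecular_volume(small_volume_spec(seed = 14))
  seg <- segment_bone(g$volume, method = "fixed", threshold = 120)
  rois <- list(all = list(x = c(1, 48), y = c(1, 48), z = c(1, 48)))
  rep <- density_report(seg, rois)
  expect_equal(rep$E2_MPa, 315 * rep$rho_b_g_cm3^3, tolerance = 1e-12)
  paths <- write_density_report(rep, tempfile(), seg)
  csv <- read.csv(paths[1])
  expect_equal(csv$rho_b_g_cm3, round(rep$rho_b_g_cm3, 2))
  expect_equal(csv$E2_MPa, round(rep$E2_MPa))
})
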