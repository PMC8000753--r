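test_that("transversely isotropic stiffness reduces to the isotropic closed form", {
  E <- 500; nu <- 0.25
  iso <- elastic_constants(E1 = E, E2 = E, G1 = E / (2 * (1 + nu)),
                           G2 = E / (2 * (1 + nu)), nu1 = nu, nu2 = nu)
  expect_lt(max(abs(stiffness_matrix(iso) - isotropic_stiffness_oracle(E, nu))),
            1e-9)
  C <- stiffness_matrix(elastic_constants())
  expect_equal(C, t(C))
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(elastic_constants(nu1 = 0.6), "Poisson")
  expect_error(elastic_constants(E2 = -5), "positive")
})

test_that("HMH equivalent stress matches its closed forms", {
  expect_equal(hmh_stress(c(7, 0, 0, 0, 0, 0)), 7)
  expect_equal(hmh_stress(diag(3) * 5), 0)
  expect_equal(hmh_stress(c(0, 0, 0, 0, 0, 3)), sqrt(3) * 3)
  sig <- matrix(0, 3, 3); sig[1, 2] <- sig[2, 1] <- 2
  expect_equal(hmh_stress(sig), sqrt(3) * 2)
  expect_true(all(hmh_stress(matrix(rnorm(60), 10, 6)) >= 0))
})

test_that("element stiffness matches an independent quadrature oracle", {
  C <- stiffness_matrix(default_bone())
  set.seed(42)
  for (i in 1:10) {
    coords <- random_parallelepiped()
    ke <- hex_stiffness(coords, C)
    expect_equal(ke, t(ke), tolerance = 1e-12)
    ko <- hex_stiffness_oracle(coords, C)
    expect_lt(max(abs(ke - ko)) / max(abs(ko)), 1e-6)
  }
})

test_that("a single element under uniform axial strain is in a uniform stress state", {
  C <- stiffness_matrix(default_bone())
  coords <- (hex_corner_signs_test() + 1) / 2   # unit cube
  eps <- -0.001
  ue <- as.vector(t(cbind(0, 0, eps * coords[, 3])))
  sig <- element_stress(coords, C, ue)
  expected <- as.numeric(C %*% c(0, 0, eps, 0, 0, 0))
  for (q in 1:8) expect_equal(unname(sig[q, ]), expected, tolerance = 1e-10)
})

test_that("structured meshes have the expected counts and scaling", {
  m <- build_box_mesh(c(1, 1, 1), 0.5)
  expect_equal(nrow(m$elems), 8L)
  expect_equal(nrow(m$nodes), 27L)
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  m1 <- build_mesh(1.2, 2.4, lay, 1.5, 0.1)
  m2 <- build_mesh(1.2, 2.4, lay, 1.5, 0.05)
  ratio <- nrow(m2$elems) / nrow(m1$elems)
  expect_gt(ratio, 6.5)
  expect_lt(ratio, 9.5)
  expect_true(all(lengths(m2$footprints) > 0))
  expect_error(build_mesh(1.2, 2.4, lay, 0.2, 0.2), "resolve")
})

test_that("uniaxial bar reaction matches the transversely isotropic closed form", {
  bone <- default_bone()
  mesh <- build_box_mesh(c(1, 1, 10), 0.5)
  res <- solve_embedding(assemble_system(mesh, bone), mesh, 0.01)
  # uniaxial stress: R = E2 * A * delta / L = 771 * 1 * 0.001
  expect_equal(abs(res$reaction_footprint_N), 0.771, tolerance = 1e-6)
  expect_lt(res$residual_balance, 1e-6)
  expect_equal(max(res$hmh_elem), 0.771, tolerance = 1e-6)
  expect_equal(min(res$hmh_elem), 0.771, tolerance = 1e-6)
  # exact for a linear field: coarse and fine meshes agree
  mesh2 <- build_box_mesh(c(1, 1, 10), 0.25)
  res2 <- solve_embedding(assemble_system(mesh2, bone), mesh2, 0.01)
  expect_equal(abs(res2$reaction_footprint_N), 0.771, tolerance = 1e-6)
})

test_that("the solve is linear and zero input gives zero output", {
  bone <- default_bone()
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  mesh <- build_mesh(1.0, 2.5, lay, 1.5, 0.1)
  sys <- assemble_system(mesh, bone)
  r0 <- solve_embedding(sys, mesh, 0)
  expect_equal(max(abs(r0$u)), 0)
  expect_equal(r0$reaction_footprint_N, 0)
  r1 <- solve_embedding(sys, mesh, 0.005)
  r2 <- solve_embedding(sys, mesh, 0.01)
  expect_equal(2 * r1$reaction_footprint_N, r2$reaction_footprint_N,
               tolerance = 1e-9)
  expect_equal(2 * r1$u, r2$u, tolerance = 1e-9)
  expect_lt(r1$residual_balance, 1e-6)
  # energy positivity
  u <- as.vector(t(r1$u))
  expect_gt(as.numeric(u %*% (sys$K %*% u)), 0)
})

test_that("embedding force scales with the limit stress and grows with depth", {
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  bone <- default_bone()
  mesh <- build_mesh(1.0, 2.5, lay, 1.5, 0.1)
  res <- solve_embedding(assemble_system(mesh, bone), mesh, 0.01)
  f1 <- embedding_force(res, bone)
  f2 <- embedding_force(res, elastic_constants(sigma_c = 50))
  expect_equal(f2$force_N, 2 * f1$force_N, tolerance = 1e-12)
  expect_equal(f1$force_N,
               bone$sigma_c / f1$hmh_ref * abs(res$reaction_footprint_N) * 4,
               tolerance = 1e-12)
  forces <- vapply(c(1.0, 1.75, 2.5), function(d) {
    m <- build_mesh(1.2, 3.0, lay, d, 0.09)
    embedding_force(solve_embedding(assemble_system(m, bone), m, 0.01),
                    bone)$force_N
  }, 0)
  expect_true(all(diff(forces) > 0))
})

test_that("the densified insert stiffens the response and is validated", {
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  bone <- default_bone()
  mesh <- build_mesh(1.0, 2.5, lay, 1.5, 0.1)
  r0 <- solve_embedding(assemble_system(mesh, bone), mesh, 0.01)
  mesh_i <- add_densified_insert(mesh, 0.4)
  expect_gt(length(mesh_i$element_sets$densified_insert), 0)
  # insert with bulk properties: identical solution
  r_same <- solve_embedding(assemble_system(mesh_i, bone, bone), mesh_i, 0.01)
  expect_equal(r_same$u, r0$u, tolerance = 1e-12)
  # stiffer insert: strictly larger reaction at fixed displacement
  ratio <- 1144 / bone$E2
  ins <- elastic_constants(E1 = bone$E1 * ratio, E2 = 1144,
                           G1 = bone$G1 * ratio, G2 = bone$G2 * ratio,
                           nu1 = bone$nu1, nu2 = bone$nu2)
  r1 <- solve_embedding(assemble_system(mesh_i, bone, ins), mesh_i, 0.01)
  expect_gt(abs(r1$reaction_footprint_N), abs(r0$reaction_footprint_N))
  expect_error(add_densified_insert(mesh, 0), "empty")
  expect_error(add_densified_insert(mesh, 5), "fit")
})

test_that("mesh convergence reports one row per size with shrinking changes", {
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  conv <- mesh_convergence(0.8, 1.6, lay, 0.8, sizes = c(0.08, 0.05, 0.04),
                           bone = default_bone(), delta = 0.005)
  expect_equal(nrow(conv), 3L)
  expect_true(is.na(conv$rel_change_reaction[1]))
  expect_true(all(diff(conv$n_elements) > 0))
  expect_lt(conv$rel_change_reaction[3], conv$rel_change_reaction[2])
})

test_that("mesh and fields export as a readable VTK unstructured grid", {
  lay <- build_spike_layout(scaffold_params(n_rings = 0L))
  mesh <- build_mesh(0.8, 1.6, lay, 0.8, 0.08)
  res <- solve_embedding(assemble_system(mesh, default_bone()), mesh, 0.01)
  path <- tempfile(fileext = ".vtk")
  write_fe_vtk(mesh, path, res)
  lines <- readLines(path)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_equal(sum(grepl("^VECTORS displacement", lines)), 1L)
  expect_equal(sum(grepl("^SCALARS hmh_stress", lines)), 1L)
  expect_equal(as.integer(strsplit(grep("^POINTS", lines, value = TRUE),
                                   " ")[[1]][2]), nrow(mesh$nodes))
})
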