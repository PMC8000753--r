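# Trilinear hexahedral finite elements, 2x2x2 Gauss quadrature, small-strain
# linear elasticity. All elements of a structured mesh are congruent bricks,
# so one element stiffness serves the whole mesh.

# Shape-function derivatives wrt natural coords at a natural point (8 x 3).
hex_dshape <- function(xi) {
  s <- hex_corner_signs
  cbind(s[, 1] * (1 + s[, 2] * xi[2]) * (1 + s[, 3] * xi[3]),
        s[, 2] * (1 + s[, 1] * xi[1]) * (1 + s[, 3] * xi[3]),
        s[, 3] * (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2])) / 8
}

gauss_points <- function(n = 2L) {
  g1 <- if (n == 2L) c(-1, 1) / sqrt(3) else c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  w1 <- if (n == 2L) c(1, 1) else c(5, 8, 5) / 9
  g <- expand.grid(x = g1, y = g1, z = g1)
  list(points = as.matrix(g),
       weights = apply(expand.grid(w1, w1, w1), 1L, prod))
}

# Strain-displacement matrix (6 x 24, Voigt 11,22,33,23,13,12 with
# engineering shears) and Jacobian determinant at a natural point.
hex_bmatrix <- function(coords, xi) {
  dN <- hex_dshape(xi)
  J <- t(dN) %*% coords # J[i, j] = dx_j / dxi_i
  detJ <- det(J)
  if (detJ <= 0) stop("inverted element (non-positive Jacobian)")
  dNdx <- dN %*% solve(t(J))
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix] <- dNdx[, 1]
  B[2, ix + 1] <- dNdx[, 2]
  B[3, ix + 2] <- dNdx[, 3]
  B[4, ix + 1] <- dNdx[, 3]; B[4, ix + 2] <- dNdx[, 2]
  B[5, ix] <- dNdx[, 3];     B[5, ix + 2] <- dNdx[, 1]
  B[6, ix] <- dNdx[, 2];     B[6, ix + 1] <- dNdx[, 1]
  list(B = B, detJ = detJ)
}

#' Element stiffness of an 8-node hexahedron
#'
#' `ke = sum_gp B' C B detJ w` over 2x2x2 Gauss points. Node order follows
#' the VTK hexahedron convention; dof order is (n1x, n1y, n1z, n2x, ...).
#'
#' @param coords 8 x 3 matrix of node coordinates, mm.
#' @param C 6x6 stiffness matrix, MPa (see [stiffness_matrix()]).
#' @return 24 x 24 symmetric element stiffness (N/mm).
#' @export
hex_stiffness <- function(coords, C) {
  gp <- gauss_points(2L)
  ke <- matrix(0, 24, 24)
  for (q in seq_len(nrow(gp$points))) {
    bq <- hex_bmatrix(coords, gp$points[q, ])
    ke <- ke + crossprod(bq$B, C %*% bq$B) * bq$detJ * gp$weights[q]
  }
  (ke + t(ke)) / 2
}

#' Stresses of a single hexahedral element at its Gauss points
#'
#' Recovers `sigma = C B u` at each of the 2x2x2 Gauss points; mainly a
#' verification tool (patch tests, constitutive checks).
#'
#' @param coords 8 x 3 node coordinates (VTK order), mm.
#' @param C 6x6 stiffness, MPa.
#' @param ue Length-24 element displacement vector (n1x, n1y, n1z, ...), mm.
#' @return 8 x 6 matrix of Voigt stresses (11, 22, 33, 23, 13, 12), MPa.
#' @export
element_stress <- function(coords, C, ue) {
  gp <- gauss_points(2L)
  t(vapply(seq_len(nrow(gp$points)), function(q) {
    bq <- hex_bmatrix(coords, gp$points[q, ])
    as.numeric(C %*% (bq$B %*% ue))
  }, numeric(6)))
}

elem_dofs <- function(elems) {
  nelem <- nrow(elems)
  edof <- matrix(0L, nelem, 24L)
  for (a in 1:8) {
    edof[, 3 * a - 2] <- 3L * (elems[, a] - 1L) + 1L
    edof[, 3 * a - 1] <- 3L * (elems[, a] - 1L) + 2L
    edof[, 3 * a]     <- 3L * elems[, a]
  }
  edof
}

#' Assemble the global stiffness system
#'
#' Builds the sparse global stiffness from the transversely isotropic bone
#' constants (longitudinal axis = z, the spike axis). Elements tagged as the
#' densified insert use the insert constants instead.
#'
#' @param mesh An `fe_mesh`.
#' @param bone [elastic_constants()] of the bulk bone.
#' @param insert Optional [elastic_constants()] for the
#'   `densified_insert` element set.
#' @return Object of class `fe_system`: sparse `K` (dgCMatrix, N/mm),
#'   `ndof`, the materials, and per-element B matrices for stress recovery.
#' @export
assemble_system <- function(mesh, bone, insert = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(bone, "elastic_constants"))
  C_bulk <- stiffness_matrix(bone)
  ndof <- 3L * nrow(mesh$nodes)
  h <- mesh$h
  coords <- (hex_corner_signs + 1) / 2 * rep(h, each = 8)
  ke_bulk <- hex_stiffness(coords, C_bulk)
  nelem <- nrow(mesh$elems)
  edof <- elem_dofs(mesh$elems)

  ins <- mesh$element_sets$densified_insert
  kes <- list(list(ke = ke_bulk, elems = setdiff(seq_len(nelem), ins)))
  C_ins <- NULL
  if (length(ins)) {
    if (is.null(insert)) {
      kes[[1]]$elems <- seq_len(nelem)
    } else {
      stopifnot(inherits(insert, "elastic_constants"))
      C_ins <- stiffness_matrix(insert)
      kes[[2]] <- list(ke = hex_stiffness(coords, C_ins), elems = ins)
    }
  } else {
    kes[[1]]$elems <- seq_len(nelem)
  }

  ii <- jj <- xx <- vector("list", length(kes))
  col_r <- rep(1:24, times = 24)
  col_c <- rep(1:24, each = 24)
  for (k in seq_along(kes)) {
    e <- kes[[k]]$elems
    if (!length(e)) next
    ii[[k]] <- as.vector(edof[e, col_r])
    jj[[k]] <- as.vector(edof[e, col_c])
    xx[[k]] <- rep(as.vector(kes[[k]]$ke), each = length(e))
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  # precompute C*B at each Gauss point of the canonical brick for recovery
  gp <- gauss_points(2L)
  CB_bulk <- lapply(seq_len(nrow(gp$points)), function(q) {
    C_bulk %*% hex_bmatrix(coords, gp$points[q, ])$B
  })
  CB_ins <- if (is.null(C_ins)) NULL else
    lapply(seq_len(nrow(gp$points)), function(q) {
      C_ins %*% hex_bmatrix(coords, gp$points[q, ])$B
    })
  structure(list(K = K, ndof = ndof, edof = edof,
                 CB_bulk = CB_bulk, CB_ins = CB_ins,
                 bone = bone, insert = insert),
            class = "fe_system")
}

# Dirichlet constraint table for a mesh: dof indices and prescribed values.
mesh_constraints <- function(mesh, delta) {
  dof <- function(nodes, k) 3L * (nodes - 1L) + k
  cdof <- c(if (mesh$base_type == "fixed") c(dof(mesh$sets$fixed_base, 1L),
                                             dof(mesh$sets$fixed_base, 2L)),
            dof(mesh$sets$fixed_base, 3L),
            dof(mesh$sets$symmetry_x, 1L),
            dof(mesh$sets$symmetry_y, 2L))
  cval <- rep(0, length(cdof))
  fp <- unique(unlist(mesh$footprints))
  cdof <- c(cdof, dof(fp, 3L))
  cval <- c(cval, rep(-delta, length(fp)))
  keep <- !duplicated(cdof)
  # a footprint node z-dof also in the base set would be contradictory
  dup <- duplicated(cdof) | duplicated(cdof, fromLast = TRUE)
  if (any(dup)) {
    vals <- split(c(cval), cdof)[as.character(unique(cdof[dup]))]
    if (any(vapply(vals, function(v) max(v) - min(v) > 0, TRUE))) {
      stop("conflicting prescribed values on a dof")
    }
  }
  list(dof = cdof[keep], val = cval[keep])
}

#' Solve the embedding problem for a prescribed apex displacement
#'
#' Boundary conditions: the cylinder base fixed in all directions (or on
#' rollers for block benchmarks), zero normal displacement on the two
#' symmetry planes, and the prescribed axial displacement on every apex
#' footprint node (the rigid-scaffold contact simplification). Sparse
#' Cholesky solve; reactions are recovered as `K u` on the constrained dofs.
#'
#' @param system An `fe_system` from [assemble_system()].
#' @param mesh The `fe_mesh` the system was assembled on.
#' @param prescribed_apex_displacement Axial displacement magnitude, mm
#'   (applied downwards).
#' @return Object of class `fe_result`: `u` (n x 3, mm), `hmh_elem`
#'   (per-element peak equivalent stress, MPa), `footprint_peak_hmh` (per
#'   spike, MPa), `reaction_footprint_N` (axial reaction summed over footprint
#'   nodes of the meshed domain), `reaction_base_N`, `residual_balance`
#'   (relative force imbalance), `embed_level` (mm), `delta` (mm).
#' @export
solve_embedding <- function(system, mesh, prescribed_apex_displacement) {
  stopifnot(inherits(system, "fe_system"), inherits(mesh, "fe_mesh"))
  delta <- prescribed_apex_displacement
  stopifnot(is.finite(delta), delta >= 0)
  con <- mesh_constraints(mesh, delta)
  ndof <- system$ndof
  free <- setdiff(seq_len(ndof), con$dof)
  u <- numeric(ndof)
  u[con$dof] <- con$val
  if (delta != 0) {
    Kff <- Matrix::forceSymmetric(system$K[free, free])
    rhs <- -system$K[free, con$dof, drop = FALSE] %*% con$val
    uf <- tryCatch({
      # supernodal Cholesky: much faster than the simplicial default on 3-D
      # elasticity sparsity patterns
      ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
      Matrix::solve(ch, rhs)
    }, error = function(e) stop("singular system (insufficient constraints): ",
                                conditionMessage(e)))
    u[free] <- as.numeric(uf)
  }
  r <- as.numeric(system$K %*% u)
  zdofs <- function(nodes) 3L * (nodes - 1L) + 3L
  fp_nodes <- unique(unlist(mesh$footprints))
  reaction_fp <- sum(r[zdofs(fp_nodes)])
  reaction_base <- sum(r[zdofs(mesh$sets$fixed_base)])
  total_z <- sum(r[con$dof[con$dof %% 3L == 0L]])
  scale_f <- max(abs(reaction_fp), abs(reaction_base), .Machine$double.eps)

  # stress recovery on the congruent brick elements
  Ue <- matrix(u[system$edof], nrow = nrow(system$edof))
  hmh <- matrix(0, nrow(Ue), length(system$CB_bulk))
  ins <- mesh$element_sets$densified_insert
  use_ins <- !is.null(system$CB_ins) && length(ins)
  for (q in seq_along(system$CB_bulk)) {
    sig <- Ue %*% t(system$CB_bulk[[q]])
    if (use_ins) sig[ins, ] <- Ue[ins, , drop = FALSE] %*% t(system$CB_ins[[q]])
    hmh[, q] <- hmh_stress(sig)
  }
  hmh_elem <- apply(hmh, 1L, max)

  # Per-footprint peak of the bone-material stress on the periapical contact:
  # elements in the vertical columns under the footprint nodes, in the two
  # element layers directly beneath the contact. The limit strength sigma_c
  # characterises the bulk bone, so when a densified insert (denser, hence
  # stronger material) is present the criterion band sits directly beneath it.
  z_top <- mesh$z_apex - if (use_ins) mesh$insert_thickness else 0
  cz <- mesh$cell_centers[, 3]
  band <- cz < z_top & cz > z_top - 2 * mesh$h[3] - 1e-9
  if (use_ins) band[ins] <- FALSE
  key <- function(x, y) round(x / mesh$h[1]) * 1e6 + round(y / mesh$h[2])
  node_key <- key(mesh$nodes[, "x"], mesh$nodes[, "y"])
  elem_key <- matrix(node_key[mesh$elems], nrow = nrow(mesh$elems))
  fp_peak <- vapply(mesh$footprints, function(nodes) {
    in_col <- rowSums(matrix(elem_key %in% node_key[nodes],
                             nrow = nrow(elem_key))) > 0L
    cand <- which(band & in_col)
    if (!length(cand)) stop("no bone-material elements beneath a footprint")
    max(hmh_elem[cand])
  }, 0)

  structure(list(u = matrix(u, ncol = 3L, byrow = TRUE),
                 hmh_elem = hmh_elem,
                 footprint_peak_hmh = fp_peak,
                 reaction_footprint_N = reaction_fp,
                 reaction_base_N = reaction_base,
                 residual_balance = abs(total_z) / scale_f,
                 embed_level = mesh$embed_depth,
                 delta = delta,
                 symmetry_factor = mesh$symmetry_factor),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("fe_result: level %.2f mm, delta %.4g mm, footprint reaction %.4g N, peak HMH %.4g MPa\n",
              x$embed_level, x$delta, x$reaction_footprint_N,
              max(x$footprint_peak_hmh)))
  invisible(x)
}

#' Embedding force from the limit-stress criterion
#'
#' The embedding force at a level is the force at which the mean of the
#' per-footprint maximum equivalent (HMH) stresses on the periapical contact
#' reaches the bone's ultimate compressive strength `sigma_c`. The linear
#' solution is rescaled so that mean peak equals `sigma_c`, and the scaled
#' axial reaction (times the symmetry factor of the quarter model) is
#' reported.
#'
#' @param result An `fe_result`.
#' @param bone The [elastic_constants()] providing `sigma_c`.
#' @return List with `force_N` (full-model embedding force), `scale`
#'   (applied to the linear solution), `hmh_ref` (mean per-footprint peak at
#'   the solved displacement), `delta_at_limit_mm`.
#' @export
embedding_force <- function(result, bone) {
  stopifnot(inherits(result, "fe_result"), inherits(bone, "elastic_constants"))
  hmh_ref <- mean(result$footprint_peak_hmh)
  if (!is.finite(hmh_ref) || hmh_ref <= .Machine$double.eps) {
    stop("degenerate load: zero periapical stress")
  }
  s <- bone$sigma_c / hmh_ref
  list(force_N = s * abs(result$reaction_footprint_N) * result$symmetry_factor,
       scale = s,
       hmh_ref = hmh_ref,
       delta_at_limit_mm = s * result$delta)
}

#' Mesh convergence study
#'
#' Re-runs the embedding solve over a decreasing sequence of element sizes
#' and reports the axial reaction and the peak periapical equivalent stress,
#' with successive relative changes; converged when both changes drop below
#' `tol`. Non-convergence is reported in the returned table, never silently
#' accepted.
#'
#' @param domain_radius,domain_height,layout,embed_depth As [build_mesh()].
#' @param sizes Decreasing element sizes, mm (>= 3 values).
#' @param bone [elastic_constants()].
#' @param delta Prescribed apex displacement, mm.
#' @param tol Relative-change tolerance (default 0.05).
#' @return data.frame with one row per size: `element_size`, `n_elements`,
#'   `reaction_N`, `peak_hmh_MPa`, `rel_change_reaction`, `rel_change_hmh`,
#'   `converged`.
#' @export
mesh_convergence <- function(domain_radius, domain_height, layout, embed_depth,
                             sizes, bone, delta = 0.01, tol = 0.05) {
  stopifnot(length(sizes) >= 3L, all(diff(sizes) < 0))
  rows <- lapply(sizes, function(hsz) {
    mesh <- build_mesh(domain_radius, domain_height, layout, embed_depth, hsz)
    res <- solve_embedding(assemble_system(mesh, bone), mesh, delta)
    data.frame(element_size = hsz, n_elements = nrow(mesh$elems),
               reaction_N = abs(res$reaction_footprint_N),
               peak_hmh_MPa = max(res$footprint_peak_hmh))
  })
  out <- do.call(rbind, rows)
  out$rel_change_reaction <- c(NA, abs(diff(out$reaction_N)) / head(out$reaction_N, -1))
  out$rel_change_hmh <- c(NA, abs(diff(out$peak_hmh_MPa)) / head(out$peak_hmh_MPa, -1))
  out$converged <- !is.na(out$rel_change_reaction) &
    out$rel_change_reaction < tol & out$rel_change_hmh < tol
  out
}
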