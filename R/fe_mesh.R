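# Structured hexahedral meshes. Elements are axis-aligned bricks (stair-step
# approximation of curved boundaries); node order within an element follows
# the VTK hexahedron convention.

hex_corner_signs <- matrix(c(-1, -1, -1,
                             +1, -1, -1,
                             +1, +1, -1,
                             -1, +1, -1,
                             -1, -1, +1,
                             +1, -1, +1,
                             +1, +1, +1,
                             -1, +1, +1), ncol = 3, byrow = TRUE)

# Full structured grid over [0,Lx]x[0,Ly]x[0,Lz]; keep_elem is a logical
# vector over cells (column-major in (ix, iy, iz)).
structured_mesh <- function(ncell, h, keep_elem = NULL) {
  nx <- ncell[1]; ny <- ncell[2]; nz <- ncell[3]
  nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L
  node_id <- function(ix, iy, iz) (iz - 1L) * nnx * nny + (iy - 1L) * nnx + ix
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  if (!is.null(keep_elem)) cells <- cells[keep_elem, , drop = FALSE]
  elems <- cbind(node_id(cells$ix,      cells$iy,      cells$iz),
                 node_id(cells$ix + 1L, cells$iy,      cells$iz),
                 node_id(cells$ix + 1L, cells$iy + 1L, cells$iz),
                 node_id(cells$ix,      cells$iy + 1L, cells$iz),
                 node_id(cells$ix,      cells$iy,      cells$iz + 1L),
                 node_id(cells$ix + 1L, cells$iy,      cells$iz + 1L),
                 node_id(cells$ix + 1L, cells$iy + 1L, cells$iz + 1L),
                 node_id(cells$ix,      cells$iy + 1L, cells$iz + 1L))
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nnx * nny * nnz)
  remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 8L)
  g <- expand.grid(ix = seq_len(nnx), iy = seq_len(nny), iz = seq_len(nnz))
  nodes <- cbind(x = (g$ix[used] - 1) * h[1],
                 y = (g$iy[used] - 1) * h[2],
                 z = (g$iz[used] - 1) * h[3])
  list(nodes = nodes, elems = elems, h = h, ncell = ncell,
       cell_centers = cbind((cells$ix - 0.5) * h[1],
                            (cells$iy - 0.5) * h[2],
                            (cells$iz - 0.5) * h[3]))
}

#' Build the quarter-cylinder embedding mesh
#'
#' A quarter cylinder of bone (symmetry planes x = 0 and y = 0) meshed with
#' uniform 8-node hexahedra; cells whose centre falls outside the cylinder
#' radius are dropped (stair-step boundary). The apex plane sits at height
#' `domain_height - embed_depth` (snapped to the nearest node plane) and one
#' footprint node set is built per spike of the quarter layout: the nodes of
#' that plane within the spike's section radius at the embedding depth.
#'
#' @param domain_radius,domain_height Bone cylinder radius and height, mm.
#' @param layout A `spike_layout`; spikes with centres in the first quadrant
#'   (including the symmetry planes) are used.
#' @param embed_depth Embedding depth of the apexes below the top surface, mm.
#' @param element_size Target element edge, mm; each footprint must span at
#'   least two elements across its diameter.
#' @return Object of class `fe_mesh`: nodes (mm), elems (VTK hex order), node
#'   sets (`fixed_base`, `symmetry_x`, `symmetry_y`), `footprints` (list per
#'   spike), element set `densified_insert` (empty until
#'   [add_densified_insert()]), `z_apex`, `embed_depth`, `symmetry_factor` = 4.
#' @export
build_mesh <- function(domain_radius, domain_height, layout, embed_depth,
                       element_size) {
  stopifnot(domain_radius > 0, domain_height > 0, element_size > 0,
            inherits(layout, "spike_layout"),
            embed_depth > 0, embed_depth < domain_height)
  sp <- layout$spikes
  quarter <- sp[sp$center_x >= -1e-9 & sp$center_y >= -1e-9, , drop = FALSE]
  r_sec <- spike_section_radius(layout, embed_depth)[
    sp$center_x >= -1e-9 & sp$center_y >= -1e-9]
  if (max(quarter$center_x^2 + quarter$center_y^2) > domain_radius^2) {
    stop("layout extends beyond the domain radius")
  }
  if (any(2 * r_sec < 2 * element_size - 1e-9)) {
    stop("element_size does not resolve the apex footprints ",
         "(need >= 2 elements across each footprint)")
  }
  nx <- max(2L, ceiling(domain_radius / element_size))
  nz <- max(2L, ceiling(domain_height / element_size))
  h <- c(domain_radius / nx, domain_radius / nx, domain_height / nz)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(nx), iz = seq_len(nz))
  cx <- (grid$ix - 0.5) * h[1]
  cy <- (grid$iy - 0.5) * h[2]
  keep <- cx^2 + cy^2 <= domain_radius^2
  mesh <- structured_mesh(c(nx, nx, nz), h, keep)

  k_apex <- round((domain_height - embed_depth) / h[3])
  if (k_apex < 1L || k_apex >= nz) stop("embedding depth leaves no bone above the base")
  z_apex <- k_apex * h[3]
  tol <- 1e-9 + h[3] * 1e-6
  nodes <- mesh$nodes
  on_apex <- abs(nodes[, "z"] - z_apex) < h[3] / 2
  footprints <- lapply(seq_len(nrow(quarter)), function(s) {
    idx <- which(on_apex &
                   (nodes[, "x"] - quarter$center_x[s])^2 +
                   (nodes[, "y"] - quarter$center_y[s])^2 <= r_sec[s]^2 + 1e-12)
    if (!length(idx)) stop("empty apex footprint: refine element_size")
    idx
  })
  names(footprints) <- paste0("spike_", seq_along(footprints))

  structure(list(nodes = nodes, elems = mesh$elems, h = h,
                 cell_centers = mesh$cell_centers,
                 sets = list(fixed_base = which(nodes[, "z"] < tol),
                             symmetry_x = which(nodes[, "x"] < tol),
                             symmetry_y = which(nodes[, "y"] < tol)),
                 footprints = footprints,
                 element_sets = list(densified_insert = integer(0)),
                 z_apex = z_apex,
                 embed_depth = domain_height - z_apex,
                 domain = c(radius = domain_radius, height = domain_height),
                 layout_quarter = quarter,
                 base_type = "fixed",
                 symmetry_factor = 4),
            class = "fe_mesh")
}

#' Build a rectangular block mesh (verification problems)
#'
#' A box `[0, Lx] x [0, Ly] x [0, Lz]` with the full top face as the loaded
#' set, symmetry planes on x = 0 and y = 0 and a roller base (`u_z = 0`),
#' the configuration of the uniaxial-stress bar benchmark.
#'
#' @param dims Box edge lengths, mm (length 3).
#' @param element_size Element edge, mm (scalar or length 3).
#' @return An `fe_mesh` with a single "footprint" = the whole top face and
#'   `symmetry_factor` = 1.
#' @export
build_box_mesh <- function(dims, element_size) {
  stopifnot(length(dims) == 3L, all(dims > 0), all(element_size > 0))
  if (length(element_size) == 1L) element_size <- rep(element_size, 3L)
  ncell <- as.integer(pmax(1, round(dims / element_size)))
  h <- dims / ncell
  mesh <- structured_mesh(ncell, h)
  nodes <- mesh$nodes
  tol <- min(h) * 1e-6
  structure(list(nodes = nodes, elems = mesh$elems, h = h,
                 cell_centers = mesh$cell_centers,
                 sets = list(fixed_base = which(nodes[, "z"] < tol),
                             symmetry_x = which(nodes[, "x"] < tol),
                             symmetry_y = which(nodes[, "y"] < tol)),
                 footprints = list(top = which(nodes[, "z"] > dims[3] - tol)),
                 element_sets = list(densified_insert = integer(0)),
                 z_apex = dims[3],
                 embed_depth = 0,
                 domain = c(dims = dims),
                 base_type = "roller",
                 symmetry_factor = 1),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d nodes, %d hexahedra, h = (%.3g, %.3g, %.3g) mm, %d footprint set(s)\n",
              nrow(x$nodes), nrow(x$elems), x$h[1], x$h[2], x$h[3],
              length(x$footprints)))
  invisible(x)
}

#' Tag the densified-bone insert layer
#'
#' Marks all elements within a layer of `insert_thickness` immediately below
#' the apex plane as the densified insert; their material is set by
#' [assemble_system()] from separate constants (typically the measured
#' periapical density via the mixture-rule/power-law chain).
#'
#' @param mesh An `fe_mesh` from [build_mesh()].
#' @param insert_thickness Layer thickness below the apex plane, mm.
#' @return The mesh with `element_sets$densified_insert` filled.
#' @export
add_densified_insert <- function(mesh, insert_thickness) {
  stopifnot(inherits(mesh, "fe_mesh"), is.numeric(insert_thickness))
  if (insert_thickness > mesh$z_apex) {
    stop("insert thickness does not fit under the apex plane")
  }
  cz <- mesh$cell_centers[, 3]
  idx <- which(cz < mesh$z_apex & cz > mesh$z_apex - insert_thickness)
  if (!length(idx)) stop("empty densified-insert element set")
  mesh$element_sets$densified_insert <- idx
  mesh$insert_thickness <- insert_thickness
  mesh
}

#' Export mesh and fields as a legacy-ASCII VTK unstructured grid
#'
#' Point data: displacement vector (mm); cell data: equivalent (HMH) stress
#' (MPa). Readable by ParaView and meshio.
#'
#' @param mesh An `fe_mesh`.
#' @param path Output `.vtk` path.
#' @param result Optional `fe_result` from [solve_embedding()].
#' @return `path`, invisibly.
#' @export
write_fe_vtk <- function(mesh, path, result = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "scaffold embedding model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  write(t(cbind(8L, mesh$elems - 1L)), con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  write(rep(12L, m), con, ncolumns = 10)
  if (!is.null(result)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double"), con)
    write(t(result$u), con, ncolumns = 3)
    writeLines(c(sprintf("CELL_DATA %d", m),
                 "SCALARS hmh_stress double 1",
                 "LOOKUP_TABLE default"), con)
    write(result$hmh_elem, con, ncolumns = 6)
  }
  invisible(path)
}
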