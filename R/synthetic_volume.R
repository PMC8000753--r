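#' Specification of a synthetic trabecular micro-CT volume
#'
#' The generator emulates the structures the densitometry chain must handle:
#' a binary-ish trabecular microstructure with a controllable marrow/soft
#' fraction, canal-like tubular pores, lacuna-like spherical pores, and
#' isolated single-voxel speckle noise, rendered as a two-class greyscale with
#' additive Gaussian noise. The microstructure is a Gaussian random field
#' smoothed to `correlation_length` and quantile-thresholded, the standard
#' trabecular-phantom construction; at the default 17.5 um voxels and a 350 um
#' correlation length, trabecular features span about 20 voxels.
#'
#' @param shape Integer vector of 3 voxel counts (x, y, z); each axis >= 16.
#' @param voxel_size Voxel size, um.
#' @param target_marrow_fraction Target soft-phase fraction, in (0, 1).
#' @param correlation_length Feature scale of the random field, um.
#' @param anisotropy Axial elongation of the trabecular features: the field's
#'   correlation along z (the loading axis) is `anisotropy` times the lateral
#'   one. Periarticular trabeculae align with the principal load direction,
#'   the same structural anisotropy the transversely isotropic continuum
#'   constants describe; 1 gives an isotropic phantom.
#' @param n_canals,canal_radius,canal_length Count, radius (um) and length
#'   (um) of tubular pores carved into the bone phase.
#' @param n_lacunae,lacuna_radius Count and radius (um) of spherical pores.
#' @param n_speckles Count of isolated single-voxel soft speckles inside bone.
#' @param intensity_bone,intensity_soft Greyscale class means; bone > soft.
#' @param noise_sd Additive Gaussian greyscale noise SD.
#' @param seed Integer seed; all randomness in the generator is behind it.
#' @return An object of class `volume_spec`.
#' @export
volume_spec <- function(shape = c(128L, 128L, 128L),
                        voxel_size = 17.5,
                        target_marrow_fraction = 0.582,
                        correlation_length = 350,
                        anisotropy = 2,
                        n_canals = 0L, canal_radius = 35, canal_length = 300,
                        n_lacunae = 0L, lacuna_radius = 30,
                        n_speckles = 0L,
                        intensity_bone = 180, intensity_soft = 60,
                        noise_sd = 8,
                        seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stop("shape must give 3 axes, each at least 16 voxels")
  }
  if (target_marrow_fraction <= 0 || target_marrow_fraction >= 1) {
    stop("target_marrow_fraction must lie strictly inside (0, 1)")
  }
  if (intensity_bone <= intensity_soft) stop("intensity_bone must exceed intensity_soft")
  counts <- c(n_canals, n_lacunae, n_speckles)
  if (any(counts < 0)) stop("pore counts must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(voxel_size > 0, correlation_length > 0, anisotropy >= 1,
            canal_radius > 0, canal_length > 0, lacuna_radius > 0)
  structure(list(shape = shape, voxel_size = voxel_size,
                 target_marrow_fraction = target_marrow_fraction,
                 correlation_length = correlation_length,
                 anisotropy = anisotropy,
                 n_canals = as.integer(n_canals), canal_radius = canal_radius,
                 canal_length = canal_length,
                 n_lacunae = as.integer(n_lacunae), lacuna_radius = lacuna_radius,
                 n_speckles = as.integer(n_speckles),
                 intensity_bone = intensity_bone, intensity_soft = intensity_soft,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "volume_spec")
}

# Gaussian smoothing of a white-noise array by multiplication of its spectrum
# with exp(-2 pi^2 sigma^2 |f|^2) (sigma in voxels, f in cycles/voxel).
# For a mean-level threshold the expected distance between crossings of the
# smoothed field is pi * sigma * sqrt(2), i.e. a full bone+marrow period of
# about 8.9 sigma: sigma = period / 8.9 reproduces a requested feature period.
smooth_random_field <- function(shape, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  w <- array(rnorm(prod(shape)), shape)
  freq2 <- lapply(1:3, function(a) {
    n <- shape[a]
    k <- 0:(n - 1L)
    f <- ifelse(k > n / 2, k - n, k) / n
    (sigma_vox[a] * f)^2
  })
  h <- exp(-2 * pi^2 *
             (outer(outer(freq2[[1]], freq2[[2]], `+`), freq2[[3]], `+`)))
  Re(fft(fft(w) * h, inverse = TRUE)) / prod(shape)
}

# Linear voxel indices of a solid tube along z (disc radius r_vox) and of a
# sphere, both about integer centres. Used for carving and clearance checks.
disc_offsets <- function(r_vox) {
  r <- ceiling(r_vox)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r_vox^2, , drop = FALSE]
}

sphere_offsets <- function(r_vox) {
  r <- ceiling(r_vox)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r_vox^2, , drop = FALSE]
}

lin_idx <- function(x, y, z, d) {
  (z - 1L) * (d[1] * d[2]) + (y - 1L) * d[1] + x
}

#' Generate a synthetic trabecular volume with ground truth
#'
#' Draws the thresholded random field so the soft fraction matches the target
#' (exact up to ties), carves canal and lacuna pores fully inside the bone
#' phase (each kept clear of the marrow space so it remains a separate pore
#' component), inserts isolated single-voxel speckles, and renders the
#' two-class greyscale with additive noise.
#'
#' @param spec A [volume_spec()].
#' @return List with `volume` (a [ct_volume()]), `bone_mask` (logical array,
#'   `TRUE` = bone ground truth), `planted` (locations of carved canals,
#'   lacunae and speckles, the fixture ground truth) and `spec`.
#' @export
generate_trabecular_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  # smoothing scale such that the bone+marrow period equals correlation_length
  sigma_vox <- spec$correlation_length / spec$voxel_size / (pi * sqrt(2) * 2)
  field <- smooth_random_field(d, sigma_vox * c(1, 1, spec$anisotropy))
  thr <- quantile(field, spec$target_marrow_fraction, names = FALSE)
  bone <- field >= thr

  # Carve pores fully inside bone, each with a 1-voxel clearance shell so it
  # stays a separate component disjoint from the marrow space. Candidate
  # centres come from a Chebyshev erosion of the bone phase (conservative:
  # the box of radius k contains the needed shell), so placement is a draw
  # from a precomputed feasible set rather than blind trials.
  erode_k <- function(m, k) {
    for (i in seq_len(k)) m <- erode26(m)
    m
  }
  erode_xy <- function(m, k) { # lateral-only Chebyshev erosion
    for (i in seq_len(k)) {
      for (axis in 1:2) {
        m <- m & shift3d(m, axis, 1L, FALSE) & shift3d(m, axis, -1L, FALSE)
      }
    }
    m
  }
  clear_border <- function(m, k) {
    m[c(seq_len(k), d[1] - seq_len(k) + 1L), , ] <- FALSE
    m[, c(seq_len(k), d[2] - seq_len(k) + 1L), ] <- FALSE
    m[, , c(seq_len(k), d[3] - seq_len(k) + 1L)] <- FALSE
    m
  }
  draw_spaced <- function(cand_idx, n, min_cheb, what, xy_only = FALSE) {
    chosen <- integer(0)
    coords <- matrix(0L, 0L, 3L)
    for (v in sample(cand_idx)) {
      xyz <- as.integer(arrayInd(v, d))
      sep <- if (xy_only) {
        pmax(abs(coords[, 1] - xyz[1]), abs(coords[, 2] - xyz[2]))
      } else {
        pmax(abs(coords[, 1] - xyz[1]), abs(coords[, 2] - xyz[2]),
             abs(coords[, 3] - xyz[3]))
      }
      if (nrow(coords) && any(sep < min_cheb)) next
      chosen <- c(chosen, v)
      coords <- rbind(coords, xyz)
      if (length(chosen) == n) return(coords)
    }
    stop(sprintf("could not place %d %ss inside the bone phase; ", n, what),
         "reduce counts or pore sizes, or lower the marrow fraction")
  }

  planted <- list(canals = NULL, lacunae = NULL, speckles = NULL)
  if (spec$n_canals > 0L) {
    r_can <- spec$canal_radius / spec$voxel_size
    len_can <- max(2L, round(spec$canal_length / spec$voxel_size))
    k <- as.integer(ceiling(r_can + 1))
    er <- clear_border(erode_xy(bone, k), 1L)
    # z-runs of eroded bone long enough for the tube plus clearance
    need <- len_can + 2L
    runlen <- array(0L, d)
    runlen[, , 1] <- er[, , 1]
    for (z in 2:d[3]) runlen[, , z] <- (runlen[, , z - 1L] + 1L) * er[, , z]
    starts <- which(runlen >= need) # index of run end; tube starts need-1 above
    if (length(starts) < spec$n_canals) {
      stop("could not place canals inside the bone phase")
    }
    ends <- draw_spaced(starts, spec$n_canals, 2L * k + 2L, "canal",
                        xy_only = TRUE)
    disc <- disc_offsets(r_can)
    for (i in seq_len(nrow(ends))) {
      zs <- (ends[i, 3] - need + 2L):(ends[i, 3] - 1L)
      base <- (ends[i, 2] + disc$dy - 1L) * d[1] + (ends[i, 1] + disc$dx)
      bone[as.vector(outer(base, (zs - 1L) * d[1] * d[2], `+`))] <- FALSE
    }
    planted$canals <- data.frame(x = ends[, 1], y = ends[, 2],
                                 z_mid = ends[, 3] - need %/% 2L)
  }
  if (spec$n_lacunae > 0L) {
    r_lac <- spec$lacuna_radius / spec$voxel_size
    k <- as.integer(ceiling(r_lac + 1))
    er <- clear_border(erode_k(bone, k), 1L)
    centres <- draw_spaced(which(er), spec$n_lacunae, 2L * k + 2L, "lacuna")
    sph <- sphere_offsets(r_lac)
    for (i in seq_len(nrow(centres))) {
      bone[lin_idx(centres[i, 1] + sph$dx, centres[i, 2] + sph$dy,
                   centres[i, 3] + sph$dz, d)] <- FALSE
    }
    planted$lacunae <- data.frame(x = centres[, 1], y = centres[, 2],
                                  z = centres[, 3])
  }

  if (spec$n_speckles > 0L) {
    interior <- which(erode26(bone))
    if (length(interior) < spec$n_speckles) stop("not enough interior bone for speckles")
    chosen <- integer(0)
    coords <- NULL
    pool <- sample(interior)
    for (v in pool) {
      xyz <- arrayInd(v, d)
      if (length(chosen) &&
          any(apply(abs(sweep(coords, 2L, as.integer(xyz))), 1L, max) < 3L)) next
      chosen <- c(chosen, v)
      coords <- rbind(coords, as.integer(xyz))
      if (length(chosen) == spec$n_speckles) break
    }
    if (length(chosen) < spec$n_speckles) {
      stop("could not place the requested number of isolated speckles")
    }
    bone[chosen] <- FALSE
    planted$speckles <- chosen
  }

  grey <- array(ifelse(bone, spec$intensity_bone, spec$intensity_soft), d)
  if (spec$noise_sd > 0) grey <- grey + array(rnorm(prod(d), 0, spec$noise_sd), d)

  meta <- list(seed = spec$seed,
               target_marrow_fraction = spec$target_marrow_fraction,
               intensity_bone = spec$intensity_bone,
               intensity_soft = spec$intensity_soft,
               noise_sd = spec$noise_sd)
  list(volume = ct_volume(grey, spec$voxel_size, meta),
       bone_mask = bone,
       planted = planted,
       spec = spec)
}

#' Densify the periapical bone under each spike apex
#'
#' Within a cylindrical zone under each spike apex (radius `zone_radius`,
#' from depth `embed_depth` to `embed_depth + zone_thickness`), the marrow
#' fraction is reduced by `delta_phi`: soft voxels nearest to existing bone
#' are flipped to bone first (layer by layer over the 6-neighbourhood), which
#' mimics trabecular compaction onto the existing network. Voxels outside the
#' zones are untouched.
#'
#' @param volume A `ct_volume` (greyscale updated for flipped voxels).
#' @param mask Logical bone mask aligned with `volume`.
#' @param layout A `spike_layout` centred on the volume axis.
#' @param embed_depth Depth of the apex plane below the top surface, mm.
#' @param zone_thickness Axial extent of the densification zone, mm.
#' @param delta_phi Absolute reduction of the zone marrow fraction. Exactly
#'   one of `delta_phi` and `target_phi` must be given.
#' @param target_phi Target marrow fraction per zone: each zone's reduction is
#'   computed from its own baseline (compaction to a density state, the
#'   quantity a periapical densitometry table reports). Zones already at or
#'   below the target are left untouched.
#' @param zone_radius Zone radius, mm; defaults to 0.9 x spike base diameter
#'   (the scale of the periapical stress bulb).
#' @param seed Seed for the (tie-breaking) choice of voxels within a layer.
#' @return List with updated `volume` and `mask`, plus `zone_report`, a
#'   data.frame of per-zone voxel counts and achieved fractions.
#' @export
apply_densification <- function(volume, mask, layout, embed_depth,
                                zone_thickness, delta_phi = NULL,
                                target_phi = NULL,
                                zone_radius = NULL, seed = 1L) {
  stopifnot(inherits(volume, "ct_volume"), is.logical(mask),
            identical(dim(mask), dim(volume$voxels)),
            inherits(layout, "spike_layout"), zone_thickness > 0)
  if (is.null(delta_phi) == is.null(target_phi)) {
    stop("give exactly one of delta_phi and target_phi")
  }
  if (!is.null(delta_phi)) stopifnot(delta_phi >= 0, delta_phi <= 1)
  if (!is.null(target_phi)) stopifnot(target_phi >= 0, target_phi <= 1)
  if (is.null(zone_radius)) zone_radius <- 0.9 * 2 * layout$spikes$base_radius[1]
  set.seed(seed)
  d <- dim(mask)
  vs <- volume$voxel_size
  z1 <- vox_index_z(embed_depth, vs)
  z2 <- vox_index_z(embed_depth + zone_thickness, vs)
  if (z1 < 2L || z2 > d[3] - 1L) stop("densification zone extends outside the volume")
  r_vox <- zone_radius * 1000 / vs
  offs <- disc_offsets(r_vox)
  nxny <- d[1] * d[2]
  zoff <- (z1:z2 - 1L) * nxny
  grey <- volume$voxels
  ib <- volume$meta$intensity_bone
  nsd <- volume$meta$noise_sd
  if (is.null(ib)) ib <- mean(grey[mask])
  if (is.null(nsd)) nsd <- 0

  rows <- list()
  for (s in seq_len(nrow(layout$spikes))) {
    cx <- vox_index_xy(layout$spikes$center_x[s], d[1], vs)
    cy <- vox_index_xy(layout$spikes$center_y[s], d[2], vs)
    xs <- cx + offs$dx
    ys <- cy + offs$dy
    if (any(xs < 2L) || any(xs > d[1] - 1L) || any(ys < 2L) || any(ys > d[2] - 1L)) {
      stop("densification zone extends outside the volume")
    }
    base <- (ys - 1L) * d[1] + xs
    zone <- as.vector(outer(base, zoff, `+`))
    n_zone <- length(zone)
    soft0 <- sum(!mask[zone])
    needed <- if (!is.null(delta_phi)) round(delta_phi * n_zone) else
      max(0L, soft0 - round(target_phi * n_zone))
    if (needed > soft0) {
      stop("delta_phi exceeds the current marrow fraction in a zone")
    }
    remaining <- needed
    nbr_off <- c(1L, -1L, d[1], -d[1], nxny, -nxny)
    while (remaining > 0L) {
      soft <- zone[!mask[zone]]
      touch <- rep(FALSE, length(soft))
      for (o in nbr_off) touch <- touch | mask[soft + o]
      cand <- soft[touch]
      if (!length(cand)) cand <- soft # disconnected pocket: fill directly
      flip <- if (length(cand) > remaining) sample(cand, remaining) else cand
      mask[flip] <- TRUE
      grey[flip] <- ib + if (nsd > 0) rnorm(length(flip), 0, nsd) else 0
      remaining <- remaining - length(flip)
    }
    rows[[s]] <- data.frame(spike = s, n_zone = n_zone,
                            phi_before = soft0 / n_zone,
                            phi_after = (soft0 - needed) / n_zone)
  }
  out <- volume
  out$voxels <- grey
  list(volume = out, mask = mask, zone_report = do.call(rbind, rows))
}
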