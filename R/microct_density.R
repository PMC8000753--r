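#' Density constants for the two-phase mixture rule
#'
#' The volumetric bone density of a region is a voxel-fraction-weighted
#' mixture of trabecular tissue (comparable to cortical bone, 1.90 g/cm^3)
#' and marrow/soft tissue (close to water, 1.00 g/cm^3):
#' `rho_b = (1 - phi) * rho_T + phi * rho_w`. The longitudinal modulus then
#' follows the cancellous-bone power law `E2 = k * rho_b^3` with
#' k = 315 MPa/(g/cm^3)^3.
#'
#' @param rho_T Trabecular tissue density, g/cm^3.
#' @param rho_w Marrow/soft tissue density, g/cm^3.
#' @param modulus_coefficient Power-law coefficient, MPa per (g/cm^3)^3.
#' @return Object of class `density_constants`.
#' @export
density_constants <- function(rho_T = 1.90, rho_w = 1.00,
                              modulus_coefficient = 315) {
  if (!(rho_T > rho_w && rho_w > 0)) stop("need rho_T > rho_w > 0")
  stopifnot(modulus_coefficient > 0)
  structure(list(rho_T = rho_T, rho_w = rho_w,
                 modulus_coefficient = modulus_coefficient),
            class = "density_constants")
}

#' Segment bone from a greyscale volume
#'
#' Bone is all voxels at or above a radiological-density threshold; the pore
#' space is the inverse segmentation. The threshold is either fixed or chosen
#' by Otsu's method on the global volume histogram. Pore components are
#' labelled with 26-connectivity (metadata records the convention).
#'
#' @param volume A `ct_volume`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Greyscale threshold, required for `method = "fixed"`.
#' @param connectivity Pore component connectivity, 6 or 26.
#' @return Object of class `segmentation` with fields `bone_mask`,
#'   `pore_labels`, `pore_sizes`, `classes` (filled by [classify_pores()]),
#'   `threshold`, `method`, `connectivity`, `voxel_size`.
#' @export
segment_bone <- function(volume, method = c("otsu", "fixed"), threshold = NULL,
                         connectivity = 26L) {
  stopifnot(inherits(volume, "ct_volume"))
  method <- match.arg(method)
  v <- volume$voxels
  if (method == "otsu") {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      threshold <- rng[1] # degenerate uniform volume: everything is bone
    } else {
      norm <- (v - rng[1]) / (rng[2] - rng[1])
      # flatten to a single frame so EBImage computes one global threshold
      t01 <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1L)),
                           range = c(0, 1))
      threshold <- rng[1] + t01 * (rng[2] - rng[1])
    }
  } else if (is.null(threshold)) {
    stop("method = \"fixed\" requires a threshold")
  }
  bone <- v >= threshold
  bf <- mean(bone)
  if (bf == 0 || bf == 1) {
    warning(sprintf("bone fraction is %.0f: threshold does not split the volume", bf))
  }
  labels <- label_components(!bone, connectivity = connectivity)
  structure(list(bone_mask = bone,
                 pore_labels = labels,
                 pore_sizes = tabulate(labels, attr(labels, "n_components")),
                 classes = NULL,
                 threshold = threshold,
                 method = method,
                 connectivity = as.integer(connectivity),
                 voxel_size = volume$voxel_size),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: threshold %.3f (%s), %d pore components, bone fraction %.3f\n",
              x$threshold, x$method, length(x$pore_sizes), mean(x$bone_mask)))
  invisible(x)
}

#' Remove single-voxel noise objects from the pore space
#'
#' Pore components of exactly one voxel are reassigned to bone, the
#' morphological-opening equivalent constrained to the surfaces of the
#' original thresholded image: no voxel outside the original pore space is
#' ever modified, and no multi-voxel pore is eroded. Idempotent.
#'
#' @param seg A `segmentation`.
#' @return The `segmentation` with noise voxels removed and pores relabelled;
#'   `n_noise_removed` records the count.
#' @export
remove_noise_objects <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  singles <- which(seg$pore_sizes == 1L)
  if (length(singles)) {
    seg$bone_mask[seg$pore_labels %in% singles] <- TRUE
    labels <- label_components(!seg$bone_mask, connectivity = seg$connectivity)
    seg$pore_labels <- labels
    seg$pore_sizes <- tabulate(labels, attr(labels, "n_components"))
    seg$classes <- NULL
  }
  seg$n_noise_removed <- (seg$n_noise_removed %||% 0L) + length(singles)
  seg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify pore components by size
#'
#' Components up to `lacuna_max_voxels` voxels are lacunae (osteocyte-scale
#' pores); larger components are canals (vascular-scale pores). The default
#' cut of 150 voxels corresponds to a sphere of roughly 3 voxels radius
#' (about 53 um at 17.5 um voxels). When `exclude_microporosity` is set,
#' classified canal and lacuna voxels are extracted from the volume of
#' interest: [marrow_fraction()] then drops them from both numerator and
#' denominator.
#'
#' @param seg A `segmentation`, after [remove_noise_objects()].
#' @param lacuna_max_voxels Largest component size labelled lacuna.
#' @param exclude_microporosity Flag stored on the result (default `FALSE`:
#'   every non-bone voxel counts towards the marrow fraction, consistent with
#'   the mixture rule needing the total soft fraction).
#' @return The `segmentation` with a `classes` factor (one entry per pore
#'   component, levels `lacuna`/`canal`) and the flag recorded.
#' @export
classify_pores <- function(seg, lacuna_max_voxels = 150L,
                           exclude_microporosity = FALSE) {
  stopifnot(inherits(seg, "segmentation"))
  if (lacuna_max_voxels <= 1L) stop("lacuna_max_voxels must exceed 1")
  if (any(seg$pore_sizes == 1L)) {
    stop("remove noise objects before classifying pores")
  }
  seg$classes <- factor(ifelse(seg$pore_sizes <= lacuna_max_voxels,
                               "lacuna", "canal"),
                        levels = c("lacuna", "canal"))
  seg$lacuna_max_voxels <- as.integer(lacuna_max_voxels)
  seg$exclude_microporosity <- isTRUE(exclude_microporosity)
  seg
}

as_roi <- function(roi, d) {
  stopifnot(is.list(roi), all(c("x", "y", "z") %in% names(roi)))
  r <- lapply(roi[c("x", "y", "z")], function(v) as.integer(round(v)))
  for (a in 1:3) {
    if (length(r[[a]]) != 2L || r[[a]][1] > r[[a]][2] ||
        r[[a]][1] < 1L || r[[a]][2] > d[a]) {
      stop("ROI must be an axis-aligned box inside the volume")
    }
  }
  r
}

#' Marrow/soft-tissue fraction of a region of interest
#'
#' The fraction of non-bone voxels over an axis-aligned box, with the first
#' and last slices of the box discarded to avoid edge effects. With
#' `exclude_microporosity` set on the segmentation, voxels of classified
#' canal/lacuna components are extracted from the region before the fraction
#' is formed.
#'
#' @param seg A `segmentation`.
#' @param roi List with `x`, `y`, `z` integer index ranges `c(lo, hi)`;
#'   `NULL` means the whole volume. The z range must span at least 3 slices.
#' @return The marrow fraction phi in `[0, 1]`.
#' @export
marrow_fraction <- function(seg, roi = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  d <- dim(seg$bone_mask)
  if (is.null(roi)) roi <- list(x = c(1L, d[1]), y = c(1L, d[2]), z = c(1L, d[3]))
  roi <- as_roi(roi, d)
  if (roi$z[2] - roi$z[1] + 1L < 3L) {
    stop("ROI must span at least 3 slices (first and last are discarded)")
  }
  zs <- (roi$z[1] + 1L):(roi$z[2] - 1L)
  sub <- seg$bone_mask[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], zs, drop = FALSE]
  if (isTRUE(seg$exclude_microporosity) && !is.null(seg$classes)) {
    lab <- seg$pore_labels[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2], zs, drop = FALSE]
    extracted <- lab > 0L # classified pore components leave the analysis set
    keep <- !extracted
    return(sum(!sub[keep]) / sum(keep))
  }
  sum(!sub) / length(sub)
}

#' Volumetric bone density from the marrow fraction
#'
#' Two-phase mixture rule `rho_b = (1 - phi) * rho_T + phi * rho_w`.
#'
#' @param phi Marrow/soft fraction(s) in `[0, 1]`.
#' @param constants A [density_constants()].
#' @return Density in g/cm^3 (unrounded).
#' @export
bone_density <- function(phi, constants = density_constants()) {
  stopifnot(inherits(constants, "density_constants"))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  (1 - phi) * constants$rho_T + phi * constants$rho_w
}

#' Longitudinal elastic modulus from bone density
#'
#' Cancellous-bone power law `E2 = k * rho_b^3`, evaluated on the unrounded
#' density.
#'
#' @param rho_b Bone density, g/cm^3 (must be positive).
#' @param constants A [density_constants()].
#' @return Modulus in MPa (unrounded).
#' @export
longitudinal_modulus <- function(rho_b, constants = density_constants()) {
  stopifnot(inherits(constants, "density_constants"))
  if (any(rho_b <= 0)) stop("rho_b must be positive")
  constants$modulus_coefficient * rho_b^3
}

#' Periapical regions of interest under each spike apex
#'
#' One axis-aligned box per spike, centred on the spike axis, starting
#' immediately below the apex plane at the given embedding depth.
#'
#' @param layout A `spike_layout` centred on the volume axis.
#' @param volume A `ct_volume` (fixes the voxel frame).
#' @param embed_depth Apex-plane depth below the top surface, mm.
#' @param roi_size Lateral box edge, mm.
#' @param roi_depth Axial box extent, mm (default `roi_size`).
#' @return List of ROI boxes (each `list(x =, y =, z =)`), one per spike.
#' @export
periapical_rois <- function(layout, volume, embed_depth, roi_size,
                            roi_depth = roi_size) {
  stopifnot(inherits(layout, "spike_layout"), inherits(volume, "ct_volume"),
            roi_size > 0, roi_depth > 0)
  d <- dim(volume$voxels)
  vs <- volume$voxel_size
  half <- round(roi_size * 1000 / vs / 2)
  z1 <- vox_index_z(embed_depth, vs)
  z2 <- z1 + max(2L, round(roi_depth * 1000 / vs)) - 1L
  rois <- lapply(seq_len(nrow(layout$spikes)), function(s) {
    cx <- vox_index_xy(layout$spikes$center_x[s], d[1], vs)
    cy <- vox_index_xy(layout$spikes$center_y[s], d[2], vs)
    roi <- list(x = c(cx - half, cx + half),
                y = c(cy - half, cy + half),
                z = c(z1, z2))
    if (roi$x[1] < 1L || roi$x[2] > d[1] || roi$y[1] < 1L || roi$y[2] > d[2] ||
        roi$z[2] > d[3]) {
      stop("periapical ROI clipped by the volume boundary")
    }
    roi
  })
  names(rois) <- paste0("spike_", seq_along(rois))
  rois
}

#' Densitometry report over regions of interest
#'
#' Runs the marrow-fraction, mixture-rule density and power-law modulus chain
#' per ROI. All downstream computation uses unrounded values; presentation
#' rounding (density to 2 decimals, modulus to integer MPa) is applied only
#' by [write_density_report()].
#'
#' @param seg A `segmentation`.
#' @param rois Named list of ROI boxes (see [marrow_fraction()]).
#' @param constants A [density_constants()].
#' @return data.frame with `roi_id`, `n_voxels`, `phi`, `bone_fraction`,
#'   `rho_b_g_cm3`, `E2_MPa`.
#' @export
density_report <- function(seg, rois, constants = density_constants()) {
  stopifnot(inherits(seg, "segmentation"), length(rois) >= 1L)
  if (is.null(names(rois))) names(rois) <- paste0("roi_", seq_along(rois))
  rows <- lapply(names(rois), function(id) {
    roi <- as_roi(rois[[id]], dim(seg$bone_mask))
    phi <- marrow_fraction(seg, roi)
    rho <- bone_density(phi, constants)
    data.frame(roi_id = id,
               n_voxels = prod(vapply(roi, function(r) diff(r) + 1L, 1L)),
               phi = phi,
               bone_fraction = 1 - phi,
               rho_b_g_cm3 = rho,
               E2_MPa = longitudinal_modulus(rho, constants))
  })
  do.call(rbind, rows)
}

#' Write a densitometry report as CSV and JSON
#'
#' Applies the presentation rounding (phi to 3 decimals, density to 2
#' decimals, modulus to integer MPa) in the CSV; the JSON keeps full
#' precision plus the segmentation metadata.
#'
#' @param report data.frame from [density_report()].
#' @param path Output path without extension; `.csv` and `.json` are added.
#' @param seg Optional `segmentation` whose metadata is recorded.
#' @return Invisibly, the two paths written.
#' @export
write_density_report <- function(report, path, seg = NULL) {
  csv <- paste0(path, ".csv")
  out <- report
  out$phi <- round(out$phi, 3)
  out$rho_b_g_cm3 <- round(out$rho_b_g_cm3, 2)
  out$E2_MPa <- round(out$E2_MPa)
  write.csv(out, csv, row.names = FALSE)
  meta <- if (is.null(seg)) NULL else
    list(threshold = seg$threshold, method = seg$method,
         connectivity = seg$connectivity,
         lacuna_max_voxels = seg$lacuna_max_voxels,
         exclude_microporosity = seg$exclude_microporosity)
  json <- paste0(path, ".json")
  jsonlite::write_json(list(report = report, segmentation = meta), json,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}
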