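#' Micro-CT volume container
#'
#' A 3-D greyscale grid with an isotropic voxel size. The array axes are
#' (x, y, z) with z the slice index: slice 1 is the top of the stack (the
#' surface the scaffold is embedded through) and depth increases with z.
#' The scaffold axis passes through the centre of the xy cross-section.
#'
#' @param voxels 3-D numeric array of greyscale values.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param meta Optional named list of provenance metadata (seed, generator
#'   settings, ...), stored verbatim.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, voxel_size, meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L) {
    stop("voxels must be a non-empty 3-D array")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (um)")
  }
  structure(list(voxels = voxels, voxel_size = voxel_size, meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels at %.2f um (%.2f x %.2f x %.2f mm)\n",
              d[1], d[2], d[3],
              x$voxel_size,
              d[1] * x$voxel_size / 1000,
              d[2] * x$voxel_size / 1000,
              d[3] * x$voxel_size / 1000))
  invisible(x)
}

# mm (scaffold frame, origin on the axis at the top surface) -> voxel indices.
# x/y: centred on the volume; z: depth below the top slice face.
vox_index_xy <- function(x_mm, n, voxel_size_um) {
  round(x_mm * 1000 / voxel_size_um + (n + 1) / 2)
}

vox_index_z <- function(depth_mm, voxel_size_um) {
  pmax(1L, as.integer(ceiling(depth_mm * 1000 / voxel_size_um + 1e-9)))
}

mm_per_voxel <- function(volume) volume$voxel_size / 1000

#' Write a volume to NIfTI with a JSON sidecar
#'
#' The sidecar records the voxel size (um) and any generator metadata, so a
#' written volume round-trips with its provenance.
#'
#' @param volume A `ct_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  pix <- volume$voxel_size / 1000
  img <- RNifti::asNifti(volume$voxels, pixdim = c(pix, pix, pix))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(c(list(voxel_size_um = volume$voxel_size), volume$meta),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_ct_volume()]
#'
#' @param path Path to the NIfTI file; the JSON sidecar is read if present.
#' @return A `ct_volume`.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list()
  voxel_size <- RNifti::pixdim(img)[1] * 1000
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um)) {
      voxel_size <- meta$voxel_size_um
      meta$voxel_size_um <- NULL
    }
  }
  ct_volume(array(as.numeric(img), dim = dim(img)), voxel_size, meta)
}

#' Write a volume or mask as a multi-page TIFF stack
#'
#' Values are rescaled to `[0, 1]`; one page per z slice.
#'
#' @param volume A `ct_volume`, or a 3-D array (e.g. a bone mask).
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(volume, path) {
  arr <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  arr <- (arr - min(arr)) / max(max(arr) - min(arr), .Machine$double.eps)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack into a `ct_volume`
#'
#' @param path `.tif` path written by [write_tiff_stack()].
#' @param voxel_size Voxel size in um (TIFF does not carry it).
#' @return A `ct_volume` with values in `[0, 1]`.
#' @export
read_tiff_stack <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  ct_volume(arr, voxel_size)
}
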