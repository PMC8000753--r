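#' Label connected components of a 3-D mask
#'
#' Flood-fill labelling of `TRUE` voxels, either face-connected (6) or fully
#' connected (26, the default used for pore components).
#'
#' @param mask 3-D logical array.
#' @param connectivity 6 or 26.
#' @return Integer array of the same shape; 0 is background, components are
#'   numbered from 1. The number of components is in attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  labels <- label3d_cpp(as.logical(mask), as.integer(dim(mask)),
                        as.integer(connectivity))
  ncomp <- attr(labels, "n_components")
  dim(labels) <- dim(mask)
  attr(labels, "n_components") <- ncomp
  labels
}

# Shift a 3-D array by one voxel along an axis, padding with `fill`.
shift3d <- function(a, axis, by, fill) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Chebyshev (26-neighbourhood) erosion of a logical mask by radius 1:
# separable box-minimum along each axis. Outside the volume counts as FALSE.
erode26 <- function(mask) {
  out <- mask
  for (axis in 1:3) {
    out <- out & shift3d(out, axis, 1L, FALSE) & shift3d(out, axis, -1L, FALSE)
  }
  out
}

# Face-neighbourhood (6-connected) dilation by radius 1.
dilate6 <- function(mask) {
  out <- mask
  for (axis in 1:3) {
    out <- out | shift3d(mask, axis, 1L, FALSE) | shift3d(mask, axis, -1L, FALSE)
  }
  out
}
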