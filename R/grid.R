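#' Voxel grid geometry
#'
#' A `cf_grid` describes a regular voxel grid: its shape (voxels per axis),
#' voxel sizes in mm, and the world-space (MNI mm) coordinate of the center of
#' voxel `(0, 0, 0)`. Voxel indices are 0-based throughout; the voxel-to-world
#' mapping is `mni = origin_mm + index * vox_mm` (axis-aligned, as in a
#' diagonal NIfTI affine).
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param vox_mm numeric vector of length 3, voxel size in mm per axis.
#' @param origin_mm numeric vector of length 3, world coordinate (mm) of the
#'   center of voxel (0, 0, 0).
#' @return A `cf_grid` object.
#' @examples
#' g <- vol_grid(c(10, 10, 6), c(3, 3, 3.5), c(-15, -15, -9))
#' mni_to_vox(c(0, 0, 0), g)
#' @export
vol_grid <- function(shape, vox_mm, origin_mm) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(vox_mm) == 3, all(vox_mm > 0),
            length(origin_mm) == 3, all(is.finite(origin_mm)))
  structure(
    list(shape = shape, vox_mm = as.numeric(vox_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "cf_grid"
  )
}

#' Default simulation grid
#'
#' An EPI-like grid covering MNI space: 61 x 73 x 33 voxels of
#' 3 x 3 x 3.5 mm (33 axial slices of 3.5-mm thickness), spanning roughly
#' x in \[-90, 90\], y in \[-108, 108\], z in \[-46, 66\] mm so that all
#' packaged ROI spheres fall inside the volume.
#'
#' @return A `cf_grid`.
#' @export
default_grid <- function() {
  vol_grid(c(61L, 73L, 33L), c(3, 3, 3.5), c(-90, -108, -46))
}

#' @export
print.cf_grid <- function(x, ...) {
  cat(sprintf("<cf_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$vox_mm[1], x$vox_mm[2], x$vox_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Convert between world (MNI mm) and voxel coordinates
#'
#' `mni_to_vox()` returns fractional 0-based voxel coordinates;
#' `vox_to_mni()` maps 0-based voxel indices to the mm coordinates of their
#' centers. Both accept a single coordinate triple or an n x 3 matrix.
#'
#' @param xyz coordinate triple or n x 3 matrix (mm for `mni_to_vox`,
#'   0-based voxel indices for `vox_to_mni`).
#' @param grid a [vol_grid()].
#' @return A matrix of the same shape as the input.
#' @export
mni_to_vox <- function(xyz, grid) {
  xyz <- rbind_coords(xyz)
  sweep(sweep(xyz, 2, grid$origin_mm, "-"), 2, grid$vox_mm, "/")
}

#' @rdname mni_to_vox
#' @export
vox_to_mni <- function(xyz, grid) {
  xyz <- rbind_coords(xyz)
  sweep(sweep(xyz, 2, grid$vox_mm, "*"), 2, grid$origin_mm, "+")
}

rbind_coords <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1)
  stopifnot(ncol(xyz) == 3)
  xyz
}

#' Linear (column-major) voxel index from 0-based ijk triples
#'
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @param grid a [vol_grid()].
#' @return Integer vector of 1-based linear indices into an array of the
#'   grid's shape.
#' @export
vox_linear_index <- function(ijk, grid) {
  ijk <- rbind_coords(ijk)
  as.integer(ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3]) + 1)
}

in_grid <- function(ijk, grid) {
  ijk <- rbind_coords(ijk)
  ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
}
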