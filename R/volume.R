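#' 4D brain volume
#'
#' Lightweight container for a subject's voxel time-series grid: a 4D array
#' (x, y, z, t) of signal intensity together with voxel sizes in mm, the
#' repetition time in seconds and a 4x4 grid-to-world affine.
#'
#' @param data Numeric 4D array (x, y, z, t). A 3D array is promoted to a
#'   single-frame 4D array (documented promotion, used for masks).
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param tr Repetition time in seconds (sampling interval of the series).
#' @param affine Optional 4x4 grid-to-world matrix; defaults to a RAS+
#'   `diag(voxel_size)` map with the origin at the grid corner.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, voxel_size = c(3, 3, 3), tr = 2, affine = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("'data' must be a 3D or 4D array")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive lengths in mm")
  if (!is.numeric(tr) || tr <= 0) stop("'tr' must be a positive scalar (seconds)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be a 4x4 matrix")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 tr = as.numeric(tr), affine = affine),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d grid, %d volume(s), voxels %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size), collapse = " x "), x$tr))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

n_volumes <- function(vol) dim(vol$data)[4]

grid_dims <- function(vol) dim(vol$data)[1:3]

#' Extract the in-mask voxel-by-time matrix of a volume
#'
#' @param vol A `volume4d`.
#' @param mask Logical 3D array over the volume grid.
#' @return A t x V numeric matrix, one column per in-mask voxel in array
#'   (column-major) order.
#' @export
mask_matrix <- function(vol, mask) {
  check_mask(mask, grid_dims(vol))
  nt <- n_volumes(vol)
  flat <- matrix(vol$data, ncol = nt)   # voxels x t
  t(flat[as.logical(mask), , drop = FALSE])
}

#' Write a voxel-by-time matrix back into a volume's in-mask voxels
#'
#' Out-of-mask voxels are set to zero.
#' @param vol Template `volume4d` (provides grid, voxel size, TR, affine).
#' @param mat t x V matrix as produced by [mask_matrix()].
#' @param mask Logical 3D array used to produce `mat`.
#' @return A new `volume4d`.
#' @export
unmask_matrix <- function(vol, mat, mask) {
  gd <- grid_dims(vol)
  check_mask(mask, gd)
  nt <- nrow(mat)
  flat <- matrix(0, prod(gd), nt)
  flat[as.logical(mask), ] <- t(mat)
  volume4d(array(flat, c(gd, nt)), vol$voxel_size, vol$tr, vol$affine)
}

check_mask <- function(mask, gd) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L || !all(dim(mask) == gd))
    stop("mask must be a 3D array matching the volume grid")
  invisible(TRUE)
}

# Embed a vector of in-mask voxel values into a 3D array (0 elsewhere).
embed_map <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[as.logical(mask)] <- values
  out
}
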