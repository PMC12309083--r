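#' Voxel grid geometry
#'
#' A `voxel_grid` describes the sampling lattice of a volume: its integer
#' extents, the voxel edge lengths in mm, and the 4x4 affine mapping 0-based
#' voxel indices to world (scanner/template) mm coordinates, as stored in a
#' NIfTI sform/qform.
#'
#' @param shape integer vector of length 3, positive voxel extents.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world mm.
#' @return An object of class `voxel_grid` with fields `shape`, `affine`
#'   and `voxel_size` (column norms of the upper-left 3x3 of `affine`).
#' @examples
#' g <- voxel_grid(c(10, 10, 10), diag(4))
#' g$voxel_size
#' @export
voxel_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("grid shape must be 3 positive integer extents")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("grid affine must be a finite 4x4 matrix")
  rot <- affine[1:3, 1:3]
  if (abs(det(rot)) < .Machine$double.eps^0.5)
    stop("grid affine is singular: upper-left 3x3 has zero determinant")
  grid <- structure(
    list(shape = shape,
         affine = affine,
         voxel_size = sqrt(colSums(rot^2))),
    class = "voxel_grid")
  grid
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("%s vox @ %s mm", paste(x$shape, collapse = "x"),
          paste(signif(x$voxel_size, 4), collapse = "x"))
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

# Grid compatibility: same shape, affines equal within `tol` mm.
grids_compatible <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  stop(sprintf(
    "incompatible grids for %s:\n  first:  %s, affine %s\n  second: %s, affine %s",
    what, format(a), paste(signif(a$affine, 6), collapse = " "),
    format(b), paste(signif(b$affine, 6), collapse = " ")), call. = FALSE)
}

#' Affine transform between two voxel grids
#'
#' Wraps a 4x4 matrix together with the source and target grids it relates
#' and the convention its entries are written in. `world_mm` matrices map
#' source world mm coordinates to target world mm coordinates. `fsl_scaled_mm`
#' matrices follow the FLIRT .mat dialect: they act on "scaled mm" coordinates
#' (voxel index times voxel size, with the first axis flipped when the grid's
#' world affine has positive determinant).
#'
#' @param matrix 4x4 numeric matrix (must be invertible).
#' @param source_grid,target_grid `voxel_grid` objects.
#' @param convention `"world_mm"` or `"fsl_scaled_mm"`.
#' @return An object of class `affine_transform`.
#' @seealso [to_world_convention()], [apply_to_mask()]
#' @export
affine_transform <- function(matrix, source_grid, target_grid,
                             convention = c("world_mm", "fsl_scaled_mm")) {
  convention <- match.arg(convention)
  matrix <- as.matrix(matrix)
  if (!identical(dim(matrix), c(4L, 4L)) || any(!is.finite(matrix)))
    stop("transform matrix must be a finite 4x4 matrix")
  if (abs(det(matrix)) < .Machine$double.eps^0.5)
    stop("transform matrix is singular (determinant 0)")
  if (!is_voxel_grid(source_grid) || !is_voxel_grid(target_grid))
    stop("source_grid and target_grid must be voxel_grid objects")
  structure(
    list(matrix = matrix, source_grid = source_grid,
         target_grid = target_grid, convention = convention),
    class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> convention %s\n  source %s\n  target %s\n",
              x$convention, format(x$source_grid), format(x$target_grid)))
  print(signif(x$matrix, 6))
  invisible(x)
}
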