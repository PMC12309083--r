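#' Convert a transform to world-mm convention
#'
#' FLIRT-style matrices do not act on world coordinates: they act on "scaled
#' mm" coordinates, defined per grid as voxel index times voxel size, with
#' the first axis flipped (x' = dx * (nx - 1 - i)) when the grid's world
#' affine has positive determinant. This converts such a matrix to the
#' canonical world-mm form by composing it with each grid's voxel-to-scaled-mm
#' and voxel-to-world maps:
#' `W = A_tgt %*% S_tgt^-1 %*% M_fsl %*% S_src %*% A_src^-1`.
#'
#' @param t an [affine_transform].
#' @return An equivalent [affine_transform] with `convention = "world_mm"`.
#' @export
to_world_convention <- function(t) {
  stopifnot(inherits(t, "affine_transform"))
  if (t$convention == "world_mm") return(t)
  if (t$convention != "fsl_scaled_mm")
    stop(sprintf("unknown transform convention '%s'", t$convention))
  s_src <- scaled_mm_map(t$source_grid)
  s_tgt <- scaled_mm_map(t$target_grid)
  w <- t$target_grid$affine %*% solve(s_tgt) %*% t$matrix %*%
    s_src %*% solve(t$source_grid$affine)
  affine_transform(w, t$source_grid, t$target_grid, "world_mm")
}

# Voxel-index (0-based) -> FSL scaled-mm coordinates for one grid.
scaled_mm_map <- function(grid) {
  d <- grid$voxel_size
  s <- diag(c(d, 1))
  if (det(grid$affine[1:3, 1:3]) > 0) {   # radiological flip on the first axis
    s[1, 1] <- -d[1]
    s[1, 4] <- d[1] * (grid$shape[1] - 1)
  }
  s
}

#' Resample a binary mask onto a target grid
#'
#' Applies an affine transform by pull-back sampling: each target voxel takes
#' its value from the source position obtained by mapping the target voxel
#' centre back through the inverse transform. With `interp = "nearest"`
#' (default) the nearest source voxel's membership is copied — half-way
#' ties round toward the lower index — which keeps the operation exact for
#' integer-voxel translations and never invents membership. With
#' `interp = "trilinear"` the 0/1 membership field is interpolated and
#' re-binarised at `threshold`. Target voxels that pull back outside the
#' source field of view are non-members.
#'
#' @param mask a `binary_mask`.
#' @param t an [affine_transform] from `mask$grid` toward `target` (any
#'   convention; converted internally), or NULL for the identity world map
#'   (co-registered grids).
#' @param target target [voxel_grid]; defaults to the transform's target
#'   grid, or the mask's own grid when `t` is NULL.
#' @param interp `"nearest"` or `"trilinear"`.
#' @param threshold re-binarisation threshold for trilinear interpolation.
#' @return A `binary_mask` on `target`, with role and patient id preserved.
#' @export
apply_to_mask <- function(mask, t = NULL, target = NULL,
                          interp = c("nearest", "trilinear"),
                          threshold = 0.5) {
  stopifnot(inherits(mask, "binary_mask"))
  interp <- match.arg(interp)
  geo <- resolve_resampling(mask$grid, t, target)
  src <- array(as.numeric(mask$voxels), dim = mask$grid$shape)
  out <- if (interp == "nearest") {
    resample_nearest(src, geo$map, geo$target$shape) > 0.5
  } else {
    resample_trilinear(src, geo$map, geo$target$shape) > threshold
  }
  binary_mask(out, geo$target, role = mask$role, patient_id = mask$patient_id)
}

#' Resample a label volume onto a target grid
#'
#' As [apply_to_mask()] but for integer parcellations; nearest-neighbour
#' only, so every output label existed in the input. The label table is
#' unchanged. Voxels pulling back outside the source become background. A
#' dual-membership sidecar, if present, is resampled the same way.
#'
#' @param lv a `label_volume`.
#' @inheritParams apply_to_mask
#' @return A `label_volume` on `target`.
#' @export
apply_to_labels <- function(lv, t = NULL, target = NULL) {
  stopifnot(inherits(lv, "label_volume"))
  geo <- resolve_resampling(lv$grid, t, target)
  lab <- array(as.integer(resample_nearest(lv$labels, geo$map, geo$target$shape)),
               dim = geo$target$shape)
  sec <- NULL
  if (!is.null(lv$secondary)) {
    sec <- array(as.integer(resample_nearest(lv$secondary, geo$map,
                                             geo$target$shape)),
                 dim = geo$target$shape)
    if (!any(sec > 0L)) sec <- NULL
  }
  label_volume(lab, geo$target, lv$label_table, secondary = sec,
               offset = lv$offset)
}

# Works out the target grid and the 4x4 map from 0-based target voxel
# indices to 0-based source voxel indices (continuous).
resolve_resampling <- function(source_grid, t, target) {
  if (is.null(t)) {
    if (is.null(target)) target <- source_grid
    if (!is_voxel_grid(target)) stop("target must be a voxel_grid")
    world <- diag(4)
  } else {
    stopifnot(inherits(t, "affine_transform"))
    if (!grids_compatible(t$source_grid, source_grid))
      stop_grid_mismatch(t$source_grid, source_grid,
                         "transform source vs input volume")
    t <- to_world_convention(t)
    if (is.null(target)) target <- t$target_grid
    if (!is_voxel_grid(target)) stop("target must be a voxel_grid")
    world <- t$matrix
  }
  map <- solve(source_grid$affine) %*% solve(world) %*% target$affine
  list(target = target, map = map)
}

# Continuous source voxel coordinates for every target voxel: 3 x N matrix.
pullback_coords <- function(map, shape) {
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1L),
                               j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  map[1:3, ] %*% rbind(t(idx), 1)
}

# Round half toward the lower index: deterministic tie-break.
round_half_down <- function(x) ceiling(x - 0.5)

resample_nearest <- function(src, map, out_shape) {
  n <- prod(out_shape)
  co <- pullback_coords(map, out_shape)
  ijk <- round_half_down(co)
  d <- dim(src)
  inside <- ijk[1, ] >= 0 & ijk[1, ] < d[1] &
    ijk[2, ] >= 0 & ijk[2, ] < d[2] &
    ijk[3, ] >= 0 & ijk[3, ] < d[3]
  out <- numeric(n)
  if (any(inside)) {
    lin <- ijk[1, inside] + d[1] * (ijk[2, inside] + d[2] * ijk[3, inside]) + 1
    out[inside] <- src[lin]
  }
  array(out, dim = out_shape)
}

resample_trilinear <- function(src, map, out_shape) {
  n <- prod(out_shape)
  co <- pullback_coords(map, out_shape)
  d <- dim(src)
  f <- floor(co)
  w <- co - f
  out <- numeric(n)
  # voxels whose full 8-corner neighbourhood lies inside the FOV
  inside <- f[1, ] >= 0 & f[1, ] < d[1] - 1 &
    f[2, ] >= 0 & f[2, ] < d[2] - 1 &
    f[3, ] >= 0 & f[3, ] < d[3] - 1
  if (any(inside)) {
    fi <- f[, inside, drop = FALSE]
    wi <- w[, inside, drop = FALSE]
    base <- fi[1, ] + d[1] * (fi[2, ] + d[2] * fi[3, ]) + 1
    acc <- numeric(sum(inside))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wt <- (if (dx) wi[1, ] else 1 - wi[1, ]) *
        (if (dy) wi[2, ] else 1 - wi[2, ]) *
        (if (dz) wi[3, ] else 1 - wi[3, ])
      acc <- acc + wt * src[base + dx + d[1] * (dy + d[2] * dz)]
    }
    out[inside] <- acc
  }
  array(out, dim = out_shape)
}
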