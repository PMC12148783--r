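#' Map daily-image points into planning coordinates
#'
#' Applies the rigid couch-shift translation: \code{p -> p + translation}.
#' Exact arithmetic, no interpolation.
#'
#' @param points n x 3 numeric matrix of (x, y, z) mm in daily coordinates.
#' @param shift a \code{\link{rigid_shift}}.
#' @return n x 3 matrix of points in planning coordinates.
#' @export
transform_points <- function(points, shift) {
  stopifnot(inherits(shift, "rigid_shift"))
  points <- matrix(as.numeric(points), ncol = 3L)
  sweep(points, 2L, shift$translation, `+`)
}

#' Sample a dose grid at arbitrary points
#'
#' Trilinear interpolation of the planned dose at the given points (planning
#' coordinates, mm). Points outside the grid's support return 0 Gy and are
#' counted rather than raised: SABR CBCT fields of view are narrow and a
#' small out-of-grid fringe is expected, but the caller must see its size.
#'
#' @param dose a \code{\link{dose_grid}} with at least 2 voxels per axis.
#' @param points n x 3 numeric matrix of (x, y, z) mm.
#' @return A list with \code{dose} (numeric vector, Gy), \code{outside}
#'   (logical vector) and \code{n_outside}.
#' @export
sample_dose <- function(dose, points) {
  stopifnot(inherits(dose, "dose_grid"))
  if (any(dose$geometry$dims < 2L))
    stop("dose grid must have at least 2 voxels along each axis to interpolate")
  points <- matrix(as.numeric(points), ncol = 3L)
  res <- .cpp_sample_grid(as.numeric(dose$values), dose$geometry$origin,
                          dose$geometry$spacing, dose$geometry$dims, points)
  list(dose = res$dose, outside = res$outside, n_outside = sum(res$outside))
}

#' Per-voxel planned dose inside a daily structure
#'
#' The dose-superimposition step: the centres of the mask's set voxels (daily
#' grid) are shifted into planning coordinates and the planned dose is
#' sampled there. No dose recalculation is performed — the planned
#' distribution is assumed rigid ("dose cloud") under the small online couch
#' corrections this workflow handles.
#'
#' @param dose planned \code{\link{dose_grid}}.
#' @param mask daily-structure \code{\link{binary_mask}}.
#' @param shift \code{\link{rigid_shift}} mapping daily to plan coordinates.
#' @return A list with \code{doses} (Gy, one per set voxel),
#'   \code{voxel_volume_cm3}, \code{out_of_grid_fraction} and
#'   \code{n_voxels}.
#' @export
structure_doses <- function(dose, mask, shift = rigid_shift()) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "binary_mask"))
  idx <- which(mask$voxels)
  vv <- prod(mask$geometry$spacing) / 1000
  if (length(idx) == 0L) {
    warning("empty mask: no voxels to sample")
    return(list(doses = numeric(0), voxel_volume_cm3 = vv,
                out_of_grid_fraction = NA_real_, n_voxels = 0L))
  }
  ai <- arrayInd(idx, mask$geometry$dims)
  centers <- cbind(
    mask$geometry$origin[1] + (ai[, 1] - 1) * mask$geometry$spacing[1],
    mask$geometry$origin[2] + (ai[, 2] - 1) * mask$geometry$spacing[2],
    mask$geometry$origin[3] + (ai[, 3] - 1) * mask$geometry$spacing[3])
  s <- sample_dose(dose, transform_points(centers, shift))
  frac_out <- s$n_outside / length(idx)
  if (frac_out > 0)
    warning(sprintf("%.1f%% of structure voxels fall outside the dose grid",
                    100 * frac_out))
  list(doses = s$dose, voxel_volume_cm3 = vv,
       out_of_grid_fraction = frac_out, n_voxels = length(idx))
}
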