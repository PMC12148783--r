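#' Grid geometry in the DICOM patient coordinate frame
#'
#' Describes a regular 3-D voxel grid in DICOM patient coordinates
#' (millimetres; +x patient-left, +y patient-posterior, +z patient-superior,
#' so "anterior" is the -y direction). \code{origin} is the centre of voxel
#' \code{[1,1,1]}. Only axial (identity-orientation) grids are supported; dose
#' grids with other orientations are rejected rather than silently resampled.
#'
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param spacing numeric length-3, strictly positive voxel spacing in mm.
#' @param dims integer length-3, number of voxels along x, y, z.
#' @param orientation 3x3 direction-cosine matrix; must be orthonormal.
#'   Defaults to the identity (axial, head-first supine).
#' @return An object of class \code{grid_geometry}.
#' @export
grid_geometry <- function(origin, spacing, dims, orientation = diag(3)) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(spacing <= 0)) stop("grid spacing must be strictly positive")
  if (any(dims < 1L)) stop("grid dims must be positive integers")
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix must be orthonormal")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 orientation = orientation),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$dims[1], x$dims[2], x$dims[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

geom_equal <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(a$dims == b$dims) &&
    all(abs(a$orientation - b$orientation) < tol)
}

#' Voxel-centre coordinates of a grid axis
#'
#' @param geometry a \code{grid_geometry}.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of voxel-centre positions in mm.
#' @export
grid_axis <- function(geometry, axis) {
  geometry$origin[axis] + (seq_len(geometry$dims[axis]) - 1) * geometry$spacing[axis]
}

#' Planned dose distribution on a regular grid
#'
#' @param values 3-D numeric array of dose in Gy (physical dose; any stored
#'   scaling must already be applied). Dimensions are (x, y, z).
#' @param geometry a \code{grid_geometry} whose \code{dims} match
#'   \code{dim(values)}.
#' @param source_uid opaque identifier of the source object (e.g. a DICOM
#'   SOP Instance UID).
#' @return An object of class \code{dose_grid}.
#' @export
dose_grid <- function(values, geometry, source_uid = "") {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == geometry$dims))
    stop("dose array shape does not match geometry dims")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  structure(list(values = values, geometry = geometry,
                 source_uid = as.character(source_uid)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid [%s], dose %.3f - %.3f Gy\n",
              format(x$geometry), min(x$values), max(x$values)))
  invisible(x)
}

#' A single closed planar contour
#'
#' @param points numeric n x 3 matrix of (x, y, z) vertices in mm. The polygon
#'   is implicitly closed (last vertex connects back to the first). All
#'   vertices must share one z plane within 1e-3 mm.
#' @return An object of class \code{rt_contour}.
#' @export
rt_contour <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("contour points must be an n x 3 matrix")
  if (nrow(points) < 3L) stop("contour must have at least 3 vertices")
  if (diff(range(points[, 3])) > 1e-3)
    stop("contour vertices do not lie on a single z plane (spread > 1e-3 mm)")
  dimnames(points) <- NULL
  structure(list(points = points, z = mean(points[, 3])), class = "rt_contour")
}

#' A named structure (region of interest)
#'
#' @param name structure name, e.g. \code{"Bladder"}.
#' @param contours list of \code{rt_contour} objects (may be empty).
#' @return An object of class \code{rt_structure}.
#' @export
rt_structure <- function(name, contours = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!all(vapply(contours, inherits, logical(1), "rt_contour")))
    stop("contours must be a list of rt_contour objects")
  structure(list(name = name, contours = contours), class = "rt_structure")
}

#' @export
print.rt_structure <- function(x, ...) {
  cat(sprintf("rt_structure '%s': %d contour(s)\n", x$name, length(x$contours)))
  invisible(x)
}

#' A set of named structures sharing one frame of reference
#'
#' @param structures list of \code{rt_structure}; names must be unique.
#' @param frame_of_reference opaque frame-of-reference identifier.
#' @return An object of class \code{structure_set}. Structures are accessible
#'   by name via \code{$structures[[name]]}.
#' @export
structure_set <- function(structures = list(), frame_of_reference = "") {
  if (!all(vapply(structures, inherits, logical(1), "rt_structure")))
    stop("structures must be a list of rt_structure objects")
  nm <- vapply(structures, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate structure name: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(structures) <- nm
  structure(list(structures = structures,
                 frame_of_reference = as.character(frame_of_reference)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set with %d structure(s):\n", length(x$structures)))
  for (s in x$structures)
    cat(sprintf("  %-16s %d contour(s)\n", s$name, length(s$contours)))
  invisible(x)
}

#' A 3-DOF rigid couch shift
#'
#' The translation maps a point in daily (CBCT) coordinates into planning
#' coordinates: the planned dose at daily point \code{p} is sampled at
#' \code{p + translation}. Under the DICOM axis convention an isocenter shift
#' of 4 mm anteriorly corresponds to \code{rigid_shift(c(0, -4, 0))}.
#'
#' @param translation numeric length-3 (tx, ty, tz) in mm.
#' @param warn_mm warn if any component exceeds this magnitude (default 10 mm;
#'   online couch corrections larger than this deserve scrutiny).
#' @return An object of class \code{rigid_shift}.
#' @export
rigid_shift <- function(translation = c(0, 0, 0), warn_mm = 10) {
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (any(!is.finite(translation))) stop("shift components must be finite")
  if (any(abs(translation) > warn_mm))
    warning(sprintf("shift component exceeds %g mm: (%g, %g, %g)", warn_mm,
                    translation[1], translation[2], translation[3]))
  structure(list(translation = translation), class = "rigid_shift")
}

#' @export
print.rigid_shift <- function(x, ...) {
  cat(sprintf("rigid_shift (%g, %g, %g) mm [daily -> plan]\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' A voxelised structure mask
#'
#' @param voxels 3-D logical array.
#' @param geometry \code{grid_geometry} matching \code{dim(voxels)}.
#' @return An object of class \code{binary_mask}.
#' @export
binary_mask <- function(voxels, geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "logical"
  if (length(dim(voxels)) != 3L || !all(dim(voxels) == geometry$dims))
    stop("mask shape does not match geometry dims")
  structure(list(voxels = voxels, geometry = geometry), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask [%s]: %d voxels set, %.2f cm^3\n",
              format(x$geometry), sum(x$voxels), mask_volume(x)))
  invisible(x)
}
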