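#' Rasterize a structure onto a voxel grid
#'
#' A voxel is set iff its centre lies inside the union of the slice's
#' contours under the even-odd rule (so coplanar nested contours carve
#' holes). Each contour is assigned to the nearest grid slice; a contour
#' whose plane is farther than half the slice spacing from every grid slice
#' is an error.
#'
#' @param structure an \code{\link{rt_structure}}.
#' @param geometry the target \code{\link{grid_geometry}}.
#' @return A \code{\link{binary_mask}} on \code{geometry}.
#' @export
rasterize <- function(structure, geometry) {
  stopifnot(inherits(structure, "rt_structure"),
            inherits(geometry, "grid_geometry"))
  dims <- geometry$dims
  vox <- array(FALSE, dim = dims)
  if (length(structure$contours) == 0L)
    return(binary_mask(vox, geometry))

  zc <- vapply(structure$contours, `[[`, numeric(1), "z")
  dz <- geometry$spacing[3]
  kf <- (zc - geometry$origin[3]) / dz
  k <- as.integer(round(kf)) + 1L
  off <- abs(zc - (geometry$origin[3] + (k - 1L) * dz))
  bad <- off > dz / 2 + 1e-9 | k < 1L | k > dims[3]
  if (any(bad))
    stop("contour z planes outside grid slices (tolerance dz/2): ",
         paste(sprintf("%.3f", zc[bad]), collapse = ", "), " mm")

  xs <- grid_axis(geometry, 1)
  ys <- grid_axis(geometry, 2)
  px <- rep(xs, times = dims[2])
  py <- rep(ys, each = dims[1])
  for (kk in unique(k)) {
    polys <- lapply(structure$contours[k == kk],
                    function(ct) ct$points[, 1:2, drop = FALSE])
    inside <- .cpp_slice_parity(px, py, polys)
    vox[, , kk] <- vox[, , kk] | matrix(inside, dims[1], dims[2])
  }
  binary_mask(vox, geometry)
}

#' Volume of a binary mask
#'
#' @param mask a \code{\link{binary_mask}}.
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * prod(mask$geometry$spacing) / 1000
}

#' Expand a mask by an isotropic margin
#'
#' Euclidean dilation on voxel centres: a voxel is set in the result iff its
#' centre lies within \code{margin} mm of the centre of some set voxel. The
#' default is a true 3-D expansion, matching treatment-planning-system margin
#' tools; \code{mode = "2d"} restricts the dilation to within each axial
#' slice for clinics whose planning structures were grown slice-wise.
#'
#' @param mask a \code{\link{binary_mask}}.
#' @param margin margin in mm, must be >= 0. \code{expand_mask(m, 0)} is
#'   \code{m}.
#' @param mode \code{"3d"} (default) or \code{"2d"}.
#' @return The dilated \code{\link{binary_mask}}.
#' @export
expand_mask <- function(mask, margin, mode = c("3d", "2d")) {
  stopifnot(inherits(mask, "binary_mask"))
  mode <- match.arg(mode)
  if (margin < 0) stop("margin must be non-negative")
  if (margin == 0 || !any(mask$voxels)) return(mask)

  dims <- mask$geometry$dims
  sp <- mask$geometry$spacing
  rx <- floor(margin / sp[1]); ry <- floor(margin / sp[2])
  rz <- if (mode == "3d") floor(margin / sp[3]) else 0
  offs <- expand.grid(ox = -rx:rx, oy = -ry:ry, oz = -rz:rz)
  d2 <- (offs$ox * sp[1])^2 + (offs$oy * sp[2])^2 + (offs$oz * sp[3])^2
  offs <- as.matrix(offs[d2 <= margin^2 + 1e-9, , drop = FALSE])

  vox <- mask$voxels
  # dilation = mask U (surface voxels + ball offsets); a 6-connected surface
  # voxel exists on every digital path leaving the mask
  all_nb <- array(TRUE, dims)
  shift1 <- function(a, d, s) {
    out <- array(FALSE, dims)
    idx_to <- lapply(dims, seq_len); idx_from <- idx_to
    if (s > 0) { idx_to[[d]] <- seq_len(dims[d] - s)
                 idx_from[[d]] <- seq_len(dims[d] - s) + s }
    else { idx_to[[d]] <- seq_len(dims[d] + s) - s
           idx_from[[d]] <- seq_len(dims[d] + s) }
    out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      a[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    out
  }
  for (d in 1:3) for (s in c(-1L, 1L))
    all_nb <- all_nb & shift1(vox, d, s)
  surf <- which(vox & !all_nb)
  ai <- arrayInd(surf, dims)

  out <- vox
  d1 <- dims[1]; d12 <- dims[1] * dims[2]
  for (m in seq_len(nrow(offs))) {
    xi <- ai[, 1] + offs[m, 1]; yi <- ai[, 2] + offs[m, 2]
    zi <- ai[, 3] + offs[m, 3]
    keep <- xi >= 1L & xi <= dims[1] & yi >= 1L & yi <= dims[2] &
      zi >= 1L & zi <= dims[3]
    if (!any(keep)) next
    out[xi[keep] + d1 * (yi[keep] - 1L) + d12 * (zi[keep] - 1L)] <- TRUE
  }
  binary_mask(out, mask$geometry)
}

#' Compare a daily organ volume against its planning volume
#'
#' Computes the inter-fraction volume-change quantities used for setup
#' assessment: the volume difference \eqn{\Delta V = V_{CBCT} - V_{pCT}}, the
#' volume ratio \eqn{V_{CBCT}/V_{pCT} \times 100\%}, and the percent
#' deviation \eqn{(V_{CBCT}-V_{pCT})/V_{pCT} \times 100\%}. The bladder
#' decision tree requires the treatment volume to be at least two-thirds of
#' the planning volume; \code{under_filled} flags ratios below that.
#'
#' @param v_pct planning-CT structure volume, cm^3 (> 0).
#' @param v_cbct daily (CBCT) structure volume, cm^3.
#' @return An object of class \code{volume_comparison} with fields
#'   \code{v_pct}, \code{v_cbct}, \code{delta_v}, \code{ratio_pct},
#'   \code{deviation_pct}, \code{under_filled}.
#' @export
compare_volumes <- function(v_pct, v_cbct) {
  if (!is.finite(v_pct) || v_pct <= 0) stop("v_pct must be positive")
  if (!is.finite(v_cbct) || v_cbct < 0) stop("v_cbct must be non-negative")
  ratio <- v_cbct / v_pct * 100
  structure(list(v_pct = v_pct, v_cbct = v_cbct,
                 delta_v = v_cbct - v_pct,
                 ratio_pct = ratio,
                 deviation_pct = ratio - 100,
                 under_filled = ratio < 200 / 3 - 1e-7),
            class = "volume_comparison")
}

#' @export
print.volume_comparison <- function(x, ...) {
  cat(sprintf(
    "volume_comparison: pCT %.1f cm^3, CBCT %.1f cm^3 (%.1f%%, deviation %+.1f%%)%s\n",
    x$v_pct, x$v_cbct, x$ratio_pct, x$deviation_pct,
    if (x$under_filled) " [under-filled: < 2/3 of planning volume]" else ""))
  invisible(x)
}

#' Count axial slices with anterior rectal distension
#'
#' For each axial slice on which both masks are non-empty, compares the most
#' anterior extent (minimum y of set voxel centres; anterior is -y) of the
#' daily rectum against that of the expanded planning rectum. A slice counts
#' as distended when the daily rectum reaches strictly more anterior than the
#' expanded planning structure. The rectum decision rule flags setups
#' distended on at least three slices.
#'
#' @param daily_rectum daily rectum \code{\link{binary_mask}}.
#' @param pct_rectum_expanded planning rectum mask already expanded by the
#'   clinical margin (typically 5 mm), on the same geometry.
#' @return Integer count of distended slices.
#' @export
anterior_distension_slices <- function(daily_rectum, pct_rectum_expanded) {
  stopifnot(inherits(daily_rectum, "binary_mask"),
            inherits(pct_rectum_expanded, "binary_mask"))
  if (!geom_equal(daily_rectum$geometry, pct_rectum_expanded$geometry))
    stop("masks must share one grid geometry")
  dims <- daily_rectum$geometry$dims
  n <- 0L
  for (k in seq_len(dims[3])) {
    d <- daily_rectum$voxels[, , k]
    p <- pct_rectum_expanded$voxels[, , k]
    if (!any(d) || !any(p)) next
    ymin_d <- min(which(apply(d, 2, any)))
    ymin_p <- min(which(apply(p, 2, any)))
    if (ymin_d < ymin_p) n <- n + 1L
  }
  n
}
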