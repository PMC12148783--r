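#' Cumulative dose-volume histogram
#'
#' Builds the cumulative DVH by direct voxel counting: the curve value at
#' dose d is the volume receiving at least d. The curve is for reporting and
#' plotting; clinical metrics are computed from the raw voxel doses
#' (\code{\link{metric_V}}, \code{\link{metric_D}}) so that binning never
#' biases classification.
#'
#' @param doses per-voxel dose vector, Gy (non-negative).
#' @param voxel_volume_cm3 volume of one voxel, cm^3.
#' @param bin_width_gy histogram bin width, Gy (default 0.01).
#' @param name structure name carried on the curve.
#' @return An object of class \code{dvh_curve} with \code{bin_edges_gy},
#'   \code{cumulative_volume_cm3}, \code{total_volume_cm3}, \code{name}.
#' @export
compute_dvh <- function(doses, voxel_volume_cm3, bin_width_gy = 0.01,
                        name = "") {
  if (any(doses < 0)) stop("doses must be non-negative")
  if (bin_width_gy <= 0) stop("bin width must be positive")
  total <- length(doses) * voxel_volume_cm3
  top <- if (length(doses)) max(doses) else 0
  edges <- seq(0, top + bin_width_gy, by = bin_width_gy)
  cum <- vapply(edges, function(e) sum(doses >= e), numeric(1)) *
    voxel_volume_cm3
  structure(list(bin_edges_gy = edges, cumulative_volume_cm3 = cum,
                 total_volume_cm3 = total, name = name),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve%s: total %.2f cm^3, max dose < %.2f Gy, %d bins\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              x$total_volume_cm3, max(x$bin_edges_gy), length(x$bin_edges_gy)))
  invisible(x)
}

#' @param x a \code{dvh_curve}.
#' @param relative plot percent volume instead of cm^3.
#' @param ... passed to \code{plot}.
#' @rdname compute_dvh
#' @export
plot.dvh_curve <- function(x, relative = TRUE, ...) {
  y <- x$cumulative_volume_cm3
  ylab <- "Volume (cm³)"
  if (relative && x$total_volume_cm3 > 0) {
    y <- y / x$total_volume_cm3 * 100
    ylab <- "Volume (%)"
  }
  graphics::plot(x$bin_edges_gy, y, type = "s", xlab = "Dose (Gy)",
                 ylab = ylab, main = x$name, ...)
  invisible(x)
}

#' Export a DVH curve as a data frame (dose, cm^3, percent)
#'
#' @param curve a \code{dvh_curve}.
#' @return data.frame with columns \code{dose_gy}, \code{volume_cm3},
#'   \code{volume_pct}.
#' @export
dvh_table <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  data.frame(dose_gy = curve$bin_edges_gy,
             volume_cm3 = curve$cumulative_volume_cm3,
             volume_pct = if (curve$total_volume_cm3 > 0)
               curve$cumulative_volume_cm3 / curve$total_volume_cm3 * 100
             else 0 * curve$cumulative_volume_cm3)
}

#' V-at-dose metric
#'
#' Volume receiving at least \code{dose_level_gy} (closed inequality: a voxel
#' exactly at the level counts, the conservative convention for OAR limits).
#'
#' @param doses per-voxel dose vector, Gy.
#' @param voxel_volume_cm3 volume of one voxel, cm^3.
#' @param dose_level_gy dose level, Gy.
#' @param units \code{"cm3"} (absolute) or \code{"pct"} (percent of
#'   structure volume).
#' @return The metric value.
#' @export
metric_V <- function(doses, voxel_volume_cm3, dose_level_gy,
                     units = c("cm3", "pct")) {
  units <- match.arg(units)
  if (any(doses < 0)) stop("doses must be non-negative")
  vol <- sum(doses >= dose_level_gy) * voxel_volume_cm3
  if (units == "cm3") return(vol)
  total <- length(doses) * voxel_volume_cm3
  if (total == 0) stop("empty structure: relative metric undefined")
  vol / total * 100
}

#' D-at-volume metric
#'
#' Minimum dose received by the hottest \code{volume_level} of the
#' structure. Computed from the sorted voxel doses with linear interpolation
#' of the cumulative-volume curve between voxel steps, so sub-voxel volumes
#' such as D0.003cc are supported; a request below one voxel's volume returns
#' the maximum voxel dose with a sub-resolution warning (near-point-dose
#' metrics are only trustworthy when the probing volume exceeds the dose-grid
#' resolution).
#'
#' @param doses per-voxel dose vector, Gy (non-empty).
#' @param voxel_volume_cm3 volume of one voxel, cm^3.
#' @param volume_level volume at which to read the dose.
#' @param volume_units \code{"cm3"} or \code{"pct"} (percent of total).
#' @param output \code{"gy"} or \code{"pct_rx"} (percent of prescription).
#' @param prescription_gy prescription dose for \code{"pct_rx"} (default 40).
#' @return Dose in Gy, or percent of prescription.
#' @export
metric_D <- function(doses, voxel_volume_cm3, volume_level,
                     volume_units = c("cm3", "pct"),
                     output = c("gy", "pct_rx"), prescription_gy = 40) {
  volume_units <- match.arg(volume_units)
  output <- match.arg(output)
  if (length(doses) == 0L) stop("empty structure: D metric undefined")
  total <- length(doses) * voxel_volume_cm3
  v <- if (volume_units == "pct") volume_level / 100 * total else volume_level
  if (v <= 0) stop("volume level must be positive")
  if (v - total >= voxel_volume_cm3 * (1 - 1e-12))
    stop(sprintf("volume level %.4g cm^3 exceeds structure volume %.4g cm^3",
                 v, total))
  sorted <- sort(doses, decreasing = TRUE)
  cumvol <- seq_along(sorted) * voxel_volume_cm3
  if (v > total) {
    # within one voxel of the whole structure: a sub-resolution request on a
    # structure smaller than the probing volume (e.g. D0.003cc on a single
    # sub-0.003 cm^3 voxel); the whole structure is the hottest volume
    warning(sprintf(
      "requested volume %.4g cm^3 exceeds the structure volume %.4g cm^3 by less than one voxel; returning the coldest voxel dose (sub-resolution metric)",
      v, total))
    d <- sorted[length(sorted)]
  } else if (v < voxel_volume_cm3) {
    if (v < voxel_volume_cm3 * (1 - 1e-12))
      warning(sprintf(
        "requested volume %.4g cm^3 is below the voxel volume %.4g cm^3; returning the maximum voxel dose (sub-resolution metric)",
        v, voxel_volume_cm3))
    d <- sorted[1]
  } else {
    d <- stats::approx(cumvol, sorted, xout = v, rule = 2)$y
  }
  if (output == "pct_rx") d / prescription_gy * 100 else d
}

#' Maximum dose metric
#'
#' @inheritParams metric_D
#' @return Maximum voxel dose (Gy or percent of prescription).
#' @export
metric_Dmax <- function(doses, output = c("gy", "pct_rx"),
                        prescription_gy = 40) {
  output <- match.arg(output)
  if (length(doses) == 0L) stop("empty structure: Dmax undefined")
  d <- max(doses)
  if (output == "pct_rx") d / prescription_gy * 100 else d
}
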