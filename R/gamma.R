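#' Gamma-analysis parameters
#'
#' Local-normalisation gamma comparison parameters. Defaults follow the
#' clinical QA protocol this package targets: 2\% local dose tolerance, 2 mm
#' distance-to-agreement (DTA), evaluation restricted to reference voxels at
#' or above 10\% of the reference maximum, and candidate points sampled on a
#' lattice with pitch DTA / interpolation fraction (default fraction 10, i.e.
#' 0.2 mm). The search ball radius defaults to 3 x DTA; a candidate farther
#' than that can only win when the dose term is tiny there, and the cap is
#' configurable.
#'
#' @param dose_tolerance_pct local dose-difference tolerance, percent.
#' @param dta_mm distance-to-agreement, mm.
#' @param low_dose_threshold_pct evaluate only reference voxels with dose at
#'   or above this percent of the reference maximum.
#' @param interpolation_fraction positive integer; the candidate lattice
#'   pitch is \code{dta_mm / interpolation_fraction}.
#' @param max_search_radius_mm candidate search radius (>= dta_mm).
#' @return A list of class \code{gamma_params}.
#' @export
gamma_params <- function(dose_tolerance_pct = 2, dta_mm = 2,
                         low_dose_threshold_pct = 10,
                         interpolation_fraction = 10L,
                         max_search_radius_mm = 3 * dta_mm) {
  stopifnot(dose_tolerance_pct > 0, dta_mm > 0,
            low_dose_threshold_pct > 0, low_dose_threshold_pct < 100,
            interpolation_fraction >= 1)
  if (max_search_radius_mm < dta_mm)
    stop("max_search_radius_mm must be at least dta_mm")
  structure(list(dose_tolerance_pct = dose_tolerance_pct,
                 dta_mm = dta_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 interpolation_fraction = as.integer(interpolation_fraction),
                 max_search_radius_mm = max_search_radius_mm),
            class = "gamma_params")
}

.gamma_result <- function(gamma_values, geometry) {
  evaluated <- !is.na(gamma_values)
  n_eval <- sum(evaluated)
  structure(list(
    gamma = array(gamma_values, dim = geometry$dims),
    geometry = geometry,
    evaluated_voxels = n_eval,
    passing_rate_pct = if (n_eval)
      100 * sum(gamma_values[evaluated] <= 1) / n_eval else NaN),
    class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma_result: %d voxels evaluated, passing rate %.2f%%\n",
              x$evaluated_voxels, x$passing_rate_pct))
  invisible(x)
}

#' Local gamma-index map between two dose distributions
#'
#' For every reference voxel with dose at or above the low-dose threshold,
#' computes
#' \deqn{\gamma(r) = \min_c \sqrt{ \frac{|r-c|^2}{\mathrm{DTA}^2} +
#'   \frac{(D_e(c) - D_r(r))^2}{(t \cdot D_r(r))^2} }}
#' over candidate points \eqn{c} on a regular lattice (pitch = DTA /
#' interpolation fraction) inside the search ball, with the evaluated dose
#' trilinearly interpolated at each candidate and the dose denominator
#' normalised to the reference voxel's own dose (local gamma). Candidates
#' outside the evaluated grid's support are skipped. The optimised search
#' visits candidates in order of increasing distance and terminates early
#' once no farther candidate can improve the minimum;
#' \code{\link{gamma_bruteforce}} evaluates the identical definition
#' exhaustively.
#'
#' @param reference reference \code{\link{dose_grid}} (sets the evaluation
#'   points and the local normalisation).
#' @param evaluated evaluated \code{\link{dose_grid}}.
#' @param params a \code{\link{gamma_params}}.
#' @return A \code{gamma_result}: the gamma array (NA below threshold), the
#'   evaluated-voxel count and the passing rate (\eqn{\gamma \le 1}) in
#'   percent.
#' @export
gamma_map <- function(reference, evaluated, params = gamma_params()) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"),
            inherits(params, "gamma_params"))
  if (max(reference$values) <= 0)
    stop("reference distribution has zero maximum dose")
  if (any(evaluated$geometry$dims < 2L))
    stop("evaluated grid must have at least 2 voxels along each axis")
  g <- .cpp_gamma_map(
    as.numeric(reference$values), reference$geometry$origin,
    reference$geometry$spacing, reference$geometry$dims,
    as.numeric(evaluated$values), evaluated$geometry$origin,
    evaluated$geometry$spacing, evaluated$geometry$dims,
    params$dose_tolerance_pct / 100, params$dta_mm,
    params$low_dose_threshold_pct / 100,
    params$dta_mm / params$interpolation_fraction,
    params$max_search_radius_mm)
  .gamma_result(g, reference$geometry)
}

#' Exhaustive gamma-index oracle
#'
#' Same definition as \code{\link{gamma_map}}, evaluated by exhaustive
#' vectorised search over the full candidate lattice with no pruning or
#' early termination. Intended as an independent correctness oracle on small
#' grids; complexity is O(voxels x candidates).
#'
#' @inheritParams gamma_map
#' @param max_voxels guard against accidental use on large grids.
#' @return A \code{gamma_result}.
#' @export
gamma_bruteforce <- function(reference, evaluated, params = gamma_params(),
                             max_voxels = 32^3) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"))
  if (prod(reference$geometry$dims) > max_voxels)
    stop("gamma_bruteforce is an oracle for small grids (<= ", max_voxels,
         " voxels)")
  refmax <- max(reference$values)
  if (refmax <= 0) stop("reference distribution has zero maximum dose")

  step <- params$dta_mm / params$interpolation_fraction
  ns <- floor(params$max_search_radius_mm / step + 1e-9)
  offs <- as.matrix(expand.grid(ox = (-ns:ns) * step, oy = (-ns:ns) * step,
                                oz = (-ns:ns) * step))
  d2 <- rowSums(offs^2)
  keep <- d2 <= params$max_search_radius_mm^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  d2 <- d2[keep]

  rg <- reference$geometry
  eg <- evaluated$geometry
  ev <- evaluated$values
  cutoff <- params$low_dose_threshold_pct / 100 * refmax
  tol <- params$dose_tolerance_pct / 100
  dta2 <- params$dta_mm^2

  out <- rep(NA_real_, prod(rg$dims))
  idx <- which(reference$values >= cutoff)
  ai <- arrayInd(idx, rg$dims)
  rx <- rg$origin[1] + (ai[, 1] - 1) * rg$spacing[1]
  ry <- rg$origin[2] + (ai[, 2] - 1) * rg$spacing[2]
  rz <- rg$origin[3] + (ai[, 3] - 1) * rg$spacing[3]

  for (q in seq_along(idx)) {
    dr <- reference$values[idx[q]]
    cx <- rx[q] + offs[, 1]; cy <- ry[q] + offs[, 2]; cz <- rz[q] + offs[, 3]
    fx <- (cx - eg$origin[1]) / eg$spacing[1]
    fy <- (cy - eg$origin[2]) / eg$spacing[2]
    fz <- (cz - eg$origin[3]) / eg$spacing[3]
    ok <- fx >= 0 & fx <= eg$dims[1] - 1 & fy >= 0 & fy <= eg$dims[2] - 1 &
      fz >= 0 & fz <= eg$dims[3] - 1
    if (!any(ok)) {
      out[idx[q]] <- Inf
      next
    }
    i0 <- pmin(floor(fx[ok]), eg$dims[1] - 2); i0 <- pmax(i0, 0)
    j0 <- pmin(floor(fy[ok]), eg$dims[2] - 2); j0 <- pmax(j0, 0)
    k0 <- pmin(floor(fz[ok]), eg$dims[3] - 2); k0 <- pmax(k0, 0)
    ax <- fx[ok] - i0; ay <- fy[ok] - j0; az <- fz[ok] - k0
    n1 <- eg$dims[1]; n12 <- eg$dims[1] * eg$dims[2]
    base <- i0 + n1 * j0 + n12 * k0 + 1
    de <-
      ((ev[base] * (1 - ax) + ev[base + 1] * ax) * (1 - ay) +
       (ev[base + n1] * (1 - ax) + ev[base + n1 + 1] * ax) * ay) * (1 - az) +
      ((ev[base + n12] * (1 - ax) + ev[base + n12 + 1] * ax) * (1 - ay) +
       (ev[base + n12 + n1] * (1 - ax) + ev[base + n12 + n1 + 1] * ax) * ay) * az
    g2 <- d2[ok] / dta2 + ((de - dr) / (tol * dr))^2
    out[idx[q]] <- sqrt(min(g2))
  }
  .gamma_result(out, rg)
}

#' Gamma passing rates at several low-dose thresholds
#'
#' Re-runs the gamma analysis at each threshold (e.g. 10\% of the reference
#' maximum to include most patient voxels, 50\% to examine only the
#' high-dose region near the target). Raising the threshold never increases
#' the evaluated-voxel count.
#'
#' @inheritParams gamma_map
#' @param thresholds_pct numeric vector of thresholds in (0, 100).
#' @return A data.frame with columns \code{threshold_pct},
#'   \code{passing_rate_pct}, \code{evaluated_voxels}; the per-threshold
#'   \code{gamma_result}s are attached as attribute \code{"results"}.
#' @export
passing_rate_at_thresholds <- function(reference, evaluated,
                                       params = gamma_params(),
                                       thresholds_pct = c(10, 50)) {
  stopifnot(all(thresholds_pct > 0 & thresholds_pct < 100))
  results <- lapply(thresholds_pct, function(th) {
    p <- params
    p$low_dose_threshold_pct <- th
    gamma_map(reference, evaluated, p)
  })
  out <- data.frame(
    threshold_pct = thresholds_pct,
    passing_rate_pct = vapply(results, `[[`, numeric(1), "passing_rate_pct"),
    evaluated_voxels = vapply(results, `[[`, numeric(1), "evaluated_voxels"))
  attr(out, "results") <- results
  out
}
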