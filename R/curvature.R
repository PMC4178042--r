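#' Boundary trace in physical coordinates
#'
#' A BM (or other boundary) trace expressed in micrometres: sample positions
#' along the scan line (negative = left of the fovea) and posterior-positive
#' depth. Constructed by [to_physical()]; densified by [resample_dense()].
#'
#' @param position_um Strictly increasing sample positions, µm.
#' @param depth_um Depth at each position, µm (posterior positive). May be NA
#'   where invalid.
#' @param valid Logical validity per sample.
#' @return An object of class `physical_trace`.
#' @export
physical_trace <- function(position_um, depth_um, valid = rep(TRUE, length(position_um))) {
  n <- length(position_um)
  if (length(depth_um) != n || length(valid) != n)
    stopf("position, depth and valid must have equal length")
  if (n >= 2 && any(diff(position_um) <= 0))
    stopf("`position_um` must be strictly increasing")
  if (any(!is.finite(depth_um[valid])))
    stopf("non-finite depth at valid samples")
  structure(list(position_um = as.numeric(position_um),
                 depth_um = as.numeric(depth_um),
                 valid = as.logical(valid)),
            class = "physical_trace")
}

#' Convert a pixel-space boundary trace to physical coordinates
#'
#' Applies the pixel calibration so that both axes are in micrometres:
#' `position = (col - center_col) * lateral_um_per_px`,
#' `depth = depth_px * axial_um_per_px`. This is the resolution-anisotropy
#' correction that must precede any curvature computation.
#'
#' @param trace A [boundary_trace()].
#' @param calib A [calibration()].
#' @param center_col 1-based fovea column; position 0 maps there.
#' @return A [physical_trace()].
#' @export
to_physical <- function(trace, calib, center_col) {
  stopifnot(inherits(trace, "boundary_trace"), inherits(calib, "calibration"))
  if (sum(trace$valid) < 2L) stopf("trace has fewer than 2 valid columns")
  n <- length(trace$depth_px)
  pos <- (seq_len(n) - center_col) * calib$lateral_um_per_px
  depth <- trace$depth_px * calib$axial_um_per_px
  depth[!trace$valid] <- NA_real_
  physical_trace(pos, depth, trace$valid)
}

#' Resample a physical trace onto a uniform fine grid
#'
#' Linear interpolation onto a `step_um` grid (default 1 µm) spanning the
#' valid extent. Grid points falling between valid samples that are further
#' apart than `max_gap_um` remain invalid, as do points outside the valid
#' extent. Interpolation is deliberately linear: smoothing belongs to the
#' active-contour stage, so the curvature stencil stays the only
#' differentiator.
#'
#' @param trace A [physical_trace()].
#' @param step_um Grid step, µm.
#' @param max_gap_um Largest gap between valid samples that may be bridged.
#' @return A [physical_trace()] on the uniform grid.
#' @export
resample_dense <- function(trace, step_um = 1, max_gap_um = 1000) {
  stopifnot(inherits(trace, "physical_trace"))
  assert_scalar_pos(step_um, "step_um")
  vp <- trace$position_um[trace$valid]
  vd <- trace$depth_um[trace$valid]
  if (length(vp) < 2L) stopf("need at least 2 valid samples to resample")
  grid <- seq(ceiling(vp[1] / step_um) * step_um,
              floor(vp[length(vp)] / step_um) * step_um, by = step_um)
  depth <- stats::approx(vp, vd, xout = grid, method = "linear", rule = 1)$y
  valid <- !is.na(depth)
  # mask samples that sit inside an over-wide gap between valid source samples
  gaps <- which(diff(vp) > max_gap_um)
  for (g in gaps)
    valid[grid > vp[g] & grid < vp[g + 1L]] <- FALSE
  depth[!valid] <- NA_real_
  physical_trace(grid, depth, valid)
}

#' Signed local curvature from a three-point stencil
#'
#' The curvature of the membrane line f(x) is
#' \deqn{\kappa = f''(x) / (1 + f'(x)^2)^{3/2}}
#' with both derivatives taken by central differences over three samples a
#' stencil arm `h_um` apart: `f' = (f(x+h) - f(x-h)) / (2h)` and
#' `f'' = (f(x+h) - 2 f(x) + f(x-h)) / h^2`. Depth is posterior-positive, so
#' the sign convention follows directly: positive where the membrane is
#' convex toward the vitreous, negative over a posterior bowl (the normal
#' spherical pole gives a small negative value, exactly -1/R for a circle),
#' and exactly zero for collinear points.
#'
#' @param f_minus,f0,f_plus Depths (µm) at x-h, x, x+h. Vectorised.
#' @param h_um Stencil arm, µm (default 500, the radial A-scan spacing; the
#'   stencil then spans 1000 µm first point to third point).
#' @return Signed curvature in 1/µm.
#' @examples
#' local_curvature(100, 150, 200)        # collinear: exactly 0
#' local_curvature(0, 25, 0)             # posterior pit: -2e-4
#' @export
local_curvature <- function(f_minus, f0, f_plus, h_um = 500) {
  assert_scalar_pos(h_um, "h_um")
  if (any(!is.finite(c(f_minus, f0, f_plus))))
    stopf("non-finite depth passed to local_curvature()")
  fp <- (f_plus - f_minus) / (2 * h_um)
  fpp <- (f_plus - 2 * f0 + f_minus) / h_um^2
  fpp / (1 + fp^2)^1.5
}

#' Dense curvature profile along one scan line
#'
#' Evaluates [local_curvature()] at every grid centre of a resampled trace
#' whose full `±h_um` stencil neighbourhood is valid. Centres within `h_um`
#' of the trace ends, or whose window touches an invalid span, are masked
#' invalid — on a full 9-mm line this trims 500 µm from each side, leaving an
#' 8-mm evaluation extent.
#'
#' @param trace A [physical_trace()] on a uniform grid (see [resample_dense()]).
#' @param h_um Stencil arm, µm; must be a multiple of the grid step.
#' @return An object of class `curvature_profile` with fields `position_um`,
#'   `kappa` (NA where invalid), `valid` and `h_um`.
#' @export
curvature_profile <- function(trace, h_um = 500) {
  stopifnot(inherits(trace, "physical_trace"))
  assert_scalar_pos(h_um, "h_um")
  n <- length(trace$position_um)
  step <- if (n >= 2) trace$position_um[2] - trace$position_um[1] else NA_real_
  kappa <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  out <- structure(list(position_um = trace$position_um, kappa = kappa,
                        valid = valid, h_um = h_um),
                   class = "curvature_profile")
  if (n < 3 || !is.finite(step) || (n - 1) * step < 2 * h_um) {
    warnf("trace shorter than the 2h stencil span; empty curvature profile")
    return(out)
  }
  if (any(abs(diff(trace$position_um) - step) > 1e-9))
    stopf("trace grid is not uniform; resample first")
  k <- round(h_um / step)
  if (abs(k * step - h_um) > 1e-9)
    stopf("h_um (%g) is not a multiple of the grid step (%g)", h_um, step)

  # a centre is valid iff every grid sample within +-h is valid
  inv <- cumsum(c(0L, as.integer(!trace$valid)))
  win_bad <- inv[pmin(n, seq_len(n) + k) + 1L] - inv[pmax(1L, seq_len(n) - k)]
  idx <- seq_len(n)
  ok <- idx > k & idx <= n - k & win_bad == 0L
  if (any(ok)) {
    i <- idx[ok]
    out$kappa[ok] <- local_curvature(trace$depth_um[i - k], trace$depth_um[i],
                                     trace$depth_um[i + k], h_um)
    out$valid[ok] <- TRUE
  }
  out
}

#' @export
print.curvature_profile <- function(x, ...) {
  nv <- sum(x$valid)
  rng <- if (nv) sprintf("kappa in [%.3g, %.3g] 1/um",
                         min(x$kappa[x$valid]), max(x$kappa[x$valid])) else "empty"
  cat(sprintf("<curvature_profile> %d/%d valid samples, h = %g um, %s\n",
              nv, length(x$valid), x$h_um, rng))
  invisible(x)
}

#' One-call curvature profile from a pixel-space boundary trace
#'
#' Convenience wrapper: [to_physical()] then [resample_dense()] then
#' [curvature_profile()].
#'
#' @inheritParams to_physical
#' @inheritParams resample_dense
#' @inheritParams curvature_profile
#' @return A `curvature_profile`.
#' @export
trace_curvature <- function(trace, calib, center_col, h_um = 500,
                            step_um = 1, max_gap_um = 1000) {
  pt <- to_physical(trace, calib, center_col)
  curvature_profile(resample_dense(pt, step_um, max_gap_um), h_um)
}
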