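#' Curvature color scale
#'
#' The map anchors three colors: yellow RGB(255, 255, 0) at zero curvature,
#' green RGB(0, 192, 32) at +`kappa_max`, red RGB(255, 0, 0) at -`kappa_max`,
#' with per-channel linear gradients toward yellow in between and clamping
#' beyond the saturation magnitude (default 1/2000 = 5e-4 1/µm).
#'
#' @param kappa_max Saturation magnitude, 1/µm.
#' @param yellow,green,red RGB triples (0-255).
#' @return An object of class `color_scale`.
#' @export
color_scale <- function(kappa_max = 5e-4,
                        yellow = c(255, 255, 0),
                        green = c(0, 192, 32),
                        red = c(255, 0, 0)) {
  assert_scalar_pos(kappa_max, "kappa_max")
  chk <- function(x, nm) {
    if (length(x) != 3L || any(!is.finite(x)) || any(x < 0 | x > 255))
      stopf("`%s` must be an RGB triple in 0..255", nm)
    as.numeric(x)
  }
  structure(list(kappa_max = kappa_max, yellow = chk(yellow, "yellow"),
                 green = chk(green, "green"), red = chk(red, "red")),
            class = "color_scale")
}

#' Map signed curvature to the display color
#'
#' Zero curvature maps to yellow; positive curvature interpolates linearly
#' per channel from yellow to green over (0, kappa_max]; negative curvature
#' from yellow to red over [-kappa_max, 0). Magnitudes beyond `kappa_max`
#' clamp to the endpoint color. Channels are rounded half-up to integers.
#'
#' @param kappa Signed curvature value(s), 1/µm; must be finite.
#' @param scale A [color_scale()].
#' @return For a single value, a named integer RGB triple; otherwise an
#'   n x 3 integer matrix with columns `red`, `green`, `blue`.
#' @examples
#' kappa_to_rgb(0)        # 255 255 0
#' kappa_to_rgb(5e-4)     # 0 192 32
#' kappa_to_rgb(-5e-4)    # 255 0 0
#' @export
kappa_to_rgb <- function(kappa, scale = color_scale()) {
  stopifnot(inherits(scale, "color_scale"))
  if (any(!is.finite(kappa))) stopf("non-finite curvature passed to kappa_to_rgb()")
  t <- pmax(-1, pmin(1, kappa / scale$kappa_max))
  pos <- pmax(0, t)
  neg <- pmax(0, -t)
  y <- scale$yellow; g <- scale$green; r <- scale$red
  out <- vapply(1:3, function(ch) {
    y[ch] + pos * (g[ch] - y[ch]) + neg * (r[ch] - y[ch])
  }, numeric(length(kappa)))
  out <- matrix(as.integer(round_half_up(out)), ncol = 3L,
                dimnames = list(NULL, c("red", "green", "blue")))
  if (length(kappa) == 1L) out[1L, ] else out
}

#' Render the en-face curvature map from radial profiles
#'
#' Builds a top-down color raster of the scanned disk. Each radial profile
#' covers two en-face half-lines (its angle for positive positions, angle +
#' 180 for negative positions). For every raster pixel the polar coordinates
#' about the fovea are computed, curvature is interpolated linearly in radius
#' along each of the two angularly adjacent half-lines and then linearly in
#' angle between them, and the result is colored with [kappa_to_rgb()].
#' Interpolating curvature (rather than colors) preserves the zero-crossing
#' ring at a staphyloma edge. A pixel is invalid if either neighbouring
#' half-line lacks a valid curvature at its radius.
#'
#' @param profiles List of [curvature_profile()]s, one per scan line.
#' @param angles_deg Scan-line angles (degrees, in `[0, 180)`), same length.
#' @param resolution_um_per_px Raster scale (default 10 µm/px; 9-mm field ->
#'   901 x 901 px).
#' @param scale A [color_scale()].
#' @param field_radius_um Radius of the rendered field (default 4500).
#' @return An object of class `eye_curvature_map` with the profiles, the
#'   interpolated curvature raster (`kappa`), the RGB `raster` (n x n x 3,
#'   0-255), the logical `valid_mask` and the raster scale.
#' @export
render_enface <- function(profiles, angles_deg, resolution_um_per_px = 10,
                          scale = color_scale(), field_radius_um = 4500) {
  if (!length(profiles)) stopf("no curvature profiles to render")
  if (length(profiles) != length(angles_deg))
    stopf("profiles and angles_deg differ in length")
  if (length(profiles) < 2L)
    stopf("need at least 2 profiles at distinct angles to interpolate")
  if (anyDuplicated(angles_deg %% 180)) stopf("duplicate profile angles")
  assert_scalar_pos(resolution_um_per_px, "resolution_um_per_px")

  r_max <- ceiling(field_radius_um)
  radii <- 0:r_max
  # curvature and validity per half-line direction at integer radii
  dirs <- c(angles_deg %% 180, angles_deg %% 180 + 180)
  K <- matrix(NA_real_, length(dirs), length(radii))
  V <- matrix(FALSE, length(dirs), length(radii))
  np <- length(profiles)
  for (j in seq_len(np)) {
    p <- profiles[[j]]
    kv <- ifelse(p$valid, p$kappa, 0)   # masked below; avoid NA interpolation
    for (side in 0:1) {
      row <- j + side * np
      s <- if (side == 0) radii else -radii
      if (length(p$position_um) >= 2 && any(p$valid)) {
        kr <- stats::approx(p$position_um, kv, xout = s, rule = 1)$y
        # a radius is valid only if both bracketing profile samples are valid
        vv <- stats::approx(p$position_um, as.numeric(p$valid),
                            xout = s, rule = 1)$y
        ok <- !is.na(kr) & !is.na(vv) & vv > 1 - 1e-9
        kr[!ok] <- NA_real_
      } else kr <- rep(NA_real_, length(s))
      K[row, ] <- kr
      V[row, ] <- !is.na(kr)
    }
  }
  ord <- order(dirs)
  dirs <- dirs[ord]; K <- K[ord, , drop = FALSE]; V <- V[ord, , drop = FALSE]
  # wrap around 360 for angular interpolation
  dirs_w <- c(dirs, dirs[1] + 360)
  K <- rbind(K, K[1, ]); V <- rbind(V, V[1, ])

  n <- 2L * floor(field_radius_um / resolution_um_per_px) + 1L
  c0 <- (n + 1L) / 2
  xs <- (seq_len(n) - c0) * resolution_um_per_px
  X <- matrix(xs, n, n, byrow = TRUE)    # en-face x, increasing rightward
  Y <- matrix(rev(xs), n, n)             # en-face y, increasing upward
  R <- sqrt(X^2 + Y^2)
  TH <- (atan2(Y, X) * 180 / pi) %% 360
  # shift into [dirs[1], dirs[1] + 360) so every pixel falls in a sector
  TH <- (TH - dirs_w[1]) %% 360 + dirs_w[1]

  j_lo <- findInterval(TH, dirs_w)
  w <- (TH - dirs_w[j_lo]) / (dirs_w[j_lo + 1L] - dirs_w[j_lo])

  # radial linear interpolation on the integer-radius tables
  r_lo <- pmin(floor(R), r_max - 1)
  fr <- R - r_lo
  idx <- function(jj, rr) cbind(as.vector(jj), as.vector(rr) + 1L)
  k_at <- function(jj) {
    k1 <- K[idx(jj, r_lo)]; k2 <- K[idx(jj, r_lo + 1)]
    f <- as.vector(fr)
    on_node <- f == 0                 # exact-radius hits need only one node
    k2[on_node] <- k1[on_node]
    v <- V[idx(jj, r_lo)] & (V[idx(jj, r_lo + 1)] | on_node)
    list(k = (1 - f) * k1 + f * k2, v = v)
  }
  a <- k_at(j_lo); b <- k_at(j_lo + 1L)
  kap <- (1 - as.vector(w)) * a$k + as.vector(w) * b$k
  val <- a$v & b$v & as.vector(R) <= field_radius_um
  kap[!val] <- NA_real_

  rgb <- matrix(0L, length(kap), 3L)
  if (any(val)) rgb[val, ] <- kappa_to_rgb(kap[val], scale)
  raster <- array(0L, c(n, n, 3L))
  for (ch in 1:3) raster[, , ch] <- matrix(rgb[, ch], n, n)

  structure(list(profiles = profiles, angles_deg = angles_deg,
                 kappa = matrix(kap, n, n), valid_mask = matrix(val, n, n),
                 raster = raster, um_per_px = resolution_um_per_px,
                 field_radius_um = field_radius_um),
            class = "eye_curvature_map")
}

#' @export
print.eye_curvature_map <- function(x, ...) {
  cat(sprintf("<eye_curvature_map> %d profiles, raster %d x %d px @ %g um/px, %.1f%% valid\n",
              length(x$profiles), nrow(x$valid_mask), ncol(x$valid_mask),
              x$um_per_px, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Coverage of the analysis disk
#'
#' Fraction of the nominal analysis disk that carries a valid curvature
#' estimate. The disk default is 8 mm in diameter: the 9-mm scan field minus
#' the 500-µm stencil margin at each end of every line.
#'
#' @param map An [render_enface()] result.
#' @param analysis_radius_um Radius of the reference disk (default 4000).
#' @return Coverage fraction in `[0, 1]`.
#' @export
coverage_of_map <- function(map, analysis_radius_um = 4000) {
  stopifnot(inherits(map, "eye_curvature_map"))
  n <- nrow(map$valid_mask)
  c0 <- (n + 1L) / 2
  xs <- (seq_len(n) - c0) * map$um_per_px
  R <- sqrt(outer(xs^2, xs^2, `+`))
  disk <- R <= analysis_radius_um
  if (!any(disk)) return(0)
  sum(map$valid_mask & disk) / sum(disk)
}

#' Write the en-face map as an RGBA PNG
#'
#' Invalid pixels (outside the scanned disk or lacking a valid curvature)
#' get alpha 0.
#'
#' @param map An [render_enface()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path) {
  stopifnot(inherits(map, "eye_curvature_map"))
  n <- nrow(map$valid_mask)
  rgba <- array(0, c(n, n, 4L))
  for (ch in 1:3) rgba[, , ch] <- map$raster[, , ch] / 255
  rgba[, , 4L] <- ifelse(map$valid_mask, 1, 0)
  png::writePNG(rgba, path)
  invisible(path)
}
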