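#' Parametric ground-truth surface for phantom eyes
#'
#' Models the Bruch's membrane surface over the 9-mm posterior-pole field as
#' a spherical cap plus optional Gaussian features, in posterior-positive
#' depth relative to the foveal reference point:
#' \itemize{
#'   \item `sphere`: depth(r) = sqrt(R^2 - r^2) - R (non-positive; the wall
#'     moves anteriorly off-axis, giving constant curvature -1/R).
#'   \item `staphyloma`: sphere plus a broad positive Gaussian bowl
#'     (posterior ectasia) of height `bowl_depth_um` and width
#'     `bowl_sigma_um`. The floor has strongly negative curvature and the
#'     edge carries a zero-to-positive curvature ring whenever the bowl is
#'     steep enough (`bowl_depth_um / bowl_sigma_um^2 > 1/R`, amply satisfied
#'     by the defaults).
#'   \item `excavation`: sphere plus a narrow deep Gaussian pit (focal
#'     choroidal excavation; `excavation_sigma_um <= 400`).
#'   \item `composite`: sphere + bowl + excavation.
#' }
#' Gaussian features may be decentred via `center_offset_um`.
#'
#' @param kind Surface type.
#' @param base_radius_um Posterior-pole sphere radius (default 13000 µm).
#' @param bowl_depth_um,bowl_sigma_um Staphyloma bowl height and width, µm.
#' @param excavation_depth_um,excavation_sigma_um Excavation pit height and
#'   width, µm.
#' @param center_offset_um Length-2 en-face offset (x, y) of the Gaussian
#'   features, µm.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(kind = c("sphere", "staphyloma", "excavation", "composite"),
                          base_radius_um = 13000,
                          bowl_depth_um = 800, bowl_sigma_um = 1500,
                          excavation_depth_um = 500, excavation_sigma_um = 300,
                          center_offset_um = c(0, 0)) {
  kind <- match.arg(kind)
  assert_scalar_pos(base_radius_um, "base_radius_um")
  assert_scalar_pos(bowl_sigma_um, "bowl_sigma_um")
  assert_scalar_pos(excavation_sigma_um, "excavation_sigma_um")
  if (length(center_offset_um) != 2L || any(!is.finite(center_offset_um)))
    stopf("`center_offset_um` must be a finite length-2 vector")
  structure(list(kind = kind, base_radius_um = base_radius_um,
                 bowl_depth_um = bowl_depth_um, bowl_sigma_um = bowl_sigma_um,
                 excavation_depth_um = excavation_depth_um,
                 excavation_sigma_um = excavation_sigma_um,
                 center_offset_um = as.numeric(center_offset_um)),
            class = "surface_model")
}

#' Ground-truth surface depth
#'
#' Posterior-positive depth of the model surface at en-face coordinates
#' (x, y), relative to the foveal reference (`surface_depth(m, 0, 0)` is 0
#' for a centred sphere). Deterministic and vectorised.
#'
#' @param model A [surface_model()].
#' @param x_um,y_um En-face coordinates, µm.
#' @return Depth in µm (posterior positive).
#' @export
surface_depth <- function(model, x_um, y_um) {
  stopifnot(inherits(model, "surface_model"))
  R <- model$base_radius_um
  r2 <- x_um^2 + y_um^2
  if (any(r2 >= R^2))
    stopf("field point outside the base sphere (r >= %g um)", R)
  depth <- sqrt(R^2 - r2) - R
  dx <- x_um - model$center_offset_um[1]
  dy <- y_um - model$center_offset_um[2]
  d2 <- dx^2 + dy^2
  if (model$kind %in% c("staphyloma", "composite"))
    depth <- depth + model$bowl_depth_um *
      exp(-d2 / (2 * model$bowl_sigma_um^2))
  if (model$kind %in% c("excavation", "composite"))
    depth <- depth + model$excavation_depth_um *
      exp(-d2 / (2 * model$excavation_sigma_um^2))
  depth
}

#' Ideal BM traces along radial scan lines
#'
#' Samples the model surface along `n_angles` radial lines through the fovea
#' at angles `0, 180/n, ..., 180 (n-1)/n` degrees, positions
#' `s in [-half_width_um, +half_width_um]` at `step_um` spacing
#' (`t(theta, s) = depth(s cos(theta), s sin(theta))`).
#'
#' @param model A [surface_model()].
#' @param n_angles Number of radial lines (default 12).
#' @param half_width_um Half scan width, µm (default 4500: a 9-mm line).
#' @param step_um Sample spacing, µm.
#' @return List of [physical_trace()]s, each with attribute `angle_deg`.
#' @export
sample_radial_traces <- function(model, n_angles = 12, half_width_um = 4500,
                                 step_um = 1) {
  assert_scalar_pos(n_angles, "n_angles")
  assert_scalar_pos(half_width_um, "half_width_um")
  angles <- (seq_len(n_angles) - 1L) * 180 / n_angles
  s <- seq(-half_width_um, half_width_um, by = step_um)
  lapply(angles, function(a) {
    th <- a * pi / 180
    tr <- physical_trace(s, surface_depth(model, s * cos(th), s * sin(th)))
    attr(tr, "angle_deg") <- a
    tr
  })
}

#' Render a synthetic B-scan from an ideal BM trace
#'
#' Draws a layered-retina column profile over the trace: dark vitreous, a
#' bright ILM band, mid-grey retina, a bright RPE/BM band whose posterior
#' half-intensity edge sits exactly on the (rounded) BM row, and a dim
#' choroid. Optional multiplicative log-normal speckle
#' (`I * exp(sigma Z - sigma^2/2)`) is applied per pixel, seeded and
#' reproducible. The drawn integer BM row per column is returned as ground
#' truth alongside the continuous row.
#'
#' @param trace A [physical_trace()] (ideal BM depth vs position, µm).
#' @param calib Pixel [calibration()] of the output image.
#' @param ilm_offset_um Anterior offset of the ILM above the BM, µm (> 0).
#' @param intensities Named list of band intensities in `[0, 1]`:
#'   `bg`, `ilm`, `retina`, `bm`, `choroid`.
#' @param n_rows Image rows; default sized to fit the trace with margins.
#' @param speckle_sigma Log-normal speckle level (0 = noiseless).
#' @param seed Optional seed for the speckle field.
#' @param bits Output bit depth (8 or 16).
#' @return List with `scan` (a [bscan()] at the trace's angle),
#'   `gt_bm_px` (drawn integer BM row per column) and `gt_bm_row`
#'   (continuous BM row per column).
#' @export
render_bscan <- function(trace, calib, ilm_offset_um = 350,
                         intensities = list(bg = 0.08, ilm = 0.85,
                                            retina = 0.30, bm = 0.90,
                                            choroid = 0.12),
                         n_rows = NULL, speckle_sigma = 0, seed = NULL,
                         bits = 16L) {
  stopifnot(inherits(trace, "physical_trace"), inherits(calib, "calibration"))
  assert_scalar_pos(ilm_offset_um, "ilm_offset_um")
  lat <- calib$lateral_um_per_px
  ax <- calib$axial_um_per_px
  half_width <- max(abs(trace$position_um))
  half_cols <- floor(half_width / lat)
  nc <- 2L * half_cols + 1L
  center_col <- half_cols + 1L
  pos <- (seq_len(nc) - center_col) * lat
  depth <- stats::approx(trace$position_um, trace$depth_um, xout = pos)$y

  ilm_rows <- ceiling(ilm_offset_um / ax)
  band <- 3L                                   # bright-band thickness, rows
  margin <- 6L
  ref_row <- margin + ilm_rows + band + 1L - floor(min(depth) / ax)
  bm_rowf <- ref_row + depth / ax
  bm_row <- as.integer(round(bm_rowf))
  need_rows <- max(bm_row) + margin
  if (is.null(n_rows)) n_rows <- need_rows
  if (max(bm_row) + 1L > n_rows || min(bm_row) - ilm_rows - band - 1L < 1L)
    stopf("trace exceeds image depth (need %d rows, have %d)", need_rows, n_rows)

  ii <- intensities
  img <- matrix(ii$bg, n_rows, nc)
  rows <- seq_len(n_rows)
  for (j in seq_len(nc)) {
    b <- bm_row[j]
    il <- b - ilm_rows
    col <- rep(ii$bg, n_rows)
    col[rows > il & rows < b - band] <- ii$retina
    col[rows >= il + 1 & rows <= il + band] <- ii$ilm
    col[il] <- (ii$bg + ii$ilm) / 2            # anterior half-edge on the ILM row
    col[rows >= b - band & rows <= b - 1] <- ii$bm
    col[b] <- (ii$bm + ii$choroid) / 2         # posterior half-edge on the BM row
    col[rows > b] <- ii$choroid
    img[, j] <- col
  }
  if (speckle_sigma > 0) {
    img <- with_seed(seed, {
      z <- matrix(stats::rnorm(length(img)), n_rows, nc)
      img * exp(speckle_sigma * z - speckle_sigma^2 / 2)
    })
  }
  maxv <- 2^bits - 1
  px <- matrix(as.integer(round(pmax(0, pmin(1, img)) * maxv)), n_rows, nc)
  scan <- bscan(px, calib, angle_deg = attr(trace, "angle_deg") %||% 0,
                center_col = center_col, bits = bits)
  list(scan = scan, gt_bm_px = bm_row, gt_bm_row = bm_rowf)
}

#' Build a complete phantom eye (12 radial B-scans)
#'
#' Samples the model along radial lines and renders each as a B-scan. One
#' seed drives every per-scan speckle field deterministically.
#'
#' @param model A [surface_model()].
#' @param n_angles Number of radial scan lines.
#' @param calib Pixel [calibration()] (default 7 µm axial, 15 µm lateral,
#'   close to the roughly 3:1 lateral-to-axial pixel aspect of spectral-domain
#'   devices; much stronger anisotropy makes steep staphyloma flanks poorly
#'   resolved in pixel space).
#' @param half_width_um Half scan width, µm.
#' @param speckle_sigma Speckle level.
#' @param seed Seed for the speckle fields.
#' @param eye_id Identifier.
#' @param ... Passed on to [render_bscan()].
#' @return List with `set` (a [radial_scan_set()]), `gt_bm_px` (list of
#'   per-scan ground-truth rows) and `model`.
#' @export
phantom_eye <- function(model, n_angles = 12, calib = calibration(7, 15),
                        half_width_um = 4500, speckle_sigma = 0, seed = NULL,
                        eye_id = "phantom", ...) {
  traces <- sample_radial_traces(model, n_angles, half_width_um,
                                 step_um = calib$lateral_um_per_px)
  seeds <- if (is.null(seed)) vector("list", n_angles)
           else as.list(seed + seq_len(n_angles))
  rendered <- lapply(seq_along(traces), function(i)
    render_bscan(traces[[i]], calib, speckle_sigma = speckle_sigma,
                 seed = seeds[[i]], ...))
  set <- radial_scan_set(lapply(rendered, `[[`, "scan"), eye_id = eye_id)
  ord <- order(vapply(traces, attr, numeric(1), "angle_deg"))
  list(set = set, gt_bm_px = lapply(rendered, `[[`, "gt_bm_px")[ord],
       model = model)
}

#' Ground-truth eye metrics of a surface model
#'
#' Analytic/numerical reference values: curvature profiles are evaluated on
#' noiseless 1-µm radial traces of the surface and pooled exactly as the
#' measurement pipeline pools them.
#'
#' @param model A [surface_model()].
#' @param n_angles,half_width_um,h_um As in the measurement pipeline.
#' @return An [eye_metrics()] object (coverage 1 by construction).
#' @export
ground_truth_metrics <- function(model, n_angles = 12, half_width_um = 4500,
                                 h_um = 500) {
  traces <- sample_radial_traces(model, n_angles, half_width_um, step_um = 1)
  profiles <- lapply(traces, curvature_profile, h_um = h_um)
  eye_metrics(profiles, coverage = 1)
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-eye surface parameters from group-wise distributions and
#' returns, per eye, the surface model, its ground-truth metrics (from
#' noiseless traces) and the group label; optionally also rendered phantom
#' scan sets. Deterministic given `seed`.
#'
#' @param groups List of group specs, each a list with `label`, `n`,
#'   `kind`, and per-parameter entries that are either a scalar or a
#'   `c(mean, sd)` pair (sampled from a normal truncated at 10% of its
#'   mean): `base_radius_um`, `bowl_depth_um`, `bowl_sigma_um`,
#'   `excavation_depth_um`, `excavation_sigma_um`; plus optional
#'   `speckle_sigma` (scalar).
#' @param seed Integer seed.
#' @param render If `TRUE`, also render the phantom scan sets (slower).
#' @param n_angles Scan lines per eye.
#' @return List of eyes; each has `label`, `model`, `truth`
#'   (ground-truth [eye_metrics()]), `speckle_sigma` and, if requested,
#'   `eye` (the rendered phantom).
#' @export
generate_cohort <- function(groups, seed = 1L, render = FALSE, n_angles = 12) {
  if (!length(groups)) stopf("cohort spec has zero groups")
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n) || g$n < 1)
      stopf("each group needs a label and n >= 1")
  }
  draw <- function(spec, default) {
    if (is.null(spec)) return(default)
    if (length(spec) == 1L) return(as.numeric(spec))
    v <- stats::rnorm(1, spec[1], spec[2])
    max(v, 0.1 * abs(spec[1]))
  }
  with_seed(seed, {
    eyes <- list()
    for (g in groups) {
      for (i in seq_len(g$n)) {
        model <- surface_model(
          kind = g$kind %||% "sphere",
          base_radius_um = draw(g$base_radius_um, 13000),
          bowl_depth_um = draw(g$bowl_depth_um, 800),
          bowl_sigma_um = draw(g$bowl_sigma_um, 1500),
          excavation_depth_um = draw(g$excavation_depth_um, 500),
          excavation_sigma_um = draw(g$excavation_sigma_um, 300))
        eye <- list(label = g$label, model = model,
                    truth = ground_truth_metrics(model, n_angles),
                    speckle_sigma = g$speckle_sigma %||% 0)
        if (render) {
          eye$eye <- phantom_eye(model, n_angles,
                                 speckle_sigma = eye$speckle_sigma,
                                 seed = stats::runif(1, 1, 2^30),
                                 eye_id = sprintf("%s_%03d", g$label, i))
        }
        eyes[[length(eyes) + 1L]] <- eye
      }
    }
    eyes
  })
}

#' Sample a metric-space cohort from group summary statistics
#'
#' Draws per-eye (mean absolute curvature, curvature variance) pairs directly
#' in metric space from correlated log-normal distributions matched to the
#' given per-group means and SDs. Log-normal marginals keep both quantities
#' positive and right-skewed, as variance-type statistics are; the log-scale
#' correlation (default 0.85) reproduces the elongated diagonal cloud that
#' eyes trace out in the (mean |kappa|, var kappa) plane, since both summaries
#' grow with ectasia severity.
#'
#' @param groups Named list; each element a list with `n` and `mean_abs`,
#'   `var_kappa`, both `c(mean, sd)` on the natural scale.
#' @param rho Log-scale correlation between the two metrics.
#' @param seed Integer seed.
#' @return Data frame with columns `label`, `mean_abs_kappa`, `var_kappa`.
#' @export
sample_metric_cohort <- function(groups, rho = 0.85, seed = 1L) {
  if (abs(rho) >= 1) stopf("`rho` must lie in (-1, 1)")
  lnorm_par <- function(m, s) {
    sig2 <- log(1 + (s / m)^2)
    c(mu = log(m) - sig2 / 2, sigma = sqrt(sig2))
  }
  with_seed(seed, {
    out <- lapply(names(groups), function(lab) {
      g <- groups[[lab]]
      p1 <- lnorm_par(g$mean_abs[1], g$mean_abs[2])
      p2 <- lnorm_par(g$var_kappa[1], g$var_kappa[2])
      z1 <- stats::rnorm(g$n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(g$n)
      data.frame(label = lab,
                 mean_abs_kappa = unname(exp(p1["mu"] + p1["sigma"] * z1)),
                 var_kappa = unname(exp(p2["mu"] + p2["sigma"] * z2)))
    })
    do.call(rbind, out)
  })
}

#' Reference group statistics for the staphyloma classifier check
#'
#' Mean and SD of mean absolute curvature (1/µm) and curvature variance
#' (1/µm²) for eyes without and with posterior staphyloma, as printed for the
#' 182-eye cohort the thresholds were derived from.
#'
#' @param n Eyes per group.
#' @return Group spec list for [sample_metric_cohort()].
#' @export
staphyloma_reference_groups <- function(n = 100) {
  list(without = list(n = n, mean_abs = c(5.36e-5, 1.24e-5),
                      var_kappa = c(1.35e-9, 0.65e-9)),
       with = list(n = n, mean_abs = c(13.71e-5, 3.50e-5),
                   var_kappa = c(8.26e-9, 6.03e-9)))
}
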