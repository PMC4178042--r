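#' Per-column boundary trace in pixel space
#'
#' @param depth_px Real-valued row position of the boundary per image column
#'   (row 1 = most anterior); NA allowed where invalid.
#' @param valid Logical validity per column.
#' @param manual Logical manual-override flag per column; manual implies valid.
#' @param layer One of `"ILM"`, `"NFL"`, `"BM"`.
#' @param n_rows Optional image row count for range checking.
#' @return An object of class `boundary_trace`.
#' @export
boundary_trace <- function(depth_px, valid = is.finite(depth_px),
                           manual = rep(FALSE, length(depth_px)),
                           layer = c("BM", "ILM", "NFL"), n_rows = NULL) {
  layer <- match.arg(layer)
  n <- length(depth_px)
  if (length(valid) != n || length(manual) != n)
    stopf("depth_px, valid and manual must have equal length")
  if (any(manual & !valid)) stopf("manual columns must be valid")
  if (any(!is.finite(depth_px[valid])))
    stopf("non-finite depth at valid columns")
  if (!is.null(n_rows) && any(depth_px[valid] < 1 | depth_px[valid] > n_rows))
    stopf("boundary depth outside image rows at valid columns")
  structure(list(depth_px = as.numeric(depth_px), valid = as.logical(valid),
                 manual = as.logical(manual), layer = layer),
            class = "boundary_trace")
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("<boundary_trace> %s: %d/%d valid cols (%d manual)\n",
              x$layer, sum(x$valid), length(x$valid), sum(x$manual)))
  invisible(x)
}

#' Active-contour parameters
#'
#' @param alpha Tension (first-derivative) weight, >= 0.
#' @param beta Stiffness (second-derivative) weight, >= 0.
#' @param iterations Maximum iterations.
#' @param step Initial explicit-Euler step, pixels.
#' @param tol Convergence threshold on the largest per-column displacement.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 1.0, iterations = 200L,
                         step = 0.5, tol = 0.01) {
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be >= 0")
  assert_scalar_pos(iterations, "iterations")
  assert_scalar_pos(step, "step")
  structure(list(alpha = alpha, beta = beta,
                 iterations = as.integer(iterations), step = step, tol = tol),
            class = "snake_params")
}

intensity_matrix <- function(image) {
  if (inherits(image, "bscan")) image$pixels else image
}

#' Median-filter denoising
#'
#' Speckle pre-smoothing with a square median window (default 3x3). Operates
#' on the stored grey levels and returns the same scale and shape.
#'
#' @param image A [bscan()] or numeric matrix.
#' @param size Window half-width in pixels (1 -> 3x3 window).
#' @return Denoised numeric matrix.
#' @export
oct_denoise <- function(image, size = 1L) {
  px <- intensity_matrix(image)
  if (!is.matrix(px) || length(px) == 0L) stopf("`image` must be a non-empty matrix")
  if (2L * size + 1L > min(dim(px)))
    stopf("median window (%d px) larger than the image", 2L * size + 1L)
  mx <- max(px)
  if (mx <= 0) return(px + 0)
  out <- EBImage::medianFilter(px / mx, as.integer(size)) * mx
  matrix(out, nrow(px), ncol(px))
}

# zero-mean discrete Gaussian second-derivative kernel (ridge detector core)
d2gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  d2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
  d2 - mean(d2)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

#' Layer-structure (Hessian ridge) response
#'
#' Emphasises bright, roughly horizontal bands: the response is the rectified
#' negative second derivative of the image in the depth direction at scale
#' `axial_sigma`, after mild lateral Gaussian smoothing. Bright band centres
#' give strong positive response; uniform regions give zero.
#'
#' @param image A [bscan()] or numeric matrix (ideally denoised).
#' @param axial_sigma Ridge scale in the depth direction, pixels (default 2,
#'   matching band thicknesses of a few pixels).
#' @param lateral_sigma Lateral smoothing scale, pixels.
#' @return Non-negative response matrix of the same shape.
#' @export
layer_response <- function(image, axial_sigma = 2, lateral_sigma = 1) {
  px <- intensity_matrix(image)
  # bright band centres have negative axial second derivative: rectify -L_rr
  kern <- outer(-d2gauss_kernel(axial_sigma), gauss_kernel(lateral_sigma))
  resp <- EBImage::filter2(px, kern, boundary = "replicate")
  pmax(matrix(resp, nrow(px), ncol(px)), 0)
}

#' Signed vertical gradient (Sobel) response
#'
#' 3x3 Sobel derivative in the depth direction; positive where intensity
#' increases with depth (dark-above / bright-below edges), negative for the
#' opposite transition.
#'
#' @param image A [bscan()] or numeric matrix (ideally denoised).
#' @return Signed gradient matrix of the same shape.
#' @export
gradient_response <- function(image) {
  px <- intensity_matrix(image)
  # EBImage::filter2 performs true convolution (kernel flipped), so the
  # increasing-with-depth orientation needs the reversed Sobel column
  kern <- outer(c(1, 0, -1), c(1, 2, 1))
  matrix(EBImage::filter2(px, kern, boundary = "replicate"), nrow(px), ncol(px))
}

# strict local maxima of a vector; ties resolved by `first` (toward index 1)
local_peaks <- function(v, first = TRUE) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  if (first) pk <- v[i] > v[i - 1L] & v[i] >= v[i + 1L]
  else       pk <- v[i] >= v[i - 1L] & v[i] > v[i + 1L]
  i[pk]
}

# nearest local peak of `v` at or beyond `from` in `direction` (+1 posterior,
# -1 anterior), within `window` rows; falls back to `from`
nearest_peak <- function(v, from, direction, window) {
  pk <- local_peaks(v, first = direction < 0)
  pk <- if (direction > 0) pk[pk >= from & pk <= from + window]
        else pk[pk <= from & pk >= from - window]
  if (!length(pk)) return(from)
  pk[which.min(abs(pk - from))]
}

#' Detect ILM, NFL-boundary and BM traces
#'
#' Per A-scan column, working on the denoised image: the layer-structure
#' response is scanned in depth from the vitreous side and its first peak at
#' or above `threshold_frac` of the image-wide maximum response seeds the
#' inner boundaries; the ILM is refined anteriorly to the nearest
#' rising-gradient peak and the NFL boundary posteriorly to the nearest
#' falling-gradient peak. The *last* supra-threshold layer-response peak in
#' depth seeds the Bruch's membrane line, refined posteriorly to the nearest
#' falling-gradient peak (the posterior margin of the RPE/BM complex).
#' Columns without any supra-threshold peak are marked invalid; listed
#' `invalid_cols` of a [bscan()] are masked up front.
#'
#' @param image A [bscan()] or numeric matrix.
#' @param threshold_frac Peak threshold as a fraction of the maximum layer
#'   response over the image, in (0, 1]. Scale-free across bit depths.
#' @param denoise_size Median pre-filter half-width ([oct_denoise()]).
#' @param axial_sigma,lateral_sigma Ridge filter scales ([layer_response()]).
#' @param refine_window Search span for gradient refinement, rows.
#' @return List with elements `ilm`, `nfl`, `bm` ([boundary_trace()]s).
#' @export
detect_boundaries <- function(image, threshold_frac = 0.3, denoise_size = 1L,
                              axial_sigma = 2, lateral_sigma = 1,
                              refine_window = 8L) {
  if (!is_scalar_num(threshold_frac) || threshold_frac <= 0 || threshold_frac > 1)
    stopf("`threshold_frac` must lie in (0, 1]")
  px <- intensity_matrix(image)
  den <- oct_denoise(px, denoise_size)
  resp <- layer_response(den, axial_sigma, lateral_sigma)
  grad <- gradient_response(den)
  # a response at numerical-roundoff level means no layered structure at all
  if (max(resp) <= 1e-8 * max(abs(den)))
    stopf("segmentation failure: no column has a supra-threshold layer peak")
  thr <- threshold_frac * max(resp)
  nr <- nrow(px); nc <- ncol(px)

  ilm <- nfl <- bm <- rep(NA_real_, nc)
  valid <- rep(FALSE, nc)
  masked <- rep(FALSE, nc)
  if (inherits(image, "bscan") && !is.null(image$invalid_cols))
    masked[image$invalid_cols] <- TRUE

  for (j in seq_len(nc)) {
    if (masked[j]) next
    rc <- resp[, j]
    pk_first <- local_peaks(rc, first = TRUE)
    pk_first <- pk_first[rc[pk_first] >= thr]
    pk_last <- local_peaks(rc, first = FALSE)
    pk_last <- pk_last[rc[pk_last] >= thr]
    if (!length(pk_first) || !length(pk_last)) next
    seed_in <- pk_first[1]
    seed_bm <- pk_last[length(pk_last)]
    ilm[j] <- nearest_peak(grad[, j], seed_in, -1L, refine_window)
    nfl[j] <- nearest_peak(-grad[, j], seed_in, +1L, refine_window)
    bm[j] <- nearest_peak(-grad[, j], seed_bm, +1L, refine_window)
    valid[j] <- TRUE
  }
  if (!any(valid))
    stopf("segmentation failure: no column has a supra-threshold layer peak")
  list(ilm = boundary_trace(ilm, valid, layer = "ILM", n_rows = nr),
       nfl = boundary_trace(nfl, valid, layer = "NFL", n_rows = nr),
       bm = boundary_trace(bm, valid, layer = "BM", n_rows = nr))
}

# snake energy: internal tension/stiffness plus external -response
snake_energy <- function(y, ext_at, alpha, beta) {
  n <- length(y)
  e_t <- if (n >= 2) sum((diff(y))^2) else 0
  e_s <- if (n >= 3) sum((y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)])^2) else 0
  alpha * e_t + beta * e_s + sum(ext_at(y))
}

#' Refine a boundary trace with an active contour (snake)
#'
#' Smooths the detected boundary by explicit-Euler minimisation of the
#' discrete snake energy: tension (`alpha`) and stiffness (`beta`) internal
#' terms plus an image term equal to the negative layer-structure response
#' sampled at the contour (so the contour is attracted to bright bands).
#' Each maximal run of valid columns is refined independently. Manual and
#' invalid columns are fixed points. The step is backtracked whenever a
#' trial update would raise the total energy, making the energy
#' non-increasing; if no admissible step remains the routine errors with the
#' iteration count (divergence).
#'
#' @param trace A [boundary_trace()].
#' @param image A [bscan()] or numeric matrix (the layer response is
#'   computed from it; a precomputed response matrix may be passed via
#'   `response`).
#' @param params A [snake_params()].
#' @param response Optional precomputed layer-response matrix.
#' @return The refined [boundary_trace()], with attribute `energy` holding
#'   the per-iteration energy path of the last refined span.
#' @export
refine_snakes <- function(trace, image, params = snake_params(),
                          response = NULL) {
  stopifnot(inherits(trace, "boundary_trace"), inherits(params, "snake_params"))
  resp <- response %||% layer_response(oct_denoise(image))
  mx <- max(resp)
  if (mx > 0) resp <- resp / mx   # scale-free external energy in [0, 1]
  nr <- nrow(resp)

  # central-difference depth gradient of the response, for a force field that
  # vanishes exactly on band centres (fixed-point contract)
  dresp <- (resp[c(2:nr, nr), ] - resp[c(1, 1:(nr - 1)), ]) / 2

  # linear sampling (in depth) of external energy -resp and its derivative
  ext_col <- function(y, cols) {
    y0 <- pmax(1, pmin(nr - 1, floor(y)))
    f <- pmax(0, pmin(1, y - y0))
    v1 <- resp[cbind(y0, cols)]; v2 <- resp[cbind(y0 + 1, cols)]
    d1 <- dresp[cbind(y0, cols)]; d2 <- dresp[cbind(y0 + 1, cols)]
    list(e = -((1 - f) * v1 + f * v2), de = -((1 - f) * d1 + f * d2))
  }

  y_all <- trace$depth_px
  runs <- rle(trace$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  energy_path <- NULL
  for (ri in which(runs$values)) {
    cols <- starts[ri]:ends[ri]
    if (length(cols) < 3L) next
    y <- y_all[cols]
    free <- !trace$manual[cols]
    if (!any(free)) next
    ext_at <- function(yy) ext_col(yy, cols)$e
    e <- snake_energy(y, ext_at, params$alpha, params$beta)
    path <- e
    step <- params$step
    n <- length(y)
    for (it in seq_len(params$iterations)) {
      # internal forces: alpha * y'' - beta * y'''' (free ends)
      d2 <- c(y[2] - y[1], diff(y, differences = 2), y[n - 1] - y[n])
      yp <- c(y[1], y, y[n]); yp <- c(yp[1], yp, yp[length(yp)])
      d4 <- diff(yp, differences = 4)
      force <- params$alpha * d2 - params$beta * d4 - ext_col(y, cols)$de
      force[!free] <- 0
      y_new <- pmax(1, pmin(nr, y + step * force))
      e_new <- snake_energy(y_new, ext_at, params$alpha, params$beta)
      if (e_new > e + 1e-9 * (1 + abs(e))) {
        step <- step / 2
        if (step < params$step * 1e-6)
          stopf("snake diverged at iteration %d (no admissible step)", it)
        next
      }
      moved <- max(abs(y_new - y))
      y <- y_new; e <- e_new; path <- c(path, e)
      if (moved < params$tol) break
    }
    y_all[cols] <- y
    energy_path <- path
  }
  out <- boundary_trace(y_all, trace$valid, trace$manual, trace$layer, nr)
  attr(out, "energy") <- energy_path
  out
}

#' Apply manual boundary corrections
#'
#' Overwrites the trace at the given columns, marking them valid and manual
#' (re-plotted points survive subsequent snake refinement untouched).
#'
#' @param trace A [boundary_trace()].
#' @param corrections Data frame with columns `column` (1-based) and
#'   `depth_px`, or a two-column matrix.
#' @return The corrected [boundary_trace()].
#' @export
apply_corrections <- function(trace, corrections) {
  stopifnot(inherits(trace, "boundary_trace"))
  if (is.null(corrections) || !NROW(corrections)) return(trace)
  corrections <- as.data.frame(corrections)
  if (!all(c("column", "depth_px") %in% names(corrections)))
    stopf("corrections need columns `column` and `depth_px`")
  cols <- as.integer(corrections$column)
  if (any(cols < 1L | cols > length(trace$depth_px)))
    stopf("correction column out of range 1..%d", length(trace$depth_px))
  depth <- trace$depth_px; valid <- trace$valid; manual <- trace$manual
  depth[cols] <- corrections$depth_px
  valid[cols] <- TRUE
  manual[cols] <- TRUE
  boundary_trace(depth, valid, manual, trace$layer)
}

#' Read a manual-corrections CSV
#'
#' Format: `angle_deg,column,depth_px`, one row per re-plotted point;
#' `column` is 1-based.
#'
#' @param path CSV path.
#' @return Data frame of corrections.
#' @export
read_corrections_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("angle_deg", "column", "depth_px") %in% names(df)))
    stopf("corrections CSV needs columns angle_deg, column, depth_px")
  df
}
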