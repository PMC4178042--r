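#' Pixel calibration of a B-scan
#'
#' Physical size of one pixel in the axial (depth) and lateral (transverse)
#' directions. OCT pixels are strongly anisotropic; curvature is only
#' meaningful after both axes are expressed in micrometres.
#'
#' @param axial_um_per_px Axial pixel pitch, µm per pixel (depth direction).
#' @param lateral_um_per_px Lateral pixel pitch, µm per pixel (along the scan).
#' @return An object of class `calibration`.
#' @examples
#' calibration(3.87, 11.7)
#' @export
calibration <- function(axial_um_per_px, lateral_um_per_px) {
  assert_scalar_pos(axial_um_per_px, "axial_um_per_px")
  assert_scalar_pos(lateral_um_per_px, "lateral_um_per_px")
  structure(list(axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px),
            class = "calibration")
}

#' A calibrated OCT B-scan
#'
#' Wraps a grayscale pixel grid (rows = depth, row 1 most anterior; columns =
#' A-scans left to right) with its calibration and scan geometry. Intensities
#' are kept exactly as stored on disk (integer grey levels; no rescaling).
#'
#' @param pixels Integer matrix of grey levels.
#' @param calib A [calibration()].
#' @param angle_deg Orientation of the scan line in en-face space, degrees
#'   counter-clockwise from horizontal, in `[0, 180)`. Columns right of
#'   `center_col` lie along `angle_deg`; columns left of it along
#'   `angle_deg + 180`.
#' @param center_col 1-based column index of the fovea centre.
#' @param scan_width_um Nominal transverse extent of the scan (default 9000).
#' @param bits Stored bit depth (8 or 16).
#' @param invalid_cols Optional integer vector of 1-based column indices to be
#'   excluded from analysis (e.g. mirror-inversion artifacts near the scan
#'   edges, for which no boundary can be traced).
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, calib, angle_deg, center_col,
                  scan_width_um = 9000, bits = 8L, invalid_cols = NULL) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stopf("`pixels` must be a non-empty matrix")
  if (!inherits(calib, "calibration")) stopf("`calib` must be a calibration object")
  if (!is_scalar_num(angle_deg) || angle_deg < 0 || angle_deg >= 180)
    stopf("`angle_deg` must lie in [0, 180)")
  if (!is_scalar_num(center_col) || center_col < 1 || center_col > ncol(pixels))
    stopf("`center_col` (%s) outside 1..%d", format(center_col), ncol(pixels))
  if (!bits %in% c(8L, 16L)) stopf("`bits` must be 8 or 16")
  attr(pixels, "bits") <- NULL   # bit depth lives in the `bits` field
  if (!is.null(invalid_cols)) {
    invalid_cols <- as.integer(invalid_cols)
    if (any(invalid_cols < 1L | invalid_cols > ncol(pixels)))
      stopf("`invalid_cols` outside 1..%d", ncol(pixels))
  }
  structure(list(pixels = pixels, calib = calib, angle_deg = angle_deg,
                 center_col = as.integer(center_col),
                 scan_width_um = scan_width_um, bits = as.integer(bits),
                 invalid_cols = invalid_cols),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d px, %g deg, %g/%g um/px, center col %d\n",
              nrow(x$pixels), ncol(x$pixels), x$angle_deg,
              x$calib$axial_um_per_px, x$calib$lateral_um_per_px, x$center_col))
  invisible(x)
}

#' A radial scan set (one eye)
#'
#' @param scans List of [bscan()] objects with pairwise distinct angles.
#' @param eye_id Identifier used in output file names.
#' @return An object of class `radial_scan_set`, scans sorted by angle.
#' @export
radial_scan_set <- function(scans, eye_id = "eye") {
  if (!length(scans) || !all(vapply(scans, inherits, logical(1), "bscan")))
    stopf("`scans` must be a non-empty list of bscan objects")
  ang <- vapply(scans, function(s) s$angle_deg, numeric(1))
  if (anyDuplicated(ang))
    stopf("duplicate scan angle(s): %s",
          paste(unique(ang[duplicated(ang)]), collapse = ", "))
  scans <- scans[order(ang)]
  if (length(scans) == 1L)
    warnf("radial scan set '%s' has a single scan line", eye_id)
  structure(list(scans = scans, eye_id = as.character(eye_id),
                 n_lines = length(scans)),
            class = "radial_scan_set")
}

#' @export
print.radial_scan_set <- function(x, ...) {
  cat(sprintf("<radial_scan_set> '%s': %d lines at %s deg\n", x$eye_id,
              x$n_lines,
              paste(vapply(x$scans, function(s) format(s$angle_deg), ""),
                    collapse = ", ")))
  invisible(x)
}

scan_angles <- function(set) vapply(set$scans, function(s) s$angle_deg, numeric(1))

#' Read a grayscale B-scan image (PNG or TIFF)
#'
#' Returns the stored integer grey levels without rescaling; 8- and 16-bit
#' files are preserved as stored. Multi-channel images use the first channel.
#'
#' @param path Image file path.
#' @return Integer matrix with attribute `bits`.
#' @export
read_bscan_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    bits <- attr(img, "info")$bit.depth %||% 8L
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    px <- matrix(as.integer(round(img * (2^bits - 1))), nrow(img), ncol(img))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    px <- matrix(as.integer(img), nrow(img), ncol(img))
    bits <- if (max(px) > 255L) 16L else 8L
  } else {
    stopf("unsupported image format '%s' (use PNG or TIFF)", ext)
  }
  attr(px, "bits") <- as.integer(bits)
  px
}

#' Write a grayscale B-scan image
#'
#' 8-bit images are written as PNG or TIFF by extension; 16-bit images must
#' use TIFF.
#'
#' @param pixels Integer matrix of grey levels.
#' @param path Output path (`.png`, `.tif`/`.tiff`).
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_bscan_image <- function(pixels, path, bits = 8L) {
  maxv <- 2^bits - 1
  if (any(pixels < 0 | pixels > maxv)) stopf("pixel values outside 0..%d", maxv)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits > 8L) stopf("16-bit output requires TIFF")
    png::writePNG(pixels / maxv, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pixels / maxv, path, bits.per.sample = as.integer(bits))
  } else stopf("unsupported image format '%s'", ext)
  invisible(path)
}

#' Load a radial scan set from a JSON manifest
#'
#' The manifest is one JSON file per eye:
#' \preformatted{
#' {
#'   "eye_id": "eye01",
#'   "scan_width_um": 9000,
#'   "scans": [
#'     {"image": "scan_000.tif", "angle_deg": 0, "center_col": 151,
#'      "axial_um_per_px": 5, "lateral_um_per_px": 30,
#'      "invalid_cols": [[1, 10]]},
#'     ...
#'   ]
#' }
#' }
#' Image paths are resolved relative to the manifest location. `center_col`
#' is a 1-based column index; `invalid_cols` is an optional list of 1-based
#' inclusive column ranges to mask out. Scans are sorted by ascending angle;
#' duplicate angles are a validation error.
#'
#' @param manifest_path Path to the manifest JSON.
#' @return A [radial_scan_set()].
#' @export
load_radial_set <- function(manifest_path) {
  if (!file.exists(manifest_path)) stopf("manifest not found: %s", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$scans) || !length(man$scans))
    stopf("manifest '%s' lists no scans", manifest_path)
  base <- dirname(normalizePath(manifest_path))
  width <- man$scan_width_um %||% 9000
  scans <- lapply(seq_along(man$scans), function(i) {
    e <- man$scans[[i]]
    for (f in c("image", "angle_deg", "center_col",
                "axial_um_per_px", "lateral_um_per_px"))
      if (is.null(e[[f]]))
        stopf("manifest entry %d is missing field '%s'", i, f)
    img_path <- if (grepl("^(/|[A-Za-z]:)", e$image)) e$image
                else file.path(base, e$image)
    px <- tryCatch(read_bscan_image(img_path),
                   error = function(err)
                     stopf("manifest entry %d ('%s'): %s",
                           i, e$image, conditionMessage(err)))
    inv <- NULL
    if (!is.null(e$invalid_cols) && length(e$invalid_cols)) {
      inv <- unlist(lapply(e$invalid_cols, function(rg) {
        rg <- as.integer(unlist(rg))
        if (length(rg) != 2L) stopf("invalid_cols ranges must be [from, to]")
        seq.int(rg[1], rg[2])
      }))
    }
    bscan(px, calibration(e$axial_um_per_px, e$lateral_um_per_px),
          angle_deg = e$angle_deg, center_col = e$center_col,
          scan_width_um = width, bits = attr(px, "bits"), invalid_cols = inv)
  })
  radial_scan_set(scans, eye_id = man$eye_id %||% "eye")
}

#' Write a radial scan set (images + manifest)
#'
#' Inverse of [load_radial_set()]: writes one image file per scan (16-bit
#' TIFF when needed) plus the JSON manifest, so a load/write/load round trip
#' preserves pixels, calibration and angles exactly.
#'
#' @param set A [radial_scan_set()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_radial_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(set$scans), function(i) {
    s <- set$scans[[i]]
    ext <- if (s$bits > 8L) "tif" else "png"
    fname <- sprintf("%s_scan_%03d.%s", set$eye_id, i, ext)
    write_bscan_image(s$pixels, file.path(dir, fname), bits = s$bits)
    e <- list(image = fname, angle_deg = s$angle_deg, center_col = s$center_col,
              axial_um_per_px = s$calib$axial_um_per_px,
              lateral_um_per_px = s$calib$lateral_um_per_px)
    if (!is.null(s$invalid_cols))
      e$invalid_cols <- unname(lapply(split_ranges(s$invalid_cols),
                                      function(r) c(r[1], r[2])))
    e
  })
  man <- list(eye_id = set$eye_id,
              scan_width_um = set$scans[[1]]$scan_width_um,
              scans = entries)
  path <- file.path(dir, paste0(set$eye_id, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# collapse a sorted index vector into inclusive [from, to] ranges
split_ranges <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  if (!length(idx)) return(list())
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  lapply(seq_len(length(brk) - 1L),
         function(k) c(idx[brk[k] + 1L], idx[brk[k + 1L]]))
}

#' Write per-eye analysis outputs
#'
#' Writes three artifacts keyed by the eye identifier: a per-point curvature
#' CSV (`<id>_curvature.csv`: scan angle, position along the line in µm,
#' signed curvature in 1/µm, validity flag), a one-row metrics CSV
#' (`<id>_metrics.csv`) and the rendered en-face map (`<id>_map.png`, RGBA
#' with invalid pixels fully transparent). Curvature values are serialised
#' with 17 significant digits so that re-reading the CSV reproduces the
#' in-memory doubles bit-exactly.
#'
#' @param metrics An [eye_metrics()] result, or `NULL` if no valid curvature
#'   samples exist (a header-only curvature CSV and an `NA` metrics row with
#'   coverage 0 are then written).
#' @param map An [render_enface()] result, or `NULL` to skip the raster.
#' @param out_dir Output directory (created if needed).
#' @param eye_id Identifier used in file names.
#' @return Data frame manifest of written files (columns `kind`, `path`).
#' @export
write_outputs <- function(metrics, map, out_dir, eye_id = "eye") {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  files <- list()

  kappa_path <- file.path(out_dir, paste0(eye_id, "_curvature.csv"))
  kt <- curvature_long_table(map)
  write_exact_csv(kt, kappa_path)
  files$curvature_csv <- kappa_path

  met_path <- file.path(out_dir, paste0(eye_id, "_metrics.csv"))
  mrow <- if (is.null(metrics)) {
    data.frame(eye_id = eye_id, mean_abs_kappa = NA_real_, var_kappa = NA_real_,
               coverage = 0, n_samples = 0L, staphyloma = NA)
  } else {
    data.frame(eye_id = eye_id, mean_abs_kappa = metrics$mean_abs_kappa,
               var_kappa = metrics$var_kappa, coverage = metrics$coverage,
               n_samples = metrics$n_samples,
               staphyloma = metrics$staphyloma %||% NA)
  }
  write_exact_csv(mrow, met_path)
  files$metrics_csv <- met_path

  if (!is.null(map) && !is.null(map$raster)) {
    map_path <- file.path(out_dir, paste0(eye_id, "_map.png"))
    write_map_png(map, map_path)
    files$map_png <- map_path
  }
  data.frame(kind = names(files), path = unlist(files, use.names = FALSE),
             stringsAsFactors = FALSE)
}

curvature_long_table <- function(map) {
  empty <- data.frame(angle_deg = numeric(0), position_um = numeric(0),
                      kappa = numeric(0), valid = logical(0))
  if (is.null(map) || !length(map$profiles)) return(empty)
  do.call(rbind, lapply(seq_along(map$profiles), function(j) {
    p <- map$profiles[[j]]
    data.frame(angle_deg = map$angles_deg[j], position_um = p$position_um,
               kappa = p$kappa, valid = p$valid)
  }))
}

# CSV writer that round-trips doubles exactly (17 significant digits)
write_exact_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.17g", df[[j]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-point curvature CSV written by [write_outputs()]
#' @param path CSV path.
#' @return Data frame with columns `angle_deg`, `position_um`, `kappa`, `valid`.
#' @export
read_curvature_csv <- function(path) {
  df <- utils::read.csv(path)
  df$valid <- as.logical(df$valid)
  df
}
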