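#' Per-eye curvature summary metrics
#'
#' Pools the valid signed-curvature samples of all radial profiles of one eye
#' and computes the two shape indices: mean absolute curvature (overall
#' steepness of the posterior pole) and the population variance of signed
#' curvature (surface undulation; a mosaic of convex and concave patches
#' drives it up far more than a smooth bowl does).
#'
#' @param profiles List of [curvature_profile()]s (typically 12).
#' @param coverage Map coverage fraction to record (see [coverage_of_map()]).
#' @param sampling `"dense"` pools every 1-µm grid sample; `"ascan"`
#'   restricts the pool to the 500-µm A-scan node positions.
#' @param node_spacing_um Node spacing for `sampling = "ascan"`.
#' @param eye_id Identifier carried through to outputs.
#' @return An object of class `eye_metrics` with fields `mean_abs_kappa`
#'   (1/µm), `var_kappa` (1/µm²), `coverage`, `n_samples`, `eye_id` and a
#'   `staphyloma` slot filled by [classify_staphyloma()].
#' @export
eye_metrics <- function(profiles, coverage = NA_real_,
                        sampling = c("dense", "ascan"),
                        node_spacing_um = 500, eye_id = "eye") {
  sampling <- match.arg(sampling)
  if (inherits(profiles, "curvature_profile")) profiles <- list(profiles)
  ks <- unlist(lapply(profiles, function(p) {
    sel <- p$valid
    if (sampling == "ascan")
      sel <- sel & (p$position_um %% node_spacing_um == 0)
    p$kappa[sel]
  }))
  if (!length(ks)) stopf("no valid curvature samples; cannot compute eye metrics")
  m <- mean(abs(ks))
  v <- mean((ks - mean(ks))^2)   # population variance of signed curvature
  structure(list(mean_abs_kappa = m, var_kappa = v, coverage = coverage,
                 n_samples = length(ks), staphyloma = NA, eye_id = eye_id),
            class = "eye_metrics")
}

#' @export
print.eye_metrics <- function(x, ...) {
  cat(sprintf(paste0("<eye_metrics> '%s': mean |kappa| = %.4g 1/um, ",
                     "var kappa = %.4g 1/um^2, coverage = %s, n = %d, ",
                     "staphyloma = %s\n"),
              x$eye_id, x$mean_abs_kappa, x$var_kappa,
              ifelse(is.na(x$coverage), "NA", sprintf("%.1f%%", 100 * x$coverage)),
              x$n_samples, format(x$staphyloma)))
  invisible(x)
}

#' Staphyloma decision thresholds
#'
#' The two watershed values that separate eyes with posterior staphyloma from
#' eyes without in the (mean |kappa|, var kappa) plane: 7.8e-5 1/µm on mean
#' absolute curvature and 0.26e-8 1/µm² on curvature variance.
#'
#' @param mean_cut Mean absolute curvature cut, 1/µm.
#' @param var_cut Curvature variance cut, 1/µm².
#' @return An object of class `staphyloma_thresholds`.
#' @export
staphyloma_thresholds <- function(mean_cut = 7.8e-5, var_cut = 2.6e-9) {
  assert_scalar_pos(mean_cut, "mean_cut")
  assert_scalar_pos(var_cut, "var_cut")
  structure(list(mean_cut = mean_cut, var_cut = var_cut),
            class = "staphyloma_thresholds")
}

#' Two-threshold staphyloma classifier
#'
#' An eye is flagged as having a posterior staphyloma iff its mean absolute
#' curvature AND its curvature variance are both at or above their cuts
#' (inclusive boundaries).
#'
#' @param metrics An [eye_metrics()] object, or a numeric vector/list with
#'   `mean_abs_kappa` and `var_kappa`.
#' @param thresholds A [staphyloma_thresholds()].
#' @return Logical.
#' @export
classify_staphyloma <- function(metrics, thresholds = staphyloma_thresholds()) {
  stopifnot(inherits(thresholds, "staphyloma_thresholds"))
  m <- if (is.list(metrics)) metrics$mean_abs_kappa else metrics[[1]]
  v <- if (is.list(metrics)) metrics$var_kappa else metrics[[2]]
  if (!is.finite(m) || !is.finite(v)) stopf("metrics must be finite")
  m >= thresholds$mean_cut && v >= thresholds$var_cut
}

#' Descriptive cohort summary table
#'
#' Per-label n, mean and sample SD (n - 1 denominator) of the three eye
#' metrics, in deterministic label order. Groups of a single eye report
#' SD 0 with `sd_defined = FALSE`.
#'
#' @param metrics_list List of [eye_metrics()] objects.
#' @param labels Character vector of group labels, one per eye.
#' @return Data frame with one row per label.
#' @export
cohort_table <- function(metrics_list, labels) {
  if (!length(metrics_list)) stopf("empty cohort")
  if (length(labels) != length(metrics_list))
    stopf("labels and metrics_list differ in length")
  df <- data.frame(
    label = as.character(labels),
    mean_abs_kappa = vapply(metrics_list, `[[`, numeric(1), "mean_abs_kappa"),
    var_kappa = vapply(metrics_list, `[[`, numeric(1), "var_kappa"),
    coverage = vapply(metrics_list, function(m) m$coverage %||% NA_real_,
                      numeric(1)))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  out <- do.call(rbind, lapply(sort(unique(df$label)), function(lab) {
    g <- df[df$label == lab, ]
    data.frame(label = lab, n = nrow(g),
               mean_abs_kappa_mean = mean(g$mean_abs_kappa),
               mean_abs_kappa_sd = sd0(g$mean_abs_kappa),
               var_kappa_mean = mean(g$var_kappa),
               var_kappa_sd = sd0(g$var_kappa),
               coverage_mean = mean(g$coverage),
               coverage_sd = sd0(g$coverage),
               sd_defined = nrow(g) >= 2L)
  }))
  rownames(out) <- NULL
  out
}
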