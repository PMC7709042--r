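#' Detection parameters for the PSR detectors
#'
#' Thresholds use the `>=` convention (ties are included in the mask). The
#' default values are the package's reference calibration, derived with
#' [calibrate_global_threshold] from the canonical phantom palette: each
#' threshold sits midway between the evidence of saturated stain and the
#' evidence of the confounder that filter must reject (counterstain for
#' chromaticity, erythrocyte-like chromogen for the optimized signal, the
#' mean non-stain response for green suppression). Re-derive per deployment
#' on representative stained/unstained patches.
#'
#' @param t_rgb threshold on the green-suppression evidence in `[0, 255]`.
#' @param t_opt threshold on the optimized signal in `[0, 255]`.
#' @param t_chrom threshold on red chromaticity in `[0, 255]`.
#' @param chrom_completion if `TRUE`, chromaticity completes fiber margins
#'   around the thresholded core.
#' @param chrom_collar if `TRUE` (default) completion is restricted to a
#'   1-px dilation collar of the core, so chromaticity can never seed
#'   isolated noise; `FALSE` gives the unconstrained union, for sensitivity
#'   analysis only.
#' @param min_object_px components smaller than this are removed from the
#'   final mask (0 disables).
#' @return A list of class `psr_detection_params`.
#' @export
detection_params <- function(t_rgb = 165, t_opt = 84, t_chrom = 149,
                             chrom_completion = TRUE, chrom_collar = TRUE,
                             min_object_px = 3L) {
  stopifnot(t_rgb >= 0, t_rgb <= 255, t_opt >= 0, t_opt <= 255,
            t_chrom >= 0, t_chrom <= 255, min_object_px >= 0)
  structure(list(t_rgb = t_rgb, t_opt = t_opt, t_chrom = t_chrom,
                 chrom_completion = isTRUE(chrom_completion),
                 chrom_collar = isTRUE(chrom_collar),
                 min_object_px = as.integer(min_object_px)),
            class = "psr_detection_params")
}

new_mask <- function(values, method, sample_id) {
  structure(values, method = method, sample_id = sample_id)
}

#' Simple RGB-filter detection (PSR_RGB)
#'
#' Thresholds the green-suppression evidence: `mask = [255 - G >= t_rgb]`,
#' with small-object removal. Fast but prone to false positives on any
#' non-green element (erythrocytes, debris) and to missing faint margins.
#'
#' @param img a [psr_image].
#' @param params a [detection_params] object.
#' @return Logical H x W mask with attributes `method = "PSR_RGB"` and
#'   `sample_id`.
#' @export
detect_psr_rgb <- function(img, params = detection_params()) {
  assert_image(img)
  mask <- green_suppression(img) >= params$t_rgb
  mask <- remove_small_components(mask, params$min_object_px)
  new_mask(mask, "PSR_RGB", img$sample_id)
}

#' Optimized detection (PSR_OPT)
#'
#' Thresholds the noise-subtracted signal to obtain a high-specificity core,
#' then (optionally) completes fiber margins with the red-chromaticity
#' filter, restricted to a 1-px collar around the core so completion can
#' extend fibers but never seed isolated noise.
#'
#' @inheritParams detect_psr_rgb
#' @param fparams a [filter_params] object.
#' @return Logical H x W mask with attributes `method = "PSR_OPT"` and
#'   `sample_id`.
#' @export
detect_psr_opt <- function(img, fparams = filter_params(),
                           params = detection_params()) {
  assert_image(img)
  core <- build_opt_signal(img, fparams) >= params$t_opt
  mask <- core
  if (params$chrom_completion) {
    chrom <- chromaticity_red(img) >= params$t_chrom
    if (params$chrom_collar) {
      collar <- from_ebi(EBImage::dilate(as_ebi(core), brush_diamond(1L))) > 0
      mask <- core | (chrom & collar)
    } else {
      mask <- core | chrom
    }
  }
  mask <- remove_small_components(mask, params$min_object_px)
  new_mask(mask, "PSR_OPT", img$sample_id)
}

#' Calibrate a shared detection threshold from example patches
#'
#' Documented replacement for the visual choice of a single threshold on
#' stained versus non-stained regions, shared across organs: returns the
#' value midway between the mean evidence of the stained and unstained patch
#' populations (mean of per-patch means), clipped to `[0, 255]`. A warning
#' is raised when the two populations do not separate.
#'
#' @param stained_patches list of numeric matrices/vectors of evidence
#'   values sampled from stained regions.
#' @param unstained_patches list of evidence patches from unstained regions.
#' @return A single threshold in `[0, 255]`, with attribute
#'   `separation` (difference of population means).
#' @export
calibrate_global_threshold <- function(stained_patches, unstained_patches) {
  if (!is.list(stained_patches)) stained_patches <- list(stained_patches)
  if (!is.list(unstained_patches)) unstained_patches <- list(unstained_patches)
  if (length(stained_patches) == 0L || length(unstained_patches) == 0L)
    stop("calibration requires at least one stained and one unstained patch")
  m_s <- mean(vapply(stained_patches, function(p) mean(as.numeric(p)), numeric(1)))
  m_u <- mean(vapply(unstained_patches, function(p) mean(as.numeric(p)), numeric(1)))
  sep <- m_s - m_u
  if (sep <= 0)
    warning("stained and unstained populations do not separate (stained mean <= unstained mean)")
  thr <- clip01((m_s + m_u) / 2)
  attr(thr, "separation") <- sep
  thr
}
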