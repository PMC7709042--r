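#' Colour-filter parameters for PSR stain evidence
#'
#' Parameters of the pixel-wise transforms that turn an RGB brightfield image
#' into scalar stain-evidence images. All evidence images are oriented
#' "higher = more stain" so a single `>= threshold` convention serves every
#' detector.
#'
#' The noise image combines two non-collagen cues by pixel-wise maximum: the
#' raw green channel (bright on picric-yellow counterstain and pale
#' cytoplasm) and an AEC-like optical-density channel (bright on diffuse
#' reddish-brown chromogen such as erythrocytes). The AEC-like channel
#' cross-reacts with the primary stain itself -- both are red chromogens --
#' so its weight defaults to 0.3, low enough that the veto can never exceed
#' the red-green contrast of genuine PSR staining at any dilution, while
#' still penalising pixels whose AEC evidence overwhelms their red evidence.
#'
#' @param noise_weight_green weight (>= 0) of the green-channel noise cue.
#' @param noise_weight_haec weight (>= 0) of the AEC-like channel noise cue.
#' @param smoothing_radius_px median-smoothing radius applied to the noise
#'   image only; 0 disables.
#' @param od_intensity_floor intensity floor in `[1, 255]` guarding the
#'   optical-density logarithm against zero transmission.
#' @param haec_stain_vectors 3 x 2 matrix whose columns are the
#'   hematoxylin-like and AEC-like stain directions (unit Euclidean norm,
#'   non-collinear). Defaults to the standard published directions.
#' @param od_ceiling optical density mapped to evidence value 255
#'   (default 2.5).
#' @return A list of class `psr_filter_params`.
#' @export
filter_params <- function(noise_weight_green = 1.0,
                          noise_weight_haec = 0.3,
                          smoothing_radius_px = 1L,
                          od_intensity_floor = 1L,
                          haec_stain_vectors = default_stain_vectors(),
                          od_ceiling = 2.5) {
  stopifnot(noise_weight_green >= 0, noise_weight_haec >= 0,
            smoothing_radius_px >= 0,
            od_intensity_floor >= 1, od_intensity_floor <= 255,
            od_ceiling > 0)
  v <- haec_stain_vectors
  if (!is.matrix(v) || !identical(dim(v), c(3L, 2L)))
    stop("`haec_stain_vectors` must be a 3 x 2 matrix (columns = H, AEC)")
  nrm <- sqrt(colSums(v^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("stain vectors must have unit Euclidean norm")
  if (abs(sum(v[, 1] * v[, 2])) > 1 - 1e-6)
    stop("stain vectors are collinear; cannot separate stains")
  structure(list(noise_weight_green = noise_weight_green,
                 noise_weight_haec = noise_weight_haec,
                 smoothing_radius_px = as.integer(smoothing_radius_px),
                 od_intensity_floor = as.integer(od_intensity_floor),
                 haec_stain_vectors = v,
                 od_ceiling = od_ceiling),
            class = "psr_filter_params")
}

#' Standard hematoxylin / AEC stain directions
#'
#' The published hematoxylin (0.650, 0.704, 0.286) and AEC
#' (0.274, 0.680, 0.680) optical-density directions, normalised to unit
#' length.
#'
#' @return A 3 x 2 numeric matrix with columns `H` and `AEC`.
#' @export
default_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  a <- c(0.274, 0.680, 0.680)
  m <- cbind(H = h / sqrt(sum(h^2)), AEC = a / sqrt(sum(a^2)))
  rownames(m) <- c("R", "G", "B")
  m
}

#' Green-suppression evidence (RGB-G filter)
#'
#' `255 - G`: red stain absorbs green light, so stronger staining gives a
#' higher response; white background and yellow counterstain respond weakly.
#' This is the evidence image of the simple PSR_RGB detector.
#'
#' @param img a [psr_image].
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
green_suppression <- function(img) {
  assert_image(img)
  255 - channel_g(img)
}

#' Red-green contrast evidence
#'
#' `clip(R - G, 0, 255)`. Yellow counterstain (high R and G) is nulled;
#' red collagen (high R, low G) responds strongly.
#'
#' @inheritParams green_suppression
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
red_green_contrast <- function(img) {
  assert_image(img)
  clip01(channel_r(img) - channel_g(img))
}

#' Red chromaticity evidence
#'
#' `255 * R / (R + G + B)`, with 0 at black pixels by convention.
#' Chromaticity is insensitive to brightness and sensitive to hue, which
#' makes it useful for completing faint anti-aliased fiber margins.
#'
#' @inheritParams green_suppression
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
chromaticity_red <- function(img) {
  assert_image(img)
  s <- channel_r(img) + channel_g(img) + channel_b(img)
  out <- matrix(0, nrow(s), ncol(s))
  nz <- s > 0
  out[nz] <- 255 * channel_r(img)[nz] / s[nz]
  out
}

#' Two-stain optical-density separation (H / AEC channels)
#'
#' Converts each pixel to optical density,
#' `OD_c = log10(255 / max(I_c, floor))`, and decomposes the OD vector by
#' least squares onto the hematoxylin-like and AEC-like stain directions.
#' Negative coefficients are clamped to zero and each coefficient is
#' rescaled so that an optical density of `od_ceiling` maps to 255.
#'
#' @inheritParams green_suppression
#' @param params a [filter_params] object.
#' @return A list with H x W matrices `haematoxylin` and `aec`, both in
#'   `[0, 255]`.
#' @export
deconvolve_haec <- function(img, params = filter_params()) {
  assert_image(img)
  v <- params$haec_stain_vectors
  fl <- params$od_intensity_floor
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  od <- rbind(
    as.vector(log10(255 / pmax(channel_r(img), fl))),
    as.vector(log10(255 / pmax(channel_g(img), fl))),
    as.vector(log10(255 / pmax(channel_b(img), fl)))
  )
  # least squares onto the two stain directions, then clamp
  coefs <- solve(crossprod(v), crossprod(v, od))
  coefs[coefs < 0] <- 0
  scale <- 255 / params$od_ceiling
  list(
    haematoxylin = clip01(matrix(coefs[1L, ] * scale, h, w)),
    aec          = clip01(matrix(coefs[2L, ] * scale, h, w))
  )
}

#' Non-collagen noise image
#'
#' Pixel-wise maximum of the weighted green-channel cue and the weighted
#' AEC-like channel, median-smoothed. Either cue alone can veto a pixel:
#' the green term captures counterstained tissue and pale cytoplasm, the
#' AEC term diffuse reddish-brown chromogen.
#'
#' @inheritParams deconvolve_haec
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
build_noise_image <- function(img, params = filter_params()) {
  assert_image(img)
  noise <- pmax(params$noise_weight_green * channel_g(img),
                params$noise_weight_haec * deconvolve_haec(img, params)$aec)
  noise <- clip01(noise)
  r <- params$smoothing_radius_px
  if (r > 0L && min(dim(noise)) > 2L * r) {
    noise <- from_ebi(EBImage::medianFilter(as_ebi(noise / 255), r)) * 255
  }
  clip01(noise)
}

#' Optimized PSR stain-evidence image (PSR_OPT signal)
#'
#' Red-green contrast with the noise image subtracted and clipped at zero:
#' the robust "true signal" evidence thresholded by the optimized detector.
#'
#' @inheritParams deconvolve_haec
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
build_opt_signal <- function(img, params = filter_params()) {
  assert_image(img)
  clip01(red_green_contrast(img) - build_noise_image(img, params))
}
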