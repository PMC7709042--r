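test_that("pixel-wise filters give the expected responses on pure colours", {
  img <- pixel_row_image(list(c(255, 0, 0), c(255, 255, 255), c(255, 255, 0),
                              c(100, 180, 40), c(128, 128, 128), c(0, 0, 0)))
  gs <- green_suppression(img)
  expect_equal(gs[1, 1:3], c(255, 0, 0))
  rg <- red_green_contrast(img)
  expect_equal(rg[1, 1:4], c(255, 0, 0, 0))   # negative contrast clips to 0
  cr <- chromaticity_red(img)
  expect_equal(cr[1, 1], 255)
  expect_equal(round(cr[1, 5]), 85)           # gray -> 255/3
  expect_equal(cr[1, 6], 0)                   # black: divide-by-zero convention
})

test_that("filter outputs are bounded, shape-preserving and pixel-wise", {
  set.seed(7)
  arr <- array(runif(10 * 12 * 3, 0, 255), dim = c(10, 12, 3))
  img <- psr_image(arr, 0.5)
  for (f in list(green_suppression, red_green_contrast, chromaticity_red)) {
    out <- f(img)
    expect_identical(dim(out), c(10L, 12L))
    expect_true(all(out >= 0 & out <= 255))
    # permuting pixels commutes with a pixel-wise filter
    perm <- sample(10 * 12)
    arr_p <- array(apply(arr, 3, function(m) m[perm]), dim = dim(arr))
    expect_equal(as.vector(f(psr_image(arr_p, 0.5))), as.vector(out)[perm])
  }
})

test_that("stain separation recovers single-stain forward-model images", {
  v <- default_stain_vectors()
  # white pixel: zero optical density in both channels
  white <- deconvolve_haec(flat_image(PAL$white, 2, 2))
  expect_equal(white$haematoxylin, matrix(0, 2, 2))
  expect_equal(white$aec, matrix(0, 2, 2))
  # hematoxylin-only pixel at OD 1.0 -> rescaled 1.0/2.5*255, AEC ~ 0
  img <- forward_model_image(matrix(1.0, 1, 1), v[, "H"])
  dec <- deconvolve_haec(img)
  expect_equal(dec$haematoxylin[1, 1], 1.0 / 2.5 * 255, tolerance = 1e-6)
  expect_equal(dec$aec[1, 1], 0, tolerance = 1e-6)
  # black pixel: floored OD log10(255) per channel, finite response
  blk <- deconvolve_haec(flat_image(c(0, 0, 0), 1, 1))
  expect_true(is.finite(blk$haematoxylin[1, 1]) && is.finite(blk$aec[1, 1]))
  # round-trip on an 8-bit quantized OD ramp: >= 0.99 correlation in the
  # synthesized channel, near-zero response in the other
  for (st in c("H", "AEC")) {
    od <- matrix(seq(0.1, 2, length.out = 64), 8, 8)
    dec <- deconvolve_haec(forward_model_image(od, v[, st], quantize = TRUE))
    own <- if (st == "H") dec$haematoxylin else dec$aec
    other <- if (st == "H") dec$aec else dec$haematoxylin
    expect_gt(cor(as.vector(own), as.vector(od)), 0.99)
    expect_lt(mean(other), 2)
  }
})

test_that("collinear stain vectors are rejected", {
  v <- default_stain_vectors()
  v[, 2] <- v[, 1]
  expect_error(filter_params(haec_stain_vectors = v), "collinear")
})

test_that("noise image vetoes counterstain and vanishes where configured off", {
  # white background is pure noise (green cue saturates), so the optimized
  # signal there is identically zero
  expect_equal(build_noise_image(flat_image(PAL$white, 4, 4)),
               matrix(255, 4, 4))
  # zero weights: no noise, and the optimized signal degrades to pure
  # red-green contrast
  fp0 <- filter_params(noise_weight_green = 0, noise_weight_haec = 0)
  img <- flat_image(PAL$ery, 4, 4)
  expect_equal(build_noise_image(img, fp0), matrix(0, 4, 4))
  expect_equal(build_opt_signal(img, fp0), red_green_contrast(img))
  # on a phantom, noise is higher on yellow background than on fibers
  ph <- generate_phantom(phantom_spec(n_artifacts = 0, n_gaps = 0, seed = 21))
  noise <- build_noise_image(ph$image)
  bg <- ph$tissue & !ph$fiber_masks$all
  expect_gt(mean(noise[bg]), mean(noise[ph$fiber_masks$compact]))
})

test_that("optimized signal separates fibers from background", {
  expect_equal(build_opt_signal(flat_image(PAL$white, 4, 4)), matrix(0, 4, 4))
  ph <- generate_phantom(phantom_spec(n_artifacts = 0, n_gaps = 0, seed = 22))
  sig <- build_opt_signal(ph$image)
  expect_true(all(sig >= 0 & sig <= 255))
  bg <- ph$tissue & !ph$fiber_masks$all
  expect_gt(mean(sig[ph$fiber_masks$all]), mean(sig[bg]))
})

test_that("optimized signal is anti-monotone in the noise weights", {
  set.seed(11)
  arr <- array(runif(16 * 16 * 3, 0, 255), dim = c(16, 16, 3))
  img <- psr_image(arr, 0.5)
  base <- build_opt_signal(img, filter_params(noise_weight_green = 0.5,
                                              noise_weight_haec = 0.2))
  for (fp in list(filter_params(noise_weight_green = 1.5, noise_weight_haec = 0.2),
                  filter_params(noise_weight_green = 0.5, noise_weight_haec = 1.0))) {
    expect_true(all(build_opt_signal(img, fp) <= base + 1e-9))
  }
})
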