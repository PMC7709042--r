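test_that("segmentation handles empty masks and disjoint blobs exactly", {
  empty <- segment_fibers(matrix(FALSE, 6, 6), matrix(0, 6, 6))
  expect_equal(nrow(empty$segments), 0)
  expect_true(all(empty$labels == 0L))

  mask <- matrix(FALSE, 20, 20)
  mask[3:7, 3:7] <- TRUE
  mask[12:17, 12:17] <- TRUE
  sig <- matrix(100, 20, 20)
  fit <- segment_fibers(mask, sig, morph_params(seed_min_distance_px = 3))
  expect_equal(nrow(fit$segments), 2)
  expect_identical(fit$labels > 0L, mask)           # pixel-exact partition
  expect_equal(sort(fit$segments$pixel_count), c(25L, 36L))
})

test_that("watershed splits a dumbbell like the brute-force flood oracle", {
  fx <- dumbbell_fixture()
  fit <- segment_fibers(fx$mask, fx$signal,
                        morph_params(min_segment_px = 1, seed_min_distance_px = 5))
  expect_equal(nrow(fit$segments), 2)
  oracle <- flood_oracle(fx$mask, fx$signal, fx$peaks)
  # align label identities through the peak pixels
  map <- c(fit$labels[fx$peaks[1]], fit$labels[fx$peaks[2]])
  relabelled <- matrix(match(fit$labels, map, nomatch = 0L),
                       nrow(fit$labels), ncol(fit$labels))
  expect_identical(relabelled, oracle)
})

test_that("undersized fragments merge into neighbours or are dropped", {
  mask <- matrix(FALSE, 12, 12)
  mask[4:6, 4:6] <- TRUE          # 9-px blob
  mask[10, 10:11] <- TRUE         # isolated 2-px speck
  sig <- matrix(90, 12, 12)
  fit <- segment_fibers(mask, sig, morph_params(min_segment_px = 4))
  expect_equal(nrow(fit$segments), 1)
  expect_equal(fit$segments$pixel_count, 9L)
  expect_true(all(fit$labels[10, 10:11] == 0L))     # speck dropped
})

test_that("classification follows the intensity-and-density rule", {
  # solid saturated disc: density 1, high signal -> compact
  mask <- disc_mask(15, 15, 8, 8, 5)
  sig <- matrix(0, 15, 15); sig[mask] <- 100
  fit <- segment_fibers(mask, sig)
  expect_equal(fit$segments$fiber_class, "compact")
  expect_gte(fit$segments$density, 0.9)

  # faint 1-px meandering line: low intensity and loose -> scattered
  zig <- matrix(FALSE, 20, 20)
  r <- 5L; dir <- 1L
  for (c in 3:17) {
    zig[r, c] <- TRUE
    zig[r + dir, c] <- TRUE
    r <- r + dir
    if (r >= 12L || r <= 4L) dir <- -dir
  }
  zsig <- matrix(0, 20, 20); zsig[zig] <- 60
  zfit <- segment_fibers(zig, zsig, morph_params(min_segment_px = 1))
  expect_true(all(zfit$segments$fiber_class == "scattered"))

  # sweeping the intensity cutoff upward never increases the compact count
  ph <- generate_phantom(phantom_spec(seed = 61))
  msk <- detect_psr_opt(ph$image) & ph$tissue
  fit2 <- segment_fibers(msk, build_opt_signal(ph$image), px_size_um = 0.5)
  counts <- vapply(seq(0, 255, by = 15), function(t) {
    cl <- classify_fibers(fit2$segments, morph_params(intensity_cutoff = t))
    sum(cl$fiber_class == "compact")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("compact and scattered pixels partition the segmented mask", {
  ph <- generate_phantom(phantom_spec(seed = 62))
  msk <- detect_psr_opt(ph$image) & ph$tissue
  fit <- segment_fibers(msk, build_opt_signal(ph$image), px_size_um = 0.5)
  cm <- psrquant:::fiber_class_masks(fit)
  expect_false(any(cm$compact & cm$scattered))
  expect_identical(cm$compact | cm$scattered, fit$labels > 0L)
  # and the segmentation is deterministic
  fit2 <- segment_fibers(msk, build_opt_signal(ph$image), px_size_um = 0.5)
  expect_identical(fit$labels, fit2$labels)
})

test_that("generated fiber classes are recovered on a two-class phantom", {
  # thick saturated strokes vs thin, moderately stained meandering strokes
  spec <- phantom_spec(
    width_px = 448L, height_px = 448L,
    compact_fibers = list(n = 6, width_um = 3.0, color = c(180, 30, 40),
                          jitter = 2),
    scattered_fibers = list(n = 4, width_um = 2.0, color = c(194, 52, 63),
                            jitter = 2),
    n_artifacts = 0, n_gaps = 0, n_lumens = 2, class_layout = "split",
    seed = 63)
  ph <- generate_phantom(spec)
  msk <- detect_psr_opt(ph$image) & ph$tissue
  fit <- segment_fibers(msk, build_opt_signal(ph$image), px_size_um = 0.5)
  cm <- psrquant:::fiber_class_masks(fit)
  gt <- ph$fiber_masks
  recovered <- sum(cm$compact & gt$compact) + sum(cm$scattered & gt$scattered)
  expect_gte(recovered / sum(gt$all), 0.9)
})
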