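test_that("tissue detection matches analytic disc area and rejects blank frames", {
  h <- 200; w <- 200; px <- 0.5
  arr <- array(rep(PAL$white, each = h * w), dim = c(h, w, 3))
  expect_error(detect_tissue(psr_image(arr, px)), "no tissue")
  arr <- paint_disc(arr, 100, 100, 80, PAL$yellow)
  tissue <- detect_tissue(psr_image(arr, px))
  expect_equal(sum(tissue) * px^2, pi * (80 * px)^2, tolerance = 0.02)
  # degenerate cutoff: whole frame is tissue, with a warning
  expect_warning(t2 <- detect_tissue(psr_image(arr, px), brightness_cutoff = 256),
                 "whole frame")
  expect_true(all(t2))
})

test_that("lumen detection is analytic on an annulus and honours the area threshold", {
  h <- 200; w <- 200; px <- 0.5
  prof <- organ_profile("liver", lumen_min_area_um2 = 200)
  arr <- array(rep(PAL$white, each = h * w), dim = c(h, w, 3))
  arr <- paint_disc(arr, 100, 100, 80, PAL$yellow)
  arr <- paint_disc(arr, 100, 100, 20, PAL$white)        # qualifying lumen
  arr <- paint_disc(arr, 100, 150, 10, PAL$white)        # below threshold
  tissue <- detect_tissue(psr_image(arr, px), fill_holes_max_um2 = 0)
  lum <- detect_lumens(tissue, prof, px)
  lab <- max(0, max(tabulate(as.integer(lum))))
  expect_equal(sum(lum) * px^2, pi * (20 * px)^2, tolerance = 0.02)
  # solid disc: no lumens at all
  solid <- disc_mask(60, 60, 30, 30, 25)
  expect_false(any(detect_lumens(solid, prof, px)))
  # border-touching hole is never a lumen
  open_mask <- matrix(TRUE, 60, 60)
  open_mask[1:40, 28:32] <- FALSE
  expect_false(any(detect_lumens(open_mask, prof, px)))
})

test_that("exclusions subtract ROE pixels and keep roe_keep_in_tissue pixels", {
  tissue <- matrix(TRUE, 20, 20)
  expect_identical(apply_exclusions(tissue, NULL), tissue)
  vals <- matrix(0L, 20, 20)
  vals[1:20, 1:2] <- 1L     # 10% capsule ROE
  vals[1:20, 19:20] <- 2L   # kept-in-tissue exclusion
  tb <- region_table(1:2, c("capsule", "dense_periduct"),
                     c("roe", "roe_keep_in_tissue"))
  map <- region_label_map(vals, tb, 0.5)
  out <- apply_exclusions(tissue, map)
  expect_equal(sum(out) / sum(tissue), 0.9)
  expect_true(all(out[, 19:20]))
  # unknown label in the raster is rejected at map construction
  bad <- vals; bad[5, 5] <- 9L
  expect_error(region_label_map(bad, tb, 0.5), "missing from the region table")
})

test_that("liver rule set separates perivascular rings from parenchymal bridges", {
  h <- 120; w <- 120; px <- 0.5
  prof <- organ_profile("liver")
  tissue <- disc_mask(h, w, 60, 60, 50)
  lumen <- disc_mask(h, w, 60, 60, 12)
  tissue <- tissue & !lumen
  ring <- disc_mask(h, w, 60, 60, 17) & !disc_mask(h, w, 60, 60, 12)
  streak <- matrix(FALSE, h, w); streak[30:33, 30:90] <- TRUE
  streak <- streak & tissue & !ring

  # no stain: everything is parenchyma
  none <- build_liver_rois(tissue, matrix(FALSE, h, w), lumen, prof, px)
  a0 <- psrquant:::region_areas_um2(none)
  expect_equal(unname(a0["parenchyma"]), sum(tissue) * px^2)

  # a ring hugging the only lumen: perivascular, no bridges
  rr <- build_liver_rois(tissue, ring, lumen, prof, px)
  ar <- psrquant:::region_areas_um2(rr)
  expect_gt(ar[["perivascular"]], 0)
  expect_equal(ar[["bridges"]], 0)

  # a streak away from any lumen: bridge only
  rs <- build_liver_rois(tissue, streak, lumen, prof, px)
  as_ <- psrquant:::region_areas_um2(rs)
  expect_gt(as_[["bridges"]], 0)
  expect_equal(as_[["perivascular"]], 0)

  # ROI labels partition tissue exactly
  both <- build_liver_rois(tissue, ring | streak, lumen, prof, px)
  expect_equal(sum(psrquant:::region_areas_um2(both)), sum(tissue) * px^2)
  expect_true(all((both$values > 0) == tissue))
})

test_that("lung distance band matches the analytic annulus", {
  h <- 160; w <- 160; px <- 0.5
  prof <- organ_profile("lung", band_um = 25)
  duct <- disc_mask(h, w, 80, 80, 20)
  tissue <- matrix(TRUE, h, w) & !duct
  rois <- build_lung_rois(tissue, duct, matrix(FALSE, h, w), prof, px)
  band_px <- sum(rois$values == 1L)
  expect_equal(band_px, pi * (70^2 - 20^2), tolerance = 0.03)
  # no structures at all: everything is parenchyma
  r0 <- build_lung_rois(tissue, matrix(FALSE, h, w), matrix(FALSE, h, w),
                        prof, px)
  expect_true(all(r0$values[tissue] == 3L))
})

test_that("overlapping lung bands split by nearest structure (brute-force oracle)", {
  h <- 100; w <- 128; px <- 0.5
  prof <- organ_profile("lung", band_um = 25)
  duct <- disc_mask(h, w, 50, 34, 8)
  vessel <- disc_mask(h, w, 50, 94, 8)
  tissue <- !(duct | vessel)
  rois <- build_lung_rois(tissue, duct, vessel, prof, px)
  band_px <- prof$band_um / px
  dd <- brute_force_distance(duct)
  dv <- brute_force_distance(vessel)
  expected <- matrix(3L, h, w)
  expected[dd <= band_px & dd <= dv] <- 1L   # ties -> peri-air duct
  expected[dv <= band_px & dv < dd] <- 2L
  expected[!tissue] <- 0L
  expect_identical(rois$values, expected)
})

test_that("kidney cortical vessels carry their rim and partition the cortex", {
  h <- 160; w <- 160; px <- 1
  prof <- organ_profile("kidney", lumen_min_area_um2 = 200, vessel_rim_um = 10)
  vals <- matrix(3L, h, w)                   # cortex everywhere ...
  vals[1:10, ] <- 1L                         # ... with thin medulla stripes
  vals[11:20, ] <- 2L
  tb <- region_table(1:3, c("inner_medulla", "outer_medulla", "cortex"),
                     rep("roi", 3))
  labels <- region_label_map(vals, tb, px)
  lumens <- disc_mask(h, w, 90, 80, 50)
  rois <- build_kidney_rois(labels, lumens, prof)
  a <- psrquant:::region_areas_um2(rois)
  expect_equal(a[["cortical_vessels"]], pi * 60^2, tolerance = 0.03)
  # vessel + vessel-free areas sum exactly to the cortex area
  expect_equal(a[["cortical_vessels"]] + a[["cortex_vessel_free"]],
               sum(vals == 3L) * px^2)
  expect_equal(rois$table$parent[rois$table$name == "cortical_vessels"], "cortex")
  # a cortex without qualifying lumens keeps all its area vessel-free
  small <- disc_mask(h, w, 90, 80, 5)
  r2 <- build_kidney_rois(labels, small, prof)
  a2 <- psrquant:::region_areas_um2(r2)
  expect_equal(a2[["cortical_vessels"]], 0)
  expect_equal(a2[["cortex_vessel_free"]], sum(vals == 3L) * px^2)
  # missing compartments are reported by name
  tb2 <- region_table(1:2, c("inner_medulla", "outer_medulla"), rep("roi", 2))
  expect_error(
    build_kidney_rois(region_label_map(matrix(1L, 4, 4), tb2, px), lumens, prof),
    "cortex")
})
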