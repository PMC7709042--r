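test_that("the four metrics compute their defining ratios", {
  expect_equal(relative_roi_area(250000, 1e6), 25)
  expect_equal(relative_roi_area(1e6, 1e6), 100)
  expect_equal(in_toto_cpa(50000, 1e6), 5)
  expect_equal(in_toto_cpa(0, 1e6), 0)
  expect_equal(collagen_proportion(300, 300), 100)
  expect_equal(roi_cpa(10000, 1e6), 1)
  expect_error(in_toto_cpa(10, 0), "positive")
  expect_error(relative_roi_area(10, 0), "positive")
})

test_that("published arithmetic identities hold", {
  # control liver relative ROI areas sum to 100
  expect_equal(1.20 + 0.04 + 98.76, 100)
  # kidney cortex decomposition: sub-region collagen proportions reproduce
  # the parent cortex value from the same stained areas
  stained <- c(vessel_free = 6533, vessels = 1515)
  total_stain <- 10000
  cp <- collagen_proportion(stained, total_stain)
  expect_equal(unname(cp), c(65.33, 15.15))
  expect_equal(sum(cp), collagen_proportion(sum(stained), total_stain))
  expect_equal(sum(cp), 80.48)
  # two-class complementarity of the liver perivascular pair
  expect_equal(100 - 81.23, 18.77)
})

test_that("collagen proportion is undefined (not zero) without detected stain", {
  expect_warning(cp <- collagen_proportion(0, 0), "undefined")
  expect_true(is.na(cp))
})

test_that("quantification records satisfy normalization, additivity and scaling", {
  ph <- generate_phantom(organ_preset("liver", seed = 71))
  for (px_mult in c(1, 2)) {
    tissue <- ph$tissue
    px <- 0.5 * px_mult
    rois <- region_label_map(ph$regions$values, ph$regions$table, px)
    rec <- quantify_stain(tissue, rois,
                          list(PSR_OPT = ph$fiber_masks$all),
                          px_size_um = px, sample_id = "p")
    roi_rows <- rec$roi_name != "in_toto"
    # CP normalization and ROI-CPA additivity over the partition
    expect_equal(sum(rec$cp_pct[roi_rows]), 100, tolerance = 1e-12)
    expect_equal(sum(rec$roi_cpa_pct[roi_rows]),
                 rec$cpa_pct[rec$roi_name == "in_toto"], tolerance = 1e-12)
    expect_equal(sum(rec$relative_roi_area_pct[roi_rows]), 100,
                 tolerance = 1e-12)
    if (px_mult == 1) base <- rec
  }
  # doubling the pixel size scales areas by 4 and leaves percentages alone
  expect_equal(rec$stained_area_um2, base$stained_area_um2 * 4)
  expect_equal(rec$cp_pct, base$cp_pct)
  expect_equal(rec$cpa_pct, base$cpa_pct)
})

test_that("per-class records are conserved against the all-fibers records", {
  ph <- generate_phantom(phantom_spec(seed = 72))
  tissue <- ph$tissue
  sig <- build_opt_signal(ph$image)
  mask <- detect_psr_opt(ph$image) & tissue
  fit <- segment_fibers(mask, sig, px_size_um = 0.5)
  cm <- psrquant:::fiber_class_masks(fit)
  rec <- quantify_stain(tissue, NULL, list(PSR_OPT = fit$labels > 0L),
                        list(PSR_OPT = cm), px_size_um = 0.5)
  a <- rec[rec$fiber_class == "all", ]
  k <- rec[rec$fiber_class == "compact", ]
  s <- rec[rec$fiber_class == "scattered", ]
  expect_equal(k$stained_area_um2 + s$stained_area_um2, a$stained_area_um2)
  expect_equal(k$cpa_pct + s$cpa_pct, a$cpa_pct, tolerance = 1e-12)
  expect_equal(k$roi_cpa_pct + s$roi_cpa_pct, a$roi_cpa_pct, tolerance = 1e-12)
})

test_that("summaries are invariant to record order and expose class shares", {
  ph <- generate_phantom(organ_preset("liver", seed = 73))
  run <- run_sample(ph, run_config(profile = organ_profile("liver")))
  s1 <- summarize_quant(run$records)
  set.seed(1)
  shuffled <- run$records[sample(nrow(run$records)), ]
  s2 <- summarize_quant(shuffled)
  expect_equal(s1$long, s2$long)
  expect_equal(s1$cp_wide, s2$cp_wide)
  # within each ROI the class shares of stained area sum to 100
  lg <- s1$long
  cls <- lg[lg$fiber_class %in% c("compact", "scattered") &
              lg$method == "PSR_OPT", ]
  sums <- tapply(cls$class_relative_area_pct,
                 paste(cls$roi_name), sum)
  stained <- tapply(cls$stained_area_um2, paste(cls$roi_name), sum) > 0
  expect_equal(as.vector(sums[stained]), rep(100, sum(stained)),
               tolerance = 1e-9)
})
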