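#' Run configuration for the end-to-end pipeline
#'
#' Bundles the organ profile and all stage parameters for [run_sample] /
#' [run_manifest].
#'
#' @param profile an [organ_profile].
#' @param fparams a [filter_params].
#' @param dparams a [detection_params].
#' @param mparams a [morph_params].
#' @param methods subset of `c("rgb", "opt", "morf")` (non-empty);
#'   `"morf"` implies the optimized detection.
#' @param brightness_cutoff,min_tissue_area_um2 passed to [detect_tissue].
#' @return A list of class `psr_run_config`.
#' @export
run_config <- function(profile = organ_profile("liver"),
                       fparams = filter_params(),
                       dparams = detection_params(),
                       mparams = morph_params(),
                       methods = c("rgb", "opt", "morf"),
                       brightness_cutoff = 240,
                       min_tissue_area_um2 = 1000) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0L) stop("method selection must be non-empty")
  structure(list(profile = profile, fparams = fparams, dparams = dparams,
                 mparams = mparams, methods = methods,
                 brightness_cutoff = brightness_cutoff,
                 min_tissue_area_um2 = min_tissue_area_um2),
            class = "psr_run_config")
}

#' Run the full analysis on one sample
#'
#' Executes tissue detection, exclusion handling, lumen detection,
#' organ-specific ROI construction, the selected stain detections, fiber
#' segmentation/classification (for `"morf"`), and all metrics in toto and
#' per ROI.
#'
#' Lung runs require duct/vessel structure masks (via `structures` or a
#' label map with regions named `airducts` and `vessels`); kidney runs
#' require a label map with `inner_medulla`, `outer_medulla` and `cortex`.
#' A [generate_phantom] result can be passed directly as `x`, in which case
#' its ground-truth structures and compartments are used as the annotation
#' input.
#'
#' @param x a [psr_image] or a `psr_phantom`.
#' @param config a [run_config].
#' @param labels optional [region_label_map] carrying manual annotations
#'   (ROEs, kidney compartments, lung structures).
#' @param structures optional list with logical masks `airducts` and
#'   `vessels` (lung).
#' @return An object of class `psr_run`: tissue/lumen masks, detection
#'   masks, ROI map, fiber segmentation and the quantification records.
#' @export
run_sample <- function(x, config = run_config(), labels = NULL,
                       structures = NULL) {
  phantom <- NULL
  if (inherits(x, "psr_phantom")) {
    phantom <- x
    img <- phantom$image
    if (is.null(structures)) structures <- phantom$structures
    if (config$profile$organ == "kidney" && is.null(labels) &&
        !is.null(phantom$compartments)) labels <- phantom$compartments
  } else img <- x
  assert_image(img)
  px <- img$px_size_um
  profile <- config$profile

  tissue_raw <- detect_tissue(img, config$brightness_cutoff,
                              config$min_tissue_area_um2,
                              fill_holes_max_um2 = profile$lumen_min_area_um2 / 2)
  lumens <- detect_lumens(tissue_raw, profile, px)
  tissue <- apply_exclusions(tissue_raw, labels)
  if (!any(tissue)) stop("exclusions removed all tissue: nothing to quantify")

  masks <- list()
  signal <- NULL
  need_opt <- any(c("opt", "morf") %in% config$methods)
  if ("rgb" %in% config$methods)
    masks$PSR_RGB <- detect_psr_rgb(img, config$dparams) & tissue
  if (need_opt) {
    signal <- build_opt_signal(img, config$fparams)
    masks$PSR_OPT <- detect_psr_opt(img, config$fparams, config$dparams) & tissue
  }

  roi_mask_for_regions <- if (need_opt) masks$PSR_OPT else masks$PSR_RGB
  rois <- switch(profile$organ,
    liver = build_liver_rois(tissue, roi_mask_for_regions, lumens, profile, px),
    lung = {
      if (is.null(structures) && !is.null(labels) &&
          all(c("airducts", "vessels") %in% labels$table$name))
        structures <- list(airducts = region_mask(labels, "airducts"),
                           vessels = region_mask(labels, "vessels"))
      if (is.null(structures))
        stop("lung analysis requires air-duct and vessel structure masks ",
             "(supply `structures` or a label map with regions 'airducts' ",
             "and 'vessels')")
      build_lung_rois(tissue, structures$airducts, structures$vessels,
                      profile, px)
    },
    kidney = {
      if (is.null(labels))
        stop("kidney analysis requires a label map with regions ",
             "'inner_medulla', 'outer_medulla' and 'cortex'")
      km <- build_kidney_rois(labels, lumens, profile)
      # the kidney domain is the labelled compartment map
      tissue <- apply_exclusions(km$values > 0L, km)
      km
    })

  fibers <- NULL
  class_masks <- NULL
  if ("morf" %in% config$methods) {
    fibers <- segment_fibers(masks$PSR_OPT, signal, config$mparams, px)
    class_masks <- list(PSR_OPT = fiber_class_masks(fibers))
  }

  records <- quantify_stain(tissue, rois, masks, class_masks, px,
                            img$sample_id)
  structure(list(sample_id = img$sample_id, config = config,
                 tissue = tissue, lumens = lumens, rois = rois,
                 masks = masks, signal = signal, fibers = fibers,
                 records = records, phantom = phantom),
            class = "psr_run")
}

#' @export
print.psr_run <- function(x, ...) {
  px <- if (!is.null(x$rois)) x$rois$px_size_um else NA_real_
  cat(sprintf("psr_run '%s' (%s): tissue %.3g mm^2\n", x$sample_id,
              x$config$profile$organ,
              sum(x$tissue) * px^2 / 1e6))
  it <- x$records[x$records$roi_name == "in_toto" &
                  x$records$fiber_class == "all", ]
  for (i in seq_len(nrow(it)))
    cat(sprintf("  %s in toto CPA: %.2f%%\n", it$method[i], it$cpa_pct[i]))
  invisible(x)
}

#' @export
summary.psr_run <- function(object, ...) summarize_quant(object$records)

#' Write run outputs (CSV records, masks, manifest) to a directory
#'
#' Percentages are rounded to 2 decimals at CSV export only; reruns with
#' identical configuration and inputs give byte-identical files.
#'
#' @param run a `psr_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- run$records
  pct <- grep("_pct$", names(rec))
  rec[pct] <- lapply(rec[pct], round, digits = 2)
  rec[c("stained_area_um2", "roi_area_um2", "total_tissue_area_um2")] <-
    lapply(rec[c("stained_area_um2", "roi_area_um2", "total_tissue_area_um2")],
           round, digits = 4)
  utils::write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE)
  if (!is.null(run$fibers) && nrow(run$fibers$segments)) {
    utils::write.csv(run$fibers$segments, file.path(dir, "segments.csv"),
                     row.names = FALSE)
  }
  for (m in names(run$masks))
    write_psr_raster(run$masks[[m]], file.path(dir, paste0(tolower(m), "_mask.png")))
  manifest <- list(sample_id = run$sample_id,
                   organ = run$config$profile$organ,
                   methods = run$config$methods,
                   profile = unclass(run$config$profile),
                   filter_params = unclass(run$config$fparams)[
                     setdiff(names(run$config$fparams), "haec_stain_vectors")],
                   stain_vectors = as.data.frame(run$config$fparams$haec_stain_vectors),
                   detection_params = unclass(run$config$dparams),
                   morph_params = unclass(run$config$mparams))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run a manifest of samples and aggregate per group
#'
#' Each manifest row describes one sample: either an image file
#' (columns `image`, optional `labels` indexed-PNG path + `region_table`
#' JSON) or a phantom (`phantom_organ`, `phantom_seed`). Per-sample records
#' are preserved and group mean/SD tables are computed.
#'
#' @param manifest data.frame with columns `sample_id`, `group` and input
#'   columns as above.
#' @param config a [run_config].
#' @param px_size_um calibration used for image files.
#' @return A list with `records` (all samples) and `groups`
#'   (per-group mean/SD via [group_stats]).
#' @export
run_manifest <- function(manifest, config = run_config(), px_size_um = 0.5) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest must list at least one sample")
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample_id in manifest")
  all_rec <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (!is.null(row$phantom_organ) && !is.na(row$phantom_organ)) {
      spec <- if (row$phantom_organ == "flat")
        phantom_spec(seed = row$phantom_seed)
      else organ_preset(row$phantom_organ, seed = row$phantom_seed)
      x <- generate_phantom(spec)
      x$image$sample_id <- row$sample_id
    } else {
      x <- read_psr_image(row$image, px_size_um, sample_id = row$sample_id)
    }
    run <- run_sample(x, config)
    rec <- run$records
    rec$group <- row$group
    all_rec[[i]] <- rec
  }
  records <- do.call(rbind, all_rec)
  list(records = records, groups = group_stats(records))
}
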