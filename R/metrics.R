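#' Relative ROI area
#'
#' Percentage of total tissue occupied by a ROI:
#' `100 * roi_area / total_tissue_area`. Over a ROI partition of tissue the
#' values sum to 100.
#'
#' @param roi_area ROI area (um^2), possibly vectorised over ROIs.
#' @param total_tissue_area total tissue area (um^2), > 0.
#' @return Percentage(s) in `[0, 100]`.
#' @export
relative_roi_area <- function(roi_area, total_tissue_area) {
  if (!is.finite(total_tissue_area) || total_tissue_area <= 0)
    stop("total tissue area must be positive")
  100 * roi_area / total_tissue_area
}

#' In toto collagen proportionate area (CPA)
#'
#' Percentage of total tissue that is PSR-positive:
#' `100 * stained_total / total_tissue_area`.
#'
#' @param stained_total stained area over the whole section (um^2).
#' @param total_tissue_area total tissue area (um^2), > 0.
#' @return Percentage in `[0, 100]`.
#' @export
in_toto_cpa <- function(stained_total, total_tissue_area) {
  if (!is.finite(total_tissue_area) || total_tissue_area <= 0)
    stop("total tissue area must be positive")
  100 * stained_total / total_tissue_area
}

#' Collagen proportion (CP)
#'
#' Percentage of all detected collagen that lies inside a ROI:
#' `100 * stained_in_roi / stained_total`. Sums to 100 over a ROI
#' partition. Undefined when no collagen was detected at all: returns `NA`
#' with a warning rather than 0.
#'
#' @param stained_in_roi stained area inside the ROI (um^2), possibly
#'   vectorised over ROIs.
#' @param stained_total stained area over the whole section (um^2).
#' @return Percentage(s) in `[0, 100]`, or `NA` when `stained_total == 0`.
#' @export
collagen_proportion <- function(stained_in_roi, stained_total) {
  if (!is.finite(stained_total) || stained_total < 0)
    stop("total stained area must be a non-negative number")
  if (stained_total == 0) {
    warning("no stained area detected: collagen proportion is undefined")
    return(rep(NA_real_, length(stained_in_roi)))
  }
  100 * stained_in_roi / stained_total
}

#' ROI collagen proportionate area (ROI CPA)
#'
#' Stained area of a ROI as a percentage of total tissue:
#' `100 * stained_in_roi / total_tissue_area`. Shares its denominator with
#' [in_toto_cpa], so ROI CPA values over a partition sum exactly to the in
#' toto CPA.
#'
#' @param stained_in_roi stained area inside the ROI (um^2).
#' @param total_tissue_area total tissue area (um^2), > 0.
#' @return Percentage(s) in `[0, 100]`.
#' @export
roi_cpa <- function(stained_in_roi, total_tissue_area) {
  if (!is.finite(total_tissue_area) || total_tissue_area <= 0)
    stop("total tissue area must be positive")
  100 * stained_in_roi / total_tissue_area
}

#' Quantify detected stain per ROI and fiber class
#'
#' Assembles the long-format quantification table: one row per
#' ROI x fiber-class combination (plus `in_toto` rows), carrying the raw
#' areas in um^2 and the four derived metrics. Rows with fiber class
#' `"all"` describe the full detection mask; `"compact"`/`"scattered"` rows
#' are present when class masks are supplied and are additive to the
#' `"all"` rows by construction.
#'
#' @param tissue logical total-tissue mask (after exclusions).
#' @param rois a [region_label_map] whose ROI labels partition tissue, or
#'   `NULL` for in-toto-only quantification.
#' @param stain_masks named list of logical stain masks; names are method
#'   tags (e.g. `PSR_OPT`).
#' @param class_masks optional named list (per method) of lists with
#'   `compact` and `scattered` masks, as from [fiber_class_masks].
#' @param px_size_um pixel size in micrometres.
#' @param sample_id sample identifier.
#' @return A `data.frame` of quantification records.
#' @export
quantify_stain <- function(tissue, rois, stain_masks, class_masks = NULL,
                           px_size_um = 1, sample_id = "sample") {
  px2 <- px_size_um^2
  total_tissue <- sum(tissue) * px2
  if (total_tissue <= 0) stop("empty tissue: nothing to quantify")
  roe_keep <- NULL
  roi_names <- character(0)
  if (!is.null(rois)) {
    roi_names <- rois$table$name[rois$table$role == "roi"]
    keep <- rois$table$label[rois$table$role == "roe_keep_in_tissue"]
    if (length(keep)) roe_keep <- rois$values %in% keep
  }
  rows <- list()
  for (method in names(stain_masks)) {
    m <- stain_masks[[method]] & tissue
    cls <- list(all = m)
    if (!is.null(class_masks[[method]])) {
      cls$compact <- class_masks[[method]]$compact & tissue
      cls$scattered <- class_masks[[method]]$scattered & tissue
    }
    stained_total <- sum(cls$all) * px2
    for (cl in names(cls)) {
      stained_cl_total <- sum(cls[[cl]]) * px2
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, method = method, roi_name = "in_toto",
        fiber_class = cl,
        stained_area_um2 = stained_cl_total,
        roi_area_um2 = total_tissue,
        total_tissue_area_um2 = total_tissue,
        relative_roi_area_pct = 100,
        cpa_pct = in_toto_cpa(stained_cl_total, total_tissue),
        cp_pct = if (stained_total > 0) 100 * stained_cl_total / stained_total
                 else NA_real_,
        roi_cpa_pct = roi_cpa(stained_cl_total, total_tissue),
        stringsAsFactors = FALSE)
      for (rn in roi_names) {
        rmask <- region_mask(rois, rn) & tissue
        if (!is.null(roe_keep)) rmask <- rmask & !roe_keep
        roi_area <- sum(rmask) * px2
        stained_in_roi <- sum(cls[[cl]] & rmask) * px2
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, method = method, roi_name = rn,
          fiber_class = cl,
          stained_area_um2 = stained_in_roi,
          roi_area_um2 = roi_area,
          total_tissue_area_um2 = total_tissue,
          relative_roi_area_pct = relative_roi_area(roi_area, total_tissue),
          cpa_pct = if (roi_area > 0) 100 * stained_in_roi / roi_area
                    else NA_real_,
          cp_pct = if (stained_total > 0) 100 * stained_in_roi / stained_total
                   else NA_real_,
          roi_cpa_pct = roi_cpa(stained_in_roi, total_tissue),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize quantification records
#'
#' Produces the long table (one record per row, deterministic ordering) and
#' wide per-method collagen-proportion tables (ROIs as rows), in the shape
#' of the per-organ result tables. Per-class relative areas within a ROI --
#' the share of that ROI's stain held by each fiber class -- are added and
#' sum to 100 where stain is present. Output is invariant to the input row
#' order.
#'
#' @param records data.frame from [quantify_stain] (possibly several
#'   samples row-bound).
#' @return A list with `long` (ordered records, with
#'   `class_relative_area_pct`) and `cp_wide` (per method: sample x ROI CP
#'   table for the full detection).
#' @export
summarize_quant <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  ord <- order(records$sample_id, records$method, records$roi_name,
               records$fiber_class)
  long <- records[ord, , drop = FALSE]
  rownames(long) <- NULL
  # share of each ROI's stain held by each fiber class
  key_all <- paste(long$sample_id, long$method, long$roi_name)
  all_rows <- long$fiber_class == "all"
  denom <- long$stained_area_um2[all_rows][match(key_all, key_all[all_rows])]
  long$class_relative_area_pct <- ifelse(denom > 0,
                                         100 * long$stained_area_um2 / denom,
                                         NA_real_)
  cp_wide <- lapply(split(long[all_rows, ], long$method[all_rows]),
                    function(d) {
    w <- stats::reshape(
      d[, c("sample_id", "roi_name", "cp_pct")],
      idvar = "sample_id", timevar = "roi_name", direction = "wide")
    names(w) <- sub("^cp_pct\\.", "", names(w))
    rownames(w) <- NULL
    w
  })
  list(long = long, cp_wide = cp_wide)
}

#' Group mean and standard deviation tables
#'
#' Aggregates per-sample records into per-group mean (SD) values for every
#' metric column, in the shape of the published organ tables.
#'
#' @param records data.frame from [quantify_stain] with an added `group`
#'   column.
#' @return A data.frame with one row per
#'   group x method x ROI x fiber class, mean and SD columns per metric.
#' @export
group_stats <- function(records) {
  stopifnot("group" %in% names(records))
  metrics <- c("relative_roi_area_pct", "cpa_pct", "cp_pct", "roi_cpa_pct")
  keys <- c("group", "method", "roi_name", "fiber_class")
  agg <- stats::aggregate(records[metrics], records[keys],
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1L) stats::sd(v) else 0))
  out <- agg[keys]
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- agg[[m]][, "mean"]
    out[[paste0(m, "_sd")]] <- agg[[m]][, "sd"]
  }
  out[order(out$group, out$method, out$roi_name, out$fiber_class), ,
      drop = FALSE]
}
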