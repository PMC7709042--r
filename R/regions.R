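#' Region table: label semantics for a label map
#'
#' Declares what each integer label in a [region_label_map] means. Label 0
#' is reserved for non-tissue and never appears in the table. Roles:
#' \describe{
#'   \item{`roi`}{a quantified compartment; ROI labels partition tissue.}
#'   \item{`roe`}{region of exclusion, removed from total tissue (capsule,
#'     hilum, pleura, large lumens).}
#'   \item{`roe_keep_in_tissue`}{excluded from every ROI but kept inside the
#'     total-tissue denominator (e.g. dense peri-air-duct connective
#'     tissue).}
#'   \item{`background`}{labelled non-tissue.}
#' }
#' The optional `parent` column records hierarchical ROIs (e.g. the two
#' kidney cortex sub-regions with parent `"cortex"`).
#'
#' @param label positive integer labels (unique).
#' @param name region names (unique).
#' @param role one of `"roi"`, `"roe"`, `"roe_keep_in_tissue"`,
#'   `"background"` per entry.
#' @param parent optional parent ROI name per entry (`NA` for top level).
#' @return A `data.frame` of class `psr_region_table`.
#' @export
region_table <- function(label, name, role, parent = NA_character_) {
  label <- as.integer(label)
  role <- as.character(role)
  if (any(label <= 0L)) stop("labels must be positive integers (0 is reserved for non-tissue)")
  if (anyDuplicated(label)) stop("labels must be unique")
  if (anyDuplicated(name)) stop("region names must be unique")
  bad <- setdiff(role, c("roi", "roe", "roe_keep_in_tissue", "background"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  tb <- data.frame(label = label, name = as.character(name), role = role,
                   parent = rep_len(as.character(parent), length(label)),
                   stringsAsFactors = FALSE)
  class(tb) <- c("psr_region_table", "data.frame")
  tb
}

#' Region label map
#'
#' Integer raster assigning every pixel to non-tissue (0) or to a labelled
#' region described by a [region_table].
#'
#' @param values H x W integer matrix of labels.
#' @param table a [region_table] covering every nonzero value.
#' @param px_size_um pixel edge length in micrometres.
#' @return A list of class `psr_region_map`.
#' @export
region_label_map <- function(values, table, px_size_um) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  present <- setdiff(unique(as.vector(values)), 0L)
  unknown <- setdiff(present, table$label)
  if (length(unknown))
    stop("label map contains labels missing from the region table: ",
         paste(sort(unknown), collapse = ", "))
  stopifnot(px_size_um > 0)
  structure(list(values = values, table = table, px_size_um = px_size_um),
            class = "psr_region_map")
}

#' @export
print.psr_region_map <- function(x, ...) {
  cat(sprintf("psr_region_map: %d x %d px, %.4g um/px\n",
              nrow(x$values), ncol(x$values), x$px_size_um))
  areas <- region_areas_um2(x)
  tb <- x$table
  tb$area_um2 <- areas[tb$name]
  print.data.frame(tb, row.names = FALSE)
  invisible(x)
}

# named vector of region areas in um^2
region_areas_um2 <- function(map) {
  counts <- tabulate(map$values[map$values > 0L], nbins = max(map$table$label))
  a <- counts[map$table$label] * map$px_size_um^2
  names(a) <- map$table$name
  a
}

region_mask <- function(map, name) {
  lb <- map$table$label[match(name, map$table$name)]
  if (is.na(lb)) stop("no region named '", name, "' in the region table")
  map$values == lb
}

#' Organ profile
#'
#' Organ-specific geometric parameters of the ROI construction rules.
#'
#' @param organ `"liver"`, `"lung"` or `"kidney"`.
#' @param band_um width of the lung peri-structure distance band in
#'   micrometres (default 25).
#' @param lumen_min_area_um2 minimum area for a background hole to count as
#'   a lumen.
#' @param vessel_rim_um rim width added around qualifying cortical lumens in
#'   the kidney (default 10).
#' @param connective_min_area_um2 minimum area of a liver connective-tissue
#'   component (default 50).
#' @param closing_radius_px radius of the morphological closing applied to
#'   the stain mask before liver connective components are formed
#'   (default 2).
#' @return A list of class `psr_organ_profile`.
#' @export
organ_profile <- function(organ = c("liver", "lung", "kidney"),
                          band_um = 25, lumen_min_area_um2 = 200,
                          vessel_rim_um = 10,
                          connective_min_area_um2 = 50,
                          closing_radius_px = 2L) {
  organ <- match.arg(organ)
  stopifnot(band_um > 0, lumen_min_area_um2 > 0, vessel_rim_um > 0,
            connective_min_area_um2 > 0, closing_radius_px >= 0)
  structure(list(organ = organ, band_um = band_um,
                 lumen_min_area_um2 = lumen_min_area_um2,
                 vessel_rim_um = vessel_rim_um,
                 connective_min_area_um2 = connective_min_area_um2,
                 closing_radius_px = as.integer(closing_radius_px)),
            class = "psr_organ_profile")
}

#' Detect the tissue section
#'
#' Tissue is defined as non-white pixels (minimum channel below
#' `brightness_cutoff`). Small holes -- pale intratissue gaps below
#' `fill_holes_max_um2` -- are filled back into tissue; larger holes are
#' kept open so that lumens remain available to [detect_lumens]. Components
#' smaller than `min_tissue_area_um2` (dust, debris) are removed.
#'
#' @param img a [psr_image].
#' @param brightness_cutoff pixels whose minimum channel is below this value
#'   are tissue (default 240).
#' @param min_tissue_area_um2 minimum component area kept (default 1000).
#' @param fill_holes_max_um2 holes up to this area are filled
#'   (default 200; use `Inf` to fill all holes, 0 to fill none).
#' @return Logical tissue mask.
#' @export
detect_tissue <- function(img, brightness_cutoff = 240,
                          min_tissue_area_um2 = 1000,
                          fill_holes_max_um2 = 200) {
  assert_image(img)
  if (brightness_cutoff > 255)
    warning("brightness_cutoff > 255: the whole frame is treated as tissue")
  mn <- pmin(channel_r(img), channel_g(img), channel_b(img))
  tissue <- mn < brightness_cutoff
  px2 <- img$px_size_um^2
  if (any(tissue) && fill_holes_max_um2 > 0) {
    holes <- (from_ebi(EBImage::fillHull(as_ebi(tissue))) > 0) & !tissue
    if (any(holes)) {
      lab <- label_components(holes)
      sizes <- tabulate(lab[lab > 0L])
      fill <- which(sizes * px2 <= fill_holes_max_um2)
      if (length(fill)) tissue <- tissue | matrix(lab %in% fill, nrow(lab), ncol(lab))
    }
  }
  tissue <- remove_small_components(tissue, ceiling(min_tissue_area_um2 / px2))
  if (!any(tissue)) stop("no tissue detected")
  tissue
}

#' Remove regions of exclusion from the tissue mask
#'
#' Subtracts every pixel labelled with role `"roe"`; the result is the
#' total-tissue denominator of all metrics. Labels with role
#' `"roe_keep_in_tissue"` are left inside tissue (they are excluded from
#' ROIs at quantification, not from the denominator).
#'
#' @param tissue logical tissue mask.
#' @param labels a [region_label_map] (or `NULL` for no exclusions).
#' @return Logical mask of total tissue.
#' @export
apply_exclusions <- function(tissue, labels = NULL) {
  if (is.null(labels)) return(tissue)
  if (!identical(dim(tissue), dim(labels$values)))
    stop("tissue mask and label map shapes differ")
  roe <- labels$table$label[labels$table$role == "roe"]
  if (length(roe) == 0L) return(tissue)
  tissue & !(labels$values %in% roe)
}

#' Detect lumens (enclosed background holes)
#'
#' Lumens are background-coloured holes fully enclosed by tissue with area
#' at least `lumen_min_area_um2`; holes touching the image border are never
#' lumens.
#'
#' @param tissue logical tissue mask (holes preserved, see
#'   [detect_tissue]).
#' @param profile an [organ_profile].
#' @param px_size_um pixel size in micrometres.
#' @return Logical lumen mask.
#' @export
detect_lumens <- function(tissue, profile, px_size_um) {
  holes <- (from_ebi(EBImage::fillHull(as_ebi(tissue))) > 0) & !tissue
  if (!any(holes)) return(holes)
  lab <- label_components(holes)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0L])
  keep <- setdiff(which(sizes * px_size_um^2 >= profile$lumen_min_area_um2),
                  border)
  matrix(lab %in% keep, nrow(lab), ncol(lab))
}

#' Construct liver ROIs (perivascular / bridges / parenchyma)
#'
#' Connective tissue is derived from the morphologically closed stain mask:
#' connected components above `connective_min_area_um2` that touch a lumen
#' boundary (within 1 px after closing) become perivascular ROI, the others
#' become bridges; the remaining tissue is parenchyma. The three ROI labels
#' partition the tissue mask.
#'
#' @param tissue logical total-tissue mask (after exclusions).
#' @param psr_mask logical detected-stain mask.
#' @param lumens logical lumen mask from [detect_lumens].
#' @param profile an [organ_profile].
#' @param px_size_um pixel size in micrometres.
#' @return A [region_label_map] with ROIs `perivascular`, `bridges`,
#'   `parenchyma`.
#' @export
build_liver_rois <- function(tissue, psr_mask, lumens, profile, px_size_um) {
  stopifnot(identical(dim(tissue), dim(psr_mask)),
            identical(dim(tissue), dim(lumens)))
  closed <- psr_mask & tissue
  if (profile$closing_radius_px > 0L && any(closed))
    closed <- from_ebi(EBImage::closing(as_ebi(closed),
                                        brush_disc(profile$closing_radius_px))) > 0
  closed <- closed & tissue
  min_px <- ceiling(profile$connective_min_area_um2 / px_size_um^2)
  lab <- label_components(closed)
  vals <- matrix(0L, nrow(tissue), ncol(tissue))
  if (any(lab > 0L)) {
    sizes <- tabulate(lab[lab > 0L])
    big <- which(sizes >= min_px)
    near_lumen <- from_ebi(EBImage::dilate(as_ebi(lumens), brush_diamond(1L))) > 0
    touching <- unique(lab[lab > 0L & near_lumen])
    peri <- intersect(big, touching)
    bridge <- setdiff(big, touching)
    vals[matrix(lab %in% peri, nrow(lab), ncol(lab))] <- 1L
    vals[matrix(lab %in% bridge, nrow(lab), ncol(lab))] <- 2L
  }
  vals[tissue & vals == 0L] <- 3L
  vals[!tissue] <- 0L
  tb <- region_table(1:3, c("perivascular", "bridges", "parenchyma"),
                     rep("roi", 3))
  region_label_map(vals, tb, px_size_um)
}

#' Construct lung ROIs (peri-air-duct / perivascular bands, parenchyma)
#'
#' Euclidean distance bands of width `band_um` are drawn around the air-duct
#' and blood-vessel structure masks (measured from the structure wall,
#' pixel-centre distances) and clipped to tissue. Where the two bands
#' overlap, the pixel goes to the nearer structure; exact ties go to the
#' peri-air-duct ROI. Remaining tissue is parenchyma.
#'
#' @param tissue logical total-tissue mask.
#' @param airduct_mask logical mask of air-duct structures.
#' @param vessel_mask logical mask of blood-vessel structures.
#' @param profile an [organ_profile].
#' @param px_size_um pixel size in micrometres.
#' @return A [region_label_map] with ROIs `peri_air_ducts`, `perivascular`,
#'   `parenchyma`.
#' @export
build_lung_rois <- function(tissue, airduct_mask, vessel_mask, profile,
                            px_size_um) {
  if (profile$band_um <= 0) stop("band_um must be positive")
  stopifnot(identical(dim(tissue), dim(airduct_mask)),
            identical(dim(tissue), dim(vessel_mask)))
  band_px <- profile$band_um / px_size_um
  dist_to <- function(structure) {
    if (!any(structure)) return(matrix(Inf, nrow(tissue), ncol(tissue)))
    from_ebi(EBImage::distmap(as_ebi(!structure), metric = "euclidean"))
  }
  d_duct <- dist_to(airduct_mask)
  d_vessel <- dist_to(vessel_mask)
  vals <- matrix(0L, nrow(tissue), ncol(tissue))
  in_duct_band <- d_duct <= band_px
  in_vessel_band <- d_vessel <= band_px
  vals[tissue & in_duct_band & d_duct <= d_vessel] <- 1L        # ties -> duct
  vals[tissue & in_vessel_band & d_vessel < d_duct] <- 2L
  vals[tissue & vals == 0L] <- 3L
  tb <- region_table(1:3, c("peri_air_ducts", "perivascular", "parenchyma"),
                     rep("roi", 3))
  region_label_map(vals, tb, px_size_um)
}

#' Construct kidney ROIs from a manual compartment map
#'
#' Ingests a label map carrying `inner_medulla`, `outer_medulla` and
#' `cortex` ROI labels (manually or phantom-defined). Within the cortex,
#' large cortical vessels are the qualifying lumens plus a `vessel_rim_um`
#' rim; the remainder of the cortex is vessel-free cortex. The two
#' sub-regions carry `parent = "cortex"` in the returned table so that
#' hierarchical additivity can be reported. Note that for the kidney the
#' quantified domain is the labelled compartment map (which includes
#' enclosed vessel lumens), mirroring the manual morphological delineation.
#'
#' @param labels a [region_label_map] with the three compartments.
#' @param lumens logical lumen mask (see [detect_lumens]).
#' @param profile an [organ_profile].
#' @return A [region_label_map] with ROIs `inner_medulla`, `outer_medulla`,
#'   `cortical_vessels`, `cortex_vessel_free`.
#' @export
build_kidney_rois <- function(labels, lumens, profile) {
  need <- c("inner_medulla", "outer_medulla", "cortex")
  missing <- setdiff(need, labels$table$name)
  if (length(missing))
    stop("kidney label map is missing required label(s): ",
         paste(missing, collapse = ", "))
  px <- labels$px_size_um
  cortex <- region_mask(labels, "cortex")
  vessels <- matrix(FALSE, nrow(cortex), ncol(cortex))
  if (any(lumens)) {
    lab <- label_components(lumens)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * px^2 >= profile$lumen_min_area_um2)
    qual <- matrix(lab %in% keep, nrow(lab), ncol(lab))
    if (any(qual)) {
      rim_px <- as.integer(round(profile$vessel_rim_um / px))
      if (rim_px > 0L)
        qual <- from_ebi(EBImage::dilate(as_ebi(qual), brush_disc(rim_px))) > 0
      vessels <- qual & cortex
    }
  }
  vals <- matrix(0L, nrow(cortex), ncol(cortex))
  vals[region_mask(labels, "inner_medulla")] <- 1L
  vals[region_mask(labels, "outer_medulla")] <- 2L
  vals[cortex & vessels] <- 3L
  vals[cortex & !vessels] <- 4L
  # carry through any ROE labels from the ingested map
  roe <- labels$table[labels$table$role != "roi", , drop = FALSE]
  tb <- region_table(
    c(1:4, if (nrow(roe)) 4L + seq_len(nrow(roe))),
    c("inner_medulla", "outer_medulla", "cortical_vessels",
      "cortex_vessel_free", if (nrow(roe)) roe$name),
    c(rep("roi", 4), if (nrow(roe)) roe$role),
    c(NA, NA, "cortex", "cortex", if (nrow(roe)) rep(NA_character_, nrow(roe)))
  )
  if (nrow(roe)) {
    for (i in seq_len(nrow(roe)))
      vals[labels$values == roe$label[i]] <- 4L + i
  }
  region_label_map(vals, tb, px)
}
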