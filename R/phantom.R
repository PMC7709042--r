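#' Specification of a synthetic PSR phantom
#'
#' Describes a deterministic synthetic brightfield image emulating a
#' picrosirius-red-stained section: a picric-yellow counterstained tissue
#' area containing red collagen fibers of graded intensity and compactness,
#' lumens, and artifact regions, with exact ground-truth masks. Stain
#' colours follow the visual appearance of PSR / picric staining and are
#' configurable; they are not asserted to match any particular scanner.
#'
#' @param organ phantom layout: `"flat"` (plain tissue disc),
#'   `"liver"`, `"lung"` or `"kidney"` (use [organ_preset]).
#' @param width_px,height_px canvas size in pixels.
#' @param px_size_um pixel edge length in micrometres (default 0.5,
#'   typical of a 20x scan).
#' @param background_color RGB of the counterstained tissue (picric
#'   yellow).
#' @param compact_fibers list with `n`, `width_um`, `color`, `jitter`
#'   describing the strongly stained, plain fibers.
#' @param scattered_fibers list describing the weakly stained, loose
#'   (meandering, thin) fibers.
#' @param n_lumens number of lumens.
#' @param lumen_radius_um lumen radius in micrometres.
#' @param n_artifacts number of erythrocyte-like bright red-orange blobs.
#' @param n_gaps number of small off-white gap artifacts inside tissue.
#' @param target_cpa_pct if not `NA` (flat layout only), compact fibers are
#'   added until the ground-truth in toto CPA reaches this percentage
#'   (`n` is ignored for compact fibers).
#' @param class_layout `"mixed"` (default) draws both fiber classes over
#'   the whole tissue; `"split"` (flat layout) confines compact fibers to
#'   the left tissue half and scattered fibers to the right, emulating the
#'   regional organization of dense septa versus loose interstitial
#'   collagen.
#' @param seed RNG seed fixing all randomness.
#' @return A list of class `psr_phantom_spec`.
#' @export
phantom_spec <- function(organ = "flat",
                         width_px = 320L, height_px = 320L,
                         px_size_um = 0.5,
                         background_color = c(230, 220, 60),
                         compact_fibers = list(n = 6, width_um = 2.5,
                                               color = c(180, 30, 40),
                                               jitter = 8),
                         scattered_fibers = list(n = 5, width_um = 1.2,
                                                 color = c(210, 140, 110),
                                                 jitter = 8),
                         n_lumens = 3L, lumen_radius_um = 6,
                         n_artifacts = 4L, n_gaps = 2L,
                         target_cpa_pct = NA_real_,
                         class_layout = c("mixed", "split"),
                         seed = 1L) {
  class_layout <- match.arg(class_layout)
  stopifnot(width_px >= 32, height_px >= 32, px_size_um > 0,
            all(background_color >= 0 & background_color <= 255),
            all(compact_fibers$color >= 0 & compact_fibers$color <= 255),
            all(scattered_fibers$color >= 0 & scattered_fibers$color <= 255),
            compact_fibers$n >= 0, scattered_fibers$n >= 0,
            n_lumens >= 0, n_artifacts >= 0, n_gaps >= 0)
  structure(list(organ = organ, width_px = as.integer(width_px),
                 height_px = as.integer(height_px), px_size_um = px_size_um,
                 background_color = background_color,
                 compact_fibers = compact_fibers,
                 scattered_fibers = scattered_fibers,
                 n_lumens = as.integer(n_lumens),
                 lumen_radius_um = lumen_radius_um,
                 n_artifacts = as.integer(n_artifacts),
                 n_gaps = as.integer(n_gaps),
                 target_cpa_pct = target_cpa_pct,
                 class_layout = class_layout,
                 seed = as.integer(seed)),
            class = "psr_phantom_spec")
}

#' Organ-preset phantom specifications
#'
#' Presets whose ROI layout matches the organ's region vocabulary: liver
#' (perivascular / bridges / parenchyma around lumens), lung (air ducts and
#' vessels with 25 um distance bands and parenchyma), kidney (nested
#' inner/outer medulla and cortex with large cortical vessels).
#'
#' @param organ `"liver"`, `"lung"` or `"kidney"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [phantom_spec].
#' @return A `psr_phantom_spec`.
#' @export
organ_preset <- function(organ = c("liver", "lung", "kidney"), seed = 1L, ...) {
  organ <- match.arg(organ)
  defaults <- switch(organ,
    liver  = list(organ = "liver", n_lumens = 3L, lumen_radius_um = 10,
                  compact_fibers = list(n = 3, width_um = 2.5,
                                        color = c(180, 30, 40), jitter = 8),
                  scattered_fibers = list(n = 4, width_um = 1.2,
                                          color = c(210, 140, 110), jitter = 8)),
    lung   = list(organ = "lung", n_lumens = 0L,
                  compact_fibers = list(n = 5, width_um = 2.5,
                                        color = c(180, 30, 40), jitter = 8),
                  scattered_fibers = list(n = 5, width_um = 1.2,
                                          color = c(210, 140, 110), jitter = 8)),
    kidney = list(organ = "kidney", n_lumens = 2L, lumen_radius_um = 12,
                  compact_fibers = list(n = 5, width_um = 2.5,
                                        color = c(180, 30, 40), jitter = 8),
                  scattered_fibers = list(n = 4, width_um = 1.2,
                                          color = c(210, 140, 110), jitter = 8))
  )
  args <- utils::modifyList(c(defaults, list(seed = seed)), list(...))
  do.call(phantom_spec, args)
}

# ---- rendering primitives -------------------------------------------------

# anti-aliased coverage of a disc; pixel centres at integer (row, col)
coverage_disc <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rows - cy)^2 + (cols - cx)^2)
  clip01(r + 0.5 - d, 0, 1)
}

# anti-aliased coverage of a stroked polyline of half-width hw
coverage_stroke <- function(h, w, path, hw) {
  cov <- matrix(0, h, w)
  pad <- ceiling(hw) + 2
  r0 <- max(1L, floor(min(path[, 1]) - pad)); r1 <- min(h, ceiling(max(path[, 1]) + pad))
  c0 <- max(1L, floor(min(path[, 2]) - pad)); c1 <- min(w, ceiling(max(path[, 2]) + pad))
  if (r0 > r1 || c0 > c1) return(cov)
  rows <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cols <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  d <- matrix(Inf, nrow(rows), ncol(rows))
  for (i in seq_len(nrow(path) - 1L)) {
    p1 <- path[i, ]; p2 <- path[i + 1L, ]
    v <- p2 - p1; L2 <- sum(v^2)
    if (L2 == 0) {
      di <- sqrt((rows - p1[1])^2 + (cols - p1[2])^2)
    } else {
      t <- clip01(((rows - p1[1]) * v[1] + (cols - p1[2]) * v[2]) / L2, 0, 1)
      di <- sqrt((rows - (p1[1] + t * v[1]))^2 + (cols - (p1[2] + t * v[2]))^2)
    }
    d <- pmin(d, di)
  }
  cov[r0:r1, c0:c1] <- clip01(hw + 0.5 - d, 0, 1)
  cov
}

# composite a colour onto an RGB canvas with per-pixel coverage
composite <- function(canvas, cov, color) {
  for (ch in 1:3)
    canvas[, , ch] <- (1 - cov) * canvas[, , ch] + cov * color[ch]
  canvas
}

# random meandering path inside an allowed mask
wiggly_path <- function(allowed, n_steps, step_px, curvature_sd) {
  idx <- which(allowed)
  if (!length(idx)) stop("fibers requested outside tissue: no room to draw")
  h <- nrow(allowed)
  start <- idx[sample.int(length(idx), 1L)]
  p <- c((start - 1L) %% h + 1L, (start - 1L) %/% h + 1L)
  heading <- stats::runif(1, 0, 2 * pi)
  path <- matrix(NA_real_, n_steps + 1L, 2L)
  path[1L, ] <- p
  n_ok <- 1L
  for (i in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, curvature_sd)
    q <- p + step_px * c(sin(heading), cos(heading))
    qr <- round(q)
    if (qr[1] < 1 || qr[1] > h || qr[2] < 1 || qr[2] > ncol(allowed) ||
        !allowed[qr[1], qr[2]]) break
    p <- q
    n_ok <- i + 1L
    path[n_ok, ] <- p
  }
  if (n_ok == 1L) { path[2L, ] <- path[1L, ]; n_ok <- 2L }
  path[seq_len(n_ok), , drop = FALSE]
}

# tight zigzag path: loose, meandering geometry whose concavities are at the
# scale of the fiber-closing radius, as rendered for scattered collagen
zigzag_path <- function(allowed, n_steps, step_px, amplitude_rad = 1.25) {
  idx <- which(allowed)
  if (!length(idx)) stop("fibers requested outside tissue: no room to draw")
  h <- nrow(allowed)
  start <- idx[sample.int(length(idx), 1L)]
  p <- c((start - 1L) %% h + 1L, (start - 1L) %/% h + 1L)
  base <- stats::runif(1, 0, 2 * pi)
  path <- matrix(NA_real_, n_steps + 1L, 2L)
  path[1L, ] <- p
  n_ok <- 1L
  for (i in seq_len(n_steps)) {
    base <- base + stats::rnorm(1, 0, 0.15)
    heading <- base + (if (i %% 2L == 0L) amplitude_rad else -amplitude_rad)
    q <- p + step_px * c(sin(heading), cos(heading))
    qr <- round(q)
    if (qr[1] < 1 || qr[1] > h || qr[2] < 1 || qr[2] > ncol(allowed) ||
        !allowed[qr[1], qr[2]]) break
    p <- q
    n_ok <- i + 1L
    path[n_ok, ] <- p
  }
  if (n_ok == 1L) { path[2L, ] <- path[1L, ]; n_ok <- 2L }
  path[seq_len(n_ok), , drop = FALSE]
}

# circular path (closed) of radius r around (cy, cx)
circle_path <- function(cy, cx, r) {
  n <- max(12L, ceiling(2 * pi * r / 2))
  a <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(cy + r * sin(a), cx + r * cos(a))
}

# ---- generator ------------------------------------------------------------

#' Generate a synthetic PSR phantom with exact ground truth
#'
#' Renders the phantom described by a [phantom_spec] with anti-aliased
#' fibers (an edge pixel belongs to the ground truth iff its fiber coverage
#' is at least 0.5) and returns the image together with pixel-exact
#' ground-truth masks and the ground-truth region label map. Identical
#' seeds give bit-identical outputs; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [phantom_spec].
#' @return A list of class `psr_phantom` with elements `image`
#'   ([psr_image]), `tissue`, `lumens`, `fiber_masks` (list `compact`,
#'   `scattered`, `all`), `artifacts`, `structures` (lung only),
#'   `regions` (ground-truth [region_label_map]), `areas_um2`
#'   (named ground-truth areas), `gt_cpa_pct`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "psr_phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  h <- spec$height_px; w <- spec$width_px; px <- spec$px_size_um
  canvas <- array(255, dim = c(h, w, 3))

  # tissue ellipse
  margin <- round(min(h, w) * 0.06)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ay <- h / 2 - margin; ax <- w / 2 - margin
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dn <- sqrt(((rows - cy) / ay)^2 + ((cols - cx) / ax)^2)
  cov_tissue <- clip01((1 - dn) * min(ay, ax) + 0.5, 0, 1)
  tissue <- cov_tissue >= 0.5
  canvas <- composite(canvas, cov_tissue, spec$background_color)

  interior <- dn < 0.85

  # organ scaffolding ------------------------------------------------------
  lumens <- matrix(FALSE, h, w)
  structures <- NULL
  compartments <- NULL
  lum_centres <- NULL
  if (spec$organ %in% c("flat", "liver", "kidney") && spec$n_lumens > 0L) {
    r_lum <- spec$lumen_radius_um / px
    ang <- stats::runif(spec$n_lumens, 0, 2 * pi)
    rad <- stats::runif(spec$n_lumens, 0.25, 0.6)
    lum_centres <- cbind(cy + rad * ay * sin(ang), cx + rad * ax * cos(ang))
    for (i in seq_len(spec$n_lumens)) {
      cov <- coverage_disc(h, w, lum_centres[i, 1], lum_centres[i, 2], r_lum)
      canvas <- composite(canvas, cov, c(255, 255, 255))
      lumens <- lumens | (cov >= 0.5)
    }
    tissue <- tissue & !lumens
  }
  if (spec$organ == "lung") {
    # two air ducts (large) and two vessels (small): wall + carved lumen
    duct <- matrix(FALSE, h, w); vessel <- matrix(FALSE, h, w)
    place <- cbind(cy + c(-0.45, 0.45, 0.05, -0.05) * ay,
                   cx + c(-0.35, 0.3, -0.5, 0.5) * ax)
    radii <- c(16, 14, 8, 8)
    for (i in 1:4) {
      cov <- coverage_disc(h, w, place[i, 1], place[i, 2], radii[i])
      obj <- cov >= 0.5
      lum_cov <- coverage_disc(h, w, place[i, 1], place[i, 2], radii[i] - 4)
      canvas <- composite(canvas, lum_cov, c(255, 255, 255))
      lumens <- lumens | (lum_cov >= 0.5)
      if (i <= 2) duct <- duct | obj else vessel <- vessel | obj
    }
    tissue <- tissue & !lumens
    structures <- list(airducts = duct, vessels = vessel)
  }
  if (spec$organ == "kidney") {
    # nested compartments: inner medulla disc, outer medulla annulus, cortex
    compartments <- matrix(0L, h, w)
    compartments[tissue | lumens] <- 3L                       # cortex (lumens included)
    compartments[dn < 0.55 & (tissue | lumens)] <- 2L         # outer medulla
    compartments[dn < 0.3 & (tissue | lumens)] <- 1L          # inner medulla
    # qualifying cortical lumens were placed above; keep them in the cortex zone
  }

  # fibers ------------------------------------------------------------------
  gt_compact <- matrix(FALSE, h, w)
  gt_scattered <- matrix(FALSE, h, w)

  draw_fiber <- function(canvas, gt, fib, path) {
    hw <- fib$width_um / px / 2
    cov <- coverage_stroke(h, w, path, hw)
    col <- clip01(fib$color + stats::runif(3, -fib$jitter, fib$jitter))
    canvas <- composite(canvas, cov, col)
    list(canvas = canvas, gt = gt | (cov >= 0.5 & tissue))
  }

  allowed <- tissue & interior
  if (!any(allowed)) stop("fibers requested outside tissue: no room to draw")

  scatter_region <- allowed
  compact_region <- allowed
  if (spec$organ == "kidney") scatter_region <- allowed & compartments != 3L
  if (spec$organ == "flat" && identical(spec$class_layout, "split")) {
    compact_region <- allowed & cols < cx
    scatter_region <- allowed & cols > cx
  }
  for (i in seq_len(spec$scattered_fibers$n)) {
    path <- zigzag_path(scatter_region, n_steps = 24L, step_px = 7)
    res <- draw_fiber(canvas, gt_scattered, spec$scattered_fibers, path)
    canvas <- res$canvas; gt_scattered <- res$gt
  }

  if (spec$organ == "liver" && !is.null(lum_centres)) {
    # perivascular collagen: a ring hugging every lumen wall
    r_ring <- spec$lumen_radius_um / px + spec$compact_fibers$width_um / px / 2
    for (i in seq_len(nrow(lum_centres))) {
      path <- circle_path(lum_centres[i, 1], lum_centres[i, 2], r_ring)
      res <- draw_fiber(canvas, gt_compact, spec$compact_fibers, path)
      canvas <- res$canvas; gt_compact <- res$gt
    }
  }

  add_compact_stroke <- function(canvas, gt) {
    if (spec$organ == "liver") {
      # parenchymal bridges away from the lumens
      path <- wiggly_path(allowed & !lumens, n_steps = 30L, step_px = 4,
                          curvature_sd = 0.25)
    } else if (spec$organ == "lung") {
      # compact collagen hugs duct/vessel walls
      near <- from_ebi(EBImage::dilate(as_ebi(structures$airducts | structures$vessels),
                                       brush_disc(round(20 / px / 2)))) > 0
      path <- wiggly_path(allowed & near, n_steps = 12L, step_px = 3,
                          curvature_sd = 0.5)
    } else if (spec$organ == "kidney") {
      path <- wiggly_path(allowed & compartments == 3L, n_steps = 20L,
                          step_px = 4, curvature_sd = 0.4)
    } else {
      path <- wiggly_path(compact_region, n_steps = 18L, step_px = 4,
                          curvature_sd = 0.3)
    }
    draw_fiber(canvas, gt, spec$compact_fibers, path)
  }

  if (!is.na(spec$target_cpa_pct) && spec$organ == "flat") {
    target_px <- spec$target_cpa_pct / 100 * sum(tissue)
    guard <- 0L
    while (sum(gt_compact) < target_px && guard < 10000L) {
      res <- add_compact_stroke(canvas, gt_compact)
      canvas <- res$canvas; gt_compact <- res$gt
      guard <- guard + 1L
    }
  } else {
    for (i in seq_len(spec$compact_fibers$n)) {
      res <- add_compact_stroke(canvas, gt_compact)
      canvas <- res$canvas; gt_compact <- res$gt
    }
  }
  gt_scattered <- gt_scattered & !gt_compact   # compact takes precedence
  gt_all <- gt_compact | gt_scattered

  # artifacts ---------------------------------------------------------------
  artifacts <- matrix(FALSE, h, w)
  art_region <- tissue & interior & !gt_all
  idx_art <- which(art_region)
  for (i in seq_len(spec$n_artifacts)) {
    at <- idx_art[sample.int(length(idx_art), 1L)]
    acy <- (at - 1L) %% h + 1L; acx <- (at - 1L) %/% h + 1L
    r <- stats::runif(1, 3, 5)
    cov <- coverage_disc(h, w, acy, acx, r)
    canvas <- composite(canvas, cov, c(220, 80, 60))
    artifacts <- artifacts | (cov >= 0.5)
  }
  for (i in seq_len(spec$n_gaps)) {
    at <- idx_art[sample.int(length(idx_art), 1L)]
    acy <- (at - 1L) %% h + 1L; acx <- (at - 1L) %/% h + 1L
    cov <- coverage_disc(h, w, acy, acx, stats::runif(1, 2, 4))
    canvas <- composite(canvas, cov, c(245, 245, 245))
  }

  img <- psr_image(canvas, px_size_um = px,
                   sample_id = sprintf("phantom_%s_seed%d", spec$organ, spec$seed))

  # ground-truth regions -----------------------------------------------------
  profile <- organ_profile(if (spec$organ == "flat") "liver" else spec$organ)
  compartment_map <- NULL
  if (spec$organ == "kidney") {
    comp_tb <- region_table(1:3, c("inner_medulla", "outer_medulla", "cortex"),
                            rep("roi", 3))
    compartment_map <- region_label_map(compartments, comp_tb, px)
  }
  regions <- switch(spec$organ,
    liver = build_liver_rois(tissue, gt_all, lumens, profile, px),
    lung  = build_lung_rois(tissue, structures$airducts, structures$vessels,
                            profile, px),
    kidney = build_kidney_rois(compartment_map, lumens, profile),
    NULL)

  areas <- c(tissue = sum(tissue), lumens = sum(lumens),
             compact = sum(gt_compact), scattered = sum(gt_scattered),
             stain = sum(gt_all), artifacts = sum(artifacts)) * px^2
  structure(list(image = img, tissue = tissue, lumens = lumens,
                 fiber_masks = list(compact = gt_compact,
                                    scattered = gt_scattered, all = gt_all),
                 artifacts = artifacts, structures = structures,
                 compartments = compartment_map,
                 regions = regions, areas_um2 = areas,
                 gt_cpa_pct = 100 * sum(gt_all) / sum(tissue),
                 spec = spec),
            class = "psr_phantom")
}

#' @export
print.psr_phantom <- function(x, ...) {
  cat(sprintf("psr_phantom (%s, seed %d): %d x %d px, GT CPA %.2f%%\n",
              x$spec$organ, x$spec$seed, nrow(x$tissue), ncol(x$tissue),
              x$gt_cpa_pct))
  invisible(x)
}

#' Write a phantom to disk (image, label map, JSON sidecar)
#'
#' @param phantom a `psr_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_psr_raster(phantom$image, file.path(dir, "image.png"))
  if (!is.null(phantom$regions))
    png::writePNG(phantom$regions$values / 255,
                  target = file.path(dir, "regions.png"))
  sidecar <- list(
    spec = unclass(phantom$spec),
    seed = phantom$spec$seed,
    areas_um2 = as.list(phantom$areas_um2),
    gt_cpa_pct = phantom$gt_cpa_pct,
    region_table = if (!is.null(phantom$regions))
      as.data.frame(unclass(phantom$regions$table))
  )
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
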