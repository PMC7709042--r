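#' Morphological segmentation parameters (PSR_MORF)
#'
#' @param min_segment_px segments smaller than this are merged into their
#'   largest touching neighbour, or dropped when isolated (default 4).
#' @param seed_min_distance_px minimum Euclidean distance between watershed
#'   seeds (default 5).
#' @param intensity_cutoff mean-signal cutoff of the compact class in
#'   `[0, 255]`. The default (96) is the reference calibration: midway
#'   between the optimized-signal response of saturated stain (107) and the
#'   minimum signal a detected segment core can carry (the detection
#'   threshold, 84), so that strongly stained segments separate from
#'   segments that are detected but weak.
#' @param density_cutoff closure fill-ratio cutoff of the compact class in
#'   `[0, 1]` (default 0.6).
#' @return A list of class `psr_morph_params`.
#' @export
morph_params <- function(min_segment_px = 4L, seed_min_distance_px = 5L,
                         intensity_cutoff = 96, density_cutoff = 0.6) {
  stopifnot(min_segment_px >= 1, seed_min_distance_px >= 1,
            intensity_cutoff >= 0, intensity_cutoff <= 255,
            density_cutoff >= 0, density_cutoff <= 1)
  structure(list(min_segment_px = as.integer(min_segment_px),
                 seed_min_distance_px = as.integer(seed_min_distance_px),
                 intensity_cutoff = intensity_cutoff,
                 density_cutoff = density_cutoff),
            class = "psr_morph_params")
}

# Select watershed seeds: local maxima of `signal` within `mask` under a
# disc neighbourhood of radius r, one representative per plateau, then
# greedy non-maximum suppression (descending signal, then row-major index)
# enforcing the minimum seed distance. Components left without a seed get
# their maximum-signal pixel, so every mask component is seeded.
select_seeds <- function(mask, signal, r) {
  h <- nrow(mask); w <- ncol(mask)
  sig <- signal * mask
  dil <- from_ebi(EBImage::dilate(as_ebi(sig / 255), brush_disc(r))) * 255
  cand <- mask & (sig >= dil - 1e-9) & (sig > 0)
  seeds <- integer(0)
  if (any(cand)) {
    plab <- label_components(cand)
    reps <- vapply(seq_len(max(plab)), function(k) min(which(plab == k)),
                   integer(1))
    ord <- reps[order(-sig[reps], reps)]
    ri <- (ord - 1L) %% h + 1L; ci <- (ord - 1L) %/% h + 1L
    keep <- logical(length(ord))
    for (i in seq_along(ord)) {
      if (i == 1L) { keep[1L] <- TRUE; next }
      kept <- which(keep)
      d2 <- (ri[kept] - ri[i])^2 + (ci[kept] - ci[i])^2
      if (all(d2 >= r^2)) keep[i] <- TRUE
    }
    seeds <- ord[keep]
  }
  # guarantee one seed per connected component of the mask
  comp <- label_components(mask)
  seeded <- unique(comp[seeds])
  for (k in setdiff(seq_len(max(comp, 0L)), seeded)) {
    idx <- which(comp == k)
    seeds <- c(seeds, idx[which.max(signal[idx])])
  }
  sort(seeds)
}

# Seeded watershed by descending-intensity flooding with a bucket queue.
# Pixels leave the queue in order of decreasing (quantized) signal, FIFO
# within a level; a popped pixel takes the label of its highest-signal
# already-labelled 4-neighbour. Deterministic for fixed inputs.
flood_watershed <- function(mask, signal, seeds) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- integer(h * w)
  lab[seeds] <- seq_along(seeds)
  lev <- as.integer(round(pmin(pmax(signal, 0), 255) * 4))  # quarter-level buckets
  nlev <- 1022L
  buckets <- vector("list", nlev + 1L)
  nb_of <- function(idx) {
    r <- (idx - 1L) %% h + 1L; c <- (idx - 1L) %/% h + 1L
    out <- c(if (r > 1L) idx - 1L, if (r < h) idx + 1L,
             if (c > 1L) idx - h, if (c < w) idx + h)
    out[mask[out]]
  }
  queued <- logical(h * w)
  push <- function(idx) {
    idx <- idx[!queued[idx] & lab[idx] == 0L]
    for (p in idx) {
      l <- lev[p] + 1L
      buckets[[l]] <<- c(buckets[[l]], p)
      queued[p] <<- TRUE
    }
  }
  for (s in seeds) push(nb_of(s))
  top <- nlev + 1L
  repeat {
    while (top >= 1L && length(buckets[[top]]) == 0L) top <- top - 1L
    if (top < 1L) break
    p <- buckets[[top]][1L]
    buckets[[top]] <- buckets[[top]][-1L]
    if (lab[p] == 0L) {
      nb <- nb_of(p)
      labelled <- nb[lab[nb] > 0L]
      if (length(labelled)) {
        best <- labelled[order(-lev[labelled], labelled)][1L]
        lab[p] <- lab[best]
        newnb <- nb[lab[nb] == 0L]
        if (length(newnb)) {
          push(newnb)
          if (any(lev[newnb] + 1L > top)) top <- max(lev[newnb] + 1L, top)
        }
      }
    }
  }
  matrix(lab, h, w)
}

# closure fill ratio: segment pixel count over the pixel count of its
# morphologically closed footprint (closing radius 2 px)
closure_density <- function(seg_mask) {
  closed <- from_ebi(EBImage::closing(as_ebi(seg_mask), brush_disc(2L))) > 0
  sum(seg_mask) / max(sum(closed), sum(seg_mask))
}

#' Segment detected collagen into fibers (PSR_MORF)
#'
#' Watershed on the negated PSR_OPT signal restricted to the detection mask:
#' seeds are signal local maxima separated by at least
#' `seed_min_distance_px`, touching objects are split along watershed lines
#' by descending-intensity flooding, and segments below `min_segment_px`
#' are merged into their largest touching neighbour (dropped when
#' isolated). The union of segment pixels equals the mask minus dropped
#' specks.
#'
#' @param mask logical detection mask (from [detect_psr_opt]).
#' @param signal the PSR_OPT evidence image ([build_opt_signal]).
#' @param params a [morph_params] object.
#' @param px_size_um pixel size in micrometres.
#' @return A list with `labels` (integer H x W segment map) and `segments`
#'   (data.frame with `id`, `pixel_count`, `area_um2`, `mean_signal`,
#'   `density`, `fiber_class`).
#' @export
segment_fibers <- function(mask, signal, params = morph_params(),
                           px_size_um = 1) {
  if (!identical(dim(mask), dim(signal)))
    stop("mask and signal shapes differ")
  empty <- data.frame(id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), mean_signal = numeric(0),
                      density = numeric(0), fiber_class = character(0),
                      stringsAsFactors = FALSE)
  if (!any(mask))
    return(list(labels = matrix(0L, nrow(mask), ncol(mask)), segments = empty))
  seeds <- select_seeds(mask, signal, params$seed_min_distance_px)
  lab <- flood_watershed(mask, signal, seeds)
  lab <- merge_small_segments(lab, params$min_segment_px)
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids)) {
    lab <- matrix(match(lab, c(0L, ids), nomatch = 1L) - 1L, nrow(lab), ncol(lab))
    ids <- seq_along(ids)
  }
  segs <- lapply(ids, function(k) {
    m <- lab == k
    data.frame(id = k, pixel_count = sum(m),
               area_um2 = sum(m) * px_size_um^2,
               mean_signal = mean(signal[m]),
               density = closure_density(m),
               stringsAsFactors = FALSE)
  })
  segs <- if (length(segs)) do.call(rbind, segs) else empty[, 1:5]
  segs$fiber_class <- NA_character_
  out <- list(labels = lab, segments = segs)
  classify_fibers(out, params)
}

# merge segments below min_px into their largest 4-connected neighbour,
# smallest first; isolated small segments are dropped (label 0)
merge_small_segments <- function(lab, min_px) {
  if (min_px <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  repeat {
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes > 0L & sizes < min_px)
    if (!length(small)) break
    k <- small[which.min(sizes[small])]
    idx <- which(lab == k)
    r <- (idx - 1L) %% h + 1L; c <- (idx - 1L) %/% h + 1L
    nb <- c(idx[r > 1L] - 1L, idx[r < h] + 1L, idx[c > 1L] - h, idx[c < w] + h)
    nb_lab <- lab[nb]
    nb_lab <- nb_lab[nb_lab > 0L & nb_lab != k]
    if (length(nb_lab)) {
      counts <- sizes[unique(nb_lab)]
      target <- unique(nb_lab)[order(-counts, unique(nb_lab))][1L]
      lab[idx] <- target
    } else {
      lab[idx] <- 0L  # isolated speck
    }
  }
  lab
}

#' Classify fiber segments as compact or scattered
#'
#' A segment is compact iff its mean signal is at least `intensity_cutoff`
#' AND its closure fill ratio (density) is at least `density_cutoff`
#' (ties classify compact); otherwise it is scattered. Compact fibers are
#' the strongly stained, plain segments; scattered fibers the weakly
#' stained, loose ones.
#'
#' @param x a result of [segment_fibers] (or its `segments` data.frame).
#' @param params a [morph_params] object.
#' @return Same shape as the input, with `fiber_class` filled in.
#' @export
classify_fibers <- function(x, params = morph_params()) {
  segs <- if (is.data.frame(x)) x else x$segments
  if (nrow(segs)) {
    compact <- segs$mean_signal >= params$intensity_cutoff &
      segs$density >= params$density_cutoff
    segs$fiber_class <- ifelse(compact, "compact", "scattered")
  }
  if (is.data.frame(x)) return(segs)
  x$segments <- segs
  x
}

# per-class masks from a segmentation result
fiber_class_masks <- function(fit) {
  lab <- fit$labels
  cls <- fit$segments$fiber_class[match(lab, fit$segments$id)]
  list(
    compact   = matrix(!is.na(cls) & cls == "compact", nrow(lab), ncol(lab)),
    scattered = matrix(!is.na(cls) & cls == "scattered", nrow(lab), ncol(lab))
  )
}
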