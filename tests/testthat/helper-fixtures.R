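# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; crisp (non-anti-aliased) geometry is
# used wherever a test compares against an analytic area.

# canonical phantom palette
PAL <- list(
  white     = c(255, 255, 255),
  yellow    = c(230, 220, 60),    # picric-acid counterstain
  compact   = c(180, 30, 40),     # saturated PSR collagen
  scattered = c(210, 140, 110),   # faint loose collagen
  ery       = c(220, 80, 60)      # erythrocyte-like chromogen
)

# solid-colour image
flat_image <- function(color, h = 8, w = 8, px = 0.5, id = "flat") {
  arr <- array(rep(color, each = h * w), dim = c(h, w, 3))
  psr_image(arr, px_size_um = px, sample_id = id)
}

# image from a list of colours, one pixel each (1 x n)
pixel_row_image <- function(colors, px = 0.5) {
  arr <- array(0, dim = c(1, length(colors), 3))
  for (i in seq_along(colors)) arr[1, i, ] <- colors[[i]]
  psr_image(arr, px_size_um = px)
}

# paint a crisp (hard-edged) disc of a colour onto an image array
paint_disc <- function(arr, cy, cx, r, color) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- (rows - cy)^2 + (cols - cx)^2 <= r^2
  for (ch in 1:3) {
    plane <- arr[, , ch]
    plane[inside] <- color[ch]
    arr[, , ch] <- plane
  }
  arr
}

disc_mask <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# image synthesized from the optical-density forward model
# I_c = 255 * 10^(-a * v_c); `od` is an H x W matrix of stain amounts
forward_model_image <- function(od, stain_vector, px = 0.5, quantize = FALSE) {
  h <- nrow(od); w <- ncol(od)
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- 255 * 10^(-od * stain_vector[ch])
  if (quantize) arr <- round(arr)
  psr_image(arr, px_size_um = px)
}

# evidence values of the two detectors on a single solid colour
opt_signal_of <- function(color, fparams = filter_params()) {
  build_opt_signal(flat_image(color, 4, 4), fparams)[1, 1]
}

# ---- independent oracles --------------------------------------------------

# brute-force per-pixel Euclidean distance to the nearest TRUE pixel
brute_force_distance <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, h, w)
  if (nrow(pts) == 0L) return(out)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    out[r, c] <- sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
  }
  out
}

# brute-force two-seed flood assignment: sweep unique signal levels from
# high to low; within a level repeatedly hand each unassigned mask pixel
# adjacent (4-connectivity) to a labelled pixel the label of its
# highest-signal labelled neighbour. Independent re-implementation of
# descending-intensity flooding used to cross-check the watershed.
flood_oracle <- function(mask, signal, seeds) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  for (i in seq_along(seeds)) lab[seeds[i]] <- i
  nb <- function(r, c) {
    out <- list()
    if (r > 1) out <- c(out, list(c(r - 1L, c)))
    if (r < h) out <- c(out, list(c(r + 1L, c)))
    if (c > 1) out <- c(out, list(c(r, c - 1L)))
    if (c < w) out <- c(out, list(c(r, c + 1L)))
    out
  }
  levels <- sort(unique(signal[mask]), decreasing = TRUE)
  for (lv in levels) {
    repeat {
      cand <- which(mask & lab == 0L & signal >= lv)
      if (!length(cand)) break
      cand <- cand[order(-signal[cand], cand)]
      changed <- FALSE
      for (p in cand) {
        r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
        qs <- vapply(nb(r, c), function(q) as.integer((q[2] - 1L) * h + q[1]),
                     integer(1))
        qs <- qs[mask[qs] & lab[qs] > 0L]
        if (length(qs)) {
          # highest-signal labelled neighbour, lowest linear index on ties
          best <- qs[order(-signal[qs], qs)][1L]
          lab[p] <- lab[best]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  lab
}

# recall / false-positive rate of a mask against ground truth, within tissue
score_mask <- function(mask, gt, tissue) {
  pos <- gt & tissue
  neg <- !gt & tissue
  c(recall = sum(mask & pos) / sum(pos),
    fpr = sum(mask & neg) / sum(neg))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# dumbbell fixture: two intensity bumps joined by a 1-px neck; signal values
# are multiples of 0.25 so the flooding and the level-sweep oracle see the
# same landscape
dumbbell_fixture <- function() {
  h <- 9L; w <- 15L
  mask <- disc_mask(h, w, 5, 4, 3) | disc_mask(h, w, 5, 12, 3)
  mask[5, 4:12] <- TRUE
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d1 <- abs(rows - 5) + abs(cols - 4)
  d2 <- abs(rows - 5) + abs(cols - 12)
  signal <- pmax(200 - 8 * d1, 184 - 8 * d2)
  signal[!mask] <- 0
  list(mask = mask, signal = signal,
       peaks = c(which(rows == 5 & cols == 4), which(rows == 5 & cols == 12)))
}

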