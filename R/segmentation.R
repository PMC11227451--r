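# Nucleus segmentation from the DAPI channel and per-nucleus geometry.
# The segmenter is a classical baseline (Gaussian smoothing -> Otsu
# threshold -> hole filling -> distance-transform watershed -> small-object
# removal); segment_nuclei() also accepts a precomputed label mask from any
# external segmenter (e.g. a deep-learning model) through `external_mask`.

#' Segment nuclei in a DAPI image
#'
#' @param dapi A `FieldImage` (DAPI channel) or numeric matrix.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels. Generous
#'   smoothing (default 8) suppresses intranuclear chromatin texture so the
#'   threshold follows the nuclear outline, not the texture.
#' @param min_area_px Objects smaller than this many pixels are removed.
#' @param watershed_tolerance Minimum depth (in distance-transform units)
#'   between adjacent basins for them to stay separate objects; raises or
#'   lowers the tendency to split touching nuclei.
#' @param mask_smooth_radius Brush diameter (px) for morphological closing +
#'   opening of the binary mask before watershed; rounds off residual
#'   boundary raggedness. 0 disables.
#' @param external_mask Optional integer label matrix supplied by an external
#'   segmenter; when given it is validated, relabeled to 1..K and returned
#'   unchanged otherwise (adapter hook).
#' @return Integer label matrix (`LabelMask`): 0 = background, 1..K nuclei.
#' @export
segment_nuclei <- function(dapi, smooth_sigma_px = 8, min_area_px = 500,
                           watershed_tolerance = 2, mask_smooth_radius = 15,
                           external_mask = NULL) {
  px <- if (inherits(dapi, "FieldImage")) dapi$pixels else dapi
  if (!is.matrix(px)) stop("'dapi' must be a FieldImage or matrix")
  if (!is.null(external_mask)) {
    if (!identical(dim(external_mask), dim(px))) {
      stop("external mask shape does not match the image")
    }
    return(.relabel_sequential(external_mask))
  }
  rng <- range(px)
  if (rng[2] <= rng[1]) {
    return(matrix(0L, nrow(px), ncol(px)))  # blank image: no nuclei
  }
  img <- EBImage::Image((px - rng[1]) / (rng[2] - rng[1]))
  sm <- EBImage::gblur(img, sigma = smooth_sigma_px)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  bw <- EBImage::fillHull(sm > thr)
  if (mask_smooth_radius > 0 && sum(bw) > 0) {
    brush <- EBImage::makeBrush(mask_smooth_radius, shape = "disc")
    bw <- EBImage::fillHull(EBImage::opening(EBImage::closing(bw, brush), brush))
  }
  if (sum(bw) == 0) return(matrix(0L, nrow(px), ncol(px)))
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  # drop sub-nuclear debris, then compact the label set
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_area_px)
  if (length(small) > 0) lab[lab %in% small] <- 0L
  .relabel_sequential(lab)
}

.relabel_sequential <- function(lab) {
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (any(lab < 0)) stop("label mask must be non-negative")
  u <- sort(unique(lab[lab > 0]))
  if (length(u) > 0 && !identical(u, seq_along(u))) {
    map <- integer(max(u))
    map[u] <- seq_along(u)
    pos <- lab > 0
    lab[pos] <- map[lab[pos]]
  }
  lab
}

# Crofton-style perimeter estimate: count foreground runs (chords) along
# rows, columns and both diagonals; P = pi/4 * (Nh + Nv + (Nd1 + Nd2)/sqrt(2)).
# Calibrated so an ideal rasterized disc of radius R scores close to 2*pi*R,
# which keeps circularity of a disc near 1 (naive edge counting would not).
.crofton_perimeter <- function(bw) {
  runs_along <- function(m) {
    # number of 0->1 transitions scanning each row of m
    padded <- cbind(0L, m)
    sum(padded[, -1] == 1L & padded[, -ncol(padded)] == 0L)
  }
  nr <- nrow(bw); nc <- ncol(bw)
  n_h <- runs_along(bw)        # chords along image rows
  n_v <- runs_along(t(bw))     # chords along image columns
  # diagonal scans: group pixels by (row - col) and (row + col)
  idx <- which(bw == 1L, arr.ind = TRUE)
  diag_runs <- function(key, ord) {
    if (nrow(idx) == 0) return(0L)
    o <- order(key, ord)
    k <- key[o]; p <- ord[o]
    new_line <- c(TRUE, k[-1] != k[-length(k)])
    gap <- c(TRUE, p[-1] != p[-length(p)] + 1L)
    sum(new_line | gap)
  }
  n_d1 <- diag_runs(idx[, 1] - idx[, 2], idx[, 1])  # "\" diagonals
  n_d2 <- diag_runs(idx[, 1] + idx[, 2], idx[, 1])  # "/" diagonals
  (pi / 4) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Measure nucleus morphometrics
#'
#' Computes, for every label in a mask: centroid (0-based row/col), area,
#' equivalent circular diameter, Crofton perimeter, and circularity
#' `4*pi*area / perimeter^2` (about 1 for an ideal disc; low for elongated
#' or ragged segmentation errors).
#'
#' @param mask Integer label matrix from [segment_nuclei()].
#' @param pixel_size_um Microns per pixel.
#' @return `data.frame` with one row per label: `cell_id`, `centroid_row`,
#'   `centroid_col`, `area_um2`, `equiv_diameter_um`, `perimeter_um`,
#'   `circularity`.
#' @export
measure_nuclei <- function(mask, pixel_size_um = 0.108) {
  labs <- sort(unique(mask[mask > 0]))
  out <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                    centroid_col = numeric(0), area_um2 = numeric(0),
                    equiv_diameter_um = numeric(0), perimeter_um = numeric(0),
                    circularity = numeric(0))
  for (k in labs) {
    idx <- which(mask == k, arr.ind = TRUE)
    area_px <- nrow(idx)
    bb <- c(range(idx[, 1]), range(idx[, 2]))
    sub <- matrix(0L, bb[2] - bb[1] + 3L, bb[4] - bb[3] + 3L)
    sub[cbind(idx[, 1] - bb[1] + 2L, idx[, 2] - bb[3] + 2L)] <- 1L
    per_px <- .crofton_perimeter(sub)
    area_um2 <- area_px * pixel_size_um^2
    out <- rbind(out, data.frame(
      cell_id = as.integer(k),
      centroid_row = mean(idx[, 1]) - 1,   # 0-based convention
      centroid_col = mean(idx[, 2]) - 1,
      area_um2 = area_um2,
      equiv_diameter_um = 2 * sqrt(area_um2 / pi),
      perimeter_um = per_px * pixel_size_um,
      circularity = if (per_px > 0) 4 * pi * area_px / per_px^2 else 0
    ))
  }
  out
}

#' Flag nuclei failing morphometric quality control
#'
#' Nuclei with an equivalent circular diameter below `min_diameter_um` or a
#' circularity below `min_circularity` are marked as segmentation errors
#' (`qc_pass = FALSE`). Records are flagged, never deleted, so exclusion
#' counts stay auditable.
#'
#' @param records Output of [measure_nuclei()].
#' @param min_diameter_um Minimum equivalent diameter in microns (default 10).
#' @param min_circularity Minimum circularity (default 0.95).
#' @return `records` with a logical `qc_pass` column added.
#' @export
qc_filter <- function(records, min_diameter_um = 10, min_circularity = 0.95) {
  records$qc_pass <- records$equiv_diameter_um >= min_diameter_um &
    records$circularity >= min_circularity
  records
}

#' Normalized radial position map
#'
#' For each nucleus independently: take the Euclidean distance transform of
#' its binary mask, rescale it so the deepest pixel maps to 0 and the
#' periphery to 1. The resulting coordinate is 0 at the nucleus center and
#' 1 at the nuclear envelope, regardless of nucleus size or shape. Background
#' pixels are `NA`.
#'
#' @param mask Integer label matrix.
#' @return Numeric matrix of radial values in [0, 1] over nucleus pixels.
#' @export
radial_map <- function(mask) {
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  labs <- sort(unique(mask[mask > 0]))
  for (k in labs) {
    idx <- which(mask == k, arr.ind = TRUE)
    bb <- c(range(idx[, 1]), range(idx[, 2]))
    # one-pixel zero border so the distance transform sees background
    sub <- matrix(0, bb[2] - bb[1] + 3L, bb[4] - bb[3] + 3L)
    sub_idx <- cbind(idx[, 1] - bb[1] + 2L, idx[, 2] - bb[3] + 2L)
    sub[sub_idx] <- 1
    d <- EBImage::imageData(EBImage::distmap(sub))
    dv <- d[sub_idx]
    # periphery pixels of the transform sit one unit from background; shift
    # so they map exactly to 1 after normalization, deepest pixel to 0
    dmin <- min(dv); dmax <- max(dv)
    rad <- if (dmax > dmin) 1 - (dv - dmin) / (dmax - dmin) else rep(0, length(dv))
    out[idx] <- rad
  }
  out
}
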