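# FISH spot detection: scale-normalized Laplacian-of-Gaussian filtering,
# local-maximum extraction with non-maximum suppression, and sub-pixel
# refinement by intensity-weighted centroid. Spot positions are 0-based
# (row, col) floats in the image frame.

.log_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- seq.int(-h, h)
  xx <- matrix(g, 2L * h + 1L, 2L * h + 1L)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)  # zero net response on constant images
}

# negated, scale-normalized LoG response; bright blobs of scale ~sigma
# become positive peaks of height ~ amplitude / 2
.log_response <- function(px, sigma) {
  k <- -sigma^2 * .log_kernel(sigma)
  as.matrix(EBImage::imageData(EBImage::filter2(EBImage::Image(px), k)))
}

#' Detect FISH spots by Laplacian-of-Gaussian filtering
#'
#' Candidates are local maxima of the negated, scale-normalized LoG response
#' exceeding a threshold; candidates closer than `min_separation_px` are
#' reduced to the strongest (non-maximum suppression); positions are refined
#' to the background-subtracted intensity-weighted centroid in a
#' `(2*ceil(2*sigma)+1)`-pixel window. Detection is deterministic.
#'
#' @param img A `FieldImage` or numeric matrix.
#' @param sigma_px Spot scale in pixels (Gaussian sigma of the expected
#'   spot profile; diffraction-limited FISH signals at 0.108 um/px are
#'   around 1-2 px).
#' @param threshold Detection threshold. With `threshold_mode = "absolute"`
#'   (default) it is a floor on the LoG response; with `"adaptive"` the floor
#'   is `median(response) + threshold * mad(response)` per image.
#' @param min_separation_px Minimum distance between retained spots.
#' @param threshold_mode `"absolute"` or `"adaptive"`.
#' @return `data.frame` (`SpotRecord` rows): `spot_id`, `row`, `col`
#'   (0-based float), `intensity` (raw image value at the detection peak),
#'   `response` (LoG response), plus `channel` when `img` is a `FieldImage`.
#' @export
detect_spots <- function(img, sigma_px = 1.5, threshold = 10,
                         min_separation_px = 3,
                         threshold_mode = c("absolute", "adaptive")) {
  threshold_mode <- match.arg(threshold_mode)
  px <- if (inherits(img, "FieldImage")) img$pixels else img
  if (!is.matrix(px)) stop("'img' must be a FieldImage or matrix")
  if (sigma_px <= 0) stop("sigma_px must be positive")
  empty <- data.frame(spot_id = integer(0), row = numeric(0),
                      col = numeric(0), intensity = numeric(0),
                      response = numeric(0))
  if (inherits(img, "FieldImage")) empty$channel <- character(0)
  resp <- .log_response(px, sigma_px)
  thr <- if (threshold_mode == "adaptive") {
    stats::median(resp) + threshold * stats::mad(resp)
  } else threshold
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(empty)
  # local maxima over the 8-neighborhood (image border excluded)
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core >= resp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  hits <- hits + 1L  # back to full-image indices
  vals <- resp[hits]
  ord <- order(-vals, hits[, 1], hits[, 2])
  hits <- hits[ord, , drop = FALSE]
  vals <- vals[ord]
  # greedy non-maximum suppression, strongest first
  keep <- logical(nrow(hits))
  min2 <- min_separation_px^2
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- hits[keep, , drop = FALSE]
      if (any((prev[, 1] - hits[i, 1])^2 + (prev[, 2] - hits[i, 2])^2 < min2)) {
        ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  vals <- vals[keep]
  h <- as.integer(ceiling(2 * sigma_px))
  pos <- matrix(NA_real_, nrow(hits), 2)
  for (i in seq_len(nrow(hits))) {
    r <- hits[i, 1]; c <- hits[i, 2]
    rr <- max(1L, r - h):min(nr, r + h)
    cc <- max(1L, c - h):min(nc, c + h)
    w <- px[rr, cc, drop = FALSE]
    w <- w - min(w)   # local background removal
    sw <- sum(w)
    if (sw > 0) {
      pos[i, 1] <- sum(outer(rr, rep(1, length(cc))) * w) / sw - 1
      pos[i, 2] <- sum(outer(rep(1, length(rr)), cc) * w) / sw - 1
    } else {
      pos[i, ] <- c(r - 1, c - 1)
    }
  }
  out <- data.frame(spot_id = seq_len(nrow(hits)),
                    row = pos[, 1], col = pos[, 2],
                    intensity = px[hits], response = vals)
  if (inherits(img, "FieldImage")) out$channel <- img$channel
  out <- out[order(out$row, out$col), , drop = FALSE]
  out$spot_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assign detected spots to nuclei and sample their radial position
#'
#' Each spot is assigned to the nucleus label under its nearest integer
#' pixel; spots over background are dropped and counted. Assigned spots get
#' the radial coordinate of that pixel.
#'
#' @param spots `data.frame` from [detect_spots()].
#' @param mask Label mask from [segment_nuclei()].
#' @param radial Radial map from [radial_map()] (same field).
#' @return List with `spots` (retained spots, columns `cell_id` and `radial`
#'   added) and `n_dropped` (spots over background).
#' @export
assign_spots <- function(spots, mask, radial) {
  if (!identical(dim(mask), dim(radial))) {
    stop("mask and radial map shapes differ")
  }
  if (nrow(spots) == 0) {
    spots$cell_id <- integer(0)
    spots$radial <- numeric(0)
    return(list(spots = spots, n_dropped = 0L))
  }
  ri <- pmin(pmax(round(spots$row) + 1, 1), nrow(mask))
  ci <- pmin(pmax(round(spots$col) + 1, 1), ncol(mask))
  lab <- mask[cbind(ri, ci)]
  spots$cell_id <- as.integer(lab)
  spots$radial <- radial[cbind(ri, ci)]
  keep <- lab > 0
  dropped <- sum(!keep)
  spots <- spots[keep, , drop = FALSE]
  rownames(spots) <- NULL
  list(spots = spots, n_dropped = as.integer(dropped))
}
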