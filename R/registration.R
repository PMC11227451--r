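# Translation registration of sequential imaging rounds from the DAPI
# channel. The model is a pure integer-pixel translation with zero-filled
# boundaries; the displacement is found at the peak of the cross-correlation
#   C(dr, dc) = sum over overlapping pixels of A(r, c) * B(r + dr, c + dc).

#' Cross-correlation map between two images over a bounded displacement grid
#'
#' Computes the raw (or optionally mean-subtracted) cross-correlation of `A`
#' and `B` at every integer displacement with |dr|, |dc| <= `max_shift`,
#' summing only over the pixels where the shifted images overlap. The
#' computation runs through zero-padded FFTs; `method = "direct"` evaluates
#' the defining double sum and is intended for small images and validation.
#'
#' @param A,B Numeric matrices of identical dimensions. `A` is the reference
#'   (DNA-round) image, `B` the moving (RNA-round) image.
#' @param max_shift Maximum displacement searched, in pixels; must be smaller
#'   than the smallest image dimension.
#' @param normalized If `TRUE`, subtract each image's mean before
#'   correlating (zero-normalized correlation, robust to uneven
#'   illumination). Default `FALSE`: plain product correlation.
#' @param method `"fft"` (default) or `"direct"`.
#' @return An object of class `CorrelationMap`: list with `C` (a
#'   `(2*max_shift+1)` square matrix), and `d_row`/`d_col` (the displacement
#'   value along each axis, `-max_shift ... max_shift`).
#' @export
cross_correlate <- function(A, B, max_shift = 50L,
                            normalized = FALSE, method = c("fft", "direct")) {
  method <- match.arg(method)
  if (!is.matrix(A) || !is.matrix(B) || !identical(dim(A), dim(B))) {
    stop("A and B must be matrices with identical dimensions")
  }
  m <- as.integer(max_shift)
  if (m < 0L || m >= min(dim(A))) {
    stop("max_shift must be >= 0 and smaller than the smallest image dimension")
  }
  if (normalized) {
    A <- A - mean(A)
    B <- B - mean(B)
  }
  disp <- seq.int(-m, m)
  if (method == "direct") {
    C <- matrix(NA_real_, 2L * m + 1L, 2L * m + 1L)
    nr <- nrow(A); nc <- ncol(A)
    for (i in seq_along(disp)) {
      dr <- disp[i]
      r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
      for (j in seq_along(disp)) {
        dc <- disp[j]
        c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
        C[i, j] <- sum(A[r1:r2, c1:c2] *
                         B[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)])
      }
    }
  } else {
    nr <- nrow(A); nc <- ncol(A)
    Nr <- nr + 2L * m; Nc <- nc + 2L * m
    PA <- matrix(0, Nr, Nc); PB <- matrix(0, Nr, Nc)
    PA[1:nr, 1:nc] <- A
    PB[1:nr, 1:nc] <- B
    # circular cross-correlation: sum_x A(x) B(x + d) at index d (mod N)
    CC <- Re(stats::fft(Conj(stats::fft(PA)) * stats::fft(PB), inverse = TRUE)) /
      (Nr * Nc)
    idx_r <- ((disp %% Nr) + 1L)
    idx_c <- ((disp %% Nc) + 1L)
    C <- CC[idx_r, idx_c, drop = FALSE]
  }
  dimnames(C) <- list(d_row = disp, d_col = disp)
  structure(list(C = C, d_row = disp, d_col = disp), class = "CorrelationMap")
}

#' Locate the correlation peak
#'
#' Returns the displacement at which the correlation map attains its
#' maximum. Ties are broken by the smallest Euclidean displacement
#' magnitude, then by row-major order over the displacement grid.
#'
#' @param map A `CorrelationMap` from [cross_correlate()].
#' @return A `TranslationVector`: list with integer `d_row`, `d_col`.
#' @export
find_peak <- function(map) {
  stopifnot(inherits(map, "CorrelationMap"))
  C <- map$C
  if (length(C) == 0) stop("empty correlation map")
  rng <- range(C)
  if (!all(is.finite(rng))) stop("correlation map contains non-finite values")
  if (rng[1] == rng[2]) stop("no correlation structure: map is constant")
  tol <- max(abs(rng)) * 1e-12
  hits <- which(C >= rng[2] - tol, arr.ind = TRUE)
  dr <- map$d_row[hits[, 1]]
  dc <- map$d_col[hits[, 2]]
  # tie-break: |d| ascending, then row-major (d_row, then d_col)
  ord <- order(dr^2 + dc^2, hits[, 1], hits[, 2])
  structure(list(d_row = as.integer(dr[ord[1]]), d_col = as.integer(dc[ord[1]])),
            class = "TranslationVector")
}

#' Shift image content by a translation vector, zero-filling the boundary
#'
#' Content at position (r, c) of `B` appears at (r + d_row, c + d_col) in the
#' output; pixels whose source falls outside the input are set to zero. The
#' output has the same shape as the input.
#'
#' @param B Numeric matrix.
#' @param v A `TranslationVector` or integer vector `c(d_row, d_col)`.
#' @return Shifted matrix.
#' @export
apply_translation <- function(B, v) {
  if (inherits(v, "TranslationVector")) v <- c(v$d_row, v$d_col)
  v <- as.integer(round(v))
  nr <- nrow(B); nc <- ncol(B)
  if (abs(v[1]) > nr || abs(v[2]) > nc) stop("translation exceeds image size")
  out <- matrix(0, nr, nc)
  src_r <- intersect(seq_len(nr) - v[1], seq_len(nr))
  src_c <- intersect(seq_len(nc) - v[2], seq_len(nc))
  if (length(src_r) > 0 && length(src_c) > 0) {
    out[src_r + v[1], src_c + v[2]] <- B[src_r, src_c]
  }
  out
}

# Pearson correlation of A and B-shifted-by-v over their overlap.
# Used as the registration quality score; in [-1, 1].
.overlap_quality <- function(A, B, v) {
  nr <- nrow(A); nc <- ncol(A)
  dr <- v[1]; dc <- v[2]
  r1 <- max(1L, 1L + dr); r2 <- min(nr, nr + dr)
  c1 <- max(1L, 1L + dc); c2 <- min(nc, nc + dc)
  if (r1 > r2 || c1 > c2) return(0)
  a <- A[r1:r2, c1:c2]
  b <- B[(r1 - dr):(r2 - dr), (c1 - dc):(c2 - dc)]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Register an RNA-round field onto the DNA round using the DAPI channel
#'
#' Estimates the translation between the two rounds from their DAPI images,
#' then applies the same vector to the RNA-probe image so RNA and DNA spots
#' share one coordinate frame. The quality score is the Pearson correlation
#' of the two DAPI images over their overlap at the estimated shift; fields
#' scoring below `min_quality` are flagged for exclusion.
#'
#' @param dapi_dna_round `FieldImage`, DAPI channel of the DNA round
#'   (reference frame).
#' @param dapi_rna_round `FieldImage`, DAPI channel of the RNA round.
#' @param rna_channel `FieldImage`, RNA-probe channel of the RNA round.
#' @param max_shift Displacement search bound in pixels (default 50; plate
#'   re-mounting drift is small relative to a full field).
#' @param normalized Passed to [cross_correlate()].
#' @param min_quality Quality floor below which the field is flagged.
#' @return List with `rna_registered` (a `FieldImage` in the DNA-round
#'   frame), `vector` (`TranslationVector` that was applied), `quality`
#'   (numeric in [-1, 1]) and `flagged` (logical).
#' @export
register_pair <- function(dapi_dna_round, dapi_rna_round, rna_channel,
                          max_shift = 50L, normalized = FALSE,
                          min_quality = 0.3) {
  stopifnot(inherits(dapi_dna_round, "FieldImage"),
            inherits(dapi_rna_round, "FieldImage"),
            inherits(rna_channel, "FieldImage"))
  A <- dapi_dna_round$pixels
  B <- dapi_rna_round$pixels
  if (!identical(dim(A), dim(B)) ||
      !identical(dim(A), dim(rna_channel$pixels))) {
    stop("all images of a field must share one shape")
  }
  if (dapi_dna_round$well != dapi_rna_round$well ||
      dapi_dna_round$field != dapi_rna_round$field) {
    stop("DAPI images come from different fields")
  }
  peak <- find_peak(cross_correlate(A, B, max_shift = max_shift,
                                    normalized = normalized))
  # C peaks at the displacement of B's content relative to A; moving B's
  # content by the opposite vector maximizes its overlap with A.
  v <- structure(list(d_row = -peak$d_row, d_col = -peak$d_col),
                 class = "TranslationVector")
  q <- .overlap_quality(A, B, c(v$d_row, v$d_col))
  reg <- field_image(apply_translation(rna_channel$pixels, v),
                     well = rna_channel$well, field = rna_channel$field,
                     channel = rna_channel$channel, round = "dna_round",
                     pixel_size_um = rna_channel$pixel_size_um)
  list(rna_registered = reg, vector = v, quality = q,
       flagged = q < min_quality)
}
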