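# Allele-level analysis: per-cell spot counting and selection, minimum
# DNA-RNA distances, active/inactive/no-transcription calls, and the
# radial-position comparison between activity classes.

.count_bin <- function(n) {
  ifelse(n >= 3, ">=3", as.character(n))
}

.expression_class <- function(n_rna) {
  out <- c("silent", "monoallelic", "biallelic")[pmin(n_rna, 2) + 1]
  out[n_rna >= 3] <- "multi"
  out
}

#' Summarize spot counts per cell and flag analyzable cells
#'
#' Counts DNA and RNA spots per nucleus, bins counts into
#' `"0"/"1"/"2"/">=3"`, derives the per-cell expression class from the RNA
#' count (0 = silent, 1 = monoallelic, 2 = biallelic, >=3 = multi), and
#' selects cells for allele-level analysis: QC-passing nuclei with exactly
#' two DNA FISH spots and at most two RNA FISH spots.
#'
#' @param spots Assigned spot table (columns `cell_id`, `channel`).
#' @param nuclei Nucleus table with `cell_id` and `qc_pass`.
#' @return `nuclei` with columns `n_dna`, `n_rna`, `dna_bin`, `rna_bin`,
#'   `expression_class`, `selected` appended.
#' @export
summarize_cells <- function(spots, nuclei) {
  cnt <- function(ch) {
    s <- spots[spots$channel == ch, , drop = FALSE]
    n <- integer(nrow(nuclei))
    if (nrow(s) > 0) {
      t <- table(factor(s$cell_id, levels = nuclei$cell_id))
      n <- as.integer(t)
    }
    n
  }
  nuclei$n_dna <- cnt("DNA")
  nuclei$n_rna <- cnt("RNA")
  nuclei$dna_bin <- .count_bin(nuclei$n_dna)
  nuclei$rna_bin <- .count_bin(nuclei$n_rna)
  nuclei$expression_class <- .expression_class(nuclei$n_rna)
  nuclei$selected <- nuclei$qc_pass & nuclei$n_dna == 2L & nuclei$n_rna <= 2L
  nuclei
}

#' Minimum DNA-to-RNA spot distance per DNA spot
#'
#' For each DNA FISH spot of one cell, computes all 2D Euclidean distances
#' to the cell's RNA FISH spots and keeps the minimum, converted to microns.
#' Cells without any RNA spot yield `NA` (no transcription site present).
#'
#' @param dna_spots,rna_spots Spot tables (columns `row`, `col`, pixel
#'   units) for one cell.
#' @param pixel_size_um Microns per pixel.
#' @return Numeric vector, one entry per DNA spot (`NA` when no RNA spots).
#' @export
min_dna_rna_distance <- function(dna_spots, rna_spots, pixel_size_um = 0.108) {
  if (nrow(dna_spots) == 0) return(numeric(0))
  if (nrow(rna_spots) == 0) return(rep(NA_real_, nrow(dna_spots)))
  vapply(seq_len(nrow(dna_spots)), function(i) {
    d <- sqrt((dna_spots$row[i] - rna_spots$row)^2 +
                (dna_spots$col[i] - rna_spots$col)^2)
    min(d) * pixel_size_um
  }, numeric(1))
}

#' Classify allele transcriptional activity from DNA-RNA distance
#'
#' An allele (one DNA FISH spot) is `"active"` when an RNA FISH signal lies
#' strictly within `threshold_um` (default 1.0 um), `"inactive"` when the
#' nearest RNA signal is at or beyond the threshold, and
#' `"no_transcription"` when the cell has no RNA signal at all (missing
#' distance).
#'
#' @param distance_um Numeric vector of minimum DNA-RNA distances (um);
#'   `NA` = no RNA spot in the cell.
#' @param threshold_um Activity-calling radius in microns.
#' @return Character vector of classes.
#' @export
classify_allele <- function(distance_um, threshold_um = 1.0) {
  if (any(distance_um < 0, na.rm = TRUE)) {
    stop("distances must be non-negative")
  }
  ifelse(is.na(distance_um), "no_transcription",
         ifelse(distance_um < threshold_um, "active", "inactive"))
}

#' Compare radial positions of active versus inactive alleles
#'
#' Two-sided two-sample Kolmogorov-Smirnov test (asymptotic p-value) on the
#' normalized radial positions of the two activity groups, with group
#' summaries.
#'
#' @param active,inactive Numeric vectors of radial positions in [0, 1].
#' @return List of class `KSResult`: `D`, `p_value`, `n_active`,
#'   `n_inactive`, `mean_active`, `mean_inactive`, `sd_active`,
#'   `sd_inactive`.
#' @export
compare_radial <- function(active, inactive) {
  active <- active[!is.na(active)]
  inactive <- inactive[!is.na(inactive)]
  if (length(active) == 0) stop("'active' group is empty")
  if (length(inactive) == 0) stop("'inactive' group is empty")
  kt <- suppressWarnings(stats::ks.test(active, inactive,
                                        alternative = "two.sided",
                                        exact = FALSE))
  structure(list(
    D = unname(kt$statistic), p_value = kt$p.value,
    n_active = length(active), n_inactive = length(inactive),
    mean_active = mean(active), mean_inactive = mean(inactive),
    sd_active = stats::sd(active), sd_inactive = stats::sd(inactive)
  ), class = "KSResult")
}

#' @export
print.KSResult <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (n = %d vs %d)\n",
              x$D, x$p_value, x$n_active, x$n_inactive))
  cat(sprintf("  radial mean +- sd: active %.2f +- %.2f, inactive %.2f +- %.2f\n",
              x$mean_active, x$sd_active, x$mean_inactive, x$sd_inactive))
  invisible(x)
}

# Per-cell allele calls for the selected cells of one field's tables.
# Returns the spot table with min_dna_rna_dist_um / activity_class filled
# in for DNA spots of selected cells.
.call_alleles <- function(spots, cells, pixel_size_um, threshold_um = 1.0) {
  spots$min_dna_rna_dist_um <- NA_real_
  spots$activity_class <- NA_character_
  sel_ids <- cells$cell_id[cells$selected]
  for (cid in sel_ids) {
    di <- which(spots$cell_id == cid & spots$channel == "DNA")
    ri <- which(spots$cell_id == cid & spots$channel == "RNA")
    if (length(di) == 0) next
    d <- min_dna_rna_distance(spots[di, , drop = FALSE],
                              spots[ri, , drop = FALSE], pixel_size_um)
    spots$min_dna_rna_dist_um[di] <- d
    spots$activity_class[di] <- classify_allele(d, threshold_um)
  }
  spots
}
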