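# End-to-end plate analysis: (registration) -> segmentation + QC ->
# spot detection + assignment -> per-cell selection -> allele activity
# calls -> radial-position comparison. Deterministic for a fixed manifest
# and configuration; every filter step is counted for the exclusion log.

#' Pipeline configuration
#'
#' Stage parameters for [run_pipeline()]. Defaults are tuned for the
#' simulator's acquisition geometry (0.108 um pixels, spots of sigma
#' ~1.5 px) and the standard nucleus QC rule (minimum equivalent diameter
#' 10 um, minimum circularity 0.95) with a strict 1.0 um activity radius.
#'
#' @param pixel_size_um Microns per pixel.
#' @param max_shift Registration displacement search bound (px).
#' @param normalized_correlation Use mean-subtracted cross-correlation.
#' @param min_quality Registration quality floor; fields below it are
#'   excluded and logged.
#' @param smooth_sigma_px,min_area_px,watershed_tolerance,mask_smooth_radius
#'   Segmentation parameters, see [segment_nuclei()].
#' @param spot_sigma_px,spot_threshold,spot_threshold_mode,min_separation_px
#'   Detection parameters, see [detect_spots()].
#' @param activity_threshold_um Allele activity-calling radius (um).
#' @param min_diameter_um,min_circularity Nucleus QC thresholds.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(pixel_size_um = 0.108,
                            max_shift = 50L,
                            normalized_correlation = FALSE,
                            min_quality = 0.3,
                            smooth_sigma_px = 8,
                            min_area_px = 500,
                            watershed_tolerance = 2,
                            mask_smooth_radius = 15,
                            spot_sigma_px = 1.5,
                            spot_threshold = 2000,
                            spot_threshold_mode = "absolute",
                            min_separation_px = 3,
                            activity_threshold_um = 1.0,
                            min_diameter_um = 10,
                            min_circularity = 0.95) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

.load_or_null <- function(manifest, well, field, channel, round, psz) {
  hit <- manifest$well == well & manifest$field == field &
    manifest$channel == channel & manifest$round == round
  if (!any(hit)) return(NULL)
  load_field(manifest, well, field, channel, round, pixel_size_um = psz)
}

#' Run the full allele-level analysis over a plate manifest
#'
#' For each field: in sequential mode the RNA-round images are first
#' registered onto the DNA round via the DAPI channel; nuclei are then
#' segmented from DAPI, measured and QC-filtered; DNA and RNA spots are
#' detected, assigned to nuclei and given radial positions; cells with two
#' DNA spots and at most two RNA spots are selected; and each DNA spot of a
#' selected cell is classified active / inactive / no_transcription from
#' its minimum distance to an RNA spot.
#'
#' @param manifest A `PlateManifest` from [read_manifest()] (or a path).
#' @param config A [pipeline_config()].
#' @param mode `"auto"` (default; inferred from the manifest's round
#'   tokens), `"simultaneous"`, or `"sequential"`.
#' @return List of class `PipelineResult`:
#'   `tables` (a `ResultsTables`), `report` (see [summarize_run()]),
#'   `shifts` (per-field registration results, sequential mode),
#'   `exclusions` (named counts at every filter step).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         mode = c("auto", "simultaneous", "sequential")) {
  mode <- match.arg(mode)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (mode == "auto") {
    mode <- if (any(manifest$round == "single")) "simultaneous" else "sequential"
  }
  psz <- config$pixel_size_um
  fields <- unique(manifest[c("well", "field")])
  fields <- fields[order(fields$well, fields$field), , drop = FALSE]

  cells_all <- NULL; spots_all <- NULL; shifts <- NULL
  excl <- c(fields_total = nrow(fields), fields_registration_flagged = 0L,
            nuclei_segmented = 0L, nuclei_qc_failed = 0L,
            spots_detected = 0L, spots_outside_nuclei = 0L,
            cells_not_selected = 0L, cells_selected = 0L)

  for (i in seq_len(nrow(fields))) {
    w <- fields$well[i]; f <- fields$field[i]
    if (mode == "simultaneous") {
      dapi <- .load_or_null(manifest, w, f, "DAPI", "single", psz)
      dna_img <- .load_or_null(manifest, w, f, "DNA", "single", psz)
      rna_img <- .load_or_null(manifest, w, f, "RNA", "single", psz)
    } else {
      dapi <- .load_or_null(manifest, w, f, "DAPI", "dna_round", psz)
      dna_img <- .load_or_null(manifest, w, f, "DNA", "dna_round", psz)
      dapi_rna <- .load_or_null(manifest, w, f, "DAPI", "rna_round", psz)
      rna_raw <- .load_or_null(manifest, w, f, "RNA", "rna_round", psz)
      if (is.null(dapi) || is.null(dapi_rna) || is.null(rna_raw)) {
        stop(sprintf("field %s/%d lacks sequential-mode images", w, f))
      }
      reg <- register_pair(dapi, dapi_rna, rna_raw,
                           max_shift = config$max_shift,
                           normalized = config$normalized_correlation,
                           min_quality = config$min_quality)
      shifts <- rbind(shifts, data.frame(
        well = w, field = f, d_row = reg$vector$d_row,
        d_col = reg$vector$d_col, quality = reg$quality,
        flagged = reg$flagged))
      if (reg$flagged) {
        excl["fields_registration_flagged"] <-
          excl["fields_registration_flagged"] + 1L
        next
      }
      rna_img <- reg$rna_registered
    }
    if (is.null(dapi)) stop(sprintf("field %s/%d has no DAPI image", w, f))

    mask <- segment_nuclei(dapi, smooth_sigma_px = config$smooth_sigma_px,
                           min_area_px = config$min_area_px,
                           watershed_tolerance = config$watershed_tolerance,
                           mask_smooth_radius = config$mask_smooth_radius)
    rec <- measure_nuclei(mask, pixel_size_um = psz)
    rec <- qc_filter(rec, min_diameter_um = config$min_diameter_um,
                     min_circularity = config$min_circularity)
    excl["nuclei_segmented"] <- excl["nuclei_segmented"] + nrow(rec)
    excl["nuclei_qc_failed"] <- excl["nuclei_qc_failed"] + sum(!rec$qc_pass)
    rad <- radial_map(mask)

    fs <- NULL
    for (img in list(dna_img, rna_img)) {
      if (is.null(img)) next
      det <- detect_spots(img, sigma_px = config$spot_sigma_px,
                          threshold = config$spot_threshold,
                          min_separation_px = config$min_separation_px,
                          threshold_mode = config$spot_threshold_mode)
      excl["spots_detected"] <- excl["spots_detected"] + nrow(det)
      asg <- assign_spots(det, mask, rad)
      excl["spots_outside_nuclei"] <- excl["spots_outside_nuclei"] +
        asg$n_dropped
      fs <- rbind(fs, asg$spots)
    }
    if (is.null(fs)) {
      fs <- data.frame(spot_id = integer(0), row = numeric(0),
                       col = numeric(0), intensity = numeric(0),
                       response = numeric(0), channel = character(0),
                       cell_id = integer(0), radial = numeric(0))
    }
    rec <- summarize_cells(fs, rec)
    excl["cells_selected"] <- excl["cells_selected"] + sum(rec$selected)
    excl["cells_not_selected"] <- excl["cells_not_selected"] +
      sum(!rec$selected)
    fs <- .call_alleles(fs, rec, psz, config$activity_threshold_um)

    rec$well <- w; rec$field <- f
    fs$well <- w; fs$field <- f
    fs$spot_id <- seq_len(nrow(fs))
    cells_all <- rbind(cells_all, rec)
    spots_all <- rbind(spots_all, fs)
  }

  if (is.null(cells_all) || nrow(cells_all) == 0) {
    stop("no analyzable fields in manifest")
  }
  tables <- results_tables(cells_all, spots_all)
  res <- structure(list(tables = tables, shifts = shifts,
                        exclusions = excl, mode = mode, config = config),
                   class = "PipelineResult")
  res$report <- summarize_run(res)
  res
}

#' Summary report for a pipeline run
#'
#' Aggregates the per-well tables into the run-level readout: DNA/RNA spot
#' count histograms over QC-passing cells, expression-class fractions over
#' selected cells, allele activity fractions, and the radial-position
#' comparison of active versus inactive alleles (KS test), reported both
#' with no-transcription alleles kept separate and merged into inactive.
#'
#' @param result A `PipelineResult` (or a list with a `tables` element).
#' @return List with `count_histograms`, `expression_fractions`,
#'   `activity_fractions`, `radial_by_class`, `ks_active_vs_inactive`,
#'   `ks_active_vs_nonactive`, `exclusions`.
#' @export
summarize_run <- function(result) {
  cells <- result$tables$cells
  spots <- result$tables$spots
  qc <- cells[cells$qc_pass, , drop = FALSE]
  sel <- cells[cells$selected, , drop = FALSE]
  bins <- c("0", "1", "2", ">=3")
  hist_tab <- function(x) table(factor(x, levels = bins))
  expr_frac <- if (nrow(sel) > 0) {
    tab <- table(factor(sel$expression_class,
                        levels = c("silent", "monoallelic", "biallelic", "multi")))
    tab / sum(tab)
  } else NULL
  dna_sel <- spots[spots$channel == "DNA" & !is.na(spots$activity_class), ,
                   drop = FALSE]
  act_frac <- if (nrow(dna_sel) > 0) {
    tab <- table(factor(dna_sel$activity_class,
                        levels = c("active", "inactive", "no_transcription")))
    tab / sum(tab)
  } else NULL
  rad_by_class <- split(dna_sel$radial, dna_sel$activity_class)
  ks1 <- ks2 <- NULL
  act <- dna_sel$radial[dna_sel$activity_class == "active"]
  ina <- dna_sel$radial[dna_sel$activity_class == "inactive"]
  non <- dna_sel$radial[dna_sel$activity_class != "active"]
  if (length(act) > 0 && length(ina) > 0) ks1 <- compare_radial(act, ina)
  if (length(act) > 0 && length(non) > 0) ks2 <- compare_radial(act, non)
  list(
    n_cells = nrow(cells), n_cells_qc = nrow(qc), n_cells_selected = nrow(sel),
    count_histograms = list(dna = hist_tab(qc$dna_bin),
                            rna = hist_tab(qc$rna_bin)),
    expression_fractions = expr_frac,
    activity_fractions = act_frac,
    radial_by_class = rad_by_class,
    ks_active_vs_inactive = ks1,
    ks_active_vs_nonactive = ks2,
    exclusions = result$exclusions
  )
}

#' @export
print.PipelineResult <- function(x, ...) {
  r <- x$report
  cat(sprintf("HiFISH pipeline run (%s mode)\n", x$mode))
  cat(sprintf("  cells: %d segmented, %d QC-pass, %d selected\n",
              r$n_cells, r$n_cells_qc, r$n_cells_selected))
  if (!is.null(r$expression_fractions)) {
    ef <- r$expression_fractions
    cat(sprintf("  expression (selected cells): silent %.1f%%, mono %.1f%%, bi %.1f%%, multi %.1f%%\n",
                100 * ef[["silent"]], 100 * ef[["monoallelic"]],
                100 * ef[["biallelic"]], 100 * ef[["multi"]]))
  }
  if (!is.null(r$activity_fractions)) {
    af <- r$activity_fractions
    cat(sprintf("  alleles: active %.1f%%, inactive %.1f%%, no transcription %.1f%%\n",
                100 * af[["active"]], 100 * af[["inactive"]],
                100 * af[["no_transcription"]]))
  }
  if (!is.null(r$ks_active_vs_inactive)) {
    cat("  radial, active vs inactive: ")
    print(r$ks_active_vs_inactive)
  }
  invisible(x)
}

#' Render report plots
#'
#' Writes spot-count histograms and radial-position ECDF curves for the
#' activity classes as PNG files.
#'
#' @param result A `PipelineResult`.
#' @param out_dir Output directory.
#' @return Character vector of files written.
#' @export
render_report <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  r <- result$report
  files <- character(0)
  f1 <- file.path(out_dir, "count_histograms.png")
  grDevices::png(f1, width = 900, height = 450)
  graphics::par(mfrow = c(1, 2))
  graphics::barplot(r$count_histograms$dna, main = "DNA spots per cell",
                    xlab = "spots", ylab = "cells")
  graphics::barplot(r$count_histograms$rna, main = "RNA spots per cell",
                    xlab = "spots", ylab = "cells")
  grDevices::dev.off()
  files <- c(files, f1)
  rad <- r$radial_by_class
  rad <- rad[vapply(rad, length, 1L) > 0]
  if (length(rad) > 0) {
    f2 <- file.path(out_dir, "radial_ecdf.png")
    grDevices::png(f2, width = 600, height = 500)
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "radial position (0 = center, 1 = periphery)",
                   ylab = "ECDF", main = "Radial position by activity class")
    cols <- stats::setNames(c("firebrick", "navy", "gray40"),
                            c("active", "inactive", "no_transcription"))
    for (nm in names(rad)) {
      graphics::plot(stats::ecdf(rad[[nm]]), add = TRUE, col = cols[[nm]],
                     do.points = FALSE, verticals = TRUE)
    }
    graphics::legend("topleft", legend = names(rad), col = cols[names(rad)],
                     lty = 1, bty = "n")
    grDevices::dev.off()
    files <- c(files, f2)
  }
  files
}
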