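# Coordinate convention used throughout the package: positions are 0-based
# (row, col) with the origin at the top-left pixel and rows increasing
# downward. Physical distance = pixel distance * pixel_size_um.

.CHANNELS <- c("DAPI", "DNA", "RNA")
.ROUNDS <- c("single", "rna_round", "dna_round")

.CELL_COLUMNS <- c(
  "well", "field", "cell_id", "area_um2", "equiv_diameter_um",
  "perimeter_um", "circularity", "centroid_row", "centroid_col",
  "qc_pass", "n_dna", "n_rna", "dna_bin", "rna_bin",
  "expression_class", "selected"
)

.SPOT_COLUMNS <- c(
  "well", "field", "channel", "spot_id", "cell_id", "row", "col",
  "intensity", "radial", "min_dna_rna_dist_um", "activity_class"
)

#' Construct a single-field image with plate metadata
#'
#' A `FieldImage` bundles one single-plane grayscale image with the plate
#' coordinates it was acquired at (well, field, channel, imaging round) and
#' the physical pixel size. It is the unit every pipeline stage operates on.
#'
#' @param pixels Numeric matrix of non-negative intensities; rows index image
#'   rows (top to bottom), columns index image columns (left to right).
#' @param well Plate-well label, e.g. `"B02"`.
#' @param field Field-of-view index within the well (integer >= 1).
#' @param channel One of `"DAPI"`, `"DNA"`, `"RNA"`.
#' @param round Imaging round: `"single"` for simultaneous DNA/RNA
#'   hybridization, or `"rna_round"` / `"dna_round"` for sequential mode.
#' @param pixel_size_um Microns per pixel (> 0); 0.108 um for a 60x objective
#'   on a 2048 x 2048 sCMOS camera is the expected acquisition setting.
#' @return An object of class `FieldImage`.
#' @export
field_image <- function(pixels, well, field, channel, round = "single",
                        pixel_size_um = 0.108) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and non-negative")
  }
  channel <- match.arg(channel, .CHANNELS)
  round <- match.arg(round, .ROUNDS)
  field <- as.integer(field)
  if (is.na(field) || field < 1L) stop("'field' must be an integer >= 1")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("'pixel_size_um' must be a single positive number")
  }
  structure(
    list(pixels = pixels, well = as.character(well), field = field,
         channel = channel, round = round,
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "FieldImage"
  )
}

#' @export
print.FieldImage <- function(x, ...) {
  cat(sprintf("FieldImage %s/f%02d %s (%s): %d x %d px, %.3f um/px\n",
              x$well, x$field, x$channel, x$round,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Read and validate a plate manifest
#'
#' The manifest is a CSV with columns `well,field,channel,round,path` listing
#' one image file per (well, field, channel, round) combination. Paths are
#' resolved relative to the manifest's own directory unless absolute.
#'
#' @param path Path to the manifest CSV (header row required).
#' @param check_files If `TRUE` (default), verify every referenced image file
#'   exists.
#' @return A `data.frame` of class `PlateManifest` with character columns
#'   `well`, `channel`, `round`, `path` and integer `field`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well", "field", "channel", "round", "path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$well <- as.character(df$well)
  df$field <- as.integer(df$field)
  bad_channel <- setdiff(unique(df$channel), .CHANNELS)
  if (length(bad_channel) > 0) {
    stop("unknown channel token(s): ", paste(bad_channel, collapse = ", "),
         " (expected ", paste(.CHANNELS, collapse = "/"), ")")
  }
  bad_round <- setdiff(unique(df$round), .ROUNDS)
  if (length(bad_round) > 0) {
    stop("unknown round token(s): ", paste(bad_round, collapse = ", "))
  }
  key <- paste(df$well, df$field, df$channel, df$round, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate manifest entries for (well, field, channel, round): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  base_dir <- dirname(normalizePath(path, mustWork = TRUE))
  abs <- grepl("^(/|[A-Za-z]:)", df$path)
  df$path <- ifelse(abs, df$path, file.path(base_dir, df$path))
  if (check_files) {
    gone <- df$path[!file.exists(df$path)]
    if (length(gone) > 0) {
      stop("manifest references missing file(s): ",
           paste(gone, collapse = ", "))
    }
  }
  class(df) <- c("PlateManifest", "data.frame")
  df
}

#' Load one field image referenced by a manifest
#'
#' @param manifest A `PlateManifest` from [read_manifest()].
#' @param well,field,channel,round Plate coordinates of the image to load.
#' @param pixel_size_um Microns per pixel to attach to the image.
#' @return A [field_image()] with integer-valued intensities as stored.
#' @export
load_field <- function(manifest, well, field, channel, round = "single",
                       pixel_size_um = 0.108) {
  hit <- manifest$well == well & manifest$field == as.integer(field) &
    manifest$channel == channel & manifest$round == round
  if (!any(hit)) {
    stop(sprintf("manifest entry not found: well=%s field=%s channel=%s round=%s",
                 well, field, channel, round))
  }
  px <- read_grayscale_tiff(manifest$path[which(hit)[1]])
  field_image(px, well = well, field = field, channel = channel,
              round = round, pixel_size_um = pixel_size_um)
}

#' Read a single-plane grayscale TIFF as an integer-valued matrix
#'
#' Accepts 8- or 16-bit unsigned grayscale images. Multi-page stacks are
#' rejected: pipeline inputs are already maximum-projected (use
#' [max_project()] to collapse a stack first).
#'
#' @param path TIFF file path.
#' @return Numeric matrix of raw integer intensity values.
#' @export
read_grayscale_tiff <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(pages) != 1L) {
    stop(sprintf(
      "%s has %d pages; inputs must be single-plane (max_project() a stack first)",
      path, length(pages)))
  }
  px <- pages[[1]]
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1] else
      stop(path, " is not grayscale (", dim(px)[3], " samples per pixel)")
  }
  storage.mode(px) <- "double"
  px
}

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' Values are stored as unsigned 16-bit integers; inputs are rounded and
#' clipped to [0, 65535].
#'
#' @param pixels Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grayscale_tiff <- function(pixels, path) {
  v <- pmin(pmax(round(pixels), 0), 65535)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses an ordered list of same-shaped planes into one 2D image by
#' taking the per-pixel maximum, reproducing the real-time projection done
#' at acquisition.
#'
#' @param stack List of numeric matrices, all with identical dimensions.
#' @return A single matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) < 1L) {
    stop("'stack' must be a non-empty list of matrices")
  }
  d <- dim(stack[[1]])
  for (i in seq_along(stack)) {
    if (!is.matrix(stack[[i]]) || !identical(dim(stack[[i]]), d)) {
      stop("plane ", i, " has mismatched shape")
    }
  }
  out <- stack[[1]]
  for (i in seq_along(stack)[-1]) out <- pmax(out, stack[[i]])
  out
}

#' Validate a pair of cell/spot result tables
#'
#' @param cells Cell table (one row per segmented nucleus).
#' @param spots Spot table (one row per retained spot).
#' @return A list with elements `cells` and `spots`, columns coerced to the
#'   documented order; class `ResultsTables`.
#' @export
results_tables <- function(cells, spots) {
  miss_c <- setdiff(.CELL_COLUMNS, names(cells))
  if (length(miss_c)) stop("cell table missing column(s): ",
                           paste(miss_c, collapse = ", "))
  miss_s <- setdiff(.SPOT_COLUMNS, names(spots))
  if (length(miss_s)) stop("spot table missing column(s): ",
                           paste(miss_s, collapse = ", "))
  cells <- as.data.frame(cells)[.CELL_COLUMNS]
  spots <- as.data.frame(spots)[.SPOT_COLUMNS]
  if (nrow(spots) > 0) {
    ck <- paste(cells$well, cells$field, cells$cell_id, sep = "|")
    sk <- paste(spots$well, spots$field, spots$cell_id, sep = "|")
    orphans <- setdiff(sk, ck)
    if (length(orphans) > 0) {
      stop("spot rows reference missing cells: ",
           paste(utils::head(orphans, 5), collapse = "; "))
    }
  }
  structure(list(cells = cells, spots = spots), class = "ResultsTables")
}

#' Write result tables as flat text files, one file per well
#'
#' Cell- and spot-level results are written as `cells_<well>.csv` and
#' `spots_<well>.csv` with a fixed column order, so a whole-plate analysis
#' can be reassembled from the per-well flat files alone.
#'
#' @param tables A `ResultsTables` object (see [results_tables()]).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(inherits(tables, "ResultsTables"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  wells <- sort(unique(c(tables$cells$well, tables$spots$well)))
  paths <- character(0)
  for (w in wells) {
    cf <- file.path(out_dir, sprintf("cells_%s.csv", w))
    sf <- file.path(out_dir, sprintf("spots_%s.csv", w))
    utils::write.csv(tables$cells[tables$cells$well == w, , drop = FALSE],
                     cf, row.names = FALSE)
    utils::write.csv(tables$spots[tables$spots$well == w, , drop = FALSE],
                     sf, row.names = FALSE)
    paths <- c(paths, cf, sf)
  }
  paths
}

#' Read back per-well result tables written by [write_results()]
#'
#' @param dir Directory containing `cells_*.csv` / `spots_*.csv` files.
#' @return A `ResultsTables` object.
#' @export
read_results <- function(dir) {
  cfs <- sort(list.files(dir, pattern = "^cells_.*\\.csv$", full.names = TRUE))
  sfs <- sort(list.files(dir, pattern = "^spots_.*\\.csv$", full.names = TRUE))
  if (length(cfs) == 0) stop("no cell tables found in ", dir)
  rd <- function(f) utils::read.csv(f, stringsAsFactors = FALSE,
                                    colClasses = c(well = "character"))
  cells <- do.call(rbind, lapply(cfs, rd))
  spots <- do.call(rbind, lapply(sfs, rd))
  # all-NA columns read back as logical; restore documented types
  for (col in c("dna_bin", "rna_bin", "expression_class", "activity_class")) {
    if (col %in% names(cells)) cells[[col]] <- as.character(cells[[col]])
    if (col %in% names(spots)) spots[[col]] <- as.character(spots[[col]])
  }
  for (col in c("radial", "min_dna_rna_dist_um")) {
    if (col %in% names(spots)) spots[[col]] <- as.numeric(spots[[col]])
  }
  results_tables(cells, spots)
}
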