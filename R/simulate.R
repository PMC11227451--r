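# Synthetic HiFISH plate simulator. Renders three-channel fields (DAPI
# nuclei, DNA FISH spots, RNA transcription-site spots) with known ground
# truth, in either simultaneous-hybridization mode (one imaging round) or
# sequential mode (two rounds related by an unknown integer translation).
# The generator is the source of truth for every downstream validation.

#' Simulation configuration
#'
#' Defaults emulate a typical high-content acquisition: 0.108 um pixels,
#' nuclei of 11-15 um diameter, two DNA FISH spots per nucleus, and
#' per-cell expression classes drawn with silent/monoallelic/biallelic
#' fractions 0.66/0.26/0.064 (the kind of skewed distribution seen for a
#' lowly expressed gene). Active transcription sites are placed within
#' `active_rna_offset_um` (default 0-0.8 um) of their DNA spot, safely
#' under the 1.0 um activity-calling radius.
#'
#' @param n_fields Fields per well.
#' @param nuclei_per_field Nuclei placed per field.
#' @param image_size_px Field edge length in pixels (square fields).
#' @param pixel_size_um Microns per pixel.
#' @param nucleus_radius_um Range of nucleus semi-minor axis (um).
#' @param nucleus_eccentricity Range of axis ratio (major/minor, >= 1).
#' @param spot_sigma_px Gaussian sigma of rendered FISH spots (px).
#' @param spot_peak_intensity Peak spot amplitude above local background.
#' @param dapi_intensity DAPI amplitude inside nuclei.
#' @param texture_intensity Amplitude of the low-pass intranuclear DAPI
#'   texture (gives registration distinctive high-intensity features).
#' @param background_level Constant camera background offset.
#' @param photon_scaling Photons per intensity unit for shot noise
#'   (smaller = noisier); `Inf` disables photon noise.
#' @param read_noise_sd Gaussian read noise sd (intensity units); 0 disables.
#' @param expression_fractions Length-3 vector (silent, monoallelic,
#'   biallelic); renormalized to sum to 1.
#' @param active_rna_offset_um Range of DNA-to-RNA spot distances for active
#'   alleles (um).
#' @param false_positive_spot_rate Expected spurious RNA spots per nucleus
#'   (Poisson), emulating false-positive FISH signals.
#' @param inter_round_shift_px Integer `c(d_row, d_col)` applied to the
#'   RNA-round images in sequential mode, or `"random"` to draw one within
#'   `shift_bound_px`.
#' @param shift_bound_px Bound for random inter-round shifts.
#' @param noise If `FALSE`, render noiseless images (for geometric tests).
#' @param seed Integer RNG seed; recorded in all outputs.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_fields = 20L,
                              nuclei_per_field = 25L,
                              image_size_px = 1024L,
                              pixel_size_um = 0.108,
                              nucleus_radius_um = c(5.5, 7.5),
                              nucleus_eccentricity = c(1.0, 1.3),
                              spot_sigma_px = 1.5,
                              spot_peak_intensity = 1500,
                              dapi_intensity = 1200,
                              texture_intensity = 350,
                              background_level = 400,
                              photon_scaling = 1.0,
                              read_noise_sd = 10,
                              expression_fractions = c(0.66, 0.26, 0.064),
                              active_rna_offset_um = c(0, 0.8),
                              false_positive_spot_rate = 0.03,
                              inter_round_shift_px = "random",
                              shift_bound_px = 20L,
                              noise = TRUE,
                              seed = 1L) {
  stopifnot(length(expression_fractions) == 3, all(expression_fractions >= 0),
            sum(expression_fractions) > 0)
  stopifnot(all(nucleus_radius_um > 0), all(nucleus_eccentricity >= 1),
            spot_sigma_px > 0, pixel_size_um > 0, image_size_px >= 64)
  cfg <- list(
    n_fields = as.integer(n_fields),
    nuclei_per_field = as.integer(nuclei_per_field),
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    nucleus_radius_um = nucleus_radius_um,
    nucleus_eccentricity = nucleus_eccentricity,
    spot_sigma_px = spot_sigma_px,
    spot_peak_intensity = spot_peak_intensity,
    dapi_intensity = dapi_intensity,
    texture_intensity = texture_intensity,
    background_level = background_level,
    photon_scaling = photon_scaling,
    read_noise_sd = read_noise_sd,
    expression_fractions = expression_fractions / sum(expression_fractions),
    active_rna_offset_um = active_rna_offset_um,
    false_positive_spot_rate = false_positive_spot_rate,
    inter_round_shift_px = inter_round_shift_px,
    shift_bound_px = as.integer(shift_bound_px),
    noise = isTRUE(noise),
    seed = as.integer(seed)
  )
  class(cfg) <- "SimulationConfig"
  cfg
}

# deterministic per-field seed below 2^31, derived from config seed + coords
.field_seed <- function(seed, well, field) {
  h <- sum(utf8ToInt(well) * seq_along(utf8ToInt(well)))
  as.integer((as.numeric(seed) * 100003 + h * 10007 + field * 101) %% 2147483629)
}

.add_gaussian_spot <- function(scene, row0, col0, sigma, amp) {
  n <- nrow(scene)
  h <- ceiling(4 * sigma)
  r <- round(row0) + 1; c <- round(col0) + 1
  rr <- max(1, r - h):min(n, r + h)
  cc <- max(1, c - h):min(ncol(scene), c + h)
  dr <- (rr - 1) - row0
  dc <- (cc - 1) - col0
  g <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  scene[rr, cc] <- scene[rr, cc] + amp * g
  scene
}

.apply_camera_noise <- function(scene, cfg) {
  v <- scene
  if (cfg$noise && is.finite(cfg$photon_scaling) && cfg$photon_scaling > 0) {
    v <- stats::rpois(length(v), lambda = v * cfg$photon_scaling) /
      cfg$photon_scaling
  }
  if (cfg$noise && cfg$read_noise_sd > 0) {
    v <- v + stats::rnorm(length(v), sd = cfg$read_noise_sd)
  }
  matrix(pmax(round(v), 0), nrow(scene), ncol(scene))
}

# uniform draw over the ellipse interior scaled by `scale` (area-uniform)
.sample_in_ellipse <- function(center, a, b, theta, scale = 0.8) {
  u <- sqrt(stats::runif(1)) * scale
  phi <- stats::runif(1, 0, 2 * pi)
  ex <- u * a * cos(phi); ey <- u * b * sin(phi)
  c(center[1] + ex * cos(theta) - ey * sin(theta),
    center[2] + ex * sin(theta) + ey * cos(theta))
}

#' Simulate one imaging field with ground truth
#'
#' Renders the DAPI, DNA and RNA channels of one field. In `"simultaneous"`
#' mode all three channels come from a single imaging round; in
#' `"sequential"` mode the field is imaged twice (DAPI + DNA in the DNA
#' round; DAPI + RNA in the RNA round) and the RNA-round images are the same
#' scene translated by the truth shift with zero-filled boundaries and
#' independently re-noised.
#'
#' @param config A [simulation_config()].
#' @param well,field Plate coordinates stamped on the images.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   only (`images` and `scenes` are `NULL`); useful for statistical
#'   experiments that need many replicate geometries.
#' @return List with `images` (named list of `FieldImage`s, names like
#'   `"DAPI.single"` or `"RNA.rna_round"`), `scenes` (noiseless unshifted
#'   channel matrices), and `truth` (list of `nuclei`, `spots`, `shift`
#'   data.frames; positions 0-based in the DNA-round frame).
#' @export
simulate_field <- function(config, well = "A01", field = 1L,
                           mode = c("simultaneous", "sequential"),
                           render = TRUE) {
  mode <- match.arg(mode)
  cfg <- config
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(.field_seed(cfg$seed, well, field))

  n <- cfg$image_size_px
  psz <- cfg$pixel_size_um
  # --- place non-overlapping elliptical nuclei -------------------------
  nuc <- data.frame(nucleus_id = integer(0), center_row = numeric(0),
                    center_col = numeric(0), a_px = numeric(0),
                    b_px = numeric(0), theta = numeric(0),
                    expression_class = character(0))
  max_try <- 300L * cfg$nuclei_per_field
  tries <- 0L
  classes <- c("silent", "monoallelic", "biallelic")
  while (nrow(nuc) < cfg$nuclei_per_field) {
    tries <- tries + 1L
    if (tries > max_try) {
      stop("could not place ", cfg$nuclei_per_field, " non-overlapping nuclei;",
           " reduce nuclei_per_field or enlarge image_size_px")
    }
    b <- stats::runif(1, cfg$nucleus_radius_um[1], cfg$nucleus_radius_um[2]) / psz
    ecc <- stats::runif(1, cfg$nucleus_eccentricity[1], cfg$nucleus_eccentricity[2])
    a <- b * ecc
    margin <- a + 2
    ctr <- c(stats::runif(1, margin, n - 1 - margin),
             stats::runif(1, margin, n - 1 - margin))
    if (nrow(nuc) > 0) {
      d <- sqrt((nuc$center_row - ctr[1])^2 + (nuc$center_col - ctr[2])^2)
      if (any(d < (nuc$a_px + a + 4))) next  # bounding-circle overlap
    }
    cls <- sample(classes, 1, prob = cfg$expression_fractions)
    nuc <- rbind(nuc, data.frame(
      nucleus_id = nrow(nuc) + 1L, center_row = ctr[1], center_col = ctr[2],
      a_px = a, b_px = b, theta = stats::runif(1, 0, pi),
      expression_class = cls))
  }

  # --- DAPI scene: smooth ellipse profile + low-pass texture -----------
  dapi <- dna <- rna <- NULL
  if (render) {
  dapi <- matrix(cfg$background_level, n, n)
  texture <- as.matrix(EBImage::imageData(EBImage::gblur(
    EBImage::Image(matrix(stats::rnorm(n * n), n, n)), sigma = 3))) * 12
  for (i in seq_len(nrow(nuc))) {
    a <- nuc$a_px[i]; b <- nuc$b_px[i]; th <- nuc$theta[i]
    r0 <- nuc$center_row[i]; c0 <- nuc$center_col[i]
    rr <- max(1, floor(r0 - a)):min(n, ceiling(r0 + a) + 1)
    cc <- max(1, floor(c0 - a)):min(n, ceiling(c0 + a) + 1)
    dr <- (rr - 1) - r0
    dc <- (cc - 1) - c0
    xr <- outer(dr, dc * 0, "+") ; xc <- outer(dr * 0, dc, "+")
    u <- xr * cos(th) + xc * sin(th)
    v <- -xr * sin(th) + xc * cos(th)
    q <- (u / a)^2 + (v / b)^2
    inside <- q <= 1
    block <- dapi[rr, cc]
    prof <- cfg$dapi_intensity * (1 - 0.3 * q) +
      cfg$texture_intensity * texture[rr, cc]
    block[inside] <- block[inside] + pmax(prof[inside], 0)
    dapi[rr, cc] <- block
  }
  dna <- matrix(cfg$background_level, n, n)
  rna <- matrix(cfg$background_level, n, n)
  }

  # --- DNA and RNA spots ----------------------------------------------
  spots <- NULL
  offset_px <- cfg$active_rna_offset_um / psz
  for (i in seq_len(nrow(nuc))) {
    ctr <- c(nuc$center_row[i], nuc$center_col[i])
    active_alleles <- switch(nuc$expression_class[i],
                             silent = integer(0),
                             monoallelic = sample(1:2, 1),
                             biallelic = 1:2)
    for (al in 1:2) {
      p <- .sample_in_ellipse(ctr, nuc$a_px[i], nuc$b_px[i], nuc$theta[i])
      if (render) dna <- .add_gaussian_spot(dna, p[1], p[2], cfg$spot_sigma_px,
                                            cfg$spot_peak_intensity)
      is_active <- al %in% active_alleles
      spots <- rbind(spots, data.frame(
        channel = "DNA", nucleus_id = nuc$nucleus_id[i], allele = al,
        row = p[1], col = p[2], active = is_active, false_positive = FALSE))
      if (is_active) {
        dist_px <- stats::runif(1, offset_px[1], offset_px[2])
        ang <- stats::runif(1, 0, 2 * pi)
        rp <- c(p[1] + dist_px * cos(ang), p[2] + dist_px * sin(ang))
        rp <- pmin(pmax(rp, 0), n - 1)
        if (render) rna <- .add_gaussian_spot(rna, rp[1], rp[2],
                                              cfg$spot_sigma_px,
                                              cfg$spot_peak_intensity)
        spots <- rbind(spots, data.frame(
          channel = "RNA", nucleus_id = nuc$nucleus_id[i], allele = al,
          row = rp[1], col = rp[2], active = TRUE, false_positive = FALSE))
      }
    }
    n_fp <- stats::rpois(1, cfg$false_positive_spot_rate)
    for (k in seq_len(n_fp)) {
      p <- .sample_in_ellipse(ctr, nuc$a_px[i], nuc$b_px[i], nuc$theta[i],
                              scale = 0.95)
      if (render) rna <- .add_gaussian_spot(rna, p[1], p[2], cfg$spot_sigma_px,
                                            cfg$spot_peak_intensity)
      spots <- rbind(spots, data.frame(
        channel = "RNA", nucleus_id = nuc$nucleus_id[i], allele = NA_integer_,
        row = p[1], col = p[2], active = FALSE, false_positive = TRUE))
    }
  }
  if (is.null(spots)) {
    spots <- data.frame(channel = character(0), nucleus_id = integer(0),
                        allele = integer(0), row = numeric(0),
                        col = numeric(0), active = logical(0),
                        false_positive = logical(0))
  }
  spots$spot_id <- seq_len(nrow(spots))
  spots <- spots[c("channel", "spot_id", "nucleus_id", "allele", "row",
                   "col", "active", "false_positive")]

  # --- inter-round shift ----------------------------------------------
  if (mode == "sequential") {
    if (identical(cfg$inter_round_shift_px, "random")) {
      shift <- c(sample(-cfg$shift_bound_px:cfg$shift_bound_px, 1),
                 sample(-cfg$shift_bound_px:cfg$shift_bound_px, 1))
    } else {
      shift <- as.integer(cfg$inter_round_shift_px)
    }
  } else {
    shift <- c(0L, 0L)
  }

  nuc_out <- cbind(well = well, field = as.integer(field), nuc)
  spots_out <- cbind(well = well, field = as.integer(field), spots)
  shift_out <- data.frame(well = well, field = as.integer(field),
                          d_row = shift[1], d_col = shift[2])
  truth <- list(nuclei = nuc_out, spots = spots_out, shift = shift_out)
  if (!render) {
    return(list(images = NULL, scenes = NULL, truth = truth))
  }
  mk <- function(px, channel, round) {
    field_image(px, well = well, field = field, channel = channel,
                round = round, pixel_size_um = psz)
  }
  scenes <- list(DAPI = dapi, DNA = dna, RNA = rna)
  if (mode == "simultaneous") {
    images <- list(
      DAPI.single = mk(.apply_camera_noise(dapi, cfg), "DAPI", "single"),
      DNA.single = mk(.apply_camera_noise(dna, cfg), "DNA", "single"),
      RNA.single = mk(.apply_camera_noise(rna, cfg), "RNA", "single"))
  } else {
    dapi_shift <- apply_translation(dapi, shift)
    rna_shift <- apply_translation(rna, shift)
    images <- list(
      DAPI.dna_round = mk(.apply_camera_noise(dapi, cfg), "DAPI", "dna_round"),
      DNA.dna_round = mk(.apply_camera_noise(dna, cfg), "DNA", "dna_round"),
      DAPI.rna_round = mk(.apply_camera_noise(dapi_shift, cfg), "DAPI", "rna_round"),
      RNA.rna_round = mk(.apply_camera_noise(rna_shift, cfg), "RNA", "rna_round"))
  }
  list(images = images, scenes = scenes, truth = truth)
}

#' Simulate a whole plate to disk
#'
#' Writes per-field 16-bit TIFFs, a manifest CSV loadable by
#' [read_manifest()], truth tables (`nuclei_truth.csv`, `spots_truth.csv`,
#' `shifts_truth.csv`) and the realized configuration (`sim_config.yaml`,
#' seed included) into `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param wells Character vector of well labels.
#' @param out_dir Output directory.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @return List with `manifest` (a `PlateManifest`), `manifest_path`, and
#'   `truth` (combined truth tables).
#' @export
simulate_plate <- function(config, wells = "A01", out_dir,
                           mode = c("simultaneous", "sequential")) {
  mode <- match.arg(mode)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- NULL; nuclei <- NULL; spots <- NULL; shifts <- NULL
  for (w in wells) {
    for (f in seq_len(config$n_fields)) {
      sim <- simulate_field(config, well = w, field = f, mode = mode)
      for (im in sim$images) {
        fname <- sprintf("%s_f%02d_%s_%s.tif", w, f, im$channel, im$round)
        write_grayscale_tiff(im$pixels, file.path(out_dir, fname))
        rows <- rbind(rows, data.frame(well = w, field = f,
                                       channel = im$channel,
                                       round = im$round, path = fname))
      }
      nuclei <- rbind(nuclei, sim$truth$nuclei)
      spots <- rbind(spots, sim$truth$spots)
      shifts <- rbind(shifts, sim$truth$shift)
    }
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(rows, manifest_path, row.names = FALSE)
  utils::write.csv(nuclei, file.path(out_dir, "nuclei_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(spots, file.path(out_dir, "spots_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(shifts, file.path(out_dir, "shifts_truth.csv"),
                   row.names = FALSE)
  cfg_out <- config
  class(cfg_out) <- NULL
  cfg_out$mode <- mode
  yaml::write_yaml(cfg_out, file.path(out_dir, "sim_config.yaml"))
  list(manifest = read_manifest(manifest_path),
       manifest_path = manifest_path,
       truth = list(nuclei = nuclei, spots = spots, shifts = shifts))
}

#' Rasterize ground-truth nuclei into a label mask
#'
#' Builds the ideal label mask implied by a field's truth table (each
#' nucleus its exact ellipse), e.g. to evaluate a segmenter against truth
#' or to read off radial positions of true spot coordinates without any
#' detection step.
#'
#' @param nuclei_truth Truth nucleus table from [simulate_field()] (one
#'   field's rows).
#' @param image_size_px Field edge length in pixels.
#' @return Integer label matrix; labels follow `nucleus_id`.
#' @export
truth_label_mask <- function(nuclei_truth, image_size_px) {
  n <- as.integer(image_size_px)
  mask <- matrix(0L, n, n)
  for (i in seq_len(nrow(nuclei_truth))) {
    a <- nuclei_truth$a_px[i]; b <- nuclei_truth$b_px[i]
    th <- nuclei_truth$theta[i]
    r0 <- nuclei_truth$center_row[i]; c0 <- nuclei_truth$center_col[i]
    rr <- max(1, floor(r0 - a)):min(n, ceiling(r0 + a) + 1)
    cc <- max(1, floor(c0 - a)):min(n, ceiling(c0 + a) + 1)
    dr <- (rr - 1) - r0
    dc <- (cc - 1) - c0
    u <- outer(dr, dc * 0, "+") * cos(th) + outer(dr * 0, dc, "+") * sin(th)
    v <- -outer(dr, dc * 0, "+") * sin(th) + outer(dr * 0, dc, "+") * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    block <- mask[rr, cc]
    block[inside] <- as.integer(nuclei_truth$nucleus_id[i])
    mask[rr, cc] <- block
  }
  mask
}
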