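# Shared fixtures. Expensive simulated plates are built once per test run
# and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# rasterized disc label mask (single label 1)
make_disc_mask <- function(radius, pad = 10) {
  n <- 2 * radius + 2 * pad + 1
  ctr <- radius + pad + 1
  outer(seq_len(n), seq_len(n), function(r, c) {
    as.integer((r - ctr)^2 + (c - ctr)^2 <= radius^2)
  })
}

# noiseless image with Gaussian spots at given 0-based positions
make_spot_image <- function(n, positions, sigma = 1.5, peak = 1000,
                            background = 100) {
  img <- matrix(background, n, n)
  for (i in seq_len(nrow(positions))) {
    r0 <- positions[i, 1]; c0 <- positions[i, 2]
    rr <- max(1, round(r0) - 8):min(n, round(r0) + 10)
    cc <- max(1, round(c0) - 8):min(n, round(c0) + 10)
    g <- exp(-(outer(((rr - 1) - r0)^2, ((cc - 1) - c0)^2, "+")) /
               (2 * sigma^2))
    img[rr, cc] <- img[rr, cc] + peak * g
  }
  img
}

# greedy 1-px matching of detections to truth; returns recall/precision/rmse
match_spots <- function(det, truth, match_px = 1) {
  if (nrow(truth) == 0) {
    return(list(recall = NA, precision = NA, rmse = NA, tp = 0))
  }
  tp <- 0L; err2 <- numeric(0)
  used <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(truth))) {
    if (nrow(det) == 0) break
    d2 <- (det$row - truth$row[i])^2 + (det$col - truth$col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] < match_px^2) {
      tp <- tp + 1L
      err2 <- c(err2, d2[j])
      used[j] <- TRUE
    }
  }
  list(recall = tp / nrow(truth),
       precision = if (nrow(det) > 0) tp / nrow(det) else NA,
       rmse = if (tp > 0) sqrt(mean(err2)) else NA,
       tp = tp)
}

# brute-force two-sample sup-ECDF distance (independent KS oracle)
ks_stat_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# default-scale simulated plate (hundreds of nuclei) + full pipeline run
default_plate <- function() {
  fixture("default_plate", function() {
    cfg <- simulation_config(n_fields = 28L, seed = 101L)
    dir <- file.path(tempdir(), "hifishr-default-plate")
    sim <- simulate_plate(cfg, wells = "A01", out_dir = dir,
                          mode = "simultaneous")
    res <- run_pipeline(sim$manifest)
    list(cfg = cfg, sim = sim, res = res, dir = dir)
  })
}

# small 2-field plate for cheap pipeline tests
small_plate <- function() {
  fixture("small_plate", function() {
    cfg <- simulation_config(n_fields = 2L, nuclei_per_field = 20L,
                             image_size_px = 1024L, seed = 7L)
    dir <- file.path(tempdir(), "hifishr-small-plate")
    sim <- simulate_plate(cfg, wells = "A01", out_dir = dir,
                          mode = "simultaneous")
    res <- run_pipeline(sim$manifest)
    list(cfg = cfg, sim = sim, res = res, dir = dir)
  })
}

# the 12-cell filter-accounting construction: counts are hand-computed in
# the tests that use it
toy_cell_table <- function() {
  # diameter/circularity pairs chosen to pass or fail each QC rule
  morph <- data.frame(
    cell_id = 1:12,
    equiv_diameter_um = c(12, 12, 12, 12, 12, 12, 12, 8, 12, 12, 12, 8),
    circularity = c(0.97, 0.97, 0.97, 0.97, 0.97, 0.97,
                    0.97, 0.99, 0.90, 0.97, 0.97, 0.90)
  )
  counts <- data.frame(
    cell_id = 1:12,
    n_dna = c(2L, 2L, 2L, 2L, 1L, 3L, 0L, 2L, 2L, 4L, 2L, 2L),
    n_rna = c(0L, 1L, 2L, 3L, 1L, 1L, 0L, 1L, 2L, 4L, 2L, 0L)
  )
  spots <- do.call(rbind, lapply(1:12, function(id) {
    rbind(
      if (counts$n_dna[id] > 0)
        data.frame(channel = "DNA", cell_id = id,
                   spot_id = seq_len(counts$n_dna[id])),
      if (counts$n_rna[id] > 0)
        data.frame(channel = "RNA", cell_id = id,
                   spot_id = seq_len(counts$n_rna[id]))
    )
  }))
  list(morph = morph, counts = counts, spots = spots)
}
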