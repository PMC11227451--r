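test_that("simulation is deterministic for a fixed seed", {
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 6,
                           image_size_px = 256,
                           nucleus_radius_um = c(1.5, 2.2), seed = 9)
  a <- simulate_field(cfg, "A01", 1)
  b <- simulate_field(cfg, "A01", 1)
  expect_identical(a$images$DAPI.single$pixels, b$images$DAPI.single$pixels)
  expect_identical(a$truth, b$truth)
  # different fields give different scenes
  c2 <- simulate_field(cfg, "A01", 2)
  expect_false(identical(a$truth$nuclei$center_row,
                         c2$truth$nuclei$center_row))
})

test_that("expression fractions drive RNA truth spot counts", {
  base <- list(n_fields = 1, nuclei_per_field = 15, image_size_px = 512,
               nucleus_radius_um = c(2, 2.8), false_positive_spot_rate = 0,
               seed = 13)
  all_silent <- do.call(simulation_config,
                        c(base, list(expression_fractions = c(1, 0, 0))))
  s <- simulate_field(all_silent, "A01", 1, render = FALSE)
  expect_identical(sum(s$truth$spots$channel == "RNA"), 0L)

  all_bi <- do.call(simulation_config,
                    c(base, list(expression_fractions = c(0, 0, 1))))
  b <- simulate_field(all_bi, "A01", 1, render = FALSE)
  tr <- b$truth$spots
  rna <- tr[tr$channel == "RNA", ]
  expect_identical(nrow(rna), 2L * 15L)
  # each RNA spot within 0.8 um of its own DNA spot
  dna <- tr[tr$channel == "DNA", ]
  for (i in seq_len(nrow(rna))) {
    mate <- dna[dna$nucleus_id == rna$nucleus_id[i] &
                  dna$allele == rna$allele[i], ]
    d_um <- sqrt((mate$row - rna$row[i])^2 + (mate$col - rna$col[i])^2) *
      all_bi$pixel_size_um
    expect_lte(d_um, 0.8)
  }
  # DNA spots: exactly two per nucleus, strictly inside the ellipse
  expect_identical(as.vector(table(dna$nucleus_id)), rep(2L, 15L))
  nuc <- b$truth$nuclei
  for (i in seq_len(nrow(dna))) {
    nu <- nuc[nuc$nucleus_id == dna$nucleus_id[i], ]
    dr <- dna$row[i] - nu$center_row; dc <- dna$col[i] - nu$center_col
    u <- dr * cos(nu$theta) + dc * sin(nu$theta)
    v <- -dr * sin(nu$theta) + dc * cos(nu$theta)
    expect_lt((u / nu$a_px)^2 + (v / nu$b_px)^2, 1)
  }
})

test_that("allele counts per class are conserved in the truth tables", {
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 200,
                           image_size_px = 2048, false_positive_spot_rate = 0,
                           nucleus_radius_um = c(3, 4),
                           expression_fractions = c(0.4, 0.4, 0.2), seed = 29)
  sim <- simulate_field(cfg, "A01", 1, render = FALSE)
  nuc <- sim$truth$nuclei
  rna <- sim$truth$spots[sim$truth$spots$channel == "RNA", ]
  per_nuc <- table(factor(rna$nucleus_id, levels = nuc$nucleus_id))
  expected <- c(silent = 0L, monoallelic = 1L, biallelic = 2L)
  expect_identical(as.integer(per_nuc),
                   unname(expected[nuc$expression_class]))
})

test_that("realized class proportions follow the configured fractions", {
  fr <- c(0.66, 0.26, 0.064)
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 250,
                           image_size_px = 2048, nucleus_radius_um = c(3, 4),
                           expression_fractions = fr, seed = 7)
  cls <- NULL
  for (f in 1:2) {
    cls <- c(cls, simulate_field(cfg, "A01", f, render = FALSE)$truth$
               nuclei$expression_class)
  }
  p <- fr / sum(fr)
  n <- length(cls)
  realized <- table(factor(cls, levels = c("silent", "monoallelic",
                                           "biallelic"))) / n
  for (k in 1:3) {
    se <- sqrt(p[k] * (1 - p[k]) / n)
    expect_lt(abs(realized[[k]] - p[k]), 3 * se)
  }
})

test_that("noiseless rendered spots sit at their truth positions", {
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 8,
                           image_size_px = 512, noise = FALSE, seed = 37)
  sim <- simulate_field(cfg, "A01", 1)
  scene <- sim$scenes$DNA - cfg$background_level
  tr <- sim$truth$spots[sim$truth$spots$channel == "DNA", ]
  for (i in seq_len(nrow(tr))) {
    r <- round(tr$row[i]) + 1; c <- round(tr$col[i]) + 1
    win_r <- (r - 4):(r + 4); win_c <- (c - 4):(c + 4)
    w <- scene[win_r, win_c]
    cen_r <- sum(outer(win_r - 1, rep(1, 9)) * w) / sum(w)
    cen_c <- sum(outer(rep(1, 9), win_c - 1) * w) / sum(w)
    expect_lt(sqrt((cen_r - tr$row[i])^2 + (cen_c - tr$col[i])^2), 0.25)
  }
})

test_that("simulated plates are written as loadable manifests with truth", {
  cfg <- simulation_config(n_fields = 2, nuclei_per_field = 4,
                           image_size_px = 256,
                           nucleus_radius_um = c(1.5, 2.2), seed = 21)
  dir <- withr::local_tempdir()
  sim <- simulate_plate(cfg, wells = c("A01", "B07"), out_dir = dir,
                        mode = "simultaneous")
  # 2 wells x 2 fields x 3 channels
  expect_identical(nrow(sim$manifest), 12L)
  expect_true(file.exists(file.path(dir, "nuclei_truth.csv")))
  m <- read_manifest(sim$manifest_path)
  fi <- load_field(m, "B07", 2, "RNA", "single")
  expect_identical(dim(fi$pixels), c(256L, 256L))

  # sequential mode: DAPI in both rounds, DNA in dna_round, RNA in rna_round
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_plate(cfg, wells = "A01", out_dir = dir2,
                         mode = "sequential")
  m2 <- sim2$manifest
  expect_identical(nrow(m2), 2L * 4L)
  expect_setequal(
    unique(paste(m2$channel, m2$round)),
    c("DAPI dna_round", "DNA dna_round", "DAPI rna_round", "RNA rna_round"))
  expect_identical(nrow(sim2$truth$shifts), 2L)
  expect_true(all(abs(sim2$truth$shifts$d_row) <= cfg$shift_bound_px))
})

test_that("overcrowded fields fail with an actionable error", {
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 60,
                           image_size_px = 256, seed = 3)
  expect_error(simulate_field(cfg, "A01", 1, render = FALSE),
               "reduce nuclei_per_field")
})
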