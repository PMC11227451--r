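test_that("per-cell summaries bin counts and apply the selection rule", {
  toy <- toy_cell_table()
  nuclei <- qc_filter(toy$morph)
  cells <- summarize_cells(toy$spots, nuclei)

  # representative cells: 2 DNA / 0 RNA is a selected silent cell;
  # 3 RNA spots put a cell in the ">=3" bin and out of selection
  c1 <- cells[cells$cell_id == 1, ]
  expect_identical(c(c1$dna_bin, c1$rna_bin, c1$expression_class),
                   c("2", "0", "silent"))
  expect_true(c1$selected)
  c4 <- cells[cells$cell_id == 4, ]
  expect_identical(c(c4$rna_bin, c4$expression_class), c(">=3", "multi"))
  expect_false(c4$selected)
  c10 <- cells[cells$cell_id == 10, ]
  expect_identical(c10$dna_bin, ">=3")
  expect_false(c10$selected)
  # QC failures are never selected even with perfect counts
  expect_false(any(cells$selected[!cells$qc_pass]))
  expect_identical(cells$n_dna, toy$counts$n_dna)
  expect_identical(cells$n_rna, toy$counts$n_rna)
})

test_that("filter accounting on the 12-cell construction matches hand counts", {
  toy <- toy_cell_table()
  cells <- summarize_cells(toy$spots, qc_filter(toy$morph))
  expect_identical(nrow(cells), 12L)
  expect_identical(sum(cells$qc_pass), 9L)            # cells 8, 9, 12 fail QC
  expect_identical(which(cells$selected), c(1L, 2L, 3L, 11L))
  qc <- cells[cells$qc_pass, ]
  expect_identical(as.vector(table(factor(qc$dna_bin,
                                          levels = c("0", "1", "2", ">=3")))),
                   c(1L, 1L, 5L, 2L))
  expect_identical(as.vector(table(factor(qc$rna_bin,
                                          levels = c("0", "1", "2", ">=3")))),
                   c(2L, 3L, 2L, 2L))
  expect_identical(as.vector(table(factor(qc$expression_class,
                                          levels = c("silent", "monoallelic",
                                                     "biallelic", "multi")))),
                   c(2L, 3L, 2L, 2L))
})

test_that("minimum DNA-RNA distances follow the per-DNA-spot rule", {
  # 3-4-5 triangle: 5 px at 0.108 um/px = 0.54 um
  dna <- data.frame(row = 10, col = 10)
  rna <- data.frame(row = 13, col = 14)
  expect_equal(min_dna_rna_distance(dna, rna, 0.108), 0.54)
  # minimum over the cell's RNA spots
  rna2 <- data.frame(row = c(13, 10), col = c(14, 11))
  expect_equal(min_dna_rna_distance(dna, rna2, 0.108), 0.108)
  # no RNA spots: missing
  expect_identical(min_dna_rna_distance(dna, rna[0, , drop = FALSE], 0.108),
                   NA_real_)
  # vectorized over DNA spots
  dna2 <- data.frame(row = c(10, 13), col = c(10, 14))
  expect_equal(min_dna_rna_distance(dna2, rna, 0.108), c(0.54, 0))
})

test_that("activity classes follow the 1.0-micron rule with strict boundary", {
  expect_identical(classify_allele(0.54), "active")
  expect_identical(classify_allele(NA_real_), "no_transcription")
  expect_identical(classify_allele(1.0), "inactive")      # boundary is strict
  expect_identical(classify_allele(0.999999), "active")
  expect_identical(classify_allele(c(0.2, NA, 3)),
                   c("active", "no_transcription", "inactive"))
  expect_error(classify_allele(-0.1), "non-negative")
  # raising the threshold never decreases active calls
  d <- c(0.1, 0.5, 0.9, 1.1, 1.9, NA, 2.5)
  n_active <- vapply(c(0.5, 1.0, 1.5, 2.0),
                     function(t) sum(classify_allele(d, t) == "active"),
                     numeric(1))
  expect_true(all(diff(n_active) >= 0))
})

test_that("KS comparison matches the brute-force ECDF oracle", {
  same <- c(0.1, 0.4, 0.7)
  r <- compare_radial(same, same)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
  disjoint <- compare_radial(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(disjoint$D, 1)
  set.seed(19)
  x <- runif(50); y <- rbeta(50, 2, 1)
  r2 <- compare_radial(x, y)
  expect_equal(r2$D, ks_stat_oracle(x, y))
  expect_equal(r2$n_active, 50)
  expect_error(compare_radial(numeric(0), y), "active")
  expect_error(compare_radial(x, numeric(0)), "inactive")
})

test_that("allele calls partition the DNA spots of selected cells", {
  plate <- small_plate()
  spots <- plate$res$tables$spots
  cells <- plate$res$tables$cells
  sel <- cells[cells$selected, ]
  dna <- spots[spots$channel == "DNA", ]
  called <- dna[!is.na(dna$activity_class), ]
  # every DNA spot of a selected cell gets exactly one class
  key <- paste(called$field, called$cell_id)
  sel_key <- paste(sel$field, sel$cell_id)
  expect_setequal(unique(key), sel_key)
  expect_identical(nrow(called), 2L * nrow(sel))
  expect_true(all(called$activity_class %in%
                    c("active", "inactive", "no_transcription")))
  # no_transcription iff the distance is missing
  expect_identical(is.na(called$min_dna_rna_dist_um),
                   called$activity_class == "no_transcription")
})

test_that("activity calls are perfect on noiseless fields", {
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 20,
                           image_size_px = 1024, seed = 83, noise = FALSE,
                           false_positive_spot_rate = 0)
  dir <- withr::local_tempdir()
  sim <- simulate_plate(cfg, "A01", dir, mode = "simultaneous")
  res <- run_pipeline(sim$manifest)
  spots <- res$tables$spots
  truth <- sim$truth$spots
  dna <- spots[spots$channel == "DNA" & !is.na(spots$activity_class), ]
  tr_dna <- truth[truth$channel == "DNA", ]
  expect_gt(nrow(dna), 20)
  n_checked <- 0L
  for (i in seq_len(nrow(dna))) {
    d2 <- (tr_dna$row - dna$row[i])^2 + (tr_dna$col - dna$col[i])^2
    j <- which.min(d2)
    expect_lt(d2[j], 1)
    # oracle: classify the true geometry directly
    cell_rna <- truth[truth$channel == "RNA" &
                        truth$nucleus_id == tr_dna$nucleus_id[j], ]
    true_dist <- min_dna_rna_distance(tr_dna[j, ], cell_rna, 0.108)
    expect_identical(dna$activity_class[i], classify_allele(true_dist))
    # every generatively active allele must be called active (offsets are
    # well inside the 1.0 um radius)
    if (tr_dna$active[j]) {
      expect_identical(dna$activity_class[i], "active")
    }
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, nrow(dna))
})
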