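test_that("correlation peaks where the images align", {
  set.seed(5)
  A <- matrix(runif(40 * 40), 40, 40)
  p <- find_peak(cross_correlate(A, A, max_shift = 6))
  expect_identical(c(p$d_row, p$d_col), c(0L, 0L))

  # impulse displacement: B's impulse at (13,12) maps onto A's at (10,10)
  A2 <- matrix(0, 32, 32); A2[11, 11] <- 1   # 0-based (10,10)
  B2 <- matrix(0, 32, 32); B2[14, 13] <- 1   # 0-based (13,12)
  m <- cross_correlate(A2, B2, max_shift = 6, method = "direct")
  p2 <- find_peak(m)
  expect_identical(c(p2$d_row, p2$d_col), c(3L, 2L))
  # applying the negated peak brings the impulse home
  moved <- apply_translation(B2, c(-p2$d_row, -p2$d_col))
  expect_equal(moved, A2)

  # shifted random content with zero fill
  set.seed(6)
  A3 <- matrix(runif(64 * 64), 64, 64)
  B3 <- apply_translation(A3, c(3, 2))
  p3 <- find_peak(cross_correlate(A3, B3, max_shift = 10))
  expect_identical(c(p3$d_row, p3$d_col), c(3L, 2L))
})

test_that("FFT path matches the direct-sum definition", {
  set.seed(11)
  for (i in 1:5) {
    A <- matrix(runif(24 * 20), 24, 20)
    B <- matrix(runif(24 * 20), 24, 20)
    cf <- cross_correlate(A, B, max_shift = 5, method = "fft")
    cd <- cross_correlate(A, B, max_shift = 5, method = "direct")
    expect_lt(max(abs(cf$C - cd$C)) / max(abs(cd$C)), 1e-9)
    # also with mean subtraction
    cfn <- cross_correlate(A, B, max_shift = 5, normalized = TRUE)
    cdn <- cross_correlate(A, B, max_shift = 5, normalized = TRUE,
                           method = "direct")
    expect_lt(max(abs(cfn$C - cdn$C)) / max(abs(cdn$C)), 1e-9)
  }
})

test_that("peak ties break toward the smallest displacement", {
  disp <- -4:4
  C <- matrix(0, 9, 9, dimnames = list(d_row = disp, d_col = disp))
  C[5, 5] <- 1  # (0,0)
  C[9, 5] <- 1  # (4,0)
  m <- structure(list(C = C, d_row = disp, d_col = disp),
                 class = "CorrelationMap")
  p <- find_peak(m)
  expect_identical(c(p$d_row, p$d_col), c(0L, 0L))
  expect_error(find_peak(structure(list(C = matrix(2, 9, 9), d_row = disp,
                                        d_col = disp),
                                   class = "CorrelationMap")),
               "no correlation structure")
})

test_that("apply_translation moves content with zero boundary fill", {
  B <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(apply_translation(B, c(0, 0)), B)
  down <- apply_translation(B, c(1, 0))
  expect_equal(down, matrix(c(0, 0, 0, 1, 2, 3, 4, 5, 6), 3, 3, byrow = TRUE))
  imp <- matrix(0, 4, 4); imp[1, 1] <- 1
  expect_equal(apply_translation(imp, c(-1, -1)), matrix(0, 4, 4))
})

test_that("translation conserves intensity up to content leaving the frame", {
  set.seed(12)
  B <- matrix(rpois(30 * 30, 20), 30, 30)
  for (v in list(c(0, 0), c(4, -3), c(-7, 7), c(29, 0))) {
    out <- apply_translation(B, v)
    kept_r <- intersect(seq_len(30) - v[1], seq_len(30))
    kept_c <- intersect(seq_len(30) - v[2], seq_len(30))
    kept <- if (length(kept_r) && length(kept_c))
      sum(B[kept_r, kept_c]) else 0
    expect_equal(sum(out), kept)
  }
})

test_that("register_pair recovers simulated inter-round shifts end to end", {
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 6,
                           image_size_px = 512, seed = 31,
                           inter_round_shift_px = c(4, -3))
  sim <- simulate_field(cfg, "A01", 1, mode = "sequential")
  reg <- register_pair(sim$images$DAPI.dna_round, sim$images$DAPI.rna_round,
                       sim$images$RNA.rna_round, max_shift = 20)
  expect_identical(c(reg$vector$d_row, reg$vector$d_col), c(-4L, 3L))
  expect_false(reg$flagged)
  expect_gt(reg$quality, 0.9)
  # registered RNA content sits where the unshifted scene had it
  expect_lt(mean(abs(reg$rna_registered$pixels[50:450, 50:450] -
                       sim$scenes$RNA[50:450, 50:450])), 30)

  # zero shift on noiseless images: identity registration, quality ~ 1
  cfg0 <- simulation_config(n_fields = 1, nuclei_per_field = 6,
                            image_size_px = 512, seed = 32, noise = FALSE,
                            inter_round_shift_px = c(0, 0))
  sim0 <- simulate_field(cfg0, "A01", 1, mode = "sequential")
  reg0 <- register_pair(sim0$images$DAPI.dna_round, sim0$images$DAPI.rna_round,
                        sim0$images$RNA.rna_round, max_shift = 10)
  expect_identical(c(reg0$vector$d_row, reg0$vector$d_col), c(0L, 0L))
  expect_gt(reg0$quality, 0.999)
})

test_that("uncorrelated noise fields are flagged as low quality", {
  set.seed(41)
  mk <- function() field_image(matrix(rpois(256^2, 100), 256, 256),
                               "A01", 1, "DAPI", "dna_round")
  a <- mk()
  b <- mk(); b$round <- "rna_round"
  r <- mk(); r$channel <- "RNA"; r$round <- "rna_round"
  reg <- register_pair(a, b, r, max_shift = 20)
  expect_true(reg$flagged)
  expect_lt(abs(reg$quality), 0.2)
})

test_that("round-trip recovery holds across random shifts under noise", {
  cfg <- simulation_config(n_fields = 1, nuclei_per_field = 6,
                           image_size_px = 512, seed = 55)
  scene <- simulate_field(cfg, "A01", 1)$scenes$DAPI
  set.seed(56)
  ok <- 0L
  for (i in 1:10) {
    s <- sample(-20:20, 2, replace = TRUE)
    An <- matrix(rpois(length(scene), scene), nrow(scene))
    Bn <- matrix(rpois(length(scene), apply_translation(scene, s)),
                 nrow(scene))
    v <- find_peak(cross_correlate(An, Bn, max_shift = 25))
    if (v$d_row == s[1] && v$d_col == s[2]) ok <- ok + 1L
  }
  expect_identical(ok, 10L)
})
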