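test_that("baseline correction removes affine trends exactly", {
  expect_equal(baseline_correct(rep(5, 100)), rep(5, 100))
  k <- 1:100
  expect_equal(baseline_correct(2 * k), rep(2, 100))
  # any affine function of the index maps to a constant
  for (coef in list(c(3, -0.5), c(-1, 4), c(0.25, 100))) {
    out <- baseline_correct(coef[1] + coef[2] * k)
    expect_equal(max(out) - min(out), 0, tolerance = 1e-10)
  }
})

test_that("baseline correction matches the literal transcription oracle", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    x <- cumsum(rnorm(n)) + sin(seq(0, 6, length.out = n))
    expect_equal(baseline_correct(x), baseline_oracle(x), tolerance = 1e-10)
  }
  # fixed-length case called out explicitly
  x <- rnorm(200)
  expect_lt(max(abs(baseline_correct(x) - baseline_oracle(x))), 1e-10)
})

test_that("baseline correction rejects short or non-finite input", {
  expect_error(baseline_correct(rnorm(21)), "below the minimum")
  expect_error(baseline_correct(c(rnorm(50), NA)), "NA")
})

test_that("SNV centres and scales a spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(10:500, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
    out <- snv(x)
    expect_lt(abs(mean(out)), 1e-9)
    expect_lt(abs(sd(out) - 1), 1e-9)
    expect_equal(snv(out), out, tolerance = 1e-9) # idempotent
  }
  expect_error(snv(rep(3, 10)), "Degenerate")
})

test_that("EEM flattening uses excitation-outer ordering and round-trips", {
  g <- fluorescence_grid()
  E <- matrix(seq_len(26 * 36), nrow = 26, byrow = TRUE)
  v <- flatten_eem(E, g)
  expect_length(v, 936)
  # element (excitation index 2, emission index 1) lands at position 37
  expect_equal(v[37], E[2, 1])
  expect_equal(unflatten_eem(v, g), E)
  expect_error(flatten_eem(t(E), g), "shape")
  expect_error(unflatten_eem(v[-1], g), "does not match")
})

test_that("modality preprocessing applies the documented recipe", {
  set.seed(9)
  x <- cumsum(rnorm(200)) + 3
  for (mod in c("nir", "raman")) {
    out <- preprocess_modality(x, mod)
    expect_lt(abs(mean(out)), 1e-9)
    expect_lt(abs(sd(out) - 1), 1e-9)
    expect_equal(attr(out, "provenance"), c("baseline_correct", "snv"))
  }
  fl <- preprocess_modality(x, "fluorescence")
  expect_equal(as.vector(fl), x) # raw in single-modality mode
  fl2 <- preprocess_modality(x, "fluorescence", snv_fluorescence = TRUE)
  expect_lt(abs(mean(fl2)), 1e-9)
  expect_error(preprocess_modality(rep(1, 100), "nir"), "Degenerate")
})

test_that("fusion concatenates SNV fluorescence, NIR and Raman blocks", {
  set.seed(13)
  fluo <- runif(936)
  nir <- preprocess_modality(cumsum(rnorm(134)), "nir")
  raman <- preprocess_modality(cumsum(rnorm(1681)), "raman")
  fused <- fuse_spectra(fluo, nir, raman)
  expect_length(fused, 2751)
  expect_equal(attr(fused, "offsets"),
               c(fluorescence = 0, nir = 936, raman = 1070))
  # fluorescence block is SNV-scaled at fusion time
  expect_lt(abs(mean(fused[1:936])), 1e-9)
  expect_lt(abs(sd(fused[1:936]) - 1), 1e-9)
  # block contents are preserved bit-exactly
  expect_identical(fused[1:936], snv(fluo))
  expect_identical(fused[937:1070], as.vector(nir))
  expect_identical(fused[1071:2751], as.vector(raman))
  expect_error(fuse_spectra(fluo, NULL, raman), "required")
})

test_that("dataset preprocessing yields per-modality feature matrices", {
  ds <- generate_dataset(design_mexican()[1:3, ], endmember_library(1),
                         tiny_grids(), noise_profile("default", seed = 2),
                         n_measurements = 2)
  n_expect <- 3 * 3 * 2
  p_fluo <- n_points(tiny_grids()$fluorescence)
  p_all <- p_fluo + 40 + 45

  f_raw <- preprocess_dataset(ds, "fluo_raw")
  expect_equal(dim(f_raw$x), c(n_expect, p_fluo))
  f_fused <- preprocess_dataset(ds, "fused")
  expect_equal(dim(f_fused$x), c(n_expect, p_all))
  expect_equal(attr(f_fused, "blocks")$start, c(1, p_fluo + 1, p_fluo + 41))
  # fused rows embed the single-modality preprocessing bit-exactly
  f_nir <- preprocess_dataset(ds, "nir")
  expect_equal(f_fused$x[, p_fluo + (1:40)], f_nir$x)
  # alias accepted
  expect_equal(preprocess_dataset(ds, "fluorescence")$x, f_raw$x)
  expect_error(preprocess_dataset(ds, "uv"), "Unknown modality")
})
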