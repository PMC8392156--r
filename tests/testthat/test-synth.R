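test_that("endmember library is deterministic and signatures are distinct", {
  lib1 <- endmember_library(seed = 1)
  lib2 <- endmember_library(seed = 1)
  expect_identical(lib1, lib2)
  expect_setequal(names(lib1),
                  c("A", "B", "S", "R", "C", "U", "V", "W", "X", "Y", "Z"))

  grids <- default_grids()
  rendered <- sapply(names(lib1), function(o) {
    p <- render_pure_spectrum(lib1, o, grids)
    c(flatten_eem(p$eem, grids$fluorescence), p$nir, p$raman)
  })
  cs <- crossprod(rendered)
  nrm <- sqrt(diag(cs))
  cs <- cs / outer(nrm, nrm)
  diag(cs) <- 0
  expect_lt(max(cs), 1 - 1e-3)
})

test_that("every chia oil carries the chlorophyll fluorescence peak", {
  lib <- endmember_library(seed = 3)
  for (oil in c("A", "B", "U", "V", "W", "X", "Y", "Z")) {
    pk <- lib[[oil]]$fluoro_peaks
    hit <- abs(pk$ex - 405) <= 10 & abs(pk$em - 670) <= 10
    expect_true(any(hit), label = sprintf("chlorophyll peak present for %s", oil))
    # and it is a major feature, not an accident of the jitter
    expect_gt(max(pk$amplitude[hit]), 0.5)
  }
})

test_that("noise-free synthesis is exactly linear in mass fraction", {
  lib <- endmember_library(1)
  grids <- tiny_grids()
  clean <- noise_profile("clean")
  pure_a <- synth_measurement(oil_blend(A = 1), lib, grids, clean)
  pure_s <- synth_measurement(oil_blend(S = 1), lib, grids, clean)
  half <- synth_measurement(oil_blend(A = 0.5, S = 0.5), lib, grids, clean)

  rendered_a <- render_pure_spectrum(lib, "A", grids)
  expect_equal(pure_a, rendered_a)
  for (mod in c("eem", "nir", "raman")) {
    expect_equal(half[[mod]], (pure_a[[mod]] + pure_s[[mod]]) / 2)
  }
  # arbitrary 3-component blend, pointwise
  b <- oil_blend(A = 0.2, S = 0.3, R = 0.5)
  mix <- synth_measurement(b, lib, grids, clean)
  pure_r <- synth_measurement(oil_blend(R = 1), lib, grids, clean)
  expect_equal(mix$raman,
               0.2 * pure_a$raman + 0.3 * pure_s$raman + 0.5 * pure_r$raman)
})

test_that("unknown oils are rejected by name", {
  lib <- endmember_library(1)
  expect_error(synth_measurement(oil_blend(Q = 1), lib, tiny_grids(),
                                 noise_profile("clean")), "Q")
})

test_that("additive noise is unbiased (Monte-Carlo over replicate draws)", {
  lib <- endmember_library(1)
  grids <- list(
    fluorescence = fluorescence_grid(excitation = c(300, 400),
                                     emission = c(350, 500, 650)),
    nir = nir_grid(wavelength = seq(800, 2800, length.out = 25)),
    raman = raman_grid(shift = seq(350, 3200, length.out = 10))
  )
  blend <- oil_blend(A = 0.9, S = 0.1)
  clean <- synth_measurement(blend, lib, grids, noise_profile("clean"))
  add_sd <- 0.05
  n_draws <- 10000
  acc <- lapply(clean, function(x) x * 0)
  for (i in seq_len(n_draws)) {
    nm <- noise_model(additive_sd = add_sd, multiplicative_sd = 0,
                      baseline_drift_sd = 0, seed = i)
    draw <- synth_measurement(blend, lib, grids, nm)
    acc <- Map(`+`, acc, draw)
  }
  tol <- 4 * add_sd / sqrt(n_draws)
  for (mod in c("eem", "nir", "raman")) {
    expect_true(all(abs(acc[[mod]] / n_draws - clean[[mod]]) < tol),
                label = sprintf("MC mean within 4 sigma/sqrt(n) for %s", mod))
  }
})

test_that("generated datasets have the designed spectrum counts", {
  ds <- generate_dataset(design_both(), endmember_library(1), tiny_grids(),
                         noise_profile("default", seed = 1), n_measurements = 5)
  expect_equal(nrow(ds) / 3, 710) # per modality
  ds_mex <- tiny_mexican(seed = 1)
  expect_equal(nrow(ds_mex) / 3, 570)
  expect_equal(sum(ds_mex$modality == "nir"), 570)

  one <- generate_dataset(design_kenyan()[1, ], endmember_library(1),
                          tiny_grids(), noise_profile("clean"),
                          n_measurements = 1)
  expect_equal(nrow(one), 3) # one spectrum per modality

  # (label, preparation, measurement) triples unique within each modality
  key <- paste(ds$sample_label, ds$preparation, ds$measurement, ds$modality)
  expect_false(anyDuplicated(key) > 0)
})

test_that("generation is bit-reproducible under a fixed seed", {
  d <- design_mexican()[c(1, 6), ]
  ds1 <- generate_dataset(d, endmember_library(1), tiny_grids(),
                          noise_profile("default", seed = 11), n_measurements = 2)
  ds2 <- generate_dataset(d, endmember_library(1), tiny_grids(),
                          noise_profile("default", seed = 11), n_measurements = 2)
  expect_identical(ds1$intensity, ds2$intensity)
  ds3 <- generate_dataset(d, endmember_library(1), tiny_grids(),
                          noise_profile("default", seed = 12), n_measurements = 2)
  expect_false(identical(ds1$intensity, ds3$intensity))
})

test_that("empty designs are refused", {
  expect_error(generate_dataset(design_mexican()[0, ], endmember_library(1),
                                tiny_grids(), noise_profile("clean")),
               "non-empty")
})
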