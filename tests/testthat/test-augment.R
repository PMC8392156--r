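test_that("spectra simulation perturbs mean- and original-based rows", {
  set.seed(7)
  base <- matrix(rnorm(8 * 20), nrow = 8)
  sim1 <- simulate_spectra(base, 10, 10, seed = 3)
  sim2 <- simulate_spectra(base, 10, 10, seed = 3)
  expect_identical(sim1, sim2)
  expect_equal(dim(sim1), c(20, 20))
  expect_equal(attr(sim1, "source"),
               rep(c("simulated_mean", "simulated_original"), each = 10))

  # zero SD base (identical rows): simulated rows equal the base exactly
  flat <- matrix(rep(c(1, 2, 3, 4), each = 5), nrow = 5)
  simz <- simulate_spectra(flat, 3, 7, seed = 1)
  expect_true(all(apply(simz, 1, function(r) identical(unname(r), c(1, 2, 3, 4)))))

  expect_error(simulate_spectra(matrix(numeric(0), 0, 5), 1, 1), "non-empty")
})

test_that("simulated spectra are unbiased around their base (Monte-Carlo)", {
  set.seed(11)
  base <- matrix(rnorm(6 * 15, sd = 2), nrow = 6)
  m <- colMeans(base)
  sdv <- apply(base, 2, sd)
  sim <- simulate_spectra(base, n_mean_based = 10000, n_original_based = 0,
                          seed = 99)
  mc_mean <- colMeans(sim)
  expect_true(all(abs(mc_mean - m) < 4 * sdv / 100))
})

test_that("the 5-class assembly reproduces the printed class structure", {
  ds <- tiny_mexican(seed = 1)
  lab <- assemble_classification_set(ds, modality = "fused", seed = 1)

  expect_equal(nrow(lab), 1125)
  expect_equal(unname(table(lab$class)), rep(225L, 5),
               ignore_attr = TRUE)
  expect_equal(levels(lab$class), c("A", "AdultA", "B", "AdultB", "Adult"))

  # Adult class: 90 real spectra before augmentation, 90 simulated, 45 extra
  adult <- lab[lab$class == "Adult", ]
  expect_equal(sum(adult$source == "real"), 90)
  expect_equal(sum(grepl("^simulated", adult$source)), 90)
  expect_equal(sum(adult$source == "replicated"), 45)
  expect_setequal(unique(adult$sample_label[adult$source == "real"]),
                  c("S100", "R100", "C100", "RS50", "RC50", "SC50"))

  # pure classes: 15 real, originals used five times, 75 + 75 simulated
  for (cl in c("A", "B")) {
    sub <- lab[lab$class == cl, ]
    expect_equal(sum(sub$source == "real"), 15)
    expect_equal(sum(sub$source == "replicated"), 60)
    expect_equal(sum(sub$source == "simulated_mean"), 75)
    expect_equal(sum(sub$source == "simulated_original"), 75)
  }

  # adulterated classes are purely real: 15 labels x 15 spectra
  for (cl in c("AdultA", "AdultB")) {
    sub <- lab[lab$class == cl, ]
    expect_equal(nrow(sub), 225)
    expect_true(all(sub$source == "real"))
    expect_equal(length(unique(sub$sample_label)), 15)
  }

  # no measured spectrum is shared between classes
  real <- lab[lab$source == "real", ]
  expect_equal(anyDuplicated(real$x), 0)

  # pure function of (dataset, seed)
  lab2 <- assemble_classification_set(ds, modality = "fused", seed = 1)
  expect_identical(lab$x, lab2$x)
  lab3 <- assemble_classification_set(ds, modality = "fused", seed = 2)
  expect_false(identical(lab$x, lab3$x))
})

test_that("assembly reports missing labels and wrong replication", {
  ds <- tiny_mexican(seed = 1)
  drop <- ds[!ds$sample_label %in% c("S100", "RC50"), ]
  attr(drop, "grids") <- attr(ds, "grids")
  class(drop) <- class(ds)
  expect_error(assemble_classification_set(drop, "fluo_raw", 1), "S100")

  short <- generate_dataset(design_mexican(), endmember_library(1),
                            tiny_grids(), noise_profile("default", seed = 1),
                            n_measurements = 2)
  expect_error(assemble_classification_set(short, "fluo_raw", 1),
               "15 spectra per design label")
})
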