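test_that("range-normalized RMSEP and detection limit match hand arithmetic", {
  expect_equal(rmsep_range(c(0, 100), c(10, 110)), 10)
  expect_equal(rmsep_range(c(0, 50, 100), c(0, 50, 100)), 0)
  expect_equal(rmsep_range(c(0, 50, 100), c(10, 50, 90)),
               100 * sqrt(200 / 3) / 100, tolerance = 1e-12)
  expect_error(rmsep_range(c(5, 5), c(1, 2)), "Degenerate")

  expect_equal(detection_limit(c(1, 1, 1))$detection_limit, 1)
  blanks <- c(0.5, 1.0, 1.5) # mean 1, sd 0.5
  dl <- detection_limit(blanks)
  expect_equal(dl$blank_mean, 1)
  expect_equal(dl$blank_sd, 0.5)
  expect_equal(dl$detection_limit, 2.5, tolerance = 1e-12)
  expect_error(detection_limit(2), "At least 2")
  # dl >= m always
  set.seed(2)
  for (i in 1:20) {
    b <- rnorm(sample(2:10, 1))
    expect_gte(detection_limit(b)$detection_limit, mean(b))
  }
})

test_that("PLSR recovers noiseless low-rank mixtures to machine precision", {
  set.seed(17)
  n <- 20; p <- 50
  scores <- matrix(rnorm(n * 2), n, 2)
  loadings <- matrix(rnorm(2 * p), 2, p)
  X <- scores %*% loadings
  y <- drop(scores %*% c(2, -1)) + 5
  task <- tibble::tibble(sample_label = as.character(1:n), y = y, x = X)
  res <- fit_plsr_cv(task, ncomp_min = 1, ncomp_max = 6)
  expect_lte(res$n_components, 3)
  expect_gt(res$r2, 1 - 1e-6)
  expect_lt(res$rmsep, 1e-6)
})

test_that("component bounds are validated and honoured", {
  set.seed(23)
  task <- tibble::tibble(y = rnorm(12), x = matrix(rnorm(12 * 30), 12))
  task$y <- task$y + rowSums(task$x[, 1:3])
  res <- fit_plsr_cv(task, ncomp_min = 1, ncomp_max = 4)
  expect_lte(res$n_components, 4)
  expect_error(fit_plsr_cv(task, 1, 11), "Invalid component range")
  expect_error(fit_plsr_cv(task, 3, 2), "Invalid component range")
  expect_error(fit_plsr_cv(task[1:3, ], 1, 1), "At least 4")
})

test_that("LOO-CV predictions are invariant to sample order", {
  set.seed(29)
  n <- 15
  X <- matrix(rnorm(n * 40), n)
  y <- rowSums(X[, 1:4]) + rnorm(n, sd = 0.1)
  task <- tibble::tibble(sample_label = as.character(1:n), y = y, x = X)
  res <- fit_plsr_cv(task, 1, 5)
  perm <- sample(n)
  task_p <- task[perm, ]
  res_p <- fit_plsr_cv(task_p, 1, 5)
  expect_equal(res_p$predictions$.fitted[order(perm)],
               res$predictions$.fitted, tolerance = 1e-8)
  expect_equal(res_p$rmsep, res$rmsep, tolerance = 1e-8)
})

test_that("PLSR tasks carry the right samples and reference levels", {
  ds <- tiny_mexican(seed = 1)
  features <- preprocess_dataset(ds, "fluo_raw")
  task <- plsr_task(features, "AS")
  expect_equal(nrow(task), 7 * 3 * 5) # 7 labels x 3 preps x 5 measurements
  expect_setequal(unique(task$y), c(0, 1, 2, 5, 10, 50, 100))
  expect_equal(sum(task$y == 0), 15) # blanks = pure chia A

  # "A all" pools the three series without double-counting the blanks
  all_task <- plsr_task(features, "A all")
  expect_equal(length(unique(all_task$sample_label)), 19)
  expect_equal(nrow(all_task), 19 * 15)
  expect_equal(sum(all_task$sample_label == "A100"), 15)

  expect_error(plsr_task(features, "QS"), "Unknown quantification series")
  sub <- features[features$sample_label != "S100", ]
  expect_error(plsr_task(sub, "AS"), "S100")
})

test_that("the quantification suite mirrors the reporting tables", {
  ds <- tiny_mexican(seed = 1)
  suite <- run_quantification_suite(ds, modalities = c("nir", "fused"),
                                    ncomp_max = 8)
  expect_equal(nrow(suite), 8 * 2) # 8 Mexican series x 2 modalities
  expect_setequal(unique(suite$series),
                  c("AC", "AR", "AS", "A all", "BC", "BR", "BS", "B all"))
  expect_true(all(suite$rmsep_range >= 0))
  expect_true(all(suite$detection_limit >= suite$blank_mean))
  expect_true(all(suite$n_components <= 8))

  # Kenyan series: the shared pure sunflower anchors the 100 % level
  dmex <- design_mexican()
  dk_design <- dplyr::bind_rows(design_kenyan(), dmex[dmex$label == "S100", ])
  dk <- generate_dataset(dk_design, endmember_library(1), tiny_grids(),
                         noise_profile("default", seed = 1), n_measurements = 5)
  ks <- run_quantification_suite(dk, modalities = "nir")
  expect_equal(nrow(ks), 6) # U..Z
  expect_true(all(ks$n_components >= 3 & ks$n_components <= 10))
  # W spans three levels (0, 50, 100) even without a 90:10 blend
  tw <- plsr_task(dk, "W", modality = "nir")
  expect_setequal(unique(tw$y), c(0, 50, 100))
})

test_that("more additive noise monotonically degrades the median R2", {
  labels <- c("A100", "AS99", "AS98", "AS95", "AS90", "AS50", "S100")
  design <- design_mexican()
  design <- design[design$label %in% labels, ]
  med_r2 <- vapply(c(0.005, 0.1, 0.8), function(noise_sd) {
    r2 <- vapply(1:5, function(s) {
      nm <- noise_model(additive_sd = noise_sd, multiplicative_sd = 0.01,
                        baseline_drift_sd = 0.005, seed = s)
      ds <- generate_dataset(design, endmember_library(1), tiny_grids(), nm,
                             n_measurements = 2)
      fit_plsr_cv(plsr_task(ds, "AS", modality = "nir"), 1, 6)$r2
    }, numeric(1))
    median(r2)
  }, numeric(1))
  expect_true(all(diff(med_r2) < 0))
})
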