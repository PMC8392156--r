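test_that("confusion-matrix metrics follow the one-vs-rest definitions", {
  # two-class collapse: TP=9 FN=1 / FP=2 TN=8
  cm <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- compute_metrics(cm)
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$sensitivity, 90)
  expect_equal(pos$specificity, 80)
  expect_equal(pos$accuracy, 85)
  expect_equal(pos$precision, 100 * 9 / 11, tolerance = 1e-12) # 81.81..%

  # perfect confusion matrix: every metric 100
  eye <- diag(5) * 45
  dimnames(eye) <- list(LETTERS[1:5], LETTERS[1:5])
  me <- compute_metrics(eye)
  expect_equal(me$tpr, 100)
  expect_true(all(unlist(me$per_class[, -1]) == 100))

  # all predictions in one column of a balanced 5-class problem
  onecol <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  onecol[, 1] <- 45
  mo <- compute_metrics(onecol)
  expect_equal(mo$per_class$precision[1], 20)
  expect_true(all(is.na(mo$per_class$precision[-1]))) # undefined, not 0
})

test_that("metrics agree with a brute-force tally oracle", {
  set.seed(31)
  for (i in 1:25) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, 5), K, K)
    dimnames(cm) <- list(seq_len(K), seq_len(K))
    got <- compute_metrics(cm)
    want <- metrics_oracle(cm)
    expect_equal(got$per_class$sensitivity, want$sensitivity)
    expect_equal(got$per_class$specificity, want$specificity)
    expect_equal(got$per_class$precision, want$precision)
    expect_equal(got$per_class$accuracy, want$accuracy)
    expect_equal(got$tpr, want$tpr[1])
  }
  expect_error(compute_metrics(matrix(1:6, 2, 3)), "square")
})

test_that("all five classifiers separate well-separated classes perfectly", {
  data <- separable_classes()
  for (meth in c("DT", "LD", "KNN", "SVMl", "SVMc")) {
    run <- train_and_eval(data, meth, split_seed = 1, train_accuracy = FALSE)
    expect_equal(run$metrics$tpr, 100,
                 label = sprintf("TPR for %s", meth))
    # confusion rows sum to the holdout class supports
    expect_equal(unname(rowSums(run$confusion)), rep(8, 5))
  }
  expect_error(train_and_eval(data, "XGB"), "Unknown")
})

test_that("evaluation is deterministic and split-seed sensitive", {
  data <- separable_classes(n_per = 30, gap = 3) # overlapping classes
  r1 <- train_and_eval(data, "LD", split_seed = 4)
  r2 <- train_and_eval(data, "LD", split_seed = 4)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$accuracy_training, r2$accuracy_training)
  expect_true(is.finite(r1$accuracy_training))
  g <- glance(r1)
  expect_named(g, c("method", "split_seed", "tpr", "accuracy_training",
                    "accuracy_validation"))
  expect_equal(tidy(r1), r1$metrics$per_class)
})

test_that("repeated runs aggregate mean, SD and median correctly", {
  data <- separable_classes(n_per = 30, gap = 2.5, seed = 8)
  rs <- repeat_runs(data, "KNN", seeds = 1:6, train_accuracy = FALSE)
  expect_length(rs$runs, 6)
  tprs <- vapply(rs$runs, function(r) r$metrics$tpr, numeric(1))
  expect_equal(sum(rs$per_run$metric == "tpr"), 6)

  # sort-based median oracle and n-1 SD on the retained values
  srt <- sort(tprs)
  med_oracle <- (srt[3] + srt[4]) / 2
  summ <- rs$summary
  expect_equal(summ$median[summ$metric == "tpr"], med_oracle)
  expect_equal(summ$mean[summ$metric == "tpr"], mean(tprs))
  expect_equal(summ$sd[summ$metric == "tpr"],
               sqrt(sum((tprs - mean(tprs))^2) / 5))

  expect_error(repeat_runs(data, "KNN", seeds = 1), "At least 2")
})

test_that("identical runs collapse to zero SD and median equal to mean", {
  data <- separable_classes()
  rs <- repeat_runs(data, "KNN", seeds = c(2, 2, 2), train_accuracy = FALSE)
  summ <- rs$summary[rs$summary$metric == "tpr", ]
  expect_equal(summ$sd, 0)
  expect_equal(summ$median, summ$mean)
})
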