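## Classification evaluation protocol: stratified 80/20 holdout for the
## true positive rate and confusion matrix, 5-fold cross-validation inside
## the training partition for the training accuracy.

stratified_split <- function(y, frac_holdout = 0.2) {
  holdout <- integer(0)
  for (l in levels(y)) {
    idx <- which(y == l)
    n_h <- round(length(idx) * frac_holdout)
    holdout <- c(holdout, sample(idx, n_h))
  }
  sort(holdout)
}

stratified_folds <- function(y, k = 5) {
  fold <- integer(length(y))
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Collapses each class of a confusion matrix (rows = true, columns =
#' predicted) to its one-vs-rest 2 x 2 table and applies the standard
#' definitions: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/(TP+TN+FP+FN)` and precision `TP/(TP+FP)`, each in
#' percent. The overall true positive rate is `100 * trace / total`.
#' When a class is never predicted, its precision is undefined and reported
#' as `NA` (never silently 0).
#'
#' @param cm Square integer confusion matrix with named dimensions.
#' @return A list of class `class_metrics`: `per_class` tibble (class,
#'   sensitivity, specificity, precision, accuracy), `tpr`, and
#'   `accuracy_validation` (mean one-vs-rest accuracy).
#' @examples
#' cm <- matrix(c(9, 2, 1, 8), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' compute_metrics(cm)$per_class
#' @export
compute_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0)) {
    abort("`cm` must be a square confusion matrix with non-negative counts.")
  }
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  per <- purrr::map_dfr(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = classes[k],
      sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp),
      precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp),
      accuracy = 100 * (tp + tn) / total
    )
  })
  structure(list(per_class = per,
                 tpr = 100 * sum(diag(cm)) / total,
                 accuracy_validation = mean(per$accuracy)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics: TPR %.1f%%>\n", x$tpr))
  print(x$per_class)
  invisible(x)
}

#' Train a classifier and evaluate it on a stratified holdout
#'
#' Splits the labelled set 80/20 stratified by class (driven by
#' `split_seed`), fits the requested classifier on the 80 % partition,
#' computes the training accuracy as 5-fold cross-validated accuracy within
#' that partition, and evaluates the confusion matrix and true positive
#' rate on the held-out 20 %. Identical inputs and seed give identical
#' results.
#'
#' @param data A `labeled_dataset` from [assemble_classification_set()], or
#'   any tibble with a `class` factor column and matrix column `x`.
#' @param method `"DT"`, `"LD"`, `"KNN"`, `"SVMl"` or `"SVMc"`.
#' @param split_seed Integer seed for the split (and CV folds).
#' @param train_accuracy Compute the 5-fold CV training accuracy? Skipping
#'   it (`FALSE`) saves most of the fit time when only the holdout TPR is
#'   needed.
#' @param cv_folds Folds for the training accuracy (default 5).
#' @param ... Passed to [fit_classifier()].
#' @return An object of class `classification_run`: confusion matrix
#'   (`confusion`, rows = true class), `metrics` ([compute_metrics()]
#'   result), `accuracy_training` (%), `method`, `split_seed`. [tidy()]
#'   returns the per-class metrics, [glance()] the one-row summary.
#' @export
train_and_eval <- function(data, method, split_seed = 1,
                           train_accuracy = TRUE, cv_folds = 5, ...) {
  y <- droplevels(as.factor(data$class))
  x <- data$x
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(split_seed))
  holdout <- stratified_split(y)
  tr <- setdiff(seq_along(y), holdout)
  if (any(table(y[tr]) < 2) || any(table(y[holdout]) < 1)) {
    abort("A class has too few members in a partition.")
  }

  acc_train <- NA_real_
  if (train_accuracy) {
    fold <- stratified_folds(y[tr], cv_folds)
    hits <- 0
    for (f in seq_len(cv_folds)) {
      in_f <- tr[fold == f]
      out_f <- tr[fold != f]
      m <- fit_classifier(x[out_f, , drop = FALSE], y[out_f], method, ...)
      hits <- hits + sum(predict(m, x[in_f, , drop = FALSE]) == y[in_f])
    }
    acc_train <- 100 * hits / length(tr)
  }

  model <- fit_classifier(x[tr, , drop = FALSE], y[tr], method, ...)
  pred <- predict(model, x[holdout, , drop = FALSE])
  cm <- table(true = y[holdout], predicted = pred)
  cm <- unclass(cm)
  metrics <- compute_metrics(cm)
  structure(list(confusion = cm, metrics = metrics,
                 accuracy_training = acc_train,
                 method = method, split_seed = split_seed,
                 n_holdout = length(holdout)),
            class = "classification_run")
}

#' @export
print.classification_run <- function(x, ...) {
  cat(sprintf("<classification_run: %s, TPR %.1f%% (holdout n = %d), training accuracy %s>\n",
              x$method, x$metrics$tpr, x$n_holdout,
              if (is.na(x$accuracy_training)) "not computed"
              else sprintf("%.1f%%", x$accuracy_training)))
  invisible(x)
}

#' @rdname train_and_eval
#' @param x A `classification_run`.
#' @method tidy classification_run
#' @export
tidy.classification_run <- function(x, ...) {
  x$metrics$per_class
}

#' @rdname train_and_eval
#' @method glance classification_run
#' @export
glance.classification_run <- function(x, ...) {
  tibble::tibble(method = x$method, split_seed = x$split_seed,
                 tpr = x$metrics$tpr,
                 accuracy_training = x$accuracy_training,
                 accuracy_validation = x$metrics$accuracy_validation)
}

## long per-run metric table used by repeat_runs summaries
run_metric_row <- function(run) {
  per <- run$metrics$per_class
  dplyr::bind_rows(
    tibble::tibble(metric = "tpr", value = run$metrics$tpr),
    tibble::tibble(metric = "accuracy_training", value = run$accuracy_training),
    tibble::tibble(metric = "accuracy_validation", value = run$metrics$accuracy_validation),
    tibble::tibble(metric = paste0("sensitivity_", per$class), value = per$sensitivity),
    tibble::tibble(metric = paste0("specificity_", per$class), value = per$specificity),
    tibble::tibble(metric = paste0("precision_", per$class), value = per$precision)
  )
}

#' Repeat the classification evaluation over several seeds
#'
#' Runs [train_and_eval()] once per seed and aggregates each metric's mean,
#' SD (`n - 1`) and median over the runs. When `data` is a raw
#' `spectra_dataset`, the class-balancing augmentation is re-simulated for
#' every run with that run's seed (so both the simulated spectra and the
#' split vary); when `data` is an already assembled `labeled_dataset`, only
#' the split varies. Undefined precisions (class never predicted) are
#' excluded from the aggregation with a warning.
#'
#' @inheritParams train_and_eval
#' @param data A `spectra_dataset` or `labeled_dataset`.
#' @param modality Analysis modality (used when re-assembling per run).
#' @param seeds Integer vector of run seeds (default `1:10`; >= 2 required).
#' @return An object of class `run_summary`: `runs` (list of
#'   `classification_run`), `per_run` (long tibble seed/metric/value) and
#'   `summary` (metric, mean, sd, median, n). [tidy()] returns the summary
#'   table, [glance()] a one-row overview.
#' @export
repeat_runs <- function(data, method, seeds = 1:10, modality = "fused",
                        train_accuracy = TRUE, ...) {
  if (length(seeds) < 2) abort("At least 2 run seeds are required.")
  runs <- lapply(seeds, function(s) {
    d <- if (inherits(data, "spectra_dataset")) {
      assemble_classification_set(data, modality = modality, seed = s)
    } else data
    train_and_eval(d, method, split_seed = s,
                   train_accuracy = train_accuracy, ...)
  })
  per_run <- purrr::map2_dfr(runs, seeds, function(r, s) {
    dplyr::mutate(run_metric_row(r), seed = s, .before = 1)
  })
  if (anyNA(per_run$value[grepl("^precision", per_run$metric)])) {
    warn("Undefined precision in at least one run (class never predicted); excluded from the summary.")
  }
  summ <- per_run |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     median = median(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  structure(list(method = method, seeds = seeds, runs = runs,
                 per_run = per_run, summary = summ),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  tpr <- x$summary[x$summary$metric == "tpr", ]
  cat(sprintf("<run_summary: %s, %d runs, TPR %.1f +- %.1f %% (median %.1f)>\n",
              x$method, length(x$seeds), tpr$mean, tpr$sd, tpr$median))
  invisible(x)
}

#' @rdname repeat_runs
#' @param x A `run_summary`.
#' @method tidy run_summary
#' @export
tidy.run_summary <- function(x, ...) {
  x$summary
}

#' @rdname repeat_runs
#' @method glance run_summary
#' @export
glance.run_summary <- function(x, ...) {
  g <- function(metric, col) {
    v <- x$summary[x$summary$metric == metric, ][[col]]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(method = x$method, n_runs = length(x$seeds),
                 tpr_mean = g("tpr", "mean"), tpr_sd = g("tpr", "sd"),
                 tpr_median = g("tpr", "median"),
                 accuracy_training_mean = g("accuracy_training", "mean"))
}
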