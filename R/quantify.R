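## Partial least squares regression of adulteration level.
##
## SIMPLS with mean-centering only (SNV already handles scale for the
## preprocessed blocks), leave-one-out cross-validation over a range of
## latent-variable counts, model selection by minimum LOO RMSECV with ties
## broken toward fewer components, and reporting of R^2, RMSEP and the
## range-normalized RMSEP from the CV predictions at the selected count.

simpls_fit <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, n - 1, p)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  s <- crossprod(Xc, yc)
  R <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- s
    t_ <- Xc %*% r
    normt <- sqrt(sum(t_^2))
    if (!is.finite(normt) || normt < 1e-12) break
    t_ <- t_ / normt
    r <- r / normt
    pl <- crossprod(Xc, t_)
    q <- sum(yc * t_)
    v <- pl
    if (a > 1) {
      Va <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    V[, a] <- v
    R[, a] <- r
    Q[a] <- q
    s <- s - v * sum(v * s)
    a_used <- a
  }
  if (a_used == 0L) abort("PLSR failed: response has no covariance with X.")
  R <- R[, seq_len(a_used), drop = FALSE]
  Q <- Q[seq_len(a_used)]
  ## cumulative coefficients: column a gives the a-component model
  B <- sweep(R, 2, Q, "*") %*% upper.tri(diag(a_used), diag = TRUE)
  intercept <- ym - drop(xm %*% B)
  list(coefficients = B, intercept = intercept, ncomp = a_used)
}

simpls_predict <- function(fit, X) {
  ## matrix of predictions, one column per component count 1..ncomp
  sweep(X %*% fit$coefficients, 2, fit$intercept, "+")
}

#' Range-normalized root mean square error of prediction
#'
#' `100 * sqrt(mean((y_true - y_pred)^2)) / (max(y_true) - min(y_true))`,
#' i.e. the RMSEP expressed as a percentage of the span of the reference
#' values.
#'
#' @param y_true,y_pred Reference and predicted values.
#' @return RMSEP_range in percent.
#' @examples
#' rmsep_range(c(0, 50, 100), c(10, 50, 90)) # ~8.165
#' @export
rmsep_range <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  rng <- max(y_true) - min(y_true)
  if (rng <= 0) abort("Degenerate reference range: max(y_true) == min(y_true).")
  100 * sqrt(mean((y_true - y_pred)^2)) / rng
}

#' Three-sigma detection limit from blank predictions
#'
#' The detection limit of the adulteration quantification is taken from
#' the cross-validated predictions of the blank (100 % pure chia) samples:
#' `dl = m + 3 * SD` with `m` the mean and `SD` the sample standard
#' deviation of the blank predictions, in mass %.
#'
#' @param blank_predictions Predicted adulteration (mass %) of >= 2 blanks.
#' @return A tibble with `blank_mean`, `blank_sd`, `detection_limit`.
#' @examples
#' detection_limit(c(0.5, 1.5)) # mean 1, sd ~0.707, dl ~3.12
#' @export
detection_limit <- function(blank_predictions) {
  if (length(blank_predictions) < 2) {
    abort("At least 2 blank predictions are required for the detection limit.")
  }
  m <- mean(blank_predictions)
  s <- sd(blank_predictions)
  tibble::tibble(blank_mean = m, blank_sd = s, detection_limit = m + 3 * s)
}

## adulteration level (mass %) implied by a blend: 100 x (1 - chia fraction)
chia_oils <- c("A", "B", "U", "V", "W", "X", "Y", "Z")

adulteration_level <- function(blend) {
  ## round away binary-representation fuzz (levels are printed percentages)
  round(100 * (1 - sum(unclass(blend)[names(blend) %in% chia_oils])), 9)
}

## design labels entering each quantification series
series_labels <- function(series) {
  mex_single <- function(chia, ad) {
    c(paste0(chia, "100"),
      paste0(chia, ad, c(99, 98, 95, 90, 50)), paste0(ad, "100"))
  }
  if (grepl("^[AB][SRC]$", series)) {
    return(mex_single(substr(series, 1, 1), substr(series, 2, 2)))
  }
  if (series %in% c("A all", "B all")) {
    chia <- substr(series, 1, 1)
    return(unique(unlist(lapply(c("S", "R", "C"), function(ad) mex_single(chia, ad)))))
  }
  if (series %in% c("U", "V", "W", "X", "Y", "Z")) {
    mixes <- paste0(series, "S", c(90, 50))
    if (series == "W") mixes <- "WS50" # W has no 90:10 blend
    ## the shared pure sunflower anchors the 100 % level of every series
    return(c(paste0(series, "100"), mixes, "S100"))
  }
  abort(sprintf("Unknown quantification series '%s'.", series))
}

#' Build a PLSR task for one adulteration series
#'
#' Extracts the spectra and reference adulteration levels (mass %) of one
#' series from a dataset: e.g. `"AS"` is chia oil A adulterated with
#' sunflower (A100, AS99, AS98, AS95, AS90, AS50, S100; levels 0, 1, 2, 5,
#' 10, 50, 100), `"A all"` pools the S, R and C series of oil A without
#' double-counting the shared blanks, and the Kenyan series `"U"` .. `"Z"`
#' contain the pure oil, its 10 / 50 % sunflower blends (oil W has only the
#' 50 % blend) and the shared pure sunflower S100 as the 100 % level, so
#' every series spans at least three adulteration levels.
#'
#' @param dataset A `spectra_dataset` or a [preprocess_dataset()] feature
#'   table.
#' @param series Series id (`"AS"`, `"AR"`, `"AC"`, `"A all"`, `"BS"`,
#'   `"BR"`, `"BC"`, `"B all"`, `"U"` .. `"Z"`).
#' @param modality Analysis modality (used when `dataset` is raw).
#' @return A tibble of class `plsr_task` with columns `sample_label`, `y`
#'   (mass % adulteration) and matrix column `x`; attributes `series`,
#'   `modality`.
#' @export
plsr_task <- function(dataset, series, modality = "fused") {
  features <- if (inherits(dataset, "spectra_dataset")) {
    preprocess_dataset(dataset, modality)
  } else dataset
  labels <- series_labels(series)
  miss <- setdiff(labels, unique(features$sample_label))
  if (length(miss) > 0) {
    abort(sprintf("Series '%s' is missing design label(s): %s.",
                  series, paste(miss, collapse = ", ")))
  }
  idx <- which(features$sample_label %in% labels)
  y <- vapply(features$sample_label[idx],
              function(l) adulteration_level(blend_from_label(l)), numeric(1))
  if (length(unique(y)) < 3) {
    abort(sprintf("Series '%s' has fewer than 3 distinct adulteration levels.", series))
  }
  out <- tibble::tibble(sample_label = features$sample_label[idx],
                        y = unname(y),
                        x = features$x[idx, , drop = FALSE])
  attr(out, "series") <- series
  attr(out, "modality") <- attr(features, "modality") %||% modality
  class(out) <- c("plsr_task", class(tibble::tibble()))
  out
}

#' PLSR with leave-one-out cross-validated component selection
#'
#' For every candidate latent-variable count in `ncomp_min:ncomp_max`,
#' leave-one-out CV predictions are computed (one SIMPLS fit per left-out
#' sample, predictions for all counts read off the same fit). The count
#' minimizing the CV root mean square error is selected, ties broken toward
#' fewer components, and R^2, RMSEP and RMSEP_range are reported from the
#' CV predictions at that count. The detection limit is computed from the
#' CV predictions of the blank (0 % adulteration) samples via
#' [detection_limit()].
#'
#' @param task A [plsr_task()] (or tibble with `y` and matrix column `x`).
#' @param ncomp_min,ncomp_max Candidate component range;
#'   `ncomp_max` must be below `min(n - 1, n_features)`. Counts are
#'   additionally capped at `n - 2` inside each LOO fold.
#' @return An object of class `pls_result` with fields `n_components`,
#'   `r2`, `rmsep`, `rmsep_range`, `detection_limit`, `blank_mean`,
#'   `blank_sd`, `rmsecv` (per candidate count) and `predictions`
#'   (tibble `sample_label`, `y`, `.fitted`). [tidy()] returns the
#'   predictions, [glance()] the one-row summary.
#' @export
fit_plsr_cv <- function(task, ncomp_min = 1, ncomp_max = 32) {
  y <- task$y
  X <- task$x
  n <- length(y)
  if (n < 4) abort("At least 4 samples are required for PLSR with LOO-CV.")
  if (ncomp_min < 1 || ncomp_max < ncomp_min || ncomp_max >= min(n - 1, ncol(X))) {
    abort(sprintf(
      "Invalid component range [%d, %d]: need 1 <= min <= max < min(n - 1, p) = %d.",
      ncomp_min, ncomp_max, min(n - 1, ncol(X))))
  }
  a_max <- min(ncomp_max, n - 2)
  preds <- matrix(NA_real_, n, a_max)
  for (i in seq_len(n)) {
    fit <- simpls_fit(X[-i, , drop = FALSE], y[-i], a_max)
    pr <- simpls_predict(fit, X[i, , drop = FALSE])
    ## a fold may support fewer components than requested; carry the last
    preds[i, ] <- pr[1, pmin(seq_len(a_max), fit$ncomp)]
  }
  cand <- ncomp_min:a_max
  rmsecv <- sqrt(colMeans((preds[, cand, drop = FALSE] - y)^2))
  a_sel <- cand[which.min(rmsecv)]
  yhat <- preds[, a_sel]
  rmsep <- sqrt(mean((y - yhat)^2))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  blanks <- yhat[y == 0]
  dl <- if (length(blanks) >= 2) detection_limit(blanks) else
    tibble::tibble(blank_mean = NA_real_, blank_sd = NA_real_,
                   detection_limit = NA_real_)
  structure(list(
    series = attr(task, "series"), modality = attr(task, "modality"),
    n = n, n_components = a_sel,
    r2 = r2, rmsep = rmsep, rmsep_range = rmsep_range(y, yhat),
    blank_mean = dl$blank_mean, blank_sd = dl$blank_sd,
    detection_limit = dl$detection_limit,
    rmsecv = setNames(rmsecv, cand),
    predictions = tibble::tibble(
      sample_label = if ("sample_label" %in% names(task)) task$sample_label
                     else as.character(seq_len(n)),
      y = y, .fitted = yhat)
  ), class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(
    "<pls_result%s%s: n = %d, %d components, R2 = %.3f, RMSEP_range = %.2f%%, dl = %s>\n",
    if (is.null(x$series)) "" else paste0(" ", x$series),
    if (is.null(x$modality)) "" else paste0(" (", x$modality, ")"),
    x$n, x$n_components, x$r2, x$rmsep_range,
    if (is.na(x$detection_limit)) "NA" else sprintf("%.1f%%", x$detection_limit)))
  invisible(x)
}

#' @rdname fit_plsr_cv
#' @param x A `pls_result`.
#' @method tidy pls_result
#' @export
tidy.pls_result <- function(x, ...) {
  x$predictions
}

#' @rdname fit_plsr_cv
#' @method glance pls_result
#' @export
glance.pls_result <- function(x, ...) {
  tibble::tibble(series = x$series %||% NA_character_,
                 modality = x$modality %||% NA_character_,
                 n = x$n, n_components = x$n_components,
                 r2 = x$r2, rmsep = x$rmsep, rmsep_range = x$rmsep_range,
                 blank_mean = x$blank_mean, blank_sd = x$blank_sd,
                 detection_limit = x$detection_limit)
}

#' Run the PLSR quantification suite over series and modalities
#'
#' Fits [fit_plsr_cv()] for every adulteration series present in the
#' dataset's design (Mexican: AC, AR, AS, A all, BC, BR, BS, B all;
#' Kenyan: U .. Z) and every requested modality. Mexican series use
#' components 1..32; Kenyan series use 3..min(10, n - 2) (sample-size
#' limited).
#'
#' @param dataset A `spectra_dataset`.
#' @param modalities Character vector of analysis modalities (default all
#'   of `"fluo_raw"`, `"fluo_snv"`, `"nir"`, `"raman"`, `"fused"`).
#' @param series `"all"` (inferred from the design) or a character vector
#'   of series ids.
#' @param ncomp_max Upper component bound for Mexican series (default 32).
#' @return A tibble with one row per (series, modality):
#'   `series`, `modality`, `n`, `n_components`, `r2`, `rmsep`,
#'   `rmsep_range`, `blank_mean`, `blank_sd`, `detection_limit`.
#' @export
run_quantification_suite <- function(dataset, modalities = modality_choices,
                                     series = "all", ncomp_max = 32) {
  labels <- unique(dataset$sample_label)
  if (identical(series, "all")) {
    series <- character(0)
    if ("A100" %in% labels) series <- c(series, "AC", "AR", "AS", "A all",
                                        "BC", "BR", "BS", "B all")
    if ("U100" %in% labels) series <- c(series, "U", "V", "W", "X", "Y", "Z")
    if (length(series) == 0) abort("No known quantification series in dataset.")
  }
  rows <- list()
  for (mod in modalities) {
    features <- preprocess_dataset(dataset, mod)
    for (s in series) {
      task <- plsr_task(features, s)
      kenyan <- s %in% c("U", "V", "W", "X", "Y", "Z")
      res <- if (kenyan) {
        fit_plsr_cv(task, ncomp_min = 3, ncomp_max = min(10, nrow(task) - 2))
      } else {
        fit_plsr_cv(task, ncomp_min = 1, ncomp_max = ncomp_max)
      }
      rows[[length(rows) + 1]] <- glance(res)
    }
  }
  dplyr::bind_rows(rows)
}
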