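#' Derivative-cumsum baseline correction
#'
#' Removes slowly varying background from a spectrum by subtracting the
#' cumulative sum of the smoothed first differences:
#' the first differences of the intensities are smoothed with a centered
#' moving average (span `window`, forced down to the next odd value, with
#' symmetric shrinking windows at the ends), cumulated, and subtracted with
#' a one-point offset so that the first intensity stays anchored:
#' `out[1] = I[1]`, `out[k] = I[k] - c[k-1]` for `k >= 2` where
#' `c = cumsum(smooth(diff(I)))`. Any affine trend in the spectrum is
#' mapped to a constant.
#'
#' @param x Numeric intensity vector (length >= `window + 2`, no `NA`).
#' @param window Nominal smoothing span (default 20; effective span 19).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' baseline_correct(2 * (1:100))  # slope removed: constant 2
#' @export
baseline_correct <- function(x, window = 20) {
  if (anyNA(x) || any(!is.finite(x))) abort("`x` must not contain NA/NaN/Inf.")
  n <- length(x)
  if (n < window + 2) {
    abort(sprintf("Input length %d is below the minimum %d (window + 2).",
                  n, window + 2))
  }
  d <- diff(x)
  s <- moving_average_shrink(d, span = window)
  c_ <- cumsum(s)
  x - c(0, c_)
}

## centered moving average with span forced odd and symmetric shrinking
## endpoint windows: at index i the half-width is min((span-1)/2, i-1, m-i)
moving_average_shrink <- function(y, span) {
  span <- as.integer(span)
  if (span %% 2 == 0) span <- span - 1L
  span <- max(span, 1L)
  m <- length(y)
  h <- pmin((span - 1L) %/% 2L, seq_len(m) - 1L, m - seq_len(m))
  cs <- c(0, cumsum(y))
  i <- seq_len(m)
  (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
}

#' Standard normal variate transformation
#'
#' Centers and scales a single spectrum to zero mean and unit standard
#' deviation (sample SD, `n - 1` denominator):
#' `(x - mean(x)) / sd(x)`.
#'
#' @param x Numeric vector with positive standard deviation.
#' @return Numeric vector with mean 0 and SD 1 (within 1e-9).
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (anyNA(x) || any(!is.finite(x))) abort("`x` must not contain NA/NaN/Inf.")
  s <- sd(x)
  if (!is.finite(s) || s <= 0) {
    abort("Degenerate spectrum: standard deviation is zero, SNV undefined.")
  }
  (x - mean(x)) / s
}

#' Flatten / restore an excitation-emission matrix
#'
#' An EEM is stored as a matrix with rows = excitation, columns = emission.
#' Flattening concatenates rows in ascending excitation order with ascending
#' emission inside (so element `(ex index 2, em index 1)` of a 26 x 36 EEM
#' lands at flattened position 37). `unflatten_eem()` inverts it exactly.
#'
#' @param E EEM matrix, `length(grid$excitation)` x `length(grid$emission)`.
#' @param v Flattened EEM vector.
#' @param grid A fluorescence [axis_grid].
#' @return `flatten_eem()`: numeric vector of length `n_ex * n_em`;
#'   `unflatten_eem()`: the matrix.
#' @export
flatten_eem <- function(E, grid = fluorescence_grid()) {
  n_ex <- length(grid$excitation)
  n_em <- length(grid$emission)
  if (!is.matrix(E) || nrow(E) != n_ex || ncol(E) != n_em) {
    abort(sprintf("EEM shape %s does not match grid %d x %d.",
                  paste(dim(E), collapse = " x "), n_ex, n_em))
  }
  as.vector(t(E))
}

#' @rdname flatten_eem
#' @export
unflatten_eem <- function(v, grid = fluorescence_grid()) {
  n_ex <- length(grid$excitation)
  n_em <- length(grid$emission)
  if (length(v) != n_ex * n_em) {
    abort(sprintf("Vector length %d does not match grid %d x %d.",
                  length(v), n_ex, n_em))
  }
  matrix(v, nrow = n_ex, ncol = n_em, byrow = TRUE)
}

#' Modality-specific preprocessing of one spectrum
#'
#' NIR and Raman spectra are baseline-corrected ([baseline_correct()]) and
#' then SNV-scaled ([snv()]). Fluorescence is returned unchanged in
#' single-modality analyses (`snv_fluorescence = FALSE`, the default); SNV
#' scaling of fluorescence is applied at fusion time, or here on request
#' for the "fluorescence with preprocessing" variant.
#'
#' @param x Numeric intensity vector.
#' @param modality `"fluorescence"`, `"nir"` or `"raman"`.
#' @param window Baseline-correction span, see [baseline_correct()].
#' @param snv_fluorescence Apply SNV to fluorescence too?
#' @return Numeric vector of the same length, with attribute `provenance`
#'   listing the applied steps.
#' @export
preprocess_modality <- function(x, modality = c("fluorescence", "nir", "raman"),
                                window = 20, snv_fluorescence = FALSE) {
  modality <- match.arg(modality)
  if (modality == "fluorescence") {
    if (snv_fluorescence) {
      out <- snv(x)
      attr(out, "provenance") <- "snv"
    } else {
      out <- x
      attr(out, "provenance") <- character(0)
    }
  } else {
    out <- snv(baseline_correct(x, window = window))
    attr(out, "provenance") <- c("baseline_correct", "snv")
  }
  out
}

#' Low-level fusion of the three modality blocks
#'
#' Concatenates, in fixed order, the SNV-scaled fluorescence vector, the
#' preprocessed NIR vector and the preprocessed Raman vector of one
#' measurement into a single fused spectrum. The fluorescence block is
#' SNV-scaled here so its intensity scale matches the SNV-scaled NIR and
#' Raman blocks. Zero-based block offsets are recorded in the `offsets`
#' attribute (`c(fluorescence = 0, nir = 936, raman = 1070)` on default
#' grids; total length 2751).
#'
#' @param fluo Raw fluorescence vector (flattened EEM).
#' @param nir,raman Preprocessed NIR / Raman vectors.
#' @return Numeric vector with attributes `offsets` (0-based block starts)
#'   and `blocks` (tibble with block, start, length; 1-based starts).
#' @export
fuse_spectra <- function(fluo, nir, raman) {
  if (is.null(fluo) || is.null(nir) || is.null(raman) ||
      length(fluo) == 0 || length(nir) == 0 || length(raman) == 0) {
    abort("All three blocks (fluorescence, NIR, Raman) are required for fusion.")
  }
  out <- c(snv(fluo), nir, raman)
  len <- c(fluorescence = length(fluo), nir = length(nir), raman = length(raman))
  start1 <- cumsum(c(1, unname(len[-3])))
  attr(out, "offsets") <- setNames(start1 - 1, names(len))
  attr(out, "blocks") <- tibble::tibble(
    block = names(len), start = start1, length = unname(len)
  )
  out
}

## analysis modality vocabulary: single-instrument views and the fused view
modality_choices <- c("fluo_raw", "fluo_snv", "nir", "raman", "fused")

normalize_modality <- function(modality) {
  aliases <- c(fluorescence = "fluo_raw", fluo = "fluo_raw",
               combined = "fused", setNames(modality_choices, modality_choices))
  if (!modality %in% names(aliases)) {
    abort(sprintf("Unknown modality '%s'; expected one of %s.",
                  modality, paste(modality_choices, collapse = ", ")))
  }
  unname(aliases[modality])
}

#' Preprocess a dataset into a feature table
#'
#' Applies the full preprocessing recipe to every measurement of a
#' [generate_dataset()] result and returns one feature row per measurement:
#' `"fluo_raw"` (raw flattened EEM), `"fluo_snv"` (SNV-scaled EEM),
#' `"nir"` / `"raman"` (baseline-corrected + SNV), or `"fused"`
#' (SNV fluorescence + preprocessed NIR + preprocessed Raman, 2751 points
#' on default grids). `"fluorescence"` is accepted as an alias of
#' `"fluo_raw"`.
#'
#' @param dataset A `spectra_dataset`.
#' @param modality One of `"fluo_raw"`, `"fluo_snv"`, `"nir"`, `"raman"`,
#'   `"fused"`.
#' @param window Baseline-correction span.
#' @return A tibble with columns `sample_label`, `preparation`,
#'   `measurement` and matrix column `x` (one spectrum per row); attribute
#'   `modality`, and `blocks` for fused output.
#' @export
preprocess_dataset <- function(dataset, modality = "fused", window = 20) {
  modality <- normalize_modality(modality)
  wide <- tidyr::pivot_wider(tibble::as_tibble(dataset),
                             names_from = "modality", values_from = "intensity")
  need <- switch(modality,
    fluo_raw = "fluorescence", fluo_snv = "fluorescence",
    nir = "nir", raman = "raman",
    fused = c("fluorescence", "nir", "raman"))
  miss <- setdiff(need, names(wide))
  if (length(miss) > 0) {
    abort(sprintf("Dataset is missing modality block(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  blocks <- NULL
  rows <- switch(modality,
    fluo_raw = wide$fluorescence,
    fluo_snv = lapply(wide$fluorescence, snv),
    nir = lapply(wide$nir, function(v) preprocess_modality(v, "nir", window)),
    raman = lapply(wide$raman, function(v) preprocess_modality(v, "raman", window)),
    fused = lapply(seq_len(nrow(wide)), function(i) {
      fuse_spectra(wide$fluorescence[[i]],
                   preprocess_modality(wide$nir[[i]], "nir", window),
                   preprocess_modality(wide$raman[[i]], "raman", window))
    })
  )
  if (modality == "fused") blocks <- attr(rows[[1]], "blocks")
  x <- do.call(rbind, lapply(rows, as.vector))
  out <- tibble::tibble(
    sample_label = wide$sample_label,
    preparation = wide$preparation,
    measurement = wide$measurement,
    x = x
  )
  attr(out, "modality") <- modality
  attr(out, "blocks") <- blocks
  attr(out, "design") <- attr(dataset, "design")
  out
}
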