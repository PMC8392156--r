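#' Plot spectra, confusion matrices and PLSR fits
#'
#' `autoplot()` methods for the main result types:
#' \itemize{
#'   \item `spectra_dataset`: NIR/Raman spectra as intensity traces
#'     coloured by sample label (`modality = "nir"` or `"raman"`), or the
#'     mean EEM of each label as an excitation x emission heat map
#'     (`modality = "fluorescence"`);
#'   \item `classification_run`: the row-normalized confusion matrix as a
#'     heat map with percentage labels;
#'   \item `pls_result`: cross-validated predictions against reference
#'     adulteration levels with the identity line.
#' }
#'
#' @param object The object to plot.
#' @param modality For datasets: which modality to show.
#' @param max_labels For datasets: show at most this many sample labels.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name oilspec-autoplot
NULL

#' @rdname oilspec-autoplot
#' @method autoplot spectra_dataset
#' @export
autoplot.spectra_dataset <- function(object, modality = "raman",
                                     max_labels = 8, ...) {
  grids <- attr(object, "grids")
  labs_keep <- head(unique(object$sample_label), max_labels)
  sub <- object[object$modality == modality &
                  object$sample_label %in% labs_keep, ]
  if (modality == "fluorescence") {
    g <- grids$fluorescence
    df <- sub |>
      dplyr::group_by(.data$sample_label) |>
      dplyr::summarise(intensity = list(Reduce(`+`, .data$intensity) /
                                          dplyr::n()), .groups = "drop") |>
      dplyr::mutate(grid = list(tidyr::expand_grid(excitation = g$excitation,
                                                   emission = g$emission))) |>
      tidyr::unnest(c("grid", "intensity"))
    ggplot2::ggplot(df, ggplot2::aes(.data$emission, .data$excitation,
                                     fill = .data$intensity)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~sample_label) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "emission [nm]", y = "excitation [nm]",
                    fill = "intensity")
  } else {
    axis <- if (modality == "nir") grids$nir$wavelength else grids$raman$shift
    df <- sub |>
      dplyr::mutate(spectrum_id = paste(.data$sample_label, .data$preparation,
                                        .data$measurement, sep = "/"),
                    axis = list(axis)) |>
      tidyr::unnest(c("axis", "intensity"))
    ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$intensity,
                                     group = .data$spectrum_id,
                                     colour = .data$sample_label)) +
      ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
      ggplot2::labs(x = if (modality == "nir") "wavelength [nm]"
                    else expression("Raman shift [" * cm^-1 * "]"),
                    y = "intensity", colour = "sample")
  }
}

#' @rdname oilspec-autoplot
#' @method autoplot classification_run
#' @export
autoplot.classification_run <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    true = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    n = as.vector(cm),
    pct = as.vector(100 * cm / rowSums(cm))
  )
  lev <- rownames(cm)
  df$true <- factor(df$true, levels = rev(lev))
  df$predicted <- factor(df$predicted, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("%s: TPR %.1f%%", object$method,
                                  object$metrics$tpr),
                  x = "predicted class", y = "true class", fill = "% of row")
}

#' @rdname oilspec-autoplot
#' @method autoplot pls_result
#' @export
autoplot.pls_result <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$.fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      title = sprintf("%s (%s): %d components, R2 = %.3f, RMSEP_range = %.2f%%",
                      object$series %||% "PLSR", object$modality %||% "",
                      object$n_components, object$r2, object$rmsep_range),
      x = "reference adulteration [mass %]",
      y = "LOO-CV predicted adulteration [mass %]")
}
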