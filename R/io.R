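#' Write / read a spectra dataset as wide CSV files
#'
#' `write_spectra_csv()` writes one wide CSV per modality
#' (`fluorescence.csv`, `nir.csv`, `raman.csv`; header row = axis values,
#' fluorescence columns named `ex<nm>_em<nm>`, one row per measured
#' spectrum, preceded by `sample_label`, `preparation`, `measurement`
#' columns) plus a `metadata.csv` sidecar with the sample label, the blend
#' composition as a JSON string, and the preparation / measurement indices.
#' `read_spectra_csv()` reconstructs the `spectra_dataset`, including grids
#' (parsed from the headers) and design (from the metadata).
#'
#' @param dataset A `spectra_dataset`.
#' @param dir Output / input directory.
#' @return `write_spectra_csv()`: the directory, invisibly.
#'   `read_spectra_csv()`: a `spectra_dataset`.
#' @export
write_spectra_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grids <- attr(dataset, "grids")
  design <- attr(dataset, "design")
  for (mod in c("fluorescence", "nir", "raman")) {
    sub <- dataset[dataset$modality == mod, ]
    if (nrow(sub) == 0) next
    m <- do.call(rbind, sub$intensity)
    colnames(m) <- grid_point_names(grids[[mod]])
    df <- dplyr::bind_cols(
      tibble::tibble(sample_label = sub$sample_label,
                     preparation = sub$preparation,
                     measurement = sub$measurement),
      tibble::as_tibble(m)
    )
    readr::write_csv(df, file.path(dir, paste0(mod, ".csv")))
  }
  meta <- dataset |>
    dplyr::distinct(.data$sample_label, .data$preparation, .data$measurement)
  blends <- setNames(lapply(design$blend, function(b)
    jsonlite::toJSON(as.list(unclass(b)), auto_unbox = TRUE)), design$label)
  meta$blend <- as.character(blends[meta$sample_label])
  readr::write_csv(
    meta[, c("sample_label", "blend", "preparation", "measurement")],
    file.path(dir, "metadata.csv"))
  invisible(dir)
}

parse_grid_from_names <- function(nms, modality) {
  if (modality == "fluorescence") {
    ex <- as.numeric(sub("^ex([0-9.]+)_em[0-9.]+$", "\\1", nms))
    em <- as.numeric(sub("^ex[0-9.]+_em([0-9.]+)$", "\\1", nms))
    fluorescence_grid(excitation = sort(unique(ex)), emission = sort(unique(em)))
  } else if (modality == "nir") {
    nir_grid(wavelength = as.numeric(nms))
  } else {
    raman_grid(shift = as.numeric(nms))
  }
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  grids <- list()
  parts <- list()
  for (mod in c("fluorescence", "nir", "raman")) {
    path <- file.path(dir, paste0(mod, ".csv"))
    if (!file.exists(path)) next
    df <- readr::read_csv(path, show_col_types = FALSE)
    value_cols <- setdiff(names(df), c("sample_label", "preparation", "measurement"))
    grids[[mod]] <- parse_grid_from_names(value_cols, mod)
    m <- as.matrix(df[, value_cols])
    parts[[mod]] <- tibble::tibble(
      sample_label = df$sample_label,
      preparation = as.integer(df$preparation),
      measurement = as.integer(df$measurement),
      modality = mod,
      intensity = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    )
  }
  out <- dplyr::bind_rows(parts) |>
    dplyr::arrange(.data$sample_label, .data$preparation, .data$measurement)
  design_meta <- meta |>
    dplyr::group_by(.data$sample_label, .data$blend) |>
    dplyr::summarise(n_preparations = dplyr::n_distinct(.data$preparation),
                     .groups = "drop")
  design <- new_design(
    design_meta$sample_label,
    lapply(design_meta$blend, function(j) do.call(oil_blend, jsonlite::fromJSON(j))),
    design_meta$n_preparations, region = "file")
  structure(out, grids = grids, design = design,
            class = c("spectra_dataset", class(tibble::tibble())))
}
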