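#' Instrument axis grids
#'
#' An `axis_grid` declares the measurement axis of one spectroscopic
#' modality: the excitation x emission wavelength lattice of a fluorescence
#' EEM, the wavelength axis of a NIR spectrum (nm), or the Raman shift axis
#' (cm^-1). The defaults reproduce the acquisition settings the pipeline
#' assumes throughout: a 26 x 36 = 936-point EEM (excitation 300-550 nm,
#' emission 350-700 nm, 10 nm steps), a 134-point NIR axis (800-2795 nm,
#' 15 nm steps) and a 1681-point Raman axis spanning 350-3200 cm^-1, so that
#' a fused spectrum has 936 + 134 + 1681 = 2751 points.
#'
#' @param excitation,emission Excitation / emission wavelengths in nm
#'   (strictly increasing).
#' @param wavelength NIR wavelengths in nm (strictly increasing).
#' @param shift Raman shifts in cm^-1 (strictly increasing).
#' @return An object of class `axis_grid` with elements `modality` and the
#'   axis values; for fluorescence, `excitation`, `emission` and the flattened
#'   pair order (excitation outer, emission inner).
#' @examples
#' g <- default_grids()
#' n_points(g$fluorescence)  # 936
#' n_points(g$nir) + n_points(g$raman) + n_points(g$fluorescence)  # 2751
#' @name axis_grid
NULL

new_axis_grid <- function(modality, ...) {
  structure(c(list(modality = modality), list(...)), class = "axis_grid")
}

check_increasing <- function(x, what) {
  if (length(x) < 2 || any(!is.finite(x)) || any(diff(x) <= 0)) {
    abort(sprintf("`%s` must be a finite, strictly increasing vector of length >= 2.", what))
  }
  invisible(x)
}

#' @rdname axis_grid
#' @export
fluorescence_grid <- function(excitation = seq(300, 550, by = 10),
                              emission = seq(350, 700, by = 10)) {
  check_increasing(excitation, "excitation")
  check_increasing(emission, "emission")
  new_axis_grid("fluorescence", excitation = excitation, emission = emission)
}

#' @rdname axis_grid
#' @export
nir_grid <- function(wavelength = seq(800, 2795, by = 15)) {
  check_increasing(wavelength, "wavelength")
  new_axis_grid("nir", wavelength = wavelength)
}

#' @rdname axis_grid
#' @export
raman_grid <- function(shift = seq(350, 3200, length.out = 1681)) {
  check_increasing(shift, "shift")
  new_axis_grid("raman", shift = shift)
}

#' @rdname axis_grid
#' @export
default_grids <- function() {
  list(fluorescence = fluorescence_grid(), nir = nir_grid(), raman = raman_grid())
}

#' @rdname axis_grid
#' @param grid An `axis_grid`.
#' @export
n_points <- function(grid) {
  stopifnot(inherits(grid, "axis_grid"))
  switch(grid$modality,
    fluorescence = length(grid$excitation) * length(grid$emission),
    nir = length(grid$wavelength),
    raman = length(grid$shift)
  )
}

#' @export
print.axis_grid <- function(x, ...) {
  cat(sprintf("<axis_grid: %s, %d points>\n", x$modality, n_points(x)))
  invisible(x)
}

## column names used in the wide CSV form of each modality
grid_point_names <- function(grid) {
  switch(grid$modality,
    fluorescence = as.vector(t(outer(grid$excitation, grid$emission,
                                     function(ex, em) sprintf("ex%g_em%g", ex, em)))),
    nir = sprintf("%.12g", grid$wavelength),
    raman = sprintf("%.12g", grid$shift)
  )
}
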