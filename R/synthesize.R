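#' Instrument noise model
#'
#' Measurement variability is emulated by three components applied in a
#' fixed order to the noise-free mixture spectrum: (1) a multiplicative gain
#' `1 + e`, `e ~ N(0, multiplicative_sd)`, drawn once per modality and
#' measurement (detector/lamp intensity variation); (2) a smooth additive
#' baseline drift on NIR and Raman only, a random degree-2 polynomial with
#' coefficients `~ N(0, baseline_drift_sd)` (background/offset wander, the
#' component the derivative-cumsum baseline correction removes); (3)
#' independent additive Gaussian noise `N(0, additive_sd)` at every grid
#' point. All scales are in intensity units; rendered spectra are O(1), so
#' they can equally be read as relative scales. `additive_sd = 0` etc. turn
#' a component off. The same `seed` always yields bit-identical output.
#'
#' `noise_profile("default")` is the generator's stated operating point
#' (1 % gain variability, 0.5 % additive noise, 0.5 % baseline drift);
#' `noise_profile("clean")` disables all noise.
#'
#' @param additive_sd,multiplicative_sd,baseline_drift_sd Non-negative
#'   scales, see above.
#' @param seed Integer seed.
#' @return A list of class `noise_model`.
#' @examples
#' noise_profile("clean")
#' noise_model(additive_sd = 0.01, seed = 7)
#' @export
noise_model <- function(additive_sd = 0.005, multiplicative_sd = 0.01,
                        baseline_drift_sd = 0.005, seed = 1) {
  sc <- c(additive_sd = additive_sd, multiplicative_sd = multiplicative_sd,
          baseline_drift_sd = baseline_drift_sd)
  if (any(!is.finite(sc)) || any(sc < 0)) {
    abort("Noise scales must be finite and >= 0.")
  }
  structure(list(additive_sd = additive_sd,
                 multiplicative_sd = multiplicative_sd,
                 baseline_drift_sd = baseline_drift_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' @rdname noise_model
#' @param profile `"default"` or `"clean"`.
#' @export
noise_profile <- function(profile = c("default", "clean"), seed = 1) {
  profile <- match.arg(profile)
  switch(profile,
    default = noise_model(seed = seed),
    clean = noise_model(additive_sd = 0, multiplicative_sd = 0,
                        baseline_drift_sd = 0, seed = seed)
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model: additive %g, multiplicative %g, drift %g, seed %d>\n",
              x$additive_sd, x$multiplicative_sd, x$baseline_drift_sd, x$seed))
  invisible(x)
}

## noise-free linear mixture of rendered pure spectra
mix_pure <- function(blend, pure_list) {
  acc <- NULL
  for (oil in names(blend)) {
    part <- pure_list[[oil]]
    contrib <- lapply(part, function(p) unclass(blend)[[oil]] * p)
    acc <- if (is.null(acc)) contrib else Map(`+`, acc, contrib)
  }
  acc
}

## apply the noise model to one measurement using the *current* RNG stream;
## order: multiplicative gain, baseline drift (NIR/Raman), additive noise
apply_noise_stream <- function(spectra, noise, grids) {
  out <- spectra
  for (mod in c("eem", "nir", "raman")) {
    x <- out[[mod]]
    gain <- 1 + rnorm(1, 0, noise$multiplicative_sd)
    x <- x * gain
    if (mod %in% c("nir", "raman") && noise$baseline_drift_sd > 0) {
      axis <- if (mod == "nir") grids$nir$wavelength else grids$raman$shift
      x <- x + poly_baseline(rnorm(3, 0, noise$baseline_drift_sd), axis)
    }
    x <- x + rnorm(length(x), 0, noise$additive_sd)
    out[[mod]] <- x
  }
  out
}

#' Synthesize one measurement triple for a blend
#'
#' Renders the noise-free mixture spectrum (linear in mass fraction:
#' intensity at every grid point is the blend-weighted sum of the pure-oil
#' endmember intensities) and applies the noise model, in order:
#' multiplicative gain, smooth baseline drift (NIR/Raman only), additive
#' Gaussian noise. The RNG is seeded from `noise$seed`, so a fixed noise
#' model always produces an identical draw; vary `seed` for replicate draws.
#'
#' @param blend An [oil_blend()].
#' @param library An [endmember_library()].
#' @param grids Grids as from [default_grids()].
#' @param noise A [noise_model()].
#' @return List with `eem` (excitation x emission matrix), `nir`, `raman`.
#' @examples
#' lib <- endmember_library(1)
#' m <- synth_measurement(oil_blend(A = 0.9, S = 0.1), lib,
#'                        noise = noise_profile("clean"))
#' dim(m$eem)
#' @export
synth_measurement <- function(blend, library, grids = default_grids(),
                              noise = noise_profile("default")) {
  stopifnot(inherits(blend, "oil_blend"), inherits(library, "endmember_library"))
  missing_oils <- setdiff(names(blend), names(library))
  if (length(missing_oils) > 0) {
    abort(sprintf("Blend references unknown oil(s): %s.",
                  paste(missing_oils, collapse = ", ")))
  }
  pure <- lapply(setNames(names(blend), names(blend)),
                 function(oil) render_pure_spectrum(library, oil, grids))
  clean <- mix_pure(blend, pure)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  apply_noise_stream(clean, noise, grids)
}

#' Generate a full designed spectra dataset
#'
#' Produces, for every design row, `n_preparations` independently prepared
#' samples each measured `n_measurements` times on all three instruments.
#' One RNG stream is seeded from `noise$seed` and consumed in deterministic
#' order (design row, preparation, measurement), so the whole dataset is
#' bit-reproducible. Fluorescence EEMs are stored flattened (excitation
#' outer, emission inner; see [flatten_eem()]).
#'
#' @param design An [design_mexican()]-style design tibble.
#' @param library An [endmember_library()].
#' @param grids Grids as from [default_grids()].
#' @param noise A [noise_model()]; its `seed` drives all randomness.
#' @param n_measurements Repeat measurements per prepared sample (default 5).
#' @return A tibble of class `spectra_dataset`, one row per
#'   (label, preparation, measurement, modality), with the intensity vector
#'   in the `intensity` list-column; attributes `grids` and `design`.
#' @examples
#' d <- design_mexican()[1:2, ]
#' ds <- generate_dataset(d, endmember_library(1),
#'                        noise = noise_profile("clean"), n_measurements = 1)
#' nrow(ds) # 2 labels x 3 preparations x 1 measurement x 3 modalities
#' @export
generate_dataset <- function(design, library = endmember_library(1),
                             grids = default_grids(),
                             noise = noise_profile("default"),
                             n_measurements = 5) {
  if (!is.data.frame(design) || nrow(design) == 0) {
    abort("`design` must be a non-empty design tibble.")
  }
  stopifnot(n_measurements >= 1)
  oils <- unique(unlist(lapply(design$blend, names)))
  missing_oils <- setdiff(oils, names(library))
  if (length(missing_oils) > 0) {
    abort(sprintf("Design references unknown oil(s): %s.",
                  paste(missing_oils, collapse = ", ")))
  }
  pure <- lapply(setNames(oils, oils),
                 function(oil) render_pure_spectrum(library, oil, grids))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)

  rows <- vector("list", sum(design$n_preparations) * n_measurements)
  k <- 0L
  for (i in seq_len(nrow(design))) {
    clean <- mix_pure(design$blend[[i]], pure)
    for (prep in seq_len(design$n_preparations[i])) {
      for (meas in seq_len(n_measurements)) {
        noisy <- apply_noise_stream(clean, noise, grids)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          sample_label = design$label[i],
          preparation = prep, measurement = meas,
          modality = c("fluorescence", "nir", "raman"),
          intensity = list(as.vector(t(noisy$eem)), noisy$nir, noisy$raman)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, grids = grids, design = design,
            class = c("spectra_dataset", class(tibble::tibble())))
}

#' @export
print.spectra_dataset <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<spectra_dataset: %d spectra (%d per modality), %d design rows>\n",
              nrow(x), nrow(x) / 3L, if (is.null(d)) NA_integer_ else nrow(d)))
  NextMethod()
}
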