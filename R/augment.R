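#' Simulate spectra around a base set
#'
#' Class-balancing augmentation: new spectra are drawn by adding, at every
#' grid point `k`, the per-point standard deviation `SD(k)` of the base set
#' times an independent standard-normal number to either the per-point mean
#' `m(k)` ("mean-based" rows) or to one of the original base rows
#' ("original-based" rows, cycled in order). `SD(k)` uses the sample
#' (n - 1) denominator. With a degenerate base (`SD(k) = 0` everywhere) the
#' simulated rows equal their base rows exactly.
#'
#' @param base Numeric matrix, one base spectrum per row (>= 1 row).
#' @param n_mean_based Number of mean-perturbed rows to simulate.
#' @param n_original_based Number of original-perturbed rows to simulate.
#' @param seed Optional integer; when supplied the RNG is seeded locally,
#'   otherwise the current stream is used.
#' @return Matrix with `n_mean_based + n_original_based` rows, mean-based
#'   first; attribute `source` tags each row `"simulated_mean"` /
#'   `"simulated_original"`.
#' @examples
#' base <- matrix(rnorm(60), nrow = 6)
#' sim <- simulate_spectra(base, 5, 5, seed = 1)
#' dim(sim)
#' @export
simulate_spectra <- function(base, n_mean_based, n_original_based, seed = NULL) {
  if (!is.matrix(base) || nrow(base) == 0) {
    abort("`base` must be a non-empty matrix of spectra (rows).")
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  p <- ncol(base)
  m <- colMeans(base)
  sdv <- if (nrow(base) > 1) apply(base, 2, sd) else rep(0, p)
  n_total <- n_mean_based + n_original_based
  out <- matrix(0, n_total, p)
  if (n_mean_based > 0) {
    out[seq_len(n_mean_based), ] <-
      rep(m, each = n_mean_based) +
      matrix(rnorm(n_mean_based * p), n_mean_based, p) * rep(sdv, each = n_mean_based)
  }
  if (n_original_based > 0) {
    idx <- rep_len(seq_len(nrow(base)), n_original_based)
    out[n_mean_based + seq_len(n_original_based), ] <-
      base[idx, , drop = FALSE] +
      matrix(rnorm(n_original_based * p), n_original_based, p) * rep(sdv, each = n_original_based)
  }
  attr(out, "source") <- rep(c("simulated_mean", "simulated_original"),
                             c(n_mean_based, n_original_based))
  out
}

## label membership of the five classification classes (Mexican design)
class_members <- function() {
  adult_series <- function(chia) {
    c(as.vector(outer(paste0(chia, c("S", "R", "C")), c(90, 95, 98, 99), paste0)),
      paste0(chia, c("S", "R", "C"), "50"))
  }
  list(
    A = "A100",
    AdultA = adult_series("A"),
    B = "B100",
    AdultB = adult_series("B"),
    Adult = c("S100", "R100", "C100", "RS50", "RC50", "SC50")
  )
}

#' Assemble the balanced 5-class classification set
#'
#' Builds the 1125-spectra, 5 x 225 classification table from the
#' (preprocessed) Mexican dataset:
#' \itemize{
#'   \item `A` / `B`: the 15 real pure-oil spectra (3 preparations x 5
#'     measurements) used five times (15 real + 60 replicated rows) plus
#'     150 simulated rows (75 mean-based + 75 original-based, via
#'     [simulate_spectra()]) = 225;
#'   \item `AdultA` / `AdultB`: the 15 adulterated labels (12 low-level
#'     adulterations + the three 50:50 blends) x 15 real spectra = 225;
#'   \item `Adult`: the 90 real spectra of S100, R100, C100, RS50, RC50,
#'     SC50, plus 90 simulated from the pure S, R, C spectra (15 mean-based
#'     + 15 original-based per oil) and one extra copy of the 45 pure
#'     S/R/C spectra = 225.
#' }
#' Augmentation operates on already-preprocessed spectra; the assembly is a
#' pure function of `(dataset, modality, seed)`.
#'
#' @param dataset A `spectra_dataset` containing the Mexican design with 5
#'   measurements per preparation, or a feature table from
#'   [preprocess_dataset()].
#' @param modality Analysis modality passed to [preprocess_dataset()].
#' @param seed Integer seed for the simulation draws.
#' @return A tibble of class `labeled_dataset` with columns `class`
#'   (factor A, AdultA, B, AdultB, Adult), `source` (real / replicated /
#'   simulated_mean / simulated_original), `sample_label`, and matrix
#'   column `x`; 1125 rows, 225 per class.
#' @export
assemble_classification_set <- function(dataset, modality = "fused", seed = 1) {
  features <- if (inherits(dataset, "spectra_dataset")) {
    preprocess_dataset(dataset, modality)
  } else dataset
  members <- class_members()
  needed <- unique(unlist(members))
  miss <- setdiff(needed, unique(features$sample_label))
  if (length(miss) > 0) {
    abort(sprintf("Dataset is missing design label(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  counts <- table(features$sample_label[features$sample_label %in% needed])
  if (any(counts != 15)) {
    abort(paste("The 5-class assembly requires 15 spectra per design label",
                "(3 preparations x 5 measurements)."))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  take <- function(labels) {
    idx <- which(features$sample_label %in% labels)
    idx <- idx[order(match(features$sample_label[idx], labels),
                     features$preparation[idx], features$measurement[idx])]
    list(x = features$x[idx, , drop = FALSE], label = features$sample_label[idx])
  }
  part <- function(class_id, x, label, source) {
    tibble::tibble(class = class_id, source = source, sample_label = label, x = x)
  }

  pure_class <- function(class_id) {
    re <- take(members[[class_id]])          # 15 real spectra
    sim <- simulate_spectra(re$x, 75, 75)    # uses the assembly stream
    rep_idx <- rep(seq_len(nrow(re$x)), 4)   # originals used five times in all
    dplyr::bind_rows(
      part(class_id, re$x, re$label, "real"),
      part(class_id, re$x[rep_idx, , drop = FALSE], re$label[rep_idx], "replicated"),
      part(class_id, sim, rep(re$label[1], nrow(sim)), attr(sim, "source"))
    )
  }
  adult_sub_class <- function(class_id) {
    re <- take(members[[class_id]])          # 15 labels x 15 = 225 real
    part(class_id, re$x, re$label, "real")
  }
  adult_class <- function() {
    re <- take(members$Adult)                # 90 real
    sims <- lapply(c("S100", "R100", "C100"), function(lab) {
      s <- simulate_spectra(take(lab)$x, 15, 15)
      part("Adult", s, rep(lab, nrow(s)), attr(s, "source"))
    })
    pure <- take(c("S100", "R100", "C100")) # 45 replication spectra
    dplyr::bind_rows(
      part("Adult", re$x, re$label, "real"),
      dplyr::bind_rows(sims),
      part("Adult", pure$x, pure$label, "replicated")
    )
  }

  out <- dplyr::bind_rows(
    pure_class("A"), adult_sub_class("AdultA"),
    pure_class("B"), adult_sub_class("AdultB"),
    adult_class()
  )
  out$class <- factor(out$class, levels = c("A", "AdultA", "B", "AdultB", "Adult"))
  attr(out, "modality") <- attr(features, "modality")
  class(out) <- c("labeled_dataset", class(tibble::tibble()))
  out
}
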