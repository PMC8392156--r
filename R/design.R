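#' Oil blends
#'
#' An `oil_blend` is a named vector of mass fractions over the endmember
#' oil library (chia oils `A`, `B`, `U`--`Z`; adulterants sunflower `S`,
#' rapeseed `R`, corn `C`). Fractions must be in `[0, 1]` and sum to 1
#' within `1e-12`.
#'
#' @param ... Named fractions, e.g. `oil_blend(A = 0.9, S = 0.1)`.
#' @return A named numeric vector of class `oil_blend`.
#' @examples
#' oil_blend(A = 0.95, S = 0.05)
#' @export
oil_blend <- function(...) {
  fr <- c(...)
  if (length(fr) == 0 || is.null(names(fr)) || any(names(fr) == "")) {
    abort("All blend components must be named mass fractions.")
  }
  if (anyDuplicated(names(fr))) abort("Duplicated oil ids in blend.")
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    abort("Blend fractions must be finite and in [0, 1].")
  }
  if (abs(sum(fr) - 1) > 1e-12) {
    abort(sprintf("Blend fractions must sum to 1 (got %.15g).", sum(fr)))
  }
  structure(fr, class = "oil_blend")
}

#' @export
format.oil_blend <- function(x, ...) {
  paste(sprintf("%s:%g%%", names(x), 100 * unclass(x)), collapse = " ")
}

#' @export
print.oil_blend <- function(x, ...) {
  cat("<oil_blend>", format(x), "\n")
  invisible(x)
}

new_design <- function(label, blend, n_preparations, region) {
  stopifnot(!anyDuplicated(label))
  out <- tibble::tibble(
    label = label,
    blend = blend,
    n_preparations = as.integer(n_preparations)
  )
  structure(out, region = region,
            class = c("oil_design", class(out)))
}

## labels like "AS90" -> 90% first oil, 10% second oil; "A100" -> pure A
blend_from_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])([A-Z]?)([0-9]+)$", label))[[1]]
  pct <- as.numeric(m[4]) / 100
  args <- if (m[3] == "") {
    setNames(list(pct), m[2]) # pure oil, pct must be 1
  } else {
    setNames(list(pct, 1 - pct), c(m[2], m[3]))
  }
  do.call(oil_blend, args)
}

#' Blend designs for the adulteration experiments
#'
#' `design_mexican()` returns the 38-row design for the two Mexican chia
#' oils (A, B): the 5 native oils, 12 A-series and 12 B-series adulterations
#' with sunflower (S), rapeseed (R) and corn (C) at 1/2/5/10 mass %, and 9
#' additional 50:50 combinations; every row is prepared in triplicate, giving
#' 114 prepared samples. `design_kenyan()` returns the 17-row design for the
#' six Kenyan chia oils (U--Z) adulterated with sunflower at 10/50 mass %;
#' the rows U100, X100, US90, US50, WS50 and XS90 are prepared once, all
#' others twice, giving 28 prepared samples. `design_both()` binds the two
#' (142 prepared samples).
#'
#' @return A tibble of class `oil_design` with columns `label`, `blend`
#'   (list of [oil_blend()]) and `n_preparations`.
#' @examples
#' d <- design_mexican()
#' nrow(d)                      # 38
#' sum(d$n_preparations)        # 114
#' d$blend[[match("AS90", d$label)]]
#' @export
design_mexican <- function() {
  native <- c("A100", "B100", "S100", "R100", "C100")
  series <- as.vector(outer(c("AS", "AR", "AC", "BS", "BR", "BC"),
                            c(90, 95, 98, 99), paste0))
  extra <- c("RS50", "RC50", "SC50", "AS50", "AR50", "AC50",
             "BS50", "BR50", "BC50")
  labels <- c(native, series, extra)
  new_design(labels, lapply(labels, blend_from_label),
             n_preparations = 3L, region = "mexican")
}

#' @rdname design_mexican
#' @export
design_kenyan <- function() {
  chias <- c("U", "V", "W", "X", "Y", "Z")
  mixes <- as.vector(t(outer(chias, c("S90", "S50"), paste0)))
  labels <- c(paste0(chias, "100"), setdiff(mixes, "WS90")) # W has no 90:10 blend
  once <- c("U100", "X100", "US90", "US50", "WS50", "XS90")
  new_design(labels, lapply(labels, blend_from_label),
             n_preparations = ifelse(labels %in% once, 1L, 2L),
             region = "kenyan")
}

#' @rdname design_mexican
#' @export
design_both <- function() {
  m <- design_mexican()
  k <- design_kenyan()
  out <- dplyr::bind_rows(m, k)
  structure(out, region = "both", class = c("oil_design", class(tibble::tibble())))
}
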