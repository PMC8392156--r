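# Independent oracles and small fixtures shared across the test files.
# The oracles are deliberately written as naive loops, separate from the
# vectorized library routines they check.

# literal transcription of the derivative-cumsum baseline correction:
# first differences, centered moving average with span forced odd and
# symmetric shrinking end windows, running sum subtracted with the first
# point anchored
baseline_oracle <- function(x, window = 20) {
  n <- length(x)
  d <- numeric(n - 1)
  for (k in 2:n) d[k - 1] <- x[k] - x[k - 1]
  span <- if (window %% 2 == 0) window - 1 else window
  h0 <- (span - 1) / 2
  m <- length(d)
  s <- numeric(m)
  for (i in 1:m) {
    h <- min(h0, i - 1, m - i)
    s[i] <- mean(d[(i - h):(i + h)])
  }
  out <- numeric(n)
  out[1] <- x[1]
  acc <- 0
  for (k in 2:n) {
    acc <- acc + s[k - 1]
    out[k] <- x[k] - acc
  }
  out
}

# per-class tally oracle for confusion-matrix metrics: expands the matrix
# into individual (true, predicted) records and counts TP/TN/FP/FN per class
metrics_oracle <- function(cm) {
  K <- nrow(cm)
  # expand cell counts into individual (true, predicted) records
  true <- integer(0); pred <- integer(0)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    true <- c(true, rep(i, cm[i, j]))
    pred <- c(pred, rep(j, cm[i, j]))
  }
  out <- data.frame(class = seq_len(K), sensitivity = NA_real_,
                    specificity = NA_real_, precision = NA_real_,
                    accuracy = NA_real_)
  for (k in seq_len(K)) {
    tp <- sum(true == k & pred == k)
    fn <- sum(true == k & pred != k)
    fp <- sum(true != k & pred == k)
    tn <- sum(true != k & pred != k)
    out$sensitivity[k] <- 100 * tp / (tp + fn)
    out$specificity[k] <- 100 * tn / (tn + fp)
    out$precision[k] <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
    out$accuracy[k] <- 100 * (tp + tn) / (tp + tn + fp + fn)
  }
  out$tpr <- 100 * sum(true == pred) / length(true)
  out
}

# reduced grids: same structure as the instrument defaults, far fewer points
tiny_grids <- function() {
  list(
    fluorescence = fluorescence_grid(excitation = seq(300, 550, by = 50),
                                     emission = seq(350, 700, by = 50)),
    nir = nir_grid(wavelength = seq(800, 2800, length.out = 40)),
    raman = raman_grid(shift = seq(350, 3200, length.out = 45))
  )
}

# small Mexican dataset on the reduced grids (full design, 5 measurements)
tiny_mexican <- function(seed = 1, noise = "default") {
  generate_dataset(design_mexican(), endmember_library(1), tiny_grids(),
                   noise_profile(noise, seed = seed), n_measurements = 5)
}

# well-separated 5-class Gaussian data for classifier sanity checks
separable_classes <- function(n_per = 40, p = 10, gap = 25, seed = 42) {
  set.seed(seed)
  K <- 5
  x <- do.call(rbind, lapply(seq_len(K), function(k) {
    centre <- rep(0, p)
    centre[k] <- gap
    matrix(rnorm(n_per * p), n_per, p) + rep(centre, each = n_per)
  }))
  tibble::tibble(class = factor(rep(LETTERS[1:K], each = n_per)), x = x)
}
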