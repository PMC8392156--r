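## Classifier primitives.
##
## The five methods mirror the usual point-and-click presets for this kind
## of chemometric work: a CART-style Gini decision tree (max 100 splits),
## pooled-covariance linear discriminant analysis with a ridge term (the
## p >> n spectra make plain LDA singular), 1-nearest-neighbour with
## Euclidean distance, and one-vs-one soft-margin SVMs with linear and
## cubic-polynomial kernels on standardized inputs. All tie-breaks
## (kNN votes, score argmax, SVM voting) resolve to the lowest class index.

#' Fit one of the five classifiers
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Factor of class labels.
#' @param method `"DT"`, `"LD"`, `"KNN"`, `"SVMl"` or `"SVMc"`.
#' @param ... Method options: `max_splits` (DT, default 100), `lambda`
#'   (LD ridge fraction, default 1e-6), `k` (KNN, default 1), `cost`
#'   (SVM box constraint, default 1).
#' @return An `oil_classifier` model object with a [predict()] method
#'   returning a factor of predicted classes.
#' @export
fit_classifier <- function(x, y, method = c("DT", "LD", "KNN", "SVMl", "SVMc"),
                           ...) {
  if (!method[1] %in% c("DT", "LD", "KNN", "SVMl", "SVMc")) {
    abort(sprintf("Unknown classification method '%s'.", method[1]))
  }
  method <- match.arg(method)
  y <- droplevels(as.factor(y))
  if (any(table(y) < 2)) {
    abort("Every class must have at least 2 members in the training partition.")
  }
  fit <- switch(method,
    DT = fit_cart(x, y, ...),
    LD = fit_ld(x, y, ...),
    KNN = fit_knn(x, y, ...),
    SVMl = fit_svm_ovo(x, y, kernel = "linear", ...),
    SVMc = fit_svm_ovo(x, y, kernel = "cubic", ...)
  )
  structure(list(method = method, fit = fit, levels = levels(y)),
            class = "oil_classifier")
}

#' @export
predict.oil_classifier <- function(object, newdata, ...) {
  idx <- switch(object$method,
    DT = predict_cart(object$fit, newdata),
    LD = predict_ld(object$fit, newdata),
    KNN = predict_knn(object$fit, newdata),
    SVMl = predict_svm_ovo(object$fit, newdata),
    SVMc = predict_svm_ovo(object$fit, newdata)
  )
  factor(object$levels[idx], levels = object$levels)
}

#' @export
print.oil_classifier <- function(x, ...) {
  cat(sprintf("<oil_classifier: %s, %d classes>\n", x$method, length(x$levels)))
  invisible(x)
}

## ---- CART (Gini) ----------------------------------------------------------

gini_from_counts <- function(counts, n) {
  ## counts: positions x classes; n: positions
  1 - rowSums((counts / n)^2)
}

best_split_node <- function(x, yi, K) {
  m <- length(yi)
  Y <- matrix(0, m, K)
  Y[cbind(seq_len(m), yi)] <- 1
  parent_counts <- colSums(Y)
  g_parent <- 1 - sum((parent_counts / m)^2)
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    o <- order(xj)
    xs <- xj[o]
    valid <- which(diff(xs) > 0) # split between t and t+1
    if (length(valid) == 0) next
    csum <- apply(Y[o, , drop = FALSE], 2, cumsum) # m x K
    nl <- valid
    nr <- m - nl
    cl <- csum[valid, , drop = FALSE]
    gl <- 1 - rowSums((cl / nl)^2)
    gr <- 1 - rowSums(((rep(parent_counts, each = length(valid)) - cl) / nr)^2)
    gain <- g_parent - (nl * gl + nr * gr) / m
    b <- which.max(gain)
    if (gain[b] > best$gain + 1e-12) {
      best <- list(gain = gain[b], feature = j,
                   threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2)
    }
  }
  best
}

fit_cart <- function(x, y, max_splits = 100, min_leaf = 1, ...) {
  K <- nlevels(y)
  yi <- as.integer(y)
  nodes <- list()
  n_splits <- 0L
  grow <- function(idx) {
    node_id <- length(nodes) + 1L
    counts <- tabulate(yi[idx], K)
    leaf_class <- which.max(counts) # ties -> lowest class index
    if (length(unique(yi[idx])) == 1L || n_splits >= max_splits ||
        length(idx) < 2 * min_leaf) {
      nodes[[node_id]] <<- list(leaf = TRUE, class = leaf_class)
      return(node_id)
    }
    sp <- best_split_node(x[idx, , drop = FALSE], yi[idx], K)
    if (is.na(sp$feature)) {
      nodes[[node_id]] <<- list(leaf = TRUE, class = leaf_class)
      return(node_id)
    }
    n_splits <<- n_splits + 1L
    nodes[[node_id]] <<- list(leaf = FALSE) # placeholder, filled below
    left <- idx[x[idx, sp$feature] <= sp$threshold]
    right <- idx[x[idx, sp$feature] > sp$threshold]
    l_id <- grow(left)
    r_id <- grow(right)
    nodes[[node_id]] <<- list(leaf = FALSE, feature = sp$feature,
                              threshold = sp$threshold, left = l_id, right = r_id)
    node_id
  }
  grow(seq_len(nrow(x)))
  list(nodes = nodes, n_classes = K)
}

predict_cart <- function(fit, x) {
  out <- integer(nrow(x))
  assign_node <- function(node_id, idx) {
    node <- fit$nodes[[node_id]]
    if (node$leaf) {
      out[idx] <<- node$class
      return(invisible(NULL))
    }
    go_left <- x[idx, node$feature] <= node$threshold
    if (any(go_left)) assign_node(node$left, idx[go_left])
    if (any(!go_left)) assign_node(node$right, idx[!go_left])
  }
  assign_node(1L, seq_len(nrow(x)))
  out
}

## ---- regularized LDA ------------------------------------------------------

fit_ld <- function(x, y, lambda = 1e-6, ...) {
  n <- nrow(x)
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  ## work in the (at most n-1 dimensional) subspace spanned by the data
  G <- tcrossprod(xc)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  U <- eg$vectors[, keep, drop = FALSE]
  dvals <- sqrt(eg$values[keep])
  V <- crossprod(xc, sweep(U, 2, dvals, "/")) # p x r loadings
  scores <- sweep(U, 2, dvals, "*")           # n x r
  K <- nlevels(y)
  mu <- t(vapply(levels(y), function(l) colMeans(scores[y == l, , drop = FALSE]),
                 numeric(ncol(scores))))
  W <- matrix(0, ncol(scores), ncol(scores))
  for (k in seq_len(K)) {
    sk <- sweep(scores[y == levels(y)[k], , drop = FALSE], 2, mu[k, ])
    W <- W + crossprod(sk)
  }
  W <- W / (n - K)
  W <- W + lambda * mean(diag(W)) * diag(ncol(W))
  Winv_mu <- solve(W, t(mu))                  # r x K
  const <- -0.5 * colSums(t(mu) * Winv_mu)
  list(center = center, V = V, Winv_mu = Winv_mu, const = const)
}

predict_ld <- function(fit, x) {
  scores <- sweep(x, 2, fit$center) %*% fit$V
  disc <- scores %*% fit$Winv_mu + rep(fit$const, each = nrow(x))
  max.col(disc, ties.method = "first")
}

## ---- k nearest neighbours -------------------------------------------------

fit_knn <- function(x, y, k = 1, ...) {
  list(x = x, yi = as.integer(y), k = k, K = nlevels(y),
       sq = rowSums(x^2))
}

predict_knn <- function(fit, x) {
  d2 <- outer(rowSums(x^2), fit$sq, "+") - 2 * tcrossprod(x, fit$x)
  k <- fit$k
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- tabulate(fit$yi[nn], fit$K)
    which.max(votes) # ties -> lowest class index
  })
}

## ---- one-vs-one kernel SVM ------------------------------------------------

## dual coordinate ascent on the box-constrained SVM dual with the bias
## absorbed into the kernel (K + 1); deterministic sweep order
svm_binary_dual <- function(Kt, ylab, cost = 1, max_epochs = 300, tol = 1e-6) {
  n <- length(ylab)
  alpha <- numeric(n)
  f <- numeric(n) # f_i = sum_j alpha_j y_j Kt[i, j]
  dKt <- diag(Kt)
  for (epoch in seq_len(max_epochs)) {
    max_delta <- 0
    for (i in seq_len(n)) {
      grad <- 1 - ylab[i] * f[i]
      a_new <- min(max(alpha[i] + grad / dKt[i], 0), cost)
      delta <- a_new - alpha[i]
      if (abs(delta) > 1e-15) {
        f <- f + delta * ylab[i] * Kt[, i]
        alpha[i] <- a_new
        max_delta <- max(max_delta, abs(delta))
      }
    }
    if (max_delta < tol) break
  }
  alpha
}

fit_svm_ovo <- function(x, y, kernel = c("linear", "cubic"), cost = 1, ...) {
  kernel <- match.arg(kernel)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  p <- ncol(xs)
  Klin <- tcrossprod(xs)
  Kfull <- if (kernel == "linear") Klin else (1 + Klin / p)^3
  K <- nlevels(y)
  yi <- as.integer(y)
  pairs <- utils::combn(K, 2)
  models <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    idx <- which(yi %in% c(a, b))
    ylab <- ifelse(yi[idx] == a, 1, -1)
    alpha <- svm_binary_dual(Kfull[idx, idx, drop = FALSE] + 1, ylab, cost = cost)
    sv <- which(alpha > 1e-12)
    models[[q]] <- list(a = a, b = b, idx = idx[sv],
                        coef = alpha[sv] * ylab[sv])
  }
  list(kernel = kernel, center = center, scale = scale_, p = p,
       xs = xs, models = models, K = K)
}

predict_svm_ovo <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  Klin <- tcrossprod(xs, fit$xs)
  Kte <- if (fit$kernel == "linear") Klin else (1 + Klin / fit$p)^3
  votes <- matrix(0, nrow(x), fit$K)
  for (m in fit$models) {
    dec <- (Kte[, m$idx, drop = FALSE] + 1) %*% m$coef
    winner <- ifelse(dec >= 0, m$a, m$b) # tie (dec == 0) -> lower index
    votes[cbind(seq_len(nrow(x)), winner)] <- votes[cbind(seq_len(nrow(x)), winner)] + 1
  }
  max.col(votes, ties.method = "first")
}
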