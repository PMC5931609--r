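#' Drop highly correlated feature columns
#'
#' Scans columns left to right and drops any column whose absolute Pearson
#' correlation with an already-kept column exceeds `r_max`; survivors keep
#' their original order. Anti-correlated columns are treated as redundant
#' too (the comparison is on `|r|`). Constant columns have undefined
#' correlation; they are treated as `r = 0`, kept, and a warning is issued.
#'
#' @param x Feature matrix or data frame (at least 2 rows).
#' @param r_max Correlation cutoff in `(0, 1]`; default 0.9.
#' @return The pruned matrix, with attribute `kept` holding the retained
#'   column indices.
#' @export
prune_correlated <- function(x, r_max = 0.9) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 examples to estimate correlations")
  if (!(r_max > 0 && r_max <= 1)) stop("r_max must be in (0, 1]")
  const <- apply(x, 2, sd) == 0
  if (any(const))
    warning("constant columns treated as uncorrelated: ",
            paste(colnames(x)[const], collapse = ", "))
  r <- suppressWarnings(abs(cor(x)))
  r[!is.finite(r)] <- 0
  kept <- integer(0)
  for (j in seq_len(ncol(x))) {
    if (length(kept) == 0L || all(r[j, kept] <= r_max)) kept <- c(kept, j)
  }
  out <- x[, kept, drop = FALSE]
  attr(out, "kept") <- kept
  out
}

#' Sigmoid scaling of feature columns
#'
#' Maps each feature through `1 / (1 + exp(-(x - mu) / sigma))` with `mu`
#' and `sigma` the column mean and standard deviation (estimated from the
#' data unless supplied, so parameters fitted on training data can be
#' reused on test data). Outputs lie in `(0, 1)` and the map is strictly
#' monotone. Zero-variance columns use `sigma = 1` with a warning.
#'
#' @param x Feature matrix or data frame.
#' @param center,scale Optional per-column parameters from a previous call.
#' @return The scaled matrix with attributes `center` and `scale`.
#' @export
sigmoid_scale <- function(x, center = NULL, scale = NULL) {
  x <- as_feature_matrix(x)
  if (is.null(center)) {
    if (nrow(x) < 2L) stop("need at least 2 examples to fit scaling parameters")
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    if (any(scale == 0)) {
      warning("zero-variance columns scaled with sigma = 1")
      scale[scale == 0] <- 1
    }
  }
  out <- 1 / (1 + exp(-sweep(sweep(x, 2, center, "-"), 2, scale, "/")))
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Linear auto-associative feature reduction via SVD
#'
#' Fits the rank-`n_out` linear autoencoder of a (typically
#' sigmoid-scaled) feature table: columns are centered and the top `n_out`
#' right singular vectors become the encoding map. Among all rank-`n_out`
#' linear reconstructions this minimizes the Frobenius reconstruction
#' error (Eckart-Young), so it is the closed-form optimum of a
#' one-hidden-layer linear auto-associative network.
#'
#' @param x Feature matrix or data frame.
#' @param n_out Number of reduced features; default 10.
#' @return An object of class `"feature_reducer"`: `center`, `components`
#'   (orthonormal columns, one per output feature), `n_out`, and `scores`
#'   (the reduced training data).
#' @export
fit_reducer <- function(x, n_out = 10L) {
  x <- as_feature_matrix(x)
  n_out <- as.integer(n_out)
  if (n_out < 1L || n_out > min(dim(x)))
    stop("n_out must be in [1, min(n_examples, n_features)]")
  center <- colMeans(x)
  xc <- sweep(x, 2, center, "-")
  sv <- svd(xc, nu = 0, nv = n_out)
  comp <- sv$v
  colnames(comp) <- paste0("rf", seq_len(n_out))
  structure(list(center = center, components = comp, n_out = n_out,
                 scores = xc %*% comp),
            class = "feature_reducer")
}

#' @export
print.feature_reducer <- function(x, ...) {
  cat(sprintf("Linear SVD feature reducer: %d -> %d features\n",
              length(x$center), x$n_out))
  invisible(x)
}

#' @rdname fit_reducer
#' @param object A fitted `"feature_reducer"`.
#' @param newdata Feature matrix on the same scale as the training data.
#' @param ... Unused.
#' @return For `predict`: the reduced `n x n_out` matrix.
#' @export
predict.feature_reducer <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata, "newdata")
  if (ncol(newdata) != length(object$center)) stop("feature dimension mismatch")
  sweep(newdata, 2, object$center, "-") %*% object$components
}
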