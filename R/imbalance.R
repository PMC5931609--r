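#' SMOTE oversampling
#'
#' Synthetic Minority Oversampling: classes below their target count are
#' enlarged with synthetic points drawn on the segment between a randomly
#' chosen class member `x` and one of its `k` nearest same-class neighbours
#' `x'`: the new point is `x + u (x' - x)` with `u ~ Uniform(0, 1)`.
#' Original examples are preserved verbatim and synthetic rows are appended
#' (flagged in the `synthetic` component).
#'
#' @param x Feature matrix or data frame.
#' @param y Single labels (factor or character).
#' @param target_counts Named integer vector of desired per-class counts;
#'   defaults to raising every class to the size of the largest. Must be at
#'   least the current counts.
#' @param k Number of nearest neighbours considered (capped at class size
#'   minus one).
#' @param seed Integer seed.
#' @return A list with components `x`, `y` (factor) and `synthetic`
#'   (logical, `TRUE` for generated rows).
#' @export
smote <- function(x, y, target_counts = NULL, k = 5L, seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  if (length(y) != nrow(x)) stop("length of y must match rows of x")
  cur <- table(y)
  if (is.null(target_counts))
    target_counts <- stats::setNames(rep(max(cur), nlevels(y)), levels(y))
  if (is.null(names(target_counts)) || !all(names(target_counts) %in% levels(y)))
    stop("target_counts must be named by class")
  full <- stats::setNames(as.integer(cur[levels(y)]), levels(y))
  full[names(target_counts)] <- pmax(full[names(target_counts)],
                                     as.integer(target_counts))
  if (any(as.integer(target_counts) < cur[names(target_counts)]))
    stop("target_counts below current counts for: ",
         paste(names(target_counts)[as.integer(target_counts) <
                                    cur[names(target_counts)]], collapse = ", "))
  set.seed(seed)
  new_x <- list(); new_y <- character(0)
  for (cl in levels(y)) {
    need <- full[[cl]] - as.integer(cur[[cl]])
    if (need <= 0) next
    idx <- which(y == cl)
    if (length(idx) < 2L)
      stop("class '", cl, "' has fewer than 2 examples; cannot synthesize")
    xc <- x[idx, , drop = FALSE]
    kk <- min(as.integer(k), nrow(xc) - 1L)
    dm <- as.matrix(dist(xc))
    diag(dm) <- Inf
    nn <- t(matrix(apply(dm, 1, function(d) order(d)[seq_len(kk)]), nrow = kk))
    pts <- matrix(0, nrow = need, ncol = ncol(x))
    for (s in seq_len(need)) {
      i <- sample.int(nrow(xc), 1L)
      j <- nn[i, sample.int(kk, 1L)]
      u <- runif(1)
      pts[s, ] <- xc[i, ] + u * (xc[j, ] - xc[i, ])
    }
    new_x[[cl]] <- pts
    new_y <- c(new_y, rep(cl, need))
  }
  xs <- rbind(x, do.call(rbind, new_x))
  ys <- factor(c(as.character(y), new_y), levels = levels(y))
  list(x = xs, y = ys,
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, length(new_y))))
}

#' Random undersampling
#'
#' Reduces classes to the requested sizes by a seeded uniform subsample
#' without replacement; classes not named in `target_counts` are kept whole.
#'
#' @inheritParams smote
#' @param target_counts Named integer vector of desired per-class counts,
#'   each at most the current count.
#' @return A list with components `x`, `y` and `kept` (the retained row
#'   indices into the input).
#' @export
random_undersample <- function(x, y, target_counts, seed = 1L) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  cur <- table(y)
  if (is.null(names(target_counts)) || !all(names(target_counts) %in% levels(y)))
    stop("target_counts must be named by class")
  over <- as.integer(target_counts) > cur[names(target_counts)]
  if (any(over))
    stop("target exceeds available examples for: ",
         paste(names(target_counts)[over], collapse = ", "))
  set.seed(seed)
  keep <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (cl %in% names(target_counts))
      idx <- sort(sample(idx, as.integer(target_counts[[cl]])))
    keep <- c(keep, idx)
  }
  keep <- sort(keep)
  list(x = x[keep, , drop = FALSE], y = y[keep], kept = keep)
}

#' Tally predictions into a confusion result
#'
#' Non-conclusive predictions are never forced into the confusion matrix;
#' they are counted separately, so `sum(matrix) + n_nonconclusive`
#' equals the number of examples. For multi-label truths the prediction is
#' credited on the diagonal when it matches any of the true labels,
#' otherwise charged against the first true label.
#'
#' @param y_true True labels (factor, character, or list of character sets).
#' @param predicted Predicted labels, possibly containing the
#'   [NON_CONCLUSIVE] token (e.g. the output of [predict.csom()]).
#' @param classes Class vocabulary; defaults to the union observed in
#'   `y_true` and conclusive predictions.
#' @return An object of class `"confusion_result"`: `matrix` (rows = true,
#'   cols = predicted), `n_nonconclusive`, `n_total`.
#' @export
prediction_tally <- function(y_true, predicted, classes = NULL) {
  truth <- as_label_list(y_true, classes = NULL)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("y_true and predicted must have equal length")
  if (is.null(classes))
    classes <- sort(unique(c(unlist(truth), setdiff(predicted, NON_CONCLUSIVE))))
  unknown <- setdiff(predicted, c(classes, NON_CONCLUSIVE))
  if (length(unknown)) stop("unknown predicted labels: ", paste(unknown, collapse = ", "))
  K <- length(classes)
  mat <- matrix(0L, K, K, dimnames = list(true = classes, predicted = classes))
  n_nc <- 0L
  for (i in seq_along(truth)) {
    p <- predicted[i]
    if (p == NON_CONCLUSIVE) { n_nc <- n_nc + 1L; next }
    tl <- if (p %in% truth[[i]]) p else truth[[i]][1]
    mat[tl, p] <- mat[tl, p] + 1L
  }
  structure(list(matrix = mat, n_nonconclusive = n_nc,
                 n_total = length(truth)),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("non-conclusive: %d of %d (%.1f%%)\n", x$n_nonconclusive,
              x$n_total, 100 * x$n_nonconclusive / x$n_total))
  invisible(x)
}

#' Imbalance-aware classification metrics
#'
#' Computed over conclusive predictions only: overall accuracy
#' (trace / total), per-class recall (0 for a class with no examples), its
#' arithmetic mean (`mean_recall`, insensitive to class sizes and therefore
#' the headline metric under imbalance) and geometric mean
#' (`gmean_recall`), the macro-averaged F measure (harmonic mean of
#' per-class precision and recall, 0 when both are 0), and `pct_out`, the
#' percentage of examples withheld as non-conclusive. A zero recall is
#' floored at `1e-12` inside the geometric mean (with `gmean_floored =
#' TRUE` flagged) so a single empty class does not silently collapse the
#' score to 0.
#'
#' @param cr A `"confusion_result"` from [prediction_tally()].
#' @return An object of class `"metrics_report"`: a list with `accuracy`,
#'   `recall` (per class), `mean_recall`, `gmean_recall`, `f_measure`,
#'   `pct_out`, `gmean_floored`.
#' @examples
#' cr <- structure(list(matrix = rbind(c(50, 0), c(25, 25)),
#'                      n_nonconclusive = 0L, n_total = 100L),
#'                 class = "confusion_result")
#' classification_metrics(cr)$mean_recall  # 0.75
#' @export
classification_metrics <- function(cr) {
  stopifnot(inherits(cr, "confusion_result"))
  m <- cr$matrix
  tot <- sum(m)
  if (tot <= 0)
    stop("all predictions non-conclusive: metrics over conclusive examples are undefined")
  rs <- rowSums(m); cs <- colSums(m)
  recall <- ifelse(rs > 0, diag(m) / rs, 0)
  precision <- ifelse(cs > 0, diag(m) / cs, 0)
  floored <- any(recall <= 0)
  f_per <- ifelse(precision + recall > 0,
                  2 * precision * recall / (precision + recall), 0)
  structure(list(
    accuracy = sum(diag(m)) / tot,
    recall = recall,
    mean_recall = mean(recall),
    gmean_recall = exp(mean(log(pmax(recall, 1e-12)))),
    f_measure = mean(f_per),
    pct_out = 100 * cr$n_nonconclusive / cr$n_total,
    gmean_floored = floored), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | mean recall %.3f | G-mean recall %.3f | F %.3f | %% out %.1f\n",
              x$accuracy, x$mean_recall, x$gmean_recall, x$f_measure, x$pct_out))
  if (x$gmean_floored)
    cat("  (a class had zero recall; geometric mean floored at 1e-12)\n")
  invisible(x)
}
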