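#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' over a randomly rotated fold order, so per-class fold sizes differ by
#' at most one. Classes with fewer members than folds are spread
#' round-robin with a warning (some folds then see none of that class).
#'
#' @param y Labels (factor / character; multi-label lists are stratified
#'   on their first label).
#' @param k Number of folds, at least 2; default 10.
#' @param seed Integer seed.
#' @return An integer vector of fold indices in `1..k`, one per example.
#' @export
stratified_kfold <- function(y, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (is.list(y)) y <- vapply(y, `[[`, character(1), 1L)
  y <- as.factor(y)
  small <- table(y) < k
  if (any(small))
    warning("classes with fewer than k members spread round-robin: ",
            paste(names(which(small)), collapse = ", "))
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep(sample.int(k), length.out = length(idx))
  }
  folds
}

#' k-nearest-neighbour classification, in feature space or on the map
#'
#' Majority vote over the `k` nearest training examples. In `"feature"`
#' space distances are Euclidean on the raw features; in `"som"` space
#' both training and query points are first mapped to their best-matching
#' units of a fitted SOM and distances are torus distances between BMU
#' coordinates (the classical SOM + k-NN classifier). Distance ties at the
#' k-th neighbour include all co-distant points; vote ties are broken
#' toward the smallest class index. Predictions are always conclusive.
#'
#' @param train_x,train_y Training features and single labels.
#' @param newdata Query features.
#' @param k Number of neighbours (default 5); must not exceed the number
#'   of training examples.
#' @param space `"feature"` or `"som"`.
#' @param grid A fitted `"som"`, required for `space = "som"`.
#' @return A factor of predicted classes with attribute `prob` (vote
#'   fractions, one column per class).
#' @export
knn_classify <- function(train_x, train_y, newdata, k = 5L,
                         space = c("feature", "som"), grid = NULL) {
  space <- match.arg(space)
  train_x <- as_feature_matrix(train_x)
  newdata <- as_feature_matrix(newdata, "newdata")
  train_y <- as.factor(train_y)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(train_x)) stop("k exceeds the number of training examples")
  classes <- levels(train_y)
  if (space == "som") {
    if (is.null(grid) || !inherits(grid, "som"))
      stop("space = 'som' requires a fitted som grid")
    tc <- predict(grid, train_x)
    qc <- predict(grid, newdata)
    W <- grid$config$width; H <- grid$config$height
    dfun <- function(i) {
      dr <- abs(tc[, 1] - qc[i, 1]); dr <- pmin(dr, H - dr)
      dc <- abs(tc[, 2] - qc[i, 2]); dc <- pmin(dc, W - dc)
      sqrt(dr^2 + dc^2)
    }
  } else {
    dfun <- function(i) sqrt(colSums((t(train_x) - newdata[i, ])^2))
  }
  n <- nrow(newdata)
  probs <- matrix(0, nrow = n, ncol = length(classes),
                  dimnames = list(NULL, classes))
  pred <- integer(n)
  for (i in seq_len(n)) {
    d <- dfun(i)
    kd <- sort(d, partial = k)[k]
    nb <- which(d <= kd + 1e-12)           # co-distant points all vote
    v <- tabulate(as.integer(train_y[nb]), nbins = length(classes))
    probs[i, ] <- v / sum(v)
    pred[i] <- which.max(v)                 # first max = smallest class index
  }
  out <- factor(classes[pred], levels = classes)
  attr(out, "prob") <- probs
  out
}

#' Cross-validated evaluation of a classification method
#'
#' Runs stratified k-fold cross-validation for one of the three methods:
#' `"csom"` (consensus SOM with threshold-gated predictions), `"som_knn"`
#' (SOM projection followed by k-NN on torus coordinates) or `"knn"`
#' (k-NN in raw feature space). Resampling, when requested, is fitted on
#' the training portion of each fold only -- synthetic points never reach a
#' test set. Per-fold confusion results are scored with
#' [classification_metrics()]; non-conclusive predictions (csom only) are
#' excluded from the confusion matrix and surfaced as `pct_out`.
#'
#' @param x,y Features and labels.
#' @param method One of `"csom"`, `"som_knn"`, `"knn"`.
#' @param k_folds Number of CV folds (default 10).
#' @param seed Seed controlling fold assignment, resampling and per-fold
#'   model seeds.
#' @param resample `"none"`, `"smote"` (oversample every class to the
#'   majority size) or `"undersample"` (downsample every class to the
#'   minority size).
#' @param config Base [som_config()]; each fold trains with its own seed
#'   offset derived from `seed`.
#' @param P,threshold Consensus runs and confidence threshold (csom).
#' @param knn_k Number of neighbours for the k-NN methods.
#' @return An object of class `"csom_cv"`: `method`, `folds` (assignment),
#'   `per_fold` (list of `"metrics_report"`), `metrics` (data frame with
#'   one row per fold), `seed`.
#' @export
cross_validate <- function(x, y, method = c("csom", "som_knn", "knn"),
                           k_folds = 10L, seed = 1L,
                           resample = c("none", "smote", "undersample"),
                           config = som_config(), P = 10L, threshold = 0.9,
                           knn_k = 5L) {
  method <- match.arg(method)
  resample <- match.arg(resample)
  x <- as_feature_matrix(x)
  labels <- as_label_list(y)
  classes <- attr(labels, "classes")
  yf <- factor(vapply(labels, `[[`, character(1), 1L), levels = classes)
  folds <- stratified_kfold(yf, k = k_folds, seed = seed)
  per_fold <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f; te <- !tr
    trx <- x[tr, , drop = FALSE]; trly <- yf[tr]
    if (resample == "smote") {
      rs <- smote(trx, trly, seed = seed + f)
      trx <- rs$x; trly <- rs$y
    } else if (resample == "undersample") {
      tc <- table(trly)
      rs <- random_undersample(trx, trly,
                               stats::setNames(rep(min(tc), length(tc)), names(tc)),
                               seed = seed + f)
      trx <- rs$x; trly <- rs$y
    }
    cfg <- config
    cfg$seed <- as.integer(config$seed + (f - 1L) * (P + 1L))
    pred <- switch(method,
      csom = {
        fit <- csom(trx, trly, P = P, threshold = threshold, config = cfg,
                    classes = classes)
        predict(fit, x[te, , drop = FALSE])
      },
      som_knn = {
        grid <- som(trx, cfg)
        knn_classify(trx, trly, x[te, , drop = FALSE], k = knn_k,
                     space = "som", grid = grid)
      },
      knn = knn_classify(trx, trly, x[te, , drop = FALSE], k = knn_k))
    cr <- prediction_tally(labels[te], pred, classes = classes)
    per_fold[[f]] <- classification_metrics(cr)
  }
  metrics <- do.call(rbind, lapply(seq_len(k_folds), function(f) {
    m <- per_fold[[f]]
    data.frame(method = method, fold = f, accuracy = m$accuracy,
               mean_recall = m$mean_recall, gmean_recall = m$gmean_recall,
               f_measure = m$f_measure, pct_out = m$pct_out)
  }))
  structure(list(method = method, folds = folds, per_fold = per_fold,
                 metrics = metrics, seed = seed),
            class = "csom_cv")
}

#' @export
print.csom_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, method = %s\n",
              max(x$folds), x$method))
  m <- colMeans(x$metrics[, c("accuracy", "mean_recall", "gmean_recall",
                              "f_measure", "pct_out")])
  cat(sprintf("  mean over folds: accuracy %.3f | mean recall %.3f | G-mean %.3f | F %.3f | %% out %.1f\n",
              m[1], m[2], m[3], m[4], m[5]))
  invisible(x)
}

#' @export
summary.csom_cv <- function(object, ...) {
  colMeans(object$metrics[, c("accuracy", "mean_recall", "gmean_recall",
                              "f_measure", "pct_out")])
}

#' Paired Student's t-test on per-fold scores
#'
#' Classical two-sided paired t-test on the fold-wise differences between
#' two methods' scores (e.g. mean recall series from [cross_validate()]
#' runs sharing a fold assignment). Zero-variance differences make the t
#' statistic undefined; this is reported via the `degenerate` flag rather
#' than as a silent 0 or 1.
#'
#' @param a,b Numeric vectors of equal length (>= 2), paired by position.
#' @return An object of class `"paired_t_test"`: `t_statistic`, `p_value`,
#'   `df`, `mean_difference`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("a and b must have equal length >= 2")
  d <- a - b
  if (sd(d) == 0) {
    # identical series: no evidence of a difference (t = 0, p = 1); any other
    # constant difference leaves t undefined
    zero <- all(d == 0)
    return(structure(list(t_statistic = if (zero) 0 else NA_real_,
                          p_value = if (zero) 1 else NA_real_,
                          df = length(d) - 1L, mean_difference = mean(d),
                          degenerate = TRUE),
                     class = "paired_t_test"))
  }
  tt <- t.test(a, b, paired = TRUE)
  structure(list(t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter),
                 mean_difference = unname(tt$estimate),
                 degenerate = FALSE),
            class = "paired_t_test")
}

#' @export
print.paired_t_test <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("paired t-test: degenerate (zero-variance differences), mean diff %.4g\n",
                x$mean_difference))
  } else {
    cat(sprintf("paired t-test: t = %.3f, df = %d, p = %.4g, mean diff = %.4g\n",
                x$t_statistic, x$df, x$p_value, x$mean_difference))
  }
  invisible(x)
}
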