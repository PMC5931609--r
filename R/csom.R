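#' Moore neighbourhood of a grid cell on the torus
#'
#' The 8 cells at Chebyshev distance 1, with both axes wrapped. On grids
#' narrower than 3 cells in either direction the wrapped neighbours
#' coincide and are deduplicated, so fewer than 8 distinct cells may be
#' returned; the cell itself is never included.
#'
#' @param c Length-two integer vector `(row, col)`, 0-based.
#' @param width,height Grid extent.
#' @return An integer matrix with columns `row`, `col`, one neighbour per row.
#' @examples
#' moore_neighbors(c(0, 0), 5, 5)
#' @export
moore_neighbors <- function(c, width, height) {
  check_coord(c, width, height)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  nb <- cbind(row = (c[1] + off$dr) %% height,
              col = (c[2] + off$dc) %% width)
  nb <- unique(nb)
  nb <- nb[!(nb[, 1] == c[1] & nb[, 2] == c[2]), , drop = FALSE]
  rownames(nb) <- NULL
  storage.mode(nb) <- "integer"
  nb
}

# internal: for each of the 8 Moore offsets, the row-major 0-based index of
# the neighbour of every cell; returned as an m x 8 1-based index matrix into
# cell-ordered vectors
moore_shift_index <- function(width, height) {
  m <- width * height
  cell <- 0:(m - 1)
  r <- cell %/% width; cc <- cell %% width
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  idx <- matrix(0L, nrow = m, ncol = nrow(off))
  for (j in seq_len(nrow(off))) {
    nr <- (r + off$dr[j]) %% height
    ncol_ <- (cc + off$dc[j]) %% width
    idx[, j] <- as.integer(nr * width + ncol_ + 1L)
  }
  idx
}

#' Propagate class probabilities across the torus (expansion algorithm)
#'
#' Turns a partially occupied map into a complete classifier surface. Each
#' occupied cell first receives the mean of its examples' class
#' distributions; these vectors are frozen and never modified. Empty cells
#' are then filled wavefront-wise: at each wave, every still-empty cell that
#' is Moore-adjacent to at least one previously filled cell receives the
#' weighted sum of those cells' probability vectors -- occupied sources
#' weighted by their example count, expanded sources with weight 1 -- and
#' the result is normalized to sum to 1. Because the torus is connected the
#' wavefront reaches every cell.
#'
#' @param occ A `"som_occupancy"` (see [som_project()] or [occupancy()]).
#' @param dists Numeric matrix, one row per example, one column per class;
#'   each row a distribution summing to 1 (one-hot labels or prior rows).
#' @param classes Optional class names; defaults to `colnames(dists)`.
#' @return An object of class `"probability_map"`: `probs`, an array of
#'   dimension `height x width x n_classes`; `origin`, a `height x width`
#'   character matrix with entries `"occupied"` or `"expanded"`; `classes`.
#' @examples
#' occ <- occupancy(rbind(c(0, 0), c(2, 2)), 5, 5)
#' dists <- rbind(c(1, 0), c(0, 1))
#' pm <- expand_probabilities(occ, dists, classes = c("A", "B"))
#' pm$probs[2, 2, ]  # cell (1,1): adjacent to both sources -> (0.5, 0.5)
#' @export
expand_probabilities <- function(occ, dists, classes = colnames(dists)) {
  stopifnot(inherits(occ, "som_occupancy"))
  dists <- as.matrix(dists)
  if (nrow(dists) != occ$n)
    stop("dists must have one row per example in the occupancy")
  if (any(abs(rowSums(dists) - 1) > 1e-8))
    stop("every example distribution must sum to 1")
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(dists)))
  W <- occ$width; H <- occ$height
  m <- W * H; K <- ncol(dists)

  cell <- occ$coords[, 1] * W + occ$coords[, 2] + 1L  # 1-based row-major
  V <- matrix(0, nrow = m, ncol = K)
  wt <- numeric(m)
  filled <- logical(m)
  cnt <- tabulate(cell, nbins = m)
  agg <- rowsum(dists, group = cell)
  occ_cells <- as.integer(rownames(agg))
  V[occ_cells, ] <- agg / cnt[occ_cells]
  wt[occ_cells] <- cnt[occ_cells]
  filled[occ_cells] <- TRUE

  shift <- moore_shift_index(W, H)
  while (!all(filled)) {
    wv <- V * wt
    contrib <- matrix(0, nrow = m, ncol = K)
    has_src <- logical(m)
    for (j in seq_len(ncol(shift))) {
      src <- shift[, j]
      recv <- which(filled[src] & !filled)
      if (length(recv)) {
        contrib[recv, ] <- contrib[recv, , drop = FALSE] + wv[src[recv], , drop = FALSE]
        has_src[recv] <- TRUE
      }
    }
    new <- has_src  # already excludes filled cells
    V[new, ] <- contrib[new, , drop = FALSE] / rowSums(contrib[new, , drop = FALSE])
    wt[new] <- 1
    filled[new] <- TRUE
  }

  probs <- array(0, dim = c(H, W, K), dimnames = list(NULL, NULL, classes))
  for (k in seq_len(K)) probs[, , k] <- t(matrix(V[, k], nrow = W))
  origin_vec <- ifelse(seq_len(m) %in% occ_cells, "occupied", "expanded")
  origin <- t(matrix(origin_vec, nrow = W))
  structure(list(probs = probs, origin = origin, classes = classes),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("Probability map: %d x %d torus, %d classes (%s), %d occupied cells\n",
              d[2], d[1], d[3], paste(x$classes, collapse = ", "),
              sum(x$origin == "occupied")))
  invisible(x)
}

#' Consensus class priors from repeated SOM trainings
#'
#' Because SOM training starts from random weights, consecutive runs place
#' examples differently; an example that sits inside its class in one run
#' may sit on a class boundary in another. To capture this, `P` maps are
#' trained with consecutive seeds and, in each run, the class labels of all
#' other examples landing in an example's BMU cell or its 8 Moore
#' neighbours are tallied (the example itself is excluded; runs in which an
#' example has no neighbours fall back to its own label). Per-run tallies
#' are normalized and averaged over the `P` runs, giving each example a
#' class distribution that replaces its hard label during probability
#' expansion.
#'
#' @param x Feature matrix or data frame.
#' @param y Labels: factor, character vector, or list of character vectors
#'   for multi-label examples (which contribute a uniform distribution over
#'   their labels).
#' @param config A [som_config()]; runs use seeds
#'   `base_seed, ..., base_seed + P - 1`.
#' @param P Number of repeated trainings (around 10 is usually enough for
#'   the averaged distributions to stabilize).
#' @param base_seed First seed of the run sequence.
#' @param classes Optional explicit class vocabulary.
#' @return An object of class `"prior_table"`: a numeric matrix with one
#'   row per example and one column per class, rows summing to 1, with
#'   attribute `n_runs`.
#' @export
consensus_priors <- function(x, y, config = som_config(), P = 10L,
                             base_seed = config$seed, classes = NULL) {
  P <- as.integer(P)
  if (is.na(P) || P < 1L) stop("P must be a positive integer")
  x <- as_feature_matrix(x)
  labels <- as_label_list(y, classes)
  classes <- attr(labels, "classes")
  L <- label_matrix(labels, classes)
  n <- nrow(x); K <- length(classes)
  m <- config$width * config$height
  shift <- moore_shift_index(config$width, config$height)

  acc <- matrix(0, nrow = n, ncol = K, dimnames = list(NULL, classes))
  for (p in seq_len(P) - 1L) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + p)
    g <- som(x, cfg)
    cells <- som_bmu_cpp(g$weights,
                         scale_features(x, list(center = g$center, scale = g$scale))) + 1L
    # per-cell class mass, then 9-cell neighbourhood sums
    C <- rowsum(L, group = cells)
    Cfull <- matrix(0, nrow = m, ncol = K)
    Cfull[as.integer(rownames(C)), ] <- C
    M9 <- Cfull
    for (j in seq_len(ncol(shift))) M9 <- M9 + Cfull[shift[, j], , drop = FALSE]
    tal <- M9[cells, , drop = FALSE] - L  # exclude the example itself
    tot <- rowSums(tal)
    lone <- tot <= 0
    tal[lone, ] <- L[lone, , drop = FALSE]
    acc <- acc + tal / rowSums(tal)
  }
  structure(acc / P, n_runs = P, classes = classes, class = c("prior_table", "matrix"))
}

#' @export
print.prior_table <- function(x, ...) {
  cat(sprintf("Consensus prior table: %d examples x %d classes, averaged over %d runs\n",
              nrow(x), ncol(x), attr(x, "n_runs")))
  invisible(x)
}

#' Fit a consensus self-organizing map classifier
#'
#' The full pipeline: consensus priors are estimated from `P` repeated SOM
#' trainings ([consensus_priors()]), one further map is trained with the
#' next seed in the sequence, the training data is projected onto it, and
#' the probability-expansion algorithm ([expand_probabilities()]) fills
#' every grid cell with a class-probability vector, each training example
#' contributing its prior distribution rather than a hard label. Prediction
#' reads the probability vector at a query's best-matching unit and returns
#' the most probable class only when that probability strictly exceeds
#' `threshold`; otherwise the prediction is reported as non-conclusive.
#'
#' @param x Feature matrix / data frame, or a formula.
#' @param ... Passed between methods.
#' @return An object of class `"csom"` with components `som` (the final
#'   fitted map), `prob_map` (a `"probability_map"`), `priors` (the
#'   `"prior_table"`), `P`, `threshold`, `classes` and `call`.
#' @examples
#' d <- generate_imbalanced(counts = c(a = 40, b = 40),
#'                          means = rbind(c(0, 0), c(4, 4)), sds = 1, seed = 1)
#' fit <- csom(d$x, d$labels, P = 3, threshold = 0.5,
#'             config = som_config(6, 6, rounds = 20, seed = 1))
#' table(predict(fit, d$x))
#' @export
csom <- function(x, ...) UseMethod("csom")

#' @rdname csom
#' @param formula A formula of the form `label ~ .` or
#'   `label ~ f1 + f2 + ...`.
#' @param data A data frame holding the label and feature columns.
#' @export
csom.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  out <- csom.default(x, y, ...)
  out$call <- match.call()
  out
}

#' @rdname csom
#' @param y Labels: factor, character vector, or list of character vectors
#'   (multi-label).
#' @param P Number of consensus runs.
#' @param threshold Confidence threshold `t` in `[0, 1]`; a prediction is
#'   conclusive only if its maximum class probability is strictly greater
#'   than `t`.
#' @param config A [som_config()]. Consensus runs use seeds
#'   `config$seed ... config$seed + P - 1`; the final map uses
#'   `config$seed + P`.
#' @param classes Optional explicit class vocabulary (ordering of the
#'   probability columns).
#' @export
csom.default <- function(x, y, P = 10L, threshold = 0.9,
                         config = som_config(), classes = NULL, ...) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  x <- as_feature_matrix(x)
  labels <- as_label_list(y, classes)
  classes <- attr(labels, "classes")
  priors <- consensus_priors(x, labels, config = config, P = P,
                             base_seed = config$seed, classes = classes)
  cfg_final <- config
  cfg_final$seed <- as.integer(config$seed + P)
  grid <- som(x, cfg_final)
  occ <- som_project(grid, x)
  pm <- expand_probabilities(occ, unclass(priors), classes = classes)
  structure(list(som = grid, prob_map = pm, priors = priors,
                 occupancy = occ, P = as.integer(P), threshold = threshold,
                 classes = classes, call = match.call()),
            class = "csom")
}

#' @export
print.csom <- function(x, ...) {
  cfg <- x$som$config
  cat("Consensus SOM classifier\n")
  cat(sprintf("  grid: %d x %d torus, %d features, %d training rounds\n",
              cfg$width, cfg$height, x$som$dim, cfg$rounds))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  consensus runs P = %d, threshold t = %g\n", x$P, x$threshold))
  invisible(x)
}

#' @export
summary.csom <- function(object, ...) {
  arg <- apply(object$prob_map$probs, c(1, 2), which.max)
  reg <- table(factor(object$classes[arg], levels = object$classes))
  conf <- apply(object$prob_map$probs, c(1, 2), max)
  out <- list(model = object, region_cells = reg,
              pct_cells_below_threshold = 100 * mean(conf <= object$threshold),
              occupied_cells = sum(object$prob_map$origin == "occupied"))
  class(out) <- "summary.csom"
  out
}

#' @export
print.summary.csom <- function(x, ...) {
  print(x$model)
  cat(sprintf("  occupied cells: %d\n", x$occupied_cells))
  cat("  cells per argmax class region:\n")
  print(x$region_cells)
  cat(sprintf("  %% of cells below threshold (non-conclusive zone): %.1f\n",
              x$pct_cells_below_threshold))
  invisible(x)
}

#' Predict classes (or probabilities) from a fitted consensus SOM
#'
#' @param object A fitted `"csom"`.
#' @param newdata Feature matrix or data frame on the raw scale.
#' @param type `"class"` for a factor with levels
#'   `c(classes, "non-conclusive")`, `"prob"` for the matrix of cell
#'   probabilities, `"both"` for a data frame with one probability column
#'   per class plus a `decision` column.
#' @param threshold Override of the model's confidence threshold.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.csom <- function(object, newdata, type = c("class", "prob", "both"),
                         threshold = object$threshold, ...) {
  type <- match.arg(type)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  coords <- predict(object$som, newdata)
  K <- length(object$classes)
  pm <- object$prob_map$probs
  probs <- matrix(0, nrow = nrow(coords), ncol = K,
                  dimnames = list(NULL, object$classes))
  for (k in seq_len(K))
    probs[, k] <- pm[cbind(coords[, 1] + 1L, coords[, 2] + 1L, k)]
  if (type == "prob") return(probs)
  top <- max.col(probs, ties.method = "first")
  conclusive <- probs[cbind(seq_len(nrow(probs)), top)] > threshold
  decision <- ifelse(conclusive, object$classes[top], NON_CONCLUSIVE)
  decision <- factor(decision, levels = c(object$classes, NON_CONCLUSIVE))
  if (type == "class") return(decision)
  out <- as.data.frame(probs)
  out$decision <- decision
  out
}

#' Class-region map of a fitted consensus SOM
#'
#' Draws the torus unrolled as a plane: each cell coloured by its argmax
#' class, occupied cells overplotted as points.
#'
#' @param x A fitted `"csom"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.csom <- function(x, ...) {
  pm <- x$prob_map$probs
  H <- dim(pm)[1]; W <- dim(pm)[2]
  arg <- apply(pm, c(1, 2), which.max)
  cols <- grDevices::hcl.colors(length(x$classes), "Dark 3")
  graphics::image(x = 0:(W - 1), y = 0:(H - 1), z = t(arg),
                  col = cols, xlab = "col", ylab = "row",
                  main = "CSOM class regions", useRaster = TRUE, ...)
  occ <- unique(x$occupancy$coords)
  graphics::points(occ[, "col"], occ[, "row"], pch = 16, cex = 0.5)
  graphics::legend("topright", legend = x$classes, fill = cols, bg = "white",
                   cex = 0.8)
  invisible(x)
}
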