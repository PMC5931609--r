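#' Training configuration for a toroidal self-organizing map
#'
#' Bundles grid geometry and the training schedule of an online SOM. The
#' learning rate decays geometrically from `lr_start` to `lr_end` over the
#' training rounds and the adaptation radius shrinks linearly from
#' `radius_start` to `radius_end` (both in grid units). Learning rates above
#' 1 are legal in the configuration but clamped to 1 inside the weight
#' update, which keeps each update a contraction.
#'
#' @param width,height Grid dimensions in neurons (positive integers).
#' @param rounds Number of training epochs; each epoch presents every
#'   example once in a seeded random order. `rounds = 0` is permitted and
#'   returns the randomly initialized map unchanged.
#' @param lr_start,lr_end Initial and final learning rate,
#'   `lr_start >= lr_end > 0`.
#' @param radius_start,radius_end Initial and final adaptation radius in
#'   grid units, `radius_start >= radius_end > 0`.
#' @param seed Integer seed; fixing it makes training fully deterministic.
#' @return An object of class `"som_config"`.
#' @seealso [som()]
#' @export
som_config <- function(width = 10L, height = 10L, rounds = 50L,
                       lr_start = 2, lr_end = 0.01,
                       radius_start = max(1, max(width, height) / 2), radius_end = 1,
                       seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  rounds <- as.integer(rounds); seed <- as.integer(seed)
  if (is.na(width) || width < 1L || is.na(height) || height < 1L)
    stop("grid dimensions must be positive integers")
  if (is.na(rounds) || rounds < 0L) stop("rounds must be a non-negative integer")
  if (!(lr_start >= lr_end && lr_end > 0)) stop("need lr_start >= lr_end > 0")
  if (!(radius_start >= radius_end && radius_end > 0))
    stop("need radius_start >= radius_end > 0")
  structure(list(width = width, height = height, rounds = rounds,
                 lr_start = lr_start, lr_end = lr_end,
                 radius_start = radius_start, radius_end = radius_end,
                 seed = seed),
            class = "som_config")
}

#' @export
print.som_config <- function(x, ...) {
  cat(sprintf("SOM configuration: %d x %d toroidal grid, %d rounds\n",
              x$width, x$height, x$rounds))
  cat(sprintf("  learning rate %g -> %g (geometric), radius %g -> %g (linear), seed %d\n",
              x$lr_start, x$lr_end, x$radius_start, x$radius_end, x$seed))
  invisible(x)
}

# internal: per-feature z-score parameters; zero / undefined spread maps to 1
feature_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

scale_features <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# internal: random initial weights, uniform on [0,1) per component
som_init <- function(config, dim) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) stop("feature dimension must be a positive integer")
  matrix(runif(config$width * config$height * dim),
         nrow = config$width * config$height, ncol = dim)
}

#' Fit a toroidal self-organizing map
#'
#' Trains a two-dimensional SOM whose grid wraps in both directions, so every
#' neuron has a full neighbourhood and the map has no boundary. Features are
#' standardized per column (z-score) before training and the scaler is stored
#' on the fitted object, so new data passed to [predict.som()] or
#' [som_project()] is scaled identically. Training is the classical online
#' rule: for each presented example the best-matching unit (BMU) is found by
#' Euclidean distance in feature space, and every neuron within the current
#' adaptation radius `r` of the BMU (torus distance) moves toward the example
#' by `alpha * exp(-d^2 / (2 (r/2)^2)) * (x - w)`.
#'
#' @param x Numeric matrix or all-numeric data frame of features
#'   (examples in rows).
#' @param config A [som_config()] object.
#' @return An object of class `"som"` with components `config`, `weights`
#'   (one row per neuron, row-major cell order), `center`/`scale` (the
#'   feature scaler) and `dim`.
#' @examples
#' x <- matrix(rnorm(200), ncol = 2)
#' m <- som(x, som_config(6, 6, rounds = 20, seed = 1))
#' head(predict(m, x))
#' @export
som <- function(x, config = som_config()) {
  x <- as_feature_matrix(x)
  stopifnot(inherits(config, "som_config"))
  scaler <- feature_scaler(x)
  xs <- scale_features(x, scaler)
  set.seed(config$seed)
  w0 <- som_init(config, ncol(x))
  w <- som_train_cpp(w0, xs, config$width, config$height, config$rounds,
                     config$lr_start, config$lr_end,
                     config$radius_start, config$radius_end)
  structure(list(config = config, weights = w,
                 center = scaler$center, scale = scaler$scale,
                 dim = ncol(x)),
            class = "som")
}

#' @export
print.som <- function(x, ...) {
  cat(sprintf("Toroidal SOM: %d x %d neurons, %d input features, %d training rounds\n",
              x$config$width, x$config$height, x$dim, x$config$rounds))
  invisible(x)
}

#' Euclidean distance between grid cells on the torus
#'
#' Per-axis displacement is the shorter of the direct and the wrap-around
#' path, `min(|delta|, extent - |delta|)`; the distance is the Euclidean norm
#' of the two wrapped displacements. It is a metric on the grid.
#'
#' @param a,b Length-two integer vectors `(row, col)`, 0-based.
#' @param width,height Grid extent.
#' @return A non-negative number.
#' @examples
#' torus_distance(c(0, 0), c(4, 4), 5, 5)  # sqrt(2): wraps both axes
#' @export
torus_distance <- function(a, b, width, height) {
  check_coord(a, width, height)
  check_coord(b, width, height)
  dr <- abs(a[1] - b[1]); dr <- min(dr, height - dr)
  dc <- abs(a[2] - b[2]); dc <- min(dc, width - dc)
  sqrt(dr^2 + dc^2)
}

check_coord <- function(cc, width, height) {
  if (length(cc) != 2L || any(!is.finite(cc)))
    stop("coordinate must be a finite (row, col) pair")
  if (cc[1] < 0 || cc[1] >= height || cc[2] < 0 || cc[2] >= width)
    stop("coordinate out of grid bounds")
  invisible(cc)
}

#' Best-matching unit of a (pre-scaled) feature vector
#'
#' Low-level lookup: `x` must already be on the scale of the map's weights
#' (use [predict.som()] for raw data, which applies the stored scaler).
#' Ties are broken toward the lexicographically smallest `(row, col)`.
#'
#' @param grid A fitted `"som"`.
#' @param x Numeric vector of length `grid$dim`, already scaled.
#' @return Integer `(row, col)`, 0-based.
#' @export
find_bmu <- function(grid, x) {
  stopifnot(inherits(grid, "som"))
  if (length(x) != grid$dim) stop("feature dimension mismatch")
  cell <- som_bmu_cpp(grid$weights, matrix(as.numeric(x), nrow = 1))
  cell_to_coord(cell, grid$config$width)
}

cell_to_coord <- function(cell, width) {
  cbind(row = cell %/% width, col = cell %% width)
}

#' Map new data onto a fitted SOM
#'
#' @param object A fitted `"som"`.
#' @param newdata Feature matrix or data frame (raw scale; the stored
#'   scaler is applied).
#' @param type `"coords"` for an `n x 2` matrix of 0-based `(row, col)`
#'   BMU coordinates, `"cell"` for 0-based row-major cell indices.
#' @param ... Unused.
#' @return Coordinates or cell indices of each example's best-matching unit.
#' @export
predict.som <- function(object, newdata, type = c("coords", "cell"), ...) {
  type <- match.arg(type)
  newdata <- as_feature_matrix(newdata, "newdata")
  if (ncol(newdata) != object$dim) stop("feature dimension mismatch")
  xs <- scale_features(newdata, list(center = object$center, scale = object$scale))
  cells <- som_bmu_cpp(object$weights, xs)
  if (type == "cell") return(cells)
  cell_to_coord(cells, object$config$width)
}

#' Occupancy of a fitted SOM by a dataset
#'
#' Assigns every example to its best-matching unit, producing the partition
#' of examples over grid cells that the probability-expansion algorithm
#' starts from.
#'
#' @param grid A fitted `"som"`.
#' @param x Feature matrix or data frame (raw scale).
#' @return An object of class `"som_occupancy"`: `coords` (`n x 2`, 0-based),
#'   `width`, `height`, `n`.
#' @seealso [expand_probabilities()]
#' @export
som_project <- function(grid, x) {
  coords <- predict(grid, x)
  occupancy(coords, grid$config$width, grid$config$height)
}

#' Construct an occupancy map from explicit coordinates
#'
#' @param coords `n x 2` integer matrix of 0-based `(row, col)` cell
#'   coordinates, one row per example.
#' @param width,height Grid extent.
#' @return An object of class `"som_occupancy"`.
#' @export
occupancy <- function(coords, width, height) {
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(coords) < 1L) stop("occupancy must contain at least one example")
  apply(coords, 1, check_coord, width = width, height = height)
  structure(list(coords = coords, width = as.integer(width),
                 height = as.integer(height), n = nrow(coords)),
            class = "som_occupancy")
}

#' @export
print.som_occupancy <- function(x, ...) {
  occ <- nrow(unique(x$coords))
  cat(sprintf("SOM occupancy: %d examples in %d of %d cells (%d x %d torus)\n",
              x$n, occ, x$width * x$height, x$width, x$height))
  invisible(x)
}

#' Mean quantization error of a map on a dataset
#'
#' Average Euclidean distance (in standardized feature space) between each
#' example and its best-matching unit's weight vector.
#'
#' @inheritParams som_project
#' @return A non-negative number.
#' @export
quantization_error <- function(grid, x) {
  x <- as_feature_matrix(x)
  xs <- scale_features(x, list(center = grid$center, scale = grid$scale))
  cells <- som_bmu_cpp(grid$weights, xs)
  mean(sqrt(rowSums((xs - grid$weights[cells + 1L, , drop = FALSE])^2)))
}
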