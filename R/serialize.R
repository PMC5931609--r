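#' Save and restore fitted models as JSON
#'
#' Fitted maps and classifiers are persisted in a single self-describing
#' JSON container: the training configuration is echoed verbatim, weight
#' matrices and the probability map are stored as row-major numeric
#' arrays, and the class vocabulary, threshold and consensus-run count are
#' included for `"csom"` objects. The format is plain text and
#' platform-independent.
#'
#' @param object A fitted `"som"` or `"csom"`.
#' @param path Output path.
#' @return `path`, invisibly (writers); the restored object (readers).
#' @name model_io
NULL

som_to_list <- function(s) {
  list(type = "som",
       config = unclass(s$config),
       dim = s$dim,
       feature_center = unname(s$center),
       feature_scale = unname(s$scale),
       weights = as.vector(t(s$weights)))  # row-major: neuron by neuron
}

som_from_list <- function(l) {
  cfg <- do.call(som_config, l$config)
  w <- matrix(unlist(l$weights), ncol = l$dim, byrow = TRUE)
  structure(list(config = cfg, weights = w,
                 center = unlist(l$feature_center),
                 scale = unlist(l$feature_scale),
                 dim = as.integer(l$dim)),
            class = "som")
}

#' @rdname model_io
#' @export
write_som <- function(object, path) {
  stopifnot(inherits(object, "som"))
  jsonlite::write_json(som_to_list(object), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_io
#' @export
read_som <- function(path) {
  som_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname model_io
#' @export
write_csom <- function(object, path) {
  stopifnot(inherits(object, "csom"))
  pm <- object$prob_map
  H <- dim(pm$probs)[1]; W <- dim(pm$probs)[2]
  l <- list(type = "csom",
            som = som_to_list(object$som),
            classes = object$classes,
            P = object$P,
            threshold = object$threshold,
            prob_map = as.vector(aperm(pm$probs, c(3, 2, 1))),  # cell-major, class fastest
            origin = as.vector(t(pm$origin)),
            priors = as.vector(t(unclass(object$priors))),
            occupancy = list(coords = as.vector(t(object$occupancy$coords)),
                             width = object$occupancy$width,
                             height = object$occupancy$height))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_io
#' @export
read_csom <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(l$type, "csom")) stop("not a csom model file: ", path)
  grid <- som_from_list(l$som)
  W <- grid$config$width; H <- grid$config$height
  K <- length(l$classes)
  probs <- aperm(array(unlist(l$prob_map), dim = c(K, W, H)), c(3, 2, 1))
  dimnames(probs) <- list(NULL, NULL, l$classes)
  origin <- t(matrix(unlist(l$origin), nrow = W))
  pm <- structure(list(probs = probs, origin = origin, classes = l$classes),
                  class = "probability_map")
  priors <- matrix(unlist(l$priors), ncol = K, byrow = TRUE,
                   dimnames = list(NULL, l$classes))
  priors <- structure(priors, n_runs = as.integer(l$P), classes = l$classes,
                      class = c("prior_table", "matrix"))
  coords <- matrix(as.integer(unlist(l$occupancy$coords)), ncol = 2, byrow = TRUE)
  occ <- occupancy(coords, l$occupancy$width, l$occupancy$height)
  structure(list(som = grid, prob_map = pm, priors = priors, occupancy = occ,
                 P = as.integer(l$P), threshold = l$threshold,
                 classes = l$classes, call = NULL),
            class = "csom")
}

#' Export a probability map as CSV
#'
#' Writes one row per grid cell: `row`, `col` (0-based), `origin`
#' (`occupied` / `expanded`) and one probability column per class.
#'
#' @param object A fitted `"csom"` or a `"probability_map"`.
#' @param path Output path.
#' @export
write_probability_map <- function(object, path) {
  pm <- if (inherits(object, "csom")) object$prob_map else object
  stopifnot(inherits(pm, "probability_map"))
  H <- dim(pm$probs)[1]; W <- dim(pm$probs)[2]
  grid <- expand.grid(col = 0:(W - 1), row = 0:(H - 1))
  df <- data.frame(row = grid$row, col = grid$col,
                   origin = pm$origin[cbind(grid$row + 1, grid$col + 1)])
  for (k in seq_along(pm$classes))
    df[[pm$classes[k]]] <- pm$probs[cbind(grid$row + 1, grid$col + 1, k)]
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
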