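#' Labelled dataset container
#'
#' A light container pairing a numeric feature matrix with one label set
#' per example (singleton sets for ordinary single-label data) and an
#' ordered class vocabulary. All fitting and evaluation functions accept
#' the `x` / `labels` pair directly.
#'
#' @param x Numeric feature matrix or data frame.
#' @param labels Factor, character vector, or list of character vectors
#'   (multi-label).
#' @param classes Optional explicit vocabulary.
#' @return An object of class `"labelled_data"`: `x`, `labels` (list of
#'   character sets), `classes`.
#' @export
labelled_data <- function(x, labels, classes = NULL) {
  x <- as_feature_matrix(x)
  labels <- as_label_list(labels, classes)
  if (length(labels) != nrow(x))
    stop("number of label sets must match number of rows")
  structure(list(x = x, labels = labels, classes = attr(labels, "classes")),
            class = "labelled_data")
}

#' @export
print.labelled_data <- function(x, ...) {
  cnt <- table(factor(unlist(x$labels), levels = x$classes))
  cat(sprintf("Labelled dataset: %d examples, %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(x$classes)))
  print(cnt)
  invisible(x)
}

# internal: single-label factor view (multi-label sets collapse to first label)
label_factor <- function(d) {
  factor(vapply(d$labels, `[[`, character(1), 1L), levels = d$classes)
}

#' Read a delimited feature table with a label column
#'
#' Reads a header-bearing CSV/TSV in which every column except the label
#' column is numeric. Multi-label cells use `"|"` as a separator
#' (e.g. `"P-gp|MRP1"`).
#'
#' @param path File path.
#' @param label_column Name of the label column.
#' @param sep Field separator (default `","`).
#' @return A [labelled_data()] object, row order preserved.
#' @export
read_labelled_table <- function(path, label_column, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path)
  labels <- strsplit(as.character(df[[label_column]]), "|", fixed = TRUE)
  feat <- df[, setdiff(names(df), label_column), drop = FALSE]
  bad <- !vapply(feat, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric feature columns: ", paste(names(feat)[bad], collapse = ", "))
  labelled_data(as.matrix(feat), labels)
}

#' Write a labelled dataset as a delimited table
#'
#' @param d A [labelled_data()] object.
#' @param path Output path.
#' @param label_column Name for the label column.
#' @param sep Field separator.
#' @export
write_labelled_table <- function(d, path, label_column = "label", sep = ",") {
  stopifnot(inherits(d, "labelled_data"))
  df <- as.data.frame(d$x)
  df[[label_column]] <- vapply(d$labels, paste, character(1), collapse = "|")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a KEEL-format ".dat" file
#'
#' Parses the KEEL dialect used by the public imbalanced-classification
#' benchmark repository: an `@relation` line, typed `@attribute`
#' declarations, optional `@inputs` / `@outputs` lines, and an `@data`
#' section with comma- or whitespace-separated values. The output
#' attribute becomes the label; all input attributes must be numeric
#' (`real` or `integer`).
#'
#' @param path File path.
#' @return A [labelled_data()] object.
#' @export
read_keel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^@", lines)
  data_at <- which(tolower(lines) == "@data")
  if (length(data_at) != 1L) stop("malformed KEEL file: missing @data section")
  head_lines <- lines[seq_len(data_at - 1L)]
  attr_lines <- head_lines[grepl("^@attribute", head_lines, ignore.case = TRUE)]
  if (length(attr_lines) == 0L) stop("malformed KEEL file: no @attribute declarations")
  parse_attr <- function(l) {
    body <- trimws(sub("^@attribute\\s+", "", l, ignore.case = TRUE))
    if (grepl("\\{", body)) {
      name <- trimws(sub("\\{.*$", "", body))
      vals <- sub("^.*\\{", "", body); vals <- sub("\\}.*$", "", vals)
      list(name = name, type = "categorical",
           levels = trimws(strsplit(vals, ",")[[1]]))
    } else {
      parts <- strsplit(body, "\\s+")[[1]]
      type <- tolower(parts[2])
      if (!type %in% c("real", "integer"))
        stop("unknown attribute type '", parts[2], "' for ", parts[1])
      list(name = parts[1], type = "numeric", levels = NULL)
    }
  }
  attrs <- lapply(attr_lines, parse_attr)
  names(attrs) <- vapply(attrs, `[[`, character(1), "name")
  outputs_line <- head_lines[grepl("^@outputs?", head_lines, ignore.case = TRUE)]
  out_name <- if (length(outputs_line)) {
    trimws(sub("^@outputs?\\s+", "", outputs_line[1], ignore.case = TRUE))
  } else {
    names(attrs)[length(attrs)]  # KEEL convention: class is last
  }
  if (!out_name %in% names(attrs))
    stop("declared output attribute '", out_name, "' not among attributes")
  in_names <- setdiff(names(attrs), out_name)
  cat_in <- vapply(attrs[in_names], function(a) a$type == "categorical", logical(1))
  if (any(cat_in))
    stop("categorical input attributes not supported: ",
         paste(in_names[cat_in], collapse = ", "))
  rows <- lines[(data_at + 1L):length(lines)]
  rows <- rows[!grepl("^@", rows)]
  if (length(rows) == 0L) stop("malformed KEEL file: empty @data section")
  fields <- lapply(rows, function(r) trimws(strsplit(r, "[,[:space:]]+")[[1]]))
  nf <- length(attrs)
  if (any(lengths(fields) != nf))
    stop("malformed KEEL file: data row with wrong field count")
  tab <- do.call(rbind, fields)
  colnames(tab) <- names(attrs)
  feat <- apply(tab[, in_names, drop = FALSE], 2, as.numeric)
  feat <- matrix(feat, ncol = length(in_names),
                 dimnames = list(NULL, in_names))
  if (any(!is.finite(feat))) stop("non-numeric value in a numeric input attribute")
  labels <- tab[, out_name]
  classes <- if (attrs[[out_name]]$type == "categorical")
    attrs[[out_name]]$levels else sort(unique(labels))
  labelled_data(feat, factor(labels, levels = classes))
}

#' Label compounds as transporter substrates from correlation coefficients
#'
#' Applies the substrate-calling rule used for ABC-transporter screening
#' data: a compound is a substrate of a transporter when the Pearson
#' correlation between its cytotoxicity profile and the transporter's mRNA
#' levels is strictly below `threshold` (default -0.3, the conventional
#' cutoff). Compounds below the cutoff for several transporters become
#' multi-label; compounds below it for none are labelled
#' `"non-substrate"`.
#'
#' @param r Numeric matrix or data frame of correlation coefficients, one
#'   row per compound, one column per transporter, all values in `[-1, 1]`.
#' @param threshold Cutoff; default `-0.3` (strict `<`).
#' @return A list of character label sets, one per compound, with
#'   attribute `classes` = transporter names followed by `"non-substrate"`.
#' @examples
#' r <- rbind(c(`P-gp` = -0.5, MRP1 = -0.1, BCRP = 0.2))
#' label_substrates(r)[[1]]  # "P-gp"
#' @export
label_substrates <- function(r, threshold = -0.3) {
  r <- as.matrix(r)
  if (is.null(colnames(r))) stop("transporter columns must be named")
  if (any(!is.finite(r)) || any(r < -1 | r > 1))
    stop("correlation coefficients must be finite and within [-1, 1]")
  transporters <- colnames(r)
  labels <- apply(r, 1, function(row) {
    hit <- transporters[row < threshold]
    if (length(hit) == 0L) "non-substrate" else hit
  }, simplify = FALSE)
  structure(labels, classes = c(transporters, "non-substrate"))
}

#' Generate an imbalanced multi-class Gaussian dataset
#'
#' Draws each class from a seeded multivariate Gaussian with diagonal
#' covariance. This is the package's test-bed generator: it emulates the
#' imbalance regimes of the public benchmark collections (minority:majority
#' ratios from 1:2 up to 1:93) without shipping any external data.
#'
#' @param counts Named integer vector of per-class example counts.
#' @param means Matrix with one row per class (recycled single row allowed)
#'   giving the class mean vectors; its column count sets the feature
#'   dimension.
#' @param sds Per-class-by-feature standard deviations: a scalar, a matrix
#'   shaped like `means`, or a length-`dim` vector; all entries > 0.
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return A [labelled_data()] object with `sum(counts)` rows, classes in
#'   the order of `counts`.
#' @examples
#' d <- generate_imbalanced(c(maj = 930, min = 10),
#'                          means = rbind(c(0, 0), c(5, 5)), sds = 1, seed = 1)
#' table(unlist(d$labels))  # 1:93 imbalance
#' @export
generate_imbalanced <- function(counts, means, sds = 1, seed = 1L) {
  if (is.null(names(counts))) names(counts) <- paste0("class", seq_along(counts))
  counts <- vapply(counts, as.integer, integer(1))
  if (any(counts < 1L)) stop("all class counts must be >= 1")
  means <- as.matrix(means)
  if (nrow(means) == 1L) means <- means[rep(1L, length(counts)), , drop = FALSE]
  if (nrow(means) != length(counts)) stop("means must have one row per class")
  d <- ncol(means)
  if (length(sds) == 1L) sds <- matrix(sds, nrow = length(counts), ncol = d)
  if (is.null(dim(sds)) && length(sds) == d)
    sds <- matrix(sds, nrow = length(counts), ncol = d, byrow = TRUE)
  sds <- as.matrix(sds)
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("covariance entries (sds) must be positive and finite")
  set.seed(as.integer(seed))
  xs <- vector("list", length(counts))
  for (k in seq_along(counts)) {
    n <- counts[k]
    xs[[k]] <- matrix(stats::rnorm(n * d, mean = rep(means[k, ], each = n),
                                   sd = rep(sds[k, ], each = n)),
                      nrow = n, ncol = d)
  }
  x <- do.call(rbind, xs)
  colnames(x) <- paste0("f", seq_len(d))
  labels <- factor(rep(names(counts), counts), levels = names(counts))
  labelled_data(x, labels)
}

#' Three overlapping Gaussian classes at 1:1:10 imbalance
#'
#' The package's standard synthetic benchmark: two minority classes and one
#' ten-fold majority class placed at the corners of an equilateral triangle
#' of side 3 in two dimensions with unit spherical spread, giving partial
#' overlap between all class pairs. Used throughout the tests and the
#' acceptance analysis as a desk-scale stand-in for the public imbalanced
#' benchmarks.
#'
#' @param seed Integer seed.
#' @param n_min Size of each minority class (default 30).
#' @param ratio Majority / minority size ratio (default 10).
#' @return A [labelled_data()] object.
#' @export
sim_overlap3 <- function(seed = 1L, n_min = 30L, ratio = 10L) {
  side <- 3
  means <- rbind(c(0, 0), c(side, 0), c(side / 2, side * sqrt(3) / 2))
  generate_imbalanced(
    counts = c(A = n_min, B = n_min, C = n_min * ratio),
    means = means, sds = 1, seed = seed)
}

#' Synthetic transporter correlation table with prescribed class counts
#'
#' Builds a synthetic stand-in for a curated cytotoxicity-mRNA correlation
#' table: `n_pgp`, `n_mrp1` and `n_bcrp` compounds are given a coefficient
#' below the substrate cutoff for exactly one transporter each, and
#' `n_non` compounds stay above the cutoff for all three. Defaults
#' reproduce the per-class counts of the curated ABC-transporter screening
#' set (77 P-gp, 66 MRP1, 47 BCRP substrates, 1012 non-substrates). All
#' values are synthetic; no screening data is bundled.
#'
#' @param n_pgp,n_mrp1,n_bcrp,n_non Per-class compound counts.
#' @param threshold Substrate cutoff the coefficients are placed around.
#' @param seed Integer seed for the coefficient draws.
#' @return A numeric matrix with columns `P-gp`, `MRP1`, `BCRP`, one row
#'   per compound.
#' @export
sim_correlation_table <- function(n_pgp = 77L, n_mrp1 = 66L, n_bcrp = 47L,
                                  n_non = 1012L, threshold = -0.3, seed = 1L) {
  set.seed(as.integer(seed))
  n <- n_pgp + n_mrp1 + n_bcrp + n_non
  # start everyone above the cutoff for everything
  r <- matrix(runif(n * 3, min = threshold + 0.01, max = 0.6), ncol = 3,
              dimnames = list(NULL, c("P-gp", "MRP1", "BCRP")))
  lo <- function(k) runif(k, min = -0.9, max = threshold - 0.01)
  if (n_pgp > 0) r[seq_len(n_pgp), "P-gp"] <- lo(n_pgp)
  if (n_mrp1 > 0) r[n_pgp + seq_len(n_mrp1), "MRP1"] <- lo(n_mrp1)
  if (n_bcrp > 0) r[n_pgp + n_mrp1 + seq_len(n_bcrp), "BCRP"] <- lo(n_bcrp)
  r
}

#' Named descriptor sets for ABC-transporter substrate models
#'
#' Returns the published molecular-descriptor name lists used for binary
#' substrate classification of the three transporters, plus the
#' deduplicated, decorrelated 17-descriptor union (`DD17`), read from the
#' package's bundled text fixture. Useful for selecting columns by name
#' from an externally computed descriptor table; the package does not
#' compute descriptor values.
#'
#' @return A named list of character vectors (`P-gp`, `MRP1`, `BCRP`,
#'   `DD17`).
#' @export
descriptor_sets <- function() {
  path <- system.file("extdata", "descriptor_sets.txt", package = "csom")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(parts, function(p) trimws(strsplit(p[2], ",")[[1]]))
  names(out) <- vapply(parts, function(p) trimws(p[1]), character(1))
  out
}
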