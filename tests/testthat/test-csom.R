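test_that("Moore neighbourhoods wrap on the torus", {
  nb <- moore_neighbors(c(0, 0), 5, 5)
  expected <- rbind(c(4, 4), c(4, 0), c(4, 1), c(0, 4), c(0, 1),
                    c(1, 4), c(1, 0), c(1, 1))
  expect_equal(nrow(nb), 8)
  expect_setequal(paste(nb[, 1], nb[, 2]), paste(expected[, 1], expected[, 2]))
  # no boundary anywhere, and the relation is symmetric
  for (r in 0:4) for (c in 0:2) {
    nbi <- moore_neighbors(c(r, c), 3, 5)
    expect_equal(nrow(nbi), 8)
    for (j in seq_len(nrow(nbi))) {
      back <- moore_neighbors(nbi[j, ], 3, 5)
      expect_true(any(back[, 1] == r & back[, 2] == c))
    }
  }
  nb3 <- moore_neighbors(c(1, 1), 3, 3)
  expect_setequal(paste(nb3[, 1], nb3[, 2]),
                  setdiff(paste(rep(0:2, each = 3), rep(0:2, 3)), "1 1"))
  expect_error(moore_neighbors(c(5, 0), 5, 5), "bounds")
})

test_that("a single labelled example saturates the whole map with its class", {
  occ <- occupancy(rbind(c(1, 2)), 3, 3)
  pm <- expand_probabilities(occ, rbind(c(1, 0)), classes = c("A", "B"))
  expect_true(all(pm$probs[, , "A"] == 1))
  expect_true(all(pm$probs[, , "B"] == 0))
  # also on a larger, non-square grid
  occ <- occupancy(rbind(c(4, 1)), 7, 5)
  pm <- expand_probabilities(occ, rbind(c(0, 1)), classes = c("A", "B"))
  expect_true(all(pm$probs[, , "B"] == 1))
})

test_that("occupied cells keep the example-weighted mean of their distributions", {
  # one cell holding 2 class-A and 1 class-B examples
  occ <- occupancy(rbind(c(2, 2), c(2, 2), c(2, 2), c(0, 0)), 5, 5)
  dists <- rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 0))
  pm <- expand_probabilities(occ, dists, classes = c("A", "B"))
  expect_equal(unname(pm$probs[3, 3, ]), c(2 / 3, 1 / 3))
  expect_equal(pm$origin[3, 3], "occupied")
})

test_that("a cell adjacent to two unit sources splits its probability evenly", {
  occ <- occupancy(rbind(c(0, 0), c(2, 2)), 5, 5)
  pm <- expand_probabilities(occ, rbind(c(1, 0), c(0, 1)), classes = c("A", "B"))
  expect_equal(unname(pm$probs[2, 2, ]), c(0.5, 0.5))
})

test_that("wavefront expansion matches the brute-force fixed-point oracle", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    cfgr <- random_occ_config(W = 6, H = 6, K = 3,
                              n_occ = sample(c(1, 2, 3, 5, 8, 12), 1), seed = s)
    occ <- occupancy(cfgr$coords, 6, 6)
    pm <- expand_probabilities(occ, cfgr$dists)
    got <- flatten_probs(pm$probs)
    want <- oracle_expand(cfgr$coords, cfgr$dists, 6, 6)
    worst <- max(worst, max(abs(got - want)))
    expect_true(all(abs(rowSums(got) - 1) < 1e-9))
  }
  expect_lt(worst, 1e-12)
})

test_that("expansion leaves occupied cells bit-identical and shifts with the torus", {
  cfgr <- random_occ_config(W = 6, H = 6, K = 2, n_occ = 6, seed = 42)
  occ <- occupancy(cfgr$coords, 6, 6)
  # occupied vectors frozen: recompute the per-cell means independently
  pm <- expand_probabilities(occ, cfgr$dists)
  cells <- paste(cfgr$coords[, 1], cfgr$coords[, 2])
  for (cl in unique(cells)) {
    rows <- which(cells == cl)
    rc <- cfgr$coords[rows[1], ]
    expect_identical(unname(pm$probs[rc[1] + 1, rc[2] + 1, ]),
                     unname(colMeans(cfgr$dists[rows, , drop = FALSE])))
  }
  # translation equivariance
  shift <- c(2, 5)
  occ2 <- occupancy(cbind((cfgr$coords[, 1] + shift[1]) %% 6,
                          (cfgr$coords[, 2] + shift[2]) %% 6), 6, 6)
  pm2 <- expand_probabilities(occ2, cfgr$dists)
  rolled <- pm2$probs[(0:5 + shift[1]) %% 6 + 1, (0:5 + shift[2]) %% 6 + 1, ]
  expect_equal(rolled, pm$probs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("expansion rejects bad inputs", {
  occ <- occupancy(rbind(c(0, 0)), 4, 4)
  expect_error(expand_probabilities(occ, rbind(c(0.5, 0.2))), "sum to 1")
  expect_error(occupancy(matrix(numeric(0), 0, 2), 4, 4), "at least one")
})

test_that("consensus priors collapse to one-hot for single-class data", {
  set.seed(1)
  x <- matrix(rnorm(60), ncol = 2)
  pr <- consensus_priors(x, rep("only", 30), config = small_config(), P = 3)
  expect_true(all(pr == 1))
  expect_equal(attr(pr, "n_runs"), 3L)
})

test_that("P = 1 priors equal the single-run normalized neighbour tally", {
  d <- two_blobs(n = 15, gap = 8, seed = 3)
  cfg <- small_config(seed = 5)
  pr <- consensus_priors(d$x, d$labels, config = cfg, P = 1)
  # independent tally from the same single SOM run
  g <- som(d$x, cfg)
  co <- predict(g, d$x)
  yf <- factor(vapply(d$labels, `[[`, character(1), 1), levels = d$classes)
  manual <- matrix(0, nrow(d$x), 2)
  for (i in seq_len(nrow(d$x))) {
    nbhd <- rbind(co[i, ], moore_neighbors(co[i, ], 8, 8))
    inn <- which(paste(co[, 1], co[, 2]) %in% paste(nbhd[, 1], nbhd[, 2]))
    inn <- setdiff(inn, i)
    cnt <- if (length(inn)) table(yf[inn]) else table(yf[i])
    manual[i, ] <- as.numeric(cnt) / sum(cnt)
  }
  expect_equal(unclass(pr), manual, ignore_attr = TRUE)
})

test_that("examples in a class-overlap region receive mixed priors", {
  d <- generate_imbalanced(c(a = 60, b = 60), means = rbind(c(0, 0), c(1.5, 0)),
                           sds = 1, seed = 4)
  pr <- consensus_priors(d$x, d$labels, config = small_config(seed = 2), P = 5)
  mixed <- rowSums(pr > 0.05) == 2
  expect_gt(sum(mixed), 0)
})

test_that("all-one-class data yields a one-hot probability map end to end", {
  set.seed(2)
  x <- matrix(rnorm(40), ncol = 2)
  fit <- csom(x, rep("z", 20), P = 2, threshold = 0.5,
              config = small_config(seed = 1, w = 5, h = 5))
  expect_true(all(fit$prob_map$probs == 1))
  expect_equal(fit$classes, "z")
})

test_that("with one-hot priors the map reduces to expansion on raw labels", {
  d <- two_blobs(n = 20, gap = 12, seed = 6)   # so well separated that priors are one-hot
  cfg <- small_config(seed = 7)
  fit <- csom(d$x, d$labels, P = 1, threshold = 0.5, config = cfg)
  expect_true(all(abs(fit$priors - round(fit$priors)) < 1e-12))
  L <- matrix(0, 40, 2, dimnames = list(NULL, d$classes))
  L[cbind(1:40, as.integer(label <- factor(unlist(d$labels), levels = d$classes)))] <- 1
  pm_raw <- expand_probabilities(fit$occupancy, L, classes = d$classes)
  expect_equal(pm_raw$probs, fit$prob_map$probs)
})

test_that("separated classes produce non-empty contiguous argmax regions", {
  d <- generate_imbalanced(c(a = 20, b = 20, c = 100),
                           means = rbind(c(0, 0), c(4, 0), c(2, 3.5)),
                           sds = 1, seed = 9)
  fit <- csom(d$x, d$labels, P = 3, threshold = 0.5,
              config = som_config(10, 10, rounds = 25, radius_start = 5, seed = 30))
  arg <- apply(fit$prob_map$probs, c(1, 2), which.max)
  expect_setequal(unique(as.vector(arg)), 1:3)
})

test_that("prediction gates on a strict probability threshold", {
  d <- two_blobs(n = 20, gap = 10, seed = 10)
  fit <- csom(d$x, d$labels, P = 2, threshold = 0.9, config = small_config(seed = 3))
  pr0 <- predict(fit, d$x, threshold = 0)
  expect_false(any(pr0 == NON_CONCLUSIVE))        # t = 0: always conclusive
  probs <- predict(fit, d$x, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, 40), tolerance = 1e-9)
  # decisions follow the strict > rule at any threshold
  for (t in c(0.5, 0.9, 1)) {
    cl <- predict(fit, d$x, threshold = t)
    conclusive <- cl != NON_CONCLUSIVE
    expect_equal(unname(conclusive), unname(apply(probs, 1, max) > t))
  }
  expect_error(predict(fit, matrix(0, 1, 5)), "dimension")
})

test_that("non-conclusive counts grow monotonically with the threshold", {
  d <- sim_overlap3(seed = 2, n_min = 15)
  fit <- csom(d$x, d$labels, P = 3, threshold = 0.5,
              config = som_config(10, 10, rounds = 25, radius_start = 5, seed = 12))
  counts <- vapply(seq(0, 1, by = 0.1), function(t)
    sum(predict(fit, d$x, threshold = t) == NON_CONCLUSIVE), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
})

test_that("a fitted model survives a JSON round trip", {
  d <- sim_overlap3(seed = 3, n_min = 10)
  fit <- csom(d$x, d$labels, P = 2, threshold = 0.6,
              config = small_config(seed = 21, w = 6, h = 6))
  path <- tempfile(fileext = ".json")
  write_csom(fit, path)
  back <- read_csom(path)
  expect_equal(back$prob_map$probs, fit$prob_map$probs)
  expect_equal(back$threshold, fit$threshold)
  expect_equal(predict(back, d$x), predict(fit, d$x))
  unlink(path)
})
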