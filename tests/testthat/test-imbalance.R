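test_that("SMOTE points are convex combinations of same-class neighbours", {
  x <- rbind(c(0, 0), c(1, 1), c(10, 10), c(11, 11), c(12, 12))
  y <- c("min", "min", "maj", "maj", "maj")
  out <- smote(x, y, target_counts = c(min = 3, maj = 3), k = 1, seed = 1)
  new_pt <- out$x[out$synthetic, ]
  expect_equal(new_pt[1], new_pt[2])                 # lies on the segment (l, l)
  expect_true(new_pt[1] >= 0 && new_pt[1] <= 1)
  expect_equal(as.character(out$y[out$synthetic]), "min")
})

test_that("coincident minority points synthesize copies of themselves", {
  x <- rbind(c(2, 3), c(2, 3), c(9, 9), c(9, 8), c(8, 9))
  y <- c("min", "min", "maj", "maj", "maj")
  out <- smote(x, y, target_counts = c(min = 5, maj = 3), k = 1, seed = 2)
  expect_true(all(apply(out$x[out$synthetic, ], 1, function(p) all(p == c(2, 3)))))
})

test_that("SMOTE respects exact target counts and is a no-op at current counts", {
  d <- sim_overlap3(seed = 5, n_min = 12)
  y <- factor(unlist(d$labels), levels = d$classes)
  out <- smote(d$x, y, seed = 3)
  expect_equal(as.vector(table(out$y)), rep(120, 3))
  expect_identical(out$x[seq_len(nrow(d$x)), ], d$x)   # originals verbatim
  noop <- smote(d$x, y, target_counts = table(y), seed = 3)
  expect_identical(noop$x, d$x)
  expect_false(any(noop$synthetic))
  expect_error(smote(rbind(c(0, 0), c(1, 1)), c("a", "b"),
                     target_counts = c(a = 3, b = 1)), "fewer than 2")
})

test_that("SMOTE output stays in the per-class bounding box, seeds reproduce", {
  for (s in 1:50) {
    d <- generate_imbalanced(c(m = 5, M = 40),
                             means = rbind(c(0, 0), c(6, 6)), sds = 1, seed = s)
    y <- factor(unlist(d$labels), levels = d$classes)
    out <- smote(d$x, y, k = 3, seed = s)
    syn <- out$x[out$synthetic, , drop = FALSE]
    box <- apply(d$x[1:5, ], 2, range)
    expect_true(all(sweep(syn, 2, box[1, ], ">=") & sweep(syn, 2, box[2, ], "<=")))
    expect_true(all(out$y[out$synthetic] == "m"))
  }
  a <- smote(d$x, y, seed = 7); b <- smote(d$x, y, seed = 7)
  expect_identical(a$x, b$x)
})

test_that("random undersampling hits exact counts without inventing rows", {
  set.seed(4)
  x <- matrix(rnorm(220), ncol = 2)
  y <- rep(c("maj", "min"), c(100, 10))
  out <- random_undersample(x, y, c(maj = 10), seed = 5)
  expect_equal(as.vector(table(out$y)), c(10, 10))
  expect_true(all(out$x %in% x))
  out2 <- random_undersample(x, y, c(maj = 10), seed = 5)
  expect_identical(out$kept, out2$kept)
  idt <- random_undersample(x, y, c(maj = 100, min = 10), seed = 1)
  expect_identical(idt$x, x)
  expect_error(random_undersample(x, y, c(min = 11)), "exceeds")
})

test_that("tallies conserve examples and segregate non-conclusive predictions", {
  truth <- rep(c("a", "b"), each = 5)
  perfect <- prediction_tally(truth, truth)
  expect_equal(perfect$matrix, diag(c(5L, 5L)), ignore_attr = TRUE)
  expect_equal(perfect$n_nonconclusive, 0L)
  allnc <- prediction_tally(truth, rep(NON_CONCLUSIVE, 10), classes = c("a", "b"))
  expect_true(all(allnc$matrix == 0))
  expect_equal(allnc$n_nonconclusive, 10L)
  mixed <- prediction_tally(truth, c("a", "a", "b", NON_CONCLUSIVE, "a",
                                     "b", "b", NON_CONCLUSIVE, NON_CONCLUSIVE, "a"))
  expect_equal(sum(mixed$matrix), 7)
  expect_equal(sum(mixed$matrix) + mixed$n_nonconclusive, mixed$n_total)
  expect_error(prediction_tally(truth, rep("zz", 10), classes = c("a", "b")),
               "unknown")
})

test_that("metrics match closed forms on constructed confusions", {
  cr <- prediction_tally(rep(c("a", "b"), c(50, 50)),
                         c(rep("a", 50), rep("a", 25), rep("b", 25)))
  m <- classification_metrics(cr)
  expect_equal(unname(m$recall), c(1, 0.5))
  expect_equal(m$mean_recall, 0.75)
  expect_equal(m$accuracy, 0.75)

  perfect <- classification_metrics(prediction_tally(rep(c("a", "b"), 5),
                                                     rep(c("a", "b"), 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mean_recall, 1)
  expect_equal(perfect$gmean_recall, 1)
  expect_equal(perfect$f_measure, 1)

  uni <- prediction_tally(rep(c("a", "a", "b", "b"), 1), c("a", "b", "a", "b"))
  mu <- classification_metrics(uni)
  expect_equal(mu$f_measure, 0.5)
  expect_equal(mu$mean_recall, 0.5)

  expect_error(classification_metrics(
    prediction_tally(c("a", "b"), rep(NON_CONCLUSIVE, 2), classes = c("a", "b"))),
    "non-conclusive")
})

test_that("mean recall ignores class duplication while accuracy does not", {
  truth <- rep(c("a", "b"), c(10, 40))
  pred <- c(rep("a", 8), rep("b", 2), rep("b", 30), rep("a", 10))
  base <- classification_metrics(prediction_tally(truth, pred))
  # duplicate every class-a example (same per-class recall, shifted accuracy)
  truth2 <- c(truth, rep("a", 10)); pred2 <- c(pred, rep("a", 8), rep("b", 2))
  dup <- classification_metrics(prediction_tally(truth2, pred2))
  expect_equal(dup$mean_recall, base$mean_recall)
  expect_false(isTRUE(all.equal(dup$accuracy, base$accuracy)))
})

test_that("geometric mean recall never exceeds the arithmetic mean", {
  set.seed(11)
  for (i in 1:30) {
    K <- sample(2:5, 1)
    mat <- matrix(rpois(K * K, 4), K, K) + diag(K)
    cr <- structure(list(matrix = mat, n_nonconclusive = 0L, n_total = sum(mat)),
                    class = "confusion_result")
    m <- classification_metrics(cr)
    expect_lte(m$gmean_recall, m$mean_recall + 1e-12)
  }
})
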