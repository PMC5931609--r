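# Independent reference implementations used to check the package's fast
# paths. Deliberately written with explicit per-cell loops and their own
# neighbour arithmetic; they share no code with the package internals.

# Brute-force fixed-point propagation over the torus: every iteration scans
# all cells, fills those adjacent to a previously filled cell from a snapshot
# of the filled state, and repeats until nothing changes.
# Returns an (W*H) x K matrix in row-major cell order (cell = row*W + col).
oracle_expand <- function(coords, dists, W, H) {
  m <- W * H
  K <- ncol(dists)
  vec <- matrix(0, m, K)
  wt <- numeric(m)
  for (i in seq_len(nrow(coords))) {
    ci <- coords[i, 1] * W + coords[i, 2] + 1
    vec[ci, ] <- vec[ci, ] + dists[i, ]
    wt[ci] <- wt[ci] + 1
  }
  occ <- wt > 0
  vec[occ, ] <- vec[occ, , drop = FALSE] / wt[occ]
  filled <- occ
  neighbour_cells <- function(r, c) {
    out <- matrix(0, 0, 2)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- rbind(out, c((r + dr) %% H, (c + dc) %% W))
    }
    unique(out)
  }
  repeat {
    snapshot <- filled
    newly <- list()
    for (cell in which(!snapshot)) {
      r <- (cell - 1) %/% W
      c <- (cell - 1) %% W
      nb <- neighbour_cells(r, c)
      nbi <- nb[, 1] * W + nb[, 2] + 1
      srcs <- nbi[snapshot[nbi]]
      if (length(srcs) == 0) next
      contrib <- colSums(vec[srcs, , drop = FALSE] * wt[srcs])
      newly[[length(newly) + 1]] <- list(cell = cell, v = contrib / sum(contrib))
    }
    if (length(newly) == 0) break
    for (nw in newly) {
      vec[nw$cell, ] <- nw$v
      wt[nw$cell] <- 1
      filled[nw$cell] <- TRUE
    }
  }
  vec
}

# flatten a probability_map array (H x W x K) to row-major cell order
flatten_probs <- function(probs) {
  K <- dim(probs)[3]
  sapply(seq_len(K), function(k) as.vector(t(probs[, , k])))
}

# random occupancy configuration on a WxH torus: n_occ distinct cells, each
# holding 1-3 examples with random labels from K classes
random_occ_config <- function(W, H, K, n_occ, seed) {
  set.seed(seed)
  cells <- sample(W * H, n_occ) - 1
  coords <- NULL
  labels <- integer(0)
  for (cell in cells) {
    cnt <- sample(3, 1)
    coords <- rbind(coords, matrix(c(rep(cell %/% W, cnt), rep(cell %% W, cnt)),
                                   ncol = 2))
    labels <- c(labels, sample(K, cnt, replace = TRUE))
  }
  dists <- matrix(0, length(labels), K)
  dists[cbind(seq_along(labels), labels)] <- 1
  list(coords = coords, dists = dists)
}

# two-sided p-value of a t statistic from numerical quadrature of the
# closed-form t density (no calls to pt/dt)
oracle_t_pvalue <- function(tstat, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, lower = abs(tstat), upper = Inf)$value
}

# two well-separated Gaussian blobs in 2D
two_blobs <- function(n = 40, gap = 10, seed = 1) {
  generate_imbalanced(c(a = n, b = n), means = rbind(c(0, 0), c(gap, gap)),
                      sds = 1, seed = seed)
}

small_config <- function(seed = 1, w = 8, h = 8, rounds = 20)
  som_config(w, h, rounds = rounds, radius_start = max(w, h) / 2, seed = seed)
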