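# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense projectors via generalized inverses,
# double loops, and an O(n^3) re-scanning UPGMA.

# projection matrix onto the column space of X
proj_mat <- function(X) {
  X <- as.matrix(X)
  X %*% MASS::ginv(crossprod(X)) %*% t(X)
}

# sequential sums of squares / cross-products from explicit projectors.
# order: list of model matrices, innermost first (without intercept-only).
naive_seq_cp <- function(x, y, mats) {
  n <- length(x)
  H_prev <- matrix(1 / n, n, n)  # grand-mean projector
  out <- numeric(length(mats) + 1)
  for (s in seq_along(mats)) {
    H <- proj_mat(cbind(1, mats[[s]]))
    out[s] <- drop(t(x) %*% (H - H_prev) %*% y)
    H_prev <- H
  }
  out[length(mats) + 1] <- drop(t(x) %*% (diag(n) - H_prev) %*% y)
  out
}

# model matrices for the two sequential orders of the lattice analysis
lattice_mats <- function(plots) {
  R <- stats::model.matrix(~ 0 + factor(replication), plots)
  A <- stats::model.matrix(~ 0 + factor(accession), plots)
  B <- stats::model.matrix(~ 0 + factor(paste(replication, block)), plots)
  list(
    orderA = list(R, cbind(R, A), cbind(R, A, B)),
    orderB = list(R, cbind(R, B), cbind(R, B, A))
  )
}

# brute-force Euclidean distances on an already-standardized matrix
naive_distance <- function(z) {
  g <- nrow(z)
  D <- matrix(0, g, g)
  for (i in seq_len(g)) for (j in seq_len(g))
    D[i, j] <- sqrt(sum((z[i, ] - z[j, ])^2))
  D
}

# O(n^3) UPGMA that re-derives every inter-cluster distance from the
# original matrix at each step (no Lance-Williams update), with the same
# lexicographic tie-break. Returns member sets (sorted) and heights.
naive_upgma <- function(D) {
  g <- nrow(D)
  clusters <- as.list(seq_len(g))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    clusters <- clusters[order(vapply(clusters, min, 1L))]
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# member sets of each internal node of an upgma_cluster() result
merge_member_sets <- function(mm) {
  mm <- unname(as.matrix(mm))
  sets <- vector("list", nrow(mm))
  leaf <- function(v) if (v < 0) -v else sets[[v]]
  for (s in seq_len(nrow(mm))) sets[[s]] <- sort(c(leaf(mm[s, 1]), leaf(mm[s, 2])))
  sets
}

# random symmetric distance matrix on n points (from random coordinates,
# so the triangle inequality holds)
random_distance <- function(n, dim = 3) {
  z <- matrix(stats::rnorm(n * dim), n)
  as.matrix(stats::dist(z))
}

# plot table with fully known effects, built without simulate_trial()
manual_trial <- function(design, mu, G, sigma_b = 0, sigma_e = 0) {
  lay <- design$layout
  k <- design$k
  b <- stats::rnorm(2 * k, 0, sigma_b)
  y <- mu + G[lay$accession] +
    b[(lay$replication - 1) * k + lay$block] +
    stats::rnorm(nrow(lay), 0, sigma_e)
  cbind(lay, y = y)
}
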