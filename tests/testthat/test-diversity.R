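test_that("standardized Euclidean distances match closed forms and the brute-force oracle", {
  X <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(5, 6, 7, 8))
  rownames(X) <- c("a", "b", "c")
  sd_res <- standardize_and_distance(X)
  expect_equal(sd_res$D["a", "b"], 0)
  # profiles one standardized unit apart in all 11 traits
  z <- rbind(rep(0, 11), rep(1, 11))
  expect_equal(sqrt(sum((z[1, ] - z[2, ])^2)), sqrt(11))
  set.seed(10)
  Y <- matrix(rnorm(24), 6, 4)
  res <- standardize_and_distance(Y)
  expect_equal(res$D, naive_distance(res$z), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(diag(res$D), rep(0, 6), ignore_attr = TRUE)
  expect_equal(res$D, t(res$D))
})

test_that("zero-variance traits are refused by name", {
  X <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(standardize_and_distance(X), "flat")
})

test_that("standardization is idempotent", {
  set.seed(11)
  X <- matrix(rnorm(40), 8, 5)
  z1 <- standardize_and_distance(X)$z
  z2 <- standardize_and_distance(z1)$z
  expect_equal(unclass(z1), unclass(z2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("distance summaries reduce to hand arithmetic", {
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s <- distance_summary(D)
  overall <- s[s$accession == "Overall", ]
  expect_equal(overall$mean, 4)
  expect_equal(overall$min, 2)
  expect_equal(overall$max, 6)
  expect_equal(s$mean[s$accession == "A"], 3)
  # equilateral: per-accession sd and cv are zero
  E <- matrix(3, 4, 4); diag(E) <- 0
  se <- distance_summary(E)
  expect_true(all(se$sd[1:4] == 0))
  expect_true(all(se$cv_percent[1:4] == 0))
  # 49 accessions enter 1176 unique pairs
  set.seed(12)
  D49 <- random_distance(49)
  expect_equal(length(D49[upper.tri(D49)]), 1176)
  expect_error(distance_summary(D[1:2, 1:2]), "size error")
})

test_that("UPGMA reproduces hand agglomerations", {
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  r2 <- upgma_cluster(D2, K = 1)
  expect_equal(r2$merges$height, 3)
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  r <- upgma_cluster(D, K = 2)
  expect_equal(r$merges$height, c(2, 5))   # {A,B} at 2, then with C at (4+6)/2
  expect_equal(unname(r$assignment), c(1, 1, 2))
  expect_equal(r$clusters[["1"]], c("A", "B"))
})

test_that("the merge list equals an O(n^3) re-scanning oracle on random matrices", {
  set.seed(13)
  for (i in 1:10) {
    D <- random_distance(8)
    mine <- upgma_cluster(D, K = 1)
    oracle <- naive_upgma(D)
    expect_equal(merge_member_sets(as.matrix(mine$merges[, 1:2])), oracle$merges)
    expect_equal(mine$merges$height, oracle$heights, tolerance = 1e-10)
    # independent cross-check against average-linkage hclust
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(sort(mine$merges$height), sort(hc$height), tolerance = 1e-10)
    expect_equal(unname(mine$assignment),
                 unname(stats::cutree(hc, k = 1)), ignore_attr = TRUE)
  }
})

test_that("UPGMA heights are monotone and the tree is ultrametric", {
  set.seed(14)
  D <- random_distance(12)
  r <- upgma_cluster(D, K = 3)
  expect_true(all(diff(r$merges$height) >= -1e-12))
  coph <- as.matrix(stats::cophenetic(r$hclust))
  expect_true(all(coph >= -1e-12))
  # ultrametric: for any triple, the two largest cophenetic distances tie
  for (trip in list(c(1, 2, 3), c(4, 7, 11), c(2, 6, 9))) {
    dd <- sort(c(coph[trip[1], trip[2]], coph[trip[1], trip[3]],
                 coph[trip[2], trip[3]]))
    expect_equal(dd[2], dd[3], tolerance = 1e-10)
  }
})

test_that("relabelling accessions permutes but never changes the clustering", {
  set.seed(15)
  D <- random_distance(9)
  rownames(D) <- colnames(D) <- paste0("acc", 1:9)
  perm <- sample(9)
  Dp <- D[perm, perm]
  r1 <- upgma_cluster(D, K = 3)
  r2 <- upgma_cluster(Dp, K = 3)
  part1 <- split(names(r1$assignment), r1$assignment)
  part2 <- split(names(r2$assignment), r2$assignment)
  norm <- function(p) unname(lapply(p, sort))[order(vapply(lapply(p, sort), `[`, "", 1))]
  expect_setequal(unname(unlist(part1)), unname(unlist(part2)))
  expect_equal(norm(part1), norm(part2))
  expect_equal(sort(r1$merges$height), sort(r2$merges$height), tolerance = 1e-10)
})

test_that("the newick export is ultrametric with half-height branch lengths", {
  set.seed(16)
  D <- random_distance(6)
  rownames(D) <- colnames(D) <- paste0("t", 1:6)
  r <- upgma_cluster(D, K = 2)
  ph <- ape::read.tree(text = r$newick)
  depths <- ape::node.depth.edgelength(ph)[seq_len(6)]
  expect_equal(max(depths), max(r$merges$height) / 2, tolerance = 1e-6)
  expect_equal(stats::sd(depths), 0, tolerance = 1e-6)  # all leaves equidistant
  expect_setequal(ph$tip.label, rownames(D))
})

test_that("cluster means aggregate and conserve the overall mean", {
  set.seed(17)
  X <- matrix(rnorm(40, 10), 8, 5,
              dimnames = list(paste0("a", 1:8), paste0("t", 1:5)))
  one <- cluster_means(X, setNames(rep(1L, 8), rownames(X)))
  expect_equal(unlist(one[1, -(1:2)]), colMeans(X), ignore_attr = TRUE)
  asg <- setNames(c(1L, rep(2L, 7)), rownames(X))
  cm <- cluster_means(X, asg)
  expect_equal(unlist(cm[1, -(1:2)]), X[1, ], ignore_attr = TRUE)  # singleton
  asg2 <- setNames(rep(1:2, each = 4), rownames(X))
  cm2 <- cluster_means(X, asg2)
  expect_equal(colMeans(rbind(unlist(cm2[1, -(1:2)]), unlist(cm2[2, -(1:2)]))),
               colMeans(X), ignore_attr = TRUE)
  expect_error(cluster_means(X, setNames(rep(1L, 8), paste0("b", 1:8))),
               "key error")
})

test_that("out-of-range cluster counts are rejected", {
  D <- random_distance(5)
  expect_error(upgma_cluster(D, K = 0), "value error")
  expect_error(upgma_cluster(D, K = 6), "value error")
})
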