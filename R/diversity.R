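#' Standardize traits and compute the Euclidean distance matrix
#'
#' Each trait is centred and scaled to unit sample standard deviation
#' (n - 1 denominator); accession dissimilarity is the Euclidean distance
#' on the standardized profiles.
#'
#' @param means Accession x trait numeric matrix or data frame with
#'   accession ids as row names.
#' @return List with `z` (standardized matrix) and `D` (g x g symmetric
#'   distance matrix, zero diagonal).
#' @export
standardize_and_distance <- function(means) {
  X <- as.matrix(means)
  if (nrow(X) < 2) stop("size error: need at least 2 accessions", call. = FALSE)
  if (anyNA(X)) stop("standardization error: missing cells in the mean matrix", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("standardization error: zero-variance trait(s): ",
         paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
  z <- scale(X)
  D <- as.matrix(stats::dist(z))
  dimnames(D) <- list(rownames(X), rownames(X))
  list(z = z, D = D)
}

#' Distance summaries per accession and overall
#'
#' For each accession: minimum, maximum, mean, standard deviation and
#' coefficient of variation of its g - 1 distances to the other
#' accessions; the overall row summarizes the g(g-1)/2 unique pairs.
#'
#' @param D Symmetric distance matrix (g >= 3).
#' @return Data frame with columns `accession`, `min`, `max`, `mean`,
#'   `sd`, `cv_percent`; the last row is labelled `"Overall"`.
#' @export
distance_summary <- function(D) {
  D <- as.matrix(D)
  g <- nrow(D)
  if (g < 3) stop("size error: need at least 3 accessions", call. = FALSE)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(g))
  per <- t(vapply(seq_len(g), function(i) {
    d <- D[i, -i]
    c(min(d), max(d), mean(d), stats::sd(d))
  }, numeric(4)))
  pairs <- D[upper.tri(D)]
  all_row <- c(min(pairs), max(pairs), mean(pairs), stats::sd(pairs))
  out <- rbind(per, all_row)
  out <- data.frame(accession = c(ids, "Overall"), out, row.names = NULL)
  names(out) <- c("accession", "min", "max", "mean", "sd")
  out$cv_percent <- 100 * out$sd / out$mean
  out
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration: at each step the pair of clusters with
#' the smallest size-weighted mean inter-cluster distance is merged, and
#' the distance of the merged cluster AB to any C is
#' \eqn{(|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)}. Ties are broken towards
#' the lexicographically smallest pair of smallest member indices, so the
#' dendrogram is reproducible. Merge heights are the raw merging
#' distances; the exported newick string halves them into ultrametric
#' branch lengths. Cutting after g - K merges yields the K-cluster
#' partition, clusters numbered by the first accession index they contain.
#'
#' @param D Symmetric distance matrix with accession ids as dimnames.
#' @param K Number of clusters to extract (1 <= K <= g).
#' @return List with `merges` (data frame: `a`, `b`, `height`, `size`
#'   using hclust conventions: negative = leaf), `hclust` (an equivalent
#'   `stats::hclust` object), `assignment` (named integer vector),
#'   `clusters` (list of member id vectors) and `newick`.
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma_cluster(D, K = 2)$merges$height   # 2, 5
#' @export
upgma_cluster <- function(D, K) {
  D <- as.matrix(D)
  g <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- as.character(seq_len(g))
  ids <- rownames(D)
  if (!is.numeric(K) || K < 1 || K > g)
    stop("value error: K must be between 1 and the number of accessions", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-10 || any(diag(D) != 0))
    stop("value error: D must be symmetric with a zero diagonal", call. = FALSE)

  # active cluster state
  active <- seq_len(g)                  # indices into bookkeeping vectors
  members <- as.list(seq_len(g))        # smallest member index defines order
  sizes <- rep(1L, g)
  node_id <- -seq_len(g)                # hclust coding: leaves negative
  d <- D
  merge_mat <- matrix(0L, g - 1, 2)
  heights <- numeric(g - 1)
  merge_sizes <- integer(g - 1)

  for (step in seq_len(g - 1)) {
    # scan pairs in lexicographic order of (smallest member, smallest member)
    ord <- active[order(vapply(members[active], min, 1L))]
    best <- NULL; best_d <- Inf
    for (ii in seq_len(length(ord) - 1)) {
      for (jj in (ii + 1):length(ord)) {
        dij <- d[ord[ii], ord[jj]]
        if (dij < best_d) { best_d <- dij; best <- c(ord[ii], ord[jj]) }
      }
    }
    a <- best[1]; b <- best[2]
    merge_mat[step, ] <- c(node_id[a], node_id[b])
    heights[step] <- best_d
    merge_sizes[step] <- sizes[a] + sizes[b]
    # update distances to the merged cluster (stored in slot a)
    for (c in setdiff(active, c(a, b))) {
      d[a, c] <- d[c, a] <- (sizes[a] * d[a, c] + sizes[b] * d[b, c]) /
        (sizes[a] + sizes[b])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    node_id[a] <- step
    active <- setdiff(active, b)
  }

  hc <- structure(
    list(merge = merge_mat, height = heights, order = hclust_leaf_order(merge_mat),
         labels = ids, method = "average",
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
  assignment <- cut_upgma(merge_mat, g, K)
  names(assignment) <- ids
  clusters <- split(ids, assignment)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(
    merges = data.frame(a = merge_mat[, 1], b = merge_mat[, 2],
                        height = heights, size = merge_sizes),
    hclust = hc, assignment = assignment, clusters = clusters,
    newick = newick
  )
}

# leaf order by recursive traversal of the merge tree
hclust_leaf_order <- function(merge_mat) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge_mat[node, 1]), expand(merge_mat[node, 2]))
  }
  expand(nrow(merge_mat))
}

# membership after the first g - K merges; clusters numbered by smallest
# member index
cut_upgma <- function(merge_mat, g, K) {
  parent <- seq_len(g)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  leaves_of <- vector("list", g - 1)
  for (s in seq_len(g - K)) {
    l1 <- if (merge_mat[s, 1] < 0) -merge_mat[s, 1] else leaves_of[[merge_mat[s, 1]]][1]
    l2 <- if (merge_mat[s, 2] < 0) -merge_mat[s, 2] else leaves_of[[merge_mat[s, 2]]][1]
    r1 <- find(l1); r2 <- find(l2)
    parent[max(r1, r2)] <- min(r1, r2)
    leaves_of[[s]] <- c(l1, l2)
  }
  roots <- vapply(seq_len(g), find, 1L)
  stats::setNames(match(roots, sort(unique(roots))), NULL)
}

#' Per-cluster trait means
#'
#' Arithmetic means of the raw (unstandardized) accession means per
#' cluster and trait, with an overall row over all accessions.
#'
#' @param means Accession x trait matrix (row names = accession ids).
#' @param assignment Named integer vector mapping accession id to cluster.
#' @return Data frame: one row per cluster (`cluster`, `n`, trait means)
#'   plus an `"Overall"` row.
#' @export
cluster_means <- function(means, assignment) {
  X <- as.matrix(means)
  ids <- rownames(X)
  if (!all(names(assignment) %in% ids) || !all(ids %in% names(assignment)))
    stop("key error: cluster assignment and mean matrix accessions disagree",
         call. = FALSE)
  cl <- assignment[ids]
  ks <- sort(unique(cl))
  rows <- lapply(ks, function(kk) {
    sub <- X[cl == kk, , drop = FALSE]
    data.frame(cluster = as.character(kk), n = nrow(sub),
               t(colMeans(sub)), check.names = FALSE)
  })
  overall <- data.frame(cluster = "Overall", n = nrow(X), t(colMeans(X)),
                        check.names = FALSE)
  do.call(rbind, c(rows, list(overall)))
}
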