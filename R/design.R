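#' Construct a simple (square) lattice design
#'
#' A simple lattice accommodates `g = k^2` genotypes in two replications of
#' `k` incomplete blocks with `k` plots each. In the canonical arrangement
#' genotype `(i, j)` of the `k x k` square sits in row-block `i` of
#' replication 1 and column-block `j` of replication 2, so any two genotypes
#' co-occur in at most one block. Supplying a seed permutes genotype labels
#' only; the downstream analysis is invariant to this relabelling.
#'
#' @param k Block size (plots per incomplete block), an integer >= 2.
#' @param r Number of replications; must be 2 for a simple lattice.
#' @param seed Optional integer; if given, genotype labels are assigned to
#'   the canonical positions by a reproducible random permutation.
#' @return An object of class `lattice_design`: a list with elements `k`,
#'   `r`, `g` and `layout`, the latter a data frame with columns
#'   `accession`, `replication`, `block` (one row per plot).
#' @examples
#' d <- make_design(7)
#' d$g                     # 49 genotypes
#' nrow(d$layout)          # 98 plots
#' @export
make_design <- function(k, r = 2, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2)
    stop("design error: block size 'k' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || r != 2)
    stop("design error: a simple lattice has exactly r = 2 replications", call. = FALSE)
  k <- as.integer(k)
  g <- k * k
  labels <- seq_len(g)
  if (!is.null(seed)) {
    labels <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(as.integer(seed))
      sample(labels)
    })
  }
  # position (i, j) -> row-block i in rep 1, column-block j in rep 2
  idx <- matrix(labels, nrow = k, byrow = TRUE)
  rep1 <- data.frame(
    accession   = as.vector(t(idx)),
    replication = 1L,
    block       = rep(seq_len(k), each = k)
  )
  rep2 <- data.frame(
    accession   = as.vector(idx),
    replication = 2L,
    block       = rep(seq_len(k), each = k)
  )
  design <- structure(
    list(k = k, r = 2L, g = g, layout = rbind(rep1, rep2)),
    class = "lattice_design"
  )
  validate_design(design)
  design
}

#' Validate the invariants of a simple lattice design
#'
#' Checks that every replication contains each genotype exactly once, that
#' each of the `k` blocks per replication holds `k` distinct genotypes, and
#' that any pair of genotypes meets in at most one block (concurrence
#' lambda in \{0, 1\}).
#'
#' @param design A `lattice_design` object.
#' @return The design, invisibly; errors describe the violated constraint.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "lattice_design"))
  k <- design$k; g <- design$g; lay <- design$layout
  for (j in 1:2) {
    rep_acc <- lay$accession[lay$replication == j]
    if (!identical(sort(rep_acc), seq_len(g)))
      stop("design error: replication ", j, " is not a permutation of 1..g", call. = FALSE)
    blocks <- split(lay$accession[lay$replication == j], lay$block[lay$replication == j])
    if (length(blocks) != k || !all(lengths(blocks) == k))
      stop("design error: replication ", j, " must have ", k, " blocks of ", k, " plots", call. = FALSE)
    if (any(vapply(blocks, anyDuplicated, 1L) > 0L))
      stop("design error: duplicated genotype within a block of replication ", j, call. = FALSE)
  }
  conc <- pair_concurrence(design)
  if (any(conc > 1L))
    stop("design error: some genotype pair co-occurs in more than one block", call. = FALSE)
  invisible(design)
}

# g x g matrix of block concurrences (diagonal = number of blocks containing
# the genotype, i.e. r)
pair_concurrence <- function(design) {
  lay <- design$layout
  bid <- paste(lay$replication, lay$block)
  N <- table(factor(lay$accession, levels = seq_len(design$g)), bid)
  lam <- N %*% t(N)
  diag(lam) <- diag(lam) # keep diagonal as replication count
  m <- matrix(as.integer(lam), design$g, design$g)
  diag(m) <- 0L
  m
}

#' @export
print.lattice_design <- function(x, ...) {
  cat("Simple lattice design: g =", x$g, "genotypes, k =", x$k,
      "plots/block, r =", x$r, "replications (", nrow(x$layout), "plots )\n")
  invisible(x)
}

#' Export a lattice design layout as CSV
#'
#' Writes columns `accession,replication,block` with 1-based ids.
#'
#' @param design A `lattice_design`.
#' @param path Output file path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "lattice_design"))
  utils::write.csv(design$layout, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a lattice design layout from CSV
#'
#' Reads a layout written by [write_design()] and reconstructs (and
#' re-validates) the `lattice_design` object.
#'
#' @param path CSV file with columns `accession,replication,block`.
#' @return A `lattice_design`.
#' @export
read_design <- function(path) {
  lay <- utils::read.csv(path)
  need <- c("accession", "replication", "block")
  miss <- setdiff(need, names(lay))
  if (length(miss))
    stop("design error: layout file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  k <- length(unique(lay$block[lay$replication == 1]))
  design <- structure(
    list(k = k, r = 2L, g = k * k,
         layout = data.frame(accession = as.integer(lay$accession),
                             replication = as.integer(lay$replication),
                             block = as.integer(lay$block))),
    class = "lattice_design"
  )
  validate_design(design)
  design
}
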