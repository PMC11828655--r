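# Sequential (type-I) projections for the intra-block analysis of a simple
# lattice. Everything downstream -- ANOVA sums of squares, mean
# cross-products for covariance components, adjusted means -- is built on
# the same incremental least-squares fits, applied bilinearly:
#   CP_source(x, y) = x' (H_s - H_{s-1}) y,  x' H y = fitted(x) . y.
# Two nesting orders are kept:
#   order A: mean -> replication -> accession (unadjusted) -> blocks (adj.)
#   order B: mean -> replication -> blocks (unadjusted) -> accession (adj.)
# Both share the replication, total and residual terms; order B yields the
# block-adjusted accession mean square whose expectation is
# sigma2_e + (k r / (k+1)) sigma2_g, the basis of the variance-component
# estimator.

# validate and align a plot table against a design; returns factors
check_balance <- function(plots, design, traits = NULL) {
  need <- c("accession", "replication", "block")
  miss <- setdiff(need, names(plots))
  if (length(miss))
    stop("schema error: plot table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(plots$accession, plots$replication)
  dup <- duplicated(key)
  if (any(dup))
    stop("balance error: duplicated (accession, replication) pair(s): ",
         paste(unique(key[dup]), collapse = "; "), call. = FALSE)
  lay <- design$layout
  expected <- paste(lay$accession, lay$replication)
  missing_cells <- setdiff(expected, key)
  if (length(missing_cells))
    stop("balance error: missing (accession, replication) pair(s): ",
         paste(missing_cells, collapse = "; "), call. = FALSE)
  extra <- setdiff(key, expected)
  if (length(extra))
    stop("balance error: plot(s) not in the design layout: ",
         paste(extra, collapse = "; "), call. = FALSE)
  # block consistency with the layout
  lk <- paste(lay$accession, lay$replication, lay$block)
  pk <- paste(plots$accession, plots$replication, plots$block)
  if (!all(pk %in% lk))
    stop("balance error: block assignment inconsistent with the design layout",
         call. = FALSE)
  if (!is.null(traits)) {
    for (tr in traits) {
      if (!tr %in% names(plots))
        stop("schema error: trait '", tr, "' not found in plot table", call. = FALSE)
      v <- plots[[tr]]
      if (!is.numeric(v) || anyNA(v))
        stop("balance error: trait '", tr,
             "' has missing or non-numeric values", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# QR factorizations of the nested model matrices; computed once per
# (plots, design) and reused across traits/pairs
lattice_projectors <- function(plots, design) {
  R <- factor(plots$replication)
  B <- factor(paste(plots$replication, plots$block))
  A <- factor(plots$accession)
  X1  <- stats::model.matrix(~R)
  X2a <- stats::model.matrix(~R + A)
  X2b <- stats::model.matrix(~R + B)
  X3  <- stats::model.matrix(~R + A + B)
  qrs <- lapply(list(X1 = X1, X2a = X2a, X2b = X2b, X3 = X3), qr)
  n <- nrow(plots)
  df <- list(
    replication = qrs$X1$rank - 1L,
    accession   = qrs$X2a$rank - qrs$X1$rank,
    block       = qrs$X3$rank - qrs$X2a$rank,
    residual    = n - qrs$X3$rank
  )
  list(qrs = qrs, df = df, n = n, factors = list(R = R, B = B, A = A))
}

# bilinear sequential cross-products under both orders
lattice_crossprod <- function(proj, x, y = x) {
  hxy <- function(q) sum(qr.fitted(q, x) * y)
  n <- proj$n
  c1  <- hxy(proj$qrs$X1)
  c2a <- hxy(proj$qrs$X2a)
  c2b <- hxy(proj$qrs$X2b)
  c3  <- hxy(proj$qrs$X3)
  mean_cp <- sum(x) * sum(y) / n
  tot <- sum(x * y)
  list(
    replication     = c1 - mean_cp,
    accession_unadj = c2a - c1,
    block_adj       = c3 - c2a,
    block_unadj     = c2b - c1,
    accession_adj   = c3 - c2b,
    residual        = tot - c3,
    total           = tot - mean_cp
  )
}
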