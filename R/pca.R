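#' Principal component analysis of the trait correlation matrix
#'
#' Traits are standardized to zero mean and unit (n - 1) variance, and the
#' eigendecomposition of their correlation matrix is taken (computed via
#' the singular value decomposition of the standardized data). Loadings
#' are unit-norm eigenvectors with a deterministic sign: the
#' largest-magnitude entry of every column is positive. Scores are the
#' standardized data projected on the loadings; components with
#' eigenvalue > 1 are retained under the Kaiser criterion. Variance
#' explained is 100 * eigenvalue / t, the eigenvalues of a correlation
#' matrix summing to the number of traits t.
#'
#' @param means Accession x trait numeric matrix (>= 3 accessions, no
#'   zero-variance trait).
#' @return Class `pca_corr`: list with `eigenvalues` (descending),
#'   `loadings` (trait x component), `var_explained_percent`,
#'   `cum_var_explained_percent`, `scores` (accession x component),
#'   `retained` (Kaiser), `trait_coords` (loadings scaled by
#'   sqrt(eigenvalue), the trait arrows of a biplot), `n` and `t`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50), 10, 5)
#' p <- pca_correlation(X)
#' sum(p$eigenvalues)   # 5
#' @export
pca_correlation <- function(means) {
  X <- as.matrix(means)
  n <- nrow(X); t <- ncol(X)
  if (n < 3) stop("size error: need at least 3 accessions", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("standardization error: zero-variance trait(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  if (t > n - 1)
    warning("more traits than accessions - 1; trailing eigenvalues are zero",
            call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- numeric(t)
  eig[seq_along(pc$sdev)] <- pc$sdev^2
  load <- matrix(0, t, t, dimnames = list(colnames(X), paste0("PC", seq_len(t))))
  load[, seq_len(ncol(pc$rotation))] <- pc$rotation
  scores <- matrix(0, n, t, dimnames = list(rownames(X), paste0("PC", seq_len(t))))
  scores[, seq_len(ncol(pc$x))] <- pc$x
  # deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(t)) {
    col <- load[, j]
    if (any(col != 0) && col[which.max(abs(col))] < 0) {
      load[, j] <- -col
      scores[, j] <- -scores[, j]
    }
  }
  ve <- 100 * eig / t
  structure(
    list(eigenvalues = eig, loadings = load,
         var_explained_percent = ve,
         cum_var_explained_percent = cumsum(ve),
         scores = scores,
         retained = which(eig > 1),
         trait_coords = load %*% diag(sqrt(eig), t),
         n = n, t = t),
    class = "pca_corr"
  )
}

#' @export
print.pca_corr <- function(x, ...) {
  cat("Correlation-matrix PCA:", x$t, "traits,", x$n, "accessions\n")
  tab <- data.frame(eigenvalue = round(x$eigenvalues, 3),
                    var_percent = round(x$var_explained_percent, 2),
                    cum_percent = round(x$cum_var_explained_percent, 2))
  rownames(tab) <- paste0("PC", seq_len(x$t))
  print(utils::head(tab, max(3, length(x$retained))))
  cat("Kaiser-retained components:", length(x$retained), "\n")
  invisible(x)
}
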