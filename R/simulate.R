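#' Simulate one lattice trial under a generating model
#'
#' Draws genotype effects (multivariate normal across traits), independent
#' block-within-replication effects and correlated plot errors, and returns
#' the plot-level trait table for the supplied design. Identical
#' `(design, model, seed)` give a byte-identical table.
#'
#' @param design A `lattice_design` from [make_design()].
#' @param model A `genetic_model`.
#' @param seed Integer seed (required; simulation must be reproducible).
#' @return A data frame with columns `accession`, `replication`, `block`
#'   and one numeric column per trait, one row per plot.
#' @examples
#' d <- make_design(3)
#' m <- genetic_model("y", mu = 10, sigma2_g = 4, sigma2_e = 1)
#' head(simulate_trial(d, m, seed = 1))
#' @export
simulate_trial <- function(design, model, seed) {
  stopifnot(inherits(design, "lattice_design"), inherits(model, "genetic_model"))
  if (missing(seed) || is.null(seed))
    stop("model error: a seed is required for reproducible simulation", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  t <- length(model$trait_names)
  g <- design$g; k <- design$k
  lay <- design$layout
  n <- nrow(lay)

  Sg <- diag(sqrt(model$sigma2_g), t) %*% model$Rg %*% diag(sqrt(model$sigma2_g), t)
  Se <- diag(sqrt(model$sigma2_e), t) %*% model$Re %*% diag(sqrt(model$sigma2_e), t)
  G <- mvn_rows(g, Sg)                       # g x t genotype effects
  E <- mvn_rows(n, Se)                       # n x t plot errors
  B <- matrix(stats::rnorm(2 * k * t), 2 * k, t) *
    rep(sqrt(model$sigma2_b), each = 2 * k)  # block effects, independent per trait

  bid <- (lay$replication - 1L) * k + lay$block
  Y <- matrix(model$mu, n, t, byrow = TRUE) +
    model$rep_effects[lay$replication, , drop = FALSE] +
    B[bid, , drop = FALSE] +
    G[lay$accession, , drop = FALSE] +
    E
  colnames(Y) <- model$trait_names
  cbind(lay, as.data.frame(Y))
}

# symmetric square root via eigendecomposition; tolerates PSD matrices with
# zero eigenvalues (chol() would fail there)
chol_factor <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(e$values)) %*% t(e$vectors)
}

mvn_rows <- function(n, Sigma) {
  t <- nrow(Sigma)
  Z <- matrix(stats::rnorm(n * t), n, t)
  Z %*% chol_factor(Sigma)
}

#' Write a plot-level trait table to CSV
#'
#' Header `accession,replication,block,<trait...>`, suitable for
#' [read_plot_table()].
#'
#' @param plots Plot table (data frame).
#' @param path Output file.
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
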