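#' Specify the generating model for a simulated lattice trial
#'
#' The simulator assumes, for each trait v and plot (accession a,
#' replication j, block b):
#' \deqn{y = \mu_v + \rho_{jv} + \beta_{bv} + G_{av} + E_{ajv}}
#' where replication effects \eqn{\rho} are fixed shifts, block effects
#' \eqn{\beta} are i.i.d. normal with variance `sigma2_b` (independent
#' across traits), rows of G are multivariate normal with covariance
#' `diag(sd_g) Rg diag(sd_g)` and rows of E likewise built from `Re` and
#' `sigma2_e`. Phenotypic variance on an accession-mean basis is
#' `sigma2_g + sigma2_e`.
#'
#' @param trait_names Character vector of trait names (length t).
#' @param mu Per-trait grand means.
#' @param sigma2_g Per-trait genotypic variances (>= 0).
#' @param sigma2_e Per-trait plot-error variances (>= 0).
#' @param Rg t x t genetic correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite). Default identity.
#' @param Re t x t plot-error correlation matrix, same constraints.
#' @param sigma2_b Block-within-replication variance, one value per trait
#'   (recycled from a scalar). Default 0.
#' @param rep_effects r x t matrix of fixed replication shifts (default 0).
#' @return An object of class `genetic_model`.
#' @seealso [simulate_trial()], [true_values()], [barley_reference_model()]
#' @export
genetic_model <- function(trait_names, mu, sigma2_g, sigma2_e,
                          Rg = NULL, Re = NULL, sigma2_b = 0,
                          rep_effects = NULL) {
  t <- length(trait_names)
  if (t < 1L) stop("model error: 'trait_names' must name at least one trait", call. = FALSE)
  if (is.null(Rg)) Rg <- diag(t)
  if (is.null(Re)) Re <- diag(t)
  mu <- check_len(mu, t, "mu")
  sigma2_g <- check_len(sigma2_g, t, "sigma2_g")
  sigma2_e <- check_len(sigma2_e, t, "sigma2_e")
  sigma2_b <- check_len(sigma2_b, t, "sigma2_b")
  for (nm in c("sigma2_g", "sigma2_e", "sigma2_b")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v < 0))
      stop("model error: '", nm, "' must be finite and >= 0", call. = FALSE)
  }
  check_corr(Rg, t, "Rg")
  check_corr(Re, t, "Re")
  if (is.null(rep_effects)) rep_effects <- matrix(0, 2, t)
  rep_effects <- as.matrix(rep_effects)
  if (ncol(rep_effects) != t)
    stop("model error: 'rep_effects' must have one column per trait", call. = FALSE)
  structure(
    list(trait_names = trait_names, mu = stats::setNames(mu, trait_names),
         sigma2_g = stats::setNames(sigma2_g, trait_names),
         sigma2_e = stats::setNames(sigma2_e, trait_names),
         sigma2_b = stats::setNames(sigma2_b, trait_names),
         Rg = `dimnames<-`(Rg, list(trait_names, trait_names)),
         Re = `dimnames<-`(Re, list(trait_names, trait_names)),
         rep_effects = rep_effects),
    class = "genetic_model"
  )
}

check_len <- function(x, t, name) {
  if (length(x) == 1L) x <- rep(x, t)
  if (length(x) != t)
    stop("model error: '", name, "' has length ", length(x),
         ", expected ", t, call. = FALSE)
  as.numeric(x)
}

check_corr <- function(R, t, name) {
  if (!is.matrix(R) || nrow(R) != t || ncol(R) != t)
    stop("model error: '", name, "' must be a ", t, " x ", t, " matrix", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8)
    stop("model error: '", name, "' is not symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("model error: '", name, "' must have a unit diagonal", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("model error: '", name, "' is not positive semi-definite", call. = FALSE)
  invisible(R)
}

#' Ground-truth parameters implied by a generating model
#'
#' Returns the quantities that recovery tests compare estimates against:
#' per-trait genotypic, error and phenotypic variances (phenotypic =
#' genotypic + error on an accession-mean expectation basis) and the
#' genotypic correlation matrix.
#'
#' @param model A `genetic_model`.
#' @return A list with `sigma2_g`, `sigma2_e`, `sigma2_p` and `Rg`.
#' @export
true_values <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  list(sigma2_g = model$sigma2_g,
       sigma2_e = model$sigma2_e,
       sigma2_p = model$sigma2_g + model$sigma2_e,
       Rg = model$Rg)
}

#' Project a symmetric matrix to the nearest positive semi-definite
#' correlation matrix
#'
#' Eigenvalue clipping at `eps` followed by rescaling to a unit diagonal.
#' Used when a correlation matrix assembled from separately estimated (or
#' rounded, published) components fails positive semi-definiteness.
#'
#' @param R Symmetric matrix with unit diagonal intent.
#' @param eps Smallest retained eigenvalue (default 1e-6).
#' @return A valid correlation matrix.
#' @export
near_psd_corr <- function(R, eps = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(R)
  out
}

#' Reference generating model calibrated to a barley landrace trial
#'
#' An 11-trait model for a 7 x 7 simple lattice (49 accessions, 2
#' replications) whose genotypic variances, trait means, and genotypic and
#' phenotypic correlation structures are calibrated to a published
#' evaluation of Ethiopian barley accessions (days to heading and maturity,
#' plant height, peduncle and spike length, tiller and kernel counts,
#' kernel weights and grain yield). The error correlation matrix is derived
#' from the difference between phenotypic and genotypic covariances and
#' projected to the nearest positive semi-definite correlation matrix;
#' block variances are back-calculated from the block-adjusted mean squares.
#' This synthetic stand-in emulates the variance magnitudes of the real
#' trial, not its raw plot data (which were not deposited).
#'
#' @return A `genetic_model` for traits DTH, DTM, PLHT, PDL, NFT, SL, NSPS,
#'   NKPS, WKPS, TKW and GY.
#' @export
barley_reference_model <- function() {
  tr <- c("DTH", "DTM", "PLHT", "PDL", "NFT", "SL", "NSPS", "NKPS", "WKPS", "TKW", "GY")
  mu  <- c(71.7, 113.7, 97.5, 36.9, 3.11, 7.87, 21.8, 41.2, 1.70, 37.4, 4.02)
  s2g <- c(51.12, 62.39, 109.3, 5.94, 0.16, 0.85, 3.70, 83.6, 0.30, 31.4, 1.07)
  s2p <- c(55.27, 67.89, 123.3, 7.84, 0.36, 1.10, 4.90, 103.3, 0.36, 36.35, 1.23)
  s2e <- s2p - s2g
  # block-adjusted block MS and residual MS, trait by trait; sigma2_b from
  # E[MS_block(adj)] ~ sigma2_e + (k/2) sigma2_b with k = 7
  msb <- c(10.56, 69.90, 98.83, 2.47, 0.19, 0.78, 1.48, 28.64, 0.09, 5.83, 0.25)
  mse <- c(4.15, 5.5, 13.95, 1.9, 0.21, 0.25, 1.2, 19.72, 0.06, 4.93, 0.16)
  s2b <- pmax(0, (msb - mse) * 2 / 7)
  Rg <- reference_corr("genotypic")
  Re <- reference_error_corr(s2g, s2p, Rg)
  genetic_model(tr, mu, s2g, s2e, Rg = Rg, Re = Re, sigma2_b = s2b)
}

#' Reference trait correlation matrices
#'
#' The genotypic and phenotypic trait correlation matrices of the
#' calibration trial behind [barley_reference_model()], as published
#' (2 decimal places).
#'
#' @param level `"genotypic"` or `"phenotypic"`.
#' @return An 11 x 11 correlation matrix with trait dimnames.
#' @export
reference_corr <- function(level = c("genotypic", "phenotypic")) {
  level <- match.arg(level)
  tr <- c("DTH", "DTM", "PLHT", "PDL", "NFT", "SL", "NSPS", "NKPS", "WKPS", "TKW", "GY")
  # upper triangle row by row (DTH x DTM ... TKW x GY)
  gup <- c(0.72, 0.45, -0.07, 0.20, -0.37, 0.30, 0.56, 0.68, 0.09, 0.39,
           0.43, -0.23, 0.27, -0.18, 0.42, 0.54, 0.69, 0.26, 0.51,
           0.46, 0.23, -0.09, 0.45, 0.47, 0.56, 0.39, 0.40,
           0.17, 0.30, 0.16, 0.07, -0.06, 0.34, 0.12,
           -0.06, 0.77, 0.56, 0.27, 0.72, 0.85,
           0.13, -0.40, -0.46, 0.19, -0.11,
           0.62, 0.47, 0.79, 0.87,
           0.81, 0.45, 0.73,
           0.27, 0.51,
           0.81)
  pup <- c(0.69, 0.38, -0.07, 0.19, -0.30, 0.29, 0.51, 0.64, 0.06, 0.36,
           0.31, -0.18, 0.29, -0.09, 0.41, 0.48, 0.63, 0.24, 0.47,
           0.42, 0.16, -0.13, 0.42, 0.43, 0.52, 0.34, 0.33,
           0.16, 0.30, 0.18, 0.06, -0.05, 0.31, 0.11,
           -0.02, 0.63, 0.44, 0.25, 0.61, 0.72,
           0.12, -0.31, -0.35, 0.16, -0.09,
           0.57, 0.46, 0.70, 0.78,
           0.76, 0.43, 0.69,
           0.26, 0.46,
           0.77)
  R <- diag(11)
  R[upper.tri(R)] <- 0
  vals <- if (level == "genotypic") gup else pup
  idx <- 0L
  for (i in 1:10) for (j in (i + 1):11) {
    idx <- idx + 1L
    R[i, j] <- R[j, i] <- vals[idx]
  }
  diag(R) <- 1
  dimnames(R) <- list(tr, tr)
  R
}

reference_error_corr <- function(s2g, s2p, Rg) {
  Rp <- reference_corr("phenotypic")
  covg <- diag(sqrt(s2g)) %*% Rg %*% diag(sqrt(s2g))
  covp <- diag(sqrt(s2p)) %*% Rp %*% diag(sqrt(s2p))
  cove <- covp - covg
  Re <- stats::cov2cor(cove)
  Re[Re > 1] <- 1; Re[Re < -1] <- -1
  if (min(eigen(Re, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    Re <- near_psd_corr(Re)
  dimnames(Re) <- dimnames(Rg)
  Re
}

#' Write a generating model to YAML
#' @param model A `genetic_model`.
#' @param path Output file.
#' @export
write_genetic_model <- function(model, path) {
  stopifnot(inherits(model, "genetic_model"))
  yaml::write_yaml(list(
    trait_names = model$trait_names,
    mu = as.numeric(model$mu),
    sigma2_g = as.numeric(model$sigma2_g),
    sigma2_e = as.numeric(model$sigma2_e),
    sigma2_b = as.numeric(model$sigma2_b),
    Rg = apply(model$Rg, 1, as.numeric, simplify = FALSE),
    Re = apply(model$Re, 1, as.numeric, simplify = FALSE),
    rep_effects = apply(model$rep_effects, 1, as.numeric, simplify = FALSE)
  ), path)
  invisible(path)
}

#' Read a generating model from YAML
#' @param path YAML file written by [write_genetic_model()].
#' @return A validated `genetic_model`.
#' @export
read_genetic_model <- function(path) {
  y <- yaml::read_yaml(path)
  genetic_model(
    trait_names = y$trait_names, mu = y$mu,
    sigma2_g = y$sigma2_g, sigma2_e = y$sigma2_e,
    Rg = do.call(rbind, y$Rg), Re = do.call(rbind, y$Re),
    sigma2_b = y$sigma2_b,
    rep_effects = do.call(rbind, y$rep_effects)
  )
}

#' @export
print.genetic_model <- function(x, ...) {
  cat("Generating model for", length(x$trait_names), "trait(s):",
      paste(x$trait_names, collapse = ", "), "\n")
  cat("  sigma2_g:", paste(signif(x$sigma2_g, 4), collapse = " "), "\n")
  cat("  sigma2_e:", paste(signif(x$sigma2_e, 4), collapse = " "), "\n")
  invisible(x)
}
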