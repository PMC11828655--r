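#' Genotypic, error and phenotypic covariance components for a trait pair
#'
#' The sequential lattice partition of [anova_table()] applied bilinearly:
#' each stratum's cross-product is \eqn{x' P_s y}, mean cross-products are
#' CP/df, and the components follow the same moment equations as the
#' variances, \eqn{cov_g = (k+1)(MCP_{acc} - MCP_{res})/(kr)},
#' \eqn{cov_e = MCP_{res}}, \eqn{cov_p = cov_g + cov_e}. With
#' `traitY = traitX` the genotypic covariance equals the genotypic
#' variance component exactly.
#'
#' @inheritParams anova_table
#' @param traitX,traitY Trait column names.
#' @param adjust Use the block-adjusted accession stratum (default TRUE,
#'   matching [genetic_params()]).
#' @return List with `cov_g`, `cov_e`, `cov_p`.
#' @export
covariance_components <- function(plots, design, traitX, traitY,
                                  adjust = TRUE) {
  stopifnot(inherits(design, "lattice_design"))
  check_balance(plots, design, traits = c(traitX, traitY))
  proj <- lattice_projectors(plots, design)
  cov_from_proj(proj, as.numeric(plots[[traitX]]), as.numeric(plots[[traitY]]),
                design$k, design$r, adjust)
}

cov_from_proj <- function(proj, x, y, k, r, adjust = TRUE) {
  cp <- lattice_crossprod(proj, x, y)
  mcp_acc <- (if (adjust) cp$accession_adj else cp$accession_unadj) / proj$df$accession
  mcp_res <- cp$residual / proj$df$residual
  cov_g <- (k + 1) * (mcp_acc - mcp_res) / (k * r)
  list(cov_g = cov_g, cov_e = mcp_res, cov_p = cov_g + mcp_res)
}

#' Genotypic and phenotypic correlation matrices
#'
#' Correlations between every pair of traits from the variance and
#' covariance components: \eqn{r_g = cov_g / \sqrt{\sigma^2_{g,x}
#' \sigma^2_{g,y}}} and analogously for the phenotypic level. Component
#' estimates can stray outside \[-1, 1\]; such cells are clamped and
#' flagged. Significance uses the t approximation
#' \eqn{t = r\sqrt{g-2}/\sqrt{1-r^2}} on g - 2 df at the 0.05 and 0.01
#' levels (applied at both levels; for genotypic correlations this is an
#' approximation).
#'
#' @inheritParams anova_table
#' @param traits Character vector of at least two trait columns.
#' @param adjust Use block-adjusted accession cross-products (default TRUE).
#' @return Class `corr_matrices`: list with matrices `rg`, `rp`, character
#'   significance matrices `sig_g`, `sig_p` (`""`, `"*"`, `"**"`), logical
#'   overflow flag matrices `raw_g_outside`, `raw_p_outside`, `df` and
#'   `traits`. Cells where a genotypic variance component is <= 0 are NA
#'   and flagged in `undefined_g`.
#' @export
correlation_matrices <- function(plots, design, traits, adjust = TRUE) {
  stopifnot(inherits(design, "lattice_design"))
  if (length(traits) < 2) stop("schema error: need at least two traits", call. = FALSE)
  if (design$g < 3) stop("df error: need at least 3 genotypes", call. = FALSE)
  check_balance(plots, design, traits = traits)
  proj <- lattice_projectors(plots, design)
  t <- length(traits)
  xs <- lapply(traits, function(tr) as.numeric(plots[[tr]]))
  names(xs) <- traits
  vcs <- lapply(xs, function(x) cov_from_proj(proj, x, x, design$k, design$r, adjust))
  s2g <- vapply(vcs, function(v) max(v$cov_g, 0), 1.0)
  s2p <- vapply(vcs, function(v) v$cov_p, 1.0)
  rg <- rp <- matrix(1, t, t, dimnames = list(traits, traits))
  out_g <- out_p <- undef_g <- matrix(FALSE, t, t, dimnames = list(traits, traits))
  for (i in seq_len(t - 1)) for (j in (i + 1):t) {
    cc <- cov_from_proj(proj, xs[[i]], xs[[j]], design$k, design$r, adjust)
    if (s2g[i] <= 0 || s2g[j] <= 0) {
      rg[i, j] <- rg[j, i] <- NA_real_
      undef_g[i, j] <- undef_g[j, i] <- TRUE
    } else {
      raw <- cc$cov_g / sqrt(s2g[i] * s2g[j])
      if (abs(raw) > 1) out_g[i, j] <- out_g[j, i] <- TRUE
      rg[i, j] <- rg[j, i] <- max(-1, min(1, raw))
    }
    rawp <- cc$cov_p / sqrt(s2p[i] * s2p[j])
    if (abs(rawp) > 1) out_p[i, j] <- out_p[j, i] <- TRUE
    rp[i, j] <- rp[j, i] <- max(-1, min(1, rawp))
  }
  df <- design$g - 2L
  structure(
    list(rg = rg, rp = rp,
         sig_g = corr_stars(rg, df), sig_p = corr_stars(rp, df),
         raw_g_outside = out_g, raw_p_outside = out_p,
         undefined_g = undef_g, df = df, traits = traits),
    class = "corr_matrices"
  )
}

# two-sided t approximation for the significance of a correlation
corr_pvalue <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(tt, df, lower.tail = FALSE)
}

corr_stars <- function(R, df) {
  p <- corr_pvalue(R, df)
  s <- matrix("", nrow(R), ncol(R), dimnames = dimnames(R))
  s[!is.na(p) & p <= 0.05] <- "*"
  s[!is.na(p) & p <= 0.01] <- "**"
  diag(s) <- ""
  s
}

#' Wrap published correlation matrices for downstream analysis
#'
#' Builds a `corr_matrices` object directly from genotypic and phenotypic
#' correlation matrices (e.g. transcribed from a published table), so that
#' predictor selection and path analysis can run on them.
#'
#' @param rg,rp Genotypic and phenotypic correlation matrices with trait
#'   dimnames (`rp` defaults to `rg`).
#' @param g Number of genotypes behind the estimates (sets the df for
#'   significance marks).
#' @return A `corr_matrices` object.
#' @export
as_corr_matrices <- function(rg, rp = rg, g) {
  stopifnot(is.matrix(rg), !is.null(colnames(rg)))
  df <- as.integer(g) - 2L
  t <- ncol(rg)
  structure(
    list(rg = rg, rp = rp, sig_g = corr_stars(rg, df), sig_p = corr_stars(rp, df),
         raw_g_outside = matrix(FALSE, t, t), raw_p_outside = matrix(FALSE, t, t),
         undefined_g = matrix(FALSE, t, t), df = df, traits = colnames(rg)),
    class = "corr_matrices"
  )
}

#' Critical correlation at a significance level
#'
#' Smallest |r| declared significant by the t approximation on `df`
#' degrees of freedom.
#'
#' @param df Degrees of freedom (number of genotypes minus 2).
#' @param alpha Two-sided significance level.
#' @export
critical_r <- function(df, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(df + tc^2)
}

#' @export
print.corr_matrices <- function(x, ...) {
  t <- length(x$traits)
  cat("Trait correlations (", t, " traits, df = ", x$df,
      "): genotypic above, phenotypic below diagonal\n", sep = "")
  M <- matrix("1", t, t, dimnames = list(x$traits, x$traits))
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (i < j) M[i, j] <- paste0(sprintf("%.2f", x$rg[i, j]), x$sig_g[i, j])
    if (i > j) M[i, j] <- paste0(sprintf("%.2f", x$rp[i, j]), x$sig_p[i, j])
  }
  print(as.data.frame(M))
  invisible(x)
}

#' Render the combined triangular correlation table
#'
#' Phenotypic correlations below the diagonal, genotypic above, with
#' significance stars appended, as a character data frame ready for CSV
#' export.
#'
#' @param corr A `corr_matrices` object.
#' @param digits Decimal places (default 2).
#' @export
corr_table <- function(corr, digits = 2) {
  t <- length(corr$traits)
  M <- matrix("1", t, t, dimnames = list(corr$traits, corr$traits))
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (i < j) M[i, j] <- paste0(sprintf(fmt, corr$rg[i, j]), corr$sig_g[i, j])
    if (i > j) M[i, j] <- paste0(sprintf(fmt, corr$rp[i, j]), corr$sig_p[i, j])
  }
  data.frame(trait = corr$traits, M, check.names = FALSE, row.names = NULL)
}
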