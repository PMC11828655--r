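#' Choose predictor traits for path analysis
#'
#' Keeps the traits whose correlation with the yield trait, at the chosen
#' level, is significant at `alpha` (t approximation on g - 2 df), in the
#' original trait order. An explicit `include` list overrides the
#' selection.
#'
#' @param corr A `corr_matrices` object.
#' @param yield_trait Name of the dependent (yield) trait.
#' @param level `"genotypic"` or `"phenotypic"`.
#' @param alpha Significance level for inclusion (default 0.05).
#' @param include Optional explicit character vector of predictors.
#' @return Character vector of predictor trait names.
#' @export
select_predictors <- function(corr, yield_trait,
                              level = c("genotypic", "phenotypic"),
                              alpha = 0.05, include = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(corr, "corr_matrices"))
  if (!yield_trait %in% corr$traits)
    stop("selection error: yield trait '", yield_trait, "' not present", call. = FALSE)
  if (!is.null(include)) return(intersect(corr$traits, include))
  R <- if (level == "genotypic") corr$rg else corr$rp
  cand <- setdiff(corr$traits, yield_trait)
  p <- corr_pvalue(R[cand, yield_trait], corr$df)
  sel <- cand[!is.na(p) & p <= alpha]
  if (!length(sel))
    stop("selection error: no trait is significantly correlated with '",
         yield_trait, "' at alpha = ", alpha, call. = FALSE)
  sel
}

#' Path coefficients: direct and indirect effects on yield
#'
#' Solves the normal equations \eqn{R_{xx} P = r_{xy}} for the direct
#' effects P; the indirect effect of predictor i via predictor j is
#' \eqn{P_j r_{ij}}. Each row of the effect matrix (direct on the
#' diagonal) sums to the predictor's correlation with yield. The residual
#' effect is reported as \eqn{1 - \sum_i P_i r_{iy}} (the share of yield
#' variation left unexplained), with its square root as the residual path
#' coefficient.
#'
#' @param Rxx Predictor correlation matrix (symmetric, unit diagonal).
#' @param rxy Correlations of the predictors with yield, same order.
#' @param predictors Optional trait names (default from `Rxx` dimnames).
#' @return Class `path_result`: list with `predictors`, `direct`,
#'   `effects` (direct on the diagonal, indirect off it),
#'   `reconstructed_r` (row sums), `residual_effect`, `residual_path`,
#'   `categories` (negligible < 0.10, low 0.10-0.19, moderate 0.20-0.29,
#'   high 0.30-1.00, very high > 1.00, on absolute value) and `condition`
#'   (2-norm condition number of `Rxx`).
#' @examples
#' p <- path_coefficients(matrix(c(1, .5, .5, 1), 2), c(0.6, 0.5),
#'                        c("A", "B"))
#' p$direct            # 0.4667 0.2667
#' p$residual_effect   # 0.5867
#' @export
path_coefficients <- function(Rxx, rxy, predictors = NULL) {
  Rxx <- as.matrix(Rxx)
  if (is.null(predictors)) predictors <- colnames(Rxx)
  if (is.null(predictors)) predictors <- paste0("X", seq_len(ncol(Rxx)))
  t <- length(predictors)
  if (nrow(Rxx) != t || ncol(Rxx) != t || length(rxy) != t)
    stop("schema error: Rxx and rxy dimensions disagree with the predictor list",
         call. = FALSE)
  if (max(abs(Rxx - t(Rxx))) > 1e-8 || max(abs(diag(Rxx) - 1)) > 1e-8)
    stop("schema error: Rxx must be symmetric with a unit diagonal", call. = FALSE)
  dimnames(Rxx) <- list(predictors, predictors)
  rxy <- stats::setNames(as.numeric(rxy), predictors)
  cond <- tryCatch(kappa(Rxx, exact = TRUE), error = function(e) Inf)
  P <- tryCatch(solve(Rxx, rxy), error = function(e) {
    off <- abs(Rxx); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("singularity error: predictor correlation matrix is singular; ",
         "most collinear pair: ", predictors[worst[1]], " / ",
         predictors[worst[2]], call. = FALSE)
  })
  if (cond > 1e3)
    warning("ill-conditioned predictor correlation matrix (condition number ",
            format(cond, digits = 3), ")", call. = FALSE)
  effects <- Rxx * rep(P, each = t)      # cell [i, j] = P_j * r_ij
  reconstructed <- rowSums(effects)      # = (Rxx %*% P) = rxy for exact inputs
  residual_effect <- 1 - sum(P * rxy)
  if (residual_effect < 0)
    warning("negative residual effect (", format(residual_effect, digits = 3),
            "); inputs are likely inconsistent rounded correlations",
            call. = FALSE)
  structure(
    list(predictors = predictors,
         direct = stats::setNames(as.numeric(P), predictors),
         effects = effects,
         reconstructed_r = stats::setNames(reconstructed, predictors),
         rxy = rxy,
         residual_effect = residual_effect,
         residual_path = sqrt(max(0, residual_effect)),
         categories = apply(effects, c(1, 2), effect_category),
         condition = cond),
    class = "path_result"
  )
}

effect_category <- function(x) {
  a <- abs(x)
  if (a > 1) "very high"
  else if (a >= 0.30) "high"
  else if (a >= 0.20) "moderate"
  else if (a >= 0.10) "low"
  else "negligible"
}

#' Full path analysis from estimated correlation matrices
#'
#' Selects significant predictors of the yield trait and solves the path
#' system at the requested level using the (clamped) estimated
#' correlations.
#'
#' @inheritParams select_predictors
#' @return A `path_result` with an added `level` element.
#' @export
path_analysis <- function(corr, yield_trait,
                          level = c("genotypic", "phenotypic"),
                          alpha = 0.05, include = NULL) {
  level <- match.arg(level)
  pred <- select_predictors(corr, yield_trait, level, alpha, include)
  R <- if (level == "genotypic") corr$rg else corr$rp
  res <- path_coefficients(R[pred, pred, drop = FALSE], R[pred, yield_trait], pred)
  res$level <- level
  res
}

#' @export
print.path_result <- function(x, ...) {
  cat("Path analysis", if (!is.null(x$level)) paste0("(", x$level, ")"),
      "with", length(x$predictors), "predictors\n")
  tab <- cbind(round(x$effects, 3), r_with_yield = round(x$rxy, 3))
  print(tab)
  cat(sprintf("residual effect %.4f (residual path %.4f)\n",
              x$residual_effect, x$residual_path))
  invisible(x)
}
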