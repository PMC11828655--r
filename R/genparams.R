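#' Variance components from lattice mean squares
#'
#' Moment estimator for the genotypic variance from the block-adjusted
#' accession mean square `msg` and the intra-block residual mean square
#' `mse` of a simple lattice:
#' \deqn{\hat\sigma^2_g = \frac{(k+1)(Msg - Mse)}{k\,r}, \qquad
#'   \hat\sigma^2_e = Mse, \qquad \hat\sigma^2_p = \hat\sigma^2_g +
#'   \hat\sigma^2_e.}
#' The coefficient \eqn{(k+1)/(kr)} inverts the expectation
#' \eqn{E[Msg] = \sigma^2_e + kr/(k+1)\,\sigma^2_g} of the adjusted
#' accession mean square. A negative estimate is truncated at zero and
#' flagged.
#'
#' @param msg Accession mean square (>= 0).
#' @param mse Residual mean square (>= 0).
#' @param k Block size (>= 2).
#' @param r Number of replications (>= 2).
#' @return Class `variance_components`: list with `sigma2_g`, `sigma2_e`,
#'   `sigma2_p`, `truncated`.
#' @examples
#' variance_components(93.6, 4.15, k = 7, r = 2)$sigma2_g  # ~51.11
#' @export
variance_components <- function(msg, mse, k, r) {
  if (!is.numeric(msg) || msg < 0 || !is.numeric(mse) || mse < 0)
    stop("value error: mean squares must be non-negative", call. = FALSE)
  if (k < 2 || r < 2)
    stop("value error: need k >= 2 and r >= 2", call. = FALSE)
  s2g <- (k + 1) * (msg - mse) / (k * r)
  truncated <- s2g < 0
  if (truncated) s2g <- 0
  structure(list(sigma2_g = s2g, sigma2_e = mse, sigma2_p = s2g + mse,
                 truncated = truncated),
            class = "variance_components")
}

#' Default classification thresholds for variability parameters
#'
#' Coefficients of variation: low < 10, moderate 10-20, high > 20 (%).
#' Broad-sense heritability: low < 30, moderate 30-60, high > 60 (%).
#' Genetic advance as percent of mean: low < 10, moderate 10-20,
#' high > 20 (%).
#'
#' @return Named list of `c(low_upper, moderate_upper)` cut points.
#' @export
default_thresholds <- function() {
  list(cv = c(10, 20), h2 = c(30, 60), gam = c(10, 20))
}

classify3 <- function(x, cuts) {
  ifelse(x < cuts[1], "low", ifelse(x <= cuts[2], "moderate", "high"))
}

#' Derived genetic parameters for one trait
#'
#' From variance components and the trait mean: genotypic and phenotypic
#' coefficients of variation \eqn{GCV = 100\sqrt{\sigma^2_g}/\bar X},
#' \eqn{PCV = 100\sqrt{\sigma^2_p}/\bar X}; broad-sense heritability
#' \eqn{H^2 = 100\,\sigma^2_g/\sigma^2_p}; expected genetic advance under
#' truncation selection \eqn{GA = k_{sel}\,\sigma_p\,H^2} (heritability as
#' a proportion) and its percentage of the mean. `k_sel` is the
#' standardized selection differential, 2.063 at 5% selection intensity.
#'
#' @param vc A `variance_components` object (or list with `sigma2_g`,
#'   `sigma2_e`, `sigma2_p`).
#' @param mean Trait mean (> 0).
#' @param k_sel Standardized selection differential (default 2.063).
#' @param thresholds Category cut points, see [default_thresholds()].
#' @return Class `genetic_params`: list with `sigma2_g`, `sigma2_e`,
#'   `sigma2_p`, `gcv_percent`, `pcv_percent`, `h2_percent`, `ga`,
#'   `gam_percent`, `truncated` and a `categories` character vector
#'   (gcv, pcv, h2, gam).
#' @examples
#' vc <- variance_components(93.6, 4.15, 7, 2)
#' derived_parameters(vc, mean = 71.7)$h2_percent   # ~92.5
#' @export
derived_parameters <- function(vc, mean, k_sel = 2.063,
                               thresholds = default_thresholds()) {
  if (!is.numeric(mean) || mean <= 0)
    stop("value error: trait mean must be positive", call. = FALSE)
  s2g <- vc$sigma2_g; s2p <- vc$sigma2_p
  gcv <- 100 * sqrt(s2g) / mean
  pcv <- 100 * sqrt(s2p) / mean
  h2 <- if (s2p > 0) 100 * s2g / s2p else 0
  ga <- k_sel * sqrt(s2p) * (h2 / 100)
  gam <- 100 * ga / mean
  structure(
    list(sigma2_g = s2g, sigma2_e = vc$sigma2_e, sigma2_p = s2p,
         gcv_percent = gcv, pcv_percent = pcv, h2_percent = h2,
         ga = ga, gam_percent = gam,
         truncated = isTRUE(vc$truncated),
         categories = c(gcv = classify3(gcv, thresholds$cv),
                        pcv = classify3(pcv, thresholds$cv),
                        h2 = classify3(h2, thresholds$h2),
                        gam = classify3(gam, thresholds$gam))),
    class = "genetic_params"
  )
}

#' Genetic parameters for every trait of a trial
#'
#' Runs the intra-block ANOVA per trait and derives the full variability
#' table: range, mean, variance components, GCV/PCV, heritability, genetic
#' advance and categories.
#'
#' @inheritParams anova_table
#' @param traits Character vector of trait columns (default: every numeric
#'   column other than the design keys).
#' @param k_sel Standardized selection differential (default 2.063).
#' @param thresholds Category cut points, see [default_thresholds()].
#' @param msg Which accession mean square feeds the variance-component
#'   formula: `"adjusted"` (block-adjusted, default; unbiased under the
#'   lattice model) or `"unadjusted"`.
#' @return Data frame, one row per trait, mirroring the standard
#'   variability-components table.
#' @export
genetic_params <- function(plots, design, traits = NULL, k_sel = 2.063,
                           thresholds = default_thresholds(),
                           msg = c("adjusted", "unadjusted")) {
  msg <- match.arg(msg)
  if (is.null(traits)) traits <- trait_columns(plots)
  rows <- lapply(traits, function(tr) {
    a <- anova_table(plots, design, tr)
    am <- adjusted_means(plots, design, tr)
    m <- if (msg == "adjusted") a$msg_adjusted else a$msg_unadjusted
    vc <- variance_components(m, a$mse, design$k, design$r)
    gp <- derived_parameters(vc, a$grand_mean, k_sel, thresholds)
    data.frame(
      trait = tr,
      min = min(am$adjusted_mean), max = max(am$adjusted_mean),
      mean = a$grand_mean,
      sem = stats::sd(am$adjusted_mean) / sqrt(design$g),
      sigma2_g = gp$sigma2_g, sigma2_p = gp$sigma2_p,
      gcv_percent = gp$gcv_percent, pcv_percent = gp$pcv_percent,
      h2_percent = gp$h2_percent, ga = gp$ga, gam_percent = gp$gam_percent,
      truncated = gp$truncated,
      gcv_class = gp$categories[["gcv"]], pcv_class = gp$categories[["pcv"]],
      h2_class = gp$categories[["h2"]], gam_class = gp$categories[["gam"]]
    )
  })
  do.call(rbind, rows)
}

trait_columns <- function(plots) {
  cand <- setdiff(names(plots), c("accession", "replication", "block"))
  cand[vapply(plots[cand], is.numeric, TRUE)]
}
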