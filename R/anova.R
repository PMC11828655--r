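#' Intra-block ANOVA of a simple lattice for one trait
#'
#' Partitions the total sum of squares sequentially into replication,
#' accession, block-within-replication and intra-block residual strata by
#' incremental least-squares projection. Two complementary sequential
#' orders are computed from the same projections: the displayed table
#' carries the block-adjusted accession stratum (accessions fitted after
#' blocks, the quantity whose expectation is
#' \eqn{\sigma^2_e + kr/(k+1)\,\sigma^2_g}) together with the
#' treatment-unadjusted block stratum, so the four sums of squares add to
#' the total; the treatment-unadjusted accession mean square is kept
#' alongside. F ratios test each stratum against the intra-block residual.
#'
#' @param plots Plot-level table (see [simulate_trial()] /
#'   [read_plot_table()]).
#' @param design The `lattice_design` the plots follow.
#' @param trait Name of the trait column to analyse.
#' @return An object of class `lattice_anova`: list with `table` (source,
#'   df, ss, ms, f, p, sig), `grand_mean`, `cv_percent`
#'   (\eqn{100\sqrt{MS_e}}/grand mean), `msg_adjusted`, `msg_unadjusted`,
#'   `mse`, `df_accession`, `df_error` and `trait`.
#' @examples
#' d <- make_design(3)
#' m <- genetic_model("y", mu = 20, sigma2_g = 6, sigma2_e = 1, sigma2_b = 1)
#' a <- anova_table(simulate_trial(d, m, seed = 42), d, "y")
#' a$table$df   # 1, 8, 4, 4
#' @export
anova_table <- function(plots, design, trait) {
  stopifnot(inherits(design, "lattice_design"))
  check_balance(plots, design, traits = trait)
  proj <- lattice_projectors(plots, design)
  if (proj$df$residual < 1L)
    stop("degenerate design: zero residual degrees of freedom", call. = FALSE)
  y <- as.numeric(plots[[trait]])
  cp <- lattice_crossprod(proj, y)
  df <- c(replication = proj$df$replication,
          accession   = proj$df$accession,
          block       = proj$df$block,
          residual    = proj$df$residual)
  ss <- c(cp$replication, cp$accession_adj, cp$block_unadj, cp$residual)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  tab <- data.frame(
    source = c("replication", "accession", "block_within_rep", "residual"),
    df = as.integer(df), ss = ss, ms = ms, f = f, p = p,
    sig = c(sig_stars(p[1:3]), ""),
    row.names = NULL
  )
  gm <- mean(y)
  structure(
    list(table = tab,
         grand_mean = gm,
         cv_percent = 100 * sqrt(ms[4]) / gm,
         msg_adjusted = cp$accession_adj / df[["accession"]],
         msg_unadjusted = cp$accession_unadj / df[["accession"]],
         ms_block_adjusted = cp$block_adj / df[["block"]],
         mse = ms[[4]],
         df_accession = df[["accession"]],
         df_error = df[["residual"]],
         trait = trait),
    class = "lattice_anova"
  )
}

sig_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.lattice_anova <- function(x, ...) {
  cat("Intra-block ANOVA for trait '", x$trait, "'\n", sep = "")
  tab <- x$table
  tab$ss <- signif(tab$ss, 6); tab$ms <- signif(tab$ms, 6)
  tab$f <- signif(tab$f, 4); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("grand mean %.4g   CV%% %.2f   accession MS (unadj.) %.4g\n",
              x$grand_mean, x$cv_percent, x$msg_unadjusted))
  invisible(x)
}

#' Block-adjusted accession means
#'
#' Least-squares accession means from the full fixed-effects intra-block
#' model (replication + block within replication + accession) under
#' sum-to-zero constraints: adjusted mean = grand mean + accession effect.
#' With no block contribution in the data the adjustment vanishes and the
#' raw per-accession means are returned.
#'
#' @inheritParams anova_table
#' @return Class `accession_means`: data frame with columns `accession`
#'   and `adjusted_mean`; attributes `overall_mean`, `se` (standard error
#'   of an accession mean, \eqn{\sqrt{MS_e/r}}), `r` and `trait`.
#' @export
adjusted_means <- function(plots, design, trait) {
  stopifnot(inherits(design, "lattice_design"))
  check_balance(plots, design, traits = trait)
  y <- as.numeric(plots[[trait]])
  k <- design$k; g <- design$g; r <- design$r
  R <- factor(plots$replication)
  A <- factor(plots$accession, levels = sort(unique(design$layout$accession)))
  B <- factor(paste(plots$replication, plots$block))
  # sum-to-zero design matrix: intercept | rep | blocks within rep | accession
  Cr <- stats::contr.sum(nlevels(R))
  Ca <- stats::contr.sum(nlevels(A))
  Xr <- Cr[as.integer(R), , drop = FALSE]
  Xa <- Ca[as.integer(A), , drop = FALSE]
  # blocks within each replication get their own sum-to-zero contrasts
  Xb <- matrix(0, length(y), 0)
  for (j in sort(unique(plots$replication))) {
    Bj <- factor(plots$block[plots$replication == j])
    Cb <- stats::contr.sum(nlevels(Bj))
    M <- matrix(0, length(y), ncol(Cb))
    M[plots$replication == j, ] <- Cb[as.integer(Bj), , drop = FALSE]
    Xb <- cbind(Xb, M)
  }
  X <- cbind(1, Xr, Xb, Xa)
  fit <- qr(X)
  if (fit$rank < ncol(X))
    stop("degenerate design: intra-block model is not of full rank", call. = FALSE)
  beta <- qr.coef(fit, y)
  acc_cols <- (ncol(X) - ncol(Xa) + 1):ncol(X)
  effects <- as.numeric(Ca %*% beta[acc_cols])
  gm <- beta[1]
  mse <- sum(qr.resid(fit, y)^2) / (length(y) - fit$rank)
  out <- data.frame(accession = levels(A), adjusted_mean = gm + effects)
  structure(out,
            overall_mean = gm, se = sqrt(mse / r), r = r, trait = trait,
            class = c("accession_means", "data.frame"))
}

#' Tukey mean separation with letter groupings
#'
#' Honest significant difference \eqn{HSD = q_{1-\alpha}(g, df_e)
#' \sqrt{MS_e / r}} applied to the accession means; accessions whose means
#' differ by less than HSD share a letter. Letters are assigned
#' deterministically: means are sorted descending and maximal runs of
#' mutually non-separated means receive successive letters. The common
#' replicate count r is used for the standard error (no effective-error
#' inflation for the lattice adjustment).
#'
#' @param means An `accession_means` object (or data frame with columns
#'   `accession` and `adjusted_mean`).
#' @param mse Intra-block residual mean square.
#' @param df_error Residual degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param r Replicate count behind each mean (default taken from `means`).
#' @return Data frame `accession`, `mean`, `group`, sorted by descending
#'   mean, with attributes `hsd` and `q_crit`.
#' @export
tukey_hsd <- function(means, mse, df_error, alpha = 0.05, r = NULL) {
  if (is.null(r)) r <- attr(means, "r")
  if (is.null(r)) stop("value error: replicate count 'r' is required", call. = FALSE)
  if (!is.numeric(mse) || mse <= 0)
    stop("value error: 'mse' must be positive", call. = FALSE)
  if (df_error < 1) stop("value error: 'df_error' must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("value error: 'alpha' must be in (0,1)", call. = FALSE)
  m <- means$adjusted_mean
  names(m) <- means$accession
  g <- length(m)
  q <- stats::qtukey(1 - alpha, nmeans = g, df = df_error)
  hsd <- q * sqrt(mse / r)
  ord <- order(-m)
  ms <- m[ord]
  # maximal intervals of mutually non-separated means (means sorted
  # descending, so non-separation sets are contiguous)
  upper <- vapply(seq_len(g), function(i) {
    max(which(ms[i] - ms < hsd))
  }, 1L)
  runs <- list()
  for (i in seq_len(g)) {
    cand <- c(i, upper[i])
    if (length(runs) == 0L || runs[[length(runs)]][2] < cand[2]) runs[[length(runs) + 1L]] <- cand
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  grp <- character(g)
  for (s in seq_along(runs)) {
    idx <- runs[[s]][1]:runs[[s]][2]
    grp[idx] <- paste0(grp[idx], letters_pool[s])
  }
  structure(
    data.frame(accession = names(ms), mean = as.numeric(ms), group = grp,
               row.names = NULL),
    hsd = hsd, q_crit = q
  )
}
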