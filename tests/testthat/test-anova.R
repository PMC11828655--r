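sim_for_anova <- function(k, seed, s2g = 6, s2e = 1, s2b = 1) {
  d <- make_design(k)
  m <- genetic_model("y", mu = 50, sigma2_g = s2g, sigma2_e = s2e, sigma2_b = s2b)
  list(design = d, plots = simulate_trial(d, m, seed = seed))
}

test_that("degrees of freedom follow the lattice partition", {
  s7 <- sim_for_anova(7, seed = 1)
  a7 <- anova_table(s7$plots, s7$design, "y")
  expect_equal(a7$table$df, c(1L, 48L, 12L, 36L))
  s3 <- sim_for_anova(3, seed = 2)
  a3 <- anova_table(s3$plots, s3$design, "y")
  expect_equal(a3$table$df, c(1L, 8L, 4L, 4L))
  expect_equal(sum(a3$table$df), nrow(s3$plots) - 1L)
})

test_that("sums of squares are additive and non-negative", {
  for (seed in 1:5) {
    for (k in c(3, 4)) {
      s <- sim_for_anova(k, seed = seed)
      a <- anova_table(s$plots, s$design, "y")
      y <- s$plots$y
      total <- sum((y - mean(y))^2)
      expect_equal(sum(a$table$ss), total, tolerance = 1e-8)
      expect_true(all(a$table$ss >= -1e-10))
      expect_equal(a$table$ms, a$table$ss / a$table$df)
    }
  }
})

test_that("both sequential orders match an explicit projector oracle", {
  for (seed in 1:3) {
    s <- sim_for_anova(3, seed = 100 + seed)
    y <- s$plots$y
    mats <- lattice_mats(s$plots)
    oA <- naive_seq_cp(y, y, mats$orderA)   # rep, acc(unadj), block(adj), resid
    oB <- naive_seq_cp(y, y, mats$orderB)   # rep, block(unadj), acc(adj), resid
    a <- anova_table(s$plots, s$design, "y")
    expect_equal(a$table$ss[1], oA[1], tolerance = 1e-8)
    expect_equal(a$msg_unadjusted * a$df_accession, oA[2], tolerance = 1e-8)
    expect_equal(a$ms_block_adjusted * a$table$df[3], oA[3], tolerance = 1e-8)
    expect_equal(a$table$ss[3], oB[2], tolerance = 1e-8)   # block unadjusted
    expect_equal(a$table$ss[2], oB[3], tolerance = 1e-8)   # accession adjusted
    expect_equal(a$table$ss[4], oB[4], tolerance = 1e-8)
  }
})

test_that("plot row order never changes the analysis", {
  s <- sim_for_anova(4, seed = 7)
  shuffled <- s$plots[sample(nrow(s$plots)), ]
  a1 <- anova_table(s$plots, s$design, "y")
  a2 <- anova_table(shuffled, s$design, "y")
  expect_equal(a1$table, a2$table, tolerance = 1e-10)
  m1 <- adjusted_means(s$plots, s$design, "y")
  m2 <- adjusted_means(shuffled, s$design, "y")
  expect_equal(m1$adjusted_mean, m2$adjusted_mean, tolerance = 1e-10)
})

test_that("the plot-level CV concentrates at its generating value", {
  cvs <- vapply(1:20, function(s) {
    d <- make_design(7)
    m <- dth_recovery_model(extra_traits = FALSE)
    anova_table(simulate_trial(d, m, seed = 300 + s), d, "DTH")$cv_percent
  }, 1.0)
  expect_lt(abs(mean(cvs) - 100 * sqrt(4.15) / 71.7), 0.4)
})

test_that("adjusted means equal raw means when blocks contribute nothing", {
  d <- make_design(4)
  G <- rnorm(16, 0, 3)
  p <- manual_trial(d, mu = 30, G = G, sigma_b = 0, sigma_e = 0)
  am <- adjusted_means(p, d, "y")
  raw <- tapply(p$y, p$accession, mean)
  expect_equal(am$adjusted_mean, as.numeric(raw[am$accession]), tolerance = 1e-8)
})

test_that("adjusted means track the true genotype effects and average to the grand mean", {
  set.seed(42)
  d <- make_design(7)
  G <- rnorm(49, 0, sqrt(51.12))
  p <- manual_trial(d, mu = 71.7, G = G, sigma_b = sqrt(3), sigma_e = sqrt(4.15))
  am <- adjusted_means(p, d, "y")
  expect_gt(stats::cor(am$adjusted_mean, G[as.integer(am$accession)]), 0.95)
  expect_equal(mean(am$adjusted_mean), mean(p$y), tolerance = 1e-8)
  expect_equal(attr(am, "overall_mean"), mean(p$y), tolerance = 1e-8)
})

test_that("imbalance is reported with the offending cells", {
  s <- sim_for_anova(3, seed = 9)
  dropped <- s$plots[-5, ]
  expect_error(anova_table(dropped, s$design, "y"), "missing \\(accession, replication\\)")
  dup <- rbind(s$plots, s$plots[1, ])
  expect_error(anova_table(dup, s$design, "y"), "duplicated")
  wrong_block <- s$plots
  wrong_block$block[1] <- wrong_block$block[1] %% 3 + 1
  expect_error(anova_table(wrong_block, s$design, "y"), "block")
})

test_that("tukey groupings separate means exactly when differences exceed the HSD", {
  mk <- function(v) structure(data.frame(accession = seq_along(v), adjusted_mean = v),
                              r = 2, class = c("accession_means", "data.frame"))
  all_eq <- tukey_hsd(mk(rep(5, 6)), mse = 1, df_error = 36)
  expect_true(all(all_eq$group == "a"))
  q <- qtukey(0.95, 2, 36)
  hsd <- q * sqrt(1 / 2)
  two <- tukey_hsd(mk(c(0, 10 * hsd)), mse = 1, df_error = 36)
  expect_length(unique(two$group), 2)
  # hand case at df = 36: letters must encode exactly the pairwise rule
  five <- tukey_hsd(mk(c(10, 9.9, 7, 6.9, 3)), mse = 1, df_error = 36)
  hsd5 <- attr(five, "hsd")
  expect_equal(hsd5, qtukey(0.95, 5, 36) * sqrt(1 / 2))
  share <- function(g1, g2) any(strsplit(g1, "")[[1]] %in% strsplit(g2, "")[[1]])
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(share(five$group[i], five$group[j]),
                 abs(five$mean[i] - five$mean[j]) < hsd5,
                 info = paste("pair", i, j))
  }
  expect_error(tukey_hsd(mk(c(1, 2)), mse = -1, df_error = 10), "value error")
})
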