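# Published reference values of the calibration trial (7 x 7 simple
# lattice, 49 barley accessions, 2 replications) used by worked-example
# tests: mean squares, variance components and derived parameters, and the
# printed path tables.

ref_traits <- c("DTH", "DTM", "PLHT", "PDL", "NFT", "SL", "NSPS", "NKPS",
                "WKPS", "TKW", "GY")

# accession (block-adjusted) and residual mean squares per trait
ref_msg <- c(93.6, 114.68, 205.26, 12.3, 0.48, 1.73, 7.68, 165.93, 0.58, 59.91, 2.03)
ref_mse <- c(4.15, 5.5, 13.95, 1.9, 0.21, 0.25, 1.2, 19.72, 0.06, 4.93, 0.16)

# variability-components table: mean, sigma2_g, sigma2_p, GCV, PCV, H2, GA, GAM
ref_gp <- data.frame(
  trait = ref_traits,
  mean  = c(71.7, 113.7, 97.5, 36.9, 3.11, 7.87, 21.8, 41.2, 1.70, 37.4, 4.02),
  s2g   = c(51.12, 62.39, 109.3, 5.94, 0.16, 0.85, 3.70, 83.6, 0.30, 31.4, 1.07),
  s2p   = c(55.27, 67.89, 123.3, 7.84, 0.36, 1.10, 4.90, 103.3, 0.36, 36.35, 1.23),
  gcv   = c(9.97, 6.95, 10.7, 6.61, 12.7, 11.7, 8.84, 22.2, 32.3, 14.9, 25.7),
  pcv   = c(10.36, 7.25, 11.39, 7.59, 19.32, 13.31, 10.17, 24.65, 35.18, 16.13, 27.60),
  h2    = c(92.50, 91.90, 88.68, 75.75, 43.18, 76.81, 75.53, 80.90, 84.05, 86.45, 86.95),
  ga    = c(14.19, 15.62, 20.31, 4.38, 0.54, 1.66, 3.45, 16.96, 1.04, 10.75, 1.99),
  gam   = c(19.78, 13.74, 20.84, 11.87, 17.21, 21.09, 15.85, 41.83, 60.99, 28.76, 49.51)
)

# half-ulps of the printed values (printed decimal places differ by cell)
ref_hu <- data.frame(
  mean = c(.05, .05, .05, .05, .005, .005, .05, .05, .005, .05, .005),
  s2g  = c(.005, .005, .05, .005, .005, .005, .005, .05, .005, .05, .005),
  s2p  = c(.005, .005, .05, .0005, .0005, .0005, .0005, .05, .0005, .005, .0005)
)

# range of f over the corners of the printed-rounding intervals
corner_range <- function(f, ins, hus) {
  grid <- expand.grid(rep(list(c(-1, 1)), length(ins)))
  vals <- apply(grid, 1, function(s) f(ins + s * hus))
  range(vals)
}

ref_path_predictors <- c("DTH", "DTM", "PLHT", "NFT", "NSPS", "NKPS", "WKPS", "TKW")

# printed genotypic path table: direct effects (diagonal) and correlations
# of the predictors with grain yield
ref_path_g_direct <- c(0.094, 0.136, -0.055, 0.271, 0.225, 0.324, -0.147, 0.308)
ref_path_g_rxy    <- c(0.397, 0.505, 0.402, 0.849, 0.870, 0.733, 0.507, 0.811)
# full printed genotypic effect matrix, row by row (direct on the diagonal)
ref_path_g_rows <- rbind(
  c(0.094, 0.098, -0.025, 0.055, 0.068, 0.180, -0.101, 0.028),
  c(0.068, 0.136, -0.024, 0.073, 0.095, 0.174, -0.101, 0.085),
  c(0.042, 0.059, -0.055, 0.062, 0.102, 0.153, -0.082, 0.122),
  c(0.019, 0.037, -0.013, 0.271, 0.173, 0.182, -0.041, 0.221),
  c(0.028, 0.058, -0.025, 0.208, 0.225, 0.200, -0.069, 0.246),
  c(0.052, 0.073, -0.026, 0.152, 0.139, 0.324, -0.120, 0.138),
  c(0.064, 0.094, -0.031, 0.075, 0.106, 0.263, -0.147, 0.084),
  c(0.008, 0.038, -0.022, 0.195, 0.179, 0.145, -0.040, 0.308)
)

ref_path_p_direct <- c(0.112, 0.103, -0.075, 0.167, 0.233, 0.355, -0.157, 0.388)
ref_path_p_rxy    <- c(0.360, 0.464, 0.326, 0.716, 0.784, 0.689, 0.457, 0.771)

# conditions for parameter-recovery simulations at days-to-heading scale
dth_recovery_model <- function(extra_traits = TRUE) {
  if (extra_traits) {
    Rg <- matrix(c(1, 0.72, 0.39,
                   0.72, 1, 0.51,
                   0.39, 0.51, 1), 3, byrow = TRUE)
    genetic_model(c("DTH", "DTM", "GY"),
                  mu = c(71.7, 113.7, 4.02),
                  sigma2_g = c(51.12, 62.39, 1.07),
                  sigma2_e = c(4.15, 5.5, 0.16),
                  Rg = Rg, sigma2_b = c(3, 3, 0.03))
  } else {
    genetic_model("DTH", mu = 71.7, sigma2_g = 51.12, sigma2_e = 4.15,
                  sigma2_b = 3)
  }
}
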