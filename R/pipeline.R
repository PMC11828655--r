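#' Read and validate a plot-level trait table
#'
#' Expects a CSV with columns `accession,replication,block,<trait...>`.
#' Duplicated (accession, replication) rows are an error (never silently
#' averaged), as are non-numeric trait cells; both errors cite the
#' offending row numbers.
#'
#' @param path CSV file path.
#' @param traits Optional trait columns to require and validate (default:
#'   every column beyond the three keys).
#' @param strip_thousands If TRUE, commas inside quoted accession ids are
#'   removed (ids such as "243,599" become "243599"). Default FALSE: ids
#'   are opaque strings.
#' @return A validated plot-table data frame.
#' @export
read_plot_table <- function(path, traits = NULL, strip_thousands = FALSE) {
  raw <- utils::read.csv(path, colClasses = c(accession = "character"),
                         check.names = FALSE)
  need <- c("accession", "replication", "block")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (strip_thousands) raw$accession <- gsub(",", "", raw$accession, fixed = TRUE)
  key <- paste(raw$accession, raw$replication)
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    rows <- which(key == bad)
    stop("schema error: duplicated (accession, replication) = (",
         gsub(" ", ", rep ", bad), ") in rows ",
         paste(rows + 1L, collapse = " and "), call. = FALSE)
  }
  if (is.null(traits)) traits <- setdiff(names(raw), need)
  for (tr in traits) {
    if (!tr %in% names(raw))
      stop("schema error: trait column '", tr, "' not found", call. = FALSE)
    v <- suppressWarnings(as.numeric(raw[[tr]]))
    bad <- which(is.na(v) & !is.na(raw[[tr]]) & raw[[tr]] != "")
    if (length(bad))
      stop("schema error: non-numeric value(s) in trait '", tr, "' at row(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    raw[[tr]] <- v
  }
  raw$replication <- as.integer(raw$replication)
  raw$block <- as.integer(raw$block)
  raw
}

#' Reconstruct a lattice design from plot-level data
#'
#' Builds the `lattice_design` implied by the `(accession, replication,
#' block)` columns of a plot table with arbitrary accession ids. Accessions
#' are coded 1..g in sorted-id order; the original ids are returned
#' alongside. The reconstructed layout is validated against the simple
#' lattice invariants.
#'
#' @param plots Plot table with `accession`, `replication`, `block`.
#' @return List with `design` (accessions coded as integers) and
#'   `accession_labels` (original id for each code).
#' @export
design_from_plots <- function(plots) {
  need <- c("accession", "replication", "block")
  miss <- setdiff(need, names(plots))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  labels <- sort(unique(as.character(plots$accession)))
  g <- length(labels)
  k <- sqrt(g)
  if (k != round(k))
    stop("design error: ", g, " accessions is not a perfect square", call. = FALSE)
  layout <- data.frame(
    accession = match(as.character(plots$accession), labels),
    replication = as.integer(plots$replication),
    block = as.integer(plots$block)
  )
  design <- structure(list(k = as.integer(k), r = 2L, g = g, layout = layout),
                      class = "lattice_design")
  validate_design(design)
  list(design = design, accession_labels = labels)
}

#' Assemble a pipeline configuration
#'
#' @param input Path to a plot-level CSV, or NULL to simulate.
#' @param model A `genetic_model` (required when `input` is NULL).
#' @param k,r Lattice dimensions (defaults 7 and 2).
#' @param traits Trait columns to analyse (default: all).
#' @param yield_trait Dependent trait for path analysis (default `"GY"`).
#' @param alpha Significance level for correlation stars and predictor
#'   selection (default 0.05).
#' @param k_sel Standardized selection differential (default 2.063, 5%
#'   selection intensity).
#' @param thresholds Category cut points, see [default_thresholds()].
#' @param n_clusters Number of UPGMA clusters K (default 6).
#' @param outdir Output directory for the report bundle.
#' @param seed Integer seed driving the simulation (and recorded in the
#'   manifest).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, model = NULL, k = 7, r = 2,
                            traits = NULL, yield_trait = "GY", alpha = 0.05,
                            k_sel = 2.063, thresholds = default_thresholds(),
                            n_clusters = 6, outdir = "lattivar-report",
                            seed = 1) {
  if (is.null(input) && is.null(model))
    stop("config error: provide an input CSV or a generating model", call. = FALSE)
  structure(list(input = input, model = model, k = k, r = r, traits = traits,
                 yield_trait = yield_trait, alpha = alpha, k_sel = k_sel,
                 thresholds = thresholds, n_clusters = n_clusters,
                 outdir = outdir, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' From a plot-level table (read from `config$input` or simulated from
#' `config$model`) to the complete report bundle: per-trait ANOVA mean
#' squares, genetic-parameter table, combined correlation matrix,
#' genotypic and phenotypic path tables, distance summary, cluster
#' membership and means, PCA table with scores, a newick dendrogram and a
#' JSON manifest of all settings. Identical config and seed give an
#' identical bundle. Any stage failure removes partial outputs and
#' propagates with the stage name.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every stage result and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  fresh <- !dir.exists(outdir)
  if (fresh) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "input"
    if (is.null(config$input)) {
      design <- make_design(config$k, config$r)
      plots <- simulate_trial(design, config$model, seed = config$seed)
      labels <- as.character(seq_len(design$g))
    } else {
      plots <- read_plot_table(config$input, traits = config$traits)
      dfp <- design_from_plots(plots)
      design <- dfp$design
      labels <- dfp$accession_labels
      plots$accession <- match(plots$accession, labels)
    }
    traits <- config$traits
    if (is.null(traits)) traits <- trait_columns(plots)
    if (!config$yield_trait %in% traits)
      stop("yield trait '", config$yield_trait, "' not among the traits")

    stage <- "anova"
    anovas <- lapply(traits, function(tr) anova_table(plots, design, tr))
    names(anovas) <- traits
    ms_tab <- data.frame(
      source = c(anovas[[1]]$table$source, "cv_percent"),
      df = c(anovas[[1]]$table$df, NA)
    )
    for (tr in traits)
      ms_tab[[tr]] <- c(paste0(signif(anovas[[tr]]$table$ms, 5),
                               anovas[[tr]]$table$sig),
                        sprintf("%.2f", anovas[[tr]]$cv_percent))
    emit(ms_tab, "anova_mean_squares.csv")

    stage <- "adjusted means"
    am <- lapply(traits, function(tr) adjusted_means(plots, design, tr))
    names(am) <- traits
    mean_mat <- do.call(cbind, lapply(am, function(m) m$adjusted_mean))
    dimnames(mean_mat) <- list(labels[as.integer(am[[1]]$accession)], traits)
    emit(data.frame(accession = rownames(mean_mat), mean_mat,
                    check.names = FALSE), "adjusted_means.csv")

    stage <- "genetic parameters"
    gp <- genetic_params(plots, design, traits, k_sel = config$k_sel,
                         thresholds = config$thresholds)
    gp_out <- gp
    num <- vapply(gp_out, is.numeric, TRUE)
    gp_out[num] <- lapply(gp_out[num], round, 2)
    emit(gp_out, "genetic_parameters.csv")

    stage <- "correlations"
    corr <- correlation_matrices(plots, design, traits)
    emit(corr_table(corr), "correlations.csv")

    stage <- "path analysis"
    paths <- list()
    for (lv in c("genotypic", "phenotypic")) {
      pr <- path_analysis(corr, config$yield_trait, lv, config$alpha)
      paths[[lv]] <- pr
      tab <- data.frame(trait = pr$predictors, round(pr$effects, 3),
                        r_with_yield = round(pr$rxy, 3),
                        residual_effect = round(pr$residual_effect, 4),
                        check.names = FALSE)
      emit(tab, paste0("path_", lv, ".csv"))
    }

    stage <- "diversity"
    sd_res <- standardize_and_distance(mean_mat)
    emit(data.frame(accession = rownames(sd_res$D), round(sd_res$D, 4),
                    check.names = FALSE), "distance_matrix.csv")
    ds <- distance_summary(sd_res$D)
    dsr <- ds; dsr[-1] <- lapply(dsr[-1], round, 2)
    emit(dsr, "distance_summary.csv")
    cl <- upgma_cluster(sd_res$D, K = config$n_clusters)
    memb <- data.frame(
      cluster = names(cl$clusters),
      n = lengths(cl$clusters),
      accessions = vapply(cl$clusters, paste, "", collapse = " ")
    )
    emit(memb, "cluster_membership.csv")
    cm <- cluster_means(mean_mat, cl$assignment)
    cmr <- cm; cmr[-(1:2)] <- lapply(cmr[-(1:2)], round, 2)
    emit(cmr, "cluster_means.csv")
    nwk <- file.path(outdir, "dendrogram.nwk")
    writeLines(cl$newick, nwk)
    written <- c(written, nwk)

    stage <- "pca"
    pca <- pca_correlation(mean_mat)
    pca_tab <- data.frame(
      component = paste0("PC", seq_len(pca$t)),
      t(round(pca$loadings, 3)),
      eigenvalue = round(pca$eigenvalues, 3),
      var_percent = round(pca$var_explained_percent, 2),
      cum_var_percent = round(pca$cum_var_explained_percent, 2),
      check.names = FALSE
    )
    emit(pca_tab, "pca.csv")
    emit(data.frame(accession = rownames(pca$scores), round(pca$scores, 4),
                    check.names = FALSE), "pca_scores.csv")

    stage <- "manifest"
    manifest <- list(
      package = "lattivar",
      seed = config$seed, k = config$k, r = config$r,
      traits = traits, yield_trait = config$yield_trait,
      alpha = config$alpha, k_sel = config$k_sel,
      thresholds = config$thresholds, n_clusters = config$n_clusters,
      input = if (is.null(config$input)) "simulated" else config$input,
      files = basename(written)
    )
    mpath <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, mpath)

    list(design = design, plots = plots, anovas = anovas,
         adjusted_means = am, genetic_params = gp, correlations = corr,
         paths = paths, distance = sd_res, distance_summary = ds,
         clustering = cl, cluster_means = cm, pca = pca, files = written)
  }, error = function(e) {
    unlink(written)
    if (fresh) unlink(outdir, recursive = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
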