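#' Assemble the per-tree analysis dataset
#'
#' Joins damage summaries with plot covariates (plot level) and, for
#' focal trees, neighborhood covariates. This is the common front end of
#' the two analysis levels.
#'
#' @param study List with `trees`, `assessments`, `leaf_samples`,
#'   `oak_leaf_samples` (a `synthetic_study` or equivalently-shaped field
#'   data).
#' @param gap,plot_size Neighborhood geometry parameters.
#' @param taxonomy Classification table.
#' @return data.frame, one row per focal tree, with damage indices, plot
#'   covariates and neighborhood covariates (`nb_*`, `delta_h`,
#'   `n_neighbors`, `margin_excluded`).
#' @export
build_dataset <- function(study, gap = 3, plot_size = 30,
                          taxonomy = default_taxonomy()) {
  trees <- study$trees
  resolved <- resolve_assessments(study$assessments)
  dmg <- damage_summary(resolved, study$leaf_samples)
  if (any(dmg$excluded)) {
    warning(sum(dmg$excluded), " fully dead crown(s) excluded")
    dmg <- dmg[!dmg$excluded, , drop = FALSE]
  }
  dmg$plot_id <- trees$plot_id[match(dmg$tree_id, trees$tree_id)]

  pcov <- plot_covariates(trees, study$oak_leaf_samples, taxonomy)
  dat <- merge(dmg, pcov, by = "plot_id", sort = FALSE)

  ctx <- neighborhood_contexts(trees, dmg$tree_id, gap = gap,
                               plot_size = plot_size)
  ncov <- neighborhood_covariates(ctx, trees, taxonomy)
  dat <- merge(dat, ncov, by.x = "tree_id", by.y = "focal_id",
               sort = FALSE)
  dat[order(dat$tree_id), , drop = FALSE]
}

#' Plot-level analysis
#'
#' Screens total defoliation for outliers (parametric-simulation
#' envelope), fits the six-model plot-level set (null plus five
#' univariate models of log defoliation with a plot random intercept),
#' and computes the correlation battery: total defoliation against total
#' damaged crown, leaf gall incidence, oak galls, taxonomic diversity and
#' host proportion.
#'
#' @param dataset From [build_dataset()].
#' @param seed Seed for the outlier screen.
#' @param keep_outliers If TRUE, models are also fitted on the unfiltered
#'   data (robustness redo) and returned as `comparison_full`.
#' @param ... Passed to [screen_outliers()] (`n_sim`, `level`,
#'   `envelope`).
#' @return List of class `plot_level_analysis`: `comparison`,
#'   `correlations` (data.frame pair, r, p, n), `screen` (outlier
#'   report), `data` (filtered), `manifest`; plus `comparison_full` when
#'   requested.
#' @export
run_plot_level <- function(dataset, seed = 1, keep_outliers = FALSE, ...) {
  scr <- apply_screen(dataset, "td", seed = seed, ...)
  dat <- scr$filtered

  comparison <- compare_models(dat, plot_model_set(), response = "td")

  correlations <- rbind(
    .cor_row("td_vs_tdc", dat$td, dat$tdc),
    .cor_row("td_vs_leaf_gall", dat$td, dat$leaf_gall_pct),
    .cor_row("td_vs_oak_galls", dat$td, dat$oak_gall_pct),
    .cor_row("td_vs_tax_div", dat$td, dat$tax_div),
    .cor_row("td_vs_prop_castanea", dat$td, dat$prop_castanea)
  )

  out <- list(
    comparison = comparison,
    correlations = correlations,
    screen = scr$report,
    data = dat,
    manifest = list(
      level = "plot", seed = seed,
      n_input = nrow(dataset), n_outliers = length(scr$report$flagged),
      n_analysed = nrow(dat),
      mean_td_pct = 100 * mean(dat$td),
      sd_td_pct = 100 * stats::sd(dat$td),
      range_td_pct = 100 * range(dat$td),
      estimation = "REML estimates, ML likelihoods for AICc"
    )
  )
  if (keep_outliers) {
    out$comparison_full <- compare_models(scr$full, plot_model_set(),
                                          response = "td")
  }
  class(out) <- "plot_level_analysis"
  out
}

.cor_row <- function(label, x, y) {
  keep <- stats::complete.cases(x, y)
  if (sum(keep) < 3) {
    return(data.frame(pair = label, r = NA_real_, p = NA_real_,
                      n = sum(keep)))
  }
  ct <- pearson(x, y)
  data.frame(pair = label, r = ct$r, p = ct$p, n = ct$n)
}

#' Neighborhood-level analysis
#'
#' Restricts the dataset to focal trees that survive margin exclusion and
#' have at least one neighbor, screens for outliers within that subset,
#' fits the fifteen-model neighborhood set, and runs the sequential
#' variance decomposition of tree apparency and the plot-level Shannon
#' index in both orders.
#'
#' @inheritParams run_plot_level
#' @param decompose Character vector of two predictor columns for the
#'   sequential decomposition (default apparency then plot-level
#'   Shannon).
#' @return List of class `neighborhood_analysis`: `comparison`,
#'   `decomposition`, `screen`, `data`, `manifest`; plus
#'   `comparison_full` when requested.
#' @export
run_neighborhood_level <- function(dataset, seed = 1,
                                   keep_outliers = FALSE,
                                   decompose = c("delta_h", "shannon"),
                                   ...) {
  nb <- dataset[!dataset$margin_excluded & dataset$n_neighbors > 0, ,
                drop = FALSE]
  if (nrow(nb) == 0) {
    stop("no focal tree survives margin exclusion: neighborhood-level ",
         "analysis impossible")
  }
  scr <- apply_screen(nb, "td", seed = seed, ...)
  dat <- scr$filtered

  comparison <- compare_models(dat, neighborhood_model_set(),
                               response = "td")
  decomposition <- sequential_decomposition(dat, decompose[1],
                                            decompose[2], response = "td")

  out <- list(
    comparison = comparison,
    decomposition = decomposition,
    screen = scr$report,
    data = dat,
    manifest = list(
      level = "neighborhood", seed = seed,
      n_input = nrow(dataset), n_margin_kept = nrow(nb),
      n_outliers = length(scr$report$flagged), n_analysed = nrow(dat),
      estimation = "REML estimates, ML likelihoods for AICc"
    )
  )
  if (keep_outliers) {
    out$comparison_full <- compare_models(scr$full,
                                          neighborhood_model_set(),
                                          response = "td")
  }
  class(out) <- "neighborhood_analysis"
  out
}

#' Run the complete study pipeline
#'
#' Front-to-back orchestration: build the per-tree dataset, then the
#' plot-level and neighborhood-level analyses. Input is either a
#' simulated study (see [simulate_study()]) or field data shaped the
#' same way. When `out_dir` is given, comparison tables and correlations
#' are written as CSV and the run manifest as JSON.
#'
#' @param study Study data list (see [build_dataset()]).
#' @param seed Seed for the outlier screens.
#' @param out_dir Optional output directory.
#' @param ... Passed on to [run_plot_level()] and
#'   [run_neighborhood_level()].
#' @return List of class `study_analysis`: `dataset`, `plot`,
#'   `neighborhood`, `manifest`.
#' @export
run_study <- function(study, seed = 1, out_dir = NULL, ...) {
  dataset <- build_dataset(study,
                           gap = if (!is.null(study$config)) {
                             study$config$gap
                           } else 3,
                           plot_size = if (!is.null(study$config)) {
                             study$config$plot_size
                           } else 30)
  plot_res <- run_plot_level(dataset, seed = seed, ...)
  nb_res <- run_neighborhood_level(dataset, seed = seed, ...)
  manifest <- list(seed = seed,
                   plot = plot_res$manifest,
                   neighborhood = nb_res$manifest)
  out <- list(dataset = dataset, plot = plot_res, neighborhood = nb_res,
              manifest = manifest)
  class(out) <- "study_analysis"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(plot_res$comparison),
                     file.path(out_dir, "comparison_plot.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(nb_res$comparison),
                     file.path(out_dir, "comparison_neighborhood.csv"),
                     row.names = FALSE)
    utils::write.csv(plot_res$correlations,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset, file.path(out_dir, "dataset.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("== Plot level ==\n")
  print(x$plot$comparison)
  cat("\n== Neighborhood level ==\n")
  print(x$neighborhood$comparison)
  cat("\n")
  print(x$neighborhood$decomposition)
  invisible(x)
}
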