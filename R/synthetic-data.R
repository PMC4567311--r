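#' Configuration for the synthetic stand generator
#'
#' Defaults reproduce the field sampling design: 15 plots of 30 m x 30 m
#' along a tree-species-richness gradient (2 monocultures, 3 two-species,
#' 5 three-species and 5 four-species plots), chestnut always present,
#' companion species drawn from three oaks and hop-hornbeam. Tree sizes
#' are drawn near the published stand means (chestnut height 15.2 +/- 3.3
#' m; basal areas around 0.03 m^2; crown areas around 15 m^2; companion
#' species on average taller than the focal chestnuts, so that focal
#' apparency decreases along the diversity gradient as observed in the
#' field). Log total
#' defoliation follows a linear predictor with a plot random intercept, a
#' negative richness effect and a positive apparency effect; default
#' effect sizes equal the published estimates (-0.26 per species, +0.15
#' per metre) so parameter-recovery tests double as plausibility checks.
#' The intercept places mean defoliation near 13% at the design's mean
#' richness. Focal crown-assessment counts per richness class (19, 14,
#' 18, 19 = 70 trees) and the leaf-sampled subset (12, 9, 15, 15 = 51)
#' follow the published sampling effort.
#'
#' @param plots_per_richness Number of plots per richness class 1-4.
#' @param plot_size Plot side length, m.
#' @param trees_per_plot Stems per plot (before focal selection).
#' @param min_spacing Minimum stem-to-stem distance, m (rejection
#'   sampling).
#' @param focal_per_richness Crown-assessed focal chestnuts per richness
#'   class.
#' @param leaf_per_richness Leaf-sampled focal chestnuts per richness
#'   class.
#' @param height_mean,height_sd Named per-species height distributions, m.
#' @param dbh_meanlog,dbh_sdlog Lognormal dbh parameters (cm scale).
#' @param crown_meanlog,crown_sdlog Lognormal crown-area parameters (m^2).
#' @param beta0 Intercept of log defoliation (proportion scale).
#' @param beta_richness Richness effect on log defoliation (per species).
#' @param beta_apparency Apparency effect on log defoliation (per metre).
#' @param sigma_plot Plot random-intercept SD.
#' @param sigma_resid Residual SD.
#' @param leaf_gall_slope Logit-scale link from defoliation to per-leaf
#'   gall probability.
#' @param oak_gall_range Range of per-plot oak gall incidence
#'   (proportion).
#' @param n_branches,n_leaves Leaf-sampling protocol per tree.
#' @param gap Crown neighbor gap, m.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    plots_per_richness = c(2, 3, 5, 5),
    plot_size = 30,
    trees_per_plot = 40,
    min_spacing = 2,
    focal_per_richness = c(19, 14, 18, 19),
    leaf_per_richness = c(12, 9, 15, 15),
    height_mean = c(CS = 15.2, QC = 19, QI = 16, QP = 19, OC = 14),
    height_sd = c(CS = 3.3, QC = 3, QI = 2.5, QP = 3, OC = 2.5),
    dbh_meanlog = log(18), dbh_sdlog = 0.45,
    crown_meanlog = log(13), crown_sdlog = 0.55,
    beta0 = -1.65,
    beta_richness = -0.26,
    beta_apparency = 0.15,
    sigma_plot = 0.2,
    sigma_resid = 0.4,
    leaf_gall_slope = 1,
    oak_gall_range = c(0.05, 0.35),
    n_branches = 2,
    n_leaves = 30,
    gap = 3) {
  stopifnot(length(plots_per_richness) == 4,
            sigma_plot >= 0, sigma_resid >= 0,
            all(focal_per_richness >= leaf_per_richness))
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# Rejection-sample n positions with minimum spacing inside a square plot.
.place_trees <- function(n, side, min_spacing, max_tries = 2000) {
  xs <- numeric(0)
  ys <- numeric(0)
  tries <- 0
  while (length(xs) < n) {
    x <- stats::runif(1, 0, side)
    y <- stats::runif(1, 0, side)
    if (length(xs) == 0 ||
        min((xs - x)^2 + (ys - y)^2) >= min_spacing^2) {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
    tries <- tries + 1
    if (tries > max_tries) {
      stop("could not place ", n, " trees with ", min_spacing,
           " m spacing in a ", side, " m plot")
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic multi-plot stand
#'
#' Draws tree maps for all plots: uniform positions with a minimum
#' spacing, species compositions matching each plot's richness class
#' (chestnut always present; companions sampled from QC, QI, QP, OC),
#' and sizes from the configured distributions. Focal chestnuts are the
#' largest-dbh chestnuts per plot, with per-richness-class totals from
#' the config; the leaf-sampled subset is the largest-dbh focal trees.
#'
#' @param config From [synthetic_config()].
#' @param seed Integer seed.
#' @return data.frame of trees: `tree_id`, `plot_id`, `richness_class`,
#'   `species`, `x`, `y`, `dbh`, `height`, `crown_area`, `clump_id` (NA:
#'   the generator emits single stems), `focal`, `leaf_sampled`.
#' @export
generate_stands <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  pool <- c("QC", "QI", "QP", "OC")
  plots <- rep(1:4, config$plots_per_richness)
  out <- list()
  for (p in seq_along(plots)) {
    rich <- plots[p]
    species_set <- c("CS", if (rich > 1) sample(pool, rich - 1))
    n <- config$trees_per_plot
    # chestnut-dominated mixtures: host share decreases with richness
    w <- c(2, rep(1, rich - 1))
    sp <- sample(species_set, n, replace = TRUE, prob = w / sum(w))
    sp[sample.int(n, rich)] <- species_set  # every species present
    pos <- .place_trees(n, config$plot_size, config$min_spacing)
    height <- stats::rnorm(n, config$height_mean[sp], config$height_sd[sp])
    height <- pmax(height, 2)
    out[[p]] <- data.frame(
      tree_id = sprintf("P%02dT%02d", p, seq_len(n)),
      plot_id = sprintf("P%02d", p),
      richness_class = rich,
      species = sp,
      x = pos[, "x"], y = pos[, "y"],
      dbh = stats::rlnorm(n, config$dbh_meanlog, config$dbh_sdlog),
      height = height,
      crown_area = stats::rlnorm(n, config$crown_meanlog,
                                 config$crown_sdlog),
      clump_id = NA_character_
    )
  }
  trees <- do.call(rbind, out)
  rownames(trees) <- NULL

  # focal selection: largest-dbh chestnuts, class quota split over plots
  trees$focal <- FALSE
  trees$leaf_sampled <- FALSE
  for (rich in 1:4) {
    ids <- unique(trees$plot_id[trees$richness_class == rich])
    quota <- .split_quota(config$focal_per_richness[rich], length(ids))
    leaf_quota <- .split_quota(config$leaf_per_richness[rich], length(ids))
    for (k in seq_along(ids)) {
      cs <- trees[trees$plot_id == ids[k] & trees$species == "CS", ]
      top <- cs$tree_id[order(-cs$dbh)][seq_len(min(quota[k], nrow(cs)))]
      trees$focal[trees$tree_id %in% top] <- TRUE
      trees$leaf_sampled[
        trees$tree_id %in% top[seq_len(min(leaf_quota[k], length(top)))]
      ] <- TRUE
    }
  }
  trees
}

# Split a class-level quota as evenly as possible over k plots.
.split_quota <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + (seq_len(k) <= extra)
}

#' Generate crown assessments from a latent damage model
#'
#' Draws log total defoliation for every focal tree from
#' `beta0 + beta_richness * richness + beta_apparency * delta_H + b_plot
#' + eps`, back-transforms, clips to (0, 1), decomposes the latent
#' defoliation into the five crown variables and discretizes them into
#' the 7 percentage classes on two viewing sides, so the class-resolution
#' pipeline is exercised end-to-end. The decomposition draws the sunlit
#' crown fraction around 0.6, sets shaded defoliation to 0.8 of sunlit
#' defoliation, inverts the defoliation equation for the sunlit value and
#' adds small dead-branch proportions; only its round-trip consistency
#' matters. Apparency is computed from the synthetic map (0 where a tree
#' has no neighbors).
#'
#' @param trees From [generate_stands()].
#' @param config From [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `assessments` (tree_id, side, five `*_class` columns),
#'   `latent` (tree_id, plot_id, td_latent, delta_h, b_plot).
#' @export
generate_damage <- function(trees, config = synthetic_config(), seed = 1) {
  set.seed(seed + 1L)
  focal <- trees[trees$focal, , drop = FALSE]
  ctx <- neighborhood_contexts(trees, focal$tree_id, gap = config$gap,
                               plot_size = config$plot_size)$contexts
  dh <- ifelse(is.na(ctx$delta_h), 0, ctx$delta_h)

  plot_ids <- unique(focal$plot_id)
  b_plot <- stats::rnorm(length(plot_ids), 0, config$sigma_plot)
  names(b_plot) <- plot_ids
  eta <- config$beta0 + config$beta_richness * focal$richness_class +
    config$beta_apparency * dh + b_plot[focal$plot_id] +
    stats::rnorm(nrow(focal), 0, config$sigma_resid)
  td <- pmin(pmax(exp(eta), 1e-3), 0.98)
  if (mean(exp(eta) >= 1) > 0.01) {
    warning("more than 1% of simulated defoliation draws at or above 1; ",
            "consider smaller effect sizes")
  }

  # decompose td into the five crown variables (inverts the defoliation
  # equation given pcl and small dead-branch proportions)
  n <- nrow(focal)
  pcl <- stats::rbeta(n, 6, 4)              # centred at 0.6
  pdbl <- stats::rbeta(n, 1, 40)            # small dead-branch shares
  pdbs <- stats::rbeta(n, 1, 25)
  pacl <- living_crown_light_fraction(pcl, pdbl, pdbs)
  pdl <- pmin(td / (0.8 + 0.2 * pacl), 1)   # so that eq 2 returns td
  pds <- 0.8 * pdl

  scheme <- damage_class_scheme()
  to_class <- function(p, jitter_sd = 0.01) {
    pj <- pmin(pmax(p + stats::rnorm(length(p), 0, jitter_sd), 0), 1)
    findInterval(100 * pj, scheme$lower + c(0, rep(1e-9, 6))) - 1L
  }
  side_of <- function(jitter_sd) data.frame(
    tree_id = focal$tree_id,
    pcl_class = to_class(pcl, jitter_sd),
    pdbl_class = to_class(pdbl, jitter_sd),
    pdbs_class = to_class(pdbs, jitter_sd),
    pdl_class = to_class(pdl, jitter_sd),
    pds_class = to_class(pds, jitter_sd)
  )
  assessments <- rbind(cbind(side = 1L, side_of(0)),
                       cbind(side = 2L, side_of(0.01)))
  assessments <- assessments[order(assessments$tree_id, assessments$side), ]
  rownames(assessments) <- NULL
  latent <- data.frame(tree_id = focal$tree_id, plot_id = focal$plot_id,
                       td_latent = td, delta_h = dh,
                       b_plot = unname(b_plot[focal$plot_id]))
  list(assessments = assessments, latent = latent)
}

#' Generate branch-level leaf samples
#'
#' Per leaf-sampled focal chestnut: binomial galled-leaf counts on each
#' branch, with per-leaf gall probability increasing in the tree's latent
#' defoliation (logit link plus tree-level noise). Per oak in mixed
#' plots: binomial counts at the plot's oak gall incidence, drawn
#' uniformly from the configured range.
#'
#' @param trees From [generate_stands()].
#' @param latent `latent` element of [generate_damage()].
#' @param config From [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `chestnut` (plot_id, tree_id, branch, n_leaves,
#'   n_galled), `oak` (same columns, oak trees).
#' @export
generate_leaf_samples <- function(trees, latent,
                                  config = synthetic_config(), seed = 1) {
  set.seed(seed + 2L)
  sampled <- trees[trees$leaf_sampled, , drop = FALSE]
  td <- latent$td_latent[match(sampled$tree_id, latent$tree_id)]
  p <- stats::plogis(stats::qlogis(pmin(pmax(td, 0.01), 0.95)) *
                       config$leaf_gall_slope +
                       stats::rnorm(nrow(sampled), 0, 0.5))
  chestnut <- do.call(rbind, lapply(seq_len(nrow(sampled)), function(i) {
    data.frame(plot_id = sampled$plot_id[i], tree_id = sampled$tree_id[i],
               branch = seq_len(config$n_branches),
               n_leaves = config$n_leaves,
               n_galled = stats::rbinom(config$n_branches, config$n_leaves,
                                        p[i]))
  }))

  oaks <- trees[trees$species %in% c("QC", "QI", "QP"), , drop = FALSE]
  oak <- NULL
  if (nrow(oaks) > 0) {
    plot_inc <- stats::runif(length(unique(oaks$plot_id)),
                             config$oak_gall_range[1],
                             config$oak_gall_range[2])
    names(plot_inc) <- unique(oaks$plot_id)
    # sample up to 3 oaks per plot, mirroring the field effort
    keep <- unlist(lapply(split(oaks$tree_id, oaks$plot_id), function(ids) {
      ids[seq_len(min(3, length(ids)))]
    }))
    oaks <- oaks[oaks$tree_id %in% keep, , drop = FALSE]
    oak <- do.call(rbind, lapply(seq_len(nrow(oaks)), function(i) {
      data.frame(plot_id = oaks$plot_id[i], tree_id = oaks$tree_id[i],
                 branch = seq_len(config$n_branches),
                 n_leaves = config$n_leaves,
                 n_galled = stats::rbinom(config$n_branches,
                                          config$n_leaves,
                                          plot_inc[oaks$plot_id[i]]))
    }))
  }
  list(chestnut = chestnut, oak = oak)
}

#' Simulate a complete study dataset
#'
#' Runs the three generator stages under one seed and returns every table
#' the analysis pipeline consumes.
#'
#' @param config From [synthetic_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_study`: `trees`, `assessments`,
#'   `leaf_samples` (chestnut), `oak_leaf_samples`, `latent`, `config`,
#'   `seed`.
#' @export
simulate_study <- function(config = synthetic_config(), seed = 1) {
  trees <- generate_stands(config, seed)
  dmg <- generate_damage(trees, config, seed)
  leaves <- generate_leaf_samples(trees, dmg$latent, config, seed)
  out <- list(trees = trees, assessments = dmg$assessments,
              leaf_samples = leaves$chestnut,
              oak_leaf_samples = leaves$oak,
              latent = dmg$latent, config = config, seed = seed)
  class(out) <- "synthetic_study"
  out
}
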