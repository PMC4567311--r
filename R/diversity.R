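#' Basal area from diameter at breast height
#'
#' Standard forestry cross-section: `pi * (dbh / 2)^2` with dbh converted
#' from centimetres to metres.
#'
#' @param dbh Diameter at breast height, cm.
#' @return Basal area in m^2.
#' @export
basal_area <- function(dbh) {
  if (any(!is.na(dbh) & dbh <= 0)) stop("dbh must be positive")
  pi * (dbh / 200)^2
}

#' Shannon diversity index
#'
#' `H' = -sum(p_i log p_i)` on natural logs. Shares are renormalized with a
#' warning when they do not sum to one; zero shares contribute nothing.
#'
#' @param shares Non-negative abundance shares (here: relative basal area).
#' @return H' >= 0; 0 for a single species.
#' @export
shannon_index <- function(shares) {
  if (length(shares) == 0 || all(is.na(shares))) stop("empty community")
  if (any(shares < 0, na.rm = TRUE)) stop("negative share")
  s <- sum(shares, na.rm = TRUE)
  if (s <= 0) stop("empty community")
  if (abs(s - 1) > 1e-8) {
    warning("shares do not sum to 1; renormalizing")
  }
  p <- shares[!is.na(shares) & shares > 0] / s
  -sum(p * log(p))
}

#' Default taxonomy for the study species pool
#'
#' The five broadleaved species of the Tuscan chestnut stands, classified
#' to order: sweet chestnut (CS), three oaks (QC, QI, QP; all Quercus,
#' Fagaceae) and hop-hornbeam (OC, Betulaceae). Under this classification
#' all three oaks are equidistant from both C. sativa and
#' O. carpinifolia.
#'
#' @return data.frame with columns `species`, `genus`, `family`, `order`,
#'   rownames = species codes.
#' @export
default_taxonomy <- function() {
  data.frame(
    species = c("Castanea sativa", "Quercus cerris", "Quercus ilex",
                "Quercus petraea", "Ostrya carpinifolia"),
    genus = c("Castanea", "Quercus", "Quercus", "Quercus", "Ostrya"),
    family = c("Fagaceae", "Fagaceae", "Fagaceae", "Fagaceae", "Betulaceae"),
    order = c("Fagales", "Fagales", "Fagales", "Fagales", "Fagales"),
    row.names = c("CS", "QC", "QI", "QP", "OC")
  )
}

#' Pairwise taxonomic distances through a Linnaean classification
#'
#' Path length between two species through the classification, with unit
#' step length per level: congeneric species are 2 steps apart (up to the
#' genus and down again), confamilial 4, same order 6. Distance of a
#' species to itself is 0.
#'
#' @param taxonomy Classification table as in [default_taxonomy()]:
#'   rownames are species codes, columns ordered from the lowest rank
#'   (species) upwards.
#' @param step_lengths Per-level step weights, one per column of
#'   `taxonomy` (default all 1).
#' @return Symmetric distance matrix with species codes as dimnames.
#' @export
taxonomic_distances <- function(taxonomy = default_taxonomy(),
                                step_lengths = rep(1, ncol(taxonomy))) {
  stopifnot(length(step_lengths) == ncol(taxonomy))
  codes <- rownames(taxonomy)
  n <- length(codes)
  d <- matrix(0, n, n, dimnames = list(codes, codes))
  cum <- cumsum(step_lengths)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      shared <- which(taxonomy[i, ] == taxonomy[j, ])
      if (length(shared) == 0) {
        stop("species ", codes[i], " and ", codes[j],
             " share no classification level")
      }
      # up to the lowest shared rank and down again
      d[i, j] <- 2 * cum[min(shared) - 1]
    }
  }
  d
}

#' Abundance-weighted taxonomic diversity
#'
#' Clarke & Warwick's taxonomic diversity Delta: the mean taxonomic path
#' length between two randomly chosen individuals,
#' `sum_{i<j} d_ij x_i x_j / (n (n - 1) / 2)` with `n = sum(x)`. Zero for
#' monocultures; invariant to rescaling all abundances. Abundances here
#' are basal areas, so they need not be integers.
#'
#' @param abundances Named non-negative abundances (names = species codes).
#' @param dist Distance matrix from [taxonomic_distances()].
#' @return Delta >= 0.
#' @export
taxonomic_diversity <- function(abundances, dist = taxonomic_distances()) {
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0) stop("empty community")
  sp <- names(abundances)
  missing <- setdiff(sp, rownames(dist))
  if (length(missing) > 0) {
    stop("species missing from taxonomy: ", paste(missing, collapse = ", "))
  }
  if (length(sp) == 1) return(0)
  x <- as.numeric(abundances)
  n <- sum(x)
  dd <- dist[sp, sp]
  num <- 0
  for (i in seq_along(sp)[-length(sp)]) {
    for (j in (i + 1):length(sp)) {
      num <- num + dd[i, j] * x[i] * x[j]
    }
  }
  num / (n * (n - 1) / 2)
}

#' Oak cynipid-gall covariate per plot
#'
#' Averages tree-level oak gall incidence (percent of oak leaves with at
#' least one cynipid gall, a proxy for shared-parasitoid abundance) over
#' all sampled oaks in each plot. Plots without oaks get 0.
#'
#' @param oak_leaf_samples Branch-level leaf samples from oak trees:
#'   columns `plot_id`, `tree_id`, `n_leaves`, `n_galled`. NULL or empty
#'   means no oaks anywhere.
#' @param plot_ids Plot ids the covariate is needed for.
#' @return data.frame `plot_id`, `oak_gall_pct`.
#' @export
oak_gall_covariate <- function(oak_leaf_samples, plot_ids) {
  out <- data.frame(plot_id = unique(plot_ids), oak_gall_pct = 0)
  if (is.null(oak_leaf_samples) || nrow(oak_leaf_samples) == 0) return(out)
  inc <- leaf_gall_incidence(oak_leaf_samples)
  inc$plot_id <- oak_leaf_samples$plot_id[
    match(inc$tree_id, oak_leaf_samples$tree_id)]
  by_plot <- aggregate(list(oak_gall_pct = inc$leaf_gall_pct),
                       by = list(plot_id = inc$plot_id), FUN = mean)
  got <- match(out$plot_id, by_plot$plot_id)
  out$oak_gall_pct[!is.na(got)] <- by_plot$oak_gall_pct[got[!is.na(got)]]
  out
}

# Diversity covariates for one community of trees (rows of the tree table).
.community_covariates <- function(trees, dist) {
  ba <- tapply(basal_area(trees$dbh), trees$species, sum)
  shares <- ba / sum(ba)
  cs <- if ("CS" %in% names(shares)) unname(shares["CS"]) else 0
  data.frame(
    richness = length(ba),
    shannon = shannon_index(as.numeric(shares)),
    prop_castanea = cs,
    tax_div = taxonomic_diversity(ba, dist = dist)
  )
}

#' Plot-level explanatory covariates
#'
#' Per plot: species richness, Shannon index on relative basal area, the
#' basal-area proportion of C. sativa, abundance-weighted taxonomic
#' diversity and the oak gall covariate.
#'
#' @param trees Tree table (all stems; clumps are collapsed first).
#' @param oak_leaf_samples Optional oak leaf samples, see
#'   [oak_gall_covariate()].
#' @param taxonomy Classification table, default [default_taxonomy()].
#' @return data.frame, one row per plot: `plot_id`, `richness`, `shannon`,
#'   `prop_castanea`, `tax_div`, `oak_gall_pct`.
#' @export
plot_covariates <- function(trees, oak_leaf_samples = NULL,
                            taxonomy = default_taxonomy()) {
  trees <- collapse_clumps(trees)
  dist <- taxonomic_distances(taxonomy)
  parts <- split(trees, trees$plot_id)
  cov <- do.call(rbind, lapply(parts, .community_covariates, dist = dist))
  cov <- cbind(plot_id = names(parts), cov)
  rownames(cov) <- NULL
  galls <- oak_gall_covariate(oak_leaf_samples, cov$plot_id)
  merge(cov, galls, by = "plot_id", sort = FALSE)
}

#' Neighborhood-level explanatory covariates
#'
#' The same diversity covariates as [plot_covariates()], computed over
#' each focal tree's neighbor set plus the focal tree itself (the focal
#' chestnut is part of the local host concentration). Margin-excluded or
#' neighbor-less focal trees get NA covariates.
#'
#' @param contexts Output of [neighborhood_contexts()].
#' @param trees Tree table used to build the contexts.
#' @param taxonomy Classification table.
#' @return data.frame, one row per focal tree: `focal_id`, `nb_richness`,
#'   `nb_shannon`, `nb_prop_castanea`, `nb_tax_div`, plus `n_neighbors`,
#'   `delta_h`, `margin_excluded` carried over.
#' @export
neighborhood_covariates <- function(contexts, trees,
                                    taxonomy = default_taxonomy()) {
  trees <- collapse_clumps(trees)
  dist <- taxonomic_distances(taxonomy)
  ctx <- contexts$contexts
  rows <- lapply(seq_len(nrow(ctx)), function(k) {
    ids <- contexts$neighbors[[as.character(ctx$focal_id[k])]]
    if (length(ids) == 0) {
      return(data.frame(richness = NA_real_, shannon = NA_real_,
                        prop_castanea = NA_real_, tax_div = NA_real_))
    }
    .community_covariates(
      trees[trees$tree_id %in% c(ctx$focal_id[k], ids), , drop = FALSE],
      dist = dist)
  })
  cov <- do.call(rbind, rows)
  names(cov) <- paste0("nb_", names(cov))
  cbind(ctx["focal_id"], cov,
        ctx[c("n_neighbors", "delta_h", "margin_excluded")])
}
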