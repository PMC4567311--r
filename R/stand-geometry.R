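#' Crown radius from projected crown area
#'
#' Crowns are modelled as circles of equivalent projected area, so the
#' radius is `sqrt(area / pi)`.
#'
#' @param crown_area Projected crown area in m^2.
#' @return Radius in metres.
#' @export
crown_radius <- function(crown_area) {
  stopifnot(all(crown_area > 0, na.rm = TRUE))
  sqrt(crown_area / pi)
}

#' Collapse coppice clumps into single trees
#'
#' Multiple stems regrowing from one stump are treated as one tree:
#' height is the tallest stem, crown area the sum of stem crown areas,
#' basal area the sum of stem basal areas (dbh back-computed from it),
#' and position the basal-area-weighted centroid of the stems. Stems
#' without a `clump_id` (NA) are left as they are.
#'
#' @param trees Tree table with columns `tree_id`, `plot_id`, `species`,
#'   `x`, `y`, `dbh` (cm), `height` (m), `crown_area` (m^2) and
#'   optionally `clump_id`.
#' @return Tree table with one row per clump or single stem. Collapsed
#'   rows take `tree_id` from the clump's largest-dbh stem.
#' @export
collapse_clumps <- function(trees) {
  req <- c("tree_id", "plot_id", "species", "x", "y", "dbh", "height",
           "crown_area")
  stopifnot(is.data.frame(trees), all(req %in% names(trees)))
  if (is.null(trees$clump_id) || all(is.na(trees$clump_id))) return(trees)

  single <- trees[is.na(trees$clump_id), , drop = FALSE]
  clumped <- trees[!is.na(trees$clump_id), , drop = FALSE]
  parts <- split(clumped, clumped$clump_id)
  rows <- lapply(parts, function(cl) {
    if (length(unique(cl$plot_id)) > 1) {
      stop("clump ", cl$clump_id[1], " spans multiple plots")
    }
    ba <- basal_area(cl$dbh)
    lead <- which.max(cl$dbh)
    out <- cl[lead, , drop = FALSE]
    out$x <- sum(cl$x * ba) / sum(ba)
    out$y <- sum(cl$y * ba) / sum(ba)
    out$height <- max(cl$height)
    out$crown_area <- sum(cl$crown_area)
    out$dbh <- 200 * sqrt(sum(ba) / pi)  # dbh of the summed basal area, cm
    out
  })
  out <- rbind(single, do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(match(out$plot_id, unique(trees$plot_id)), out$tree_id), ,
      drop = FALSE]
}

#' Identify crown neighbors of a focal tree
#'
#' Two trees are neighbors when the edge-to-edge distance between their
#' crown circles is at most `gap` metres:
#' `dist(centres) - r_focal - r_neighbor <= gap`. The relation is
#' symmetric and a tree is never its own neighbor. Only trees in the same
#' plot are considered.
#'
#' @param focal_id Tree id of the focal tree.
#' @param trees Tree table (after [collapse_clumps()]).
#' @param gap Maximum crown-to-crown distance in metres (default 3).
#' @return Character (or same type as `tree_id`) vector of neighbor ids,
#'   possibly empty.
#' @export
find_neighbors <- function(focal_id, trees, gap = 3) {
  i <- match(focal_id, trees$tree_id)
  if (is.na(i)) stop("focal tree ", focal_id, " not in tree table")
  same_plot <- trees$plot_id == trees$plot_id[i] & trees$tree_id != focal_id
  cand <- trees[same_plot, , drop = FALSE]
  if (nrow(cand) == 0) return(trees$tree_id[0])
  d <- sqrt((cand$x - trees$x[i])^2 + (cand$y - trees$y[i])^2)
  edge <- d - crown_radius(trees$crown_area[i]) - crown_radius(cand$crown_area)
  cand$tree_id[edge <= gap]
}

#' Plot-margin exclusion rule
#'
#' A focal tree is excluded from neighborhood analyses when part of its
#' potential neighborhood lies outside the mapped plot, i.e. when its
#' crown circle plus the neighbor search gap extends beyond the plot
#' boundary; nothing is known about neighbors growing outside the plot.
#'
#' @param x,y Stem coordinates in metres within the plot.
#' @param crown_area Crown area in m^2.
#' @param plot_size Plot side length in metres (default 30); plots are
#'   squares with origin (0, 0).
#' @param gap Neighbor search gap in metres (default 3).
#' @return Logical vector: TRUE = excluded.
#' @export
margin_excluded <- function(x, y, crown_area, plot_size = 30, gap = 3) {
  r <- crown_radius(crown_area)
  reach <- r + gap
  x - reach < 0 | y - reach < 0 | x + reach > plot_size | y + reach > plot_size
}

#' Tree apparency index
#'
#' Mean height difference between a focal tree and its neighbors:
#' `delta_H = mean(H_focal - H_neighbor_i)`. Positive values mean the
#' focal tree stands taller than its neighbors on average (more apparent
#' to searching herbivores); negative values mean it is hidden below
#' them. Undefined without neighbors.
#'
#' @param focal_height Focal tree height, metres.
#' @param neighbor_heights Numeric vector of neighbor heights, metres.
#' @return delta_H in metres, or NA (with a warning) when there are no
#'   neighbors.
#' @export
apparency <- function(focal_height, neighbor_heights) {
  stopifnot(length(focal_height) == 1, is.finite(focal_height))
  if (length(neighbor_heights) == 0) {
    warning("no neighbors: apparency undefined")
    return(NA_real_)
  }
  focal_height - mean(neighbor_heights)
}

#' Build the neighborhood table for a set of focal trees
#'
#' For each focal tree: the neighbor set under the crown-gap rule, the
#' neighbor count, the apparency index and the margin-exclusion flag.
#' Coppice clumps are collapsed first. Margin-excluded trees keep their
#' computed values but are flagged so downstream analyses can drop them.
#'
#' @param trees Full tree table (all stems, all species).
#' @param focal_ids Ids of the focal trees (must be in `trees`; clump
#'   collapsing may replace a stem id by its clump leader's id).
#' @param gap Crown gap in metres (default 3).
#' @param plot_size Plot side length in metres (default 30).
#' @param heterospecific_only If TRUE, apparency is computed over
#'   heterospecific neighbors only (default FALSE: all neighbors).
#' @return List with `contexts` (data.frame: `focal_id`, `plot_id`,
#'   `n_neighbors`, `delta_h`, `margin_excluded`) and `neighbors` (named
#'   list of neighbor id vectors).
#' @export
neighborhood_contexts <- function(trees, focal_ids, gap = 3, plot_size = 30,
                                  heterospecific_only = FALSE) {
  trees <- collapse_clumps(trees)
  missing <- setdiff(focal_ids, trees$tree_id)
  if (length(missing) > 0) {
    stop("focal tree(s) not in collapsed tree table: ",
         paste(missing, collapse = ", "))
  }
  nb <- lapply(focal_ids, find_neighbors, trees = trees, gap = gap)
  names(nb) <- as.character(focal_ids)
  idx <- match(focal_ids, trees$tree_id)
  delta_h <- vapply(seq_along(focal_ids), function(k) {
    ids <- nb[[k]]
    if (heterospecific_only) {
      sp <- trees$species[match(ids, trees$tree_id)]
      ids <- ids[sp != trees$species[idx[k]]]
    }
    if (length(ids) == 0) return(NA_real_)
    trees$height[idx[k]] - mean(trees$height[match(ids, trees$tree_id)])
  }, numeric(1))
  contexts <- data.frame(
    focal_id = focal_ids,
    plot_id = trees$plot_id[idx],
    n_neighbors = lengths(nb),
    delta_h = delta_h,
    margin_excluded = margin_excluded(trees$x[idx], trees$y[idx],
                                      trees$crown_area[idx],
                                      plot_size = plot_size, gap = gap)
  )
  list(contexts = contexts, neighbors = nb)
}
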