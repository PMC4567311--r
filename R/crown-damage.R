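#' Crown-condition percentage class scheme
#'
#' Field crown assessments score each crown-condition variable into seven
#' percentage classes rather than continuous percentages. This returns the
#' class table used to convert codes back to quantitative values: each class
#' is replaced by its midpoint. Class 0 means "absent" (0%); the top class
#' is open-ended (">75%") and is assumed to span to `upper_top`.
#'
#' @param upper_top Upper bound (in percent) assumed for the open-ended top
#'   class. Default 100.
#' @return A data.frame with columns `class_id` (integer 0-6), `lower`,
#'   `upper` and `midpoint`, all in percent.
#' @examples
#' damage_class_scheme()
#' @export
damage_class_scheme <- function(upper_top = 100) {
  stopifnot(is.numeric(upper_top), upper_top > 75.5)
  lower <- c(0, 0.5, 1.5, 12.5, 25.5, 50.5, 75.5)
  upper <- c(0, 1, 12, 25, 50, 75, upper_top)
  data.frame(
    class_id = 0:6,
    lower = lower,
    upper = upper,
    midpoint = (lower + upper) / 2
  )
}

#' Convert class codes to proportion midpoints
#'
#' @param code Integer vector of class codes (0-6). NA passes through.
#' @param scheme Class table from [damage_class_scheme()].
#' @return Numeric vector of proportions in \[0, 1\] (midpoint / 100).
#' @keywords internal
class_midpoint <- function(code, scheme = damage_class_scheme()) {
  bad <- !is.na(code) & (!code %in% scheme$class_id | code != round(code))
  if (any(bad)) {
    stop("unknown class code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  scheme$midpoint[match(code, scheme$class_id)] / 100
}

.assessment_vars <- c("pcl", "pdbl", "pdbs", "pdl", "pds")

#' Resolve class-coded crown assessments to per-tree proportions
#'
#' Takes one row per tree and viewing side and returns one row per tree with
#' the five crown variables as proportions. Class-coded columns
#' (`pcl_class`, `pdbl_class`, `pdbs_class`, `pdl_class`, `pds_class`) are
#' replaced by class midpoints; alternatively raw-proportion columns
#' (`pcl_prop`, ...) may be supplied. Where sides disagree, the mean of the
#' per-side midpoints is used, variable by variable, before any damage
#' index is computed.
#'
#' @param assessments data.frame with column `tree_id`, optionally `side`,
#'   and either the five `*_class` columns (integer codes 0-6) or the five
#'   `*_prop` columns (proportions in \[0, 1\]).
#' @param scheme Class table from [damage_class_scheme()].
#' @return data.frame with one row per tree: `tree_id`, `pcl`, `pdbl`,
#'   `pdbs`, `pdl`, `pds` (proportions in \[0, 1\]), and `n_sides`.
#' @export
resolve_assessments <- function(assessments, scheme = damage_class_scheme()) {
  stopifnot(is.data.frame(assessments), "tree_id" %in% names(assessments))
  class_cols <- paste0(.assessment_vars, "_class")
  prop_cols <- paste0(.assessment_vars, "_prop")
  has_class <- all(class_cols %in% names(assessments))
  has_prop <- all(prop_cols %in% names(assessments))
  if (!has_class && !has_prop) {
    stop("assessments must contain all *_class or all *_prop columns")
  }

  vals <- matrix(NA_real_, nrow(assessments), length(.assessment_vars),
                 dimnames = list(NULL, .assessment_vars))
  for (i in seq_along(.assessment_vars)) {
    v <- .assessment_vars[i]
    if (has_class) {
      col <- assessments[[paste0(v, "_class")]]
      p <- tryCatch(class_midpoint(col, scheme), error = function(e) {
        bad <- which(!is.na(col) &
                       (!col %in% scheme$class_id | col != round(col)))[1]
        stop("tree ", assessments$tree_id[bad], ", variable ", v,
             ": unknown class code ", col[bad], call. = FALSE)
      })
    } else {
      p <- assessments[[paste0(v, "_prop")]]
      out_of_range <- !is.na(p) & (p < 0 | p > 1)
      if (any(out_of_range)) {
        bad <- which(out_of_range)[1]
        stop("tree ", assessments$tree_id[bad], ", variable ", v,
             ": proportion out of [0, 1]", call. = FALSE)
      }
    }
    vals[, i] <- p
  }

  ids <- assessments$tree_id
  out <- aggregate(vals, by = list(tree_id = ids), FUN = mean, na.rm = TRUE)
  n_sides <- as.vector(table(ids)[match(out$tree_id, names(table(ids)))])
  out$n_sides <- n_sides
  # keep first-appearance tree order
  out[match(unique(ids), out$tree_id), , drop = FALSE]
}

.check_prop <- function(..., what = "input") {
  args <- list(...)
  for (a in args) {
    if (any(!is.na(a) & (a < 0 | a > 1))) {
      stop(what, " out of [0, 1]", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Total dead branches in the sunlit crown
#'
#' `T_DBL = P_CL * P_DBL`: the proportion of the whole crown made of dead
#' branches in the part exposed to sunlight.
#'
#' @param pcl Proportion of the crown exposed to sunlight, in \[0, 1\].
#' @param pdbl Proportion of dead branches within the sunlit part.
#' @return Numeric vector in \[0, 1\].
#' @export
total_dead_branches_light <- function(pcl, pdbl) {
  .check_prop(pcl, pdbl)
  pcl * pdbl
}

#' Proportion of the living crown exposed to sunlight
#'
#' `P_ACL = P_CL (1 - P_DBL) / [P_CL (1 - P_DBL) + (1 - P_CL)(1 - P_DBS)]`.
#' When the whole crown is dead (denominator 0) the quantity is undefined:
#' NA is returned with a warning and the tree should be excluded.
#'
#' @param pcl Proportion of crown exposed to sunlight.
#' @param pdbl Dead-branch proportion, sunlit part.
#' @param pdbs Dead-branch proportion, shaded part.
#' @return Numeric vector in \[0, 1\]; NA where the crown is fully dead.
#' @export
living_crown_light_fraction <- function(pcl, pdbl, pdbs) {
  .check_prop(pcl, pdbl, pdbs)
  num <- pcl * (1 - pdbl)
  den <- num + (1 - pcl) * (1 - pdbs)
  dead <- !is.na(den) & den <= 0
  if (any(dead)) {
    warning(sum(dead), " crown(s) fully dead: living-crown fraction undefined")
    den[dead] <- NA_real_
  }
  num / den
}

#' Total defoliation of the living crown
#'
#' `T_D = P_ACL * P_DL + (1 - P_ACL) * P_DS`: defoliation averaged over the
#' sunlit and shaded living crown, weighted by the living-crown light
#' fraction. Always lies between `P_DL` and `P_DS`.
#'
#' @param pacl Living-crown light fraction from
#'   [living_crown_light_fraction()].
#' @param pdl Defoliation of the living crown, sunlit part.
#' @param pds Defoliation of the living crown, shaded part.
#' @return Numeric vector in \[0, 1\].
#' @export
total_defoliation <- function(pacl, pdl, pds) {
  .check_prop(pacl, pdl, pds)
  pacl * pdl + (1 - pacl) * pds
}

#' Total damaged crown
#'
#' `T_DC = P_DL * P_CL (1 - P_DBL) + P_DS (1 - P_CL)(1 - P_DBS) + T_DBL`:
#' defoliation of both living-crown parts plus dead branches in the sunlit
#' part, all as proportions of the whole crown. Satisfies the identity
#' `T_DC = T_D * L + T_DBL` with
#' `L = P_CL (1 - P_DBL) + (1 - P_CL)(1 - P_DBS)` the living fraction of
#' the crown. Dead branches in the shaded part are deliberately not added:
#' shade mortality may reflect light competition or natural pruning rather
#' than gall damage.
#'
#' @inheritParams living_crown_light_fraction
#' @inheritParams total_defoliation
#' @return Numeric vector in \[0, 1\].
#' @export
total_damaged_crown <- function(pcl, pdbl, pdbs, pdl, pds) {
  .check_prop(pcl, pdbl, pdbs, pdl, pds)
  pdl * pcl * (1 - pdbl) + pds * (1 - pcl) * (1 - pdbs) +
    total_dead_branches_light(pcl, pdbl)
}

#' Leaf gall incidence per tree
#'
#' Aggregates branch-level leaf samples (protocol: 2 branches of 30 leaves
#' per tree) to the percentage of leaves carrying at least one gall, per
#' branch first, then averaged to the tree. Branches with zero leaves are
#' dropped with a warning.
#'
#' @param leaf_samples data.frame with columns `tree_id`, `n_leaves`,
#'   `n_galled` (one row per branch).
#' @return data.frame `tree_id`, `leaf_gall_pct` (percent, 0-100),
#'   `n_branches`.
#' @export
leaf_gall_incidence <- function(leaf_samples) {
  stopifnot(is.data.frame(leaf_samples),
            all(c("tree_id", "n_leaves", "n_galled") %in% names(leaf_samples)))
  with(leaf_samples, {
    if (any(n_galled > n_leaves)) {
      stop("n_galled exceeds n_leaves")
    }
  })
  empty <- leaf_samples$n_leaves == 0
  if (any(empty)) {
    warning(sum(empty), " branch(es) with zero leaves dropped")
    leaf_samples <- leaf_samples[!empty, , drop = FALSE]
  }
  if (nrow(leaf_samples) == 0) stop("no branches with leaves")
  pct <- 100 * leaf_samples$n_galled / leaf_samples$n_leaves
  out <- aggregate(list(leaf_gall_pct = pct),
                   by = list(tree_id = leaf_samples$tree_id), FUN = mean)
  nb <- aggregate(list(n_branches = pct),
                  by = list(tree_id = leaf_samples$tree_id), FUN = length)
  merge(out, nb, by = "tree_id", sort = FALSE)
}

#' Per-tree damage summary
#'
#' Computes the four crown-damage indices from resolved assessments and,
#' when leaf samples are given, merges leaf gall incidence. Trees whose
#' crown is fully dead (undefined living-crown fraction) are flagged via
#' `excluded` rather than silently zeroed.
#'
#' @param resolved Output of [resolve_assessments()] (or any data.frame
#'   with `tree_id` and proportion columns `pcl`, `pdbl`, `pdbs`, `pdl`,
#'   `pds`).
#' @param leaf_samples Optional branch-level leaf samples, see
#'   [leaf_gall_incidence()].
#' @return data.frame with one row per tree: `tree_id`, `tdbl`, `pacl`,
#'   `td`, `tdc` (proportions in \[0, 1\]), `leaf_gall_pct` (percent, NA
#'   where no leaves were sampled), `excluded`.
#' @export
damage_summary <- function(resolved, leaf_samples = NULL) {
  stopifnot(all(c("tree_id", .assessment_vars) %in% names(resolved)))
  pacl <- living_crown_light_fraction(resolved$pcl, resolved$pdbl,
                                      resolved$pdbs)
  out <- data.frame(
    tree_id = resolved$tree_id,
    tdbl = total_dead_branches_light(resolved$pcl, resolved$pdbl),
    pacl = pacl,
    td = total_defoliation(pacl, resolved$pdl, resolved$pds),
    tdc = total_damaged_crown(resolved$pcl, resolved$pdbl, resolved$pdbs,
                              resolved$pdl, resolved$pds),
    excluded = is.na(pacl)
  )
  out$leaf_gall_pct <- NA_real_
  if (!is.null(leaf_samples)) {
    inc <- leaf_gall_incidence(leaf_samples)
    out$leaf_gall_pct <- inc$leaf_gall_pct[match(out$tree_id, inc$tree_id)]
  }
  out
}
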