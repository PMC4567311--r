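# Shared fixtures built in code.

# A tiny two-plot tree table with known geometry.
make_tree_table <- function() {
  data.frame(
    tree_id = c("A1", "A2", "A3", "A4", "B1", "B2"),
    plot_id = c("A", "A", "A", "A", "B", "B"),
    species = c("CS", "QC", "CS", "OC", "CS", "QI"),
    x = c(15, 18, 25, 15, 15, 16),
    y = c(15, 15, 15, 20, 15, 15),
    dbh = c(20, 25, 15, 18, 30, 22),
    height = c(15, 18, 12, 10, 16, 14),
    crown_area = c(12, 12, 8, 10, 15, 9),
    clump_id = NA_character_
  )
}

# Class-coded assessments for two trees, two sides each.
make_assessments <- function() {
  data.frame(
    tree_id = rep(c("A1", "A3"), each = 2),
    side = rep(1:2, 2),
    pcl_class = c(4, 3, 2, 2),
    pdbl_class = c(1, 1, 0, 0),
    pdbs_class = c(2, 2, 1, 1),
    pdl_class = c(3, 4, 2, 2),
    pds_class = c(2, 2, 1, 1)
  )
}

# Random valid crown-variable draws for property sweeps.
random_crown_inputs <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(pcl = runif(n), pdbl = runif(n), pdbs = runif(n),
             pdl = runif(n), pds = runif(n))
}

# Small config for fast end-to-end runs: same design, fewer stems.
fast_config <- function(...) {
  synthetic_config(trees_per_plot = 25, ...)
}
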