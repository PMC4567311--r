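# Crown damage indices from class-coded assessments.

test_that("class scheme has seven classes with increasing midpoints", {
  sch <- damage_class_scheme()
  expect_equal(nrow(sch), 7)
  expect_equal(sch$class_id, 0:6)
  expect_equal(sch$midpoint,
               c(0, 0.75, 6.75, 18.75, 37.75, 62.75, 87.75))
  expect_true(all(diff(sch$midpoint) > 0))
  expect_equal(sch$midpoint[1], 0)
})

test_that("class codes resolve to midpoints, averaged across sides", {
  # both sides class 0 everywhere -> all proportions zero
  zero <- data.frame(tree_id = "t", side = 1:2, pcl_class = 0,
                     pdbl_class = 0, pdbs_class = 0, pdl_class = 0,
                     pds_class = 0)
  rz <- resolve_assessments(zero)
  expect_equal(unlist(rz[, c("pcl", "pdbl", "pdbs", "pdl", "pds")]),
               c(pcl = 0, pdbl = 0, pdbs = 0, pdl = 0, pds = 0))

  # side A in 25.5-50 (37.75%), side B in 12.5-25 (18.75%) -> 28.25%
  two <- data.frame(tree_id = "t", side = 1:2, pcl_class = c(4, 3),
                    pdbl_class = 0, pdbs_class = 0, pdl_class = 0,
                    pds_class = 0)
  expect_equal(resolve_assessments(two)$pcl, 0.2825)

  # single side, 50.5-75 -> 62.75%
  one <- data.frame(tree_id = "t", side = 1, pcl_class = 5,
                    pdbl_class = 0, pdbs_class = 0, pdl_class = 0,
                    pds_class = 0)
  r1 <- resolve_assessments(one)
  expect_equal(r1$pcl, 0.6275)
  expect_equal(r1$n_sides, 1L)
})

test_that("unknown class codes are rejected naming tree and variable", {
  bad <- data.frame(tree_id = "T9", side = 1, pcl_class = 7,
                    pdbl_class = 0, pdbs_class = 0, pdl_class = 0,
                    pds_class = 0)
  expect_error(resolve_assessments(bad), "T9.*pcl.*7")
})

test_that("raw-proportion input is accepted and range-checked", {
  ok <- data.frame(tree_id = "t", side = 1, pcl_prop = 0.5,
                   pdbl_prop = 0.2, pdbs_prop = 0.4, pdl_prop = 0.3,
                   pds_prop = 0.1)
  expect_equal(resolve_assessments(ok)$pdbs, 0.4)
  ok$pdl_prop <- 1.2
  expect_error(resolve_assessments(ok), "pdl")
})

test_that("damage equations match hand evaluation", {
  expect_equal(total_dead_branches_light(0, 0.7), 0)
  expect_equal(total_dead_branches_light(1, 1), 1)
  expect_equal(total_dead_branches_light(0.5, 0.2), 0.1)

  expect_equal(living_crown_light_fraction(1, 0, 0.5), 1)
  expect_equal(living_crown_light_fraction(0.5, 0.2, 0.4), 0.4 / 0.7)
  # equal dead-branch shares on both sides: fraction equals pcl
  expect_equal(living_crown_light_fraction(0.3, 0.2, 0.2), 0.3)

  expect_equal(total_defoliation(1, 0.3, 0.9), 0.3)
  expect_equal(total_defoliation(0.4 / 0.7, 0.3, 0.1),
               (0.4 / 0.7) * 0.3 + (0.3 / 0.7) * 0.1)
  expect_equal(total_defoliation(0.37, 0.25, 0.25), 0.25)

  expect_equal(total_damaged_crown(0, 0, 0, 0, 0), 0)
  expect_equal(total_damaged_crown(1, 1, 0, 1, 0), 1)
  expect_equal(total_damaged_crown(0.5, 0.2, 0.4, 0.3, 0.1),
               0.3 * 0.4 + 0.1 * 0.3 + 0.1)
  expect_error(total_damaged_crown(1.2, 0, 0, 0, 0), "out of")
})

test_that("fully dead crown is flagged, not zeroed", {
  expect_warning(p <- living_crown_light_fraction(1, 1, 0), "fully dead")
  expect_true(is.na(p))
  resolved <- data.frame(tree_id = "t", pcl = 1, pdbl = 1, pdbs = 0,
                         pdl = 0, pds = 0)
  expect_warning(dmg <- damage_summary(resolved), "fully dead")
  expect_true(dmg$excluded)
})

test_that("damaged-crown identity and bounds hold over random inputs", {
  z <- random_crown_inputs(10000)
  pacl <- living_crown_light_fraction(z$pcl, z$pdbl, z$pdbs)
  td <- total_defoliation(pacl, z$pdl, z$pds)
  tdc <- total_damaged_crown(z$pcl, z$pdbl, z$pdbs, z$pdl, z$pds)
  tdbl <- total_dead_branches_light(z$pcl, z$pdbl)
  L <- z$pcl * (1 - z$pdbl) + (1 - z$pcl) * (1 - z$pdbs)
  expect_lt(max(abs(tdc - (td * L + tdbl))), 1e-12)
  expect_true(all(td >= 0 & td <= 1))
  expect_true(all(tdc >= 0 & tdc <= 1))
  # defoliation is a convex combination of its sunlit and shaded parts
  expect_true(all(td >= pmin(z$pdl, z$pds) - 1e-12 &
                    td <= pmax(z$pdl, z$pds) + 1e-12))
})

test_that("total defoliation is monotone in each defoliation input", {
  z <- random_crown_inputs(200, seed = 7)
  pacl <- living_crown_light_fraction(z$pcl, z$pdbl, z$pdbs)
  eps <- 0.01
  up_dl <- total_defoliation(pacl, pmin(z$pdl + eps, 1), z$pds)
  up_ds <- total_defoliation(pacl, z$pdl, pmin(z$pds + eps, 1))
  base <- total_defoliation(pacl, z$pdl, z$pds)
  expect_true(all(up_dl >= base - 1e-12))
  expect_true(all(up_ds >= base - 1e-12))
})

test_that("class-resolved pipeline equals brute-force hand evaluation", {
  dmg <- damage_summary(resolve_assessments(make_assessments()))
  # tree A1: pcl mean(37.75, 18.75), pdbl 0.75, pdbs 6.75,
  # pdl mean(18.75, 37.75), pds 6.75 (all %)
  pcl <- 0.2825; pdbl <- 0.0075; pdbs <- 0.0675
  pdl <- 0.2825; pds <- 0.0675
  num <- pcl * (1 - pdbl)
  pacl <- num / (num + (1 - pcl) * (1 - pdbs))
  a1 <- dmg[dmg$tree_id == "A1", ]
  expect_equal(a1$tdbl, pcl * pdbl)
  expect_equal(a1$pacl, pacl)
  expect_equal(a1$td, pacl * pdl + (1 - pacl) * pds)
  expect_equal(a1$tdc,
               pdl * pcl * (1 - pdbl) + pds * (1 - pcl) * (1 - pdbs) +
                 pcl * pdbl)
})

test_that("leaf gall incidence averages branch percentages per tree", {
  lv <- data.frame(tree_id = rep(c("a", "b", "c"), each = 2),
                   n_leaves = 30,
                   n_galled = c(0, 0, 30, 30, 12, 18))
  inc <- leaf_gall_incidence(lv)
  expect_equal(inc$leaf_gall_pct[match(c("a", "b", "c"), inc$tree_id)],
               c(0, 100, 50))
  # zero-leaf branches are dropped with a warning
  lv2 <- rbind(lv, data.frame(tree_id = "a", n_leaves = 0, n_galled = 0))
  expect_warning(inc2 <- leaf_gall_incidence(lv2), "zero leaves")
  expect_equal(inc2$leaf_gall_pct[inc2$tree_id == "a"], 0)
  lv$n_galled[1] <- 31
  expect_error(leaf_gall_incidence(lv), "exceeds")
})
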