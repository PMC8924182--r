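# Dataset adoption rule and three-criteria strain grouping.

mkSim <- function(...) {
  # convenience constructor for a similarity table
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sag_a = r[[1]], sag_b = r[[2]], ani = as.numeric(r[[3]]),
      ani_defined = as.logical(r[[4]]),
      aligned_fraction = 1,
      tetra_corr = as.numeric(r[[5]]),
      marker_homology = as.numeric(r[[6]]), stringsAsFactors = FALSE)))
}

test_that("adoption applies strict boundaries on coverage and max ANI", {
  sags <- c("s1", "s2")
  sp <- c(s1 = "spX", s2 = "spX")
  # max same-species ANI exactly 98.5 -> not adopted (strict >)
  sim <- mkSim(list("s1", "s2", 98.5, TRUE, 0.95, 99.95))
  ad <- adoptDataset(sags, sim, sp)
  expect_false(any(ad$adopted))
  expect_equal(ad$reason, c("max_ani", "max_ani"))
  # just above the boundary -> adopted
  sim2 <- mkSim(list("s1", "s2", 98.51, TRUE, 0.95, 99.95))
  expect_true(all(adoptDataset(sags, sim2, sp)$adopted))
})

test_that("adoption requires ANI to be defined for >75% of peers", {
  sags <- sprintf("s%02d", 1:10)
  sp <- setNames(rep("spX", 10), sags)
  pairs <- t(combn(sags, 2))
  sim <- data.frame(sag_a = pairs[, 1], sag_b = pairs[, 2], ani = 99.2,
    ani_defined = TRUE, aligned_fraction = 1, tetra_corr = 0.99,
    marker_homology = 99.95, stringsAsFactors = FALSE)
  # s01: undefined against exactly 2 of 9 peers -> coverage 7/9 = 0.778 > 0.75
  sim$ani_defined[sim$sag_a == "s01" & sim$sag_b %in% c("s02", "s03")] <- FALSE
  ad <- adoptDataset(sags, sim, sp)
  expect_true(ad$adopted[ad$sag_id == "s01"])
  expect_equal(ad$ani_coverage[ad$sag_id == "s01"], 7 / 9)
  # undefined against 3 of 9 -> 0.667 <= 0.75 -> not adopted
  sim$ani_defined[sim$sag_a == "s01" & sim$sag_b == "s04"] <- FALSE
  ad2 <- adoptDataset(sags, sim, sp)
  expect_false(ad2$adopted[ad2$sag_id == "s01"])
  expect_equal(ad2$reason[ad2$sag_id == "s01"], "ani_coverage")
})

test_that("a species with a single SAG is never adopted", {
  sp <- c(s1 = "spX", s2 = "spY", s3 = "spY")
  sim <- mkSim(list("s2", "s3", 99.5, TRUE, 0.99, 99.95))
  ad <- adoptDataset(names(sp), sim, sp)
  expect_false(ad$adopted[ad$sag_id == "s1"])
  expect_equal(ad$reason[ad$sag_id == "s1"], "single_sag_species")
  expect_true(all(ad$adopted[ad$sag_id != "s1"]))
})

test_that("groups are connected components of the joint-criteria graph", {
  # chain s1-s2-s3 plus isolated s4
  sim <- mkSim(
    list("s1", "s2", 99.5, TRUE, 0.95, 99.95),
    list("s2", "s3", 99.5, TRUE, 0.95, 99.95),
    list("s1", "s3", 97.0, TRUE, 0.95, 99.95),  # fails ANI gate
    list("s1", "s4", 99.5, TRUE, 0.95, 99.5),   # fails homology gate
    list("s2", "s4", 99.5, TRUE, 0.80, 99.95),  # fails tetra gate
    list("s3", "s4", 99.5, FALSE, 0.95, 99.95)) # undefined ANI: no edge
  gr <- buildStrainGroups(c("s1", "s2", "s3", "s4"), sim)
  expect_equal(sort(unique(gr$group_id)), c("G_s1", "G_s4"))
  expect_equal(sort(gr$sag_id[gr$group_id == "G_s1"]), c("s1", "s2", "s3"))
  expect_equal(gr$sag_id[gr$group_id == "G_s4"], "s4")
})

test_that("no passing pair yields all-singleton groups; output partitions", {
  sim <- mkSim(list("s1", "s2", 97, TRUE, 0.95, 99.95),
               list("s1", "s3", 97, TRUE, 0.95, 99.95),
               list("s2", "s3", 97, TRUE, 0.95, 99.95))
  gr <- buildStrainGroups(c("s1", "s2", "s3"), sim)
  expect_equal(nrow(gr), 3L)
  expect_equal(length(unique(gr$group_id)), 3L)
  # partition: every adopted SAG appears exactly once
  expect_identical(sortC(gr$sag_id), c("s1", "s2", "s3"))
})

test_that("raising any threshold never merges groups", {
  mk <- fxMarkers()
  da <- fxDropout()
  sim <- pairwiseSimilarity(da$contigs, mk)
  ids <- names(da$contigs)
  base <- buildStrainGroups(ids, sim, groupingThresholds())
  for (t2 in list(groupingThresholds(minAni = 99),
                  groupingThresholds(minMarkerHomology = 99.95),
                  groupingThresholds(minTetraCorr = 0.95))) {
    finer <- buildStrainGroups(ids, sim, t2)
    # refinement: members of one finer group always share a base group
    baseOf <- setNames(base$group_id, base$sag_id)
    for (g in unique(finer$group_id)) {
      mem <- finer$sag_id[finer$group_id == g]
      expect_length(unique(baseOf[mem]), 1L)
    }
  }
})

test_that("group structure is invariant under SAG relabeling", {
  mk <- fxMarkers()
  da <- fxDropout()
  sim <- pairwiseSimilarity(da$contigs, mk)
  ids <- names(da$contigs)
  gr1 <- buildStrainGroups(ids, sim)
  # relabel with reversed names
  map <- setNames(sprintf("z%02d", rev(seq_along(ids))), ids)
  sim2 <- sim
  sim2$sag_a <- unname(map[sim$sag_a])
  sim2$sag_b <- unname(map[sim$sag_b])
  gr2 <- buildStrainGroups(unname(map[ids]), sim2)
  # same partition after mapping back
  part1 <- split(gr1$sag_id, gr1$group_id)
  part2 <- split(names(map)[match(gr2$sag_id, map)], gr2$group_id)
  norm <- function(p) sortC(vapply(p, function(m)
    paste(sortC(m), collapse = "|"), character(1)))
  expect_identical(unname(norm(part1)), unname(norm(part2)))
})

test_that("simulated 2x2x4 panel is recovered exactly", {
  mk <- fxMarkers()
  da <- fxDropout()
  sim <- pairwiseSimilarity(da$contigs, mk)
  sp <- setNames(da$truth$species_id, da$truth$sag_id)
  ad <- adoptDataset(names(da$contigs), sim, sp)
  gr <- buildStrainGroups(ad$sag_id[ad$adopted], sim)
  lab <- setNames(da$truth$strain_id, da$truth$sag_id)
  expect_equal(ariOf(gr$group_id, lab[gr$sag_id]), 1)
  expect_equal(length(unique(gr$group_id)), 4L)
})

test_that("average-linkage ANI mode recovers species, not strains", {
  # ANI alone cannot separate strains at 98.5% pairwise identity (that is
  # what the marker-homology gate is for); single-criterion average
  # linkage cut at 98 therefore merges same-species strains while still
  # separating species cleanly
  mk <- fxMarkers()
  da <- fxDropout()
  sim <- pairwiseSimilarity(da$contigs, mk)
  gr <- buildStrainGroups(names(da$contigs), sim, linkage = "average_ani")
  sp <- setNames(da$truth$species_id, da$truth$sag_id)
  expect_equal(ariOf(gr$group_id, sp[gr$sag_id]), 1)
  expect_equal(length(unique(gr$group_id)), 2L)
})
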