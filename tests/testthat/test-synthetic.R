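# Synthetic community generator: reference panels, Poisson capsule
# loading, PMA suppression, MDA read artifacts, determinism.

test_that("reference panel bookkeeping and determinism", {
  mk <- fxMarkers()
  p1 <- generateReferenceSet(nSpecies = 2, strainsPerSpecies = 2,
    genomeLength = 60000, markers = mk, seed = 11)
  p2 <- generateReferenceSet(nSpecies = 2, strainsPerSpecies = 2,
    genomeLength = 60000, markers = mk, seed = 11)
  expect_identical(as.character(genomes(p1)), as.character(genomes(p2)))
  expect_length(genomes(p1), 4L)
  expect_equal(anyDuplicated(strainInfo(p1)$strain_id), 0L)
  expect_length(unique(strainInfo(p1)$species_id), 2L)
  # every marker planted once per genome, within bounds
  loci <- markerLoci(p1)
  expect_equal(nrow(loci), 4L * length(mk))
  expect_true(all(loci$start >= 0 & loci$end <= 60000))
})

test_that("zero between-strain divergence yields identical strains", {
  p <- generateReferenceSet(nSpecies = 1, strainsPerSpecies = 2,
    genomeLength = 60000, withinStrainDiv = 0, betweenStrainDiv = 0,
    markers = fxMarkers(), seed = 3)
  g <- as.character(genomes(p))
  expect_identical(g[[1]], g[[2]])
})

test_that("realized between-strain mismatch matches the planted rate", {
  p <- generateReferenceSet(nSpecies = 1, strainsPerSpecies = 2,
    genomeLength = 1e5, betweenStrainDiv = 0.015, markers = fxMarkers(),
    seed = 1)
  g <- as.character(genomes(p))
  mm <- mismatchFraction(g[[1]], g[[2]])
  expect_lt(abs(mm - 0.015), 0.002)
})

test_that("mutateSequence substitution map is exact", {
  g <- randomGenome(20000, 0.45, seed = 9)
  m <- mutateSequence(g, 0.01, seed = 10)
  expect_equal(mismatchFraction(g, m$seq), length(m$sites) / 20000)
  # every recorded site actually differs
  raws <- charToRaw(g); rawm <- charToRaw(m$seq)
  expect_true(all(raws[m$sites + 1L] != rawm[m$sites + 1L]))
})

test_that("Poisson capsule occupancy matches closed form", {
  p <- fxPanel()
  si <- strainInfo(p)
  members <- data.frame(strain_id = si$strain_id,
    relative_abundance = rep(0.25, 4), viable_fraction = 1)
  spec <- communitySpec(members, pmaDose = 0, lambda = 0.35,
    nCapsules = 10000, freeDnaRate = 0, seed = 42)
  cap <- simulateCapsules(p, spec)
  occ <- mean(cap$capsules$n_cells >= 1)
  p0 <- 1 - exp(-0.35)
  expect_lt(abs(occ - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
  # conditional multi-cell fraction among occupied capsules
  multi <- sum(cap$capsules$n_cells >= 2) / sum(cap$capsules$n_cells >= 1)
  pm <- (1 - exp(-0.35) - 0.35 * exp(-0.35)) / (1 - exp(-0.35))
  n_occ <- sum(cap$capsules$n_cells >= 1)
  expect_lt(abs(multi - pm), 3 * sqrt(pm * (1 - pm) / n_occ))
  # strain draw matches relative abundance within 3 multinomial SD
  tab <- table(factor(cap$cells$strain_id, levels = si$strain_id))
  n <- sum(tab)
  for (i in seq_along(tab)) {
    expect_lt(abs(tab[i] / n - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  }
})

test_that("full PMA suppression of a dead community yields no positives", {
  p <- fxPanel()
  si <- strainInfo(p)
  members <- data.frame(strain_id = si$strain_id,
    relative_abundance = rep(0.25, 4), viable_fraction = 0)
  mda <- mdaParams(deadAmplificationProb = c("0" = 1, "5" = 0))
  spec <- communitySpec(members, pmaDose = 5, lambda = 0.35,
    nCapsules = 2000, freeDnaRate = 0, mda = mda, seed = 7)
  cap <- simulateCapsules(p, spec)
  expect_equal(sum(cap$capsules$positive), 0L)
  # and at dose 0 the same community is fully positive where occupied
  spec0 <- communitySpec(members, pmaDose = 0, lambda = 0.35,
    nCapsules = 2000, freeDnaRate = 0, mda = mda, seed = 7)
  cap0 <- simulateCapsules(p, spec0)
  expect_equal(sum(cap0$capsules$positive),
               sum(cap0$capsules$n_cells >= 1))
})

test_that("unknown strain in community spec errors", {
  p <- fxPanel()
  members <- data.frame(strain_id = "nope", relative_abundance = 1,
                        viable_fraction = 1)
  spec <- communitySpec(members, seed = 1)
  expect_error(simulateCapsules(p, spec), "unknown strain_id")
})

test_that("chimera-free reads are verbatim genome substrings", {
  mk <- fxMarkers()
  panel <- generateReferenceSet(nSpecies = 1, strainsPerSpecies = 1,
    genomeLength = 50000, withinStrainDiv = 0, betweenStrainDiv = 0.001,
    markers = mk, seed = 21)
  g <- as.character(genomes(panel)[[1]])
  members <- data.frame(strain_id = strainInfo(panel)$strain_id,
    relative_abundance = 1, viable_fraction = 1)
  spec <- communitySpec(members, lambda = 0.6, nCapsules = 10,
    freeDnaRate = 0,
    mda = mdaParams(chimeraRate = 0, readsPerPositiveCapsule = 500),
    seed = 8)
  cap <- simulateCapsules(panel, spec)
  cid <- cap$capsules$capsule_id[cap$capsules$positive][1]
  cc <- cap$cells[cap$cells$capsule_id == cid, ]
  r <- simulateSagReads(panel, spec, cid, cc, FALSE)
  expect_true(all(vapply(r$reads, function(x)
    grepl(x, g, fixed = TRUE) || grepl(revComp(x), g, fixed = TRUE),
    logical(1))))
  expect_false(any(r$readTruth$chimeric))
})

test_that("forced chimerism records exactly one junction per read", {
  sim <- fxReadSim()
  panel <- sim$panel
  members <- data.frame(strain_id = strainInfo(panel)$strain_id,
    relative_abundance = 1, viable_fraction = 1)
  spec <- communitySpec(members, lambda = 0.6, nCapsules = 10,
    freeDnaRate = 0,
    mda = mdaParams(chimeraRate = 1, readsPerPositiveCapsule = 1000),
    seed = 77)
  cap <- simulateCapsules(panel, spec)
  cid <- cap$capsules$capsule_id[cap$capsules$positive][1]
  cc <- cap$cells[cap$cells$capsule_id == cid, ]
  r <- simulateSagReads(panel, spec, cid, cc, FALSE)
  expect_true(all(r$readTruth$chimeric))
  expect_true(all(!is.na(r$readTruth$junction)))
  expect_true(all(r$readTruth$junction >= 20 &
                    r$readTruth$junction <= 150 - 20))
})

test_that("observed chimera fraction matches the configured rate", {
  sim <- fxReadSim()$sim
  rt <- sim$readTruth
  rate <- mean(rt$chimeric)
  n <- nrow(rt)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("stronger amplification bias reduces genome coverage breadth", {
  mk <- fxMarkers()
  panel <- generateReferenceSet(nSpecies = 1, strainsPerSpecies = 1,
    genomeLength = 50000, markers = mk, seed = 31)
  members <- data.frame(strain_id = strainInfo(panel)$strain_id,
    relative_abundance = 1, viable_fraction = 1)
  covered <- function(logSd) {
    spec <- communitySpec(members, lambda = 0.6, nCapsules = 6,
      freeDnaRate = 0,
      mda = mdaParams(chimeraRate = 0, readsPerPositiveCapsule = 5000,
                      logSdAmplification = logSd),
      seed = 13)
    cap <- simulateCapsules(panel, spec)
    cid <- cap$capsules$capsule_id[cap$capsules$positive][1]
    cc <- cap$cells[cap$cells$capsule_id == cid, ][1, , drop = FALSE]
    rt <- simulateSagReads(panel, spec, cid, cc, FALSE)$readTruth
    cov <- logical(50000)
    for (i in seq_len(nrow(rt)))
      cov[(rt$start1[i] + 1L):rt$end1[i]] <- TRUE
    mean(cov)
  }
  expect_lt(covered(2.0), covered(0))
})

test_that("simulation output on disk is byte-identical across repeats", {
  sim <- fxReadSim()
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(sim$sim, sim$panel, d1)
  # regenerate from scratch with the same spec and seed
  sim2 <- simulateRun(sim$panel, sim$spec)
  writeSimulation(sim2, sim$panel, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  md1 <- tools::md5sum(file.path(d1, f1))
  md2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(md1), unname(md2))
  unlink(c(d1, d2), recursive = TRUE)
})
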