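# Marker detection, completeness/contamination estimation, SAG filters
# and quality tiers.

test_that("verbatim and reverse-complement marker copies are detected", {
  mk <- fxMarkers()
  m1 <- as.character(markerSeqs(mk)[[1]])
  left <- randomGenome(3000, 0.45, seed = 51)
  right <- randomGenome(3000, 0.45, seed = 52)
  ctgF <- c(ctg1 = paste0(left, m1, right))
  hF <- detectMarkers(ctgF, mk)
  expect_equal(nrow(hF), 1L)
  expect_equal(hF$identity, 100)
  expect_equal(hF$strand, "+")
  expect_equal(hF$start, 3000)
  expect_equal(hF$end, 3000 + nchar(m1))
  ctgR <- c(ctg1 = paste0(left, revComp(m1), right))
  hR <- detectMarkers(ctgR, mk)
  expect_equal(nrow(hR), 1L)
  expect_equal(hR$identity, 100)
  expect_equal(hR$strand, "-")
})

test_that("mutated marker copies report the realized identity", {
  mk <- fxMarkers()
  m1 <- as.character(markerSeqs(mk)[[1]])
  mut1 <- mutateSequence(m1, 0.02, seed = 61)
  mut2 <- mutateSequence(m1, 0.02, seed = 62)
  ctgs <- c(c1 = paste0(randomGenome(2000, 0.45, seed = 63), mut1$seq),
            c2 = paste0(mut2$seq, randomGenome(2000, 0.45, seed = 64)))
  h <- detectMarkers(ctgs, mk)
  expect_equal(nrow(h), 2L)
  exp1 <- 100 * (1 - length(mut1$sites) / nchar(m1))
  exp2 <- 100 * (1 - length(mut2$sites) / nchar(m1))
  expect_equal(sort(h$identity), sort(c(exp1, exp2)), tolerance = 1e-8)
})

test_that("completeness and contamination follow the copy-count formula", {
  mk40 <- randomMarkerSet(n = 40, length = 120, seed = 71)
  hits <- data.frame(marker_id = markerNames(mk40)[1:30],
                     contig_id = "c", stringsAsFactors = FALSE)
  cc <- estimateCompleteness(hits, mk40)
  expect_equal(cc$completeness, 75)
  expect_equal(cc$contamination, 0)
  hits2 <- data.frame(marker_id = c(markerNames(mk40),
                                    markerNames(mk40)[1]),
                      contig_id = "c", stringsAsFactors = FALSE)
  cc2 <- estimateCompleteness(hits2, mk40)
  expect_equal(cc2$completeness, 100)
  expect_equal(cc2$contamination, 2.5)
  # empty hits
  cc0 <- estimateCompleteness(emptyMarkerHits <- data.frame(
    marker_id = character()), mk40)
  expect_equal(unlist(cc0), c(completeness = 0, contamination = 0))
})

test_that("a two-species doublet shows more contamination than singletons", {
  mk <- fxMarkers()
  p <- fxPanel()
  g <- as.character(genomes(p))
  singleA <- c(a = g[["sp01_st01"]])
  singleB <- c(b = g[["sp02_st01"]])
  doublet <- c(a = g[["sp01_st01"]], b = g[["sp02_st01"]])
  contam <- function(ctg) estimateCompleteness(
    detectMarkers(ctg, mk), mk)$contamination
  expect_gt(contam(doublet), contam(singleA))
  expect_gt(contam(doublet), contam(singleB))
})

test_that("full-genome SAG scores completeness 100 and contamination 0", {
  mk <- fxMarkers()
  g <- as.character(genomes(fxPanel()))[1]
  cc <- estimateCompleteness(detectMarkers(c(ctg = g), mk), mk)
  expect_equal(cc$completeness, 100)
  expect_equal(cc$contamination, 0)
})

test_that("QC is invariant to contig order and strand flips", {
  mk <- fxMarkers()
  da <- fxDropout()
  ctg <- da$contigs[[1]]
  base <- estimateCompleteness(detectMarkers(ctg, mk), mk)
  perm <- rev(ctg)
  flip <- ctg
  flip[1] <- revComp(flip[1])
  expect_equal(estimateCompleteness(detectMarkers(perm, mk), mk), base)
  expect_equal(estimateCompleteness(detectMarkers(flip, mk), mk), base)
})

test_that("adding a contig never decreases completeness", {
  mk <- fxMarkers()
  da <- fxDropout()
  ctg <- da$contigs[[1]]
  sub <- ctg[-1]
  cFull <- estimateCompleteness(detectMarkers(ctg, mk), mk)$completeness
  cSub <- estimateCompleteness(detectMarkers(sub, mk), mk)$completeness
  expect_gte(cFull, cSub)
})

test_that("SAG filters use strict boundaries and log the first failure", {
  qc <- data.frame(
    sag_id = sprintf("s%02d", 1:10),
    total_read_bases = c(999999, rep(2e6, 9)),
    completeness = c(60, 20.0, rep(60, 8)),
    contamination = c(0, 0, 10.0, rep(0, 7)))
  out <- filterSags(qc)
  expect_equal(sum(out$kept), 7L)
  expect_equal(out$reject_reason[1], "read_yield")
  expect_equal(out$reject_reason[2], "completeness") # exactly 20 fails >
  expect_equal(out$reject_reason[3], "contamination") # exactly 10 fails <
  # brute-force predicate oracle
  oracle <- with(qc, total_read_bases >= 1e6 & completeness > 20 &
                   contamination < 10)
  expect_identical(out$kept, oracle)
})

test_that("quality tiers follow the stated thresholds", {
  expect_equal(classifyQualityTier(56.1, 0), "medium")
  expect_equal(classifyQualityTier(0, 0), "incomplete")
  expect_equal(classifyQualityTier(95, 1), "high")
  expect_equal(classifyQualityTier(50, 0), "low")   # exactly 50 is not medium
  expect_equal(classifyQualityTier(60, 10), "low")  # exactly 10 is not medium
  expect_equal(classifyQualityTier(c(56.1, 0, 95), c(0, 0, 1)),
               c("medium", "incomplete", "high"))
})

test_that("computeQcStats drops short contigs before any statistic", {
  mk <- fxMarkers()
  long <- randomGenome(2000, 0.6, seed = 81)
  short <- randomGenome(999, 0.2, seed = 82)
  st <- computeQcStats(c(a = long, b = short), readBases = 1e6,
                       markers = mk, minContigLen = 1000)
  expect_equal(st$n_contigs, 1L)
  expect_equal(st$total_length, 2000L)
  # GC computed over kept contigs only
  expect_equal(st$gc_percent, bruteGC(long), tolerance = 1e-9)
})
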