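# Cross-reference mapping, read splitting and iterative chimera cleaning.

test_that("a verbatim substring maps as one full-coverage segment", {
  ref <- c(r1 = randomGenome(20000, 0.45, seed = 201))
  read <- substr(ref[[1]], 5001, 5150)
  seg <- crossMap(c(q = read), ref)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$read_start, 0L)
  expect_equal(seg$read_end, 150L)
  expect_equal(seg$identity, 100)
  expect_equal(seg$ref_start, 5000L)
  expect_equal(seg$ref_end, 5150L)
  expect_equal(seg$strand, "+")
})

test_that("reads absent from every reference map nowhere", {
  ref <- c(r1 = randomGenome(20000, 0.45, seed = 202))
  alien <- randomGenome(150, 0.45, seed = 203)
  seg <- crossMap(c(q = alien), ref)
  expect_equal(nrow(seg), 0L)
})

test_that("chimeric junctions are localized within 20 bp", {
  g <- randomGenome(50000, 0.45, seed = 204)
  ref <- c(r1 = g)
  set.seed(205)
  hits <- 0L; n <- 50L
  for (i in seq_len(n)) {
    j <- sample(30:120, 1)
    s1 <- sample(1:20000, 1)
    s2 <- sample(30000:49000, 1)
    read <- paste0(substr(g, s1, s1 + j - 1),
                   substr(g, s2, s2 + (150 - j) - 1))
    seg <- crossMap(setNames(read, "q"), ref)
    expect_equal(nrow(seg), 1L) # best single locus only
    boundary <- if (seg$read_start == 0) seg$read_end else seg$read_start
    if (abs(boundary - j) <= 20) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n))
})

test_that("splitRead cuts at segment boundaries and discards short parts", {
  read <- strrep("A", 150) # content irrelevant to interval arithmetic
  seg <- function(s, e) data.frame(read_start = s, read_end = e,
                                   identity = 100)
  r1 <- splitRead(read, seg(0, 90))
  expect_true(r1$split)
  expect_equal(r1$fragments$end - r1$fragments$start, c(90, 60))
  expect_equal(r1$fragments$origin, c("aligned", "unaligned"))
  expect_equal(r1$discarded_bases, 0L)

  r2 <- splitRead(read, seg(0, 140))
  expect_true(r2$split)
  expect_equal(nrow(r2$fragments), 1L)
  expect_equal(r2$fragments$end - r2$fragments$start, 140)
  expect_equal(r2$discarded_bases, 10L)

  r3 <- splitRead(read, seg(0, 150))
  expect_false(r3$split)
  expect_equal(r3$fragments$origin, "whole")

  r4 <- splitRead(read, seg(0, 149))   # coverage 0.993 >= 0.95
  expect_false(r4$split)

  r5 <- splitRead(read, NULL)          # no segments: kept whole
  expect_false(r5$split)

  r6 <- splitRead(read, seg(0, 10))    # coverage < 0.1: treated unaligned
  expect_false(r6$split)
})

test_that("overlapping segments resolve to the higher identity", {
  read <- strrep("A", 150)
  segs <- data.frame(read_start = c(0, 40), read_end = c(80, 120),
                     identity = c(90, 99))
  r <- splitRead(read, segs)
  # the 99%-identity segment wins; the other is dropped entirely
  expect_equal(r$fragments$start, c(0, 40, 120))
  expect_equal(r$fragments$end, c(40, 120, 150))
  expect_equal(r$fragments$origin, c("unaligned", "aligned", "unaligned"))
})

test_that("base conservation holds for every split", {
  read <- randomGenome(150, 0.5, seed = 211)
  cases <- list(
    data.frame(read_start = 0, read_end = 90, identity = 100),
    data.frame(read_start = 30, read_end = 140, identity = 100),
    data.frame(read_start = c(0, 100), read_end = c(60, 150),
               identity = c(100, 99)),
    data.frame(read_start = 10, read_end = 25, identity = 100))
  for (segs in cases) {
    r <- splitRead(read, segs)
    expect_equal(sum(nchar(r$fragments$seq)) + r$discarded_bases, 150L)
    expect_true(all(nchar(r$fragments$seq) >= 20))
  }
})

test_that("batch splitter agrees with splitRead on single-segment input", {
  set.seed(212)
  reads <- setNames(vapply(1:60, function(i) randomGenome(150, 0.5),
                           character(1)), sprintf("r%02d", 1:60))
  qs <- sample(0:60, 60, replace = TRUE)
  qe <- qs + sample(10:90, 60, replace = TRUE)
  qe <- pmin(qe, 150L)
  # reference coordinates internal to a long contig, so every overhang
  # counts as chimera evidence (matching plain interval splitting)
  segs <- data.frame(read_id = names(reads), read_start = qs, read_end = qe,
                     ref_start = 500L, ref_end = 500L + (qe - qs),
                     ref_len = 10000L, strand = "+",
                     identity = 100, stringsAsFactors = FALSE)
  batch <- CoSAG:::splitReadBatch(reads, segs)
  oneByOne <- lapply(seq_along(reads), function(i)
    splitRead(reads[[i]], segs[i, , drop = FALSE]))
  expTotal <- sum(vapply(oneByOne, function(x)
    sum(nchar(x$fragments$seq)), numeric(1)))
  expDisc <- sum(vapply(oneByOne, `[[`, numeric(1), "discarded_bases"))
  expSplit <- sum(vapply(oneByOne, `[[`, logical(1), "split"))
  expect_equal(sum(nchar(batch$reads)), expTotal)
  expect_equal(batch$discarded, expDisc)
  expect_equal(batch$nsplit, expSplit)
})

test_that("chimera-free groups converge in one cycle with no change", {
  mk <- fxMarkers()
  panel <- generateReferenceSet(nSpecies = 1, strainsPerSpecies = 1,
    genomeLength = 50000, markers = mk, seed = 221)
  members <- data.frame(strain_id = strainInfo(panel)$strain_id,
    relative_abundance = 1, viable_fraction = 1)
  spec <- communitySpec(members, lambda = 0.6, nCapsules = 12,
    freeDnaRate = 0,
    mda = mdaParams(chimeraRate = 0, readsPerPositiveCapsule = 3000),
    seed = 222)
  sim <- simulateRun(panel, spec)
  ids <- head(names(sim$reads), 3)
  ctgs <- lapply(sim$reads[ids], function(r)
    suppressWarnings(coassemble(r, minKmerCount = 2)))
  cl <- cleanGroup(sim$reads[ids], ctgs)
  expect_equal(cl$report$cycles, 1L)
  expect_equal(cl$report$fragments_created, 0L)
  expect_equal(cl$report$bases_discarded, 0L)
  expect_identical(unname(unlist(cl$pool)),
                   unname(unlist(sim$reads[ids])))
})

test_that("cleaning is idempotent and conserves bases", {
  fixt <- fxReadSim()
  ids <- head(names(fixt$sim$reads), 4)
  cl <- cleanGroup(fixt$sim$reads[ids], fixt$contigs[ids])
  basesIn <- sum(nchar(unlist(fixt$sim$reads[ids])))
  basesOut <- sum(nchar(unlist(cl$pool)))
  expect_equal(basesOut + cl$report$bases_discarded, basesIn)
  expect_true(all(nchar(unlist(cl$pool)) >= 20))
  # fragment counts never decrease across cycles (monotone)
  expect_gte(cl$report$fragments_out, cl$report$reads_in)
  # re-cleaning the cleaned pool changes nothing
  cl2 <- cleanGroup(cl$pool, fixt$contigs[ids])
  expect_equal(cl2$report$fragments_created, 0L)
  expect_identical(sortC(names(unlist(unname(cl2$pool)))),
                   sortC(names(unlist(unname(cl$pool)))))
})

test_that("SAM segments convert CIGAR and clips to read intervals", {
  sam <- c(
    "@SQ\tSN:r1\tLN:1000",
    # 30S120M: aligned read interval [30, 150)
    paste("q1", 0, "r1", 101, 60, "30S120M", "*", 0, 0,
          strrep("A", 150), "*", sep = "\t"),
    # reverse strand, 20S130M: aligned [0, 130) on the original read
    paste("q2", 16, "r1", 201, 60, "130M20S", "*", 0, 0,
          strrep("A", 150), "*", sep = "\t"),
    # unmapped record is skipped
    paste("q3", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 150), "*",
          sep = "\t"))
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  seg <- readSamSegments(f)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$read_start[seg$read_id == "q1"], 30L)
  expect_equal(seg$read_end[seg$read_id == "q1"], 150L)
  expect_equal(seg$ref_start[seg$read_id == "q1"], 100L)
  q2 <- seg[seg$read_id == "q2", ]
  expect_equal(q2$strand, "-")
  expect_equal(q2$read_start, 20L)
  expect_equal(q2$read_end, 150L)
  unlink(f)
})
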