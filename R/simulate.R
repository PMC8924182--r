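# Synthetic community generator: reference strain genomes with planted
# single-copy markers, Poisson encapsulation of viable/dead cells with
# dose-dependent PMA suppression, free-DNA capsules, and MDA-like read
# simulation with lognormal coverage bias and chimeric reads.

#' Generate a random single-copy marker set
#'
#' @param n Number of markers.
#' @param length Marker length in bp (>= 100).
#' @param gc GC fraction of the marker sequences.
#' @param seed Integer seed.
#' @return A [MarkerSet-class].
#' @export
randomMarkerSet <- function(n = 24, length = 200, gc = 0.5, seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) randomGenome(length, gc),
                   character(1))
    names(seqs) <- sprintf("M%02d", seq_len(n))
    MarkerSet(seqs)
  })
}

#' Generate a reference panel of strain genomes
#'
#' Per species, an ancestor genome is drawn i.i.d. at a species-specific GC
#' content and the marker loci are planted at non-overlapping positions.
#' Each strain is then the ancestor mutated by i.i.d. substitutions, so
#' marker copies diverge together with the genome backbone. Divergence
#' arguments are *expected pairwise* divergences between two sampled
#' entities: each lineage is mutated at half the stated rate from the
#' shared ancestor.
#'
#' @param nSpecies,strainsPerSpecies Community structure.
#' @param genomeLength Genome length in bp; must be at least 10x the total
#'   marker length.
#' @param withinStrainDiv Expected pairwise divergence between two cells of
#'   the same strain (applied at read-simulation time).
#' @param betweenStrainDiv Expected pairwise divergence between two strains
#'   of the same species.
#' @param betweenSpeciesDiv Expected divergence between species; species
#'   ancestors are independent random backbones, so this only has to
#'   dominate `betweenStrainDiv`.
#' @param markers A [MarkerSet-class] to plant in every genome.
#' @param gc Per-species GC fractions (recycled); defaults spread over
#'   `[0.35, 0.65]` so that genomes carry a compositional (tetranucleotide)
#'   signature.
#' @param seed Integer seed; output is fully deterministic given the seed.
#' @return A [ReferencePanel-class].
#' @export
generateReferenceSet <- function(nSpecies = 2, strainsPerSpecies = 2,
                                 genomeLength = 1e5,
                                 withinStrainDiv = 0.0005,
                                 betweenStrainDiv = 0.015,
                                 betweenSpeciesDiv = 0.25,
                                 markers = randomMarkerSet(seed = seed),
                                 gc = NULL, seed = 1) {
  stopifnot(withinStrainDiv >= 0, withinStrainDiv <= betweenStrainDiv,
            betweenStrainDiv < betweenSpeciesDiv)
  mlen <- sum(Biostrings::width(markerSeqs(markers)))
  if (genomeLength < 10 * mlen)
    stop("genomeLength must be >= 10x the total marker length (",
         10 * mlen, " bp)")
  if (is.null(gc)) {
    gc <- if (nSpecies == 1) 0.42 else seq(0.35, 0.65, length.out = nSpecies)
  }
  gc <- rep_len(gc, nSpecies)

  mseq <- as.character(markerSeqs(markers))
  mw <- nchar(mseq)

  withr::with_seed(seed, {
    genomeList <- list()
    info <- list()
    loci <- list()
    for (sp in seq_len(nSpecies)) {
      speciesId <- sprintf("sp%02d", sp)
      anc <- randomGenome(genomeLength, gc[sp])
      # plant markers at non-overlapping loci (bounded retries)
      placed <- matrix(integer(), ncol = 2)
      for (mi in seq_along(mseq)) {
        ok <- FALSE
        for (try in 1:200) {
          s <- sample.int(genomeLength - mw[mi] + 1L, 1L) - 1L
          e <- s + mw[mi]
          if (!nrow(placed) || all(e <= placed[, 1] | s >= placed[, 2])) {
            ok <- TRUE; break
          }
        }
        if (!ok)
          stop("failed to place marker ", names(mseq)[mi],
               " after bounded retries; genome too small?")
        substr(anc, s + 1L, e) <- mseq[mi]
        placed <- rbind(placed, c(s, e))
      }
      for (st in seq_len(strainsPerSpecies)) {
        strainId <- sprintf("%s_st%02d", speciesId, st)
        g <- mutateSequence(anc, betweenStrainDiv / 2)$seq
        genomeList[[strainId]] <- g
        info[[strainId]] <- data.frame(strain_id = strainId,
          species_id = speciesId, gc = gc[sp],
          pairwise_strain_div = betweenStrainDiv)
        loci[[strainId]] <- data.frame(strain_id = strainId,
          marker_id = names(mseq), start = placed[, 1], end = placed[, 2],
          strand = "+")
      }
    }
    new("ReferencePanel",
        genomes = Biostrings::DNAStringSet(unlist(genomeList)),
        strainInfo = do.call(rbind, c(info, list(make.row.names = FALSE))),
        markerLoci = do.call(rbind, c(loci, list(make.row.names = FALSE))),
        markerSet = markers,
        withinStrainDiv = withinStrainDiv,
        seed = as.integer(seed))
  })
}

#' MDA amplification / read model parameters
#'
#' Describes the in-capsule whole-genome-amplification artifacts: uneven
#' coverage (lognormal per-window amplification weights), chimeric reads
#' (per-read probability of joining two distant loci), and the
#' dose-dependent probability that a dead cell's genome amplifies at all.
#'
#' @param readLength Read length in bp (>= 40).
#' @param paired Emit proper R1/R2 mates from 300 bp inserts.
#' @param readsPerPositiveCapsule Total reads emitted per positive capsule.
#' @param coverageWindow Window size (bp) over which one lognormal
#'   amplification weight applies.
#' @param logSdAmplification Log-scale SD of the per-window weight; 0 means
#'   uniform coverage.
#' @param chimeraRate Per-read probability of a chimeric join.
#' @param deadAmplificationProb Named numeric map from PMA dose (uM, as
#'   character) to the probability that a dead cell amplifies; must be
#'   monotone non-increasing in dose.
#' @param insertLen Insert length for paired mode.
#' @param errorRate Per-base substitution sequencing error (default 0,
#'   which keeps identity arithmetic exact).
#' @param freeDnaFragmentLen Fragment length of ambient free DNA.
#' @return A validated list of class `MdaParams`.
#' @export
mdaParams <- function(readLength = 150, paired = TRUE,
                      readsPerPositiveCapsule = 8000,
                      coverageWindow = 1000, logSdAmplification = 1.5,
                      chimeraRate = 0.02,
                      deadAmplificationProb = c("0" = 1, "1" = 0.10,
                                                "5" = 0.03, "12.5" = 0.01),
                      insertLen = 300, errorRate = 0,
                      freeDnaFragmentLen = 500) {
  stopifnot(readLength >= 40, chimeraRate >= 0, chimeraRate <= 1,
            insertLen >= readLength, errorRate >= 0, errorRate < 1)
  d <- as.numeric(names(deadAmplificationProb))
  if (anyNA(d) || is.unsorted(d))
    stop("deadAmplificationProb must be named by increasing numeric dose")
  if (is.unsorted(rev(deadAmplificationProb)))
    stop("deadAmplificationProb must be monotone non-increasing in dose")
  structure(list(readLength = readLength, paired = paired,
    readsPerPositiveCapsule = readsPerPositiveCapsule,
    coverageWindow = coverageWindow,
    logSdAmplification = logSdAmplification, chimeraRate = chimeraRate,
    deadAmplificationProb = deadAmplificationProb, insertLen = insertLen,
    errorRate = errorRate, freeDnaFragmentLen = freeDnaFragmentLen),
    class = "MdaParams")
}

#' Community / experiment specification
#'
#' @param members data.frame with columns `strain_id`, `relative_abundance`
#'   (summing to 1) and `viable_fraction` (in `[0, 1]`).
#' @param pmaDose PMA dose in uM (0 = untreated control; study doses are
#'   1, 5 and 12.5).
#' @param lambda Mean cells per droplet (Poisson loading; cell suspensions
#'   in the emulated protocol are adjusted to 0.3-0.4 cells/droplet).
#' @param nCapsules Number of gel capsules.
#' @param freeDnaRate Per-capsule probability of ambient free DNA.
#' @param freeDnaAmplifiableAtDose Doses at which free DNA can amplify
#'   (default: only at dose 0 — PMA crosslinks free DNA).
#' @param mda An [mdaParams()] object.
#' @param seed Master seed; per-capsule streams are derived from it.
#' @return A validated list of class `CommunitySpec`.
#' @export
communitySpec <- function(members, pmaDose = 0, lambda = 0.35,
                          nCapsules = 300, freeDnaRate = 0.05,
                          freeDnaAmplifiableAtDose = 0,
                          mda = mdaParams(), seed = 1) {
  stopifnot(is.data.frame(members),
            all(c("strain_id", "relative_abundance", "viable_fraction")
                %in% names(members)))
  if (abs(sum(members$relative_abundance) - 1) > 1e-9)
    stop("relative abundances must sum to 1")
  if (any(members$viable_fraction < 0 | members$viable_fraction > 1))
    stop("viable_fraction must be in [0, 1]")
  if (lambda <= 0) stop("lambda must be > 0")
  structure(list(members = members, pmaDose = pmaDose, lambda = lambda,
    nCapsules = as.integer(nCapsules), freeDnaRate = freeDnaRate,
    freeDnaAmplifiableAtDose = freeDnaAmplifiableAtDose, mda = mda,
    seed = as.integer(seed)), class = "CommunitySpec")
}

deadAmpProb <- function(mda, dose) {
  m <- mda$deadAmplificationProb
  key <- as.character(dose)
  if (key %in% names(m)) return(unname(m[key]))
  d <- as.numeric(names(m))
  if (dose >= max(d)) return(unname(m[length(m)]))
  if (dose <= min(d)) return(unname(m[1]))
  stats::approx(d, m, xout = dose)$y
}

#' Simulate Poisson capsule loading, viability and PMA suppression
#'
#' Cell counts per capsule are Poisson(`lambda`); strains are drawn by
#' relative abundance, viability by per-strain viable fraction. A viable
#' cell always amplifies; a dead cell amplifies with the dose-dependent
#' probability from `mdaParams()`. Free DNA is present with `freeDnaRate`
#' and amplifiable only at the configured doses. A capsule is positive iff
#' it contains at least one amplified source.
#'
#' @param panel A [ReferencePanel-class].
#' @param spec A [communitySpec()] object; may reference only strains
#'   present in the panel.
#' @return A list with data.frames `capsules` (capsule_id, n_cells,
#'   contains_free_dna, free_dna_amplified, positive, pma_dose) and
#'   `cells` (capsule_id, cell_index, strain_id, viable, amplified).
#' @export
simulateCapsules <- function(panel, spec) {
  unknown <- setdiff(spec$members$strain_id, names(genomes(panel)))
  if (length(unknown))
    stop("unknown strain_id in community spec: ",
         paste(unknown, collapse = ", "))
  withr::with_seed(deriveSeed(spec$seed, "capsules"), {
    n <- spec$nCapsules
    ncells <- rpois(n, spec$lambda)
    capsuleId <- sprintf("C%05d", seq_len(n))
    total <- sum(ncells)
    dprob <- deadAmpProb(spec$mda, spec$pmaDose)
    if (total > 0) {
      strain <- sample(spec$members$strain_id, total, replace = TRUE,
                       prob = spec$members$relative_abundance)
      vf <- setNames(spec$members$viable_fraction, spec$members$strain_id)
      viable <- runif(total) < vf[strain]
      amplified <- viable | (runif(total) < dprob)
      cells <- data.frame(
        capsule_id = rep(capsuleId, ncells),
        cell_index = sequence(ncells),
        strain_id = strain, viable = viable, amplified = amplified,
        stringsAsFactors = FALSE)
    } else {
      cells <- data.frame(capsule_id = character(), cell_index = integer(),
        strain_id = character(), viable = logical(), amplified = logical())
    }
    freeDna <- runif(n) < spec$freeDnaRate
    freeAmp <- freeDna & (spec$pmaDose %in% spec$freeDnaAmplifiableAtDose)
    ampByCap <- tapply(cells$amplified, factor(cells$capsule_id,
                       levels = capsuleId), any, default = FALSE)
    capsules <- data.frame(capsule_id = capsuleId, n_cells = ncells,
      contains_free_dna = freeDna, free_dna_amplified = freeAmp,
      positive = as.logical(ampByCap) | freeAmp, pma_dose = spec$pmaDose,
      stringsAsFactors = FALSE)
    list(capsules = capsules, cells = cells)
  })
}

# sample nr read start positions over a genome of length L with lognormal
# per-window amplification weights; returns integer 0-based starts
mdaStarts <- function(nr, L, span, mda) {
  if (nr == 0L) return(integer())
  W <- max(1L, ceiling(L / mda$coverageWindow))
  w <- exp(rnorm(W, 0, mda$logSdAmplification))
  win <- sample.int(W, nr, replace = TRUE, prob = w)
  lo <- (win - 1L) * mda$coverageWindow
  hi <- pmin(lo + mda$coverageWindow, L - span)
  lo <- pmin(lo, max(0L, L - span))
  hi <- pmax(hi, lo + 1L)
  as.integer(lo + floor(runif(nr) * (hi - lo)))
}

applySeqError <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) mutateSequence(s, rate)$seq, character(1),
         USE.NAMES = FALSE)
}

#' Simulate MDA reads for one positive capsule
#'
#' Each amplified source genome is tiled into coverage windows that receive
#' lognormal amplification weights; read (or insert) start positions are
#' drawn proportional to those weights. With probability `chimeraRate` a
#' read is replaced by the concatenation of its own prefix and a fragment
#' from a distant locus (junction uniform in the read, both parts >= 20 bp,
#' junction recorded in the truth table). Free DNA contributes reads
#' confined to short random fragments of a randomly chosen strain genome.
#'
#' @param panel A [ReferencePanel-class].
#' @param spec The [communitySpec()] the capsule was simulated under.
#' @param capsuleId Capsule identifier.
#' @param capsuleCells Rows of the `cells` table for this capsule.
#' @param freeDnaAmplified Whether amplifiable free DNA is present.
#' @return A list with `reads` (named character vector; names carry
#'   `/1`,`/2` suffixes in paired mode) and `readTruth` (data.frame with
#'   per-read source strain, source interval(s), strand and chimera
#'   junction).
#' @export
simulateSagReads <- function(panel, spec, capsuleId, capsuleCells,
                             freeDnaAmplified = FALSE) {
  mda <- spec$mda
  rl <- mda$readLength
  sources <- capsuleCells[capsuleCells$amplified, , drop = FALSE]
  nsrc <- nrow(sources) + as.integer(freeDnaAmplified)
  if (nsrc == 0L)
    return(list(reads = character(),
                readTruth = emptyReadTruth()))
  withr::with_seed(deriveSeed(spec$seed, paste0("reads:", capsuleId)), {
    nTotal <- mda$readsPerPositiveCapsule
    alloc <- tabulate(sample.int(nsrc, nTotal, replace = TRUE), nsrc)
    allReads <- character(0)
    truth <- list()
    ridx <- 0L
    for (si in seq_len(nsrc)) {
      nr <- alloc[si]
      if (nr == 0L) next
      isFree <- si > nrow(sources)
      if (isFree) {
        strainId <- sample(spec$members$strain_id, 1L,
                           prob = spec$members$relative_abundance)
        srcLabel <- "free_dna"
        cellIdx <- NA_integer_
        genome <- as.character(genomes(panel)[[strainId]])
      } else {
        strainId <- sources$strain_id[si]
        srcLabel <- "cell"
        cellIdx <- sources$cell_index[si]
        genome <- mutateSequence(
          as.character(genomes(panel)[[strainId]]),
          panel@withinStrainDiv / 2)$seq
      }
      L <- nchar(genome)
      if (rl > L) stop("read length exceeds genome length")
      if (isFree) {
        # confine free-DNA reads to short fragments
        nfrag <- max(1L, ceiling(nr * rl / mda$freeDnaFragmentLen / 4))
        fs <- sample.int(max(1L, L - mda$freeDnaFragmentLen), nfrag)
        frag <- sample.int(nfrag, nr, replace = TRUE)
        span <- max(0L, mda$freeDnaFragmentLen - rl)
        starts <- as.integer(fs[frag] - 1L + floor(runif(nr) * max(1L, span)))
        mate <- rep(0L, nr)
      } else if (mda$paired) {
        npair <- ceiling(nr / 2)
        istarts <- mdaStarts(npair, L, mda$insertLen, mda)
        starts <- as.vector(rbind(istarts,
                                  istarts + mda$insertLen - rl))[seq_len(nr)]
        mate <- rep(c(1L, 2L), npair)[seq_len(nr)]
      } else {
        starts <- mdaStarts(nr, L, rl, mda)
        mate <- rep(0L, nr)
      }
      strand <- ifelse(mate == 2L, "-", "+")
      seqs <- substring(genome, starts + 1L, starts + rl)
      seqs[strand == "-"] <- revComp(seqs[strand == "-"])

      # per-read chimera events
      chim <- runif(nr) < mda$chimeraRate
      junction <- rep(NA_integer_, nr)
      s2 <- rep(NA_integer_, nr)
      e2 <- rep(NA_integer_, nr)
      str2 <- rep(NA_character_, nr)
      for (ci in which(chim)) {
        j <- sample(20:(rl - 20), 1L)
        # distant partner locus (>= 5 kb away when possible)
        repeat {
          p2 <- sample.int(L - rl + 1L, 1L) - 1L
          if (L < 12000 || abs(p2 - starts[ci]) >= 5000) break
        }
        st2 <- sample(c("+", "-"), 1L)
        part2 <- substr(genome, p2 + 1L, p2 + (rl - j))
        if (st2 == "-") part2 <- revComp(part2)
        seqs[ci] <- paste0(substr(seqs[ci], 1L, j), part2)
        junction[ci] <- j
        s2[ci] <- p2
        e2[ci] <- p2 + (rl - j)
        str2[ci] <- st2
      }
      seqs <- applySeqError(seqs, mda$errorRate)
      ids <- sprintf("%s_r%05d", capsuleId, ridx + seq_len(nr))
      if (mda$paired && !isFree)
        ids <- paste0(ids, "/", mate)
      ridx <- ridx + nr
      names(seqs) <- ids
      allReads <- c(allReads, seqs)
      truth[[length(truth) + 1L]] <- data.frame(
        capsule_id = capsuleId, read_id = ids, source_type = srcLabel,
        strain_id = strainId, cell_index = cellIdx,
        start1 = ifelse(chim & strand == "-", starts + rl - junction, starts),
        end1 = ifelse(chim & strand == "+", starts + junction, starts + rl),
        strand1 = strand, chimeric = chim, junction = junction,
        start2 = s2, end2 = e2, strand2 = str2, stringsAsFactors = FALSE)
    }
    list(reads = allReads,
         readTruth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

emptyReadTruth <- function() {
  data.frame(capsule_id = character(), read_id = character(),
    source_type = character(), strain_id = character(),
    cell_index = integer(), start1 = integer(), end1 = integer(),
    strand1 = character(), chimeric = logical(), junction = integer(),
    start2 = integer(), end2 = integer(), strand2 = character(),
    stringsAsFactors = FALSE)
}

#' Simulate a full capsule experiment
#'
#' Runs [simulateCapsules()] and then [simulateSagReads()] for every
#' positive capsule. Fully deterministic for a fixed spec and seed.
#'
#' @param panel A [ReferencePanel-class].
#' @param spec A [communitySpec()].
#' @return A list of class `SagSimulation`: `capsules`, `cells`,
#'   `reads` (named list of per-capsule named character vectors) and
#'   `readTruth` (one data.frame over all reads).
#' @export
simulateRun <- function(panel, spec) {
  cap <- simulateCapsules(panel, spec)
  pos <- cap$capsules$capsule_id[cap$capsules$positive]
  reads <- list()
  truths <- list()
  for (cid in pos) {
    cc <- cap$cells[cap$cells$capsule_id == cid, , drop = FALSE]
    fa <- cap$capsules$free_dna_amplified[cap$capsules$capsule_id == cid]
    sim <- simulateSagReads(panel, spec, cid, cc, fa)
    reads[[cid]] <- sim$reads
    truths[[cid]] <- sim$readTruth
  }
  structure(list(capsules = cap$capsules, cells = cap$cells, reads = reads,
    readTruth = if (length(truths))
        do.call(rbind, c(truths, list(make.row.names = FALSE)))
      else emptyReadTruth(),
    spec = spec), class = "SagSimulation")
}

#' Simulate per-SAG draft assemblies with MDA dropout (assembly-level shortcut)
#'
#' Emulates the net effect of MDA coverage bias plus assembly without
#' simulating reads: each SAG's cell genome (strain genome mutated at half
#' the within-strain divergence) is tiled into windows; each window draws a
#' lognormal amplification weight and a Poisson read count, and contigs are
#' the maximal runs of windows with at least `minReadsPerWindow` reads.
#' Used for grouping-scale experiments where only assemblies matter.
#'
#' @param panel A [ReferencePanel-class].
#' @param sagsPerStrain SAGs simulated per strain.
#' @param meanCoverage Mean sequencing coverage (the emulated study works
#'   at roughly 6x).
#' @param logSd Log-scale SD of per-window amplification weight.
#' @param window Window size in bp.
#' @param minReadsPerWindow Windows below this draw are dropped.
#' @param minContigLen Contigs shorter than this are discarded.
#' @param seed Master seed.
#' @return A list with `contigs` (named list of character vectors per SAG)
#'   and `truth` (data.frame sag_id, strain_id, species_id).
#' @export
simulateDropoutAssemblies <- function(panel, sagsPerStrain = 8,
                                      meanCoverage = 6, logSd = 1.5,
                                      window = 1000, minReadsPerWindow = 2,
                                      minContigLen = 1000, seed = 1) {
  si <- strainInfo(panel)
  contigs <- list()
  truth <- list()
  for (strain in si$strain_id) {
    genome <- as.character(genomes(panel)[[strain]])
    L <- nchar(genome)
    W <- ceiling(L / window)
    for (r in seq_len(sagsPerStrain)) {
      sagId <- sprintf("%s_sag%02d", strain, r)
      cs <- withr::with_seed(deriveSeed(seed, sagId), {
        cell <- mutateSequence(genome, panel@withinStrainDiv / 2)$seq
        w <- exp(rnorm(W, 0, logSd))
        cov <- meanCoverage * w / mean(w)
        keep <- rpois(W, cov) >= minReadsPerWindow
        runs <- rle(keep)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        out <- character()
        for (i in which(runs$values)) {
          a <- (starts[i] - 1L) * window + 1L
          b <- min(ends[i] * window, L)
          if (b - a + 1L >= minContigLen)
            out <- c(out, substr(cell, a, b))
        }
        out
      })
      if (length(cs)) names(cs) <- sprintf("%s_c%03d", sagId, seq_along(cs))
      contigs[[sagId]] <- cs
      truth[[sagId]] <- data.frame(sag_id = sagId, strain_id = strain,
        species_id = si$species_id[si$strain_id == strain])
    }
  }
  list(contigs = contigs,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Write a simulation to disk
#'
#' One FASTQ (or R1/R2 pair) per positive capsule, the panel genomes as
#' multi-FASTA, and the truth tables as JSON plus a flat TSV.
#'
#' @param sim A `SagSimulation` from [simulateRun()].
#' @param panel The [ReferencePanel-class] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeSimulation <- function(sim, panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(genomes(panel), file.path(dir, "panel.fasta"))
  for (cid in names(sim$reads)) {
    r <- sim$reads[[cid]]
    if (!length(r)) next
    mate2 <- grepl("/2$", names(r))
    if (any(mate2)) {
      writeFastq(r[!mate2], file.path(dir, paste0(cid, "_R1.fastq")))
      writeFastq(r[mate2], file.path(dir, paste0(cid, "_R2.fastq")))
    } else {
      writeFastq(r, file.path(dir, paste0(cid, "_R1.fastq")))
    }
  }
  flat <- merge(sim$capsules[, c("capsule_id", "positive", "pma_dose")],
                sim$cells, by = "capsule_id", all.x = TRUE)
  flat <- flat[order(flat$capsule_id, flat$cell_index), ]
  write.table(flat, file.path(dir, "capsule_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(capsules = sim$capsules, cells = sim$cells,
    read_truth = sim$readTruth), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

writeFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
}
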