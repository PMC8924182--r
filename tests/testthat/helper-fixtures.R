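# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from fixed seeds; nothing is stored on disk.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# 20 markers x 250 bp (5 kb of marker sequence)
fxMarkers <- function() fx("markers", function()
  randomMarkerSet(n = 20, length = 250, seed = 101))

# 2 species x 2 strains, 60 kb genomes
fxPanel <- function() fx("panel", function()
  generateReferenceSet(nSpecies = 2, strainsPerSpecies = 2,
    genomeLength = 60000, markers = fxMarkers(), seed = 202))

# MDA-dropout draft assemblies for the panel (4 SAGs per strain)
fxDropout <- function() fx("dropout", function()
  simulateDropoutAssemblies(fxPanel(), sagsPerStrain = 4,
    meanCoverage = 15, seed = 303))

# single-strain read-level simulation with chimeras (for chimera tests)
fxReadSim <- function() fx("readsim", function() {
  mk <- fxMarkers()
  panel <- generateReferenceSet(nSpecies = 1, strainsPerSpecies = 1,
    genomeLength = 50000, markers = mk, seed = 404)
  members <- data.frame(strain_id = strainInfo(panel)$strain_id,
    relative_abundance = 1, viable_fraction = 1)
  spec <- communitySpec(members, pmaDose = 0, lambda = 0.6,
    nCapsules = 20, freeDnaRate = 0,
    mda = mdaParams(chimeraRate = 0.05, readsPerPositiveCapsule = 6000),
    seed = 505)
  sim <- simulateRun(panel, spec)
  contigs <- lapply(sim$reads, function(r)
    suppressWarnings(coassemble(r, minKmerCount = 2)))
  list(panel = panel, spec = spec, sim = sim, contigs = contigs)
})

# brute-force Pearson correlation of tetranucleotide frequencies:
# enumerate every 4-window on both strands by hand
bruteTetraCorr <- function(a, b) {
  countOne <- function(s) {
    kmers <- c(substring(s, seq_len(nchar(s) - 3), seq_len(nchar(s) - 3) + 3),
               substring(revCompR(s), seq_len(nchar(s) - 3),
                         seq_len(nchar(s) - 3) + 3))
    all4 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                  1, paste, collapse = "")
    tab <- table(factor(kmers, levels = sort(all4)))
    as.numeric(tab) / sum(tab)
  }
  x <- countOne(a); y <- countOne(b)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# reverse complement without Biostrings (test-side oracle helper)
revCompR <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# brute-force N50: literal definition, scanning candidate lengths
bruteN50 <- function(lengths) {
  if (!length(lengths)) return(0L)
  tot <- sum(lengths)
  best <- 0L
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= tot / 2) best <- L
  }
  best
}

# brute-force GC percent
bruteGC <- function(contigs) {
  ch <- unlist(strsplit(paste(contigs, collapse = ""), ""))
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

# adjusted Rand index between two labelings (mclust supplies the
# independent implementation where available)
ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)
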