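# CoSAG

Strain-resolved co-assembly and viability profiling of single-amplified
genomes (SAGs).

## The problem

Droplet-based single-cell genomics captures individual bacterial cells in
gel capsules, amplifies each genome by multiple displacement
amplification (MDA) and sequences each positive capsule as a SAG. MDA's
uneven coverage leaves each SAG a partial genome (often 20–60%
complete), and its chimeric reads corrupt assemblies. Pre-treating the
sample with propidium monoazide (PMA) blocks amplification of dead-cell
and free DNA, making the sequencing selective for *viable* cells.

`CoSAG` implements the computational half of this workflow for
researchers analysing such data (or prototyping protocols against
simulations):

* **QC** — completeness and contamination from single-copy marker genes
  (completeness = % markers present; contamination =
  `100 · Σ max(cₘ − 1, 0) / M`), plus the dataset filters
  (≥ 1 Mb reads, completeness > 20%, contamination < 10%, contigs
  ≥ 1000 bp).
* **Similarity** — fragment-based average nucleotide identity (ANI) with
  aligned fraction, tetranucleotide frequency correlation, and
  single-copy marker gene homology for every SAG pair.
* **Strain grouping** — adoption rule (ANI computable for > 75% of
  same-species SAGs, max ANI > 98.5%), then groups as connected
  components of the joint-criteria graph
  (ANI > 98% ∧ homology > 99.9% ∧ tetra-correlation > 0.90).
* **Chimera cleaning** — iterative cross-reference mapping within a
  group; partially aligned reads are split into aligned and unaligned
  fragments, fragments < 20 bp discarded, repeated to a fixed point.
* **Co-assembly** — 3–8 members selected under a total-contamination
  budget of 5%, cleaned reads co-assembled by a built-in De Bruijn
  assembler into a composite SAG (CoSAG) with Table-style statistics
  (completeness, contamination, total length, N50, contigs, GC%).
* **Profiling** — positive-capsule fractions per PMA dose, composition,
  and strain abundance as a function of dose.
* **Synthetic community generator** — strain genomes with planted
  markers, Poisson droplet loading (λ ≈ 0.35 cells/droplet),
  dose-dependent PMA suppression, lognormal MDA coverage bias and
  chimeric reads, with machine-readable ground truth. All study
  experiments in the test-suite run against this generator.

## Worked example

Simulate a 2-species × 2-strain community, draw eight MDA-dropout SAG
assemblies per strain, and recover the strains:

```r
library(CoSAG)

mk    <- randomMarkerSet(n = 20, length = 500, seed = 1)
panel <- generateReferenceSet(nSpecies = 2, strainsPerSpecies = 2,
                              genomeLength = 1e5, markers = mk, seed = 1)
da  <- simulateDropoutAssemblies(panel, sagsPerStrain = 8,
                                 meanCoverage = 15, seed = 1)
sim <- pairwiseSimilarity(da$contigs, mk)
head(sim[order(-sim$ani),
         c("sag_a", "sag_b", "ani", "tetra_corr", "marker_homology")], 3)
#>               sag_a           sag_b   ani tetra_corr marker_homology
#> 288 sp01_st02_sag04 sp01_st02_sag06 99.97     0.9982           99.93
#> 432 sp02_st01_sag05 sp02_st01_sag07 99.97     0.9985           99.98
#> 409 sp02_st01_sag03 sp02_st01_sag07 99.97     0.9980           99.96

sp <- setNames(da$truth$species_id, da$truth$sag_id)
ad <- adoptDataset(names(da$contigs), sim, sp)
gr <- buildStrainGroups(ad$sag_id[ad$adopted], sim)
table(gr$group_id)
#> G_sp01_st01_sag01 G_sp01_st02_sag01 G_sp02_st01_sag01 G_sp02_st02_sag01
#>                 8                 8                 8                 8
```

The three similarity values per pair are exactly what the grouping logic
needs: same-strain pairs sit near 99.95% ANI and > 99.9% marker
homology; different strains of one species sit near 98.5% ANI — *above*
the 98% ANI gate but *below* the homology gate, so only the conjunction
of criteria separates them. All 32 SAGs land in the 4 true strain
groups.

The full pipeline (simulation → QC → similarity → grouping → chimera
cleaning → co-assembly → profiling) runs from one configuration:

```r
res <- runPipeline(smokeConfig(outputDir = "cosag_run", seed = 1))
res$coassembly$stats[1, c("completeness", "contamination", "n50")]
#>   completeness contamination  n50
#> 1     91.66667             0 9938
```

On this configuration, member SAGs average ~66% completeness while the
co-assembled CoSAGs reach ~85–96% — the gain the method exists for.
A thin command-line wrapper is installed at
`system.file("cli", "cosag.R", package = "CoSAG")` with `run-all` and
`simulate` subcommands.

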