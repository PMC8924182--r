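---
title: "Strain-resolved co-assembly of single-amplified genomes: models and methods"
author: "CoSAG package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved co-assembly of single-amplified genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Single-cell microbial genomics encapsulates individual cells in gel
droplets, amplifies each genome in place (multiple displacement
amplification, MDA) and sequences each positive capsule as a
single-amplified genome (SAG). Two compounding artifacts limit what one
SAG can say: MDA coverage is extremely uneven, so a typical SAG recovers
only a fraction of its genome, and MDA produces chimeric reads that join
non-contiguous loci. On top of this, standard preparations sequence DNA
from dead cells and ambient free DNA alongside the living community.
Pre-treatment with propidium monoazide (PMA) — a membrane-impermeant,
photo-crosslinking dye — blocks amplification of dead-cell and free DNA,
so sequencing becomes selective for viable cells.

`CoSAG` implements the downstream computational method: quality-control
SAGs, recognise which SAGs came from the *same strain*, clean their reads
of chimeras against each other, and co-assemble them into a composite SAG
(CoSAG) whose completeness far exceeds any member. A built-in synthetic
community generator reproduces the relevant physics (Poisson droplet
loading, dose-dependent PMA suppression, MDA bias, chimerism) so every
stage can be tested against known ground truth.

# Pipeline overview

1. **Simulate** (optional): reference strain genomes, capsules, reads.
2. **QC**: marker-based completeness/contamination; the dataset filters.
3. **Similarity**: fragment ANI, tetranucleotide correlation,
   single-copy marker homology for all SAG pairs.
4. **Adopt & group**: the adoption rule, then strain groups as connected
   components of the three-criteria graph.
5. **Clean**: iterative cross-reference mapping and chimera splitting
   within each group.
6. **Co-assemble**: select 3–8 members under a contamination budget,
   assemble the cleaned pool, report composite statistics.
7. **Profile**: positivity per dose, composition, strain abundance.

`runPipeline(pipelineConfig(...))` executes all stages with one master
seed; `smokeConfig()` is a bundled small configuration.

# Quality control

Completeness and contamination are estimated CheckM-style from a set of
single-copy marker genes: completeness is the percentage of markers
found at least once, contamination the percentage of excess copies,
$100 \sum_m \max(c_m - 1, 0) / M$. Markers are located by exact k-mer
seeding and gap-free diagonal alignment rather than profile HMMs — in the
substitution-only synthetic world the two coincide, and the alignment
route keeps the formula's behaviour fully testable.

The dataset filters use the working points of the emulated protocol, with
deliberately strict boundary semantics (a completeness of exactly 20
fails a "> 20%" rule):

| filter | default | comparison |
|---|---|---|
| read yield | 1 Mb | `>=` (below 1 Mb removed) |
| completeness | 20% | strict `>` |
| contamination | 10% | strict `<` |
| contig length | 1000 bp | `>=` (shorter excluded before QC) |

Quality tiers: *medium* requires completeness > 50 and contamination
< 10; *high* (an extension, configurable) completeness > 90 and
contamination < 5; *incomplete* is exactly 0% completeness, the signature
of free-DNA capsules.

# Similarity measures

**Fragment ANI.** The query is cut into non-overlapping 1000 bp
fragments; each fragment is placed on the target by shared 16-mers (both
strands) and scored gap-free at the best seed diagonal. Fragments
aligning over ≥ 80% of their length at ≥ 80% identity count as mapped;
one-way ANI is the mean identity of mapped fragments, and a direction is
*defined* when the aligned fraction reaches 0.2. The pair value is the
mean over defined directions. Undefined is an explicit tri-state, never
coerced to 0 — downstream rules treat it as missing.

**Tetranucleotide correlation.** Pearson correlation of the 256-long
4-mer frequency vectors, counted over both strands of every contig. The
package uses all 256 coordinates (not the 136 canonical collapse); both
readings are defensible and the choice is config-exposed at the profile
level.

**Marker homology.** For markers single-copy in both SAGs, the extracted
copies are compared over the intersection of their marker-coordinate
spans (strand-normalised). The mean identity over shared markers is the
homology; fewer than 3 shared markers yields *undefined*.

**Why alignment is gap-free.** The generator mutates by substitution
only, so true alignments live on one diagonal and gap-free identity is
exact; the banded-alignment general case collapses to a band of zero.
Externally produced alignments with indels enter through the SAM ingest
path, where CIGAR operations are honoured.

# Adoption and strain grouping

A SAG is adopted into the analysis set iff ANI is computable against
more than 75% of its same-species peers *and* its maximum defined ANI
exceeds 98.5% (both strict). Species labels come from nearest-reference
ANI assignment (95% floor), standing in for a full taxonomic classifier.

Strain groups join SAG pairs satisfying **all three** criteria: ANI >
98%, marker homology > 99.9%, tetranucleotide correlation > 0.90. Groups
are the connected components of this graph — i.e. single-linkage cut at
the stated thresholds. This joint-AND reading is the only one that uses
all three thresholds simultaneously; an average-linkage-on-ANI mode
(`linkage = "average_ani"`) is provided for sensitivity analysis and, as
the tests demonstrate, recovers *species* but cannot separate strains at
~98.5% ANI: the marker-homology gate is what resolves strains. The
arithmetic is delicate by design: between-strain pairs at 1.5% divergence
*pass* the ANI gate (≈ 98.5 > 98) and *fail* the homology gate
(≈ 98.5 < 99.9), while within-strain cell pairs at 0.05% divergence pass
both (homology ≈ 99.95).

# Chimera cleaning

Within a group, each SAG's reads are mapped against the contigs of the
*other* members (never its own). The best-scoring chain per read is
reported as a single gap-free segment; a read whose aligned coverage
falls in the partial band [0.1, 0.95) is split at segment boundaries into
aligned and unaligned fragments, and fragments shorter than 20 bp are
discarded. Mapping and splitting repeat (default 3 cycles) until a cycle
performs no splits; on the second cycle the severed halves of a chimera
map cleanly and the process reaches a fixed point.

Two boundary decisions matter in practice:

* An unaligned overhang that coincides with the **end of a reference
  contig** is explainable by reference truncation, not chimerism; that
  side stays attached. Without this rule, every read straddling a
  contig edge of a partial reference would be falsely split.
* Fully unaligned reads are kept whole: a read from a genome region
  absent in all other members is not a chimera candidate.

Base conservation is an invariant: for every read, the fragment lengths
plus discarded bases reconstruct the read exactly.

# Co-assembly

From each group, members are selected greedily by descending completeness
(ties by id) among medium-quality drafts, stopping when the next SAG
would push the contamination *sum* to 5.0 or the count past 8; fewer than
3 selectable members skips the group. Greedy is the documented policy,
not claimed optimal — the tests verify constraint satisfaction
exhaustively on small instances.

The assembler is a deliberately minimal De Bruijn unitig assembler
(canonical 31-mers, dead-end tip trimming, maximal non-branching paths,
deterministic output order). Its two cleaning devices mirror what
single-cell assemblers do at scale:

* a k-mer **abundance floor** (default 2 in the pipeline) removes
  chimera-junction k-mers, which are read-private;
* **bubble-arm removal** (co-assembly only): short unitigs attached at
  both ends whose coverage is below 20% of the median are minor
  within-strain variants from individual cells; removing them collapses
  the graph onto the majority path. On the bundled configuration this
  lifts CoSAG completeness from a ~66% member mean to ~85–96%.

Composite statistics are the standard table: completeness, contamination,
total length, N50 (largest L with contigs ≥ L covering half the
assembly), contig count and GC%.

# The synthetic community generator

The generator is first-class, tested code; its defaults are fixed study
conditions, not tuning knobs.

* **Panel.** Species ancestors are i.i.d. random sequences at
  species-specific GC (defaults spread over [0.35, 0.65]); markers are
  planted before strain mutation so marker copies diverge with the
  backbone. Divergence parameters are *expected pairwise* divergences:
  each lineage mutates at half the stated rate from the shared ancestor,
  which makes a "between-strain divergence of 0.015" yield strain pairs
  at ≈ 98.5% ANI as the grouping arithmetic requires.
* **Skewed GC is load-bearing.** Uniform-GC random genomes carry no
  compositional signature, and tetranucleotide correlation between
  partial SAGs of one strain collapses; composition skew restores the
  signature that real tetra binning exploits.
* **Capsules.** Cell counts are Poisson (default λ = 0.35 cells/droplet,
  the 0.3–0.4 working range of the emulated protocol); strains are drawn
  by relative abundance and viability per strain. A viable cell always
  amplifies; a dead cell amplifies with a dose-dependent probability
  (defaults 1.0 / 0.10 / 0.03 / 0.01 at 0 / 1 / 5 / 12.5 µM — invented,
  clearly-labeled configuration; the emulated study reports outcomes,
  not rates). Free DNA appears per capsule (default 5%) and amplifies
  only without PMA.
* **Reads.** Default 2 × 150 bp from 300 bp inserts, 8000 reads per
  positive capsule. Per 1000 bp window the amplification weight is
  lognormal (log-SD 1.5); read starts are drawn proportional to the
  weights, which reproduces partial genome recovery at moderate
  coverage. With probability `chimeraRate` (default 0.02; a placeholder,
  as no rate is reported for the emulated data) a read is replaced by
  the concatenation of its own prefix and a fragment from a distant
  locus, junction uniform in the read, both parts ≥ 20 bp, junction
  recorded in the truth table. Sequencing error defaults to 0 so that
  identity arithmetic stays exact in tests.
* **Seeds.** One master seed; every capsule and stage derives its own
  stream by stable hashing, so any subset of the simulation is
  reproducible in isolation.
* **Dropout shortcut.** `simulateDropoutAssemblies()` emulates the net
  effect of MDA bias plus assembly without simulating reads (windows
  with a Poisson-thinned lognormal read count below 2 are dropped);
  grouping-scale experiments use it to keep many-seed studies fast.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequencing error and indels, GC-dependent
amplification bias, real gene content (markers are random sequences),
conserved-gene selection pressure, inter-genome repeats and mobile
elements, and real taxonomic structure. Results on synthetic data
validate the *logic* of the pipeline, not its performance on real
libraries.

# Numerical and design choices

* **Problem sizes.** Toy genomes are 50–100 kb with 20–24 markers of
  200–500 bp. The marker complement is a deliberately larger fraction of
  the genome (~10%) than in real bacteria: the 99.9% homology gate sits
  0.05 percentage points above the within-strain expectation of 99.95,
  and the statistic needs enough shared marker bases to concentrate
  between those values. Real lineage marker sets (~100 genes, ~100 kb)
  have ample power; a proportionally scaled toy set would not.
* The strain-grouping experiments simulate dropout at mean coverage 15
  (completeness mostly > 50%), matching the regime in which grouping is
  actually applied — the adoption rule and the medium-quality gate
  exclude poorer SAGs in the full pipeline.
* The smoke configuration (2 species × 2 strains, 50 kb genomes, 100
  capsules per dose at 0 and 5 µM) is sized for a sub-three-minute
  end-to-end run; it is the package's own choice of demonstration scale.
* Determinism everywhere: radix (locale-independent) sorting for ids,
  seed-derived streams per capsule, deterministic tie-breaks in seeding,
  selection and assembly output order; re-running a configuration
  reproduces byte-identical TSV/JSON outputs, asserted by test.
* Degenerate inputs are values, not errors, where the science says so:
  undefined ANI and undefined homology are `NA` tri-states; empty contig
  sets give all-zero QC rows; "N.D." marks doses with no detected SAGs
  of a species.
* Config files are flat YAML key-value mappings; unknown keys are
  rejected before any stage runs.

# Known limitations

* The assembler targets small, repeat-poor genomes; it has no scaffolding,
  no paired-end awareness and no error correction. An external assembler
  can be substituted at the module boundary.
* Marker homology assumes substitution-dominated divergence; with real
  indels the gap-free extraction would underestimate identity (the SAM
  path is the escape hatch).
* Contamination counts excess marker copies only; the strain-heterogeneity
  refinements of full lineage workflows are not modeled.
* Paired mates are cleaned independently; there is no mate rescue.
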