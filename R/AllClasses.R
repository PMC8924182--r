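#' @useDynLib CoSAG, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet reverseComplement oligonucleotideFrequency
#'   readDNAStringSet writeXStringSet width
#' @importFrom stats rpois rnorm runif cor binom.test setNames
#' @importFrom utils write.table read.delim head
NULL

#' Single-copy marker gene reference set
#'
#' A named collection of nucleotide marker sequences that are expected to
#' occur exactly once per genome within the lineage of interest. Marker
#' presence/absence and copy number drive the completeness and contamination
#' estimates, and single-copy marker alignments drive the marker-homology
#' similarity measure used for strain grouping.
#'
#' @slot markers A [Biostrings::DNAStringSet] of marker sequences, uniquely
#'   named by marker id. Every marker must be at least 100 bp.
#' @slot lineageLabel Free-text label of the lineage the set applies to.
#'
#' @seealso [randomMarkerSet()], [detectMarkers()], [markerHomology()]
#' @export
setClass("MarkerSet",
  representation(markers = "DNAStringSet", lineageLabel = "character"))

setValidity("MarkerSet", function(object) {
  msg <- character()
  nm <- names(object@markers)
  if (length(object@markers) == 0L) msg <- c(msg, "MarkerSet is empty")
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msg <- c(msg, "marker ids must be unique and non-empty")
  if (length(object@markers) && any(Biostrings::width(object@markers) < 100L))
    msg <- c(msg, "every marker sequence must be >= 100 bp")
  if (length(msg)) msg else TRUE
})

#' Reference panel of simulated strain genomes
#'
#' Container for the genomes of a synthetic community: one sequence per
#' strain, strain/species bookkeeping, the coordinates of the planted
#' single-copy marker loci, and the marker set itself. `withinStrainDiv`
#' is the expected pairwise divergence between two cells sampled from the
#' same strain; individual cell genomes are drawn at simulation time by
#' mutating the strain sequence at half that rate.
#'
#' @slot genomes [Biostrings::DNAStringSet] named by strain id.
#' @slot strainInfo data.frame with columns `strain_id`, `species_id`,
#'   `gc`, `pairwise_strain_div`.
#' @slot markerLoci data.frame with columns `strain_id`, `marker_id`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @slot markerSet The [MarkerSet-class] planted in every genome.
#' @slot withinStrainDiv Expected pairwise cell-to-cell divergence.
#' @slot seed Integer seed the panel was generated from.
#'
#' @seealso [generateReferenceSet()]
#' @export
setClass("ReferencePanel",
  representation(genomes = "DNAStringSet", strainInfo = "data.frame",
    markerLoci = "data.frame", markerSet = "MarkerSet",
    withinStrainDiv = "numeric", seed = "integer"))

setValidity("ReferencePanel", function(object) {
  msg <- character()
  ids <- names(object@genomes)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "strain ids must be unique")
  if (!identical(sort(ids), sort(object@strainInfo$strain_id)))
    msg <- c(msg, "strainInfo rows must match genome names")
  af <- Biostrings::alphabetFrequency(object@genomes, baseOnly = TRUE)
  if (length(object@genomes) && any(af[, "other"] > 0))
    msg <- c(msg, "genomes must be over {A,C,G,T}")
  if (nrow(object@markerLoci)) {
    w <- setNames(Biostrings::width(object@genomes), ids)
    bad <- object@markerLoci$start < 0 |
      object@markerLoci$end > w[object@markerLoci$strain_id]
    if (any(bad)) msg <- c(msg, "marker loci outside genome bounds")
  }
  if (object@withinStrainDiv < 0 || object@withinStrainDiv >= 0.25)
    msg <- c(msg, "withinStrainDiv must be in [0, 0.25)")
  if (length(msg)) msg else TRUE
})

#' @describeIn MarkerSet-class Number of markers.
#' @param x,object A `MarkerSet`.
#' @export
setMethod("length", "MarkerSet", function(x) length(x@markers))

#' Accessors
#'
#' `markerSeqs()` returns the marker sequences, `markerNames()` their ids,
#' `lineageLabel()` the lineage label; `genomes()`, `strainInfo()` and
#' `markerLoci()` extract the corresponding slots of a [ReferencePanel-class].
#'
#' @param x A `MarkerSet` or `ReferencePanel`.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
markerSeqs <- function(x) x@markers

#' @rdname accessors
#' @export
markerNames <- function(x) names(x@markers)

#' @rdname accessors
#' @export
lineageLabel <- function(x) x@lineageLabel

#' @rdname accessors
#' @export
genomes <- function(x) x@genomes

#' @rdname accessors
#' @export
strainInfo <- function(x) x@strainInfo

#' @rdname accessors
#' @export
markerLoci <- function(x) x@markerLoci

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet of", length(object@markers), "markers",
      sprintf("(lineage: %s)\n", object@lineageLabel))
  cat("  widths:", paste(range(Biostrings::width(object@markers)),
      collapse = "-"), "bp\n")
})

setMethod("show", "ReferencePanel", function(object) {
  si <- object@strainInfo
  cat("ReferencePanel:", length(object@genomes), "strain genomes,",
      length(unique(si$species_id)), "species\n")
  cat("  genome lengths:", paste(unique(Biostrings::width(object@genomes)),
      collapse = ", "), "bp\n")
  cat("  markers planted:", length(object@markerSet@markers), "per genome;",
      "within-strain pairwise divergence:", object@withinStrainDiv, "\n")
})

#' Construct a MarkerSet
#'
#' @param markers Named [Biostrings::DNAStringSet] (or named character
#'   vector) of marker sequences.
#' @param lineageLabel Text label for the lineage.
#' @return A [MarkerSet-class].
#' @export
MarkerSet <- function(markers, lineageLabel = "synthetic") {
  if (is.character(markers)) markers <- Biostrings::DNAStringSet(markers)
  new("MarkerSet", markers = markers, lineageLabel = lineageLabel)
}
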