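# SAG quality control: marker-based completeness/contamination estimation
# and the run-level filters (read yield, contig length, completeness and
# contamination gates, quality tiers).

#' Detect single-copy marker genes on a contig set
#'
#' Each marker is searched against every contig on both strands by exact
#' k-mer seeding and diagonal projection (the generator is
#' substitution-only, so alignments are gap-free). A hit is reported where
#' the marker covers at least `minCoverage` of its length at
#' `minIdentity` percent identity or better; overlapping hits of the same
#' marker on the same contig interval are merged, keeping the best.
#'
#' @param contigs Character vector or [Biostrings::DNAStringSet] of
#'   contigs (named).
#' @param markers A [MarkerSet-class]; must be non-empty.
#' @param minIdentity Minimum percent identity (default 90).
#' @param minCoverage Minimum fraction of the marker covered (default 0.8).
#' @param k Seed k-mer size.
#' @return data.frame with columns `marker_id`, `contig_id`, `start`,
#'   `end` (0-based half-open on the contig), `strand`, `identity`,
#'   `coverage`.
#' @export
detectMarkers <- function(contigs, markers, minIdentity = 90,
                          minCoverage = 0.8, k = 16) {
  if (!is(markers, "MarkerSet") || length(markers) == 0L)
    stop("a non-empty MarkerSet is required")
  contigs <- asSeqChar(contigs)
  if (!length(contigs)) return(emptyMarkerHits())
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig%04d", seq_along(contigs))
  mseq <- as.character(markerSeqs(markers))
  hits <- cpp_map(unname(mseq), unname(contigs), k = k, local = FALSE,
                  best_only = FALSE)
  if (!nrow(hits)) return(emptyMarkerHits())
  hits$marker_id <- names(mseq)[hits$query]
  hits$contig_id <- names(contigs)[hits$ref]
  hits <- hits[hits$identity >= minIdentity & hits$coverage >= minCoverage, ,
               drop = FALSE]
  if (!nrow(hits)) return(emptyMarkerHits())
  # merge overlapping hits of one marker on one contig, keep best identity
  keep <- logical(nrow(hits))
  ord <- order(hits$marker_id, hits$contig_id, -hits$matches, hits$r_start,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(hits))) {
    key <- paste(hits$marker_id[i], hits$contig_id[i])
    iv <- kept[[key]]
    ov <- FALSE
    if (!is.null(iv)) {
      ov <- any(hits$r_start[i] < iv[, 2] & hits$r_end[i] > iv[, 1])
    }
    if (!ov) {
      kept[[key]] <- rbind(iv, c(hits$r_start[i], hits$r_end[i]))
      keep[i] <- TRUE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  out <- data.frame(marker_id = hits$marker_id, contig_id = hits$contig_id,
    start = hits$r_start, end = hits$r_end, strand = hits$strand,
    identity = hits$identity, coverage = hits$coverage,
    q_start = hits$q_start, q_end = hits$q_end,
    stringsAsFactors = FALSE)
  out[order(out$marker_id, out$contig_id, out$start, method = "radix"), ,
      drop = FALSE]
}

emptyMarkerHits <- function() {
  data.frame(marker_id = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(),
    identity = numeric(), coverage = numeric(),
    q_start = integer(), q_end = integer(), stringsAsFactors = FALSE)
}

#' Completeness and contamination from marker hits
#'
#' Completeness is the percentage of markers found at least once;
#' contamination is the percentage of excess marker copies,
#' `100 * sum(max(copies - 1, 0)) / M`.
#'
#' @param hits Marker hits from [detectMarkers()] for one SAG.
#' @param markers The [MarkerSet-class] searched.
#' @return Named list with `completeness` and `contamination` (percent).
#' @export
estimateCompleteness <- function(hits, markers) {
  M <- length(markers)
  if (M == 0L) stop("empty MarkerSet")
  if (!nrow(hits)) return(list(completeness = 0, contamination = 0))
  copies <- table(factor(hits$marker_id, levels = markerNames(markers)))
  list(completeness = 100 * sum(copies >= 1) / M,
       contamination = 100 * sum(pmax(copies - 1, 0)) / M)
}

#' Assembly summary statistics plus marker-based QC for one SAG
#'
#' Contigs shorter than `minContigLen` are dropped first; N50, GC and the
#' marker-based completeness/contamination are computed on the kept
#' contigs only.
#'
#' @param contigs Contig sequences (character or DNAStringSet).
#' @param readBases Total sequenced bases for the SAG.
#' @param markers A [MarkerSet-class].
#' @param minContigLen Minimum contig length retained (default 1000).
#' @return One-row data.frame: total_read_bases, n_contigs, total_length,
#'   n50, gc_percent, completeness, contamination.
#' @export
computeQcStats <- function(contigs, readBases, markers, minContigLen = 1000) {
  contigs <- as.character(contigs)
  contigs <- contigs[nchar(contigs) >= minContigLen]
  if (!length(contigs)) {
    return(data.frame(total_read_bases = readBases, n_contigs = 0L,
      total_length = 0L, n50 = 0L, gc_percent = 0,
      completeness = 0, contamination = 0))
  }
  lens <- nchar(contigs)
  comp <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(contigs),
                                        baseOnly = TRUE)
  acgt <- colSums(comp[, c("A", "C", "G", "T"), drop = FALSE])
  cc <- estimateCompleteness(detectMarkers(contigs, markers), markers)
  data.frame(total_read_bases = readBases, n_contigs = length(contigs),
    total_length = sum(lens), n50 = calcN50(lens),
    gc_percent = 100 * (acgt["C"] + acgt["G"]) / sum(acgt),
    completeness = cc$completeness, contamination = cc$contamination,
    row.names = NULL)
}

#' SAG-level dataset filters
#'
#' A SAG is kept iff `total_read_bases >= minReadBases` AND
#' `completeness > minCompleteness` AND `contamination < maxContamination`
#' (strict inequalities on the QC gates). The rejection log records the
#' first failed rule per rejected SAG, in that order.
#'
#' @param qc data.frame with one row per SAG, carrying `sag_id`,
#'   `total_read_bases`, `completeness`, `contamination` (e.g. rows from
#'   [computeQcStats()]).
#' @param minReadBases Read-yield floor in bp (default 1 Mb: SAGs with
#'   less than 1 Mb of reads are removed).
#' @param minCompleteness Completeness gate, percent (default 20, strict >).
#' @param maxContamination Contamination gate, percent (default 10,
#'   strict <).
#' @return The input with logical `kept` and character `reject_reason`
#'   (`NA` for kept SAGs; otherwise `"read_yield"`, `"completeness"` or
#'   `"contamination"`).
#' @export
filterSags <- function(qc, minReadBases = 1e6, minCompleteness = 20,
                       maxContamination = 10) {
  reason <- rep(NA_character_, nrow(qc))
  reason[qc$contamination >= maxContamination] <- "contamination"
  reason[qc$completeness <= minCompleteness] <- "completeness"
  reason[qc$total_read_bases < minReadBases] <- "read_yield"
  qc$kept <- is.na(reason)
  qc$reject_reason <- reason
  qc
}

#' Draft-genome quality tier
#'
#' `medium` iff completeness > 50 and contamination < 10; `high` iff
#' completeness > 90 and contamination < 5; `incomplete` iff completeness
#' is exactly 0; otherwise `low`.
#'
#' @param completeness,contamination Percent values (vectorized).
#' @param highCompleteness,highContamination Configurable bounds of the
#'   high tier.
#' @return Character vector over
#'   `{"incomplete", "low", "medium", "high"}`.
#' @export
classifyQualityTier <- function(completeness, contamination,
                                highCompleteness = 90,
                                highContamination = 5) {
  tier <- rep("low", length(completeness))
  tier[completeness > 50 & contamination < 10] <- "medium"
  tier[completeness > highCompleteness &
         contamination < highContamination] <- "high"
  tier[completeness == 0] <- "incomplete"
  tier
}

#' QC table for a list of SAGs
#'
#' Applies [computeQcStats()] per SAG, then [filterSags()] and
#' [classifyQualityTier()].
#'
#' @param sagContigs Named list of contig sets (one per SAG).
#' @param readBases Named numeric vector of total read bases per SAG
#'   (defaults to assembly length when not supplied).
#' @param markers A [MarkerSet-class].
#' @param minContigLen,minReadBases,minCompleteness,maxContamination
#'   Filter thresholds, see [computeQcStats()] and [filterSags()].
#' @return data.frame with one row per SAG (sag_id first), including
#'   `tier`, `kept` and `reject_reason`.
#' @export
sagQcTable <- function(sagContigs, readBases = NULL, markers,
                       minContigLen = 1000, minReadBases = 1e6,
                       minCompleteness = 20, maxContamination = 10) {
  ids <- names(sagContigs)
  rows <- lapply(ids, function(id) {
    rb <- if (is.null(readBases)) sum(nchar(as.character(sagContigs[[id]])))
          else unname(readBases[id])
    cbind(data.frame(sag_id = id, stringsAsFactors = FALSE),
          computeQcStats(sagContigs[[id]], rb, markers, minContigLen))
  })
  qc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  qc$tier <- classifyQualityTier(qc$completeness, qc$contamination)
  filterSags(qc, minReadBases, minCompleteness, maxContamination)
}
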