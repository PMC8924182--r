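# Member selection under the completeness/contamination budget,
# De Bruijn co-assembly of cleaned reads into a composite SAG (CoSAG),
# and composite genome statistics.

#' Select group members for co-assembly
#'
#' From one strain group, 3-8 SAGs with a total contamination below 5
#' percent are selected. Candidates must individually be medium-quality
#' drafts (completeness > 50, contamination < 10). Selection is greedy by
#' descending completeness (ties broken by sag_id), stopping when adding
#' the next SAG would push the contamination sum to 5.0 or beyond, or when
#' 8 members are reached; groups yielding fewer than `minMembers`
#' selectable SAGs are skipped with a reason.
#'
#' @param groupQc data.frame with columns `sag_id`, `completeness`,
#'   `contamination` for the group's members.
#' @param minMembers,maxMembers Member count bounds (default 3-8).
#' @param maxTotalContamination Strict bound on the contamination sum
#'   (default 5.0).
#' @return List with `members` (ordered character vector, or `character()`
#'   when skipped), `skipped` (flag), `reason` (`NA`, `"min_members"`),
#'   and `total_contamination`.
#' @export
selectMembers <- function(groupQc, minMembers = 3, maxMembers = 8,
                          maxTotalContamination = 5.0) {
  elig <- groupQc[groupQc$completeness > 50 & groupQc$contamination < 10, ,
                  drop = FALSE]
  elig <- elig[order(-elig$completeness, elig$sag_id, method = "radix"), ,
               drop = FALSE]
  sel <- character()
  tot <- 0
  for (i in seq_len(nrow(elig))) {
    if (length(sel) == maxMembers) break
    if (tot + elig$contamination[i] >= maxTotalContamination) break
    sel <- c(sel, elig$sag_id[i])
    tot <- tot + elig$contamination[i]
  }
  if (length(sel) < minMembers)
    return(list(members = character(), skipped = TRUE,
                reason = "min_members", total_contamination = NA_real_))
  list(members = sel, skipped = FALSE, reason = NA_character_,
       total_contamination = tot)
}

#' De Bruijn co-assembly of a cleaned read pool
#'
#' Builds the canonical k-mer De Bruijn graph over all reads (both
#' strands), trims short dead-end tips (length <= 2k), emits maximal
#' non-branching paths as unitigs and discards contigs shorter than
#' `minContigLen`. Output order is deterministic: length descending, then
#' sequence.
#'
#' @param reads Character vector (or DNAStringSet) of reads/fragments;
#'   reads shorter than `k + 1` cannot contribute edges.
#' @param k Odd k-mer size <= 31 (default 31).
#' @param minContigLen Contig length floor (default 1000: shorter contigs
#'   are excluded).
#' @param minKmerCount Minimum k-mer multiplicity retained (default 1).
#' @param tipRounds Graph-cleaning rounds (tips and bubble arms).
#' @param bubbleFraction When > 0, short unitigs attached at both ends
#'   whose mean k-mer multiplicity is below this fraction of the median
#'   are removed, collapsing minor within-strain variants onto the
#'   majority path (used for multi-cell co-assembly; default 0 = off).
#' @return Named character vector of contigs (possibly empty, with a
#'   warning when nothing survives).
#' @export
coassemble <- function(reads, k = 31, minContigLen = 1000,
                       minKmerCount = 1, tipRounds = 3,
                       bubbleFraction = 0) {
  reads <- as.character(reads)
  if (!length(reads)) stop("empty read pool")
  contigs <- cpp_assemble(unname(reads), k = k, min_count = minKmerCount,
                          tip_rounds = tipRounds,
                          bubble_frac = bubbleFraction)
  contigs <- contigs[nchar(contigs) >= minContigLen]
  if (!length(contigs)) {
    warning("no contig of length >= ", minContigLen, " was assembled")
    return(setNames(character(), character()))
  }
  setNames(contigs, sprintf("contig%04d", seq_along(contigs)))
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L sum to at least
#' half of the total assembly length.
#'
#' @param lengths Integer vector of contig lengths.
#' @return The N50 (0 for an empty set).
#' @export
calcN50 <- function(lengths) {
  if (!length(lengths)) return(0L)
  lengths <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.double(lengths))
  lengths[which(cum >= sum(as.double(lengths)) / 2)[1]]
}

#' Composite SAG statistics
#'
#' Table of assembly statistics for a (composite) genome: completeness,
#' contamination (marker-based), total length, N50, number of contigs and
#' GC content.
#'
#' @param contigs Contig set (post length filter).
#' @param markers A [MarkerSet-class].
#' @return One-row data.frame (all-zero with `empty = TRUE` for an empty
#'   contig set).
#' @export
compositeStats <- function(contigs, markers) {
  contigs <- as.character(contigs)
  if (!length(contigs))
    return(data.frame(completeness = 0, contamination = 0,
      total_length = 0L, n50 = 0L, n_contigs = 0L, gc_percent = 0,
      empty = TRUE))
  st <- computeQcStats(contigs, readBases = sum(nchar(contigs)),
                       markers = markers, minContigLen = 0)
  data.frame(completeness = st$completeness,
    contamination = st$contamination, total_length = st$total_length,
    n50 = st$n50, n_contigs = st$n_contigs, gc_percent = st$gc_percent,
    empty = FALSE)
}

#' Co-assemble every strain group of a run
#'
#' For each strain group: select members with [selectMembers()], clean the
#' members' reads with [cleanGroup()], co-assemble with [coassemble()]
#' and compute [compositeStats()].
#'
#' @param groups data.frame from [buildStrainGroups()].
#' @param qc QC table from [sagQcTable()].
#' @param readSets Named list of per-SAG read vectors.
#' @param contigSets Named list of per-SAG contig vectors.
#' @param markers A [MarkerSet-class].
#' @param k,minContigLen,minKmerCount,bubbleFraction Assembly parameters
#'   (bubble-arm removal on by default for multi-cell pools).
#' @param maxCycles Cleaning cycles.
#' @return List with `cosags` (named list of contig vectors per group),
#'   `stats` (data.frame, one row per group incl. selection outcome) and
#'   `cleanReports`.
#' @export
coassembleGroups <- function(groups, qc, readSets, contigSets, markers,
                             k = 31, minContigLen = 1000, minKmerCount = 1,
                             bubbleFraction = 0.2, maxCycles = 3) {
  cosags <- list()
  reports <- list()
  rows <- list()
  for (gid in sortC(unique(groups$group_id))) {
    members <- groups$sag_id[groups$group_id == gid]
    sel <- selectMembers(qc[qc$sag_id %in% members, , drop = FALSE])
    if (sel$skipped) {
      rows[[gid]] <- data.frame(group_id = gid, n_members = length(members),
        n_selected = 0L, skipped = TRUE, skip_reason = sel$reason,
        completeness = NA_real_, contamination = NA_real_,
        total_length = NA_integer_, n50 = NA_integer_,
        n_contigs = NA_integer_, gc_percent = NA_real_)
      next
    }
    if (length(sel$members) >= 2) {
      cleaned <- cleanGroup(readSets[sel$members],
                            contigSets[sel$members], maxCycles = maxCycles)
      pool <- unlist(unname(cleaned$pool))
      reports[[gid]] <- cleaned$report
    } else {
      pool <- unlist(unname(readSets[sel$members]))
    }
    ctg <- suppressWarnings(
      coassemble(pool, k = k, minContigLen = minContigLen,
                 minKmerCount = minKmerCount,
                 bubbleFraction = bubbleFraction))
    cosags[[gid]] <- ctg
    st <- compositeStats(ctg, markers)
    rows[[gid]] <- data.frame(group_id = gid, n_members = length(members),
      n_selected = length(sel$members), skipped = FALSE,
      skip_reason = NA_character_, completeness = st$completeness,
      contamination = st$contamination, total_length = st$total_length,
      n50 = st$n50, n_contigs = st$n_contigs, gc_percent = st$gc_percent)
  }
  list(cosags = cosags,
       stats = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       cleanReports = reports)
}
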