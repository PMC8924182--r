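# Cross-reference read cleaning within a strain group: iterative
# cross-reference mapping, splitting of partially aligned reads into
# aligned and unaligned fragments, and discarding of short (< 20 bp)
# fragments.

#' Cross-map reads against the other SAGs of a group
#'
#' Each read is placed by exact k-mer seeding against all reference
#' contigs (both strands); the best-scoring chain is extended gap-free by
#' X-drop and reported as a single alignment segment in read coordinates.
#' Reads with no seed hit anywhere get no segment.
#'
#' @param reads Named character vector (or DNAStringSet) of reads
#'   (>= 40 bp recommended).
#' @param references Named character vector of reference contigs from the
#'   *other* SAGs of the group; must be non-empty.
#' @param k Seed k-mer size (default 15).
#' @param xdrop X-drop extension bound.
#' @return data.frame `read_id`, `ref_contig_id`, `read_start`,
#'   `read_end` (0-based half-open on the read), `ref_start`, `ref_end`,
#'   `strand`, `identity`.
#' @export
crossMap <- function(reads, references, k = 15, xdrop = 12) {
  references <- asSeqChar(references)
  if (!length(references)) stop("empty reference set")
  reads <- asSeqChar(reads)
  if (!length(reads))
    return(emptySegments())
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  if (is.null(names(references)))
    names(references) <- sprintf("ref%05d", seq_along(references))
  m <- cpp_map(unname(reads), unname(references), k = k, local = TRUE,
               best_only = TRUE, xdrop = xdrop)
  if (!nrow(m)) return(emptySegments())
  data.frame(read_id = names(reads)[m$query],
    ref_contig_id = names(references)[m$ref],
    read_start = m$q_start, read_end = m$q_end,
    ref_start = m$r_start, ref_end = m$r_end,
    strand = m$strand, identity = m$identity, stringsAsFactors = FALSE)
}

emptySegments <- function() {
  data.frame(read_id = character(), ref_contig_id = character(),
    read_start = integer(), read_end = integer(), ref_start = integer(),
    ref_end = integer(), strand = character(), identity = numeric(),
    stringsAsFactors = FALSE)
}

#' Split one read at its alignment segment boundaries
#'
#' If the aligned coverage of the read is at least `fullFraction` the
#' read is returned unchanged; if there are no segments, or coverage is
#' below `minAlignedFraction` (effectively unaligned), the read is also
#' kept whole — fully unaligned reads are not chimera candidates.
#' Otherwise the read is cut at segment boundaries into maximal aligned
#' and unaligned intervals; intervals shorter than `minFragmentLen` are
#' discarded (counted in `discarded_bases`). Overlapping segments are
#' resolved by keeping the higher-identity segment.
#'
#' @param readSeq Character scalar, the read sequence.
#' @param segments data.frame of segments for this read (columns
#'   `read_start`, `read_end`, `identity`).
#' @param minFragmentLen Fragment floor in bp (default 20: shorter
#'   fragments are discarded).
#' @param fullFraction Aligned coverage at or above which the read counts
#'   as fully aligned (default 0.95).
#' @param minAlignedFraction Coverage below which the read counts as
#'   unaligned and is kept whole (default 0.1).
#' @return List with `fragments` (data.frame `seq`, `start`, `end`,
#'   `origin` in aligned/unaligned/whole), `discarded_bases`, and `split`
#'   (flag: was the read cut).
#' @export
splitRead <- function(readSeq, segments, minFragmentLen = 20,
                      fullFraction = 0.95, minAlignedFraction = 0.1) {
  L <- nchar(readSeq)
  whole <- function(origin) list(
    fragments = data.frame(seq = readSeq, start = 0L, end = L,
      origin = origin, stringsAsFactors = FALSE),
    discarded_bases = 0L, split = FALSE)
  if (is.null(segments) || !nrow(segments)) return(whole("whole"))
  segments <- segments[order(-segments$identity,
                             segments$read_start), , drop = FALSE]
  kept <- matrix(integer(), ncol = 2)
  for (i in seq_len(nrow(segments))) {
    s <- segments$read_start[i]; e <- segments$read_end[i]
    if (!nrow(kept) || all(e <= kept[, 1] | s >= kept[, 2]))
      kept <- rbind(kept, c(s, e))
  }
  kept <- kept[order(kept[, 1]), , drop = FALSE]
  cov <- sum(kept[, 2] - kept[, 1]) / L
  if (cov >= fullFraction || cov < minAlignedFraction)
    return(whole("whole"))
  # build the aligned/unaligned partition of [0, L)
  bounds <- sort(unique(c(0L, as.vector(kept), L)))
  frags <- list()
  discarded <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    if (e <= s) next
    aligned <- any(s >= kept[, 1] & e <= kept[, 2])
    if (e - s < minFragmentLen) {
      discarded <- discarded + (e - s)
    } else {
      frags[[length(frags) + 1L]] <- data.frame(
        seq = substr(readSeq, s + 1L, e), start = s, end = e,
        origin = if (aligned) "aligned" else "unaligned",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(frags)) # everything discarded: keep whole rather than lose it
    return(whole("whole"))
  list(fragments = do.call(rbind, c(frags, list(make.row.names = FALSE))),
       discarded_bases = discarded, split = TRUE)
}

# Vectorised splitter for the internal mapping path (one best-locus
# segment per read). A read is cut only at boundaries that are internal
# to the reference: an unaligned overhang that coincides with the end of
# the reference contig is explainable by contig truncation, not
# chimerism, and that side stays attached to the aligned piece. Each
# flagged read therefore yields at most three pieces.
splitReadBatch <- function(reads, segs, minFragmentLen = 20,
                           fullFraction = 0.95, minAlignedFraction = 0.1) {
  L <- nchar(reads)
  n <- length(reads)
  qs <- rep(NA_integer_, n)
  qe <- rep(NA_integer_, n)
  cutL <- logical(n)
  cutR <- logical(n)
  if (nrow(segs)) {
    idx <- match(segs$read_id, names(reads))
    ok <- !is.na(idx)
    qs[idx[ok]] <- segs$read_start[ok]
    qe[idx[ok]] <- segs$read_end[ok]
    refInternalLo <- segs$ref_start > 0
    refInternalHi <- segs$ref_end < segs$ref_len
    # on '-' alignments the read's left overhang extends past the
    # reference's high end and vice versa
    minus <- segs$strand == "-"
    cutL[idx[ok]] <- ifelse(minus[ok], refInternalHi[ok], refInternalLo[ok])
    cutR[idx[ok]] <- ifelse(minus[ok], refInternalLo[ok], refInternalHi[ok])
  }
  cov <- (qe - qs) / L
  band <- !is.na(cov) & cov < fullFraction & cov >= minAlignedFraction
  doCutL <- band & qs > 0L & cutL
  doCutR <- band & qe < L & cutR
  si <- which(doCutL | doCutR)
  if (!length(si)) {
    return(list(reads = reads, discarded = 0L, nsplit = 0L))
  }
  # piece boundaries per read: cut positions among {qs, qe}
  b1 <- ifelse(doCutL[si], qs[si], 0L)
  b2 <- ifelse(doCutR[si], qe[si], L[si])
  l1 <- b1                 # left unaligned piece [0, b1)
  l2 <- b2 - b1            # aligned piece (plus uncut overhangs)
  l3 <- L[si] - b2         # right unaligned piece [b2, L)
  k1 <- l1 >= minFragmentLen
  k2 <- l2 >= minFragmentLen
  k3 <- l3 >= minFragmentLen
  none <- !(k1 | k2 | k3)
  si <- si[!none]
  if (!length(si)) {
    return(list(reads = reads, discarded = 0L, nsplit = 0L))
  }
  k1 <- k1[!none]; k2 <- k2[!none]; k3 <- k3[!none]
  l1 <- l1[!none]; l2 <- l2[!none]; l3 <- l3[!none]
  b1 <- b1[!none]; b2 <- b2[!none]
  discarded <- sum(l1[!k1 & l1 > 0]) + sum(l2[!k2]) +
    sum(l3[!k3 & l3 > 0])
  ids <- names(reads)[si]
  rs <- unname(reads[si])
  i1 <- rep(1L, length(si))
  i2 <- 1L + (k1 & l1 > 0)
  i3 <- i2 + k2
  sel1 <- k1 & l1 > 0
  sel3 <- k3 & l3 > 0
  frags <- c(
    setNames(substring(rs[sel1], 1L, b1[sel1]),
             sprintf("%s.f%d", ids[sel1], i1[sel1])),
    setNames(substring(rs[k2], b1[k2] + 1L, b2[k2]),
             sprintf("%s.f%d", ids[k2], i2[k2])),
    setNames(substring(rs[sel3], b2[sel3] + 1L, L[si][sel3]),
             sprintf("%s.f%d", ids[sel3], i3[sel3])))
  frags <- frags[sortC(names(frags))]
  out <- c(reads[-si], frags)
  list(reads = out, discarded = as.integer(discarded),
       nsplit = length(si))
}

#' Iterative chimera cleaning of a strain group's reads
#'
#' Repeats cross-reference mapping and read splitting until a cycle
#' performs no splits or `maxCycles` is reached. Reads of each SAG are
#' mapped only against the contigs of the *other* SAGs in the group.
#' Fragment provenance is preserved in fragment ids
#' (`<read_id>.f<index>`).
#'
#' @param readSets Named list (per SAG) of named character vectors of
#'   reads.
#' @param referenceSets Named list (per SAG) of named character vectors of
#'   contigs; names must match `readSets`.
#' @param maxCycles Maximum cleaning cycles (default 3).
#' @param minFragmentLen,fullFraction,minAlignedFraction Passed to
#'   [splitRead()].
#' @param k Seed k-mer size for [crossMap()].
#' @return List of class `CleanResult`: `pool` (named list per SAG of
#'   cleaned fragments), `report` (one-row data.frame: reads_in,
#'   fragments_out, fragments_created, bases_discarded, cycles,
#'   splits_per_cycle).
#' @export
cleanGroup <- function(readSets, referenceSets, maxCycles = 3,
                       minFragmentLen = 20, fullFraction = 0.95,
                       minAlignedFraction = 0.1, k = 15) {
  stopifnot(length(readSets) >= 2,
            all(names(readSets) %in% names(referenceSets)))
  sags <- names(readSets)
  pool <- readSets
  readsIn <- sum(lengths(readSets))
  discarded <- 0L
  splitsPerCycle <- integer()
  for (cycle in seq_len(maxCycles)) {
    splits <- 0L
    for (s in sags) {
      reads <- pool[[s]]
      if (!length(reads)) next
      refs <- unlist(lapply(referenceSets[setdiff(sags, s)],
                            as.character))
      if (!length(refs)) next
      segs <- crossMap(reads, refs, k = k)
      segs$ref_len <- nchar(refs)[match(segs$ref_contig_id, names(refs))]
      res <- splitReadBatch(reads, segs,
                            minFragmentLen = minFragmentLen,
                            fullFraction = fullFraction,
                            minAlignedFraction = minAlignedFraction)
      discarded <- discarded + res$discarded
      splits <- splits + res$nsplit
      pool[[s]] <- res$reads
    }
    splitsPerCycle <- c(splitsPerCycle, splits)
    if (splits == 0L) break
  }
  structure(list(pool = pool,
    report = data.frame(reads_in = readsIn,
      fragments_out = sum(lengths(pool)),
      fragments_created = sum(lengths(pool)) - readsIn,
      bases_discarded = discarded, cycles = length(splitsPerCycle),
      splits_per_cycle = paste(splitsPerCycle, collapse = ","))),
    class = "CleanResult")
}

#' Ingest alignment segments from a SAM file
#'
#' Converts SAM records into the segment table consumed by [splitRead()]:
#' CIGAR M/=/X consume read and reference, I consumes read, D/N consume
#' reference, S/H delimit unaligned read intervals; coordinates are
#' converted to 0-based half-open. Secondary records (flag 0x100) are
#' skipped; reverse-strand records have their read coordinates mapped back
#' to the original read orientation.
#'
#' @param samPath Path to a SAM file.
#' @return A segment data.frame as from [crossMap()] (identity `NA`,
#'   supplied by the aligner's scoring instead).
#' @export
readSamSegments <- function(samPath) {
  lines <- readLines(samPath)
  lines <- lines[!startsWith(lines, "@")]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) next
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 256L) > 0L) next
    cigar <- f[6]
    if (cigar == "*") next
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    qlen <- sum(n[op %in% c("M", "I", "S", "=", "X")]) +
      sum(n[op == "H"])
    # leading clips
    lead <- 0L
    for (i in seq_along(op)) {
      if (op[i] %in% c("S", "H")) lead <- lead + n[i] else break
    }
    qconsumed <- sum(n[op %in% c("M", "I", "=", "X")])
    qs <- lead
    qe <- lead + qconsumed
    if (bitwAnd(flag, 16L) > 0L) {
      tmp <- qlen - qe
      qe <- qlen - qs
      qs <- tmp
      strand <- "-"
    } else strand <- "+"
    rs <- as.integer(f[4]) - 1L
    re <- rs + sum(n[op %in% c("M", "D", "N", "=", "X")])
    rows[[length(rows) + 1L]] <- data.frame(read_id = f[1],
      ref_contig_id = f[3], read_start = qs, read_end = qe,
      ref_start = rs, ref_end = re, strand = strand,
      identity = NA_real_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(emptySegments())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
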