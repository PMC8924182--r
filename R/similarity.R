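# Pairwise genome similarity measures used for strain grouping:
# fragment-based ANI with aligned fraction, tetranucleotide frequency
# correlation, and single-copy marker gene homology.

#' Fragment-based average nucleotide identity
#'
#' The query contig set is cut into non-overlapping fragments of
#' `fragmentLen`; each fragment is placed on the target by exact k-mer
#' seeding (both strands) and scored gap-free at the best seed diagonal.
#' Fragments aligning over at least 80 percent of their length at
#' `minFragmentIdentity` percent identity or better count as mapped.
#' One-way ANI is the mean identity of mapped fragments and the aligned
#' fraction is mapped/total; a direction is defined when the aligned
#' fraction reaches `minAlignedFraction`. The reported pair value is the
#' mean over the defined directions.
#'
#' @param a,b Contig sets (character vectors or DNAStringSet).
#' @param fragmentLen Fragment size in bp (default 1000).
#' @param k Seed k-mer size (default 16).
#' @param minFragmentIdentity Identity floor for a fragment to count as
#'   mapped (default 80).
#' @param minAlignedFraction Aligned-fraction floor below which a
#'   direction's ANI is undefined (default 0.2).
#' @return List with `ani` (percent, `NA` when undefined),
#'   `aligned_fraction` (max over directions), `ani_defined` (flag), and
#'   the per-direction values `ani_ab`, `ani_ba`, `af_ab`, `af_ba`.
#' @export
computeAni <- function(a, b, fragmentLen = 1000, k = 16,
                       minFragmentIdentity = 80, minAlignedFraction = 0.2) {
  oneWay <- function(q, r) {
    frags <- cutFragments(q, fragmentLen)
    if (!length(frags))
      stop("query genome shorter than fragmentLen (", fragmentLen, " bp)")
    refs <- as.character(r)
    if (!length(refs) || max(nchar(refs)) < fragmentLen)
      stop("target genome shorter than fragmentLen (", fragmentLen, " bp)")
    m <- cpp_map(frags, unname(refs), k = k, local = FALSE, best_only = TRUE)
    if (!nrow(m)) return(c(ani = NA_real_, af = 0))
    mapped <- m[m$coverage >= 0.8 & m$identity >= minFragmentIdentity, ,
                drop = FALSE]
    c(ani = if (nrow(mapped)) mean(mapped$identity) else NA_real_,
      af = nrow(mapped) / length(frags))
  }
  ab <- oneWay(a, b)
  ba <- oneWay(b, a)
  defAb <- !is.na(ab["ani"]) && ab["af"] >= minAlignedFraction
  defBa <- !is.na(ba["ani"]) && ba["af"] >= minAlignedFraction
  vals <- c(if (defAb) ab[["ani"]], if (defBa) ba[["ani"]])
  list(ani = if (length(vals)) mean(vals) else NA_real_,
       aligned_fraction = max(ab[["af"]], ba[["af"]]),
       ani_defined = defAb || defBa,
       ani_ab = ab[["ani"]], ani_ba = ba[["ani"]],
       af_ab = ab[["af"]], af_ba = ba[["af"]])
}

#' Tetranucleotide frequency profile
#'
#' Counts every 4-mer over both strands of every contig (the profile of a
#' sequence equals the profile of its reverse complement); 4-mers
#' containing non-ACGT symbols are skipped.
#'
#' @param contigs Character vector or DNAStringSet.
#' @return Object of class `TetraProfile`: integer `counts` (length 256,
#'   named by 4-mer) and `total`.
#' @export
tetraProfile <- function(contigs) {
  x <- Biostrings::DNAStringSet(as.character(contigs))
  if (sum(Biostrings::width(x)) < 4) stop("total sequence length < 4")
  fw <- Biostrings::oligonucleotideFrequency(x, width = 4)
  rv <- Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(x),
                                             width = 4)
  counts <- colSums(fw) + colSums(rv)
  if (sum(counts) == 0) stop("no usable 4-mers")
  structure(list(counts = counts, total = sum(counts)),
            class = "TetraProfile")
}

#' Pearson correlation of two tetranucleotide profiles
#'
#' Computed on the frequency vectors (counts/total) over all 256
#' coordinates.
#'
#' @param p,q `TetraProfile` objects from [tetraProfile()].
#' @return Correlation in `[-1, 1]`.
#' @export
profileCorrelation <- function(p, q) {
  stopifnot(inherits(p, "TetraProfile"), inherits(q, "TetraProfile"))
  cor(p$counts / p$total, q$counts / q$total)
}

#' Single-copy marker gene homology between two SAGs
#'
#' For every marker present in exactly one copy in both SAGs, the two
#' extracted copies are compared over the intersection of their
#' marker-coordinate spans (strand-normalised; alignment is gap-free
#' because divergence is substitution-only). Homology is the mean percent
#' identity over the shared single-copy markers and is undefined (`NA`)
#' when fewer than `minShared` markers are shared.
#'
#' @param hitsA,hitsB Marker hits from [detectMarkers()] for the two SAGs.
#' @param contigsA,contigsB The corresponding contig sets (named).
#' @param minShared Minimum number of shared single-copy markers
#'   (default 3).
#' @param minOverlap Minimum overlap (bp) of the two copies for a marker
#'   to contribute.
#' @return List with `homology` (percent or `NA`) and `n_shared`.
#' @export
markerHomology <- function(hitsA, contigsA, hitsB, contigsB,
                           minShared = 3, minOverlap = 50) {
  contigsA <- asSeqChar(contigsA)
  contigsB <- asSeqChar(contigsB)
  singleA <- names(which(table(hitsA$marker_id) == 1))
  singleB <- names(which(table(hitsB$marker_id) == 1))
  shared <- intersect(singleA, singleB)
  idents <- numeric()
  for (m in shared) {
    ha <- hitsA[hitsA$marker_id == m, ]
    hb <- hitsB[hitsB$marker_id == m, ]
    lo <- max(ha$q_start, hb$q_start)
    hi <- min(ha$q_end, hb$q_end)
    if (hi - lo < minOverlap) next
    idents <- c(idents, 100 * (1 - mismatchFraction(
      extractMarkerCopy(ha, contigsA, lo, hi),
      extractMarkerCopy(hb, contigsB, lo, hi))))
  }
  list(homology = if (length(idents) >= minShared) mean(idents) else NA_real_,
       n_shared = length(idents))
}

# extract the part of a marker hit corresponding to marker coords [lo, hi),
# oriented to the marker's strand
extractMarkerCopy <- function(hit, contigs, lo, hi) {
  ctg <- contigs[[hit$contig_id]]
  if (hit$strand == "+") {
    s <- hit$start + (lo - hit$q_start)
    substr(ctg, s + 1L, s + (hi - lo))
  } else {
    # on '-' hits, increasing marker coordinate runs right-to-left on contig
    e <- hit$end - (lo - hit$q_start)
    revComp(substr(ctg, e - (hi - lo) + 1L, e))
  }
}

#' All-pairs similarity table
#'
#' Computes ANI (+aligned fraction), tetranucleotide correlation and
#' single-copy marker homology for every unordered SAG pair.
#'
#' @param sagContigs Named list of contig sets.
#' @param markers A [MarkerSet-class].
#' @param fragmentLen,k,minFragmentIdentity,minAlignedFraction Passed to
#'   [computeAni()].
#' @param minSharedMarkers Passed to [markerHomology()].
#' @param verbose Print progress.
#' @return data.frame `sag_a`, `sag_b`, `ani`, `ani_defined`,
#'   `aligned_fraction`, `tetra_corr`, `marker_homology` — one row per
#'   unordered pair with `sag_a < sag_b`.
#' @export
pairwiseSimilarity <- function(sagContigs, markers, fragmentLen = 1000,
                               k = 16, minFragmentIdentity = 80,
                               minAlignedFraction = 0.2,
                               minSharedMarkers = 3, verbose = FALSE) {
  ids <- sortC(names(sagContigs))
  profs <- lapply(sagContigs[ids], tetraProfile)
  mhits <- lapply(sagContigs[ids], detectMarkers, markers = markers)

  # one-way ANI for all ordered pairs, with one k-mer index per target:
  # map the pooled fragments of every other SAG in a single call
  frags <- lapply(sagContigs[ids], cutFragments, fragmentLen = fragmentLen)
  nfrag <- lengths(frags)
  aniOne <- array(NA_real_, dim = c(length(ids), length(ids)),
                  dimnames = list(ids, ids))
  afOne <- array(0, dim = dim(aniOne), dimnames = dimnames(aniOne))
  for (j in seq_along(ids)) {
    refs <- as.character(sagContigs[[ids[j]]])
    if (!length(refs) || max(nchar(refs)) < fragmentLen) next
    others <- ids[-j][nfrag[ids[-j]] > 0]
    if (!length(others)) next
    qsag <- rep(others, nfrag[others])
    m <- cpp_map(unlist(frags[others], use.names = FALSE), unname(refs),
                 k = k, local = FALSE, best_only = TRUE)
    mapped <- m[m$coverage >= 0.8 & m$identity >= minFragmentIdentity, ,
                drop = FALSE]
    msag <- qsag[mapped$query]
    for (a in others) {
      sel <- msag == a
      afOne[a, ids[j]] <- sum(sel) / nfrag[a]
      if (any(sel)) aniOne[a, ids[j]] <- mean(mapped$identity[sel])
    }
    if (verbose) message("ani: ", j, "/", length(ids))
  }

  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      a <- ids[i]; b <- ids[j]
      defAb <- !is.na(aniOne[a, b]) && afOne[a, b] >= minAlignedFraction
      defBa <- !is.na(aniOne[b, a]) && afOne[b, a] >= minAlignedFraction
      vals <- c(if (defAb) aniOne[a, b], if (defBa) aniOne[b, a])
      mh <- markerHomology(mhits[[a]], sagContigs[[a]],
                           mhits[[b]], sagContigs[[b]],
                           minShared = minSharedMarkers)
      rows[[length(rows) + 1L]] <- data.frame(sag_a = a, sag_b = b,
        ani = if (length(vals)) mean(vals) else NA_real_,
        ani_defined = defAb || defBa,
        aligned_fraction = max(afOne[a, b], afOne[b, a]),
        tetra_corr = profileCorrelation(profs[[a]], profs[[b]]),
        marker_homology = mh$homology, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sag_a = character(), sag_b = character(),
      ani = numeric(), ani_defined = logical(),
      aligned_fraction = numeric(), tetra_corr = numeric(),
      marker_homology = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write / read the similarity table
#'
#' Full-precision TSV round-trip of the [pairwiseSimilarity()] output.
#'
#' @param sim Similarity data.frame.
#' @param path File path.
#' @return `readSimilarityTsv` returns the data.frame.
#' @export
writeSimilarityTsv <- function(sim, path) {
  out <- sim
  for (cn in names(out))
    if (is.double(out[[cn]]))
      out[[cn]] <- sprintf("%.17g", out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSimilarityTsv
#' @export
readSimilarityTsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$ani_defined <- as.logical(x$ani_defined)
  x
}

#' Square similarity matrix
#'
#' Expands the pair table into a symmetric matrix (diagonal = `diag`),
#' suitable for CSV export and heatmap plotting.
#'
#' @param sim Similarity data.frame.
#' @param value Column to expand (default `"ani"`).
#' @param diag Diagonal value (default 100 for ANI).
#' @return A symmetric numeric matrix.
#' @export
similarityMatrix <- function(sim, value = "ani", diag = 100) {
  ids <- sortC(unique(c(sim$sag_a, sim$sag_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- diag
  for (i in seq_len(nrow(sim))) {
    m[sim$sag_a[i], sim$sag_b[i]] <- sim[[value]][i]
    m[sim$sag_b[i], sim$sag_a[i]] <- sim[[value]][i]
  }
  m
}
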