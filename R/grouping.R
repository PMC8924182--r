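# Dataset adoption and three-criteria strain grouping: SAG pairs that pass
# ANI > 98, single-copy marker homology > 99.9 and tetranucleotide
# correlation > 0.90 are joined; strain groups are the connected
# components (single-linkage at the stated thresholds).

#' Grouping thresholds
#'
#' Defaults are the strain-grouping working points of the emulated study:
#' ANI > 98 percent, single-copy marker gene homology > 99.9 percent,
#' tetranucleotide frequency correlation > 0.90 for the same-strain
#' criteria; dataset adoption requires ANI to be computable against more
#' than 75 percent of same-species SAGs with a maximum ANI above 98.5
#' percent. All comparisons are strict.
#'
#' @param minAni,minMarkerHomology,minTetraCorr Edge criteria.
#' @param adoptionMinAniCoverage,adoptionMinMaxAni Adoption criteria.
#' @return A validated list of class `GroupingThresholds`.
#' @export
groupingThresholds <- function(minAni = 98, minMarkerHomology = 99.9,
                               minTetraCorr = 0.90,
                               adoptionMinAniCoverage = 0.75,
                               adoptionMinMaxAni = 98.5) {
  stopifnot(minAni >= 0, minAni <= 100,
            minMarkerHomology >= 0, minMarkerHomology <= 100,
            minTetraCorr >= -1, minTetraCorr <= 1,
            adoptionMinAniCoverage >= 0, adoptionMinAniCoverage <= 1,
            adoptionMinMaxAni >= 0, adoptionMinMaxAni <= 100)
  structure(list(minAni = minAni, minMarkerHomology = minMarkerHomology,
    minTetraCorr = minTetraCorr,
    adoptionMinAniCoverage = adoptionMinAniCoverage,
    adoptionMinMaxAni = adoptionMinMaxAni), class = "GroupingThresholds")
}

#' Dataset adoption rule
#'
#' A SAG is adopted iff, among the other SAGs assigned to the same
#' species, the fraction of pairs with a defined ANI exceeds
#' `adoptionMinAniCoverage` AND its maximum defined ANI exceeds
#' `adoptionMinMaxAni` (both strict). SAGs that are the only member of
#' their species have no pairs and are not adopted (logged).
#'
#' @param sagIds Character vector of SAG ids.
#' @param similarities Pair table from [pairwiseSimilarity()].
#' @param speciesAssignment Named character vector mapping each SAG id to
#'   a species label.
#' @param thresholds A [groupingThresholds()] object.
#' @return data.frame `sag_id`, `species`, `ani_coverage`, `max_ani`,
#'   `adopted`, `reason` (`NA` when adopted).
#' @export
adoptDataset <- function(sagIds, similarities, speciesAssignment,
                         thresholds = groupingThresholds()) {
  rows <- lapply(sortC(sagIds), function(s) {
    sp <- unname(speciesAssignment[s])
    peers <- setdiff(sagIds[speciesAssignment[sagIds] == sp], s)
    if (!length(peers) || is.na(sp)) {
      return(data.frame(sag_id = s, species = sp, ani_coverage = NA_real_,
        max_ani = NA_real_, adopted = FALSE,
        reason = if (is.na(sp)) "unassigned" else "single_sag_species",
        stringsAsFactors = FALSE))
    }
    rel <- similarities[(similarities$sag_a == s &
                           similarities$sag_b %in% peers) |
                        (similarities$sag_b == s &
                           similarities$sag_a %in% peers), , drop = FALSE]
    cov <- sum(rel$ani_defined) / length(peers)
    mx <- if (any(rel$ani_defined)) max(rel$ani[rel$ani_defined]) else -Inf
    ok <- cov > thresholds$adoptionMinAniCoverage &&
      mx > thresholds$adoptionMinMaxAni
    data.frame(sag_id = s, species = sp, ani_coverage = cov,
      max_ani = ifelse(is.finite(mx), mx, NA_real_), adopted = ok,
      reason = if (ok) NA_character_
               else if (cov <= thresholds$adoptionMinAniCoverage)
                 "ani_coverage" else "max_ani",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build strain groups from the three-criteria graph
#'
#' An edge joins two adopted SAGs iff their ANI is defined and exceeds
#' `minAni`, their marker homology exceeds `minMarkerHomology` and their
#' tetranucleotide correlation exceeds `minTetraCorr` (all strict;
#' undefined values never create edges). Strain groups are the connected
#' components of this graph — single linkage cut at the thresholds — with
#' deterministic group ids taken from the lexicographically smallest
#' member. An alternative `linkage = "average_ani"` mode clusters the
#' adopted SAGs by average-linkage hierarchical clustering on ANI distance
#' and cuts at `minAni`.
#'
#' @param adopted Character vector of adopted SAG ids (e.g. from
#'   [adoptDataset()]).
#' @param similarities Pair table from [pairwiseSimilarity()] covering the
#'   adopted pairs.
#' @param thresholds A [groupingThresholds()] object.
#' @param linkage `"components"` (default; joint three-criteria graph) or
#'   `"average_ani"` (sensitivity mode).
#' @return data.frame `group_id`, `sag_id`; groups partition the adopted
#'   set.
#' @export
buildStrainGroups <- function(adopted, similarities,
                              thresholds = groupingThresholds(),
                              linkage = c("components", "average_ani")) {
  linkage <- match.arg(linkage)
  ids <- sortC(adopted)
  if (!length(ids))
    return(data.frame(group_id = character(), sag_id = character(),
                      stringsAsFactors = FALSE))
  s <- similarities[similarities$sag_a %in% ids &
                      similarities$sag_b %in% ids, , drop = FALSE]
  if (linkage == "average_ani") {
    m <- similarityMatrix(s, "ani")
    d <- stats::as.dist(100 - m[ids, ids, drop = FALSE])
    d[is.na(d)] <- 100
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = 100 - thresholds$minAni)
    memb <- split(ids, cl)
  } else {
    edge <- !is.na(s$ani_defined) & s$ani_defined &
      !is.na(s$ani) & s$ani > thresholds$minAni &
      !is.na(s$marker_homology) &
      s$marker_homology > thresholds$minMarkerHomology &
      !is.na(s$tetra_corr) & s$tetra_corr > thresholds$minTetraCorr
    g <- igraph::graph_from_data_frame(
      s[edge, c("sag_a", "sag_b"), drop = FALSE],
      directed = FALSE, vertices = ids)
    cl <- igraph::components(g)$membership[ids]
    memb <- split(ids, cl)
  }
  memb <- lapply(memb, sortC)
  memb <- memb[order(vapply(memb, `[`, character(1), 1), method = "radix")]
  do.call(rbind, c(lapply(memb, function(m)
    data.frame(group_id = paste0("G_", m[1]), sag_id = m,
               stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
}

#' Write strain groups as JSON plus a membership TSV
#'
#' @param groups data.frame from [buildStrainGroups()].
#' @param speciesAssignment Optional named species labels.
#' @param jsonPath,tsvPath Output paths (either may be `NULL`).
#' @return Invisibly, the JSON-ready list.
#' @export
writeStrainGroups <- function(groups, speciesAssignment = NULL,
                              jsonPath = NULL, tsvPath = NULL) {
  gl <- lapply(split(groups$sag_id, groups$group_id), function(m) {
    sp <- if (!is.null(speciesAssignment))
      unique(unname(speciesAssignment[m])) else NULL
    list(members = sortC(m),
         species_label = if (length(sp) == 1) sp else "mixed")
  })
  gl <- gl[sortC(names(gl))]
  if (!is.null(jsonPath))
    jsonlite::write_json(gl, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsvPath))
    write.table(groups, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(gl)
}
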