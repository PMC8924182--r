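# Viability and composition profiling: positive-capsule fractions per PMA
# dose, nearest-reference taxonomy assignment, species composition and
# strain abundance as a function of dose.

#' Nearest-reference taxonomy assignment
#'
#' Each SAG is assigned to the reference genome with the maximal
#' symmetrised ANI; assignments below `speciesAniFloor` (default 95, the
#' conventional species boundary) are labeled `"unassigned"`.
#'
#' @param sagContigs Named list of per-SAG contig sets.
#' @param panel A [ReferencePanel-class] (or named list of reference
#'   genome sequences plus a `speciesMap` named vector).
#' @param speciesAniFloor Confidence floor in percent ANI.
#' @param fragmentLen Fragment size for [computeAni()].
#' @return data.frame `sag_id`, `assigned_reference_id`,
#'   `assigned_species_label`, `best_ani`, `confident`.
#' @export
assignTaxonomy <- function(sagContigs, panel, speciesAniFloor = 95,
                           fragmentLen = 1000) {
  if (is(panel, "ReferencePanel")) {
    refs <- as.character(genomes(panel))
    speciesMap <- setNames(strainInfo(panel)$species_id,
                           strainInfo(panel)$strain_id)
  } else {
    refs <- as.character(panel$genomes)
    speciesMap <- panel$speciesMap
  }
  if (!length(refs)) stop("empty reference panel")
  rows <- lapply(sortC(names(sagContigs)), function(s) {
    ctg <- as.character(sagContigs[[s]])
    best <- NA_character_; bestAni <- NA_real_
    if (length(ctg) && sum(nchar(ctg)) >= fragmentLen) {
      for (r in names(refs)) {
        ani <- tryCatch(
          computeAni(ctg, refs[[r]], fragmentLen = fragmentLen),
          error = function(e) list(ani = NA_real_, ani_defined = FALSE))
        if (ani$ani_defined && (is.na(bestAni) || ani$ani > bestAni)) {
          bestAni <- ani$ani; best <- r
        }
      }
    }
    conf <- !is.na(bestAni) && bestAni >= speciesAniFloor
    data.frame(sag_id = s,
      assigned_reference_id = if (conf) best else NA_character_,
      assigned_species_label = if (conf) unname(speciesMap[best])
                               else "unassigned",
      best_ani = bestAni, confident = conf, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Positive-capsule fraction per condition
#'
#' Fraction of capsules with amplified DNA, with an exact binomial 95
#' percent confidence interval, per PMA dose.
#'
#' @param capsules data.frame with columns `positive` and `pma_dose`
#'   (e.g. from [simulateCapsules()]), or counts via `positives` /
#'   `totals`.
#' @param positives,totals Optional named numeric vectors (per condition)
#'   used instead of `capsules`.
#' @return data.frame `pma_dose`, `n_capsules`, `n_positive`, `fraction`,
#'   `ci_lo`, `ci_hi`.
#' @export
positivityReport <- function(capsules = NULL, positives = NULL,
                             totals = NULL) {
  if (is.null(capsules)) {
    stopifnot(!is.null(positives), !is.null(totals),
              identical(names(positives), names(totals)))
    doses <- names(totals)
    pos <- as.integer(positives)
    tot <- as.integer(totals)
  } else {
    doses <- sortC(unique(as.character(capsules$pma_dose)))
    tot <- vapply(doses, function(d)
      sum(capsules$pma_dose == as.numeric(d)), integer(1))
    pos <- vapply(doses, function(d)
      sum(capsules$positive[capsules$pma_dose == as.numeric(d)]),
      integer(1))
  }
  if (!length(tot) || any(tot == 0))
    stop("zero capsules in a condition")
  ci <- t(vapply(seq_along(tot), function(i)
    binom.test(pos[i], tot[i])$conf.int, numeric(2)))
  data.frame(pma_dose = doses, n_capsules = tot, n_positive = pos,
    fraction = pos / tot, ci_lo = ci[, 1], ci_hi = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Composition profile over assigned SAGs
#'
#' Relative abundance of each label among assigned (confident) SAGs,
#' optionally per dose. Fractions sum to 1 over the assigned SAGs of a
#' dose; a dose with no assigned SAGs of any label yields `"N.D."` rows.
#'
#' @param assignments data.frame from [assignTaxonomy()] with an added
#'   `pma_dose` column.
#' @param level `"species"` or a named label map (e.g. family rollup)
#'   applied to `assigned_species_label`.
#' @return data.frame `pma_dose`, `label`, `n`, `fraction`.
#' @export
compositionProfile <- function(assignments, level = "species") {
  a <- assignments[assignments$confident, , drop = FALSE]
  lab <- a$assigned_species_label
  if (!identical(level, "species")) lab <- unname(level[lab])
  doses <- sortC(unique(as.character(assignments$pma_dose)))
  rows <- list()
  for (d in doses) {
    sel <- as.character(a$pma_dose) == d
    if (!any(sel)) {
      rows[[length(rows) + 1L]] <- data.frame(pma_dose = d, label = "N.D.",
        n = 0L, fraction = NA_real_, stringsAsFactors = FALSE)
      next
    }
    tab <- table(lab[sel])
    rows[[length(rows) + 1L]] <- data.frame(pma_dose = d,
      label = names(tab), n = as.integer(tab),
      fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Strain abundance as a function of PMA dose
#'
#' Per dose and species: the fraction of that species' SAGs that fall in
#' each strain group. Doses with no SAGs of the species yield an `"N.D."`
#' row (not detected).
#'
#' @param assignments data.frame from [assignTaxonomy()] with `pma_dose`.
#' @param groups data.frame from [buildStrainGroups()].
#' @return data.frame `pma_dose`, `species`, `group_id`, `n`, `fraction`.
#' @export
strainAbundanceByDose <- function(assignments, groups) {
  g <- setNames(groups$group_id, groups$sag_id)
  a <- assignments[assignments$confident &
                     assignments$sag_id %in% names(g), , drop = FALSE]
  doses <- sortC(unique(as.character(assignments$pma_dose)))
  species <- sortC(unique(a$assigned_species_label))
  rows <- list()
  for (sp in species) {
    for (d in doses) {
      sel <- a$assigned_species_label == sp & as.character(a$pma_dose) == d
      if (!any(sel)) {
        rows[[length(rows) + 1L]] <- data.frame(pma_dose = d, species = sp,
          group_id = "N.D.", n = 0L, fraction = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      tab <- table(g[a$sag_id[sel]])
      rows[[length(rows) + 1L]] <- data.frame(pma_dose = d, species = sp,
        group_id = names(tab), n = as.integer(tab),
        fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pma_dose = character(), species = character(),
      group_id = character(), n = integer(), fraction = numeric(),
      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
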