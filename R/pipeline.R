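# End-to-end orchestration: a validated flat config, deterministic staged
# execution (simulate -> qc -> similarity -> group -> clean -> coassemble
# -> profile) and a manifest, with every stage writing self-describing
# TSV/JSON outputs.

pipelineConfigDefaults <- function() {
  list(
    run_id = "run", master_seed = 1L, output_dir = "cosag_run",
    # simulator
    n_species = 2L, strains_per_species = 2L, genome_length = 50000L,
    within_strain_div = 0.0005, between_strain_div = 0.015,
    between_species_div = 0.25, n_markers = 24L, marker_length = 200L,
    lambda_cells_per_droplet = 0.35, n_capsules = 100L,
    pma_doses = c(0, 5), viable_fraction = 0.7, free_dna_rate = 0.05,
    reads_per_positive_capsule = 8000L, read_length = 150L, paired = TRUE,
    coverage_window = 1000L, log_sd_amplification = 1.5,
    chimera_rate = 0.02,
    # qc filters
    min_read_bases = 1e6, min_completeness = 20, max_contamination = 10,
    min_contig_len = 1000L,
    # similarity
    ani_fragment_len = 1000L, ani_k = 16L, min_fragment_identity = 80,
    min_aligned_fraction = 0.2,
    # grouping
    min_ani = 98, min_marker_homology = 99.9, min_tetra_corr = 0.90,
    adoption_min_ani_coverage = 0.75, adoption_min_max_ani = 98.5,
    # cleaning
    min_fragment_len = 20L, full_fraction = 0.95,
    chimera_min_aligned_fraction = 0.1, max_clean_cycles = 3L,
    # coassembly
    assembler_k = 31L, min_kmer_count = 2L, min_members = 3L, max_members = 8L,
    max_total_contamination = 5.0,
    # profiling
    species_ani_floor = 95)
}

#' Pipeline configuration
#'
#' Builds a validated configuration list. Every threshold default is the
#' emulated study's stated working point (ANI > 98, marker homology >
#' 99.9, tetra correlation > 0.90, completeness > 20, contamination < 10,
#' total contamination < 5 over 3-8 members, 20 bp fragment floor,
#' 1000 bp contig floor, 1 Mb read-yield floor, adoption at 75 percent /
#' 98.5 ANI, 0.35 cells per droplet). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (see
#'   `CoSAG:::pipelineConfigDefaults()`).
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  defaults <- pipelineConfigDefaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all config entries must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$lambda_cells_per_droplet > 0, cfg$n_capsules > 0,
            cfg$min_fragment_len >= 1, cfg$assembler_k %% 2 == 1)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file is a flat YAML mapping whose keys mirror the
#' [pipelineConfig()] field names; unknown keys are rejected before any
#' stage runs.
#'
#' @param path Path to the config file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' Run the full pipeline
#'
#' Stages run in order simulate, qc, similarity, group, clean, coassemble,
#' profile. Each stage writes its outputs under `output_dir`, and a
#' manifest records the package version, seeds and output digests.
#' Re-running with an identical config produces byte-identical TSV/JSON
#' outputs.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param writeReads Also write per-capsule FASTQ files (off by default to
#'   keep run directories small).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config, writeReads = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  # --- simulate ---------------------------------------------------------
  markers <- randomMarkerSet(n = config$n_markers,
    length = config$marker_length,
    seed = deriveSeed(config$master_seed, "markers"))
  panel <- generateReferenceSet(nSpecies = config$n_species,
    strainsPerSpecies = config$strains_per_species,
    genomeLength = config$genome_length,
    withinStrainDiv = config$within_strain_div,
    betweenStrainDiv = config$between_strain_div,
    betweenSpeciesDiv = config$between_species_div,
    markers = markers, seed = deriveSeed(config$master_seed, "panel"))
  si <- strainInfo(panel)
  members <- data.frame(strain_id = si$strain_id,
    relative_abundance = rep(1 / nrow(si), nrow(si)),
    viable_fraction = config$viable_fraction)
  mda <- mdaParams(readLength = config$read_length, paired = config$paired,
    readsPerPositiveCapsule = config$reads_per_positive_capsule,
    coverageWindow = config$coverage_window,
    logSdAmplification = config$log_sd_amplification,
    chimeraRate = config$chimera_rate)
  sims <- list()
  for (d in config$pma_doses) {
    spec <- communitySpec(members, pmaDose = d,
      lambda = config$lambda_cells_per_droplet,
      nCapsules = config$n_capsules, freeDnaRate = config$free_dna_rate,
      mda = mda, seed = deriveSeed(config$master_seed, paste0("dose", d)))
    sims[[as.character(d)]] <- simulateRun(panel, spec)
  }
  Biostrings::writeXStringSet(genomes(panel), out("panel.fasta"))
  capsules <- do.call(rbind, c(lapply(sims, `[[`, "capsules"),
                               list(make.row.names = FALSE)))
  write.table(capsules, out("capsules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- per-SAG assembly + qc -------------------------------------------
  readSets <- list()
  contigSets <- list()
  sagDose <- character()
  sagCapsule <- character()
  for (d in names(sims)) {
    sim <- sims[[d]]
    for (cid in names(sim$reads)) {
      sid <- paste0("d", d, "_", cid)
      readSets[[sid]] <- sim$reads[[cid]]
      contigSets[[sid]] <- suppressWarnings(coassemble(sim$reads[[cid]],
        k = config$assembler_k, minContigLen = config$min_contig_len,
        minKmerCount = config$min_kmer_count))
      sagDose[sid] <- d
      sagCapsule[sid] <- cid
      if (writeReads)
        writeFastq(sim$reads[[cid]], out(paste0(sid, ".fastq")))
    }
  }
  readBases <- vapply(readSets, function(r) sum(nchar(r)), numeric(1))
  qc <- sagQcTable(contigSets, readBases, markers,
    minContigLen = config$min_contig_len,
    minReadBases = config$min_read_bases,
    minCompleteness = config$min_completeness,
    maxContamination = config$max_contamination)
  qc$pma_dose <- unname(sagDose[qc$sag_id])
  write.table(qc, out("sag_qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  kept <- qc$sag_id[qc$kept]

  # --- taxonomy + similarity -------------------------------------------
  tax <- assignTaxonomy(contigSets[kept], panel,
    speciesAniFloor = config$species_ani_floor,
    fragmentLen = config$ani_fragment_len)
  tax$pma_dose <- unname(sagDose[tax$sag_id])
  write.table(tax, out("taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sim <- pairwiseSimilarity(contigSets[kept], markers,
    fragmentLen = config$ani_fragment_len, k = config$ani_k,
    minFragmentIdentity = config$min_fragment_identity,
    minAlignedFraction = config$min_aligned_fraction)
  writeSimilarityTsv(sim, out("similarity.tsv"))

  # --- adoption + grouping ---------------------------------------------
  thr <- groupingThresholds(minAni = config$min_ani,
    minMarkerHomology = config$min_marker_homology,
    minTetraCorr = config$min_tetra_corr,
    adoptionMinAniCoverage = config$adoption_min_ani_coverage,
    adoptionMinMaxAni = config$adoption_min_max_ani)
  speciesMap <- setNames(tax$assigned_species_label, tax$sag_id)
  adoption <- adoptDataset(kept, sim, speciesMap, thr)
  write.table(adoption, out("adoption.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  groups <- buildStrainGroups(adoption$sag_id[adoption$adopted], sim, thr)
  writeStrainGroups(groups, speciesMap, out("strain_groups.json"),
                    out("strain_groups.tsv"))

  # --- clean + coassemble ----------------------------------------------
  co <- coassembleGroups(groups, qc, readSets, contigSets, markers,
    k = config$assembler_k, minContigLen = config$min_contig_len,
    minKmerCount = config$min_kmer_count,
    maxCycles = config$max_clean_cycles)
  dir.create(out("cosag"), showWarnings = FALSE)
  for (gid in names(co$cosags)) {
    x <- Biostrings::DNAStringSet(co$cosags[[gid]])
    Biostrings::writeXStringSet(x, out("cosag", paste0(gid, ".fasta")))
  }
  write.table(co$stats, out("cosag_stats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(co$cleanReports)) {
    cr <- do.call(rbind, c(co$cleanReports, list(make.row.names = FALSE)))
    cr <- cbind(group_id = names(co$cleanReports), cr)
    write.table(cr, out("clean_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # --- profile ----------------------------------------------------------
  positivity <- positivityReport(capsules)
  comp <- compositionProfile(tax)
  strainAb <- strainAbundanceByDose(tax, groups)
  jsonlite::write_json(list(positivity = positivity, composition = comp,
    strain_abundance = strainAb), out("profile_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")

  cfgEcho <- unclass(config)
  cfgEcho$output_dir <- NULL # manifest is location-independent
  manifest <- list(package = "CoSAG",
    version = as.character(utils::packageVersion("CoSAG")),
    run_id = config$run_id, master_seed = config$master_seed,
    config = cfgEcho,
    n_sags = length(readSets), n_kept = length(kept),
    n_groups = length(unique(groups$group_id)),
    digests = as.list(tools::md5sum(sortC(list.files(config$output_dir,
      pattern = "\\.(tsv|json|fasta)$", full.names = TRUE,
      recursive = TRUE)))))
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(panel = panel, markers = markers, sims = sims, qc = qc,
    taxonomy = tax, similarity = sim, adoption = adoption, groups = groups,
    coassembly = co, positivity = positivity, composition = comp,
    strain_abundance = strainAb, manifest = manifest))
}

#' Bundled smoke configuration
#'
#' A small, fast configuration (2 species x 2 strains, 50 kb genomes,
#' 150 capsules per dose at doses 0 and 5 uM) with filter thresholds
#' scaled to the toy genome size; intended for end-to-end determinism
#' checks and examples.
#'
#' @param outputDir Output directory.
#' @param seed Master seed.
#' @return A `PipelineConfig`.
#' @export
smokeConfig <- function(outputDir = tempfile("cosag_smoke_"), seed = 1) {
  readPipelineConfigDefaultsPath <- system.file("extdata",
    "smoke_config.yaml", package = "CoSAG")
  cfg <- readPipelineConfig(readPipelineConfigDefaultsPath)
  cfg$output_dir <- outputDir
  cfg$master_seed <- as.integer(seed)
  cfg
}
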