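#' Default pipeline configuration
#'
#' One seeded end-to-end run on synthetic data: cohort simulation,
#' in-silico MassCleave measurement of the example assay, QC filtering,
#' discordance statistics, LOM/GOM concordance, genotype stratification
#' and the planted-signal motif analysis. All study thresholds (0.75
#' coverage, 0.10 call cutoff, 0.80 motif match, 500-bp flank) are
#' configuration values, not constants in code.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param outdir output directory.
#' @param nMZ,nDZ pair counts.
#' @return nested list, suitable for \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1L, outdir = "twinmeth-run",
                                  nMZ = 128L, nDZ = 128L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = c("simulate", "massarray", "qc", "discordance", "lomgom",
               "genostrat", "ctcf"),
    simulate = list(nMZ = nMZ, nDZ = nDZ, missingRate = 0.05,
                    beta = 0.15, freq = 0.5),
    qc = list(minCoverage = 0.75, excludeUnits = character(),
              alpha = 1e-4),
    lomgom = list(cutoff = 0.10, cutoffs = c(0.05, 0.10, 0.15, 0.20)),
    genostrat = list(snp = "rs10732516",
                     units = c("H19-ICR:u02", "H19-ICR:u03",
                               "H19-ICR:u04")),
    ctcf = list(minMatch = 0.85, flank = 500L, position = 6,
                from = "C", to = "T")
  )
}

#' Read a pipeline configuration file
#'
#' JSON (default) or YAML (by extension). Unknown stage names are
#' rejected at validation time.
#'
#' @param file path to a config file.
#' @return config list.
#' @export
readPipelineConfig <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(file)
  } else jsonlite::read_json(file, simplifyVector = TRUE)
  base <- defaultPipelineConfig()
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && nm %in% names(base))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

.validate_config <- function(config) {
  known <- c("simulate", "massarray", "qc", "discordance", "lomgom",
             "genostrat", "ctcf")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("unknown pipeline stage: ", paste(bad, collapse = ", "))
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stop("config$seed must be a single integer")
  invisible(TRUE)
}

#' Run the synthetic-data analysis pipeline
#'
#' Executes the configured stages in dependency order (simulate ->
#' massarray -> qc -> discordance -> lomgom -> genostrat -> ctcf),
#' writes each stage's tables under \code{config$outdir} and a JSON run
#' manifest recording package version, seeds and parameters. Re-running
#' with the same configuration reproduces the outputs byte-identically.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or path to a config file.
#' @return invisibly, a list of in-memory stage results plus
#'   \code{manifest}.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  .validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  seed <- as.integer(config$seed)
  path <- function(f) file.path(config$outdir, f)
  want <- function(s) s %in% config$stages
  need <- function(s, what) if (is.null(out[[what]]))
    stop("stage '", s, "' needs missing upstream output '", what, "'")

  if (want("simulate")) {
    sc <- config$simulate
    cohort <- simulatePedigree(sc$nMZ, sc$nDZ, seed = seed)
    snps <- defaultSnpModels(beta = sc$beta, freq = sc$freq)
    geno <- simulateGenotypes(cohort, snps, seed = seed + 1L)
    mset <- simulateMethylation(cohort, geno, defaultRegionModels(),
                                snps, seed = seed + 2L)
    mset <- applyMissingness(mset, sc$missingRate, seed = seed + 3L)
    writeCohort(cohort, path("cohort.tsv"))
    writeGenotypes(geno, path("genotypes.tsv"))
    writeMethTable(mset, path("methylation.tsv"))
    out$cohort <- cohort; out$genotypes <- geno; out$mset <- mset
  }

  if (want("massarray")) {
    design <- exampleH19Design()
    um <- buildUnitMap(design)
    writeUnitMap(um, path("assay_report.tsv"))
    k <- length(design@cpgSites)
    states <- list(
      patterns = rbind(rep(1L, k), rep(0L, k)),
      abundance = c(0.42, 0.58))
    sp <- simulateSpectrum(design, states, noiseSd = 0.05,
                           seed = seed + 4L)
    writeSpectrum(sp, path("spectrum.tsv"))
    out$unitMap <- um
    out$spectrumEstimates <- estimateMethylation(sp, um)
  }

  if (want("qc")) {
    need("qc", "mset")
    qc <- config$qc
    filtered <- filterUnits(out$mset, qc$minCoverage, qc$excludeUnits)
    out$filtered <- filtered
    out$summary <- summarizeUnits(filtered)
    out$correlations <- spearmanMatrix(filtered, alpha = qc$alpha)
    write.table(out$summary$units, path("unit_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$correlations$rho, path("spearman.tsv"),
                sep = "\t", quote = FALSE)
  }

  if (want("discordance")) {
    need("discordance", "filtered")
    nr <- makeNonrelatedPairs(out$cohort, seed = seed + 5L)
    disc <- rbind(
      pairDiscordance(out$filtered, out$cohort),
      pairDiscordance(out$filtered, nr))
    out$discordance <- disc
    out$discordanceTests <- lapply(
      split(disc, disc$region), function(d)
        kruskalWallisDunn(split(d$discordance, d$group)))
    write.table(disc, path("discordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (want("lomgom")) {
    need("lomgom", "filtered")
    lg <- config$lomgom
    calls <- callLomGom(out$filtered, cutoff = lg$cutoff)
    cls <- classifyPairConcordance(calls, out$cohort)
    out$concordance <- tabulateConcordance(cls)
    out$sweep <- cutoffSweep(out$filtered, out$cohort, lg$cutoffs)
    write.table(out$concordance, path("concordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (want("genostrat")) {
    need("genostrat", "filtered")
    gs <- config$genostrat
    groups <- assignOriginGroups(out$genotypes, gs$snp, phased = TRUE)
    out$genostrat <- methylationByGenotype(
      out$filtered, groups, units = gs$units, cohort = out$cohort)
    write.table(out$genostrat$summary, path("genostrat.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (want("ctcf")) {
    cc <- config$ctcf
    pwm <- exampleCtcfPWM()
    pg <- plantedMotifGenome(pwm, cc$position, cc$from, cc$to,
                             flank = cc$flank, seed = seed + 6L)
    hitsC <- scanPWM(pg$sequences, pwm, minMatch = cc$minMatch)
    hitsV <- scanPWM(pg$sequences, pg$variantPwm, minMatch = cc$minMatch)
    profC <- metaProfile(hitsC, pg$track, flank = cc$flank)
    profV <- metaProfile(hitsV, pg$track, flank = cc$flank)
    out$motif <- list(consensus = profC, variant = profV,
                      comparison = compareProfiles(profC, profV))
    writeBedHits(hitsC, path("ctcf_hits_consensus.bed"))
    writeBedHits(hitsV, path("ctcf_hits_variant.bed"))
    write.table(
      data.frame(offset = names(profC$profile),
                 consensus = unname(profC$profile),
                 variant = unname(profV$profile)),
      path("ctcf_profile.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  manifest <- list(
    package = "twinmeth",
    version = as.character(packageVersion("twinmeth")),
    seed = seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("outdir", "stages"))],
    outputs = sort(list.files(config$outdir))
  )
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
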