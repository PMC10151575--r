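## End-to-end orchestration: simulate or load inputs, QC, trait coding,
## heritability (pedigree and genomic), between-parity genetic correlations,
## genome scan (Bayes-Cpi then Bayes-B) and window report, with a JSON run
## manifest in the output directory.

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulation of a sow cohort; record QC; across- and
#' by-parity trait coding; threshold animal-model heritability with
#' pedigree and genomic relationships; bivariate genetic correlations for
#' requested parity pairs; Bayes-Cpi estimation of the inclusion prior
#' followed by a Bayes-B genome scan with 1 Mb window decomposition.  All
#' artifacts are plain text (CSV/TSV/JSON) under \code{outDir} together with
#' a run manifest.
#'
#' @param config named list or path to a YAML file.  Recognized entries:
#'   \code{seed}; \code{scenario} (arguments to \code{\link{simScenario}})
#'   or \code{records_csv} + \code{dose_csv} + \code{map_csv} (+ optional
#'   \code{pedigree_csv}); \code{parities} (default 2:6);
#'   \code{rg_pairs} (list of 2-vectors, default adjacent pairs);
#'   \code{chain} (\code{n_iter}, \code{burn_in}, \code{thin}),
#'   \code{chain_rg} likewise; \code{stages} (subset of \code{"h2"},
#'   \code{"rg"}, \code{"gwas"}).
#' @param outDir output directory (created).
#' @return invisible list with the main result objects (trait datasets,
#'   heritability table, correlation table, window results, manifest).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  parities <- as.integer(config$parities %||% 2:6)
  if (any(parities < 2L | parities > 6L))
    stop("parities must lie in 2..6 (low-incidence parities are excluded)")
  stages <- config$stages %||% c("h2", "rg", "gwas")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "swinePOP",
                   version = as.character(utils::packageVersion("swinePOP")),
                   seed = seed, started = format(Sys.time(), tz = "UTC"),
                   config = config, status = "running")
  manifestPath <- file.path(outDir, "manifest.json")
  .writeManifest <- function() jsonlite::write_json(
    manifest, manifestPath, auto_unbox = TRUE, pretty = TRUE, null = "null",
    force = TRUE)
  .writeManifest()
  on.exit(if (identical(manifest$status, "running")) {
    manifest$status <- "failed"; .writeManifest()
  })

  set.seed(seed)
  pedigree <- NULL
  if (!is.null(config$scenario)) {
    sc <- do.call(simScenario, c(config$scenario, list(seed = seed)))
    founders <- simulateGenotypes(sc, nInd = sc$nSires + sc$nDams,
                                  ids = c(sprintf("sire%04d", seq_len(sc$nSires)),
                                          sprintf("dam%04d", seq_len(sc$nDams))),
                                  returnHaplotypes = TRUE)
    sowIds <- sprintf("sow%05d", seq_len(sc$nSows))
    pedigree <- simulatePedigree(sc, sowIds)
    dropped <- geneDrop(founders, pedigree)
    keep <- match(sowIds, dropped$genotypes@ids)
    geno <- genotypeData(dropped$genotypes@dose[keep, , drop = FALSE],
                         dropped$genotypes@map, ids = sowIds)
    sim <- simulatePopRecords(geno, sc, pedigree = pedigree)
    records <- sim$records
    write.csv(records, file.path(outDir, "records.csv"), row.names = FALSE)
    writeDoseCSV(geno, file.path(outDir, "doses.csv"),
                 file.path(outDir, "map.csv"))
    write.csv(pedigree, file.path(outDir, "pedigree.csv"), row.names = FALSE)
    jsonlite::write_json(truthReport(sim$truth),
                         file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(config$records_csv) || is.null(config$dose_csv) ||
        is.null(config$map_csv))
      stop("config must give either a scenario or records_csv/dose_csv/map_csv")
    for (f in c(config$records_csv, config$dose_csv, config$map_csv))
      if (!file.exists(f)) stop("input file not found: ", f)
    records <- readSowRecords(config$records_csv)
    geno <- readDoseCSV(config$dose_csv, config$map_csv)
    if (!is.null(config$pedigree_csv))
      pedigree <- read.csv(config$pedigree_csv, stringsAsFactors = FALSE,
                           colClasses = "character")
  }

  qc <- qcFilter(records)
  jsonlite::write_json(qc$report, file.path(outDir, "qc_report.json"),
                       auto_unbox = TRUE)
  across <- codeAcrossParity(qc$records, parityRange = parities)
  writeTraitData(across, file.path(outDir, "trait_across.csv"))
  byParity <- lapply(parities, function(p) codeByParity(qc$records, p))
  names(byParity) <- as.character(parities)
  for (p in names(byParity))
    writeTraitData(byParity[[p]], file.path(outDir,
                                            sprintf("trait_parity%s.csv", p)))

  cchain <- function(defaults, cfg) {
    chainConfig(cfg$n_iter %||% defaults[1L], cfg$burn_in %||% defaults[2L],
                cfg$thin %||% defaults[3L], seed = seed)
  }
  chMain <- cchain(c(50000L, 5000L, 100L), config$chain %||% list())
  chRg <- cchain(c(120000L, 20000L, 100L), config$chain_rg %||% list())

  h2tab <- NULL
  if ("h2" %in% stages) {
    h2List <- list()
    genoAcross <- genotypeData(geno@dose[match(across@sowId, geno@ids), ,
                                         drop = FALSE], geno@map,
                               ids = across@sowId)
    G <- genomicRelationship(genoAcross)
    h2List[["across_genomic"]] <-
      heritabilityFromChain(fitBinaryAnimalModel(across, G, chMain,
                                                 link = "LOGIT",
                                                 includeParity = TRUE))
    if (!is.null(pedigree)) {
      A <- pedigreeRelationship(pedigree)
      h2List[["across_pedigree"]] <-
        heritabilityFromChain(fitBinaryAnimalModel(across, A, chMain,
                                                   link = "LOGIT",
                                                   includeParity = TRUE))
    }
    h2tab <- geneticParameterTable(h2List = h2List)
    inc <- mean(across@phenotype)
    h2tab$observed_scale <- underlyingToObserved(pmin(1, h2tab$estimate), inc)
    write.table(h2tab, file.path(outDir, "heritability.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }

  rgtab <- NULL
  if ("rg" %in% stages) {
    pairs <- config$rg_pairs %||%
      lapply(seq_len(length(parities) - 1L),
             function(i) parities[c(i, i + 1L)])
    rgList <- list()
    for (pr in pairs) {
      pr <- as.integer(pr)
      if (!all(pr %in% parities)) stop("rg pair outside analysed parities")
      fit <- fitBivariateLinear(byParity[[as.character(pr[1L])]],
                                byParity[[as.character(pr[2L])]], geno, chRg)
      rgList[[paste(pr, collapse = "_")]] <- geneticCorrelation(fit)
    }
    rgtab <- geneticParameterTable(rgList = rgList)
    write.table(rgtab, file.path(outDir, "genetic_correlations.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }

  winres <- NULL
  if ("gwas" %in% stages) {
    piHat <- estimatePi(across, geno, chMain, includeParity = TRUE)$pi
    chB <- chMain; chB@pi <- piHat
    fitB <- fitThresholdMarkerModel(across, geno, chB, prior = "BayesB",
                                    includeParity = TRUE)
    windows <- assignWindows(geno)
    winres <- windowVariancePosterior(fitB, geno, windows)
    writeWindowTSV(winres, file.path(outDir, "windows.tsv"))
    writeWindowTSV(callSignificant(winres),
                   file.path(outDir, "windows_significant.tsv"))
    pip <- fitB@info$pip
    write.table(data.frame(marker = names(pip), pip = as.numeric(pip)),
                file.path(outDir, "snp_pip.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    manifest$pi_estimate <- piHat
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  manifest$status <- "ok"
  .writeManifest()
  invisible(list(records = qc$records, qcReport = qc$report, across = across,
                 byParity = byParity, heritability = h2tab,
                 geneticCorrelations = rgtab, windows = winres,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
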