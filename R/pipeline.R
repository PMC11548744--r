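#' @importFrom yaml read_yaml
#' @importFrom tools md5sum file_ext
#' @importFrom utils packageVersion
NULL

#' Derive reproducible per-stage child seeds from one master seed
#'
#' Stages rerun in isolation must see the same random stream as in a full
#' run, so each named stage gets a deterministic child seed:
#' \code{(seed + 1000003 * stage_index) mod (2^31 - 1)}.
#'
#' @param seed master integer seed.
#' @param stages character vector of stage names.
#' @return named integer vector of child seeds.
#' @export
deriveStageSeeds <- function(seed, stages) {
  s <- (as.numeric(seed) + 1000003 * seq_along(stages)) %% 2147483647
  setNames(as.integer(s), stages)
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end analysis in one list: input/output paths,
#' QC parameters, HMF fit parameters, network thresholds and the master
#' seed. [readPipelineConfig()] merges a user YAML/JSON file over these
#' defaults.
#'
#' @param ... overrides.
#' @return named list.
#' @export
defaultPipelineConfig <- function(...) {
  cfg <- list(
    ctPath = NULL, metaPath = NULL, outDir = "hartleynet_out",
    simulate = TRUE, nGenes = 96L, density = 0.05, coeffScale = 0.1,
    stabilityBound = -0.05, noiseSd = 0.15, missingRate = 0,
    chipReplicateFraction = 0,
    minPresent = 0.6, replicateBand = c(0.85, 1.15),
    robustMinPresent = 0.6,
    M = 8L, N = 3L, nGrid = 257L, l1Ratio = 0.5,
    penaltyGrid = 10^seq(-4, 1, length.out = 20L),
    tSpan = c(8, 24), nOut = 101L,
    sdFactor = 2, maxFraction = 0.75,
    strains = c("SHR", "WKY"),
    seed = 1L)
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (decided by extension), merged over
#' [defaultPipelineConfig()].
#'
#' @param path config file path.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) read_yaml(path)
          else if (ext == "json") read_json(path, simplifyVector = TRUE)
          else stop("config must be YAML or JSON, got: .", ext)
  do.call(defaultPipelineConfig, user)
}

.hmf_config_of <- function(config) {
  defaultHmfConfig(M = config$M, N = config$N, nGrid = config$nGrid,
                   l1Ratio = config$l1Ratio,
                   penaltyGrid = config$penaltyGrid,
                   tSpan = config$tSpan, nOut = config$nOut)
}

#' Run the configuration-driven pipeline
#'
#' Executes the requested stages in order on the configured input (or on a
#' freshly simulated synthetic dataset when \code{config$simulate} is TRUE),
#' writing intermediate artifacts and a run manifest (package version,
#' config hash, seed, stage list) into \code{config$outDir}. Stages:
#' \describe{
#'   \item{qc}{QC + normalization; writes per-organ normalized matrices and
#'     the QC report.}
#'   \item{stats}{PCA and per-gene age x strain ANOVA; writes
#'     scores/loadings and the statistics table.}
#'   \item{fit}{one HMF network per strain; writes interaction matrix CSVs
#'     and fit diagnostics.}
#'   \item{network}{SD thresholding, organ-level counts, regulator-set
#'     comparison, peak ordering, exports.}
#' }
#'
#' @param config list as from [defaultPipelineConfig()] /
#'   [readPipelineConfig()].
#' @param stages subset of \code{c("qc", "stats", "fit", "network")}.
#' @return invisibly, a list of in-memory results per stage.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        stages = c("qc", "stats", "fit", "network")) {
  stages <- match.arg(stages, c("qc", "stats", "fit", "network"),
                      several.ok = TRUE)
  out_dir <- config$outDir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- deriveStageSeeds(config$seed, c("simulate", "qc", "stats",
                                           "fit", "network"))
  results <- list()

  if (isTRUE(config$simulate)) {
    ds <- simulateStudyDataset(
      defaultStudyDesign(nGenes = config$nGenes),
      density = config$density, coeffScale = config$coeffScale,
      stabilityBound = config$stabilityBound, noiseSd = config$noiseSd,
      missingRate = config$missingRate,
      chipReplicateFraction = config$chipReplicateFraction,
      seed = seeds[["simulate"]])
    qpcr <- ds@qpcr
    writeQpcrTables(qpcr, file.path(out_dir, "ct_long.csv"),
                    file.path(out_dir, "sample_meta.csv"))
    writeInteractionMatrix(ds@truth, file.path(out_dir, "truth_K.csv"))
    results$dataset <- ds
  } else {
    if (is.null(config$ctPath) || !file.exists(config$ctPath))
      stop("stage qc: input Ct table not found (ctPath = ",
           config$ctPath, "); run the simulate stage or point ctPath at ",
           "an existing file")
    qpcr <- readQpcrTables(config$ctPath, config$metaPath)
  }

  if ("qc" %in% stages) {
    qpcr <- normalizeQpcr(qpcr, minPresent = config$minPresent,
                          band = config$replicateBand,
                          robustMinPresent = config$robustMinPresent)
    writeNormalizedMatrices(qpcr, out_dir)
    writeQcReport(qpcr, file.path(out_dir, "qc_report.json"))
    results$qpcr <- qpcr
  }
  if ("stats" %in% stages) {
    if (!"nddct" %in% assayNames(qpcr))
      stop("stage stats: normalized assay missing; run the qc stage first")
    pca <- runPca(qpcr)
    write.csv(pca$scores, file.path(out_dir, "pca_scores.csv"))
    write.csv(pca$loadings, file.path(out_dir, "pca_loadings.csv"))
    anova <- twoWayAnova(qpcr)
    write.csv(anova$stats, file.path(out_dir, "anova_stats.csv"),
              row.names = FALSE)
    write_json(list(alpha = anova$alpha,
                    nSignificant = nrow(anova$significant),
                    significant = anova$significant),
               file.path(out_dir, "significant_genes.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$pca <- pca
    results$anova <- anova
  }
  if ("fit" %in% stages) {
    if (!"nddct" %in% assayNames(qpcr))
      stop("stage fit: normalized assay missing; run the qc stage first")
    hmf_cfg <- .hmf_config_of(config)
    nets <- lapply(config$strains, function(s)
      estimateNetwork(qpcr, s, config = hmf_cfg))
    names(nets) <- config$strains
    for (s in config$strains) {
      writeInteractionMatrix(nets[[s]],
                             file.path(out_dir, paste0("K_", s, ".csv")))
      d <- fitDiagnostics(nets[[s]])
      write_json(d[c("penaltyGrid", "rmsePath", "selectedPenalty",
                     "selectedRmse")],
                 file.path(out_dir, paste0("fit_diagnostics_", s, ".json")),
                 auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    results$networks <- nets
  }
  if ("network" %in% stages) {
    if (is.null(results$networks))
      stop("stage network: fitted networks missing; run the fit stage first")
    nets <- results$networks
    edge_sets <- lapply(nets, thresholdBySd, factor = config$sdFactor)
    for (s in names(edge_sets)) {
      exportNetwork(edge_sets[[s]],
                    file.path(out_dir, paste0("edges_", s, ".tsv")), "tsv")
      exportNetwork(edge_sets[[s]],
                    file.path(out_dir, paste0("edges_", s, ".graphml")),
                    "graphml")
      write.csv(organEdgeCounts(edge_sets[[s]]),
                file.path(out_dir, paste0("organ_counts_", s, ".csv")))
    }
    if (length(edge_sets) >= 2L) {
      organs_all <- unique(as.character(nodeInfo(nets[[1L]])$organ))
      reg <- lapply(organs_all, function(o)
        regulatorSets(edge_sets[[1L]], edge_sets[[2L]], o))
      names(reg) <- organs_all
      write_json(reg, file.path(out_dir, "regulator_sets.json"),
                 auto_unbox = TRUE, digits = NA, pretty = TRUE)
      results$regulatorSets <- reg
    }
    sims <- lapply(names(nets), function(s) {
      net <- nets[[s]]
      traj <- summarizeReplicates(results$qpcr, s)
      scaled <- minmaxScale(traj)
      E0 <- trajectoryMatrix(scaled)[, 1L]
      E0[is.na(E0)] <- 0.5
      simulateFittedModel(net, E0, tSpan = config$tSpan,
                          nOut = config$nOut)
    })
    names(sims) <- names(nets)
    for (s in names(sims))
      write.csv(peakOrder(sims[[s]]),
                file.path(out_dir, paste0("peak_order_", s, ".csv")),
                row.names = FALSE)
    results$edgeSets <- edge_sets
    results$simulations <- sims
  }

  cfg_path <- file.path(out_dir, "config.json")
  write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  manifest <- list(
    package = "HartleyNet",
    version = as.character(packageVersion("HartleyNet")),
    stages = stages, seed = config$seed,
    stageSeeds = as.list(seeds),
    configHash = unname(md5sum(cfg_path)))
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Summarize pipeline artifacts
#'
#' Tabulates the key outputs of a finished run -- QC removal counts,
#' significant genes, per-strain edge and regulator counts, first peaks --
#' into a JSON summary and a small Markdown report. Regeneration from the
#' same artifacts is idempotent.
#'
#' @param outDir the pipeline output directory.
#' @return invisibly, the summary list.
#' @export
pipelineReport <- function(outDir) {
  summary <- list()
  qc_path <- file.path(outDir, "qc_report.json")
  if (file.exists(qc_path)) {
    qc <- read_json(qc_path, simplifyVector = TRUE)
    summary$qc <- list(
      removedGenes = length(qc$filter$removedGenes),
      removedSamples = length(qc$filter$removedSamples))
  }
  sig_path <- file.path(outDir, "significant_genes.json")
  if (file.exists(sig_path)) {
    sig <- read_json(sig_path, simplifyVector = TRUE)
    summary$nSignificant <- sig$nSignificant
  }
  for (f in list.files(outDir, pattern = "^edges_.*\\.tsv$")) {
    s <- sub("^edges_(.*)\\.tsv$", "\\1", f)
    e <- edgeTable(readNetworkEdges(file.path(outDir, f), "tsv"))
    summary$edgeCounts[[s]] <- nrow(e)
  }
  if (!is.null(summary$edgeCounts) &&
      all(unlist(summary$edgeCounts) == 0))
    summary$note <- "thresholded networks contain zero edges"
  reg_path <- file.path(outDir, "regulator_sets.json")
  if (file.exists(reg_path))
    summary$regulatorSets <- read_json(reg_path, simplifyVector = TRUE)
  for (f in list.files(outDir, pattern = "^peak_order_.*\\.csv$")) {
    s <- sub("^peak_order_(.*)\\.csv$", "\\1", f)
    po <- read.csv(file.path(outDir, f))
    summary$firstPeaks[[s]] <- utils::head(po, 5L)
  }
  write_json(summary, file.path(outDir, "report.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Pipeline report", "",
          if (!is.null(summary$qc))
            sprintf("- QC removed %d gene(s) and %d sample(s)",
                    summary$qc$removedGenes, summary$qc$removedSamples),
          if (!is.null(summary$nSignificant))
            sprintf("- %d (organ, gene) pairs with an effect at p < 0.05",
                    summary$nSignificant),
          if (!is.null(summary$edgeCounts))
            sprintf("- thresholded edges: %s",
                    paste(names(summary$edgeCounts),
                          unlist(summary$edgeCounts),
                          sep = " = ", collapse = ", ")),
          if (!is.null(summary$note)) paste("-", summary$note))
  writeLines(md, file.path(outDir, "report.md"))
  invisible(summary)
}
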