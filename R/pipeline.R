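#' @include sia-manual.R
NULL

# map snake_case simulation keys from the config file onto simulationConfig()
.simConfigFromList <- function(sim) {
  args <- list()
  direct <- c(n1 = "n1", n2 = "n2", n_peaks = "nPeaks",
              responsive_fraction = "responsiveFraction",
              linewidth_h = "linewidthH", linewidth_n = "linewidthN",
              dilution_factor = "dilutionFactor", noise_sd = "noiseSd",
              dmax_sd_h = "dmaxSdH", dmax_sd_n = "dmaxSdN",
              protein_conc = "proteinConc", rna_ratio = "rnaRatio",
              n_positions = "nPositions", rna_length = "rnaLength",
              seed = "seed")
  for (key in names(direct))
    if (!is.null(sim[[key]])) args[[direct[[key]]]] <- sim[[key]]
  if (!is.null(sim$kd_by_base))
    args$kdByBase <- unlist(sim$kd_by_base)
  n1 <- args$n1 %||% 290L
  n2 <- args$n2 %||% 256L
  if (!is.null(sim$axis_h))
    args$axisH <- nmrAxis(n1, sim$axis_h$sw, sim$axis_h$first,
                          sim$axis_h$obs %||% 700.13)
  if (!is.null(sim$axis_n))
    args$axisN <- nmrAxis(n2, sim$axis_n$sw, sim$axis_n$first,
                          sim$axis_n$obs %||% 70.948)
  do.call(simulationConfig, args)
}

#' Validate a pipeline configuration file
#'
#' Parses a YAML run configuration and checks it exhaustively: every
#' violation found is reported (not fail-fast). A configuration is either
#' \code{simulate} mode (carries a \code{simulation} block) or
#' \code{analyze} mode (carries a \code{spectra} manifest listing, per
#' position, the free plane plus all four pool planes); carrying both is a
#' mode conflict. Referenced files must exist at validation time.
#'
#' @param path path to a YAML config file, or an already-parsed list.
#' @return list with \code{valid} (logical), \code{violations} (character
#'   vector, empty when valid) and \code{config} (the normalized RunConfig
#'   list, \code{NULL} when invalid).
#' @export
validateConfig <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("config parse error: ",
                                      conditionMessage(e)))
  } else path
  v <- character()
  note <- function(...) v <<- c(v, sprintf(...))

  mode <- raw$mode %||% NA_character_
  if (!isTRUE(mode %in% c("simulate", "analyze")))
    note("mode must be 'simulate' or 'analyze' (got '%s')", mode)
  hasSim <- !is.null(raw$simulation)
  hasManifest <- !is.null(raw$spectra)
  if (hasSim && hasManifest)
    note("mode conflict: config provides both a simulation block and a spectra manifest")
  if (identical(mode, "simulate") && !hasSim)
    note("simulate mode requires a simulation block")
  if (identical(mode, "analyze") && !hasManifest)
    note("analyze mode requires a spectra manifest")
  if (is.null(raw$output_dir)) note("output_dir is required")

  simCfg <- NULL
  if (hasSim && !hasManifest) {
    simCfg <- tryCatch(.simConfigFromList(raw$simulation),
                       error = function(e) {
                         note("simulation block invalid: %s",
                              conditionMessage(e))
                         NULL
                       })
  }
  manifest <- NULL
  if (hasManifest) {
    for (entry in raw$spectra) {
      pos <- entry$position
      if (is.null(pos)) { note("spectra entry lacks a position"); next }
      for (plane in c("free", BASES)) {
        p <- entry[[plane]]
        if (is.null(p))
          note("position %s: missing spectrum for plane '%s'", pos, plane)
        else if (!file.exists(p))
          note("position %s, plane '%s': file not found: %s", pos, plane, p)
      }
    }
    manifest <- raw$spectra
  }
  if (!is.null(raw$peaklists)) {
    pl <- raw$peaklists
    if (is.null(pl$free))
      note("peaklists block lacks the free-protein list")
    else if (!file.exists(pl$free))
      note("peaklists: file not found: %s", pl$free)
    for (entry in pl$positions %||% list())
      for (b in BASES) {
        p <- entry[[b]]
        if (is.null(p))
          note("peaklists position %s: missing base '%s'", entry$position, b)
        else if (!file.exists(p))
          note("peaklists position %s, base '%s': file not found: %s",
               entry$position, b, p)
      }
  }
  pca <- raw$pca %||% list()
  if (!is.null(pca$centering) &&
      !pca$centering %in% c("none", "mean", "reference"))
    note("pca.centering must be none, mean or reference")
  if (!is.null(pca$component) && !(pca$component %in% 1:5))
    note("pca.component must lie in 1..5")

  valid <- length(v) == 0L
  config <- if (valid) {
    structure(list(
      mode = mode, outputDir = raw$output_dir,
      writeSpectra = isTRUE(raw$write_spectra),
      spectraFormat = raw$spectra_format %||% "matrix",
      pca = list(centering = pca$centering %||% "none",
                 component = as.integer(pca$component %||% 2L),
                 tol = pca$tol %||% 1e-12,
                 maxIter = as.integer(pca$max_iter %||% 10000L),
                 ratioThreshold = pca$ratio_threshold %||% 1.5),
      sia = list(alpha = raw$sia$alpha %||% 0.2,
                 selectedIds = unlist(raw$sia$selected_ids) %||% NULL),
      simulation = simCfg, manifest = manifest,
      peaklists = raw$peaklists), class = "RunConfig")
  } else NULL
  list(valid = valid, violations = v, config = config)
}

.loadEnsembles <- function(config, log) {
  stacks <- list()
  for (entry in config$manifest) {
    pos <- as.integer(entry$position)
    fmt <- entry$format %||% config$spectraFormat
    rd <- function(plane) {
      log("read spectrum: %s (position %d, plane %s, format %s)",
          entry[[plane]], pos, plane, fmt)
      readSpectrum(entry[[plane]], fmt)
    }
    bound <- lapply(stats::setNames(BASES, BASES), rd)
    stacks[[as.character(pos)]] <- stackEnsemble(rd("free"), bound, pos)
  }
  stacks
}

.loadPeaklists <- function(config, log) {
  pl <- config$peaklists
  if (is.null(pl)) return(NULL)
  log("read peak list: %s (free)", pl$free)
  free <- readPeakList(pl$free)
  byPos <- list()
  for (entry in pl$positions %||% list()) {
    pos <- as.character(entry$position)
    byPos[[pos]] <- lapply(stats::setNames(BASES, BASES), function(b) {
      log("read peak list: %s (position %s, base %s)", entry[[b]], pos, b)
      readPeakList(entry[[b]])
    })
  }
  list(free = free, byPosition = byPos)
}

#' Run the SIA analysis pipeline
#'
#' End-to-end, config-driven run. In \code{simulate} mode a full synthetic
#' experiment is generated ([simulateSIAExperiment()]) and analysed; in
#' \code{analyze} mode the spectra listed in the manifest are read and
#' analysed, with manual SIA scoring added when peak lists are provided.
#' Per-position outputs written to the output directory:
#' \code{variance_tables.csv}, \code{pca_scores.csv}, \code{rankings.csv},
#' \code{reliability.csv}, \code{histogram_data.csv}, and — when peak lists
#' are available — \code{sia_scores.csv}, \code{comparison_rank.csv} and
#' \code{comparison_correlation.csv}; plus \code{report.json} and
#' \code{run.log}. Runs are deterministic: identical config and seed give
#' byte-identical tables.
#'
#' @param config a validated RunConfig (from [validateConfig()]), a config
#'   list, or the path to a YAML config file.
#' @param outputDir optional override of the configured output directory.
#' @return (invisibly) a list with the preference tables, the comparison
#'   report and the paths of all written files.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (!inherits(config, "RunConfig")) {
    val <- validateConfig(config)
    if (!val$valid)
      stop("invalid config:\n  ", paste(val$violations, collapse = "\n  "))
    config <- val$config
  }
  outDir <- outputDir %||% config$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  log <- function(...) logLines <<- c(logLines, sprintf(...))
  log("mode: %s", config$mode)
  log("pca options: centering=%s component=%d tol=%g maxIter=%d ratioThreshold=%g",
      config$pca$centering, config$pca$component, config$pca$tol,
      config$pca$maxIter, config$pca$ratioThreshold)
  log("sia options: alpha=%g", config$sia$alpha)

  sim <- NULL
  if (config$mode == "simulate") {
    log("simulation seed: %d", config$simulation$seed)
    sim <- simulateSIAExperiment(config$simulation)
    stacks <- sim$stacks
    freePeaks <- sim$freePeaks
    boundPeaks <- sim$boundPeaks
    if (config$writeSpectra) {
      specDir <- file.path(outDir, "spectra")
      dir.create(specDir, showWarnings = FALSE)
      for (pos in names(stacks)) {
        st <- stacks[[pos]]
        writeSpectrum(st@reference,
                      file.path(specDir, sprintf("pos%s_free.npm", pos)),
                      "matrix")
        for (b in BASES)
          writeSpectrum(st@bound[[b]],
                        file.path(specDir, sprintf("pos%s_%s.npm", pos, b)),
                        "matrix")
      }
      log("wrote simulated spectra to %s", specDir)
    }
  } else {
    stacks <- .loadEnsembles(config, log)
    pl <- .loadPeaklists(config, log)
    freePeaks <- pl$free
    boundPeaks <- pl$byPosition
  }

  pcaTab <- pcaPreferenceTable(stacks, component = config$pca$component,
                               centering = config$pca$centering,
                               ratioThreshold = config$pca$ratioThreshold,
                               tol = config$pca$tol,
                               maxIter = config$pca$maxIter)
  positions <- sort(as.integer(names(stacks)))
  varTab <- do.call(rbind, lapply(as.character(positions), function(p)
    cbind(position = as.integer(p),
          pcaTab@diagnostics[[p]]$varianceTable)))
  relTab <- do.call(rbind, lapply(as.character(positions), function(p) {
    r <- pcaTab@diagnostics[[p]]$reliability
    data.frame(position = as.integer(p), reliable = r$reliable,
               pc2_pc3_ratio = r$ratio, message = r$message)
  }))

  siaTab <- NULL
  comparison <- NULL
  if (!is.null(freePeaks) && length(boundPeaks)) {
    ids <- config$sia$selectedIds %||% freePeaks$id
    log("sia peak selection: %d peaks", length(ids))
    siaTab <- siaPreferenceTable(freePeaks, boundPeaks, ids,
                                 alpha = config$sia$alpha)
    comparison <- compareMethods(pcaTab, siaTab)
  }

  paths <- character()
  writeTab <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    log("wrote %s", name)
    paths <<- c(paths, p)
  }
  writeTab(varTab, "variance_tables.csv")
  writeTab(pcaTab@scores, "pca_scores.csv")
  rankings <- pcaTab@scores[, c("position", "base", "rank")]
  rankings$method <- "pca"
  hist <- pcaTab@scores[, c("position", "base", "abs_score")]
  hist$method <- "pca"
  if (!is.null(siaTab)) {
    writeTab(siaTab@scores, "sia_scores.csv")
    r2 <- siaTab@scores[, c("position", "base", "rank")]
    r2$method <- "sia_manual"
    rankings <- rbind(rankings, r2)
    h2 <- siaTab@scores[, c("position", "base", "abs_score")]
    h2$method <- "sia_manual"
    hist <- rbind(hist, h2)
    writeTab(comparison$rankAgreement, "comparison_rank.csv")
    writeTab(comparison$componentCorrelation, "comparison_correlation.csv")
  }
  writeTab(rankings, "rankings.csv")
  writeTab(relTab, "reliability.csv")
  writeTab(hist, "histogram_data.csv")

  report <- list(
    mode = config$mode,
    positions = positions,
    options = config$pca,
    seed = if (!is.null(config$simulation)) config$simulation$seed else NULL,
    reliability = stats::setNames(relTab$reliable, relTab$position),
    topBase = stats::setNames(
      pcaTab@scores$base[pcaTab@scores$rank == 1L],
      pcaTab@scores$position[pcaTab@scores$rank == 1L]),
    rankAgreement = if (!is.null(comparison)) comparison$rankAgreement else NULL)
  reportPath <- file.path(outDir, "report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, reportPath)
  log("wrote report.json")
  logPath <- file.path(outDir, "run.log")
  writeLines(logLines, logPath)
  invisible(list(pca = pcaTab, sia = siaTab, comparison = comparison,
                 varianceTables = varTab, reliability = relTab,
                 simulation = sim, paths = c(paths, logPath)))
}
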