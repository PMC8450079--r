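# Reproducible pipeline runs: one entry point wiring configuration,
# seeding, the analysis stages and a run manifest.

pipelineSubcommands <- c("contacts", "helical", "ensemble", "promoters",
                         "synth")

manifestPath <- function(outDir) file.path(outDir, "manifest.json")

writeManifest <- function(outDir, subcommand, config, inputs, seed,
                          outputs) {
  manifest <- list(
    subcommand = subcommand,
    tool_version = as.character(packageVersion("yreflank")),
    seed = seed,
    config = config,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = basename(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifestPath(outDir), auto_unbox = TRUE,
                       pretty = TRUE)
  manifestPath(outDir)
}

checkConfigKeys <- function(config, allowed, subcommand) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config keys for '", subcommand, "': ",
         paste(unknown, collapse = ", "))
}

requireInputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing inputs: ", paste(missing, collapse = ", "))
}

#' Run one pipeline stage with configuration, seed and manifest
#'
#' Single programmatic entry point behind the `yreflank` command-line
#' wrapper (`inst/scripts/yreflank.R`). Every run validates its
#' configuration keys up front, seeds all randomness from `seed`, writes
#' text tables into `outDir` and finishes with a `manifest.json` recording
#' the subcommand, tool version, seed, configuration, input hashes and
#' output inventory. Outputs are deterministic given (inputs, config,
#' seed); inputs are never mutated.
#'
#' Subcommands and their config keys:
#' \describe{
#'   \item{synth}{`n_promoters`, `length`, `yre`, `flank_design`,
#'     `flank_width`, `bins`, `base_mean`, `effect_sd`, `noise_sd` -
#'     writes `promoters.tsv` and `truth.tsv`.}
#'   \item{promoters}{`promoters` (TSV path), `flank_width` (2 or 4),
#'     `exclude_motifs` (optional TSV of motifs), `dedupe_palindrome` -
#'     writes `filtered.tsv` and `groups.tsv`.}
#'   \item{helical}{`bound`, `unbound` (paths to shift series),
#'     `sequence`, `yre_start`, `yre_length`, `neutral_band`, `threshold`
#'     - writes `states.tsv` and `alterations.tsv`.}
#'   \item{contacts}{`structure` (multi-model PDB) - writes
#'     `contacts_pairs.tsv` and `contacts_strength.tsv`.}
#'   \item{ensemble}{`structure`, `reference` (frame index), `windows`
#'     (count of equal windows) - writes `rmsd.tsv` and
#'     `convergence.tsv`.}
#' }
#'
#' @param subcommand one of `"contacts"`, `"helical"`, `"ensemble"`,
#'   `"promoters"`, `"synth"`.
#' @param config named list (see [readConfig()]) or a path to a YAML file.
#' @param outDir output directory (created if needed).
#' @param seed integer seed for all randomness.
#' @return invisible list of written paths (manifest last).
#' @export
runPipeline <- function(subcommand, config = list(), outDir, seed = 1L) {
  subcommand <- match.arg(subcommand, pipelineSubcommands)
  if (is.character(config) && length(config) == 1L)
    config <- readConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  message("run ", subcommand, " seed=", seed)
  for (k in names(config)) message("  ", k, " = ", config[[k]])
  cfg <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  inputs <- character()
  outputs <- character()
  emit <- function(df, name, col.names = TRUE) {
    p <- file.path(outDir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = col.names)
    outputs <<- c(outputs, p)
    p
  }

  if (subcommand == "synth") {
    checkConfigKeys(config, c("n_promoters", "length", "yre",
                              "flank_design", "flank_width", "bins",
                              "base_mean", "effect_sd", "noise_sd"),
                    subcommand)
    lib <- genPromoterLibrary(
      n = cfg("n_promoters", 256L), length = cfg("length", 80L),
      yre = cfg("yre", "TTACTAA"),
      flankDesign = cfg("flank_design", "sampled"),
      flankWidth = cfg("flank_width", 2L),
      bins = cfg("bins", 18L), baseMean = cfg("base_mean", 9),
      effectSd = cfg("effect_sd", 2), noiseSd = cfg("noise_sd", 1.5),
      seed = seed)
    p <- file.path(outDir, "promoters.tsv")
    writePromoterTable(lib$promoters, p)
    outputs <- c(outputs, p)
    emit(lib$truth, "truth.tsv")
  } else if (subcommand == "promoters") {
    checkConfigKeys(config, c("promoters", "flank_width", "exclude_motifs",
                              "dedupe_palindrome"), subcommand)
    width <- as.integer(cfg("flank_width", 2L))
    if (!width %in% c(2L, 4L))
      stop("invalid flank_width ", width, " (must be 2 or 4)")
    pin <- config$promoters
    if (is.null(pin)) stop("config key 'promoters' (input TSV) is required")
    inputs <- c(inputs, pin)
    excl <- character()
    if (!is.null(config$exclude_motifs)) {
      inputs <- c(inputs, config$exclude_motifs)
      requireInputs(inputs)
      excl <- read.table(config$exclude_motifs, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
    }
    requireInputs(inputs)
    tab <- readPromoterTable(pin)
    filt <- filterSingleInstance(tab, exclusionMotifs = excl,
                                 flankWidth = width,
                                 dedupePalindrome =
                                   isTRUE(cfg("dedupe_palindrome", TRUE)))
    emit(filt[, setdiff(names(filt), "members")], "filtered.tsv")
    groups <- groupByFlanks(filt, width)
    emit(groups[, setdiff(names(groups), "members")], "groups.tsv")
  } else if (subcommand == "helical") {
    checkConfigKeys(config, c("bound", "unbound", "sequence", "yre_start",
                              "yre_length", "neutral_band", "threshold"),
                    subcommand)
    inputs <- c(config$bound, config$unbound)
    if (length(inputs) != 2L)
      stop("config keys 'bound' and 'unbound' (series paths) are required")
    requireInputs(inputs)
    sq <- cfg("sequence", yreStudyOligomers()[["YRE1_ATR1"]])
    reg <- stepRegions(sq, as.integer(cfg("yre_start", 9L)),
                       as.integer(cfg("yre_length", 7L)))
    zero <- function(v) matrix(0, nrow(v), ncol(v))
    mk <- function(path) {
      tb <- seriesValues(readSeriesTable(path, "shift"))
      StepParameterSeries(tb, zero(tb), zero(tb), zero(tb), zero(tb),
                          zero(tb), reg$stepLabels, reg$regionTags)
    }
    bound <- mk(config$bound); unbound <- mk(config$unbound)
    emit(classifyStates(bound, "shift",
                        cfg("neutral_band", 0.3)), "states.tsv")
    cmp <- compareBoundUnbound(bound, unbound, "shift",
                               cfg("threshold", 0.2))
    alt <- cmp$perStep
    alt$reach5 <- cmp$reach5; alt$reach3 <- cmp$reach3
    emit(alt, "alterations.tsv")
  } else if (subcommand == "contacts") {
    checkConfigKeys(config, c("structure", "hbond_dmax", "hbond_angle_min",
                              "salt_dmax", "apolar_dmax"), subcommand)
    if (is.null(config$structure))
      stop("config key 'structure' (PDB path) is required")
    inputs <- config$structure
    requireInputs(inputs)
    ens <- readStructureEnsemble(config$structure)
    map <- dynamicContactMap(ens, criteria = list(
      hbondDmax = cfg("hbond_dmax", 3.5),
      hbondAngleMin = cfg("hbond_angle_min", 120),
      saltDmax = cfg("salt_dmax", 4.0),
      apolarDmax = cfg("apolar_dmax", 4.5)))
    outputs <- c(outputs, writeContactMap(map, file.path(outDir, "contacts")))
  } else if (subcommand == "ensemble") {
    checkConfigKeys(config, c("structure", "reference", "windows"),
                    subcommand)
    if (is.null(config$structure))
      stop("config key 'structure' (PDB path) is required")
    inputs <- config$structure
    requireInputs(inputs)
    ens <- readStructureEnsemble(config$structure)
    emit(rmsdSeries(ens, as.integer(cfg("reference", 1L))), "rmsd.tsv")
    nw <- as.integer(cfg("windows", 2L))
    nf <- nFrames(ens)
    ends <- unique(pmax(1L, round(seq_len(nw) * nf / nw)))
    conv <- convergenceRmsd(ens, lapply(ends, function(e) seq_len(e)))
    emit(as.data.frame(conv$rmsd), "convergence.tsv", col.names = FALSE)
  }

  mf <- writeManifest(outDir, subcommand, config, inputs, seed, outputs)
  invisible(c(outputs, mf))
}
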