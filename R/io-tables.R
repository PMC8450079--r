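# Whitespace-separated helical-parameter series tables, promoter TSVs,
# FASTA, expression profiles and flat run configuration.

#' Read a per-step helical-parameter time series
#'
#' Accepts the generic Canal-style layout: a whitespace-separated numeric
#' table whose first column is a frame index and whose remaining columns
#' hold one base-pair step each. Any non-numeric token maps to an absent
#' (`NA`) cell; absent cells are excluded from downstream histograms.
#'
#' @param path file path.
#' @param parameterName one of `"shift"`, `"slide"`, `"rise"`, `"tilt"`,
#'   `"roll"`, `"twist"`.
#' @return A [SeriesTable-class].
#' @export
readSeriesTable <- function(path, parameterName) {
  parameterName <- match.arg(parameterName, HELICAL_PARAMETERS)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no frames in ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  width <- lengths(toks)
  if (length(unique(width)) != 1L)
    stop("ragged row ", which(width != width[1])[1], " in ", path,
         " (expected ", width[1], " fields, found ",
         width[which(width != width[1])[1]], ")")
  if (width[1] < 2L) stop("no step columns in ", path)
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), nrow = length(toks), byrow = TRUE))
  new("SeriesTable", values = vals[, -1, drop = FALSE],
      parameterName = parameterName)
}

#' Assemble a StepParameterSeries from six SeriesTables
#'
#' @param tables named list with elements `shift`, `slide`, `rise`, `tilt`,
#'   `roll`, `twist`, each a [SeriesTable-class] of identical shape.
#' @param stepLabels,regionTags step annotation; see
#'   [StepParameterSeries-class].
#' @return A [StepParameterSeries-class].
#' @export
stepSeriesFromTables <- function(tables, stepLabels, regionTags) {
  stopifnot(all(HELICAL_PARAMETERS %in% names(tables)))
  m <- lapply(HELICAL_PARAMETERS, function(p) seriesValues(tables[[p]]))
  names(m) <- HELICAL_PARAMETERS
  StepParameterSeries(m$shift, m$slide, m$rise, m$tilt, m$roll, m$twist,
                      stepLabels, regionTags)
}

#' Read a promoter table
#'
#' Tab-separated with header columns `id`, `sequence` and optionally
#' `expression_bin`. Sequences are upper-cased on read; `U` is rejected
#' (DNA only). Records with characters outside `{A,C,G,T}` raise an error
#' naming the offending ids, or are dropped with a warning when
#' `onInvalid = "skip"`.
#'
#' @param path TSV file path.
#' @param bins integer; number of expression bins (bins are validated to lie
#'   in `[0, bins - 1]`).
#' @param onInvalid `"error"` or `"skip"`: what to do with non-ACGT records.
#' @return data.frame with columns `id`, `sequence`, `expression_bin`
#'   (`NA` when absent).
#' @export
readPromoterTable <- function(path, bins = 18L, onInvalid = c("error", "skip")) {
  onInvalid <- match.arg(onInvalid)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", quote = "", comment.char = "")
  if (!all(c("id", "sequence") %in% names(df)))
    stop("promoter table must have columns id and sequence")
  df$sequence <- toupper(df$sequence)
  if (any(grepl("U", df$sequence, fixed = TRUE)))
    stop("RNA (U) not accepted; promoter sequences must be DNA")
  bad <- grepl("[^ACGT]", df$sequence) | !nzchar(df$sequence)
  if (any(bad)) {
    if (onInvalid == "error")
      stop("non-ACGT or empty sequences for ids: ",
           paste(df$id[bad], collapse = ", "))
    warning("skipping ", sum(bad), " records with non-ACGT sequences")
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$id)) stop("duplicate promoter ids")
  if ("expression_bin" %in% names(df)) {
    binv <- suppressWarnings(as.numeric(df$expression_bin))
    binv[df$expression_bin %in% c("", "NA")] <- NA_real_
    present <- !is.na(binv)
    if (any(present & (binv != round(binv) | binv < 0 | binv > bins - 1)))
      stop("expression bins must be integers in [0, ", bins - 1, "]")
    df$expression_bin <- as.integer(round(binv))
  } else {
    df$expression_bin <- NA_integer_
  }
  rownames(df) <- NULL
  df[, c("id", "sequence", "expression_bin")]
}

#' Write a promoter table
#' @param table data.frame with columns `id`, `sequence`,
#'   `expression_bin` (optional).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePromoterTable <- function(table, path) {
  cols <- intersect(c("id", "sequence", "expression_bin"), names(table))
  write.table(table[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file as a named character vector of DNA sequences
#'
#' @param path FASTA file path.
#' @return named character vector, sequences upper-cased.
#' @export
readFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write named DNA sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a differential-expression profile
#'
#' Tab-separated with header columns `gene`, `timepoint`, `wt`, `mutant`.
#' All `wt`/`mutant` values must be strictly positive before ratio
#' computation (see [differentialProfile()]).
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene`, `timepoint`, `wt`, `mutant`.
#' @export
readExpressionProfile <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  need <- c("gene", "timepoint", "wt", "mutant")
  if (!all(need %in% names(df)))
    stop("expression profile must have columns: ",
         paste(need, collapse = ", "))
  if (!is.numeric(df$wt) || !is.numeric(df$mutant))
    stop("wt and mutant must be numeric")
  df[, need]
}

#' Read a flat key-value run configuration
#'
#' YAML with scalar values only. The configuration (with the seed) is echoed
#' through `message()` at read time so runs are reproducible from logs.
#'
#' @param path YAML file path.
#' @param quiet suppress the echo.
#' @return named list of configuration values.
#' @export
readConfig <- function(path, quiet = FALSE) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping")
  bad <- vapply(cfg, function(v) is.list(v) || length(v) != 1L, logical(1))
  if (any(bad))
    stop("config must be flat (scalar values only); offending keys: ",
         paste(names(cfg)[bad], collapse = ", "))
  if (!quiet) {
    message("config ", path, ":")
    for (k in names(cfg)) message("  ", k, " = ", cfg[[k]])
  }
  cfg
}
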