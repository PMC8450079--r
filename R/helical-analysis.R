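# Distribution, state-classification and bound-vs-unbound alteration
# analysis of step-parameter series.

stepIndex <- function(series, step) {
  if (is.character(step)) {
    i <- which(series@stepLabels == step)
    if (!length(i)) stop("unknown step label: ", step)
    if (length(i) > 1L) stop("ambiguous step label: ", step,
                             "; use a numeric index")
    return(i)
  }
  step <- as.integer(step)
  if (step < 1L || step > length(series@stepLabels))
    stop("step index out of range")
  step
}

stepValues <- function(series, parameter, step) {
  v <- paramMatrix(series, parameter)[, stepIndex(series, step)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all values absent at the requested step")
  v
}

#' Normalized distribution of one step parameter at one step
#'
#' Histogram whose densities integrate to 1 (`sum(density) * binWidth == 1`).
#' Absent (`NA`) cells are excluded. Default bin width is 0.1 Angstrom for
#' translational parameters and 2 degrees for rotational ones.
#'
#' @param series a [StepParameterSeries-class].
#' @param parameter parameter name (see [paramMatrix()]).
#' @param step step label or 1-based index.
#' @param binWidth bin width (Angstrom or degrees).
#' @return data.frame with columns `center` and `density`.
#' @export
normalizedDistribution <- function(series, parameter, step,
                                   binWidth = NULL) {
  parameter <- match.arg(parameter, HELICAL_PARAMETERS)
  if (is.null(binWidth))
    binWidth <- if (parameter %in% TRANSLATIONAL_PARAMETERS) 0.1 else 2
  stopifnot(binWidth > 0)
  v <- stepValues(series, parameter, step)
  lo <- floor(min(v) / binWidth) * binWidth
  hi <- ceiling(max(v) / binWidth + 1e-9) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  edges <- seq(lo, hi, by = binWidth)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(center = (edges[-length(edges)] + edges[-1]) / 2,
             density = counts / (length(v) * binWidth))
}

#' Most-populated state (negative / neutral / positive) of one step
#'
#' Splits the values at a step into three states: `value < -band`
#' (negative), `|value| <= band` (neutral), `value > band` (positive), and
#' calls the state with the largest population. Ties are called neutral.
#'
#' @inheritParams normalizedDistribution
#' @param neutralBand half-width of the neutral band (default 0.3 Angstrom,
#'   suited to shift/slide).
#' @return list with `step` (label), `state` (`"negative"`, `"neutral"` or
#'   `"positive"`), `fraction` (population of the called state) and
#'   `fractions` (named numeric(3), summing to 1).
#' @export
classifyState <- function(series, parameter, step, neutralBand = 0.3) {
  parameter <- match.arg(parameter, HELICAL_PARAMETERS)
  stopifnot(neutralBand >= 0)
  v <- stepValues(series, parameter, step)
  n <- length(v)
  fr <- c(negative = sum(v < -neutralBand) / n,
          neutral = sum(abs(v) <= neutralBand) / n,
          positive = sum(v > neutralBand) / n)
  top <- which(fr == max(fr))
  state <- if (length(top) > 1L) "neutral" else names(fr)[top]
  list(step = series@stepLabels[stepIndex(series, step)],
       state = state, fraction = unname(max(fr)), fractions = fr)
}

#' Per-step state calls for a whole series
#'
#' @inheritParams classifyState
#' @return data.frame with one row per step: `step_label`, `region`,
#'   `state`, `fraction`.
#' @export
classifyStates <- function(series, parameter = "shift", neutralBand = 0.3) {
  rows <- lapply(seq_along(series@stepLabels), function(s) {
    cl <- classifyState(series, parameter, s, neutralBand)
    data.frame(step_label = cl$step, region = series@regionTags[s],
               state = cl$state, fraction = cl$fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bound-versus-unbound alteration of a step parameter
#'
#' Scores each step by the two-sample Kolmogorov-Smirnov statistic between
#' the bound and unbound distributions (in `[0, 1]`, distribution-free); a
#' step is "altered" when its score exceeds `threshold`. The flanking reach
#' is computed separately on each side of the response element by walking
#' outward from the element edge (`-1`, `-2`, ... and `+1`, `+2`, ...) and
#' stopping at the first unaltered step.
#'
#' @param bound,unbound [StepParameterSeries-class] objects with identical
#'   step labels and region tags.
#' @param parameter parameter name.
#' @param threshold alteration threshold on the KS statistic (default 0.2).
#' @return list with `perStep` (data.frame: `step_label`, `region`, `score`,
#'   `altered`), `reach5` and `reach3` (integer flank reach on the 5' and
#'   3' side).
#' @export
compareBoundUnbound <- function(bound, unbound, parameter = "shift",
                                threshold = 0.2) {
  parameter <- match.arg(parameter, HELICAL_PARAMETERS)
  if (!identical(bound@stepLabels, unbound@stepLabels) ||
      !identical(bound@regionTags, unbound@regionTags))
    stop("bound and unbound series must share step labels and region tags")
  mb <- paramMatrix(bound, parameter)
  mu <- paramMatrix(unbound, parameter)
  ns <- ncol(mb)
  score <- vapply(seq_len(ns), function(s) {
    x <- mb[, s]; y <- mu[, s]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) return(NA_real_)
    if (identical(x, y)) return(0)
    unname(suppressWarnings(ks.test(x, y)$statistic))
  }, numeric(1))
  altered <- !is.na(score) & score > threshold
  perStep <- data.frame(step_label = bound@stepLabels,
                        region = bound@regionTags,
                        score = score, altered = altered,
                        stringsAsFactors = FALSE)
  reach <- function(side) {
    k <- 0L
    repeat {
      i <- which(bound@regionTags == paste0(side, k + 1L))
      if (!length(i) || !altered[i]) break
      k <- k + 1L
    }
    k
  }
  list(perStep = perStep, reach5 = reach("-"), reach3 = reach("+"))
}

#' Drop initial frames as equilibration
#'
#' Removes the first `fraction` of frames (or `nDrop` frames, when given)
#' from an ensemble or series before analysis, mirroring the usual practice
#' of discarding the start of a trajectory as equilibration.
#'
#' @param x a [StructureEnsemble-class] or [StepParameterSeries-class].
#' @param fraction fraction of frames to drop from the start.
#' @param nDrop absolute number of frames to drop (overrides `fraction`).
#' @return object of the same class with the initial frames removed.
#' @export
discardEquilibration <- function(x, fraction = 0.1, nDrop = NULL) {
  nf <- nFrames(x)
  drop <- if (!is.null(nDrop)) as.integer(nDrop) else as.integer(floor(nf * fraction))
  if (drop < 0L || drop >= nf)
    stop("cannot drop ", drop, " of ", nf, " frames")
  keep <- (drop + 1L):nf
  if (is(x, "StructureEnsemble"))
    return(StructureEnsemble(x@atoms, x@coords[, , keep, drop = FALSE]))
  if (is(x, "StepParameterSeries"))
    return(StepParameterSeries(
      x@shift[keep, , drop = FALSE], x@slide[keep, , drop = FALSE],
      x@rise[keep, , drop = FALSE], x@tilt[keep, , drop = FALSE],
      x@roll[keep, , drop = FALSE], x@twist[keep, , drop = FALSE],
      x@stepLabels, x@regionTags))
  stop("unsupported class: ", class(x)[1])
}
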