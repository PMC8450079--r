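#' @import methods
#' @importFrom stats sd ks.test t.test hclust cutree as.dist rnorm runif setNames
#' @importFrom utils read.table write.table head tail packageVersion
NULL

HELICAL_PARAMETERS <- c("shift", "slide", "rise", "tilt", "roll", "twist")
TRANSLATIONAL_PARAMETERS <- c("shift", "slide", "rise")

#' StructureEnsemble: ordered coordinate frames of a protein-DNA complex
#'
#' Holds a multi-model structure (for example snapshots of a protein-DNA
#' complex or of naked DNA) as an atom table shared by all frames plus a
#' coordinate array. Atom ordering of the first frame is canonical for the
#' whole ensemble.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain` describing every atom, in file order.
#' @slot coords numeric array of dimension (atoms, 3, frames), in Angstrom.
#'
#' @exportClass StructureEnsemble
setClass("StructureEnsemble",
  representation(atoms = "data.frame", coords = "array"))

setValidity("StructureEnsemble", function(object) {
  msgs <- character()
  need <- c("serial", "name", "element", "resname", "resno", "chain")
  if (!all(need %in% names(object@atoms)))
    msgs <- c(msgs, paste("atom table must have columns:",
                          paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msgs <- c(msgs, "coords must be an (atoms x 3 x frames) array")
  else if (d[1] != nrow(object@atoms))
    msgs <- c(msgs, "coords first dimension must equal the atom count")
  if (length(object@coords) && !all(is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a StructureEnsemble
#'
#' @param atoms atom table (see [StructureEnsemble-class]).
#' @param coords (atoms x 3 x frames) array, or a list of (atoms x 3)
#'   matrices, one per frame.
#' @return A [StructureEnsemble-class] object.
#' @export
StructureEnsemble <- function(atoms, coords) {
  if (is.list(coords)) {
    coords <- array(unlist(lapply(coords, function(m) as.numeric(m))),
                    dim = c(nrow(atoms), 3L, length(coords)))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  new("StructureEnsemble", atoms = atoms, coords = coords)
}

#' Number of frames of an ensemble, series or contact map
#' @param x a `StructureEnsemble`, `StepParameterSeries` or
#'   `ContactStrengthMap`
#' @export
nFrames <- function(x) {
  if (is(x, "StructureEnsemble")) return(dim(x@coords)[3])
  if (is(x, "StepParameterSeries")) return(nrow(x@shift))
  if (is(x, "ContactStrengthMap")) return(nrow(x@strength))
  if (is(x, "SeriesTable")) return(nrow(x@values))
  stop("no frame count for objects of class ", class(x)[1])
}

#' Number of atoms in an ensemble
#' @param x a `StructureEnsemble`
#' @export
nAtoms <- function(x) dim(x@coords)[1]

#' Atom table of an ensemble
#' @param x a `StructureEnsemble`
#' @export
atomTable <- function(x) x@atoms

#' Coordinates of one frame
#' @param x a `StructureEnsemble`
#' @param i frame index (1-based)
#' @return (atoms x 3) numeric matrix
#' @export
frameCoords <- function(x, i) {
  stopifnot(i >= 1, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble:", nAtoms(object), "atoms x",
      dim(object@coords)[3], "frames\n")
  cat("  chains:", paste(unique(object@atoms$chain), collapse = " "), "\n")
})

#' BaseFrame: reference frame of one base pair
#'
#' Origin plus a right-handed orthonormal triad. Column 1 points toward the
#' major groove (x), column 2 along the long base-pair axis toward the
#' Watson strand backbone (y), column 3 along the local helical axis (z).
#'
#' @slot origin numeric(3), Angstrom.
#' @slot axes 3x3 orthonormal rotation matrix with determinant +1; columns
#'   are the x, y, z unit vectors.
#' @exportClass BaseFrame
setClass("BaseFrame", representation(origin = "numeric", axes = "matrix"))

setValidity("BaseFrame", function(object) {
  msgs <- character()
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msgs <- c(msgs, "origin must be a finite 3-vector")
  ax <- object@axes
  if (!all(dim(ax) == c(3L, 3L))) {
    msgs <- c(msgs, "axes must be 3x3")
  } else {
    if (max(abs(crossprod(ax) - diag(3))) > 1e-8)
      msgs <- c(msgs, "axes must be orthonormal (tolerance 1e-8)")
    if (det(ax) < 0)
      msgs <- c(msgs, "axes must be right-handed (determinant +1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BaseFrame
#' @param origin numeric(3) origin in Angstrom
#' @param axes 3x3 orthonormal matrix, columns x/y/z
#' @export
BaseFrame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  new("BaseFrame", origin = as.numeric(origin), axes = axes)
}

#' @describeIn BaseFrame-class origin accessor
#' @param x a `BaseFrame`
#' @export
frameOrigin <- function(x) x@origin

#' @describeIn BaseFrame-class axes accessor
#' @param x a `BaseFrame`
#' @export
frameAxes <- function(x) x@axes

setMethod("show", "BaseFrame", function(object) {
  cat("BaseFrame at (", paste(sprintf("%.3f", object@origin), collapse = ", "),
      ")\n", sep = "")
})

#' StepParameterSeries: per-step, per-frame helical parameters
#'
#' Six (frames x steps) matrices of base-pair-step parameters with step
#' labels (dinucleotide) and region tags locating each step relative to a
#' response element: `"yre"` for steps inside the element, `"-k"` /
#' `"+k"` for the k-th step outward from the 5' / 3' element edge.
#'
#' @slot stepLabels character, one dinucleotide label per step.
#' @slot regionTags character, one tag per step (`"yre"`, `"-1"`, `"+2"`, ...).
#' @slot shift,slide,rise (frames x steps) matrices, Angstrom.
#' @slot tilt,roll,twist (frames x steps) matrices, degrees.
#' @exportClass StepParameterSeries
setClass("StepParameterSeries",
  representation(stepLabels = "character", regionTags = "character",
    shift = "matrix", slide = "matrix", rise = "matrix",
    tilt = "matrix", roll = "matrix", twist = "matrix"))

setValidity("StepParameterSeries", function(object) {
  msgs <- character()
  dims <- lapply(HELICAL_PARAMETERS, function(p) dim(slot(object, p)))
  if (length(unique(dims)) != 1L)
    msgs <- c(msgs, "all six parameter matrices must share one shape")
  ns <- dims[[1]][2]
  if (length(object@stepLabels) != ns)
    msgs <- c(msgs, "stepLabels length must equal the step count")
  if (length(object@regionTags) != ns)
    msgs <- c(msgs, "regionTags must cover every step exactly once")
  bad <- !grepl("^(yre|[+-][0-9]+)$", object@regionTags)
  if (any(bad))
    msgs <- c(msgs, paste("invalid region tags:",
                          paste(unique(object@regionTags[bad]), collapse = " ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a StepParameterSeries
#'
#' @param shift,slide,rise,tilt,roll,twist (frames x steps) matrices.
#' @param stepLabels character step labels (dinucleotides).
#' @param regionTags character region tags (`"yre"`, `"-1"`, `"+1"`, ...).
#' @export
StepParameterSeries <- function(shift, slide, rise, tilt, roll, twist,
                                stepLabels, regionTags) {
  new("StepParameterSeries",
      stepLabels = as.character(stepLabels),
      regionTags = as.character(regionTags),
      shift = as.matrix(shift), slide = as.matrix(slide),
      rise = as.matrix(rise), tilt = as.matrix(tilt),
      roll = as.matrix(roll), twist = as.matrix(twist))
}

#' Step labels of a series
#' @param x a `StepParameterSeries`
#' @export
stepLabels <- function(x) x@stepLabels

#' Region tags of a series
#' @param x a `StepParameterSeries`
#' @export
regionTags <- function(x) x@regionTags

#' One parameter matrix of a series
#' @param x a `StepParameterSeries`
#' @param parameter one of `"shift"`, `"slide"`, `"rise"`, `"tilt"`,
#'   `"roll"`, `"twist"`
#' @return (frames x steps) matrix
#' @export
paramMatrix <- function(x, parameter) {
  parameter <- match.arg(parameter, HELICAL_PARAMETERS)
  slot(x, parameter)
}

setMethod("show", "StepParameterSeries", function(object) {
  cat("StepParameterSeries:", nrow(object@shift), "frames x",
      ncol(object@shift), "steps\n")
  cat("  steps:", paste(object@stepLabels, collapse = " "), "\n")
  cat("  regions:", paste(object@regionTags, collapse = " "), "\n")
})

#' SeriesTable: one helical parameter read from a time-series file
#'
#' @slot values (frames x steps) numeric matrix; absent cells are `NA`.
#' @slot parameterName one of the six step-parameter names.
#' @exportClass SeriesTable
setClass("SeriesTable",
  representation(values = "matrix", parameterName = "character"))

setValidity("SeriesTable", function(object) {
  msgs <- character()
  if (!object@parameterName %in% HELICAL_PARAMETERS)
    msgs <- c(msgs, paste("parameterName must be one of:",
                          paste(HELICAL_PARAMETERS, collapse = ", ")))
  if (!is.numeric(object@values))
    msgs <- c(msgs, "values must be numeric")
  if (length(msgs)) msgs else TRUE
})

#' Values matrix of a SeriesTable
#' @param x a `SeriesTable`
#' @export
seriesValues <- function(x) x@values

setMethod("show", "SeriesTable", function(object) {
  cat("SeriesTable (", object@parameterName, "): ",
      nrow(object@values), " frames x ", ncol(object@values), " steps\n",
      sep = "")
})

#' ContactStrengthMap: per-residue-pair, per-frame contact strength
#'
#' Contact strength S of a (protein residue, DNA residue) pair in a frame is
#' the number of detected hydrogen bonds, salt bridges and apolar contacts
#' between the two residues, each contributing 1 regardless of type.
#' `specific` holds the strength restricted to specific contacts
#' (protein side-chain atom to DNA base atom).
#'
#' @slot pairs data.frame with one row per residue pair: `protein_chain`,
#'   `protein_resno`, `protein_resname`, `dna_chain`, `dna_resno`,
#'   `dna_resname`.
#' @slot strength (frames x pairs) integer matrix of total strength.
#' @slot specific (frames x pairs) integer matrix of specific-only strength.
#' @exportClass ContactStrengthMap
setClass("ContactStrengthMap",
  representation(pairs = "data.frame", strength = "matrix",
                 specific = "matrix"))

setValidity("ContactStrengthMap", function(object) {
  msgs <- character()
  if (ncol(object@strength) != nrow(object@pairs))
    msgs <- c(msgs, "strength columns must match pair rows")
  if (!identical(dim(object@strength), dim(object@specific)))
    msgs <- c(msgs, "strength and specific matrices must share one shape")
  if (length(object@strength) &&
      (any(object@strength < 0) || any(object@strength != round(object@strength))))
    msgs <- c(msgs, "strengths must be non-negative integers")
  if (length(object@specific) && any(object@specific > object@strength))
    msgs <- c(msgs, "specific strength cannot exceed total strength")
  if (length(msgs)) msgs else TRUE
})

#' Residue-pair table of a contact map
#' @param x a `ContactStrengthMap`
#' @export
pairInfo <- function(x) x@pairs

#' Strength matrix of a contact map
#' @param x a `ContactStrengthMap`
#' @param specific logical; return the specific-only strengths?
#' @return (frames x pairs) integer matrix
#' @export
strengthMatrix <- function(x, specific = FALSE) {
  if (specific) x@specific else x@strength
}

#' Per-pair occupancy: fraction of frames with strength > 0
#' @param x a `ContactStrengthMap`
#' @param specific logical; use the specific-only strengths?
#' @export
occupancy <- function(x, specific = FALSE) {
  m <- strengthMatrix(x, specific)
  colMeans(m > 0)
}

#' Per-pair mean contact strength over frames
#' @param x a `ContactStrengthMap`
#' @param specific logical; use the specific-only strengths?
#' @export
meanStrength <- function(x, specific = FALSE) {
  colMeans(strengthMatrix(x, specific))
}

setMethod("show", "ContactStrengthMap", function(object) {
  cat("ContactStrengthMap:", nrow(object@strength), "frames x",
      nrow(object@pairs), "residue pairs\n")
  if (nrow(object@pairs)) {
    occ <- occupancy(object)
    cat("  occupancy range:", sprintf("%.2f-%.2f", min(occ), max(occ)), "\n")
  }
})
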