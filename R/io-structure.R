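# Multi-model PDB in/out. Parsing is delegated to bio3d; a light pre-scan
# enforces the ensemble invariants (identical atom identity/ordering per
# model) with errors that name the offending model, which bio3d's multi-model
# reader does not report.

#' Read a multi-model PDB file as a StructureEnsemble
#'
#' Honours `MODEL`/`ENDMDL` records (a file without them is a single-frame
#' ensemble). Alternate locations other than blank or `'A'` are dropped;
#' hydrogens are kept unless `dropHydrogens = TRUE` (contact detection uses
#' them when present). Residue numbers are preserved verbatim.
#'
#' @param path PDB file path.
#' @param dropHydrogens logical; remove hydrogen atoms on read.
#' @return A [StructureEnsemble-class].
#' @export
readStructureEnsemble <- function(path, dropHydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom)) stop("no ATOM records in ", path)

  # model membership: 0 when the file has no MODEL records
  modelStarts <- which(rec == "MODEL ")
  modelId <- cumsum(rec == "MODEL ")
  # atom identity string: name + altloc + resname + chain + resno + icode
  ident <- substr(lines, 13, 27)
  keyByModel <- split(ident[isAtom], modelId[isAtom])
  ref <- keyByModel[[1]]
  for (k in seq_along(keyByModel)) {
    if (!identical(keyByModel[[k]], ref))
      stop("inconsistent atom ordering or count in model ",
           names(keyByModel)[k], " of ", path)
  }

  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = length(modelStarts) > 1L, verbose = FALSE),
    error = function(e) stop("unparseable PDB ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  keep <- at$alt %in% c("", " ", "A") | is.na(at$alt)
  if (dropHydrogens) {
    elt <- guessElement(at$elety, at$elesy)
    keep <- keep & elt != "H"
  }
  idx <- which(keep)
  atoms <- data.frame(
    serial = at$eleno[idx],
    name = trimws(at$elety[idx]),
    element = guessElement(at$elety[idx], at$elesy[idx]),
    resname = trimws(at$resid[idx]),
    resno = at$resno[idx],
    chain = ifelse(is.na(at$chain[idx]), "", at$chain[idx]),
    stringsAsFactors = FALSE)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  sel <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  coords <- array(NA_real_, dim = c(length(idx), 3L, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, sel], ncol = 3, byrow = TRUE)
    coords[, , f] <- m
  }
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in ", path)
  StructureEnsemble(atoms, coords)
}

guessElement <- function(name, symbol = NULL) {
  name <- trimws(name)
  out <- if (!is.null(symbol)) trimws(symbol) else rep("", length(name))
  miss <- is.na(out) | out == ""
  # strip leading digits (e.g. 1H5'), then first letter
  stripped <- sub("^[0-9']+", "", name[miss])
  out[miss] <- toupper(substr(stripped, 1, 1))
  out
}

#' Write a StructureEnsemble as a multi-model PDB file
#'
#' Coordinates are written at the standard PDB precision (1e-3 Angstrom).
#' A single-frame ensemble is still wrapped in `MODEL`/`ENDMDL` records so
#' the round trip through [readStructureEnsemble()] is exact.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructureEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  at <- ensemble@atoms
  con <- file(path, "w")
  on.exit(close(con))
  fmtName <- function(n) {
    # standard PDB alignment: short names start in column 14
    ifelse(nchar(n) >= 4, substr(n, 1, 4), sprintf(" %-3s", n))
  }
  nm <- fmtName(at$name)
  for (f in seq_len(nFrames(ensemble))) {
    writeLines(sprintf("MODEL %8d", f), con)
    m <- frameCoords(ensemble, f)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000, nm, at$resname, substr(at$chain, 1, 1), at$resno,
      m[, 1], m[, 2], m[, 3], 1.00, 0.00, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
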