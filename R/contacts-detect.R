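# Geometric contact detectors. All criteria are inclusive at the boundary
# and restricted to protein-DNA atom pairs. Defaults follow common
# trajectory-analysis practice: hydrogen bond donor-acceptor <= 3.5 A with
# D-H...A >= 120 deg when the donor hydrogen is present (distance-only
# otherwise); salt bridge <= 4.0 A between charged-group heavy atoms;
# apolar carbon/sulfur pair <= 4.5 A.

emptyContacts <- function() {
  data.frame(frame = integer(), protein_chain = character(),
             protein_resno = integer(), protein_resname = character(),
             dna_chain = character(), dna_resno = integer(),
             dna_resname = character(), type = character(),
             specific = logical(), protein_atom = character(),
             dna_atom = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

contactRows <- function(ann, pi, di, type, dist, frame = 1L) {
  data.frame(frame = frame,
             protein_chain = ann$chain[pi],
             protein_resno = ann$resno[pi],
             protein_resname = ann$resnameNorm[pi],
             dna_chain = ann$chain[di],
             dna_resno = ann$resno[di],
             dna_resname = ann$resnameNorm[di],
             type = type,
             specific = ann$role[pi] == "protein_sidechain" &
                        ann$role[di] == "base",
             protein_atom = ann$name[pi],
             dna_atom = ann$name[di],
             distance = dist,
             stringsAsFactors = FALSE)
}

crossDist <- function(a, b) {
  # |a_i - b_j| for row-vectors of two (n x 3) matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

withinPairs <- function(ann, coords, selA, selB, dMax) {
  ia <- which(selA); ib <- which(selB)
  if (!length(ia) || !length(ib)) return(NULL)
  d <- crossDist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
  hit <- which(d <= dMax, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  list(a = ia[hit[, 1]], b = ib[hit[, 2]], d = d[hit])
}

# hydrogens covalently attached to each heavy atom (distance <= 1.25 A)
attachedHydrogens <- function(ann, coords, heavyIdx) {
  hIdx <- which(ann$element == "H")
  if (!length(hIdx)) return(lapply(heavyIdx, function(i) integer()))
  d <- crossDist(coords[heavyIdx, , drop = FALSE],
                 coords[hIdx, , drop = FALSE])
  lapply(seq_along(heavyIdx), function(k) hIdx[which(d[k, ] <= 1.25)])
}

#' Detect protein-DNA hydrogen bonds in one frame
#'
#' A bond is recorded for every donor-acceptor pair (one atom protein, one
#' DNA) with donor-acceptor distance `<= dMax`. When the donor carries at
#' least one hydrogen, the best D-H...A angle must also be `>= angleMin`;
#' donors without hydrogens (e.g. heavy-atom-only models) are scored on
#' distance alone.
#'
#' @param atoms atom table (see [atomTable()]).
#' @param coords (atoms x 3) coordinate matrix for the frame.
#' @param roleTable role annotations, see [atomRoles()].
#' @param dMax donor-acceptor distance cutoff (Angstrom), inclusive.
#' @param angleMin minimum D-H...A angle (degrees), inclusive.
#' @return data.frame of contact records (zero rows when none).
#' @export
detectHbonds <- function(atoms, coords, roleTable = atomRoles(),
                         dMax = 3.5, angleMin = 120) {
  ann <- if (!is.null(atoms$role)) atoms else annotateAtoms(atoms, roleTable)
  out <- list()
  combos <- list(
    list(don = ann$donor & ann$isProtein, acc = ann$acceptor & ann$isDna,
         proteinIsDonor = TRUE),
    list(don = ann$donor & ann$isDna, acc = ann$acceptor & ann$isProtein,
         proteinIsDonor = FALSE))
  for (cb in combos) {
    pp <- withinPairs(ann, coords, cb$don, cb$acc, dMax)
    if (is.null(pp)) next
    donIdx <- unique(pp$a)
    hAtt <- attachedHydrogens(ann, coords, donIdx)
    names(hAtt) <- donIdx
    keep <- vapply(seq_along(pp$a), function(k) {
      hs <- hAtt[[as.character(pp$a[k])]]
      if (!length(hs)) return(TRUE)  # distance-only mode
      dpos <- coords[pp$a[k], ]; apos <- coords[pp$b[k], ]
      ang <- vapply(hs, function(h) {
        v1 <- dpos - coords[h, ]; v2 <- apos - coords[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(max(-1, min(1, cosang))) * 180 / pi
      }, numeric(1))
      max(ang) >= angleMin
    }, logical(1))
    if (!any(keep)) next
    a <- pp$a[keep]; b <- pp$b[keep]; d <- pp$d[keep]
    if (cb$proteinIsDonor) out[[length(out) + 1L]] <- contactRows(ann, a, b, "hbond", d)
    else out[[length(out) + 1L]] <- contactRows(ann, b, a, "hbond", d)
  }
  if (!length(out)) return(emptyContacts())
  do.call(rbind, out)
}

#' Detect protein-DNA salt bridges in one frame
#'
#' Records a salt bridge for every cationic/anionic heavy-atom pair (one
#' protein, one DNA; in practice Arg/Lys side-chain nitrogens against
#' phosphate oxygens) within `dMax`.
#'
#' @inheritParams detectHbonds
#' @param dMax distance cutoff (Angstrom), inclusive; default 4.0.
#' @return data.frame of contact records.
#' @export
detectSaltBridges <- function(atoms, coords, roleTable = atomRoles(),
                              dMax = 4.0) {
  ann <- if (!is.null(atoms$role)) atoms else annotateAtoms(atoms, roleTable)
  heavy <- ann$element != "H"
  out <- list()
  for (dir in 1:2) {
    selP <- ann$isProtein & heavy &
      ann$charge == (if (dir == 1) "cationic" else "anionic")
    selD <- ann$isDna & heavy &
      ann$charge == (if (dir == 1) "anionic" else "cationic")
    pp <- withinPairs(ann, coords, selP, selD, dMax)
    if (!is.null(pp))
      out[[length(out) + 1L]] <- contactRows(ann, pp$a, pp$b, "salt_bridge", pp$d)
  }
  if (!length(out)) return(emptyContacts())
  do.call(rbind, out)
}

#' Detect protein-DNA apolar contacts in one frame
#'
#' Records a contact for every apolar/apolar heavy-atom pair (carbon or
#' sulfur outside charged groups; one protein, one DNA) within `dMax`.
#'
#' @inheritParams detectHbonds
#' @param dMax distance cutoff (Angstrom), inclusive; default 4.5.
#' @return data.frame of contact records.
#' @export
detectApolar <- function(atoms, coords, roleTable = atomRoles(),
                         dMax = 4.5) {
  ann <- if (!is.null(atoms$role)) atoms else annotateAtoms(atoms, roleTable)
  heavy <- ann$element != "H"
  pp <- withinPairs(ann, coords, ann$isProtein & heavy & ann$apolar,
                    ann$isDna & heavy & ann$apolar, dMax)
  if (is.null(pp)) return(emptyContacts())
  contactRows(ann, pp$a, pp$b, "apolar", pp$d)
}

#' All protein-DNA contacts of one frame
#'
#' @inheritParams detectHbonds
#' @param criteria named list of cutoffs: `hbondDmax`, `hbondAngleMin`,
#'   `saltDmax`, `apolarDmax`.
#' @return data.frame of contact records of all three types.
#' @export
detectContacts <- function(atoms, coords, roleTable = atomRoles(),
                           criteria = list()) {
  cr <- utils::modifyList(list(hbondDmax = 3.5, hbondAngleMin = 120,
                               saltDmax = 4.0, apolarDmax = 4.5), criteria)
  ann <- if (!is.null(atoms$role)) atoms else annotateAtoms(atoms, roleTable)
  rbind(detectHbonds(ann, coords, dMax = cr$hbondDmax,
                     angleMin = cr$hbondAngleMin),
        detectSaltBridges(ann, coords, dMax = cr$saltDmax),
        detectApolar(ann, coords, dMax = cr$apolarDmax))
}

#' Unit-weight contact strength of a set of records
#'
#' The strength of a residue pair in a frame is the number of detected
#' contacts between the two residues, each hydrogen bond, salt bridge or
#' apolar contact contributing 1 regardless of type.
#'
#' @param records contact records (one residue pair, one frame) as returned
#'   by the detectors.
#' @return integer count.
#' @export
contactStrength <- function(records) {
  nrow(records)
}
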