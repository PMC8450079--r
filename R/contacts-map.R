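# Dynamic contact maps and conformational-substate clustering.

pairKey <- function(rec) {
  paste(rec$protein_chain, rec$protein_resno, rec$protein_resname,
        rec$dna_chain, rec$dna_resno, rec$dna_resname, sep = "|")
}

#' Dynamic contact map of a structural ensemble
#'
#' Runs all three detectors on every frame and aggregates per
#' (protein residue, DNA residue) pair the unit-weight strength, both in
#' total and restricted to specific contacts (side chain to base).
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param roleTable role annotations, see [atomRoles()].
#' @param criteria cutoff list, see [detectContacts()].
#' @return A [ContactStrengthMap-class]; also see [occupancy()] and
#'   [meanStrength()].
#' @export
dynamicContactMap <- function(ensemble, roleTable = atomRoles(),
                              criteria = list()) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  nf <- nFrames(ensemble)
  if (nf == 0L) stop("empty ensemble")
  ann <- annotateAtoms(ensemble@atoms, roleTable)
  recs <- vector("list", nf)
  for (f in seq_len(nf)) {
    r <- detectContacts(ann, frameCoords(ensemble, f), criteria = criteria)
    if (nrow(r)) r$frame <- f
    recs[[f]] <- r
  }
  all <- do.call(rbind, recs)
  if (!nrow(all)) {
    return(new("ContactStrengthMap",
               pairs = data.frame(protein_chain = character(),
                                  protein_resno = integer(),
                                  protein_resname = character(),
                                  dna_chain = character(),
                                  dna_resno = integer(),
                                  dna_resname = character(),
                                  stringsAsFactors = FALSE),
               strength = matrix(0L, nf, 0),
               specific = matrix(0L, nf, 0)))
  }
  keys <- pairKey(all)
  upairs <- !duplicated(keys)
  pairs <- all[upairs, c("protein_chain", "protein_resno", "protein_resname",
                         "dna_chain", "dna_resno", "dna_resname")]
  ord <- order(pairs$protein_chain, pairs$protein_resno,
               pairs$dna_chain, pairs$dna_resno)
  pairs <- pairs[ord, ]
  rownames(pairs) <- NULL
  ukeys <- pairKey(pairs)
  col <- match(keys, ukeys)
  S <- matrix(0L, nf, length(ukeys))
  Ssp <- matrix(0L, nf, length(ukeys))
  for (k in seq_len(nrow(all))) {
    S[all$frame[k], col[k]] <- S[all$frame[k], col[k]] + 1L
    if (all$specific[k])
      Ssp[all$frame[k], col[k]] <- Ssp[all$frame[k], col[k]] + 1L
  }
  new("ContactStrengthMap", pairs = pairs, strength = S, specific = Ssp)
}

#' Per-frame contact fingerprints of one protein residue
#'
#' A fingerprint is a binary vector over the (DNA partner atom, contact
#' type) combinations this residue is ever seen to use; it encodes which of
#' those contacts are present in a given frame.
#'
#' @param records contact records of a whole ensemble (column `frame`
#'   present), e.g. accumulated from [detectContacts()].
#' @param chain,resno protein residue selector.
#' @param nFrames total number of frames (frames without contacts get
#'   all-zero fingerprints).
#' @return (frames x bits) logical matrix; bit names are
#'   `"<dna chain>:<dna resno>:<atom>:<type>"`.
#' @export
contactFingerprints <- function(records, chain, resno, nFrames) {
  sel <- records[records$protein_chain == chain &
                 records$protein_resno == resno, , drop = FALSE]
  bits <- unique(paste(sel$dna_chain, sel$dna_resno, sel$dna_atom,
                       sel$type, sep = ":"))
  fp <- matrix(FALSE, nFrames, length(bits),
               dimnames = list(NULL, bits))
  if (nrow(sel)) {
    b <- paste(sel$dna_chain, sel$dna_resno, sel$dna_atom, sel$type,
               sep = ":")
    fp[cbind(sel$frame, match(b, bits))] <- TRUE
  }
  fp
}

#' Cluster conformational substates from contact fingerprints
#'
#' Groups frames into substates by their contact fingerprints using
#' average-linkage hierarchical clustering with Jaccard distance on the
#' distinct fingerprints, cut at the largest number of clusters for which
#' every cluster holds at least `minOccupancy` of the frames (so every pair
#' of reported clusters differs in at least one fingerprint bit while both
#' are populated). Rare fingerprints are absorbed into the nearest
#' populated cluster by the linkage. Deterministic: ties are resolved by
#' fingerprint order.
#'
#' @param fingerprints (frames x bits) logical/0-1 matrix, see
#'   [contactFingerprints()].
#' @param minOccupancy minimum occupancy of a reported cluster (default 0.1).
#' @return list with `labels` (integer per frame; cluster 1 is the most
#'   occupied) and `occupancy` (named numeric, sorted decreasing).
#' @export
clusterSubstates <- function(fingerprints, minOccupancy = 0.1) {
  fp <- as.matrix(fingerprints) * 1
  nf <- nrow(fp)
  if (nf < 2L) {
    warning("fewer than 2 frames; single substate")
    return(list(labels = rep(1L, nf), occupancy = c(`1` = 1)[seq_len(min(nf, 1))]))
  }
  key <- apply(fp, 1, paste, collapse = "")
  ukey <- unique(key)
  uidx <- match(ukey, key)
  frameCluster <- match(key, ukey)
  nu <- length(ukey)
  if (nu > 1L) {
    ufp <- fp[uidx, , drop = FALSE]
    # Jaccard distance between distinct fingerprints
    inter <- tcrossprod(ufp)
    sz <- rowSums(ufp)
    uni <- outer(sz, sz, "+") - inter
    jac <- 1 - inter / pmax(uni, 1)
    jac[uni == 0] <- 0
    hc <- hclust(as.dist(jac), method = "average")
    counts <- tabulate(frameCluster, nbins = nu)
    chosen <- rep(1L, nu)
    for (k in seq(nu, 1L)) {
      cut <- cutree(hc, k = k)
      occ <- vapply(seq_len(k), function(cl)
        sum(counts[cut == cl]) / nf, numeric(1))
      if (all(occ >= minOccupancy)) { chosen <- cut; break }
    }
    frameCluster <- chosen[frameCluster]
  }
  occ <- sort(table(frameCluster) / nf, decreasing = TRUE)
  relabel <- setNames(seq_along(occ), names(occ))
  labels <- as.integer(relabel[as.character(frameCluster)])
  occ <- sort(tabulate(labels) / nf, decreasing = TRUE)
  names(occ) <- seq_along(occ)
  list(labels = labels, occupancy = occ)
}

#' Write a contact map as TSV tables
#'
#' Emits `<prefix>_pairs.tsv` (pair table with occupancy and mean strength,
#' total and specific) and `<prefix>_strength.tsv` (frames x pairs total
#' strength matrix).
#'
#' @param map a [ContactStrengthMap-class].
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
writeContactMap <- function(map, prefix) {
  pairs <- pairInfo(map)
  pairs$occupancy <- occupancy(map)
  pairs$mean_strength <- meanStrength(map)
  pairs$occupancy_specific <- occupancy(map, specific = TRUE)
  pairs$mean_strength_specific <- meanStrength(map, specific = TRUE)
  p1 <- paste0(prefix, "_pairs.tsv")
  write.table(pairs, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(prefix, "_strength.tsv")
  write.table(strengthMatrix(map), p2, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(p1, p2))
}
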