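# Atom role annotations driving contact detection.

roleCache <- new.env(parent = emptyenv())

#' Atom role table
#'
#' Per (residue name, atom name) annotations used by the contact detectors:
#' structural role (`base`, `sugar`, `phosphate`, `protein_backbone`,
#' `protein_sidechain`), hydrogen-bond donor/acceptor flags, formal-charge
#' class (`cationic`, `anionic`, `neutral`) and an apolar flag (carbon or
#' sulfur not part of a charged group). Ships for the 20 amino acids and the
#' four deoxynucleotides; pass `extra` (a TSV with the same columns) to
#' extend it for modified residues.
#'
#' @param extra optional path to a user TSV appended to the packaged table.
#' @return data.frame with columns `residue_name`, `atom_name`, `role`,
#'   `donor`, `acceptor`, `charge_class`, `apolar`.
#' @export
atomRoles <- function(extra = NULL) {
  if (is.null(roleCache$base)) {
    path <- system.file("extdata", "atom_roles.tsv", package = "yreflank",
                        mustWork = TRUE)
    roleCache$base <- read.table(path, header = TRUE, sep = "\t",
                                 quote = "", stringsAsFactors = FALSE)
  }
  tab <- roleCache$base
  if (!is.null(extra)) {
    ext <- read.table(extra, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE)
    if (!identical(names(ext), names(tab)))
      stop("extra role table must have columns: ",
           paste(names(tab), collapse = ", "))
    tab <- rbind(tab, ext)
    tab <- tab[!duplicated(tab[, c("residue_name", "atom_name")],
                           fromLast = TRUE), ]
  }
  tab
}

#' Normalize residue names to the role-table vocabulary
#'
#' Maps common nucleotide spellings (`A`, `ADE`, `DA5`, `DA3`, ...) onto
#' `DA`/`DC`/`DG`/`DT`; amino-acid names pass through upper-cased.
#'
#' @param resname character vector of residue names.
#' @return normalized character vector.
#' @export
normalizeResname <- function(resname) {
  r <- toupper(trimws(resname))
  r <- sub("^(D[ACGT])[35]$", "\\1", r)
  map <- c(A = "DA", C = "DC", G = "DG", T = "DT",
           ADE = "DA", CYT = "DC", GUA = "DG", THY = "DT")
  hit <- r %in% names(map)
  r[hit] <- map[r[hit]]
  r
}

# Annotate an atom table with roles; unknown heavy atoms are reported via
# warning (never silently dropped), hydrogens are tagged role "hydrogen".
annotateAtoms <- function(atoms, roleTable = atomRoles()) {
  res <- normalizeResname(atoms$resname)
  key <- paste(res, atoms$name)
  tkey <- paste(roleTable$residue_name, roleTable$atom_name)
  idx <- match(key, tkey)
  out <- atoms
  out$resnameNorm <- res
  out$role <- roleTable$role[idx]
  out$donor <- roleTable$donor[idx]
  out$acceptor <- roleTable$acceptor[idx]
  out$charge <- roleTable$charge_class[idx]
  out$apolar <- roleTable$apolar[idx]
  isH <- atoms$element == "H"
  out$role[isH] <- "hydrogen"
  out$donor[isH] <- FALSE; out$acceptor[isH] <- FALSE
  out$charge[isH] <- "neutral"; out$apolar[isH] <- FALSE
  unknown <- is.na(out$role)
  if (any(unknown)) {
    warning("unknown atoms (excluded from contact analysis): ",
            paste(unique(key[unknown]), collapse = ", "))
    out$role[unknown] <- "unknown"
    out$donor[unknown] <- FALSE; out$acceptor[unknown] <- FALSE
    out$charge[unknown] <- "neutral"; out$apolar[unknown] <- FALSE
  }
  out$isProtein <- out$role %in% c("protein_backbone", "protein_sidechain")
  out$isDna <- out$role %in% c("base", "sugar", "phosphate")
  # hydrogens inherit the molecule of their residue
  protRes <- unique(res[out$isProtein])
  out$isProtein[isH] <- res[isH] %in% protRes | res[isH] %in%
    unique(roleTable$residue_name[roleTable$role == "protein_backbone"])
  dnaRes <- c("DA", "DC", "DG", "DT")
  out$isDna[isH] <- res[isH] %in% dnaRes
  out
}
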