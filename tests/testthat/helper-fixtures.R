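# Shared fixtures and independent oracles used across the test files.

# uniformly random rotation matrix via a random unit quaternion
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

randomBaseFrame <- function(spread = 10) {
  BaseFrame(rnorm(3, 0, spread), randomRotation())
}

randomStepParams <- function() {
  c(runif(1, -3, 3), runif(1, -3, 3), runif(1, 2, 5),
    runif(1, -25, 25), runif(1, -25, 25), runif(1, 5, 60))
}

# independent RMSD oracle: quaternion (Horn) method for the optimal
# superposition of mobile onto reference
quaternionRmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)  # sum over atoms of a_i b_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(mobile)
  sqrt(max(0, msd))
}

# a random annotated frame for the brute-force contact oracle: hydrogens
# excluded so hydrogen bonding is in distance-only mode for both routes
randomContactFrame <- function(nAtoms = 60, box = 12) {
  roles <- atomRoles()
  roles <- roles[!grepl("^H", roles$atom_name), ]
  pick <- roles[sample.int(nrow(roles), nAtoms, replace = TRUE), ]
  isProt <- pick$role %in% c("protein_backbone", "protein_sidechain")
  atoms <- data.frame(
    serial = seq_len(nAtoms),
    name = pick$atom_name,
    element = substr(sub("^[0-9']+", "", pick$atom_name), 1, 1),
    resname = pick$residue_name,
    resno = sample.int(12, nAtoms, replace = TRUE),
    chain = ifelse(isProt, "P", "D"),
    stringsAsFactors = FALSE)
  coords <- matrix(runif(nAtoms * 3, 0, box), ncol = 3)
  list(atoms = atoms, coords = coords, roles = pick, isProtein = isProt)
}

# all-pairs brute-force contact filter, written directly against the role
# table (independent of the package's vectorised detectors)
bruteForceContacts <- function(frame, type, dMax) {
  at <- frame$atoms; rl <- frame$roles; xyz <- frame$coords
  hits <- list()
  for (i in seq_len(nrow(at))) for (j in seq_len(nrow(at))) {
    if (!frame$isProtein[i] || frame$isProtein[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > dMax) next
    ok <- switch(type,
      hbond = (rl$donor[i] && rl$acceptor[j]) ||
              (rl$acceptor[i] && rl$donor[j]),
      salt_bridge = (rl$charge_class[i] == "cationic" &&
                     rl$charge_class[j] == "anionic") ||
                    (rl$charge_class[i] == "anionic" &&
                     rl$charge_class[j] == "cationic"),
      apolar = rl$apolar[i] && rl$apolar[j])
    if (ok) hits[[length(hits) + 1L]] <-
      data.frame(protein = i, dna = j, distance = d)
  }
  if (!length(hits)) return(data.frame(protein = integer(),
                                       dna = integer(),
                                       distance = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$protein, out$dna), , drop = FALSE]
}

# canonical key for comparing contact record sets
contactKey <- function(rec) {
  sort(paste(rec$protein_atom, rec$protein_resno, rec$dna_atom,
             rec$dna_resno, round(rec$distance, 6), sep = "/"))
}

# six-oligomer study table as a promoter table
studyTable <- function() {
  data.frame(id = names(yreStudyOligomers()),
             sequence = unname(yreStudyOligomers()),
             expression_bin = NA_integer_, stringsAsFactors = FALSE)
}
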