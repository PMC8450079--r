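# Contact detection, strength scoring, dynamic maps and substate
# clustering.

# minimal hand-built frame: a serine donor group against a thymine O4
donorFrame <- function(oxDist, withH = TRUE, hPos = NULL) {
  atoms <- data.frame(
    serial = 1:3,
    name = c("OG", "HG", "O4"),
    element = c("O", "H", "O"),
    resname = c("SER", "SER", "DT"),
    resno = c(1L, 1L, 2L),
    chain = c("P", "P", "D"), stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0),
                  if (is.null(hPos)) c(1, 0, 0) else hPos,
                  c(oxDist, 0, 0))
  if (!withH) {
    atoms <- atoms[-2, ]; coords <- coords[-2, , drop = FALSE]
  }
  list(atoms = atoms, coords = coords)
}

test_that("collinear donor-H-acceptor geometry is one hydrogen bond", {
  f <- donorFrame(3.2)
  r <- detectHbonds(f$atoms, f$coords)
  expect_equal(nrow(r), 1L)
  expect_equal(r$type, "hbond")
  expect_true(r$specific)  # SER OG side chain vs DT O4 base
  f2 <- donorFrame(5.0)
  expect_equal(nrow(detectHbonds(f2$atoms, f2$coords)), 0L)
})

test_that("the distance boundary is inclusive", {
  f <- donorFrame(3.5)
  expect_equal(nrow(detectHbonds(f$atoms, f$coords, dMax = 3.5)), 1L)
  f2 <- donorFrame(3.5000001)
  expect_equal(nrow(detectHbonds(f2$atoms, f2$coords, dMax = 3.5)), 0L)
})

test_that("the hydrogen angle criterion gates detection", {
  # H placed perpendicular: D-H...A angle ~45 deg, below the 120 cutoff
  f <- donorFrame(3.0, hPos = c(0, 1, 0))
  expect_equal(nrow(detectHbonds(f$atoms, f$coords)), 0L)
  # without the hydrogen the same geometry passes in distance-only mode
  f2 <- donorFrame(3.0, withH = FALSE)
  expect_equal(nrow(detectHbonds(f2$atoms, f2$coords)), 1L)
})

test_that("salt bridges respect the cationic/anionic distance cutoff", {
  mk <- function(d) list(
    atoms = data.frame(serial = 1:2, name = c("NH1", "OP1"),
                       element = c("N", "O"), resname = c("ARG", "DA"),
                       resno = c(1L, 2L), chain = c("P", "D"),
                       stringsAsFactors = FALSE),
    coords = rbind(c(0, 0, 0), c(d, 0, 0)))
  f <- mk(3.8)
  r <- detectSaltBridges(f$atoms, f$coords, dMax = 4.0)
  expect_equal(nrow(r), 1L)
  expect_false(r$specific)  # phosphate oxygen is not a base atom
  f2 <- mk(4.5)
  expect_equal(nrow(detectSaltBridges(f2$atoms, f2$coords, dMax = 4.0)), 0L)
})

test_that("every detector agrees with the all-pairs brute-force oracle", {
  set.seed(99)
  for (rep in 1:5) {
    fr <- randomContactFrame(nAtoms = 60)
    got <- detectHbonds(fr$atoms, fr$coords, dMax = 3.5)
    expect_identical(contactKey(got),
                     with(bruteForceContacts(fr, "hbond", 3.5),
                          sort(paste(fr$atoms$name[protein],
                                     fr$atoms$resno[protein],
                                     fr$atoms$name[dna], fr$atoms$resno[dna],
                                     round(distance, 6), sep = "/"))))
    got <- detectSaltBridges(fr$atoms, fr$coords, dMax = 4.0)
    expect_identical(contactKey(got),
                     with(bruteForceContacts(fr, "salt_bridge", 4.0),
                          sort(paste(fr$atoms$name[protein],
                                     fr$atoms$resno[protein],
                                     fr$atoms$name[dna], fr$atoms$resno[dna],
                                     round(distance, 6), sep = "/"))))
    got <- detectApolar(fr$atoms, fr$coords, dMax = 4.5)
    expect_identical(contactKey(got),
                     with(bruteForceContacts(fr, "apolar", 4.5),
                          sort(paste(fr$atoms$name[protein],
                                     fr$atoms$resno[protein],
                                     fr$atoms$name[dna], fr$atoms$resno[dna],
                                     round(distance, 6), sep = "/"))))
  }
})

test_that("specific records always pair a side-chain atom with a base atom", {
  set.seed(17)
  roles <- atomRoles()
  for (rep in 1:3) {
    fr <- randomContactFrame(nAtoms = 80)
    rec <- detectContacts(fr$atoms, fr$coords)
    if (!nrow(rec)) next
    pRole <- roles$role[match(paste(rec$protein_resname, rec$protein_atom),
                              paste(roles$residue_name, roles$atom_name))]
    dRole <- roles$role[match(paste(rec$dna_resname, rec$dna_atom),
                              paste(roles$residue_name, roles$atom_name))]
    expect_identical(rec$specific,
                     pRole == "protein_sidechain" & dRole == "base")
  }
})

test_that("contact strength is the unit-weight record count", {
  f <- donorFrame(3.2)
  expect_equal(contactStrength(detectHbonds(f$atoms, f$coords)), 1L)
  expect_equal(contactStrength(detectHbonds(f$atoms, f$coords)[0, ]), 0L)
  # engineered frame with one hbond + one salt + one apolar on one pair
  sched <- list(hbond = TRUE, salt = TRUE, apolar = TRUE)
  g <- genStructureEnsemble("TTACTAA", nFrames = 1, schedule = sched)
  rec <- detectContacts(g$ensemble@atoms, frameCoords(g$ensemble, 1))
  expect_equal(nrow(rec), 3L)
  expect_setequal(rec$type, c("hbond", "salt_bridge", "apolar"))
})

test_that("detection is invariant under rigid-body motion of the frame", {
  set.seed(31)
  fr <- randomContactFrame(nAtoms = 70)
  before <- detectContacts(fr$atoms, fr$coords)
  R <- randomRotation(); t <- rnorm(3, 0, 20)
  moved <- sweep(fr$coords %*% t(R), 2, t, "+")
  after <- detectContacts(fr$atoms, moved)
  expect_equal(nrow(after), nrow(before))
  expect_equal(sort(paste(after$protein_atom, after$dna_atom)),
               sort(paste(before$protein_atom, before$dna_atom)))
  expect_equal(sort(after$distance), sort(before$distance), tolerance = 1e-9)
})

test_that("dynamic maps reproduce a programmed contact schedule", {
  sched <- list(hbond = rep(c(TRUE, FALSE), each = 5),
                salt = rep(c(TRUE, FALSE), 5))
  g <- genStructureEnsemble("TTACTAAGG", nFrames = 10, schedule = sched)
  map <- dynamicContactMap(g$ensemble)
  expect_s4_class(map, "ContactStrengthMap")
  pr <- pairInfo(map)
  hb <- which(pr$protein_resname == "SER")
  sb <- which(pr$protein_resname == "ARG")
  expect_equal(unname(strengthMatrix(map)[, hb]), as.integer(sched$hbond))
  expect_equal(unname(strengthMatrix(map)[, sb]), as.integer(sched$salt))
  expect_equal(unname(occupancy(map)[hb]), 0.5)
  expect_equal(unname(occupancy(map)[sb]), 0.5)
  # specific map: hbond probe touches a base atom, salt probe does not
  expect_equal(sum(strengthMatrix(map, specific = TRUE)[, sb]), 0L)
  expect_equal(sum(strengthMatrix(map, specific = TRUE)[, hb]), 5L)
  # map totals equal the per-frame record counts
  for (f in c(1, 6)) {
    rec <- detectContacts(g$ensemble@atoms, frameCoords(g$ensemble, f))
    expect_equal(sum(strengthMatrix(map)[f, ]), nrow(rec))
  }
  expect_error(dynamicContactMap(
    StructureEnsemble(g$ensemble@atoms,
                      array(0, c(nAtoms(g$ensemble), 3, 0)))), "empty")
})

test_that("mean strength never exceeds the per-frame maximum", {
  sched <- list(hbond = rep(TRUE, 6), apolar = c(TRUE, TRUE, rep(FALSE, 4)))
  g <- genStructureEnsemble("TTACTAA", nFrames = 6, schedule = sched)
  map <- dynamicContactMap(g$ensemble)
  expect_true(all(meanStrength(map) <= apply(strengthMatrix(map), 2, max)))
})

test_that("substate clustering recovers trivial and planted structure", {
  # constant fingerprint: one cluster at full occupancy
  fp <- matrix(TRUE, 20, 3)
  cl <- clusterSubstates(fp)
  expect_equal(unique(cl$labels), 1L)
  expect_equal(unname(cl$occupancy), 1)

  # two alternating fingerprints: 0.5/0.5
  fp2 <- matrix(c(TRUE, FALSE), 20, 2)
  fp2[, 2] <- !fp2[, 1]
  cl2 <- clusterSubstates(fp2)
  expect_equal(sort(unique(cl2$labels)), c(1L, 2L))
  expect_equal(unname(cl2$occupancy), c(0.5, 0.5))

  expect_warning(clusterSubstates(matrix(TRUE, 1, 2)), "fewer than 2")
})

test_that("a planted 3-state schedule survives 5% fingerprint noise", {
  set.seed(77)
  states <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0),
                  c(0, 0, 0, 0, 1, 1))
  truth <- rep(1:3, times = c(120, 100, 80))
  fp <- states[truth, ]
  noise <- matrix(runif(length(fp)) < 0.05, nrow(fp))
  fp <- (fp + noise) %% 2
  cl <- clusterSubstates(fp, minOccupancy = 0.1)
  # best label matching via the confusion table
  conf <- table(truth, cl$labels)
  agreement <- sum(apply(conf, 1, max)) / length(truth)
  expect_gte(agreement, 0.9)
})
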