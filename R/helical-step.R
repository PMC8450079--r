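# Base-pair-step parameter geometry.
#
# Convention: mid-step frame decomposition in the style of the standard
# base-pair-step definition (El Hassan-Calladine / 3DNA). The net rotation
# between consecutive base-pair triads is split symmetrically about the
# bending hinge; translations (shift, slide, rise) are the components of
# the origin displacement in the mid-step frame; the bending angle is
# decomposed into roll (about the mid-frame y axis) and tilt (about x),
# twist is the residual rotation about the mid-frame z axis. With the
# builder's base-pair frames (x toward the major groove) a positive shift
# moves a base pair out of the major groove, which is the sign convention
# used throughout the package.

rotationAbout <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  c1 <- cos(theta); s1 <- sin(theta); C <- 1 - c1
  matrix(c(
    c1 + u[1]^2 * C,       u[1] * u[2] * C - u[3] * s1, u[1] * u[3] * C + u[2] * s1,
    u[2] * u[1] * C + u[3] * s1, c1 + u[2]^2 * C,       u[2] * u[3] * C - u[1] * s1,
    u[3] * u[1] * C - u[2] * s1, u[3] * u[2] * C + u[1] * s1, c1 + u[3]^2 * C),
    3, 3, byrow = TRUE)
}

rotZ <- function(theta) rotationAbout(c(0, 0, 1), theta)
rotY <- function(theta) rotationAbout(c(0, 1, 0), theta)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

checkFrame <- function(frame, what = "frame") {
  if (!is(frame, "BaseFrame")) stop(what, " must be a BaseFrame")
  validObject(frame)
  invisible(frame)
}

#' Extract the six base-pair-step parameters between two frames
#'
#' Returns the rigid-body step parameters relating `frameA` (5' side) to
#' `frameB` (3' side): translations `shift`, `slide`, `rise` (Angstrom,
#' expressed in the mid-step frame) and rotations `tilt`, `roll`, `twist`
#' (degrees). Exact inverse of [rebuildStep()].
#'
#' @param frameA,frameB [BaseFrame-class] objects of consecutive base pairs.
#' @return named numeric(6): shift, slide, rise, tilt, roll, twist.
#' @export
stepParameters <- function(frameA, frameB) {
  checkFrame(frameA, "frameA"); checkFrame(frameB, "frameB")
  Ta <- frameA@axes; Tb <- frameB@axes
  za <- Ta[, 3]; zb <- Tb[, 3]
  cosg <- max(-1, min(1, sum(za * zb)))
  gamma <- acos(cosg)
  hinge <- cross3(za, zb)
  if (sqrt(sum(hinge^2)) < 1e-12) {
    Ta2 <- Ta; Tb2 <- Tb
    hinge <- Ta[, 2]; gamma <- 0
  } else {
    Ta2 <- rotationAbout(hinge, gamma / 2) %*% Ta
    Tb2 <- rotationAbout(hinge, -gamma / 2) %*% Tb
  }
  zm <- Ta2[, 3]
  ya <- Ta2[, 2]; yb <- Tb2[, 2]
  omega <- atan2(sum(cross3(ya, yb) * zm), sum(ya * yb))
  ym <- ya + yb; ym <- ym / sqrt(sum(ym^2))
  xm <- cross3(ym, zm)
  Tm <- cbind(xm, ym, zm)
  hu <- hinge / sqrt(sum(hinge^2))
  phi <- atan2(sum(cross3(hu, ym) * zm), sum(hu * ym))
  tr <- as.numeric(crossprod(Tm, frameB@origin - frameA@origin))
  c(shift = tr[1], slide = tr[2], rise = tr[3],
    tilt = gamma * sin(phi) * 180 / pi,
    roll = gamma * cos(phi) * 180 / pi,
    twist = omega * 180 / pi)
}

#' Rebuild the 3'-side frame from step parameters
#'
#' Given the frame of base pair i and the six step parameters, constructs
#' the frame of base pair i+1 such that
#' `stepParameters(frameA, rebuildStep(params, frameA))` returns `params`
#' (to 1e-6). Used to build synthetic DNA to prescribed geometry.
#'
#' @param params numeric(6): shift, slide, rise (Angstrom), tilt, roll,
#'   twist (degrees), in that order (names are ignored).
#' @param frameA [BaseFrame-class] of the 5'-side base pair.
#' @return [BaseFrame-class] of the 3'-side base pair.
#' @export
rebuildStep <- function(params, frameA) {
  checkFrame(frameA, "frameA")
  params <- as.numeric(params)
  if (length(params) != 6L || !all(is.finite(params)))
    stop("params must be six finite values")
  tilt <- params[4] * pi / 180
  roll <- params[5] * pi / 180
  omega <- params[6] * pi / 180
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- atan2(tilt, roll)
  Ta <- frameA@axes
  Tb <- Ta %*% rotZ(omega / 2 - phi) %*% rotY(gamma) %*% rotZ(omega / 2 + phi)
  Tm <- Ta %*% rotZ(omega / 2 - phi) %*% rotY(gamma / 2) %*% rotZ(phi)
  ob <- frameA@origin + as.numeric(Tm %*% params[1:3])
  # re-orthonormalize against accumulated numerical drift when chaining
  sv <- svd(Tb)
  Tb <- sv$u %*% t(sv$v)
  BaseFrame(ob, Tb)
}

#' Build per-step parameter series from per-frame base-pair frames
#'
#' Applies [stepParameters()] to every pair of consecutive base-pair frames
#' of every snapshot.
#'
#' @param frames list of snapshots; each snapshot is a list of
#'   [BaseFrame-class] objects, 5' to 3'.
#' @param stepLabels,regionTags step annotation of the N-1 steps; see
#'   [StepParameterSeries-class].
#' @return A [StepParameterSeries-class] with one row per snapshot.
#' @export
seriesFromFrames <- function(frames, stepLabels, regionTags) {
  nbp <- unique(lengths(frames))
  if (length(nbp) != 1L)
    stop("all snapshots must have the same number of base-pair frames")
  if (nbp < 2L) stop("need at least two base pairs per snapshot")
  nf <- length(frames); ns <- nbp - 1L
  mats <- lapply(HELICAL_PARAMETERS, function(p) matrix(NA_real_, nf, ns))
  names(mats) <- HELICAL_PARAMETERS
  for (f in seq_len(nf)) {
    snap <- frames[[f]]
    for (s in seq_len(ns)) {
      p <- stepParameters(snap[[s]], snap[[s + 1L]])
      for (k in HELICAL_PARAMETERS) mats[[k]][f, s] <- p[[k]]
    }
  }
  StepParameterSeries(mats$shift, mats$slide, mats$rise,
                      mats$tilt, mats$roll, mats$twist,
                      stepLabels, regionTags)
}

#' Region tags for the steps of a sequence containing one response element
#'
#' Steps wholly inside the element are tagged `"yre"`; the step joining the
#' k-th flanking base to the element (and onward outward) is `"-k"` on the
#' 5' side and `"+k"` on the 3' side.
#'
#' @param sequence promoter/oligomer sequence (character scalar).
#' @param yreStart 1-based start of the response element in `sequence`.
#' @param yreLength length of the response element.
#' @return list with `stepLabels` (dinucleotides) and `regionTags`, each of
#'   length `nchar(sequence) - 1`.
#' @export
stepRegions <- function(sequence, yreStart, yreLength) {
  n <- nchar(sequence)
  stopifnot(yreStart >= 1, yreStart + yreLength - 1 <= n)
  starts <- seq_len(n - 1L)
  labels <- substring(sequence, starts, starts + 1L)
  yreEnd <- yreStart + yreLength - 1L
  tags <- character(n - 1L)
  for (s in starts) {
    if (s >= yreStart && s + 1L <= yreEnd) tags[s] <- "yre"
    else if (s < yreStart) tags[s] <- paste0("-", yreStart - s)
    else tags[s] <- paste0("+", s - yreEnd + 1L)
  }
  list(stepLabels = labels, regionTags = tags)
}
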