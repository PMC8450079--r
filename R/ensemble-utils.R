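# Superposition, RMSD, windowed average structures, dihedrals and BI/BII
# backbone classification.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` via singular
#' value decomposition of the covariance matrix, with the usual determinant
#' correction so the result is a proper rotation.
#'
#' @param mobile,reference (n x 3) coordinate matrices, n >= 3,
#'   non-collinear.
#' @return list with `rotation` (3x3), `translation` (3-vector; the
#'   transform is `coords %*% t(rotation) + translation`), `rmsd` (Angstrom,
#'   after superposition) and `transformed` (the superposed mobile
#'   coordinates).
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have identical dimensions")
  if (nrow(mobile) < 3L) stop("need at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (svd(B)$d[2] < 1e-8 || svd(A)$d[2] < 1e-8)
    stop("degenerate (collinear) coordinate set")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  transformed <- sweep(tcrossprod(A, R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((transformed - reference)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       rmsd = rmsd, transformed = transformed)
}

#' RMSD time series of an ensemble against a reference
#'
#' Each frame is rigidly superposed onto the reference before the RMSD is
#' taken.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param reference frame index (1-based) or an (n x 3) coordinate matrix.
#' @param selection optional integer vector of atom indices (default: all
#'   atoms). For DNA-only RMSD pass the DNA heavy-atom indices.
#' @return data.frame with columns `frame` and `rmsd` (Angstrom).
#' @export
rmsdSeries <- function(ensemble, reference = 1L, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nAtoms(ensemble))
  ref <- if (is.matrix(reference)) reference
         else frameCoords(ensemble, reference)[selection, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(ensemble)), function(f) {
    kabschSuperpose(frameCoords(ensemble, f)[selection, , drop = FALSE],
                    ref)$rmsd
  }, numeric(1))
  data.frame(frame = seq_len(nFrames(ensemble)), rmsd = vals)
}

#' Atom indices of DNA heavy atoms
#'
#' Convenience selector for the customary DNA-heavy-atom RMSD.
#' @param ensemble a [StructureEnsemble-class].
#' @export
dnaHeavyAtoms <- function(ensemble) {
  ann <- annotateAtoms(ensemble@atoms)
  which(ann$isDna & ann$element != "H")
}

#' Mean structure over a window of frames
#'
#' Frames in the window are superposed onto a reference (the raw mean of
#' the window, iterated once: mean, superpose all frames onto it,
#' re-average) before averaging, unless `superpose = FALSE`.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param window integer vector of frame indices.
#' @param superpose superpose frames before averaging?
#' @param reference optional (n x 3) matrix to superpose onto instead of
#'   the window mean.
#' @return (atoms x 3) mean coordinate matrix.
#' @export
windowedAverageStructure <- function(ensemble, window, superpose = TRUE,
                                     reference = NULL) {
  window <- as.integer(window)
  if (!length(window)) stop("empty window")
  if (any(window < 1L | window > nFrames(ensemble)))
    stop("window indices out of range")
  frames <- lapply(window, function(f) frameCoords(ensemble, f))
  raw <- Reduce("+", frames) / length(frames)
  if (!superpose) return(raw)
  ref <- if (is.null(reference)) raw else reference
  fitted <- lapply(frames, function(m) kabschSuperpose(m, ref)$transformed)
  Reduce("+", fitted) / length(fitted)
}

#' Convergence of window-averaged structures
#'
#' Computes the mean structure of each window (all superposed onto the
#' first window's mean) and the pairwise RMSDs between the means. With
#' cumulative, increasing windows this is the usual convergence check for
#' a trajectory.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param windows list of integer frame-index vectors.
#' @param superpose superpose frames before averaging?
#' @return list with `means` (list of mean coordinate matrices) and `rmsd`
#'   (symmetric matrix of pairwise mean-structure RMSDs).
#' @export
convergenceRmsd <- function(ensemble, windows, superpose = TRUE) {
  if (!length(windows)) stop("empty window list")
  ref <- windowedAverageStructure(ensemble, windows[[1]], superpose)
  means <- lapply(windows, function(w)
    windowedAverageStructure(ensemble, w, superpose, reference = ref))
  k <- length(means)
  rm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      rm[i, j] <- rm[j, i] <-
        if (superpose) kabschSuperpose(means[[i]], means[[j]])$rmsd
        else sqrt(mean(rowSums((means[[i]] - means[[j]])^2)))
    }
  }
  list(means = means, rmsd = rm)
}

#' Signed dihedral angle of four points
#'
#' Standard torsion about the b-c axis, in degrees in (-180, 180].
#'
#' @param a,b,c,d numeric(3) coordinates.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Wrap angles to (-180, 180]
#' @param theta angles in degrees.
#' @export
wrapAngle <- function(theta) {
  w <- theta - 360 * floor((theta + 180) / 360)
  w[w == -180] <- 180
  w
}

#' Classify DNA backbone substates BI / BII
#'
#' BI when the wrapped difference epsilon - zeta is negative, BII
#' otherwise (boundary at 0 degrees); angles are wrapped to (-180, 180]
#' before differencing.
#'
#' @param epsilon,zeta backbone torsions in degrees (any range).
#' @return character vector of `"BI"` / `"BII"`.
#' @export
classifyBackbone <- function(epsilon, zeta) {
  d <- wrapAngle(wrapAngle(epsilon) - wrapAngle(zeta))
  ifelse(d < 0, "BI", "BII")
}
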