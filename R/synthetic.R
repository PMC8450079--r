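# Seeded synthetic generators. Each generator emulates one input class of
# the pipeline and returns the planted ground truth alongside, so every
# downstream analysis has a recoverable answer.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

sampleBackground <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a random promoter library with one planted response element
#'
#' Emulates a random-promoter reporter assay: `length`-bp promoters (80 by
#' default) each carrying exactly one planted YRE instance with controlled
#' flanks, i.i.d. uniform background rejected until free of further YRE or
#' exclusion-motif instances, and an expression bin (0 = weakest) derived
#' from a per-flank-group mean plus Gaussian noise, rounded and clamped
#' into `[0, bins - 1]`.
#'
#' Flank designs: `"exhaustive"` emits one promoter per flank combination
#' at `flankWidth` (4^(2w) promoters; `n` is ignored), `"sampled"` draws
#' `n` promoters with random flanks, `"fixed"` uses `fixedFlanks` for all.
#' Group means are planted per flank key at width `effectWidth` (4 by
#' default, so 4-wide grouping is exactly the planted partition and 2-wide
#' grouping mixes several planted means).
#'
#' @param n number of promoters (sampled / fixed designs).
#' @param length promoter length in nt (study value: 80).
#' @param yre planted motif (default YRE1, `TTACTAA`).
#' @param flankDesign `"exhaustive"`, `"sampled"` or `"fixed"`.
#' @param flankWidth controlled flank width for the exhaustive design.
#' @param fixedFlanks list(five_prime, three_prime) for the fixed design.
#' @param bins number of expression bins (study value: 18).
#' @param baseMean grand mean expression bin.
#' @param effectSd standard deviation of planted per-group mean offsets
#'   (0 plants no flank effect).
#' @param noiseSd within-group expression noise (bins).
#' @param effectWidth flank width at which group means are planted.
#' @param exclusionMotifs motifs kept out of the background (default: the
#'   other two response elements, so the single-instance filter over all
#'   three YREs keeps every generated promoter).
#' @param position 0-based site start; `NULL` centres the site.
#' @param maxTries rejection-sampling retries per promoter.
#' @param seed integer seed; identical seeds give identical libraries.
#' @return list with `promoters` (a promoter table) and `truth`
#'   (data.frame: `id`, `start`, `strand`, `five_prime`, `three_prime`,
#'   `group_key`, `group_mean` at `effectWidth`).
#' @export
genPromoterLibrary <- function(n = 256, length = 80L, yre = "TTACTAA",
                               flankDesign = c("sampled", "exhaustive", "fixed"),
                               flankWidth = 2L,
                               fixedFlanks = NULL,
                               bins = 18L, baseMean = 9, effectSd = 2,
                               noiseSd = 1.5, effectWidth = 4L,
                               exclusionMotifs = NULL,
                               position = NULL, maxTries = 1000L,
                               seed = NULL) {
  flankDesign <- match.arg(flankDesign)
  stopifnot(bins >= 2L)
  if (is.null(exclusionMotifs))
    exclusionMotifs <- setdiff(unname(yreMotifs()), yre)
  withSeed(seed, {
    ylen <- nchar(yre)
    pos <- if (is.null(position)) (length - ylen) %/% 2L else as.integer(position)
    stopifnot(pos >= effectWidth, pos + ylen + effectWidth <= length)
    nt <- c("A", "C", "G", "T")
    flanks <- switch(flankDesign,
      exhaustive = {
        combos <- expand.grid(rep(list(nt), 2L * flankWidth),
                              stringsAsFactors = FALSE)
        apply(combos, 1, function(r) {
          list(five_prime = paste(r[seq_len(flankWidth)], collapse = ""),
               three_prime = paste(r[flankWidth + seq_len(flankWidth)],
                                   collapse = ""))
        })
      },
      sampled = replicate(n, list(
        five_prime = sampleBackground(flankWidth),
        three_prime = sampleBackground(flankWidth)), simplify = FALSE),
      fixed = {
        if (is.null(fixedFlanks)) stop("fixed design needs fixedFlanks")
        replicate(n, fixedFlanks, simplify = FALSE)
      })
    nP <- base::length(flanks)
    groupMeans <- new.env(parent = emptyenv())
    seqs <- character(nP); bins_ <- integer(nP)
    five <- character(nP); three <- character(nP)
    gkey <- character(nP); gmean <- numeric(nP)
    for (i in seq_len(nP)) {
      fw <- flanks[[i]]$five_prime; tw <- flanks[[i]]$three_prime
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        core <- paste0(fw, yre, tw)
        coreStart <- pos - nchar(fw)  # 0-based start of core in promoter
        left <- sampleBackground(coreStart)
        right <- sampleBackground(length - coreStart - nchar(core))
        s <- paste0(left, core, right)
        # exactly one site overall and no exclusion motifs anywhere
        nSites <- nrow(scanMotif(s, yre))
        if (nSites == 1L &&
            !any(vapply(exclusionMotifs, function(m)
              nrow(scanMotif(s, m)) > 0L, logical(1)))) { ok <- TRUE; break }
        # controlled flanks may themselves be infeasible; redraw them in
        # the sampled design
        if (flankDesign == "sampled") {
          fw <- sampleBackground(flankWidth)
          tw <- sampleBackground(flankWidth)
        }
      }
      if (!ok) stop("rejection sampling failed after ", maxTries,
                    " tries for promoter ", i)
      # planted effect keyed on the effectWidth flanks of the final sequence
      ef <- extractFlanks(s, pos, ylen, "+", effectWidth)
      key <- paste(ef$five_prime, ef$three_prime, sep = "|")
      if (!exists(key, envir = groupMeans, inherits = FALSE))
        assign(key, baseMean + rnorm(1, 0, effectSd), envir = groupMeans)
      mu <- get(key, envir = groupMeans, inherits = FALSE)
      b <- round(mu + rnorm(1, 0, noiseSd))
      seqs[i] <- s
      bins_[i] <- as.integer(min(max(b, 0L), bins - 1L))
      five[i] <- fw; three[i] <- tw
      gkey[i] <- key; gmean[i] <- mu
    }
    ids <- sprintf("synth_%05d", seq_len(nP))
    list(
      promoters = data.frame(id = ids, sequence = seqs,
                             expression_bin = bins_,
                             stringsAsFactors = FALSE),
      truth = data.frame(id = ids, start = pos, strand = "+",
                         five_prime = five, three_prime = three,
                         group_key = gkey, group_mean = gmean,
                         stringsAsFactors = FALSE))
  })
}

#' Generate paired bound/unbound step-parameter series with planted
#' alterations
#'
#' The unbound series draws each step's shift from a per-step Gaussian
#' mixture (bimodal by default, emulating the conformational polymorphism
#' of dinucleotide steps); slide/rise/tilt/roll/twist are Gaussian around
#' B-form values. The bound series is identical except that a mean
#' displacement is added to the shift of every step inside the response
#' element and of flanking steps up to `reach5` / `reach3` outward from
#' the element edges. The truth lists exactly the displaced steps.
#'
#' @param sequence oligomer sequence carrying the element.
#' @param yreStart 1-based element start in `sequence`.
#' @param yreLength element length.
#' @param frames number of frames (study-scale default 2000).
#' @param mixtureMeans,mixtureSds,mixtureWeights shift mixture components
#'   (Angstrom); weights must sum to 1.
#' @param displacement bound-state mean shift displacement (Angstrom).
#' @param reach5,reach3 number of flanking steps displaced on each side.
#' @param seed integer seed.
#' @return list with `bound`, `unbound` ([StepParameterSeries-class]) and
#'   `truth` (data.frame: `step_label`, `region`, `altered`).
#' @export
genHelicalSeries <- function(sequence = yreStudyOligomers()[["YRE1_ATR1"]],
                             yreStart = 9L, yreLength = 7L,
                             frames = 2000L,
                             mixtureMeans = c(-0.5, 0.5),
                             mixtureSds = c(0.25, 0.25),
                             mixtureWeights = c(0.5, 0.5),
                             displacement = 1.0,
                             reach5 = 4L, reach3 = 4L,
                             seed = NULL) {
  stopifnot(abs(sum(mixtureWeights) - 1) < 1e-9,
            length(mixtureMeans) == length(mixtureSds),
            length(mixtureMeans) == length(mixtureWeights))
  withSeed(seed, {
    reg <- stepRegions(sequence, yreStart, yreLength)
    ns <- base::length(reg$stepLabels)
    drawShift <- function() {
      comp <- sample.int(length(mixtureWeights), frames, replace = TRUE,
                         prob = mixtureWeights)
      rnorm(frames, mixtureMeans[comp], mixtureSds[comp])
    }
    mk <- function() {
      shift <- vapply(seq_len(ns), function(s) drawShift(),
                      numeric(frames))
      list(shift = shift,
           slide = matrix(rnorm(frames * ns, 0, 0.3), frames),
           rise = matrix(rnorm(frames * ns, 3.38, 0.2), frames),
           tilt = matrix(rnorm(frames * ns, 0, 3), frames),
           roll = matrix(rnorm(frames * ns, 0, 5), frames),
           twist = matrix(rnorm(frames * ns, 34.3, 4), frames))
    }
    ub <- mk(); bd <- mk()
    off5 <- suppressWarnings(as.integer(sub("^-", "", reg$regionTags)))
    altered <- reg$regionTags == "yre" |
      (startsWith(reg$regionTags, "-") & !is.na(off5) & off5 <= reach5) |
      (startsWith(reg$regionTags, "+") &
         suppressWarnings(as.integer(sub("^\\+", "", reg$regionTags))) <= reach3)
    altered[is.na(altered)] <- FALSE
    bd$shift[, altered] <- bd$shift[, altered] + displacement
    mkSeries <- function(m) StepParameterSeries(
      m$shift, m$slide, m$rise, m$tilt, m$roll, m$twist,
      reg$stepLabels, reg$regionTags)
    list(bound = mkSeries(bd), unbound = mkSeries(ub),
         truth = data.frame(step_label = reg$stepLabels,
                            region = reg$regionTags,
                            altered = altered, stringsAsFactors = FALSE))
  })
}

# ---- synthetic structures -------------------------------------------------

# Idealized planar base-pair template in the base-pair reference frame
# (x toward the major groove, y toward the Watson-strand backbone, z along
# the helix axis). Invented coordinates with standard-like bond geometry,
# used consistently by the builder and the frame-fitting code; they are a
# self-consistent template, not fitted crystallographic values.
baseTemplate <- function(base) {
  common <- list(
    c("P", -3.5, 8.0, -1.8), c("OP1", -4.6, 8.6, -1.2),
    c("OP2", -3.3, 8.4, -3.2), c("C1'", -2.0, 4.9, 0))
  bases <- list(
    DA = list(c("N9", -1.30, 4.00, 0), c("C8", -0.20, 4.70, 0),
              c("N7", 0.95, 4.00, 0), c("C5", 0.55, 2.70, 0),
              c("C6", 1.30, 1.55, 0), c("N6", 2.65, 1.60, 0),
              c("N1", 0.65, 0.35, 0), c("C2", -0.70, 0.40, 0),
              c("N3", -1.45, 1.50, 0), c("C4", -0.80, 2.65, 0)),
    DG = list(c("N9", -1.30, 4.00, 0), c("C8", -0.20, 4.70, 0),
              c("N7", 0.95, 4.00, 0), c("C5", 0.55, 2.70, 0),
              c("C6", 1.30, 1.55, 0), c("O6", 2.60, 1.60, 0),
              c("N1", 0.65, 0.30, 0), c("C2", -0.70, 0.40, 0),
              c("N2", -1.40, -0.75, 0), c("N3", -1.45, 1.55, 0),
              c("C4", -0.80, 2.65, 0)),
    DC = list(c("N1", -1.30, 4.00, 0), c("C2", -1.00, 2.65, 0),
              c("O2", -1.95, 1.80, 0), c("N3", 0.25, 2.25, 0),
              c("C4", 1.25, 3.10, 0), c("N4", 2.50, 2.75, 0),
              c("C5", 0.95, 4.45, 0), c("C6", -0.30, 4.85, 0)),
    DT = list(c("N1", -1.30, 4.00, 0), c("C2", -1.00, 2.65, 0),
              c("O2", -1.95, 1.80, 0), c("N3", 0.25, 2.25, 0),
              c("C4", 1.25, 3.05, 0), c("O4", 2.45, 2.70, 0),
              c("C5", 0.95, 4.45, 0), c("C7", 2.00, 5.40, 0),
              c("C6", -0.30, 4.85, 0)))
  rows <- c(common, bases[[base]])
  df <- data.frame(name = vapply(rows, `[`, "", 1),
                   x = as.numeric(vapply(rows, `[`, "", 2)),
                   y = as.numeric(vapply(rows, `[`, "", 3)),
                   z = as.numeric(vapply(rows, `[`, "", 4)),
                   stringsAsFactors = FALSE)
  df
}

complementBase <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# template of a whole base pair: Watson nucleotide at y > 0, Crick
# nucleotide mirrored through y (and x kept, so both major-groove edges
# face +x)
basePairTemplate <- function(watsonBase) {
  w <- baseTemplate(paste0("D", watsonBase))
  c0 <- baseTemplate(paste0("D", complementBase(watsonBase)))
  c0$y <- -c0$y
  list(watson = w, crick = c0,
       watsonRes = paste0("D", watsonBase),
       crickRes = paste0("D", complementBase(watsonBase)))
}

placeAtoms <- function(tmpl, frame) {
  m <- as.matrix(tmpl[, c("x", "y", "z")])
  sweep(m %*% t(frame@axes), 2, frame@origin, "+")
}

#' Build a synthetic protein-DNA structural ensemble with a programmed
#' contact schedule
#'
#' DNA is built by chaining [rebuildStep()] over per-step parameters using
#' an idealized base-pair template; a toy probe group (a serine hydroxyl
#' donor, an arginine guanidinium nitrogen and an alanine methyl carbon,
#' each its own residue on chain `"P"`) is placed relative to a target
#' base pair so that, in frames where the schedule switches a contact
#' type on, exactly one contact of that type is detected, and none when
#' off (the probe is displaced 25 Angstrom away).
#'
#' @param sequence Watson-strand DNA sequence (length >= 2).
#' @param stepParams (N-1 x 6) matrix of step parameters; default ideal
#'   B-form (rise 3.38 A, twist 34.3 deg).
#' @param nFrames number of frames.
#' @param schedule named list of logical vectors of length `nFrames`
#'   (`hbond`, `salt`, `apolar`); missing types are all-off. `NULL` means
#'   naked DNA (no probe atoms).
#' @param targetBp base pair the probes address (default: middle).
#' @param paramNoise per-frame Gaussian jitter added to the step
#'   parameters (6-vector of sds; default none).
#' @param seed integer seed (used only when `paramNoise` is non-zero).
#' @return list with `ensemble` ([StructureEnsemble-class]), `frames`
#'   (per-frame list of [BaseFrame-class] lists, the builder's ground
#'   truth), `schedule` (as used) and `pairing` (Watson resno vs Crick
#'   resno table).
#' @export
genStructureEnsemble <- function(sequence, stepParams = NULL, nFrames = 1L,
                                 schedule = NULL, targetBp = NULL,
                                 paramNoise = rep(0, 6), seed = NULL) {
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) >= 2L, !grepl("[^ACGT]", sequence))
  nbp <- nchar(sequence)
  if (is.null(stepParams))
    stepParams <- matrix(rep(c(0, 0, 3.38, 0, 0, 34.3), each = nbp - 1L),
                         ncol = 6)
  stopifnot(nrow(stepParams) == nbp - 1L, ncol(stepParams) == 6L)
  if (is.null(targetBp)) targetBp <- (nbp + 1L) %/% 2L
  sched <- list(hbond = rep(FALSE, nFrames), salt = rep(FALSE, nFrames),
                apolar = rep(FALSE, nFrames))
  hasProbe <- !is.null(schedule)
  if (hasProbe) sched <- utils::modifyList(sched, schedule)
  bases <- strsplit(sequence, "")[[1]]
  tmpl <- lapply(bases, basePairTemplate)

  withSeed(seed, {
    frameList <- vector("list", nFrames)
    coordList <- vector("list", nFrames)
    atoms <- NULL
    for (f in seq_len(nFrames)) {
      par <- stepParams
      if (any(paramNoise > 0))
        par <- par + matrix(rnorm(length(par), 0,
                                  rep(paramNoise, each = nrow(par))),
                            nrow(par))
      bp <- vector("list", nbp)
      bp[[1]] <- BaseFrame()
      for (s in seq_len(nbp - 1L))
        bp[[s + 1L]] <- rebuildStep(par[s, ], bp[[s]])
      frameList[[f]] <- bp

      coords <- list(); info <- list()
      for (i in seq_len(nbp)) {
        tw <- tmpl[[i]]
        coords[[length(coords) + 1L]] <- placeAtoms(tw$watson, bp[[i]])
        info[[length(info) + 1L]] <- data.frame(
          name = tw$watson$name, resname = tw$watsonRes, resno = i,
          chain = "A", stringsAsFactors = FALSE)
        coords[[length(coords) + 1L]] <- placeAtoms(tw$crick, bp[[i]])
        info[[length(info) + 1L]] <- data.frame(
          name = tw$crick$name, resname = tw$crickRes, resno = i,
          chain = "B", stringsAsFactors = FALSE)
      }
      if (hasProbe) {
        tb <- bp[[targetBp]]
        ax <- tb@axes; xhat <- ax[, 1]; zhat <- ax[, 3]
        tw <- tmpl[[targetBp]]
        wat <- placeAtoms(tw$watson, tb)
        rownames(wat) <- tw$watson$name
        cri <- placeAtoms(tw$crick, tb)
        rownames(cri) <- tw$crick$name
        # hydrogen-bond anchor: a carbonyl-type acceptor on the major
        # groove edge (O4 of T, O6 of G) on whichever strand carries it;
        # the probe approaches straight out of the major groove (+x),
        # which keeps every other donor/acceptor outside the cutoff for
        # the unjittered builder geometry
        accName <- intersect(c("O4", "O6"), tw$watson$name)
        acc <- if (length(accName)) wat[accName[1], ]
               else cri[intersect(c("O4", "O6"), tw$crick$name)[1], ]
        opos <- acc + 2.9 * xhat
        hpos <- acc + 1.9 * xhat
        p <- wat["P", ]; op1 <- wat["OP1", ]
        u <- (op1 - p) / sqrt(sum((op1 - p)^2))
        npos <- op1 + 3.8 * u
        # apolar anchor: thymine methyl when present, else a sugar carbon;
        # approached radially away from the helix axis
        radial <- function(anchor) {
          v <- anchor - tb@origin; v <- v - sum(v * zhat) * zhat
          anchor + 4.0 * v / sqrt(sum(v^2))
        }
        cpos <- if ("C7" %in% tw$watson$name) radial(wat["C7", ])
                else if ("C7" %in% tw$crick$name) radial(cri["C7", ])
                else radial(wat["C1'", ])
        off <- 25 * xhat
        probe <- rbind(
          if (sched$hbond[f]) opos else opos + off,
          if (sched$hbond[f]) hpos else hpos + off,
          if (sched$salt[f]) npos else npos + off,
          if (sched$apolar[f]) cpos else cpos + off)
        coords[[length(coords) + 1L]] <- probe
        info[[length(info) + 1L]] <- data.frame(
          name = c("OG", "HG", "NH1", "CB"),
          resname = c("SER", "SER", "ARG", "ALA"),
          resno = c(1L, 1L, 2L, 3L), chain = "P",
          stringsAsFactors = FALSE)
      }
      coordList[[f]] <- do.call(rbind, coords)
      if (is.null(atoms)) {
        at <- do.call(rbind, info)
        atoms <- data.frame(serial = seq_len(nrow(at)), name = at$name,
                            element = guessElement(at$name),
                            resname = at$resname, resno = at$resno,
                            chain = at$chain, stringsAsFactors = FALSE)
      }
    }
    ens <- StructureEnsemble(atoms, coordList)
    list(ensemble = ens, frames = frameList, schedule = sched,
         pairing = data.frame(watson = seq_len(nbp), crick = seq_len(nbp)))
  })
}

#' Fit base-pair frames to an ensemble by template superposition
#'
#' For every frame and base pair, superposes the idealized base-pair
#' template (same template the builder uses) onto the observed atoms by
#' least squares ([kabschSuperpose()]) and reports the resulting reference
#' frame.
#'
#' @param ensemble a [StructureEnsemble-class] containing DNA chains
#'   `watsonChain`/`crickChain`.
#' @param pairing data.frame with columns `watson`, `crick`: residue
#'   numbers of paired nucleotides, 5' to 3' on the Watson strand.
#' @param watsonChain,crickChain chain ids.
#' @return per-frame list of [BaseFrame-class] lists, suitable for
#'   [seriesFromFrames()].
#' @export
baseFramesFromEnsemble <- function(ensemble, pairing,
                                   watsonChain = "A", crickChain = "B") {
  at <- ensemble@atoms
  res <- normalizeResname(at$resname)
  out <- vector("list", nFrames(ensemble))
  sel <- lapply(seq_len(nrow(pairing)), function(k) {
    wi <- which(at$chain == watsonChain & at$resno == pairing$watson[k])
    ci <- which(at$chain == crickChain & at$resno == pairing$crick[k])
    if (!length(wi) || !length(ci))
      stop("missing nucleotide for base pair ", k)
    wb <- sub("^D", "", res[wi[1]])
    tw <- basePairTemplate(wb)
    tmat <- rbind(as.matrix(tw$watson[, c("x", "y", "z")]),
                  as.matrix(tw$crick[, c("x", "y", "z")]))
    tnames <- c(paste0("W", tw$watson$name), paste0("C", tw$crick$name))
    obsNames <- c(paste0("W", at$name[wi]), paste0("C", at$name[ci]))
    keep <- match(obsNames, tnames)
    if (any(is.na(keep)))
      stop("unknown atoms in base pair ", k, ": ",
           paste(obsNames[is.na(keep)], collapse = ", "))
    list(idx = c(wi, ci), tmpl = tmat[keep, , drop = FALSE])
  })
  for (f in seq_len(nFrames(ensemble))) {
    m <- frameCoords(ensemble, f)
    out[[f]] <- lapply(sel, function(s) {
      fit <- kabschSuperpose(s$tmpl, m[s$idx, , drop = FALSE])
      BaseFrame(fit$translation, fit$rotation)
    })
  }
  out
}
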