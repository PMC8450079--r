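# Response-element scanning, single-instance filtering, flank extraction
# and grouping, expression-dispersion statistics and differential profiles.

#' The three Yap1 response elements
#'
#' YRE1 `TTACTAA` (pseudo-palindromic), YRE2 `TTACGTAA` (palindromic,
#' its own reverse complement) and YRE3 `TGACAAA`.
#'
#' @return named character vector of motifs.
#' @export
yreMotifs <- function() {
  c(YRE1 = "TTACTAA", YRE2 = "TTACGTAA", YRE3 = "TGACAAA")
}

#' The six studied 23-mer oligonucleotides
#'
#' One oligomer per response element (YRE1-3) and genomic environment
#' (ATR1, OYE2), each carrying a single YRE instance with its native
#' flanking sequences.
#'
#' @return named character vector of six 23-mers.
#' @export
yreStudyOligomers <- function() {
  c(YRE1_ATR1 = "TATAGTGATTACTAATGGAATGG",
    YRE1_OYE2 = "GTTTTGCTTTACTAAGCACACGA",
    YRE2_ATR1 = "GCCACAGATTACGTAAGCGATTT",
    YRE2_OYE2 = "GAAATATCTTACGTAATGAACTT",
    YRE3_ATR1 = "TGATTATATGACAAAGTTGAGGG",
    YRE3_OYE2 = "GCTAGCGATGACAAAATGTCTCC")
}

#' Manifest of the studied systems
#'
#' Enumerates the simulated systems: one Yap1-DNA complex and one naked
#' B-DNA duplex per studied oligomer (three response elements in two
#' genomic environments).
#'
#' @return data.frame with one row per system: `system`, `kind`
#'   (`"complex"` / `"naked_dna"`), `yre`, `environment`, `sequence`.
#' @export
yreSystems <- function() {
  ol <- yreStudyOligomers()
  parts <- strsplit(names(ol), "_")
  base <- data.frame(yre = vapply(parts, `[`, "", 1),
                     environment = vapply(parts, `[`, "", 2),
                     sequence = unname(ol), stringsAsFactors = FALSE)
  rbind(
    cbind(system = paste0("Yap1-", names(ol)), kind = "complex", base),
    cbind(system = paste0(names(ol), "-free"), kind = "naked_dna", base))
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan a sequence for exact occurrences of a motif
#'
#' Finds all (overlapping) occurrences of `motif` on the forward strand
#' and, optionally, of its reverse complement (reported by forward-strand
#' 0-based start, strand `"-"`). For a palindromic motif the plus- and
#' minus-strand matches coincide site for site; with
#' `dedupePalindrome = TRUE` (default) each such site is counted once.
#'
#' @param sequence DNA string.
#' @param motif exact motif over `{A,C,G,T}`.
#' @param bothStrands scan the minus strand too?
#' @param dedupePalindrome count palindromic sites once?
#' @return data.frame with columns `start` (0-based, forward strand),
#'   `strand`, `matched` (forward-strand substring).
#' @export
scanMotif <- function(sequence, motif, bothStrands = TRUE,
                      dedupePalindrome = TRUE) {
  sequence <- toupper(sequence); motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  emptyHits <- data.frame(start = integer(), strand = character(),
                          matched = character(), stringsAsFactors = FALSE)
  if (nchar(motif) > nchar(sequence)) return(emptyHits)
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(motif, subj))
  hits <- if (length(fwd))
    data.frame(start = fwd - 1L, strand = "+",
               matched = substring(sequence, fwd, fwd + nchar(motif) - 1L),
               stringsAsFactors = FALSE) else emptyHits
  rc <- revComp(motif)
  if (bothStrands && !(dedupePalindrome && rc == motif)) {
    rev <- Biostrings::start(Biostrings::matchPattern(rc, subj))
    if (length(rev))
      hits <- rbind(hits, data.frame(
        start = rev - 1L, strand = "-",
        matched = substring(sequence, rev, rev + nchar(motif) - 1L),
        stringsAsFactors = FALSE))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# fast per-motif hit counts and positions over a whole promoter table
scanLibrary <- function(sequences, motif, bothStrands = TRUE,
                        dedupePalindrome = TRUE) {
  subj <- Biostrings::DNAStringSet(sequences)
  collect <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, subj)
    st <- Biostrings::startIndex(m)
    lapply(st, function(s)
      if (is.null(s)) data.frame(start = integer(), strand = character())
      else data.frame(start = s - 1L, strand = strand))
  }
  out <- collect(motif, "+")
  rc <- revComp(motif)
  if (bothStrands && !(dedupePalindrome && rc == motif)) {
    rev <- collect(rc, "-")
    out <- Map(rbind, out, rev)
  }
  out
}

#' Keep promoters with exactly one response-element instance
#'
#' A promoter survives when (i) across all `motifs` it contains exactly
#' one (strand-deduplicated) site, (ii) it contains no site of any
#' `exclusionMotifs` (a user-supplied set of other known TF-binding
#' motifs), and (iii) the surviving site has at least `flankWidth`
#' nucleotides on both sides. Rejection counts per reason are reported via
#' `message()`.
#'
#' @param promoters promoter table (see [readPromoterTable()]).
#' @param motifs named character vector of response-element motifs.
#' @param exclusionMotifs character vector of motifs that must be absent
#'   (may be empty).
#' @param flankWidth flank width the surviving site must accommodate.
#' @param bothStrands,dedupePalindrome see [scanMotif()].
#' @return the surviving subset of `promoters` with extra columns `motif`,
#'   `start` (0-based), `strand`.
#' @export
filterSingleInstance <- function(promoters, motifs = yreMotifs(),
                                 exclusionMotifs = character(),
                                 flankWidth = 2L, bothStrands = TRUE,
                                 dedupePalindrome = TRUE) {
  if (is.null(names(motifs))) names(motifs) <- motifs
  if (anyDuplicated(names(motifs)))
    stop("motif names must be unique")
  if (length(intersect(motifs, exclusionMotifs)))
    stop("yre and exclusion motif sets must be disjoint")
  n <- nrow(promoters)
  hitCount <- integer(n)
  hitMotif <- character(n); hitStart <- integer(n); hitStrand <- character(n)
  for (m in seq_along(motifs)) {
    hits <- scanLibrary(promoters$sequence, motifs[[m]],
                        bothStrands, dedupePalindrome)
    k <- vapply(hits, nrow, integer(1))
    hitCount <- hitCount + k
    one <- k == 1L
    hitMotif[one] <- names(motifs)[m]
    hitStart[one] <- vapply(hits[one], function(h) h$start[1], integer(1))
    hitStrand[one] <- vapply(hits[one], function(h) h$strand[1], character(1))
  }
  excl <- logical(n)
  for (em in exclusionMotifs) {
    hits <- scanLibrary(promoters$sequence, em, bothStrands,
                        dedupePalindrome)
    excl <- excl | vapply(hits, nrow, integer(1)) > 0L
  }
  motifLen <- setNames(nchar(motifs), names(motifs))
  fits <- hitCount == 1L &
    hitStart >= flankWidth &
    hitStart + ifelse(hitMotif == "", 0L, motifLen[hitMotif]) + flankWidth <=
      nchar(promoters$sequence)
  keep <- hitCount == 1L & !excl & fits
  message("filterSingleInstance: kept ", sum(keep), "/", n,
          " (multiplicity ", sum(hitCount != 1L),
          ", exclusion ", sum(hitCount == 1L & excl),
          ", insufficient flank ", sum(hitCount == 1L & !excl & !fits), ")")
  out <- promoters[keep, , drop = FALSE]
  out$motif <- hitMotif[keep]
  out$start <- hitStart[keep]
  out$strand <- hitStrand[keep]
  rownames(out) <- NULL
  out
}

#' Extract the flanking context of a motif hit
#'
#' Returns the `width` nucleotides on the 5' and 3' sides of the site, in
#' motif orientation: for a minus-strand hit the flanks are read from the
#' reverse complement, so `five_prime` always leads into the motif.
#'
#' @param sequence the promoter sequence.
#' @param start 0-based forward-strand start of the site.
#' @param motifLength length of the matched motif.
#' @param strand `"+"` or `"-"`.
#' @param width flank width (the study uses 2 or 4).
#' @return list with `five_prime` and `three_prime` strings of length
#'   `width`.
#' @export
extractFlanks <- function(sequence, start, motifLength, strand = "+",
                          width = 2L) {
  n <- nchar(sequence)
  if (start < width || start + motifLength + width > n)
    stop("insufficient flank")
  left <- substring(sequence, start - width + 1L, start)
  right <- substring(sequence, start + motifLength + 1L,
                     start + motifLength + width)
  if (strand == "-") list(five_prime = revComp(right),
                          three_prime = revComp(left))
  else list(five_prime = left, three_prime = right)
}

#' Match a flank context against IUPAC patterns
#'
#' Position-wise membership of each context base in the IUPAC class of the
#' corresponding pattern base (e.g. `C` matches `Y`, anything matches `N`).
#'
#' @param context list with `five_prime`, `three_prime` (see
#'   [extractFlanks()]).
#' @param pattern5,pattern3 IUPAC strings of the same widths as the
#'   context.
#' @return logical scalar.
#' @export
matchEnvironment <- function(context, pattern5, pattern3) {
  iupacMatch <- function(s, p) {
    if (nchar(s) != nchar(p)) stop("pattern width must match context width")
    sc <- strsplit(toupper(s), "")[[1]]
    pc <- strsplit(toupper(p), "")[[1]]
    sets <- Biostrings::IUPAC_CODE_MAP[pc]
    if (any(is.na(sets))) stop("invalid IUPAC code in pattern")
    all(mapply(grepl, sc, sets, MoreArgs = list(fixed = TRUE)))
  }
  iupacMatch(context$five_prime, pattern5) &&
    iupacMatch(context$three_prime, pattern3)
}

#' Group filtered promoters by exact flank composition
#'
#' Groups the output of [filterSingleInstance()] by the exact
#' (`five_prime`, `three_prime`) flank strings at the given width and
#' summarizes the expression bins of each group. Groups with a single
#' member are listed but carry `sd = NA` (excluded from dispersion
#' statistics).
#'
#' @param filtered output of [filterSingleInstance()].
#' @param width flank width (2 or 4 in the study).
#' @return data.frame with one row per group: `five_prime`, `three_prime`,
#'   `n`, `mean`, `sd`, plus a list column `members` of promoter ids.
#' @export
groupByFlanks <- function(filtered, width = 2L) {
  if (!nrow(filtered)) stop("no promoters to group")
  motifLen <- nchar(yreMotifs())[match(filtered$motif, names(yreMotifs()))]
  motifLen[is.na(motifLen)] <- nchar(filtered$motif[is.na(motifLen)])
  ctx <- lapply(seq_len(nrow(filtered)), function(i)
    extractFlanks(filtered$sequence[i], filtered$start[i], motifLen[i],
                  filtered$strand[i], width))
  five <- vapply(ctx, `[[`, "", "five_prime")
  three <- vapply(ctx, `[[`, "", "three_prime")
  key <- paste(five, three, sep = "|")
  idx <- split(seq_along(key), key)
  rows <- lapply(idx, function(i) {
    e <- filtered$expression_bin[i]
    data.frame(five_prime = five[i[1]], three_prime = three[i[1]],
               n = length(i),
               mean = if (all(is.na(e))) NA_real_ else mean(e, na.rm = TRUE),
               sd = if (length(i) >= 2 && !all(is.na(e)))
                 sd(e, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- I(lapply(idx, function(i) filtered$id[i]))
  rownames(out) <- NULL
  out[order(out$five_prime, out$three_prime), , drop = FALSE]
}

#' Dispersion test between two flank-grouping widths
#'
#' Collects the within-group standard deviations of expression (groups
#' with `n >= 2` only) at the two widths and compares the two SD
#' collections by a two-sample Student t-test (classical equal-variance by
#' default; set `varEqual = FALSE` for Welch). When both collections are
#' constant the pooled variance is zero and the statistic is reported as
#' `Inf` (different means, p = 0) or `NaN` (identical means).
#'
#' @param groupsW2,groupsW4 outputs of [groupByFlanks()] at the two widths.
#' @param varEqual use the classical pooled-variance test?
#' @return list with `t`, `p.value`, `df`, `meanSdW2`, `meanSdW4`,
#'   `nGroupsW2`, `nGroupsW4`.
#' @export
dispersionTest <- function(groupsW2, groupsW4, varEqual = TRUE) {
  s2 <- groupsW2$sd[!is.na(groupsW2$sd)]
  s4 <- groupsW4$sd[!is.na(groupsW4$sd)]
  if (length(s2) < 2L || length(s4) < 2L) stop("insufficient groups")
  if (sd(s2) == 0 && sd(s4) == 0) {
    t <- if (mean(s2) == mean(s4)) NaN else
      Inf * sign(mean(s2) - mean(s4))
    return(list(t = t, p.value = if (is.nan(t)) NaN else 0,
                df = length(s2) + length(s4) - 2,
                meanSdW2 = mean(s2), meanSdW4 = mean(s4),
                nGroupsW2 = length(s2), nGroupsW4 = length(s4)))
  }
  ht <- t.test(s2, s4, var.equal = varEqual)
  list(t = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter),
       meanSdW2 = mean(s2), meanSdW4 = mean(s4),
       nGroupsW2 = length(s2), nGroupsW4 = length(s4))
}

#' Differential expression profile: log2(WT / mutant)
#'
#' @param profile data.frame from [readExpressionProfile()].
#' @param pseudocount added to both channels before the ratio (default 0;
#'   required when any value is non-positive).
#' @return `profile` with an added `log2_ratio` column.
#' @export
differentialProfile <- function(profile, pseudocount = 0) {
  wt <- profile$wt + pseudocount
  mu <- profile$mutant + pseudocount
  if (any(wt <= 0) || any(mu <= 0))
    stop("non-positive expression values; supply a pseudocount")
  profile$log2_ratio <- log2(wt / mu)
  profile
}

#' Percent sequence identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62; identity is the
#' fraction of identical aligned positions over the alignment length,
#' in percent. Intended for comparing bZIP domains (e.g. Yap1 vs its
#' closest structural template) from user-supplied FASTA files.
#'
#' @param seq1,seq2 amino-acid strings.
#' @return numeric percent identity.
#' @export
sequenceIdentity <- function(seq1, seq2) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::pid(al, type = "PID1")
}
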