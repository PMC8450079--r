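# Motif scanning, filtering, flank analysis and dispersion statistics.

test_that("the YRE1 site in the ATR1 oligomer is found at offset 8", {
  h <- scanMotif(yreStudyOligomers()[["YRE1_ATR1"]], "TTACTAA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 8L)
  expect_equal(h$strand, "+")
  expect_equal(h$matched, "TTACTAA")
})

test_that("a palindromic motif is counted once with dedupe on", {
  h <- scanMotif("TTACGTAA", "TTACGTAA", bothStrands = TRUE,
                 dedupePalindrome = TRUE)
  expect_equal(nrow(h), 1L)
  h2 <- scanMotif("TTACGTAA", "TTACGTAA", bothStrands = TRUE,
                  dedupePalindrome = FALSE)
  expect_equal(nrow(h2), 2L)
  expect_setequal(h2$strand, c("+", "-"))
})

test_that("absent motifs and over-long motifs yield empty results", {
  expect_equal(nrow(scanMotif(strrep("A", 20), "TGACAAA")), 0L)
  expect_equal(nrow(scanMotif("ACG", "TTACTAA")), 0L)
})

test_that("minus-strand hits are reported by forward-strand start", {
  s <- paste0("GGGG", revComp("TGACAAA"), "CCCC")
  h <- scanMotif(s, "TGACAAA")
  expect_equal(h$strand, "-")
  expect_equal(h$start, 4L)
  expect_equal(h$matched, substring(s, 5, 11))
})

test_that("scanning is strand-consistent under reverse complement", {
  set.seed(15)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    for (m in yreMotifs()) {
      h <- scanMotif(s, m)
      hr <- scanMotif(revComp(s), m)
      # mirror image: a hit at start k maps to start n - k - len
      expect_setequal(60L - hr$start - nchar(m), h$start)
    }
  }
})

test_that("all six study oligomers pass the single-instance filter", {
  filt <- suppressMessages(filterSingleInstance(studyTable()))
  expect_equal(nrow(filt), 6L)
  expect_equal(sort(filt$motif), sort(rep(c("YRE1", "YRE2", "YRE3"), 2)))
  expect_equal(filt$start, rep(8L, 6))
})

test_that("multiplicity and exclusion motifs reject promoters", {
  twice <- data.frame(id = "x",
                      sequence = paste0("GG", "TTACTAA", "CCGG", "TTACTAA", "AA"),
                      expression_bin = NA_integer_)
  expect_equal(nrow(suppressMessages(filterSingleInstance(twice))), 0L)
  withExcl <- data.frame(id = "y",
                         sequence = paste0("GG", "TTACTAA", "CC", "GCGATGAGCT", "AA"),
                         expression_bin = NA_integer_)
  expect_equal(nrow(suppressMessages(
    filterSingleInstance(withExcl, exclusionMotifs = "GCGATGAGCT"))), 0L)
  expect_equal(nrow(suppressMessages(filterSingleInstance(withExcl))), 1L)
})

test_that("flank extraction reproduces the native study contexts", {
  ol <- yreStudyOligomers()
  f <- extractFlanks(ol[["YRE1_ATR1"]], 8L, 7L, "+", 4L)
  expect_equal(f$five_prime, "GTGA")
  expect_equal(f$three_prime, "TGGA")
  f2 <- extractFlanks(ol[["YRE1_OYE2"]], 8L, 7L, "+", 4L)
  expect_equal(f2$five_prime, "TGCT")
  expect_equal(f2$three_prime, "GCAC")
  expect_error(extractFlanks("AACGTACGT", 1L, 7L, "+", 2L),
               "insufficient flank")
})

test_that("minus-strand flanks are returned in motif orientation", {
  fwd <- "GTGATTACTAATGGA"
  rev <- revComp(fwd)
  h <- scanMotif(rev, "TTACTAA")
  expect_equal(h$strand, "-")
  f <- extractFlanks(rev, h$start, 7L, "-", 4L)
  expect_equal(f$five_prime, "GTGA")
  expect_equal(f$three_prime, "TGGA")
})

test_that("flank extraction plus motif reconstructs the subsequence", {
  set.seed(21)
  lib <- genPromoterLibrary(n = 30, flankDesign = "sampled", seed = 21)
  filt <- suppressMessages(filterSingleInstance(lib$promoters))
  for (i in seq_len(nrow(filt))) {
    f <- extractFlanks(filt$sequence[i], filt$start[i], 7L,
                       filt$strand[i], 4L)
    core <- paste0(f$five_prime, "TTACTAA", f$three_prime)
    target <- if (filt$strand[i] == "-") revComp(core) else core
    expect_equal(substring(filt$sequence[i], filt$start[i] - 3,
                           filt$start[i] + 7 + 4), target)
  }
})

test_that("IUPAC environment matching follows position-wise classes", {
  ctx <- list(five_prime = "CAGA", three_prime = "GCGA")
  expect_true(matchEnvironment(ctx, "YRGA", "GCRR"))
  ctx2 <- list(five_prime = "TGCT", three_prime = "GCAC")
  expect_false(matchEnvironment(ctx2, "YRGA", "GCRR"))
  expect_true(matchEnvironment(ctx2, "NNNN", "NNNN"))
  expect_error(matchEnvironment(ctx, "YR", "GCRR"), "width")
  expect_error(matchEnvironment(ctx, "YJGA", "GCRR"), "IUPAC")
})

test_that("an exhaustive 2-nt flank library yields one group per key", {
  lib <- genPromoterLibrary(flankDesign = "exhaustive", flankWidth = 2L,
                            seed = 42)
  filt <- suppressMessages(filterSingleInstance(lib$promoters))
  groups <- groupByFlanks(filt, 2L)
  expect_equal(nrow(groups), 256L)
  expect_true(all(groups$n == 1))
  expect_true(all(is.na(groups$sd)))
})

test_that("width-4 groups refine width-2 groups", {
  lib <- genPromoterLibrary(n = 400, flankDesign = "sampled",
                            flankWidth = 4L, seed = 5)
  filt <- suppressMessages(filterSingleInstance(lib$promoters,
                                                flankWidth = 4L))
  g2 <- groupByFlanks(filt, 2L)
  g4 <- groupByFlanks(filt, 4L)
  expect_gte(nrow(g4), nrow(g2))
  # every width-4 key maps into exactly the width-2 key of its inner bases
  inner2 <- paste(substring(g4$five_prime, 3, 4),
                  substring(g4$three_prime, 1, 2), sep = "|")
  expect_true(all(inner2 %in% paste(g2$five_prime, g2$three_prime,
                                    sep = "|")))
  # member counts are preserved by the refinement
  expect_equal(sum(g4$n), sum(g2$n))
})

test_that("the dispersion test behaves on degenerate SD collections", {
  mkGroups <- function(sds) data.frame(five_prime = "AA",
                                       three_prime = "TT",
                                       n = 2, mean = 1, sd = sds)
  same <- dispersionTest(mkGroups(c(1, 2, 3)), mkGroups(c(1, 2, 3)))
  expect_equal(same$t, 0)
  # constant collections: closed-form pooled variance is zero
  deg <- dispersionTest(mkGroups(c(1, 1, 1, 1)), mkGroups(c(3, 3, 3, 3)))
  expect_true(is.infinite(deg$t) && deg$t < 0)
  expect_equal(deg$p.value, 0)
  degSame <- dispersionTest(mkGroups(c(2, 2)), mkGroups(c(2, 2)))
  expect_true(is.nan(degSame$t))
  expect_error(dispersionTest(mkGroups(1), mkGroups(c(1, 2))),
               "insufficient groups")
})

test_that("the dispersion test matches the closed-form pooled t", {
  s2 <- c(2.0, 2.5, 3.0, 2.2); s4 <- c(1.1, 1.4, 1.0, 1.6, 1.2)
  out <- dispersionTest(data.frame(sd = s2), data.frame(sd = s4))
  n1 <- length(s2); n2 <- length(s4)
  sp <- sqrt(((n1 - 1) * var(s2) + (n2 - 1) * var(s4)) / (n1 + n2 - 2))
  tManual <- (mean(s2) - mean(s4)) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(out$t, tManual, tolerance = 1e-12)
  expect_equal(out$df, n1 + n2 - 2)
})

test_that("grouping at width 4 reduces dispersion on a planted library", {
  lib <- genPromoterLibrary(n = 2000, flankDesign = "sampled",
                            flankWidth = 4L, effectSd = 2, noiseSd = 1.5,
                            seed = 13)
  filt <- suppressMessages(filterSingleInstance(lib$promoters,
                                                flankWidth = 4L))
  g2 <- groupByFlanks(filt, 2L)
  g4 <- groupByFlanks(filt, 4L)
  out <- dispersionTest(g2, g4)
  expect_lt(out$meanSdW4, out$meanSdW2)
  expect_lt(out$p.value, 0.05)
})

test_that("sequence identity is computed from a global alignment", {
  expect_equal(sequenceIdentity("MKQLEDKVEELLSKNYHLENEVARLKKLVGER",
                                "MKQLEDKVEELLSKNYHLENEVARLKKLVGER"), 100)
  half <- sequenceIdentity("AAAAGGGG", "AAAACCCC")
  expect_lt(half, 100)
  expect_gt(half, 25)
})

test_that("the study manifest enumerates complexes and naked duplexes", {
  sys <- yreSystems()
  expect_equal(nrow(sys), 12L)
  expect_equal(sum(sys$kind == "complex"), 6L)
  expect_equal(sum(sys$kind == "naked_dna"), 6L)
  expect_setequal(unique(sys$yre), c("YRE1", "YRE2", "YRE3"))
  expect_setequal(unique(sys$environment), c("ATR1", "OYE2"))
  expect_true(all(nchar(sys$sequence) == 23L))
})
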