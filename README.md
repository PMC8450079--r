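# yreflank

Analysis toolkit for studying how the DNA sequences *flanking* a bZIP
transcription-factor response element shape recognition, built around the
yeast AP-1 factor Yap1 and its response elements YRE1 `TTACTAA`, YRE2
`TTACGTAA` (palindromic) and YRE3 `TGACAAA`.

bZIP factors read their sites mostly by direct readout — side chains of
the basic region hydrogen-bonding to base edges in the major groove —
but the same motif occurs far more often than it is functional. A second
determinant is mechanical: whether the element can adopt its bound
conformation depends on base-pair-step parameters, chiefly **shift**
(displacement of a base pair in/out of the major groove), and on the
four to six flanking nucleotides that tune this adaptability without
being contacted base-specifically. `yreflank` implements the statistics
for all three observation layers of that argument:

* **Contacts.** Geometric detection of hydrogen bonds (D–A ≤ 3.5 Å,
  D–H···A ≥ 120°), salt bridges (≤ 4.0 Å) and apolar contacts (≤ 4.5 Å)
  in multi-model protein–DNA structures; per residue pair a unit-weight
  contact strength S (every bond counts 1); *specific* = side-chain atom
  to base atom; dynamic contact maps (S per pair per frame, occupancy)
  and contact-substate clustering.
* **Helical parameters.** The six step parameters (shift, slide, rise in
  Å; tilt, roll, twist in degrees) via the standard mid-step-frame
  construction, with `rebuildStep()` the exact inverse of
  `stepParameters()`; normalized per-step distributions; −/0/+
  most-populated-state calls (neutral band ±0.3 Å); bound-vs-unbound
  alteration per step by the two-sample Kolmogorov–Smirnov statistic and
  the contiguous flanking *reach* of alteration on each side of the
  element.
* **Promoter libraries.** Exact both-strand motif scanning (palindrome
  deduplication), single-instance filtering with a motif exclusion set,
  flank extraction in motif orientation, grouping by exact flank
  composition at width 2 or 4, within-group expression-bin standard
  deviations and a Student t-test comparing the two dispersion
  collections, plus log2(WT/mutant) differential profiles.
* **Synthetic data.** Seeded generators with planted ground truth for
  every input class: 80-bp promoter libraries with one planted YRE and
  18 expression bins, paired bound/unbound step-parameter series with a
  configurable alteration reach, and structural ensembles built by
  chaining step parameters with a programmed contact schedule.

## Worked example

Recover a planted flanking-alteration signal (1 Å shift displacement
over the element and its four nearest 5′ steps, 2000 frames):

```r
library(yreflank)
gh  <- genHelicalSeries(frames = 2000, reach5 = 4L, reach3 = 0L, seed = 1)
cmp <- compareBoundUnbound(gh$bound, gh$unbound, "shift")
subset(cmp$perStep, region %in% c("-5", "-4", "-3", "-2", "-1"))
#>   step_label region score altered
#> 4         AG     -5 0.035   FALSE
#> 5         GT     -4 0.533    TRUE
#> 6         TG     -3 0.514    TRUE
#> 7         GA     -2 0.519    TRUE
#> 8         AT     -1 0.539    TRUE
c(cmp$reach5, cmp$reach3)
#> [1] 4 0
```

The KS score sits at ~0.03 (sampling noise) on undisturbed steps and
~0.52 on displaced ones; the contiguous altered reach from the 5′ edge
is exactly the planted 4 steps, none on the 3′ side.

Grouping a planted promoter library by four flanking nucleotides instead
of two concentrates the expression signal:

```r
lib  <- genPromoterLibrary(n = 2000, flankDesign = "sampled",
                           flankWidth = 4L, seed = 2)
filt <- filterSingleInstance(lib$promoters, flankWidth = 4L)
d    <- dispersionTest(groupByFlanks(filt, 2L), groupByFlanks(filt, 4L))
#> mean SD w2 = 2.42 (252 groups), w4 = 1.06 (28 groups),
#> t = 8.38, p = 2.6e-15
```

Within-group expression dispersion drops from 2.42 to 1.06 bins when the
grouping key grows from 2 to 4 flanking nucleotides — the planted
flank-dependence of expression, detected by the dispersion t-test.

Pipeline runs with config, seed and a hash-chained manifest are
available through `runPipeline()` or the thin CLI wrapper
`inst/scripts/yreflank.R` (subcommands `synth`, `promoters`, `helical`,
`contacts`, `ensemble`).

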