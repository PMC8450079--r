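---
title: "Flanking-sequence analysis of bZIP response elements with yreflank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flanking-sequence analysis of bZIP response elements with yreflank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yreflank)
```

## The scientific problem

Basic leucine zipper (bZIP) transcription factors such as the yeast AP-1
factor Yap1 recognize short response elements — here the Yap1 response
elements (YREs) `TTACTAA` (YRE1), `TTACGTAA` (YRE2, a palindrome) and
`TGACAAA` (YRE3) — mainly by direct readout: side chains of the basic
region hydrogen-bond to base edges in the major groove. These motifs are
far more frequent in a genome than functional binding sites, so direct
readout alone cannot explain binding selectivity. A second layer comes
from DNA mechanics: the ability of the element to adopt its bound ("bioactive")
conformation depends on base-pair-step parameters — chiefly *shift* (the
displacement of one base pair relative to the next along the short
base-pair axis, which moves bases in and out of the major groove) and, to
a lesser extent, *slide* and *twist* — and that conformational
adaptability is modulated by the four to six nucleotides flanking the
element, which the protein does not contact base-specifically.

`yreflank` implements the downstream analysis layer of this picture as
reusable, tested components:

1. **Contacts** — geometric detection of hydrogen bonds, salt bridges and
   apolar contacts in protein–DNA structural ensembles; a unit-weight
   *contact strength* per residue pair; specific/nonspecific
   classification; dynamic contact maps and contact-substate clustering.
2. **Helical** — base-pair-step parameter extraction and rebuilding,
   normalized per-step distributions, most-populated-state calls, and
   bound-versus-unbound alteration analysis over an element and its
   flanks.
3. **Promoters** — YRE scanning, single-instance filtering, flank
   extraction and grouping, and expression-dispersion statistics over
   random-promoter reporter libraries binned into 18 expression levels.
4. **Synthetic** — seeded generators that produce every input class with
   planted, recoverable ground truth, replacing molecular-dynamics
   trajectories and external promoter libraries.

## Contact model

Contacts are detected per frame between protein and DNA atoms only, using
role annotations shipped with the package (`atomRoles()`): every atom of
the 20 amino acids and 4 deoxynucleotides carries a structural role
(base / sugar / phosphate / protein backbone / protein side chain),
donor and acceptor flags, a formal-charge class, and an apolar flag
(carbon or sulfur outside charged groups). The criteria, all inclusive at
the boundary and configurable:

* hydrogen bond: donor–acceptor distance ≤ 3.5 Å, and D–H···A angle
  ≥ 120° whenever the donor hydrogen is present (heavy-atom-only models
  fall back to distance-only detection);
* salt bridge: cationic–anionic heavy-atom distance ≤ 4.0 Å (e.g. an
  arginine guanidinium nitrogen against a phosphate oxygen);
* apolar contact: apolar–apolar distance ≤ 4.5 Å.

These are standard trajectory-analysis cutoffs; the source literature for
this kind of analysis delegates its exact criteria to earlier work
without printing numbers, so the defaults here are stated explicitly and
logged with every pipeline run.

The *contact strength* S of a residue pair in a frame is the plain count
of its detected contacts, each type weighted 1. This deliberately ignores
the energetic differences between bond types: the weight of a bond varies
with geometry and environment, and an unweighted count is the most
transparent comparable statistic across response elements. A contact is
*specific* when a protein side-chain atom touches a DNA base atom;
everything involving backbone (protein or DNA sugar/phosphate) is
nonspecific. Specific strength tracks molecular selectivity (direct
readout), total strength tracks complex stability.

Contact substates of a residue are clustered from per-frame binary
fingerprints over its (partner atom, contact type) repertoire, with
average-linkage hierarchical clustering on Jaccard distances, cut at the
largest cluster count whose clusters all hold ≥ 10% of frames. The
source analyses name no clustering method; this choice is deterministic,
scale-free, and recovers planted on/off schedules exactly in the tests.

## Base-pair-step convention

Step parameters follow the mid-step-frame construction of the standard
base-pair-step definition (the El Hassan–Calladine / 3DNA family): the
net rotation between consecutive base-pair triads is split symmetrically
about the bending hinge; twist is the remaining rotation about the shared
mid-frame z axis; the bend angle Γ decomposes as roll = Γ·cos φ about the
mid-frame y axis and tilt = Γ·sin φ about x; shift, slide and rise are
the components of the origin displacement in the mid-frame. Rebuilding
uses the equivalent closed form

&nbsp;&nbsp;&nbsp;&nbsp;T~b~ = T~a~ · R~z~(ω/2 − φ) · R~y~(Γ) · R~z~(ω/2 + φ),

and `rebuildStep()` is the exact inverse of `stepParameters()` (round
trips hold to 10⁻⁶ over 10⁴ random draws in the acceptance suite; in
practice they agree to ~10⁻¹²). Different helical-analysis programs
differ at this level of detail; the package fixes one convention, tests
it, and uses it consistently for analysis and synthesis, rather than
trying to be bit-compatible with any particular external tool. The
builder's frames put +x toward the major groove, so a positive shift
moves a base pair out of the major groove — the sign reading used
throughout.

For real coordinate sets, base-pair frames are obtained by least-squares
superposition (`kabschSuperpose()`) of an idealized planar base-pair
template onto the observed atoms (`baseFramesFromEnsemble()`). The
template (documented in `baseTemplate()`) uses standard-like planar
geometry and is the same one the synthetic builder places atoms with, so
building and fitting are mutually consistent by construction.

## Distribution and alteration analysis

Per-step distributions are normalized histograms (densities integrate
to 1); default bin widths are 0.1 Å for translations and 2° for
rotations — fine enough to resolve the bimodality of polymorphic
pyrimidine–purine steps at the sample sizes used. The most-populated
state of a step is negative / neutral / positive relative to a neutral
band of ±0.3 Å (suited to shift and slide, whose bimodal lobes sit near
±0.5–1 Å; the three-way call is standard but the band width is not
printed anywhere, so it is a documented default). Ties are called
neutral.

Bound-versus-unbound alteration is scored per step by the two-sample
Kolmogorov–Smirnov statistic — distribution-free, in [0, 1], sensitive to
both location and shape changes ("broad" versus "narrow" distributions).
A step is *altered* when its score exceeds 0.2; with ~2000 frames per
series the null KS statistic stays below ~0.05, so 0.2 cleanly separates
sampling noise from a planted 1 Å displacement (score ≈ 0.5) while
remaining sensitive to partial shifts. The flanking *reach* is counted
outward from each element edge (−1, −2, … on the 5′ side, +1, +2, … on
the 3′ side) and stops at the first unaltered step, giving the number of
contiguous flanking steps whose conformational ensemble the protein
perturbs — the quantity summarized in the field as "four (shift, slide)
to six (twist) flanking nucleotides".

An initial fraction of frames can be discarded as equilibration
(`discardEquilibration()`), mirroring the practice of dropping the start
of a trajectory; the operation is a pure slice, so discarding then
analysing equals analysing the sliced series.

## Promoter-library analysis

`scanMotif()` finds exact motif occurrences on both strands (0-based,
half-open coordinates; minus-strand sites reported by forward-strand
start). Overlapping occurrences all count toward multiplicity, and
palindromic sites (YRE2 equals its reverse complement) are counted once
per location by default — both conventions configurable.
`filterSingleInstance()` keeps promoters with exactly one site across
the YRE set, no site from a user-supplied exclusion set (standing in for
an external database of known TF motifs, which is versioned and not
redistributed), and room for the configured flank width.
`extractFlanks()` always returns the context in motif orientation, so
grouping keys are strand-independent; `matchEnvironment()` additionally
supports IUPAC-class matching of flank patterns (e.g. `YRGA`).

Groups are keyed by the exact (5′, 3′) flank strings at width 2 or 4.
Within-group standard deviations of the expression bin are computed for
groups with ≥ 2 members (the SD of a singleton is undefined, and the
source procedure restricts itself to multi-member groups in the same
way), and the two SD collections are compared with the classical
equal-variance two-sample Student t-test — chosen because the procedure
is named after Student; Welch is available via `varEqual = FALSE`. When
both collections are constant the pooled variance is zero and the
statistic is reported as ±Inf (p = 0) or NaN for identical means, rather
than erroring. A width-4 grouping refines the width-2 grouping, so if
flank identity out to four nucleotides carries expression information,
width-4 groups are more homogeneous: mean within-group SD drops and the
t-test detects it.

`differentialProfile()` computes per-timepoint log2(WT/mutant) ratios
for wild-type versus deletion-strain expression courses, with an
optional pseudocount; values must be strictly positive.

## What the synthetic generators emulate — and what they do not

`genPromoterLibrary()` emulates a random-promoter reporter assay: 80-bp
promoters, one planted YRE with controlled flanks, i.i.d. uniform
background kept free of further YRE instances (all three YREs by
default) and of the exclusion motifs by rejection sampling, and an
expression bin from a planted per-flank-group mean (keyed at width 4 by
default) plus Gaussian noise, rounded and clamped into 0…17 — 18 bins
from weakest (0) to strongest, matching the reporter-assay binning. The
defaults (grand mean 9, group-effect SD 2, noise SD 1.5 bins) put group
structure well inside the bin range while leaving singleton groups
common at width 4, which is the regime the dispersion statistics face on
the real library. Clamping inflates the edge bins slightly; that is
intentional and tested.

`genHelicalSeries()` draws the shift of every step from a two-component
Gaussian mixture (±0.5 Å, SD 0.25, equal weights by default), emulating
the bimodal conformational polymorphism of flexible dinucleotide steps;
the bound series additionally displaces the mean by 1 Å for every step
inside the element and for a configurable number of flanking steps
(default four per side, the study-scale effect), over 2000 frames.

`genStructureEnsemble()` chains `rebuildStep()` over per-step parameters
to build DNA from the idealized template and places a three-atom toy
probe group (serine hydroxyl donor, arginine guanidinium nitrogen,
alanine methyl carbon) so that a programmed on/off schedule of hydrogen
bond / salt bridge / apolar contacts is realized *exactly* — the
generator is the oracle for the contact map.

None of this reproduces real molecular-dynamics data: there is no force
field, no correlated dynamics between steps, no sequence-dependent
stiffness beyond the user-specified mixtures, no solvent or ions, and
the probe group is not a protein. Passing tests therefore demonstrate
that the *analysis* layer recovers known ground truth under realistic
sample sizes and noise — not that the physical conclusions about any
particular protein–DNA system are reproduced, which would require the
original microsecond-scale simulations (out of scope, as are docking,
free-energy estimates, ion-density and groove-geometry analyses).

## Numerical choices and degenerate inputs

* Frames must be orthonormal to 10⁻⁸ with determinant +1; chained
  rebuilds re-orthonormalize via SVD to stop drift.
* A zero bend (Γ = 0) makes the hinge undefined; the code then takes the
  frames as sharing z and computes pure twist, which is the correct
  limit.
* Superposition requires ≥ 3 non-collinear atoms; collinearity is
  detected on the singular values.
* Missing values in series files (any non-numeric token) become absent
  cells, excluded from histograms, state calls and KS scores; an
  all-absent step errors rather than returning a silent zero.
* KS ties (heavily repeated values) only warn about the exact p-value;
  the statistic itself, which is all the alteration analysis uses, is
  unaffected.
* Substate clustering with fewer than two frames returns a single
  cluster with a warning; ties in cluster assignment resolve by
  fingerprint order, so results are deterministic without randomness.
* All generators take an integer seed, restore the caller's RNG state,
  and produce byte-identical output for identical seeds.

## Problem sizes used by the tests and the acceptance script

The suite runs its statistical checks at sizes where the planted effects
are comfortably identifiable yet the run stays interactive: 10⁴ random
draws for the extract/rebuild round trip, 2000-frame series for
alteration recovery (20 seeds), 2000-promoter sampled libraries (and the
exhaustive 256-promoter library) for the dispersion analysis, and
≤ 100-atom frames for the brute-force contact-detector cross-checks.
These choices are the package's own test design; all thresholds were
fixed from the generators' stated conditions, not tuned to outcomes.

## Known limitations

* The helical convention is internally consistent but not bit-compatible
  with any specific external helical-analysis program.
* The role table covers standard residues only; modified bases or
  nonstandard amino acids need a user-supplied extension (unknown atoms
  are reported, never silently dropped).
* The idealized base-pair template is geometrically plausible rather
  than crystallographically fitted; frame fitting against real
  high-resolution structures will show systematic (but
  convention-consistent) offsets.
* The bZIP-domain sequence-identity check (`sequenceIdentity()`)
  requires the two protein sequences from their public databases; they
  are not redistributed with the package.
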