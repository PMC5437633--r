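---
title: "Models and methods behind ssrdecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssrdecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrdecay)
```

ssrdecay studies how imperfect microsatellites (tandem repeats of 1–6 nt
motifs carrying substitution-type mismatches) are distributed in plant
genomes, how imperfection relates to repeat length, and how fast repeat loci
decay after a polyploidization event. This vignette explains the models the
package implements, the parameters that matter, and the choices made where
the design was genuinely open.

## Detecting imperfect microsatellites

`scan_sequence()` is a seed-and-extend scanner. A seed is at least three
exact tandem copies of a primitive motif (at least 8 bases for 1–2 nt motifs,
so a mononucleotide run must be 8 bp long before it is considered). From a
seed, extension walks outward base by base: a base matching the expected
phase base scores `+1`, anything else — including `N` — scores `-5`. Two rules
stop extension: a run of more than 3 consecutive mismatching bases, or the
running score falling more than `3 x 5 = 15` below its running maximum. The
locus is then trimmed back to the farthest position that attained the maximal
running score, so reported loci begin and end on matching bases. A locus is
reported when it is at least 15 bases long and scores at least 15; at these
defaults an imperfect locus therefore needs `length >= 15 + 6 x mismatches`.
Overlapping candidates (different motifs or phases) are resolved by higher
score, then shorter motif, then leftmost start, then lexicographic motif, so
the output is a non-overlapping set.

Two details deserve emphasis. First, the score-drop bound is deliberately
`max_successive_mismatch x mismatch_penalty`: a bound of one mismatch penalty
would terminate after two consecutive mismatches and make the successive-
mismatch limit unreachable. Second, the scanner is strictly ungapped: a
single inserted base shifts the repeat phase and ends the locus, which is the
intended behaviour for a substitution-only mismatch model (indel-tolerant
detection is out of scope). All constants live in `detection_config()`.

Compound microsatellites — two loci separated by fewer than 100 intervening
bases — are associated and both members excluded from genomic summaries
(`exclude_compounds()`); the count of removed members is reported separately
for coding-sequence summaries, where compound counts are a quantity of
interest in their own right.

## Motif standardization

Motifs are equivalence-classed under cyclic rotation (partial
standardization: `GA -> AG`) and additionally under reverse complementation
(complete standardization: `CT -> AG`). The canonical representative is
pinned as the lexicographically smallest string (`A < C < G < T`) over the
full orbit, which reproduces the published class counts of 2, 4, 10, 33, 102
and 350 for motif lengths 1–6 and makes all outputs bit-stable. Only
primitive motifs (minimal period equal to length) are admitted; the detector
always reports the primitive root, which is required for those counts to be
exact.

## Imperfection and repeat length

`build_mismatch_datasets()` tabulates per-genome locus counts into two
frequency matrices: lengths 20–24 nt with 0–1 mismatches (dataset I) and
lengths 25–29 nt with 1–2 mismatches (dataset II); loci under 20 nt are
excluded because they cannot carry a mismatch at the detection thresholds.
Note that at the default scoring a 1-mismatch locus needs 21 bases and a
2-mismatch locus 27, so a few cells of those windows are structurally empty;
they are kept so the column universe is explicit.

`canonical_ordination()` follows the constrained-ordination tradition:
principal coordinates of each block (Euclidean distances on raw counts),
retention of leading axes explaining at least 95% of positive-eigenvalue
variation (capped at `n - 2` axes so the canonical system stays
identifiable), then the first squared canonical correlation between the two
axis sets. Significance is a permutation test on the row order of one block
with the add-one rule, `p = (1 + #{permuted >= observed}) /
(n_permutations + 1)`, which can never return zero. The distance, the
transformation (none) and the axis-retention rule are pinned choices: the
source method names neither, and making them explicit is what makes results
reproducible.

`permanova()` implements the pseudo-F partition of squared inter-point
distances (the Gower-centred trace form), with sequential terms — repeat
length entered before mismatch level, mirroring how the two factor tests are
reported from one model — and row-label permutation. For Euclidean distances
the partition equals the classical per-column ANOVA decomposition, which the
test suite exploits as an independent oracle, alongside a cross-check against
`vegan::adonis2`. Bray–Curtis is available as an option. Permuted statistics
are compared to the observed one with a relative tolerance of 1e-8 because a
permuted Gower matrix reproduces an equivalent relabelling's statistic only
up to floating-point noise.

Pairwise Pearson correlations between mismatch levels use raw genome-wise
counts of loci at exactly the targeted repeat lengths (30–80 nt by 5); no
standardization is applied before correlating, since none is prescribed.
The mismatch–length regression is ordinary least squares of per-motif-class
mean mismatch on mean repeat length.

## Transposable elements near repeats

A TE is "near" a locus when its interval overlaps the locus window extended
by 500 nt on both sides (clamped at the sequence start) by at least one base.
Counting is per (locus, TE) pair: a TE sitting between two loci counts once
for each, a pinned choice where the aggregation was unspecified. "Intact TE"
is operationalized as whatever the supplied annotation contains — intactness
is a property of the annotation layer, not of this package. Correlations of
per-chromosome locus counts against nearby-TE counts are computed separately
for perfect and imperfect loci.

## Conservation mapping

Each progenitor locus becomes a library entry: up to 350 nt of flank on each
side with the repeat tract hard-masked. The mask character is `+` — part of
the extended DNA alphabet but distinct from `N`, so assembly gaps and masked
tracts remain distinguishable. Mononucleotide loci are excluded (homopolymer
sequencing artefacts), as are compound members and loci whose flanked windows
overlap another locus's window ("overlapping sequences", interpreted at the
window level). A self-uniqueness pass searches the library against itself and
discards any entry whose flanks hit another entry at the standard thresholds.

The homology search is implemented in-package: exact-word seeds (default
word size 12) located through a counting-sort index of the subject, ungapped
X-drop extension trimmed to maximal-score endpoints, HSP chaining into hits,
and Karlin–Altschul E-values. `lambda` is solved exactly from the score
distribution at uniform base composition; `K` has no closed form for lattice
scores and is pinned at 0.5 — E-values here separate true flank homology
(E effectively 0) from seed noise (E > 1e-4) by many orders of magnitude, so
the exact constant is immaterial against the 1e-10 ceiling. Extension stops
hard at any non-ACGT character, so no alignment column ever pairs a masked
base; the two flank alignments of an entry chain into a single hit whose
query cover counts the masked tract in the denominator (cover can still
reach 100% when flanks span the tract). Gapped extension is deliberately
absent: the package's divergence model is substitution-only, and for real
genomes with indels `read_tabular_hits()` ingests 12-column tabular output
from any external gapped aligner into the same filtering and verdict logic.

Hits qualify at cover >= 50%, identity >= 70% and E-value <= 1e-10, all
inclusive. Qualifying hits are reduced to non-overlapping candidate
positions; zero candidates means `lost`, more than two means `ambiguous`
(duplication beyond the two physical positions a whole-genome duplication
allows), and otherwise the candidate windows are searched back against the
progenitor: the entry is `conserved` when at least one reciprocal top
qualifying hit overlaps the original locus window by at least one base.
Per-class conserved proportions exclude ambiguous entries from the
denominator and report them separately.

## Decay and abundance

Assuming steady loss over a divergence time `t` (default 6 million years,
the median estimate for the cotton allotetraploid WGD), a conserved fraction
`C` implies the exponential decay rate `lambda = -ln(C) / t`. Neither
"relative decay" nor "comparative exponential decay" is given as a formula
in the source; they are pinned here as `lambda_k - lambda_overall` and the
fitted `lambda` itself, with `relative_loss = (1 - C_k) - (1 - C_overall)` as
the figure-facing quantity whose `y = 0` line marks a class decaying at
exactly the pooled rate. Complete loss (`C = 0`) is flagged and excluded
from rate contrasts rather than reported as an infinite rate. Relative
abundance of a focal genome over a reference is
`(focal - reference) / reference` density per class, zero when equal and
undefined (flagged) when the reference class is empty.

Group comparisons delegate to the standard rank-based tests (`kruskal.test`,
`friedman.test`, `pairwise.t.test`, two-sided at 0.05). Friedman blocks are
chromosomes — classes measured on each chromosome form the complete block
design — a pinned reading where the blocking unit was unstated. Fully
constant data is reported as statistic 0 with p = 1 rather than the
reference implementations' ties-correction `NaN`.

## The synthetic-data generator

`generate_genome()` emulates the study conditions end to end: chromosomes of
i.i.d. background at 35% GC (a typical plant genome composition), planted
repeat tracts with known motif, length and mismatch count, and planted TE
intervals. Its defaults are modest, minute-scale sizes; the acceptance runs
use 5 chromosomes of 2.4 Mb with 2000 loci each so that each motif-length
class holds roughly 2000 loci, enough for per-class rate recovery within a
few percent. Three construction rules keep truth tables exact rather than
approximate:

* background is rejection-sampled — any window the detector would call is
  redrawn until the detector's output equals the truth table exactly;
* mismatches are substitutions only, never within the first `max(3k, 8)`
  bases (a seed always exists), never in the last motif unit or within 5
  bases of the tract end (max-score trimming would cut them off), pairwise
  at least 6 bases apart (the score path never dips enough to truncate the
  tract), and never so numerous that the locus would fall under the score
  threshold — the realized counts are what the truth table records;
* planted tracts sit in evenly spaced slots with at least 100 intervening
  bases, so no pair merges into a compound.

A tract that still cannot be recovered (substitutions occasionally create a
higher-scoring overlapping candidate) is replanted as a perfect repeat of
the same motif and length, and dropped entirely only if that also fails —
in practice planted counts are preserved.

`evolve_tetraploid()` carries each progenitor into a subgenome: each locus
is lost with a per-class probability, flanks accumulate substitutions at a
per-base rate (default 0.01, consistent with a few million years of neutral
plant divergence and comfortably inside the 70% identity filter), and an
optional duplication flag produces two independently substituted copies per
chromosome. Loss erases the whole flanked window (tract plus 360 nt each
side, clipped halfway to neighbouring tracts) with screened random sequence.
This models locus turnover, and it is the only loss model under which
flank-based homology can measure loss at all: if only the tract were
randomized, the 350-nt flanks would still produce a qualifying hit for every
"lost" locus and the measured conserved fraction would be ~1 regardless of
the planted rates.

What the simulator does not model: indels, selection, GC heterogeneity,
nested or fragmented TEs, real TE sequence, translocation or inversion.
Passing tests therefore demonstrate correctness of the machinery under a
substitution-only, well-separated-locus regime, not performance on real
assemblies — where gapped alignment (via the tabular adapter), repeat
families sharing flanks and assembly gaps all matter.

## Problem sizes and runtime choices

The test suite runs the detector–oracle equivalence on 10,000 random
sequences of up to 200 nt; PERMANOVA calibration uses 600 null datasets of
12 observations with 199 permutations each; the identity-conservation check
uses a 60 kb genome with ~200 library loci; and the full decay-recovery run
uses two 12 Mb genomes with 10,000 loci. These sizes were chosen so each
statistical check has the resolution its tolerance needs (binomial error a
few times smaller than the allowed deviation) while the whole suite stays at
desk scale.

## Interface choices

The package is a set of pipeable functions over tibbles, with
`run_pipeline()` orchestrating full runs from a validated manifest and
writing TSV/JSON outputs (all coordinates 1-based inclusive, each file
carrying a units header). Internally coordinates are also 1-based inclusive,
the R/Bioconductor convention. No shell entry point is shipped: for an R
analysis package the functions and this vignette are the interface, and
`run_pipeline()` plays the orchestration role a command-line driver would.

## Known limitations

* The scanner reports one locus per genomic interval; overlapping repeats of
  different motifs are resolved, not reported jointly.
* E-values are approximate (pinned `K`, raw rather than effective lengths);
  they are used only against a threshold far from both signal and noise.
* The in-package search is ungapped; genomes with indel-rich divergence need
  an external aligner through `read_tabular_hits()`.
* Conservation verdicts depend on flank uniqueness; repeat-dense regions
  whose flanked windows overlap are excluded from the library rather than
  disambiguated.
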