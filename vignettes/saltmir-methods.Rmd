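---
title: "Methods: two-condition small RNA-seq analysis with saltmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition small RNA-seq analysis with saltmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltmir)
```

## Scope and design

`saltmir` re-implements, as a tested and reusable pipeline, the analysis
pattern of classical plant stress small RNA-seq studies: two pooled
single-end 50 nt libraries (control and stress) per genotype, cleaned and
collapsed to unique tags, annotated against known small-RNA categories,
screened for novel miRNA precursors, quantified in TPM, tested for
differential expression with an exact two-library Poisson statistic, and
followed by hypergeometric GO/KEGG enrichment of predicted target genes.
The motivating setting is salt-stress miRNA profiling in faba bean
(*Vicia faba*), where libraries of 40--55 million reads from control and
150 mM NaCl-stressed leaves are compared without replicates.

Because no sequencing data are deposited for that setting, the package
ships a synthetic-data generator that emulates the statistical structure
of such libraries at desk scale, with known ground truth for every
stage.  Two kinds of validation follow:

* **arithmetic validation** against published summary tables (library
  percentages, category percentages, log2 ratios of printed TPM pairs,
  up/down tallies), which is exact; and
* **statistical validation** on synthetic data (null calibration,
  spike-in direction recovery, hairpin-verdict specificity), which is
  probabilistic.

## The synthetic study

`synthetic_config()` fixes the study conditions.  Defaults: 60 known
miRNA loci, 20 novel (hairpin-embedded, unannotated) miRNA loci, 40
decoy loci split over piRNA/snoRNA/Rfam/other categories, two libraries
of 50,000 single-end 50 nt reads, one fixed 3' adapter, and a junk
fraction of 8% drawn equally from five classes (no adapter, poly-A
insert, insert under 18 nt, 5'-primer contaminant, low quality) so that
every cleaning rule is exercised.  Background reads come from 400
distinct random insert species with lengths 17--34 nt following a
bimodal distribution peaked at 21 and 24 nt, matching the length
profiles such libraries show; these tags mostly fail to map, which also
reproduces the substantial unannotated/unmapped fractions of real
tables.  The 50,000-read scale keeps a full two-library run in tens of
seconds while leaving per-locus counts (means 20--500) in the regime
the differential test is used for.

Counts are Poisson: locus counts are drawn `Poisson(mean)` in control
and `Poisson(mean x fold)` in stress.  Overdispersion is deliberately
absent — the differential test assumes Poisson sampling of a pooled
library, and the generator must match the test's assumption for the
calibration checks to be meaningful.  Per-locus control means are drawn
log-uniformly on [20, 500]; 30% of miRNA loci receive a fold change
`2^u` with `|u|` uniform on [1, 3].  A truth table records each locus's
category, realized counts and true log2 fold change.

What the generator does **not** emulate: sequencing errors and quality
decay along the read, overdispersion between biological states,
multi-locus gene families, genome-scale reference size, and adapter
mismatches.  Passing tests therefore demonstrate correctness of the
pipeline's logic and calibration under its stated assumptions, not
performance on error-laden genome-scale data.

## Read cleaning

`clean_reads()` applies, in order: mean Phred < 20 (low quality); no
occurrence of the adapter's first 8 nt (no 3' adapter; the insert is
the prefix before the first occurrence); insert beginning with the 5'
primer's first 8 nt (5' contaminant); empty insert; insert at least 80%
A (poly-A); insert outside 18--28 nt.  Survivors collapse to unique
tags with counts.  The published protocol names these read classes
without numeric thresholds, so the quality floor (Phred 20) and poly-A
fraction (80%) are declared defaults, configurable per run.  Two length
windows appear in such protocols (a hard "< 18 nt" removal and a
"16--28 nt selected" statement); the pipeline retains 18--28 nt for
analysis and reports figure-style length distributions on a wider
16--36 nt axis from pre-length-filter inserts.  Adapter matching is an
exact 8-mer substring search — with error-free synthetic reads a
mismatch-tolerant trimmer would change nothing, and the simple rule is
fully specified and testable.

## Annotation and the priority rule

Tags are matched to the reference by substitution-only search on both
strands (no indels).  Genomic mapping is exact (0 mismatches) — a
declared default, since mapping-tool internals are out of scope — while
hits to known miRNA loci tolerate up to 2 substitutions, the
conventional allowance for identifying conserved miRNA variants.  A tag
hits a locus when an alignment falls entirely within the locus span;
multi-category tags resolve to a single category by the priority rule
miRNA > piRNA > snoRNA > Rfam > other sRNA, and each tag is counted
once under its resolved category, so category counts plus the
unannotated remainder always partition the clean-tag total.

## Novel miRNA detection

For every unannotated, genome-mapped tag with at least 5 reads, a
window of the tag plus 80 nt flanks is excised and folded.  Folding is
weighted base-pair maximization (Nussinov-style dynamic programming,
implemented in C++): maximize the total pair weight (G-C = 3, A-T = 2,
G-U = 1) over pseudoknot-free structures with hairpin loops of at least
3 nt.  The weights order pair stabilities the way stacking free
energies do, and the score per window nucleotide serves as the energy
proxy; a nearest-neighbor thermodynamic model is intentionally out of
scope, keeping the stage dependency-free and exactly testable against a
brute-force enumeration oracle.

The hairpin verdict requires: (a) at least 55% of window bases paired;
(b) at least 16 mature bases paired; (c) the mature lies entirely on
one arm — all pairing partners of mature bases on the same side, with
at most 2 pairs internal to the mature; and (d) pair-weight score per
window nucleotide of at least 1.0.  Threshold (d) was set from the
score's natural scale: a genuine precursor stem pairs nearly every
window base at weight 2--3 (score about or above the window length,
empirically at least about 1.07 on constructed precursors), while
maximum-pairing folds of dinucleotide-shuffled sequence are dragged
below 1.0 (at most about 0.99 observed) by loops, bifurcations and
weight-1 G-U pairs.  Criteria (a)--(c) alone do not separate the two
populations — maximization pairs most of any sequence — so (d) carries
the specificity; together they hold the shuffled-null verdict rate at
or below 5%, which the test suite checks empirically.

siRNA-like duplexes are reported for 22--24 nt tag pairs on opposite
strands whose alignments leave exactly the 2-nt 3' overhang on each
strand that Dicer processing produces.  piRNA prediction is an explicit
stub returning none: transposon-interaction SVM classification is out
of scope, and reference tables for this library type report zero known
and novel piRNAs, consistent with the stub.

## Quantification and the two-library test

Expression is `TPM = count x 1e6 / N` with `N` the library's clean-tag
total.  Zero counts are floored at TPM 0.001 — the convention visible
in published novel-miRNA tables, where zero-count rows print 0.001 and
yield finite log2 ratios.  Published TPM values are not exactly
reconstructible from the corresponding clean-tag totals (the effective
denominators are ambiguous), so arithmetic validation takes the printed
TPM pairs as inputs rather than recomputing them from counts.

For counts `x` and `y` in libraries with totals `N1` and `N2`, the
probability of the library-2 count given the library-1 count under
equal expression is

\[ P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
   \frac{(x+y)!}{x!\,y!}
   \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}, \]

the classical two-library Poisson-mixture statistic for digital
expression profiles (a negative binomial with size `x+1` and success
probability `N1/(N1+N2)`, which the tests use as an independent
cross-check).  The two-sided p-value doubles the smaller tail of the
observed `y`: `2S` for `S = sum(i <= y) P(i|x)` when `S <= 0.5`, else
twice the upper tail, clamped to [0, 1].  The published description of
the second branch is typographically corrupted; it is resolved here to
the standard doubled tail.  Numerically the conditional is evaluated in
log space, and the upper branch is summed directly over `i > y` rather
than as `1 - S`, preserving relative precision for extreme tails.
P-values are Bonferroni-corrected and converted to FDR by
Benjamini-Hochberg step-up (the variant is unnamed in the published
description; BH is the standard choice).  Calls use the stringent
screening gates FDR <= 0.001 and |log2 ratio| >= 1; `up`/`down` follow
the sign of the ratio (stress over control) and everything else is
`ns`, so DES totals are exactly up + down.

## Targets and enrichment

Target prediction is declared plumbing standing in for dedicated plant
target finders whose algorithms are not part of this package's scope:
the reverse complement of each miRNA slides along each transcript
without indels; a mismatch costs 1, a G:U wobble 0.5, both doubled at
miRNA positions 2--13 (the seed-proximal region plant target rules
weight most heavily), and pairs at penalty <= 4 are emitted.

Enrichment is the upper-tail hypergeometric probability of observing at
least `m` target genes among `n` drawn from `N` background genes of
which `M` carry the term, computed exactly with log-space binomial
coefficients.  Bonferroni correction runs over tested terms only (terms
with annotation and at least one target gene), mirroring standard
term-finder behavior; significance is corrected p <= 0.05.  GO and
KEGG analyses are the same machinery with different flat term maps;
GO-graph ancestor propagation is not performed, since the published
method does not state it — term maps are taken as given annotations.

## Numerical and degenerate-input conventions

Folding traceback is deterministic: a pairing of the 3'-most base is
preferred over leaving it unpaired on ties, and among tied partners the
leftmost wins.  Windows are clipped at contig ends; minus-strand tags
fold the reverse-complemented window.  Empty read streams clean to
empty tag sets with zero tallies; tags longer than every contig are
unmapped, not errors; a zero raw-read total is an error.  All
randomness in a pipeline run flows from the single configuration seed,
and re-running with the same configuration reproduces every output file
byte for byte (the run manifest records seed, thresholds and output
hashes, and no output embeds a timestamp).

## Problem sizes used by the test suite

The bundled tests run the full pipeline twice at the default 50,000
reads per library (for reproducibility hashing), calibrate the null on
2,000 simulated Poisson loci, measure spike-in direction recovery on
300 spiked loci among a 1,700-locus null background, compare the
two-library p-value to direct-summation and 50-digit
arbitrary-precision oracles over the full grid x, y <= 30, enumerate
every hypergeometric configuration up to N = 12, and check folding
against brute-force enumeration for sequences up to 12 nt.  These sizes
were chosen so the whole suite completes in a few minutes on one CPU
while leaving each statistical band (calibration 0.05 +/- 0.02,
sensitivity >= 0.9, null verdict <= 5%) comfortably powered.

## Known limitations

No replicate-aware model: the two-library test treats each condition as
one pooled library, as the motivating studies do; with biological
replicates a negative-binomial framework would be preferred.  The
folding model has no stacking, bulge or dangling-end energetics, so its
scores are comparable only within this pipeline.  Target prediction and
the flat GO/KEGG maps are synthetic plumbing for exercising the
enrichment machinery — biological target lists require the dedicated
tools this package intentionally does not reimplement.
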