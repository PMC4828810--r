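---
title: "Two-library plant miRNA discovery and degradome target analysis"
author: "mirpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-library plant miRNA discovery and degradome target analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpipe)
```

## The analysis

`mirpipe` implements the classical sRNA-seq comparison of two libraries
(here labelled female/male, as in dioecious plants such as garden
asparagus), from raw reads to called miRNAs, sex-biased expression and
degradome-supported cleavage targets:

1. **Preprocessing.** 3' adapter removal, quality and length cleanup
   (15-45 nt retained), removal of reads matching an Rfam-style
   rRNA/tRNA/snRNA/snoRNA set, and collapsing to unique sRNA tags with
   per-library counts. TPM is count / library final-clean total x 10^6, so
   TPM sums to one million per library by construction.
2. **Conserved miRNA assignment.** Unique tags with TPM >= 5 in at least
   one library and length 20-24 nt are compared end-to-end (equal length,
   ungapped) against a miRBase-style mature set, allowing up to two
   mismatches; families are the `miR<digits>` token of the reference id.
3. **Novel miRNA discovery.** Unassigned candidate tags are mapped
   perfectly to the transcript set on both strands; each locus is padded by
   200 nt on each side, folded, and judged by stem-loop criteria (below).
4. **Differential expression.** Per-miRNA 2x2 count tables are tested with
   Fisher's exact test (chi-square available), BH-adjusted; calls require
   fold change >= 2 and adjusted p < 0.05.
5. **Degradome analysis.** 20-21 nt degradome reads are mapped perfectly
   (sense strand), miRNA complementarity is scored along each transcript,
   and a cleavage hit requires degradome 5' ends exactly opposite miRNA
   nucleotide 10; hits are classified into categories 0-4.

## The folding engine

Secondary structure is computed by a Zuker-style dynamic program over a
nearest-neighbor model written for this package: stacking energies for the
six canonical pairs (Watson-Crick plus G:U), hairpin/bulge/internal-loop
initiation penalties with logarithmic extrapolation, a capped internal-loop
asymmetry penalty, and affine multibranch costs (`rna_energy_params()`).
Numerical choices worth knowing:

* Energies are handled internally as integer tenths of kcal/mol, so the DP
  and the independent loop-decomposition evaluator
  (`eval_structure_energy()`) agree exactly; the test suite checks the DP
  against exhaustive enumeration of every nested structure on sequences up
  to 20 nt.
* Interior loops are bounded at 30 unpaired bases (the standard practical
  cap); the minimum hairpin loop is 3 nt; dangling-end terms are omitted,
  which keeps the enumeration oracle exact.
* Co-optimal ties are broken deterministically by a traceback that prefers
  paired/stacked options at the leftmost position, i.e. a pairing-rich
  representative structure. Only the energy is contract-relevant.
* A single-nucleotide bulge keeps the flanking stack, as in standard
  models; larger bulges and internal loops pay only their initiation plus
  asymmetry.

Absolute energies are model-dependent. The package's Turner-like table
gives hairpin MFEs in the same range as RNAfold/mfold for these lengths,
but thresholds calibrated on one model should not be treated as portable
constants — which is why the MFE cutoff and MFEI window are configuration
values, not assertions.

## Precursor criteria

`evaluate_candidate()` folds the 421-nt window, requires the mature to lie
entirely within one arm of a single stem-loop (no base in the terminal
loop), then trims to that stem-loop and refolds, iterating to a fixed point
so that re-evaluating the reported precursor coordinates reproduces the
identical verdicts. On the trimmed precursor it checks:

* **duplex** — at most 4 unpaired mature bases and no asymmetric bulge
  over 2 nt between mature and star (the Dicer-product annotation
  convention);
* **star** — the opposite-arm segment pairing the mature with a 2-nt 3'
  overhang on both strands must exist (at least mature length - 4 bases
  paired);
* **MFE** — at most -18 kcal/mol by default;
* **MFEI** — `(|MFE|/length x 100) / (GC x 100)`, computed with the
  *precursor's* GC fraction (the MFEI literature defines it on the
  precursor, and mature GC would not reproduce any published MFEI
  arithmetic). The default window 0.7-1.5 is recorded as a verdict but
  does not gate acceptance (`mfei_required = FALSE`): published
  novel-miRNA tables themselves contain values such as 2.00 and 0.62-0.65
  outside that window, so we treat the window as advisory unless the user
  opts in.

One mature may aggregate several passing loci (several precursors), and
several miRNAs may share a unigene; loci of the same mature on one
unigene/strand whose windows overlap by at least 50% are merged to the
lowest-MFE representative. Novel ids are assigned in lexicographic order of
the mature sequence.

## Differential expression choices

The test is Fisher's exact on
`[[count_F, total_F - count_F], [count_M, total_M - count_M]]`, two-sided
by the minimum-likelihood rule; the chi-square test (1 df, no continuity
correction by default) is provided alongside, and the DE decision uses
Fisher. The multiple-testing method is Benjamini-Hochberg (Bonferroni via
config) — the standard choice for sRNA count screens. Library-specific
miRNAs (one TPM zero) are callable on the adjusted p alone; their ratio is
reported as 0 or infinite and log2 is left undefined. Report files round
TPM to 2, ratios to 3 and log2 to 4 decimals, matching the conventions of
published tables so files are comparable cell for cell.

## What the synthetic generator emulates — and what it does not

`simulate_study()` builds the entire ground-truth world: a unigene set
(default GC 0.45, 600-1500 nt), planted pre-miRNAs, two read libraries and
a degradome. Its design choices:

* **Precursor shape.** A lower stem (8-12 bp), the mature/star duplex, an
  upper stem (5-8 bp) and an 8-12 nt loop drawn from {A,C} so it cannot
  self-pair. The 3' arm is the reverse complement of the 5' arm with 1-2
  injected non-pairing substitutions opposite the mature interior — always
  on the star side, so the mature still maps perfectly. At least one
  mismatch is always injected: a perfect-revcomp star would make the
  mature itself map onto the star region of its own precursor.
* **Matures** are 20-24 nt (21 nt most likely) and start with U,
  reflecting the strong 5'-uridine bias of plant miRNAs.
* **Abundances** emulate a deeply down-scaled two-library experiment:
  8-40 expected reads per miRNA per library, planted 8-fold differential
  expression (one DE miRNA per study is male-specific). DE-planted miRNAs
  draw from the upper abundance range (25-40) so that the planted 8-fold
  effect is statistically detectable at the simulated depth — at a handful
  of reads no count-based test could call direction, and the benchmark is
  meant to test correctness, not power.
* **Nuisance reads.** Contaminants are exact substrings of the bundled
  ncRNA set (5% of each library by default) plus adapter; noise is half
  random sequence and half transcript-derived decoys sampled off the
  planted precursor windows (decoys represent non-miRNA background, so
  they are kept off regions that are miRNA loci by construction).
* **Degradome.** Planted cleavage sites are perfectly complementary target
  insertions; signal reads start exactly at the position opposite miRNA
  nucleotide 10, background reads start uniformly.

Not emulated: sequencing error and quality-score realism (qualities only
matter to the FASTQ quality filter), biological replicates and
overdispersion (the study design is two pooled libraries, hence exact
tests), isomiR heterogeneity, RNA editing/polymorphism, and genomic (vs
transcript) precursor context. Passing the recovery tests therefore shows
the machinery is correct on clean, planted signal — not that every
threshold is optimal on noisy real libraries.

## Problem sizes used by the tests

Unit tests run scenarios of 30 unigenes / 10 planted miRNAs; the
end-to-end recovery checks use 50 unigenes / 20 miRNAs / 4 planted DE / 5
cleavage sites over three seeds; folding is cross-checked against
exhaustive enumeration on 200 sequences of 8-20 nt, Fisher against full
hypergeometric enumeration on 200 tables with margins up to 2000, and the
degradome classifier against an independent implementation on 500 random
profiles. These sizes were chosen so the whole suite exercises every
contract in a few minutes on a laptop while keeping the enumeration
oracles exact.

## Known limitations

* The energy model is deliberately compact (no dangles, no special
  tetraloop bonuses, no coaxial stacking); calibrated thresholds from
  RNAfold/mfold pipelines transfer only approximately.
* Conserved assignment enforces equal length; a 20-nt read never matches
  a 21-nt reference even at zero mismatches. This is configurable only by
  editing the mature set (e.g. adding trimmed variants).
* Degradome category definitions follow the t-plot convention with the
  median over occupied positions; with very few occupied positions
  category 2/3 boundaries are coarse.
* `map_perfect()` and `map_degradome()` use exact string search over the
  transcript set, which is exactly right at study scale (tens of
  thousands of unique tags) but not tuned for genome-scale references.
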