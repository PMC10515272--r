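---
title: "Methods: small secreted peptide discovery with sspminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small secreted peptide discovery with sspminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sspminer)
library(dplyr)
```

This vignette documents the models, parameter choices and numerical
conventions behind `sspminer`, and what the package's synthetic test bed
does and does not demonstrate about real data.

## The identification cascade

Small secreted peptides are defined operationally by four sequential
filters applied to a predicted proteome (after keeping the longest
transcript per gene):

1. **Size gate.** 25–250 residues, inclusive on both ends. Both bounds are
   arguments of `filter_length()`; the inclusive `[25, 250]` reading is the
   procedural convention adopted here.
2. **Signal peptide.** The cascade consumes a per-protein verdict table.
   Production use parses SignalP-5.0 short-format output
   (`read_signalp()`); for self-contained runs a deterministic heuristic
   (`predict_signal_peptide()`) stands in. The heuristic mirrors the
   classical tripartite signal-peptide model: a positively charged
   n-region (at least one K/R before the core), an 8-residue hydrophobic
   core with mean Kyte–Doolittle hydropathy ≥ 1.6 within the first 45
   residues, and a cleavage site 3–7 residues after the core whose −1 and
   −3 positions are small residues (A/G/S/C/T). When several cleavage
   positions are admissible for the leftmost core, the rightmost is taken;
   this makes detection deterministic and places the cut at the
   small-residue boundary of the canonical test template. The heuristic is
   a documented rule set, not a reimplementation of any external
   predictor, and its absolute accuracy on real proteomes is not claimed.
3. **Transmembrane exclusion.** With TMHMM-2.0 output (`read_tmhmm()`),
   `PredHel ≥ 1` removes the protein. The built-in fallback counts
   non-overlapping 19-residue windows with mean hydropathy ≥ 1.8,
   greedily left to right, on the *mature* sequence — counting after
   signal-peptide removal avoids double-counting the signal peptide's own
   hydrophobic core as a helix.
4. **ER retention.** Proteins whose last four residues are exactly KDEL or
   HDEL are removed. Internal occurrences are kept: the retention signal
   is strictly C-terminal.

The stages are monotone (each survivor set is a subset of the previous
one), and the transmembrane and ER gates commute; both properties are
asserted in the test suite. Missing predictor verdicts are a hard error
rather than an implicit failure so stage tallies can never silently
undercount.

## Family classification and cysteine patterns

Classification is rule-based: each rule is a compact motif (`x` = any
residue, `[..]` = alternatives) searched in the mature sequence, its
C-terminal window, or the full precursor, optionally with a co-occurring
second motif and an exact mature-cysteine-count constraint. Rules apply in
priority order — PTM-family motifs before generic cysteine rules — and
each candidate receives at most one family, so family counts partition the
candidates. The shipped rules (`inst/extdata/family_rules.yaml`) cover the
families with published motif evidence: CEP (SPGxG[H/N]), CLE (a
conservative dodecapeptide box, `RxxPxGPDPxHH`, deliberately editable
because no universal CLE consensus string exists), PNP (`K[VI][VI]D` plus
`LSxxA[FI]xxIA`) and RALF (four mature cysteines plus the RR dibasic
site). The remaining names of the 38-family vocabulary exist so external
assignments can be imported and linted against one taxonomy; profile-HMM
or homology search is out of scope by design.

A candidate is a cysteine-rich peptide (CRP) when its mature sequence
contains an even number of cysteines between 2 and 16. The whole mature
sequence is counted (not only a C-terminal window): the alternative
reading would change counts for peptides with dispersed cysteines, and the
whole-mature convention is the one the size distribution of known CRPs
supports.

Cysteine-spacing patterns (`parse_cys_pattern()`) use the grammar
`C x3 C x5 ... C` with exact gaps, bounded ranges (`x4-6`) and variable
gaps (`xn`, any number ≥ 0). Gap residues must be non-cysteine, so a
matched block contains exactly the pattern's cysteines and every match
aligns the pattern with consecutive cysteines of the sequence; matching is
leftmost, non-overlapping. The matcher is cross-checked against an
independent regular-expression oracle (`C[^C]{3}C…`) on thousands of
random sequences.

**Novel-family discovery** clusters unclassified CRPs by their gap
vectors. Candidates with equal cysteine count join a cluster when every
gap position except the one of maximal spread stays within a band of
± `gap_tolerance` (default 1 residue) around a common centre, i.e. spread
≤ 2 × tolerance. The centre-based reading was chosen over a seed-pairwise
reading because a family can legitimately combine one unconstrained gap
with one small-range gap (e.g. `x4-6`), which a pairwise rule at
tolerance 1 could never admit. Clustering is greedy in input order, which
is deterministic; for well-separated archetypes the resulting membership
is permutation-stable (tested). The consensus pattern reports zero-spread
positions as exact gaps, the maximal-spread position as variable when its
spread exceeds the tolerance band, and the rest as ranges.

## sORF mining

Non-coding sequence is the per-chromosome complement of the union of CDS
features (strand-ignored; UTRs and introns stay searchable, and masking
whole gene bodies is a caller choice via `mask_feature_types`). GFF3 is
1-based inclusive at the boundary; all internal arithmetic is 0-based
half-open, converted only in readers/writers, to prevent off-by-one drift.

`find_sorfs()` scans the three forward frames and the three frames of the
reverse complement. An ORF requires both an ATG and an in-frame stop
(`require_stop = TRUE` by default; segment-truncated ORFs are dropped).
Codons containing N are non-translatable and abort the ORF spanning them
— translating them as X would fabricate peptides across assembly gaps.
The reported genomic interval covers start through stop codon inclusive;
the peptide excludes the stop. Nested in-frame ORFs sharing a stop
collapse to the longest (most upstream ATG). Only single-exon ORFs are
considered; spliced reconstruction and coding-potential scoring are out of
scope. The scanner is verified against a brute-force per-position
enumerator on dozens of random sequences per run, and every reported
interval re-extracts and re-translates to its stored peptide.

## CEP domains

The CEP domain is located by the conserved box SPGxG[H/N], exactly as
printed — no substitution tolerance — with leftmost non-overlapping
resolution for determinism. The candidate mature peptide is the 15-residue
window ending at the box's last residue; both published synthesized CEP
peptides are 15-mers of this shape, but true mature boundaries are
variable in vivo (hydroxylation, trimming), so the window length is a
parameter (`mature_len`), an operational convention rather than a
biochemical claim.

## Expression and physiology

DE calling is a pure threshold rule on provided FPKM and q-values:
up when log2 FC ≥ 1 and q ≤ 0.05, down with the mirrored bound. q-values
are consumed as given (they normally come from the upstream RNA-seq
processing); `bh_adjust()` is a convenience for raw p-values on synthetic
data, not part of the method. A zero FPKM with `pseudocount = 0` is an
explicit error — never a silent infinity; whether a pseudocount is
appropriate depends on the upstream quantification, so it is exposed and
defaults to 0.

qPCR relative expression is 2^−ΔΔCt with a reference gene per sample and
a calibrator condition. The physiology formulas are evaluated with the
literal operator order of their printed forms, RWC = (FW−DW)/(SW−DW)×100%,
REC = K1/K2×100%, and MDA (nM/g) = [(A532−A600)·Vr/ε·10⁹]/(Wt·Vt/V) with
ε = 1.55×10⁵ L/mol/cm. The unit bookkeeping of the MDA expression (nM/g
versus nmol/g) is ambiguous in the field's common phrasing; the package
reproduces the printed expression verbatim and documents that ambiguity
rather than silently "fixing" it. Group comparison is classical one-way
ANOVA plus Tukey HSD; the compact letter display uses insert-and-absorb
over the significant pairs, and undefined p-values (zero variance) are
treated as non-significant, so degenerate identical groups share a single
letter.

## The synthetic test bed

The generators are pure functions of (config, seed) — reruns are
byte-identical — and their defaults define the package's standard study
conditions:

* **Proteome** (`simulate_proteome()`): 40 true SSPs (8 each CEP, CLE,
  RALF, PNP; 4 + 4 of the two six-cysteine archetypes; two CEPs carry two
  domains) and 50 decoys: 15 oversize, 20 without signal peptide, 10 with
  a transmembrane stretch, 5 K/HDEL-terminated. Positives use one fixed
  signal-peptide template (`MKTNLFLVLLLAGSALA`, cleavage after residue 17)
  with bounded hydrophobic-core mutations that are unit-tested to preserve
  heuristic detection; random filler is drawn from hydrophilic,
  cysteine-free residues so no decoy or filler can accidentally create a
  hydrophobic core, a transmembrane window, a family motif or a stray
  cysteine. Recovery is therefore provable: sensitivity and specificity of
  the cascade on these fixtures are exactly 100%.
* **Genome** (`simulate_genome()`): 12 secreted-sORF cassettes, 8
  non-signal-peptide cassettes and 2 nested pairs on 2 chromosomes, with
  3 decoy CDS blocks and ≥ 50 nt spacing. Background DNA is random at
  GC 0.38 but purged of ATG and CAT trigrams (forward and reverse start
  codons), and the back-translation codon table never creates a start
  codon across junctions (no codon ends in A or AT; a third-base C→T
  synonymous swap repairs the one junction class that could form CAT).
  Consequently the planted cassettes are the *only* ORFs in the genome and
  miner recovery is exact by construction.
* **Expression** (`simulate_expression()`): 30 up / 20 down / 50 null
  genes over five drought time points; planted |log2 FC| = 2 ± 0.25 with
  q ≤ 0.005, null q ≥ 0.2 — margins ≥ 10× the calling thresholds, so the
  tally recovers the planted counts exactly.
* **Physiology** (`simulate_physiology()`): four treatment groups
  (well-watered, drought, drought + each of two peptide treatments) of 15
  samples with group-level RWC/REC/MDA targets spanning the ranges typical
  of drought experiments and small within-group noise.

What passing these tests shows: the filters, scanners and calculators
implement their stated rules exactly, with correct coordinates, tallies
and determinism. What it does not show: performance on real proteomes and
genomes, where signal peptides are diverse, hydrophobicity is ambiguous,
ORF density is high and DE effects are noisy — the heuristics are
stand-ins for the external predictors there, and the generators
deliberately do not emulate genome-scale ORF counts, paralogy, or
borderline cases. Headline counts from real tomato data (e.g. total SSPs
or per-family sizes) depend on external predictor versions, database
services and genome releases and are not reproduced by this package.

## Problem sizes and runtime

Default fixture sizes (90-protein proteomes, two-chromosome synthetic
genomes of a few kilobases, 100-gene expression matrices, 50-sequence
oracle comparisons up to 5 kb) keep the full test suite under a minute on
a single core while still exercising every code path; they are the
package's chosen standard conditions, and all sizes are arguments if
larger simulations are wanted.
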