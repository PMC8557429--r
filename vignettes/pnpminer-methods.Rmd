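---
title: "Mining neuropeptide precursors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining neuropeptide precursors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpminer)
```

This vignette describes the scientific model behind pnpminer, the
parameters that matter, the synthetic data the package tests itself
against, and the design decisions taken where more than one reasonable
choice existed.

## The precursor model

A proneuropeptide (pNP) is modeled as a string

```
signal | peptide (G) site | intersequence peptide (G) site | ... | tail
```

where `site` is a dibasic pair (KR/RR/KK/RK), the optional `G` is the
amidation donor glycine, and intersequences are non-conserved spacers.
The processing model makes three assumptions, all standard for
prohormone convertase/carboxypeptidase maturation:

* cleavage occurs C-terminal to the dibasic pair and both basic residues
  are removed from mature products (carboxypeptidase trimming is
  implicit);
* a glycine immediately preceding a cleavage site (or the precursor
  C-terminus) is converted to a C-terminal amide on the preceding
  residue (−0.98402 Da);
* an N-terminal glutamine may cyclize to pyroglutamate (−17.02655 Da);
  glutamate is deliberately not flagged, matching the modification space
  used for the MS identifications the package consumes.

Everything the annotation produces is constrained by a *tiling
invariant*: signal peptide + mature cores + removed amidation glycines +
site residues (+ any segments that vanished after processing) must
reconstruct the precursor exactly. `check_tiling()` verifies this and
the test suite enforces it for every annotated precursor.

Two corner cases need explicit rules:

* **Overlapping basic runs.** In a run such as `KRKR`, dimers are
  counted non-overlapping from the left, giving sites after positions 2
  and 4; the empty peptide between them is dropped but recorded. This
  is what produces GWamide-style alternative products from directly
  abutting copies.
* **Monobasic sites.** A lone arginine is a cleavage candidate only
  when another basic residue lies 3–6 positions N-terminal of it.
  Monobasic sites never segment a precursor during annotation (they are
  "alternative" confidence); they are only consulted when interpreting
  observed MS peptides, where such products genuinely occur.

## The discovery screen

The screen is defined by two POSIX-extended regular expressions over the
secretome (built by `build_motif_patterns()`): at least three amidation
units separated by 2–25 residues, or at least five dibasic units
separated by 5–25 residues. The package treats the *patterns themselves*
as the specification of the result set: `scan_multicopy()` must be
decision-equivalent to direct evaluation of the printed patterns by a
reference engine. The implementation builds the patterns from
`pattern_params()` and evaluates them with R's TRE engine; tests and the
acceptance script re-evaluate the literal patterns with the PCRE engine,
so a disagreement in either the pattern construction or the engine
semantics would surface. The literal `*` inside `[KR*]` is preserved:
in six-frame translations a stop symbol can terminate an amidated
C-terminal peptide.

The `650` aa length cutoff and the `0.95` redundancy threshold follow
the screen's published protocol; redundancy reduction is greedy
longest-first clustering with identity computed over the shorter
sequence (the shorter sequence aligned end-to-end within the longer
one), which reproduces the documented convention of the usual
clustering tool without its k-mer prefilter heuristics — exact and fast
at desk scale. Dedup runs before the length filter, following the
protocol's stated order.

## Similarity search and clustering

BLAST is replaced by exact Smith–Waterman (BLOSUM62, gap open 11,
extend 1; `X` and `*` score the matrix minimum) with Karlin–Altschul
E-values `E = K·m·n·exp(−λS)` using the published gapped constants
λ = 0.267, K = 0.041. This is deterministic and exact where the
heuristic engine is approximate, which matters for reproducible tests;
an adapter for external tabular search output would be the natural
extension for genome-scale data. The two-pass contract — relaxed pass at
1e-1, recycle hits (plus motif candidates, through an optional
user-supplied curation keep-list) as stringent queries at 1e-5 — is what
recovers chain-connected "hidden orthologs", and is tested with an
explicit A→B→C construction in which C is similar only to B.

Clustering keeps only what carries scientific weight in the original
procedure: the thresholded similarity graph and its connected
components. Force-directed layout is cosmetic and intentionally out of
scope. Components at a stricter threshold always refine components at a
looser one; this is asserted as a property.

## MS confirmation

Identifications arrive as a table (peptide sequence, modifications,
observed monoisotopic mass, source id) — a documented subset of a
MaxQuant-style peptide table. Matching is sequence-level (Leu/Ile
distinct), never spectral. Each identification is located as an exact
substring of the annotated precursors; the span is then classified
against the predicted cores: exact span → `full_dibasic`; sub-spans
sharing one boundary → `truncated_C`/`truncated_N`; sharing neither →
`truncated_both` when within one residue of a predicted boundary,
otherwise `internal`; spans consistent with a supported monobasic
arginine or a consecutive-copy alternative product →
`monobasic_product`; substrings found only outside the discovered set →
`novel_precursor`. Ambiguous occurrences are all reported, with a
primary chosen by category rank, then host length, then id — the full
set of occurrences is never collapsed away. The theoretical mass is recomputed from
sequence and modifications; a located peptide whose mass error exceeds
the tolerance (default 0.01 Da, generous for synthetic data and
configurable) is demoted to `unmatched` rather than silently accepted.

Masses use the standard monoisotopic residue table plus one water;
modification deltas are fixed constants (amidation −0.984016,
pyroglutamate −17.026549, oxidation +15.994915, N-terminal acetylation
+42.010565, tyrosine sulfation +79.956815, and fixed cysteine
carbamidomethylation +57.021464 applied to every Cys). The tests verify
the whole table and all deltas against an independent
elemental-composition calculator to 1e-4 Da.

## Gene structure

Gene models are consumed as GFF3 (spliced alignment is out of scope;
when a gene has several transcripts, the longest complete CDS is used —
a deterministic rule the format itself does not dictate). Intron phase
is the cumulative CDS length modulo 3 at the junction: phase 0 falls
between codons after residue `floor(c/3)`, phases 1/2 interrupt the
codon of residue `floor(c/3)+1` — a phase-2 intron sits between the
second and third nucleotide of that codon, the configuration relevant to
cleavage-site codons in the 8-Cys peptide family. Conservation calls
project each intron to its residue's column in a supplied protein
alignment and require *identical phase* plus column agreement within a
tolerance of ±2 columns. The tolerance is a configuration knob: "similar
position" has no published number, and ±2 absorbs small alignment wobble
without merging distinct introns; phase identity is kept hard because
phase is the robust signal. Both position and phase are reported, so a
stricter reader can require both to be exact.

## What the synthetic data emulates — and what it does not

`generate_proteome()` plants nine families (six discoverable by the
screen, a vasotocin-like single-copy + Cys-domain precursor, a
CCWamide-like 8-Cys precursor, and a held-out two-copy family that only
MS can reveal), eight ortholog members each, among 1000 decoys by
default. Signal peptides follow a fixed canonical layout (Met + charged
n-region + 12-residue hydrophobic core + A-X-A cleavage motif) written
simultaneously to the signal table, so tests are independent of any
predictor's fidelity; the built-in Kyte–Doolittle heuristic
(`predict_signal()`, window mean > 1.6 in the first 30 residues) exists
for inputs without annotations. Ortholog divergence is per-site
substitution at a rate of 0.1 restricted to unprotected positions
(spacers, pro-regions, tails) over an alphabet without G/K/R/C, so
divergence can neither create nor destroy cleavage sites, amidation
donors or cysteine bookkeeping — members stay pre-aligned at equal
length. Decoys are 80% random globular-like sequences, 10%
signal-bearing non-precursors, and 10% glycine/basic-rich traps that can
legitimately satisfy the screen (the false-positive class that motivates
downstream curation). Every discoverable member is verified against
direct evaluation of the printed patterns before emission; generation
fails loudly if a family's motif geometry cannot satisfy the thresholds.

Passing on these data shows that the pipeline's logic is faithful to its
rules; it does not show robustness to what the generator omits: indels
between orthologs (alignment is trivialized), codon-usage and
composition biases, signal-peptide predictor errors, chimeric or
fragmented transcripts, and spectral-level ambiguity (Leu/Ile,
deamidation) in the MS arm. Real-data runs inherit the quality of the
external signal annotations and identifications they are given.

Gene models are emitted by back-translating planted precursors with
uniformly random synonymous codons and inserting GT..AG introns (60–500
nt) at planned phase points, on alternating strands; recovery must be
exact on both strands.

Observed masses in generated identification lists equal theoretical
masses (Gaussian error σ = 0 by default): the matcher's mass check is an
internal-consistency check, and the spread of real instrument error is
not part of the model under test.

## Numerical and scale choices

* Identity for copy grouping in architecture classification is 0.5 over
  the shorter copy; no published number exists, and 0.5 cleanly
  separates planted copies from spacers while remaining a surfaced
  parameter (`copy_identity`).
* Architecture precedence is deterministic: `cys8_peptide` >
  `single_copy_plus_cys_domain` > `multicopy` > `single_copy` >
  `other`; peptides are sorted by position first, so classification is
  order-invariant.
* The default test and acceptance problem sizes — 10,000 sequences for
  screen/oracle equivalence, 1,000 decoys for planted recovery, 200 MS
  identifications, 50 alignment-oracle pairs, 4-ortholog intron
  families — are the package's chosen desk-scale study conditions;
  generators scale to larger runs by argument.
* All generators and drivers are deterministic functions of their seed;
  manifests record parameters, seed and per-stage counts.

## Known limitations

* The screen's semantics are exactly those of the printed patterns,
  including quirks (e.g. greedy unanchored matching); "improving" the
  patterns would change the result set and is out of scope.
* CD-hit-style clustering is exact greedy clustering, not the word
  filter approximation; on very large candidate sets it is quadratic.
* The similarity engine is exact Smith–Waterman: appropriate for
  thousands of candidates, not for raw transcriptome-scale all-vs-all.
* Monobasic-site interpretation implements the stated 3–6 support rule
  only; convertase specificity beyond it (P1'/P2' context, secondary
  structure) is not modeled.
* The configuration file format is YAML.
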