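# pnpminer

Mining and annotation of neuropeptide precursors (proneuropeptides, pNPs)
from translated transcriptomes, with prohormone-processing prediction,
similarity clustering, mass-spectrometric confirmation of predicted
peptides, and exon–intron structure comparison as homology evidence.

## The problem

Proneuropeptides are secreted precursor proteins: an N-terminal signal
peptide followed by one or more short bioactive peptides, each flanked by
basic cleavage sites (KR, RR, KK, RK) recognized by prohormone
convertases, often interleaved with non-conserved spacer peptides
("intersequences"). The active peptides are short (2–40 aa) and fast
evolving, so BLAST-style homology search alone misses many of them.
pnpminer implements the complementary strategy used in comparative
neuropeptidomics:

1. **Secretome gating.** Candidate proteins must carry an N-terminal
   signal peptide (external annotations in a SignalP-style TSV, or a
   built-in hydrophobicity heuristic).
2. **Multicopy motif screen.** The secretome is scanned with two
   POSIX-extended regular expressions describing repeated processing
   signatures — at least 3 amidation sites (`G[KR][KR]`-type, with
   spacers of 2–25 aa) or at least 5 dibasic sites (`[KR][KR]`, spacers
   of 5–25 aa):

   ```
   ((.{2,25}G[KR][KR])|(.{2,25}[KR](.{1}|.{3}|.{5})G[KR*])){3,}
   (.{5,25}[KR][KR]){5,}
   ```

3. **Redundancy reduction and length filter.** Greedy longest-first
   clustering at 0.95 identity (over the shorter sequence), then removal
   of candidates longer than 650 aa.
4. **Two-pass similarity search.** A relaxed pass (E ≤ 1e-1) against
   seed queries; its hits, unioned with the motif hits, are recycled as
   queries for a stringent second pass (E ≤ 1e-5) that recovers "hidden
   orthologs". Local alignment is exact Smith–Waterman under BLOSUM62
   with affine gaps (open 11, extend 1) and Karlin–Altschul E-values
   `E = K·m·n·exp(−λS)` with λ = 0.267, K = 0.041.
5. **Similarity-graph clustering.** All-vs-all E-values thresholded at
   1e-5 (1e-10 for display); connected components are the precursor
   families.
6. **Prohormone processing model.** Cleavage C-terminal to dibasic
   pairs (both basic residues removed), monobasic Arg sites supported by
   a second basic residue 3–6 positions N-terminal (alternative
   confidence), C-terminal amidation from a glycine donor (−0.98402 Da),
   N-terminal pyroglutamate from Gln (−17.02655 Da), and architecture
   classes (multicopy, single copy + Cys-rich neurophysin-like domain,
   8-Cys terminal peptide).
7. **MS confirmation.** Observed peptide identifications (a
   MaxQuant-style table subset) are located on the predicted precursors
   and classified as full dibasic products, N/C/double truncations,
   monobasic products, internal fragments, or evidence of novel
   precursors missed by the screen.
8. **Gene-structure comparison.** Intron positions in protein
   coordinates and intron phases (0/1/2) from GFF3 gene models;
   cross-ortholog conservation calls require identical phase and
   alignment-column agreement within a small tolerance.

A deterministic synthetic-data generator emulates all inputs — planted
precursor families with ground truth, decoys (including glycine/basic
rich traps that legitimately satisfy the screen), gene models with
planted introns, and MS identification lists — so the whole pipeline is
testable offline.

## Worked example

```r
library(pnpminer)

sim <- generate_proteome(n_decoys = 200, seed = 1)   # 72 planted + 200 decoys
secretome <- gate_by_signal(sim$records, sim$signals)
hits <- scan_multicopy(secretome)
head(hits, 3)
#>   protein_id matched_branch match_spans
#> 1   fmrf_m01           both 6-115;9-115
#> 2   fmrf_m02           both 6-115;9-115
#> 3   fmrf_m03           both 6-115;9-115
```

64 sequences pass the screen: all 48 discoverable planted precursors plus
16 glycine/basic-rich decoy traps (which the published patterns genuinely
accept — exactly the false-positive class the downstream clustering and
curation stages exist for). Annotating one FMRFamide-like candidate:

```r
id  <- "fmrf_m01"
ann <- annotate_precursor(sim$records[sim$records$id == id, ],
                          sim$signals[sim$signals$protein_id == id, ])
ann
#> >fmrf_m01 [multicopy]
#> MKRLVAIVIILAAVVATAHNNVHHDDPNFLRFGKRSWDPNFLRFGKREIPPIDPNFLRFG
#> s^^sssssssssssssss              a^^         a^^            a
#> RRFPSNLDPNFLRFGRKMSDPNFLRFGKRLEPDPNFLRFGRKTDIDPNFLRFGRKAEEMI
#> ^^            a^^         a^^          a^^          a^^
#> LWS
#> 8 predicted peptide(s); s=signal, ^=cleavage site, a=amidation glycine

ann$peptides[2, c("sequence", "amidated", "flanking")]
#>    sequence amidated        flanking
#> 2 SWDPNFLRF     TRUE dibasic-dibasic
```

The precursor is classified `multicopy`: seven near-identical
`...DPNFLRF`-amide copies between dibasic sites, each with its amidation
glycine removed from the mature core. The monoisotopic mass of one
amidated copy, used when matching MS identifications:

```r
monoisotopic_mass("DPNFLRF", "amidation")
#> [1] 906.4712
```

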