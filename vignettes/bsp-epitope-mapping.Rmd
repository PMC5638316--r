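---
title: "Fine B-cell epitope mapping with GST188 biosynthetic peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine B-cell epitope mapping with GST188 biosynthetic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspmap)
```

## The method

Linear (continuous) B-cell epitopes (BCEs) are the contiguous stretches of an
antigen that antibodies recognise. `bspmap` implements the computational side
of biosynthetic-peptide (BSP) epitope mapping: instead of chemically
synthesising peptides, every peptide is encoded as a short synthetic DNA
duplex, cloned behind a truncated 188-residue glutathione S-transferase
carrier (GST188), expressed in *E. coli*, and probed on a Western blot. The
mapping proceeds in two rounds:

1. **Antigenic-peptide scan.** 16- or 18-mer peptides tile the whole target
   protein at a start-to-start step of 8 residues, so consecutive tiles
   share 8 (16-mers) or 10 (18-mers) residues. Reactive tiles localise
   antigenic regions.
2. **Fine-motif scan.** Each reactive region is re-tiled with 8-mers at
   step 1 (7 shared residues). For a run of `k` consecutive reactive 8-mers
   the epitope must lie in their intersection, a stretch of `8 - k + 1`
   residues; an isolated reactive 8-mer bounds it only to that tile. The
   intersection of the run *is* the reported fine motif, with 1-based
   inclusive coordinates on the protein.

Equal-length motif variants recovered from homologous antigens are
summarised as a degenerate consensus: positions where variants disagree are
bracketed, e.g. variants `ELRHY` and `EYRHY` give `E[LY]RHY`.

The model behind the wet-lab screening steps is deliberately small:

* **Clonable duplexes.** An `n`-residue peptide becomes a coding sequence of
  `3n` bases wrapped as plus strand `5'-GATCC cds TAA G-3'` and minus strand
  `5'-TCGACTTA revcomp(cds) G-3'`. Annealed, these leave the 4-nt BamHI and
  SalI cohesive overhangs (`GATC`, `TCGA`) single-stranded and place a TAA
  stop between the peptide and the SalI site, so the vector's downstream
  GSVD read-through is never appended to the expressed peptide. Both strands
  are `3n + 9` nt: 33, 57 and 63 nt for 8-, 16- and 18-mers.
* **Constructs as cut-to-cut distances.** Plasmids are modelled only by the
  backbone and stuffer lengths between the BamHI and SalI cut positions
  (4190 + 6 = 4196 bp for the original vector; 4190 + 321 = 4511 bp for the
  E7-stuffed vector, whose 315 bp ORF encodes 105 residues). An insert
  contributes its plus-strand length. This reproduces every published size
  without a base-resolution vector map, which is not available.
* **Gel screening.** Fusion sizes are `188 + appended` residues (GST196 for
  an 8-mer clone, GST192 for the GSVD read-through), masses are estimated as
  `0.110 kDa x residues + 0.018`, and two bands are called distinguishable
  when they differ by at least 0.8 kDa.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| round-1 window / step | 18 / 8 | residues | one step size serves both documented designs: 16-mers then share 8 residues, 18-mers share 10 |
| round-2 window / step | 8 / 1 | residues | step 1 is what makes the intersection motif well defined |
| codon policy | most-frequent, *E. coli* K-12 | — | codon optimisation is unnecessary for these short fusions, so the deterministic choice maximises reproducibility; a seeded-random mode samples codons by usage fraction |
| `pad_min_core` | 6 | residues | peptides shorter than this get a tri-alanine (`AAA`) N-terminal pad purely for cloning convenience; 3–5-mers are padded, 8-mers never. The pad is tracked and excluded from motif strings and coordinates |
| `distinct_kda` | 0.8 | kDa | picked between the resolvable 8-residue increment (~0.88 kDa) and the unresolvable 4-residue one (~0.44 kDa) |
| weak antigenic window | 21–30 | kDa | the region of the *E. coli* proteome with minimal background reactivity, where carrier–peptide fusions are deliberately sized |
| synthesis prices | 1.20 / 2.00 CNY per nt, tier at 60 nt; 20 CNY sequencing per clone | CNY | reproduces the per-residue costs 9.80 CNY/aa (16-mer) and 12.40 CNY/aa (8-mer); 60 nt exactly is priced at the short tier, which the price list leaves undefined |
| `fx_cny_per_usd` | 7.0 | — | the ratio implied by the paired CNY/USD price quotes; a reporting constant, not an exchange-rate claim |

## Numerical and edge-case choices

* **Terminal tile anchoring.** If the last regular round-1 tile stops short
  of the C-terminus, one extra full-length tile is anchored at
  `L - window + 1`. The alternative — a short terminal peptide — would break
  the fixed-window intersection arithmetic, and the expression system
  expresses fixed-length peptides.
* **Internal restriction sites.** The assembled insert
  (`GGATCC cds TAA GTCGAC`) must contain exactly one BamHI and one SalI
  site. Extra sites are removed greedily left-to-right by substituting the
  next-most-frequent synonymous codon among those overlapping the hit,
  re-scanning after every change; ties between codons are broken
  alphabetically so recoding is deterministic.
* **Runs longer than the window (`k > W`).** The intersection is empty;
  rather than guessing sub-epitopes the call is reported with status
  `ambiguous_empty_intersection` over the union interval, with a warning
  that multiple adjacent epitopes are likely.
* **Read verification** is residue-level first (the method's purpose is
  correct peptides, so a synonymous substitution still verifies as `match`)
  with nucleotide identity reported secondarily. `N` bases never match.
  Because both recognition sequences are palindromes, an insert found in the
  reverse complement of a read is a legitimate reverse-orientation clone;
  only the first BamHI→SalI pair per orientation is considered.
* **Mass from counts vs sequences.** With only a residue count the
  average-residue approximation (`0.110 kDa` per residue plus water) is
  used; with a sequence, standard average residue masses are summed. Screen
  decisions require both sides to use the same method.

## What the simulator emulates — and what it does not

`gen_protein`, `plant_epitope`, `simulate_reactivity` and `simulate_read`
generate everything the pipeline consumes. Reactivity follows a **full
containment** rule: a tile reacts exactly when it fully contains a planted
motif. This is the behaviour the intersection logic inverts, so noiseless
recovery is exact by construction — passing recovery tests demonstrates the
*design and inference arithmetic*, not blot biology. Real blots can show
partial-containment reactivity, intensity gradients, conformational
epitopes and cross-reactivity, none of which are modelled; optional
per-tile false-positive/false-negative rates are the only noise model, and
under false negatives broken runs widen (never falsify) exact calls because
every tile of a run still contains the motif.

Planted motifs are unique in the host by construction (spurious occurrences
are resampled away), and the recovery test suite plants them at interior
positions with at least 8 residues of margin, where the containment count
law — a unique motif of length `m` lights up exactly `9 - m` eight-mers —
holds exactly; at protein termini fewer containing windows exist.

All randomness flows through explicit integer seeds; no global RNG state
leaks to the caller.

## Problem sizes used in the test suite

The shipped tests run the whole pipeline at desk scale: host proteins of
80–237 residues, 1,000 random peptides for the duplex/frame laws, 200
seeded plant-and-recover simulations (motif lengths 3–8), and 50 random
plasmids for digest conservation. These sizes exercise every code path while
keeping the suite fast; all published anchor numbers are closed-form and do
not depend on simulation size.

## A worked run

```{r worked}
b <- simulate_bundle(protein_length = 120, seed = 11)
b$truth
rep <- two_round_report(b$round1_table, b$round1_tiles, b$round2_scans, b$protein)
as.data.frame(rep)

pair <- build_oligo_pair("P1", "YYGVGDYP")
pair
per_aa_cost(8)$cny_per_aa

screen_decision(fusion_product("r_clone", 8), fusion_product("carrier_only"))
```

## Known limitations

* No melting-temperature or secondary-structure screening of oligos, and no
  expression-level codon optimisation — the method needs neither.
* No base-resolution vector sequence: digestion and ligation are cut-to-cut
  arithmetic only, and gel migration is modelled as mass difference alone.
* Conformational epitopes, antibody affinity and partial-containment
  reactivity are out of scope; the containment assumption lives entirely in
  the simulator.
* Chromatogram (AB1) parsing and alignment-based indel localisation are not
  implemented; frame errors are detected by length only.
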