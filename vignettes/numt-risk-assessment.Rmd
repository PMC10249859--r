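---
title: "Detecting COI NUMTs and quantifying their inflation of species richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting COI NUMTs and quantifying their inflation of species richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtrisk)
```

## The problem

Nuclear genomes carry NUMTs — copies of mitochondrial DNA integrated into
chromosomes. After integration a NUMT evolves as a pseudogene: it
accumulates substitutions, short indels, and (because it is no longer
constrained to code) premature stop codons. NUMTs derived from the 658 bp
5' barcode region of cytochrome *c* oxidase I (COI) are a specific hazard
for DNA barcoding, metabarcoding and eDNA surveys: when a NUMT is
co-amplified with its mitochondrial homologue and is more than ~2%
diverged from it, it clusters as a separate operational taxonomic unit
(OTU) and inflates the apparent species count.

`numtrisk` implements the full analysis chain for assessing that risk on a
genome assembly:

1. **Screen** the assembly for residual mitochondrial sequence — scaffolds
   labelled "mitochondrion" in their FASTA headers, and unlabelled scaffolds
   detected by their alignable coverage of a reference mitogenome.
2. **Scan** the cleaned assembly for local alignments of the COI barcode
   (or full COI gene) with a self-contained seed-and-extend aligner, keeping
   hits ≥ 100 bp, ≥ 60% identity, E ≤ 1e-4.
3. **Filter** hits that cover the whole query (± 1 bp) at ≥ 99% identity —
   residual mitochondrial sequence or NUMTs too recent to matter at a 2%
   clustering threshold.
4. **Classify** each NUMT by length category (C1: 100–150, C2: 151–300,
   C3: 301–450, C4: 451–600, C5: ≥ 601 bp), percent divergence, and IPSC
   status (frameshift indel and/or premature stop codon under the
   invertebrate mitochondrial code), flagging the C5\* subset
   (651–661 bp span, no IPSC, > 2% divergence) that can masquerade as a
   full barcode.
5. **Quantify** the impact: windowed mitogenome-wide counts, single-linkage
   OTU clustering at 2%, and the exposure model translating category counts
   into per-protocol amplifiable NUMTs.

Because real assemblies are large and their NUMT content unknowable, the
package ships a synthetic-data module that generates annotated mitogenomes
and nuclear assemblies with *planted* NUMTs under full ground truth; every
stage of the pipeline is validated against those truth tables.

## The synthetic-data generator

`generate_mitogenome()` emits a linear mitogenome with the 13
protein-coding genes and two rRNAs in the canonical insect order (a fixed
published order; tRNAs are not modelled). Protein-coding genes are built
from codons drawn uniformly from the sense codons of translation table 5,
so no gene contains an in-frame stop; rRNA and intergenic tracts are
i.i.d. uniform A/C/G/T. The 658 bp barcode window sits near the 5' end of
COI with a configurable codon phase.

`plant_numts()` copies source intervals from the mitogenome into a random
background assembly. The pieces of the model, with defaults:

* **Length** — truncated Pareto with shape 1 (inverse-CDF sampling),
  default bounds 100–1,600 bp. This reproduces the strong skew towards
  short NUMTs observed in real insect genomes; at these bounds 71% of
  draws fall below 300 bp.
* **Divergence** — each event draws a substituted-site fraction *d*
  uniformly from a configurable range (default 0–0.36, mirroring the
  64–100% identity span of real COI NUMTs). Substitutions use an
  *exact-count* site model: exactly `round(d * length)` distinct sites are
  changed, transitions with probability κ/(κ+1) (κ = 2), so the planted
  Hamming distance equals *d* up to rounding and divergence recovery can
  be tested sharply.
* **Indels** — with probability `indel_prob`, one or two indels with
  lengths from a geometric(0.5) distribution truncated at 9 bp, placed at
  least 6 bp from the segment ends. The frameshift flag is a consequence
  (`length %% 3 != 0`), unless the policy forces frameshifting or in-frame
  lengths.
* **Premature stops** — with probability `stop_prob` an interior in-frame
  codon is overwritten with TAA/TAG; the edited sites count towards the
  substitution budget so divergence bookkeeping stays exact. The truth
  flag is then computed from the edited copy itself (the reconstructed
  source/copy alignment is screened in the COI reading frame), so stops
  *created incidentally by substitutions* are part of the ground truth —
  as they would be in a real pseudogene.
* **Copies** — an event can be duplicated up to 10 times (`copy_range`),
  all copies sharing a `copy_group`, emulating post-integration
  duplication.
* **Placement** — uniform over scaffolds (weighted by length), uniform
  position, random strand; minus-strand copies are reverse-complemented.
  Insertions never overlap.

What the generator does **not** emulate: repeat structure and GC
heterogeneity of real nuclear backgrounds, tRNAs and control regions,
heteroplasmy, within-species NUMT polymorphism, assembly errors and
sequencing chimeras. Passing recovery contracts on these simulations
therefore demonstrates the correctness of the detection and diagnosis
machinery under a clean insertion model, not performance on raw field
data.

## The aligner and its statistics

The scanner replaces BLASTn with a self-contained seed-and-extend search:
exact-match 9-mer seeds are extended without gaps under an X-drop rule and
survive when the ungapped segment reaches score 25 (match +2, mismatch
−3); surviving segments delimit candidate windows that are resolved by
*exact* affine-gap Smith–Waterman alignment (gap cost 5 + 2k), re-aligning
the flanks of each alignment so several nearby insertions sharing a window
each yield a hit. E-values follow Karlin–Altschul statistics,
`E = K·m·n·exp(−λS)`, with tabulated defaults (λ = 0.625, K = 0.41) for
this scoring scheme; `calibrate_karlin()` re-estimates them by fitting the
Gumbel law of optimal local scores of random sequence pairs.

Two deliberate departures from a vanilla local aligner:

* **Hit spans are boundary estimates.** The optimal local alignment ends at
  the maximum-scoring cell, which systematically *undershoots* the true
  homology boundary when the terminal bases are diverged (the terminal
  continuation is net-negative by construction). Reported spans therefore
  include a bounded tolerance extension (up to 15 bp per side, cumulative
  score ≥ −6). Without this, planted NUMTs of 100–130 bp at 25–30%
  divergence are trimmed below the 100 bp floor and silently lost.
  Divergence and category length are computed on the maximum-scoring core
  of the alignment, so they are not biased by the few unalignable columns
  a span can carry at its edges.
* **Overlap merging.** Same-scaffold, same-strand hits whose subject
  intervals overlap by more than half of the shorter are merged (best
  score kept), so one insertion yields one hit.

Degenerate inputs: N bases never seed, score as mismatches, and are
excluded from identity and divergence denominators; empty scaffold sets
return empty hit tables; queries outside 100–2,000 bp are rejected. The
exact aligner used as an oracle refuses sequences beyond 100 kb. Ties in
the DP are broken deterministically (smaller subject end, then smaller
query end, diagonal-preferring traceback).

## The IPSC screen

A NUMT is diagnosable when it carries a frameshift indel (gap length not a
multiple of three, judged per gap — two compensating gaps still count) or
a premature stop codon (TAA/TAG under translation table 5, read in the
frame implied by the query, re-anchoring after every gap; a terminal stop
is not premature).

Applying those definitions to *alignments* rather than known sequences
requires care at the boundaries, and `classify_numts()` layers four
safeguards, each motivated by a distinct failure mode of optimal local
alignment at 15–30% divergence:

1. **Strict re-alignment.** The search scoring is tuned for sensitivity
   and occasionally explains a run of mismatches with a pair of
   compensating micro-gaps (a spurious "frameshift"). Diagnosis therefore
   re-aligns each hit with heavier gap costs (12 + 3k); true indels — whose
   omission would misalign everything downstream — survive, score-neutral
   artifact pairs do not.
2. **Tolerant end extension.** Features in the last few bases of the
   homologous span are trimmed away by any optimal local alignment. The
   re-alignment's ends are extended without gaps under an X-drop tolerance
   (9), recovering diverged flanks while random background terminates the
   walk within a few columns.
3. **Flank-evidence anchors.** A stop codon is only called when an
   alignment segment scoring ≥ 2 touches it on both sides (≥ 8 for stops
   within three codons of the span ends, where "junction" codons straddling
   the homology boundary would otherwise be read); a frameshift gap placed
   by the sensitive alignment in the end zones the re-alignment did not
   cover is accepted only when segments scoring ≥ 10 flank it on both
   sides. Weakly supported terminal gap runs are trimmed before screening
   (threshold 8 ≈ four clean matches).

These constants were calibrated on a 500-NUMT simulated corpus and then
validated on five further corpora with fresh seeds; they are fixed
defaults, not tuning knobs. On such corpora (divergence uniform on
[0.03, 0.30], truncated-Pareto lengths from 100 bp, indel and stop
probabilities 0.4/0.25) the screen operates close to an information
floor: a 1 bp indel sitting 6–10 bp from a segment boundary can be
*score-equivalent* to a lucky shifted-register alignment, and a stop codon
in the first or last two codons of the homologous span is locally
indistinguishable from background. Measured performance across validation
seeds was 96.6–97.8% sensitivity and 97.4–100% specificity against the
planted flags; the residual errors are concentrated exactly in those
boundary classes. The package's acceptance test for this property is
stated at 98%/98%, and the sensitivity check fails by roughly one
percentage point under these corpus conditions — a limitation we consider
informative and report rather than mask by easing the corpus.

## Windowed counts and the susceptibility regression

`partition_windows()` concatenates the annotated gene regions (13 PCGs +
2 rRNAs) in genome order — windows may cross gene boundaries, the trailing
remainder is dropped — and cuts 658 bp windows (15–22 for a typical
mitogenome). `windowed_counts()` runs the scan + residual filter once per
window and once for the barcode; a NUMT overlapping two windows counts in
both, matching a per-fragment search design. Under the null hypothesis
that every mitogenome region integrates equally often, the log2–log2
regression of per-species window means on per-species COI counts has
slope 1. `survey_numt_counts()` simulates that experiment; with 100
species, per-species totals log-uniform on 4–256 and uniform source
sampling, the fitted slope falls in [0.8, 1.2] (attenuated slightly below
1 by Poisson noise in the counts, as in any errors-in-variables
regression). Species with zero in either count are dropped before taking
logs — they carry no information about proportionality.

## OTUs, exposure and PCR arithmetic

Sequence sets mapped to a common frame are clustered by single linkage at
a 2% p-distance threshold (pairwise deletion of gap/N columns). This is a
documented stand-in for the Refined Single Linkage algorithm used by
BOLD — plain single linkage reproduces its chaining behaviour but not its
refinement passes, so OTU counts on real data may differ slightly.
Clusters are the connected components of the graph joining pairs at
d ≤ 0.02; the test-suite checks this equivalence against brute-force
components exhaustively for 4 sequences and on random matrices up to 12.

Exposure converts category counts into expected amplifiable NUMTs:
`exposure(category) = mean category length / 658`, with interval midpoints
as means (C1 = 0.19, C2 = 0.34, C3 = 0.57, C4 = 0.80, C5 = 0.96 using
bounds 601–661). Built-in protocols: a single full-length barcode amplicon
(only C5\* NUMTs, exposure 1), dual mid-length amplicons (C3–C5), five
short amplicons for heavily degraded DNA (C1–C5), metabarcoding (C3–C5)
and eDNA (C1–C5). `protocol_exposure()` also accepts empirical mean
lengths in place of midpoints — published protocol totals are consistent
with empirical means, which is why the default midpoint model can differ
from them by a few percent. Richness inflation and conversion percentages
are exact integer arithmetic.

The PCR model captures why mitochondrial template usually wins:
`pcr_copy_ratio(60000, 0.005, 2)` — a nuclear genome 60,000× the
mitogenome, 0.5% mitochondrial DNA in the extract, two NUMT copies per
diploid genome — gives mtDNA a 150× head start, while
`pcr_trajectory(150, 1.2, 35)` shows a NUMT with 20% higher per-cycle
efficiency overturning that advantage within 35 cycles (final ratio
≈ 0.25).

## Problem sizes used by the test-suite

Unit tests use small corpora (≤ 60 planted NUMTs on ≤ 0.4 Mb of
background). The acceptance checks use a single fixed-seed corpus of 500
planted NUMTs on 2.5 Mb of background for recovery, IPSC and divergence
contracts, a 100-species survey for the susceptibility slope, and 10,000
draws for the length-distribution check; these sizes give binomial
standard errors comfortably below the contract margins while keeping a
full run in a few minutes.

## Known limitations

* Background assemblies are repeat-free; real repeat families would raise
  the false-seed rate and could fragment hits.
* The screen's boundary safeguards trade ~2–3% of boundary-feature
  sensitivity for specificity; both are reported per corpus by
  `evaluate_against_truth()`.
* Single linkage is not RESL; the C5\* OTU counts are a documented
  approximation.
* The mito-scaffold detector's coverage/identity thresholds (0.80/0.95)
  are package choices, configurable per call.
* Scaffolds longer than 20 kb with high mitogenome coverage are flagged
  for review, never auto-removed; whole-mitogenome insertions into
  chromosomes are indistinguishable from expanded mitogenomes without
  long-range context.
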