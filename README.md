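# numtrisk

Detection and risk assessment of nuclear mitochondrial pseudogenes (NUMTs)
derived from the COI DNA barcode, for R.

## The problem

Animal nuclear genomes carry NUMTs — fragments of the mitochondrial genome
integrated into chromosomes that then decay as pseudogenes. NUMTs derived
from the 658 bp 5' barcode region of cytochrome *c* oxidase I (COI) are a
standing hazard for DNA barcoding, metabarcoding and eDNA surveys: a
co-amplified NUMT more than 2% diverged from its mitochondrial homologue
clusters as a separate OTU and inflates the apparent species count. About
two thirds of COI NUMTs betray themselves through an IPSC — a frameshift
indel or a premature stop codon under the invertebrate mitochondrial code
(table 5: TAA/TAG are stops, AGA/AGG serine, TGA tryptophan) — but the
rest are undiagnosable, and their impact depends strongly on amplicon
length.

`numtrisk` provides the full analysis chain:

* a **mitochondrial-scaffold screen** (labelled-header removal plus
  coverage-based detection of unannotated mitogenome scaffolds, with a
  conservative 20 kb rule);
* a self-contained **seed-and-extend local aligner** (exact 9-mer seeds,
  X-drop ungapped filtering, exact affine Smith–Waterman resolution,
  Karlin–Altschul E-values, `E = K·m·n·e^{−λS}`), with a brute-force
  Smith–Waterman oracle for validation;
* the **residual-mitochondrial hit filter** (full query coverage ± 1 bp at
  ≥ 99% identity) and **NUMT classification** into length categories
  C1 (100–150 bp) … C5 (≥ 601 bp), percent divergence, IPSC status, and
  the C5\* flag (651–661 bp, no IPSC, > 2% divergence — the class able to
  masquerade as a full barcode);
* **mitogenome-wide windowed counting** (658 bp windows over the
  concatenated gene regions) and the log2–log2 regression of window-mean
  counts on COI counts, whose slope tests whether the barcode region is
  integrated at the same rate as the rest of the mitogenome;
* **OTU clustering** (single linkage at 2% p-distance, a documented
  stand-in for RESL) and the **exposure model**: per-category exposure
  `mean category length / 658` (C1 = 0.19, C2 = 0.34, C3 = 0.57,
  C4 = 0.80, C5 = 0.96), protocol-level amplifiable counts, richness
  inflation, and the PCR copy-number model
  (`genome size ratio × mt mass fraction / NUMT copies`);
* a **synthetic-data generator** that plants NUMTs with full ground truth
  (truncated-Pareto lengths with shape 1, exact-count substitutions,
  recorded indels, planted stops, up to 10 copies per event) so every
  stage can be validated without downloads.

## Worked example

```r
library(numtrisk)

# a synthetic species: 4 x 50 kb scaffolds, 20 NUMTs planted from the
# barcode region, a labelled residual mitochondrial scaffold
res <- run_numt_pipeline(list(seed = 7, n_numts = 20, source = "barcode",
                              length_range = c(120, 658)),
                         outdir = tempfile())
res$records
#> numt_records: 19 NUMT(s)
#>   categories: C1=3 C2=10 C3=4 C4=2 C5=0
#>   IPSC: 13/19   C5*: 0   mean divergence: 16.6%

# score the calls against the planted ground truth
evaluate_against_truth(res$records, res$sim$truth)
#> recovery_metrics: recall 0.950, precision 1.000, divergence MAE 0.45 pp
#>   IPSC confusion: TP=13 FP=0 FN=0 TN=6
```

Nineteen of the twenty planted NUMTs are recovered (one 120 bp copy at
high divergence is below the detection floor), every call is a planted
NUMT (precision 1.0), divergence is recovered to half a percentage point,
and all 13 planted IPSC carriers — and none of the 6 clean copies — are
flagged. The exposure arithmetic on the classified categories is in
`res$report$protocol_exposure`.

Exposure and PCR arithmetic stand alone:

```r
category_exposure(301, 450)            # 0.57  (C3 midpoint / 658)
protocol_exposure(c(C5star = 226), "full", 668)$per_species  # 0.338...
inflation_percent(139, 632)            # 22 (%)
pcr_copy_ratio(60000, 0.005, 2)        # 150
pcr_trajectory(150, 1.2, 35)           # 0.254 — the NUMT dominates
```

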