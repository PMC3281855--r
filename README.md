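# barcodegap

Distance- and character-based species identification from DNA barcodes,
built around the "barcode gap": in most animal groups, divergence at a
short standardized marker (the 5′ ~652 bp of mitochondrial COI) is small
within species and much larger between them, so an unknown specimen can be
assigned to species by its genetic distances to a reference library. The
package is aimed at people curating or auditing barcode reference
libraries (e.g. regional fish surveys): it quantifies the gap, finds the
species that violate it, screens for pseudogene contamination, and offers
a character-based fallback for markers too conserved for distances.

## What it computes

Distances use the Kimura two-parameter (K2P) correction with pairwise
deletion. For transition proportion *P* and transversion proportion *Q*
over the sites comparable in a pair,

    d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]

Saturated pairs (non-positive log argument) are masked and counted, never
silently dropped or returned as NaN.

On a full specimen matrix the package derives:

* **Rank summaries** — every specimen pair is assigned to exactly one
  comparison class (conspecific, congeneric, confamilial, same order,
  same class) and each class gets mean / min / max / SE of its distances,
  plus the count of contributing taxa (singleton species contribute no
  conspecific pairs and are excluded from that row).
* **Band table** — congeneric interspecific distances counted per family
  in half-open bands [0, 5), [5, 10), [10, ∞) percent.
* **Threshold fractions and fold ratio** — e.g. the fraction of
  conspecific distances below the 1% filter, and congeneric mean /
  conspecific mean.
* **Nearest-neighbour distances (NND)** — per species, the minimum
  distance to any heterospecific specimen; species with deep
  intraspecific splits (max intra > 1%) or low NND (< 1%) are flagged.
* **NJ tree and cluster report** — an unrooted neighbour-joining tree
  (exact on additive matrices; deterministic lexicographic tie-break) and
  a per-species test of whether some edge separates exactly that species'
  specimens.
* **Numt screen** — protein-coding sequences translated under the
  vertebrate mitochondrial code (AGA/AGG/TAA/TAG are stops); in-frame
  stops, internal gaps or frameshifted lengths mark a record
  `suspect_numt`.
* **Diagnostic sites** — for conserved markers (18S), alignment columns
  whose states in one species are disjoint from all others ("pure simple"
  characters), plus a query classifier over that library.

A rank-structured sequence simulator (`simulate_dataset()`) generates
datasets with realistic divergence structure — intraspecific ≈ 0.2%,
congeneric ≈ 13.5%, confamilial ≈ 19.7% — under a transition-biased
two-parameter substitution process, with optional planted numts and deep
intraspecific splits, so the whole pipeline is testable without any
sequence downloads.

## Worked example

```r
library(barcodegap)

cfg <- simulation_config(seed = 42)      # 4 families x 2 genera x 3 species x 3 specimens
syn <- simulate_dataset(cfg)
res <- barcode_gap_analysis(syn)         # warns: no within_class pairs (one class simulated)
res
```

```
Barcode-gap analysis (k2p distances)
barcode_dataset: 72 specimens, 24 species, 8 genera, 4 families; marker COI
  aligned, 652 bp
numt screen: 72 pass, 0 suspect

Divergence by comparison class (%):
          class n_taxa n_comparisons  mean minimum maximum   se
 within_species     24            72  0.18    0.00    0.77 0.02
   within_genus      8           216 13.41   11.24   19.62 0.11
  within_family      4           324 19.55   14.33   23.58 0.12
   within_order      1          1944 23.67   18.40   28.57 0.04

congeneric / conspecific fold ratio: 74.7
conspecific distances below 1%: 72 / 72 (100.00%)
nearest-neighbour distances below 1%: 0 / 24 (0.00%)
species forming NJ clusters: 24 / 24
```

Reading: conspecific divergence averages 0.18% while congeneric averages
13.41% — a ~75-fold jump, the barcode gap. All 24 species form exclusive
clusters on the NJ tree and none trips the 1% filter, so every simulated
species would be identifiable by distance alone. With real data, start
from files instead:

```r
res <- run_barcode_pipeline("coi.fasta", "taxonomy.tsv", marker = "COI",
                            outdir = "reports")
```

which writes the QC report, PHYLIP distance matrix, rank-summary / band /
NND / flag tables (TSV, percentages to 2 decimals), the newick tree,
cluster report, diagnostic-site library and a run log.

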