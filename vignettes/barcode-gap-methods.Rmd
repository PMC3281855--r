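---
title: "Methods: distance- and character-based barcode identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance- and character-based barcode identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The model

DNA-barcode identification rests on one empirical regularity: at a short
standardized marker, divergence between conspecific individuals is
usually an order of magnitude smaller than divergence between species.
`barcodegap` measures that regularity on a reference library and reports
where it breaks.

Distances are Kimura two-parameter (K2P). For a pair of aligned
sequences, let *P* and *Q* be the proportions of compared sites showing a
transition (A↔G, C↔T) and a transversion. Then

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big].$$

K2P assumes equal base frequencies and a single transition and
transversion rate; it is the community convention for barcode studies,
which is the reason to prefer it here over richer corrections (those are
deliberately out of scope). The estimator diverges when
$1 - 2P - Q \le 0$ or $1 - 2Q \le 0$ ("saturation"); such pairs raise an
error pairwise, and in a full matrix are masked (`NA`), flagged in a
Boolean mask and counted, so downstream consumers must deal with them
explicitly.

**Sites compared.** Gaps and every IUPAC ambiguity code are treated as
missing at that site and excluded *per pair* (pairwise deletion), never
counted as match or mismatch. Pairwise deletion rather than complete
deletion was chosen because it matches the per-pair semantics of a
distance and copes with ragged rRNA alignments; complete deletion would
discard columns globally for the worst single specimen. A pair with no
comparable sites is an error, not a zero.

## Comparison classes and summary statistics

Each unordered specimen pair is assigned to exactly one class by its most
specific shared rank: `within_species`, `within_genus` (different
species), `within_family` (different genera), `within_order` (different
families), `within_class` (different orders). The classes partition all
pairs sharing the top rank; a cumulative convention (each class also
containing the more specific ones) is available via
`rank_summaries(..., cumulative = TRUE)` because published per-rank
comparison counts are not always disjoint and the reader may need either
convention.

Per class we report the number of contributing taxa at the class's own
rank (a species sampled once contributes no conspecific pair and is
excluded from that row's taxon count), the comparison count, and
mean/min/max/SE in percent. The SE is the sample standard deviation of
the class's distances over √n. Pairwise distances sharing a specimen are
not independent, so this SE understates uncertainty; it is reported as a
descriptive scale, not for inference.

Percentages are computed as proportions internally and rendered ×100 with
two decimals (round-half-even, applied only at reporting).

Band edges for the congeneric band table are half-open: a distance of
exactly 5.00% falls in the 5–10 band. The convention is arbitrary but
fixed and configurable; ties at a band edge are rare in continuous data
but must be deterministic.

The nearest-neighbour distance (NND) is computed per species — including
singletons — as the minimum distance to any heterospecific specimen. The
1% filter flags species on either side of the gap: maximum intraspecific
distance above the threshold (possible cryptic structure or
misidentification) or NND below it (possible synonymy, introgression or
recent divergence). 1% is the conventional screening value for fish COI
surveys and is a parameter, not a constant.

Boxplot statistics follow the Tukey convention: quartiles by linear
interpolation (type-7), whiskers at the most extreme observations within
1.5×IQR of the quartiles, mild outliers between 1.5 and 3×IQR beyond a
quartile, extreme outliers past 3×IQR.

## Neighbour joining and the cluster test

The NJ implementation is the standard Saitou–Nei agglomeration on the
Q-criterion. Numerical choices that the textbook description leaves open:

* **Tie-break.** When several pairs minimize Q (exactly degenerate
  matrices, e.g. all-equal distances), the pair whose subtrees carry the
  lexicographically smallest leaf labels is joined. This makes the output
  a deterministic function of the labelled matrix.
* **Negative branch estimates.** The three-point equations can yield
  negative lengths on non-additive input. They are clamped to zero and
  the total clamped deficit is recorded in the tree's `"clamped"`
  attribute rather than discarded, so an audit can see how non-additive
  the matrix was.
* NJ requires a complete matrix; saturated cells are a hard error with
  instructions to exclude or impute upstream, because silently imputing
  would move leaves with no data support.

On additive matrices NJ is exact, which the tests exploit: random 5–8
leaf trees are converted to their path-length matrices and must be
recovered to topology and branch length.

A species "clusters" when some edge of the unrooted tree bipartitions the
leaves into exactly that species versus everything else. This is the
monophyly notion appropriate to an unrooted tree and is evaluated from
the tree's bipartition set; singletons cluster trivially.

## Numt screening

Nuclear copies of mitochondrial genes (numts) co-amplify with the target
and, being pseudogenes, accumulate frameshifts and premature stops.
Screening translates each protein-coding record under the vertebrate
mitochondrial code (table 2: AGA, AGG, TAA, TAG are stops; ATA is Met,
TGA is Trp) and flags in-frame stops, internal gap characters, and
ungapped lengths not congruent mod 3 with the dataset's modal length. The
reading frame is detected once per dataset — the frame translating the
most records without stops — then held fixed, so a frameshifted copy
cannot rescue itself by shifting frame. A numt of intact length with no
in-frame stop is undetectable by this screen; that is a recognized limit
of translation-based screening, not of the implementation.

## Diagnostic characters

For markers too conserved for distance identification (18S), the
character-based route reports "pure simple" diagnostics: alignment
columns where the target species' unambiguous states are disjoint from
every other specimen's. Specimens with a gap/ambiguity at a column are
excluded from that column's state sets, and a column is reported only if
at least 80% (configurable) of target specimens are informative there —
without that floor, a single sequenced specimen could make a
missing-data column look diagnostic. Compound (combination) characters
are intentionally out of scope. Queries are scored by the fraction of a
species' diagnostic columns matched, ranked by fraction, then library
size, then name.

## The simulator: what it does and does not emulate

`simulate_dataset()` exists so every stage is testable without
downloading sequences. It generates a balanced taxonomy (default 4
families × 2 genera × 3 species × 3 specimens, one order, one class) and
evolves a 652-bp sequence down the matching ultrametric tree under the
two-parameter (Kimura) substitution process with transition/transversion
ratio κ = 2, sampling each site from the exact K80 transition
probabilities per branch. Node heights are half the target expected
pairwise divergence per class, so conspecific pairs are separated by
0.002 expected substitutions/site, congeneric by 0.135, confamilial by
0.197 and ordinal by 0.24 — the divergence scale a large marine-fish COI
survey exhibits (intraspecific means near 0.2%, congeneric near 13.5%).
Because the generating process is exactly the process the K2P estimator
assumes, parameter-recovery tests are clean: the mean estimate over
replicate pairs must sit within 3 standard errors of the true divergence.

For coding markers the open reading frame is kept stop-free: the root is
drawn codon-wise avoiding stop codons, and any codon that evolves into a
stop is re-drawn conditional on not being a stop. This mimics purifying
selection while preserving the expected divergence of surviving draws.

What the simulator does **not** emulate, and hence what passing tests do
not establish about real data: unbalanced sampling and singleton-heavy
surveys, rate variation across sites and lineages, base-composition bias,
indel evolution (gaps arise only via planted numts), introgression and
incomplete lineage sorting, misidentified vouchers, and sequencing error.
Realized class means also scatter around their targets by a couple of
percentage points, because a survey-sized simulation draws only a handful
of deep ancestral branches and all pairwise distances reuse them; tests
therefore assert rank ordering and scale brackets, not point equality.

Planted corruptions are deterministic functions of `(name, seed)`:
`inject_numt()` writes an in-frame TAA or a single-base internal gap at a
seeded position (idempotent), and `plant_deep_split()` evolves the later
half of a species' specimens by an extra divergence, which is what the
1% filter should catch.

## Problem sizes and runtimes

The default test suite simulates surveys of 8–72 specimens at 90–652 bp,
runs 1,000 K2P oracle comparisons, 100 NJ recoveries on 5–8 leaf trees,
600 estimator-recovery pairs, 50 numt-screen simulations and 100 random
diagnostic alignments; the whole suite completes in well under a minute
on one core. These sizes were chosen to keep the full matrix stages
(O(n²) distances, O(n³) NJ) comfortably interactive while still
exercising every comparison class with dozens to hundreds of pairs per
class.

## Known limitations

* K2P only; no Jukes–Cantor, TN93 or likelihood distances by design.
* The per-class SE ignores pair non-independence (see above).
* The cluster test is topological; it does not measure branch support
  (no bootstrap, matching the descriptive use of NJ here).
* Distance and character routes are reported side by side but not fused
  into a single classifier; combining them is the user's call.
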