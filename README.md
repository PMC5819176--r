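# NLRIDscan

Discovery and enrichment analysis of plant NLR immune receptors with
integrated domains, in R.

## The problem

Plant NLR (nucleotide-binding, leucine-rich-repeat) immune receptors are
defined by the NB-ARC domain (Pfam PF00931). Some NLRs carry an
*integrated domain* (ID) — an exogenous domain such as WRKY, AP2, a
kinase or Exo70 fused into the receptor, thought to act as a bait for
pathogen effectors. These NLR-IDs cluster in particular phylogenetic
clades and are frequently arranged head-to-head with a partner NLR
(upstream gene on the reverse strand, downstream on the forward strand,
≤ 15 kbp apart, no gene between) — the sensor/helper configuration of
RRS1/RPS4 and RGA5/RGA4.

`NLRIDscan` is for comparative genomicists who already have the standard
upstream outputs — GFF3 gene models, Pfam-style domain-hit tables, a
Newick NB-ARC phylogeny with bootstrap supports, optionally motif hits
and TE coordinates in BED — and want the downstream analysis as tested,
reproducible code:

* **NLR / NLR-ID classification** — longest-isoform selection, NB-ARC
  presence, the structural exclusion set {NB-ARC, LRR*, AAA*, TIR, RPW8},
  dual e-value tiers (strict < 0.001 ⊆ relaxed < 0.05), the 70%
  NB-ARC-alignment coverage filter, per-species/per-clade census.
* **Clade partitioning** — midpoint rooting; a clade is founded at a
  node with bootstrap support ≥ 80 whose subtree's mean root-to-tip
  depth exceeds 1.4 substitutions/site; manual overrides are
  first-class.
* **Tandem pairs and enrichment** — linear-scan head-to-head detector
  (verified against a brute-force oracle), gene-level 2×2 contingency
  tables, two-sided Fisher exact test by hypergeometric summation:

  p = Σ { P(T) : P(T) ≤ P(T_obs) }, T ranging over tables with the
  observed margins, P hypergeometric — plus the clade-pairing matrix
  and TE-overlap summaries.
* **Architecture profiling** — unannotated-region extraction (≥ 20 aa)
  for motif discovery, normalised midpoint profiles, and the
  "CID immediately upstream of the integration site" classification.
* **Synthetic data with ground truth** — `simulateDataset()` plants
  NLRs, IDs at clade-specific rates, head-to-head pairs, near-miss
  negatives, decoy e-values straddling both cutoffs, clade-structured
  trees and motifs, so every stage is testable without downloads.

## A worked example

```r
library(NLRIDscan)

sim   <- simulateDataset(SimulationConfig(seed = 11, tandemRate = 0.1))
files <- writeSimulatedDataset(sim, "sim")
res   <- runPipeline(list(annotation = files[["annotation"]],
                          domains    = files[["domains"]],
                          tree       = files[["tree"]],
                          motifs     = files[["motifs"]],
                          outDir     = "results"))
res$contingency
#>   grouping a  b  c  d odds_ratio   p_value
#> 1   has_id 0 10 10 80          0 0.5920047
```

In this planted 1,000-gene genome 10 of the 100 NLRs carry a strict ID
and 10 are tandem members, but none of the ID bearers happens to be
paired — at miniature scale the exact test rightly finds nothing
(p = 0.59). Recomputing the published pooled tables instead:

```r
tab <- reproduceEnrichmentTables()
subset(tab, species == "All",
       c(panel, a, b, c, d, computed_p, pct_tandem_group, pct_tandem_other))
#>    panel  a   b   c    d   computed_p pct_tandem_group pct_tandem_other
#> 10    id 50 365 268 5511 1.015305e-08            12.04             4.63
#> 20  mic1 52 310 266 5566 4.119310e-12            14.36             4.56
```

12.04% of NLR-IDs sit in head-to-head tandems versus 4.63% of NLRs
without an ID (p ≈ 1.02e-08), and membership of the major integration
clade shows the same enrichment (p ≈ 4.12e-12).

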