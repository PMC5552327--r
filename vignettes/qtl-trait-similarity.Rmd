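---
title: "Linking heterogeneous traits through QTL regions and gene-function semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking heterogeneous traits through QTL regions and gene-function semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlgosem)
```

## The problem

Quantitative trait loci (QTL) tie a trait — a macroscopic phenotype, a
metabolite level, or a transcript abundance — to genomic intervals, not to
mechanisms. Different trait types are mapped in different populations with
different technologies, so their QTL cannot be compared coordinate by
coordinate. `qtlgosem` compares them at the level of *gene function*: each
trait is reduced to the set of Gene Ontology (GO) terms overrepresented among
the genes of its QTL regions, and traits are then related by the semantic
similarity of those term sets. The result is a trait–trait similarity matrix
per GO namespace (biological process, BP; molecular function, MF), a network
of significant maximum-similarity links, and a complete-linkage dendrogram.

## The pipeline and its assumptions

1. **Regions to genes.** Genes overlap a region under an any-overlap rule
   (≥ 1 bp); coordinates are held 0-based half-open internally. Regions with
   more than `region_gene_cap` genes (default 450) are discarded as
   uninformative, then traits with fewer than `min_regions` regions
   (default 2 for macroscopic and metabolite traits, 3 for expression
   traits) are dropped. Overlapping regions of one trait are kept distinct:
   occurrence counting (below) uses regions as given, and overlaps are
   visible in the exclusion log.

2. **Genes to terms.** Direct annotations are closed upward over `is_a` and
   (by default) `part_of` edges — the true-path rule — before any counting.
   A term is linked to a trait when three independent gates all pass:
   * a one-sided Fisher exact test (hypergeometric upper tail) against the
     annotated-genome background, Benjamini–Hochberg corrected at
     `enrichment_fdr` (default 0.1);
   * the term occurs (via propagated annotations) in at least
     `occurrence_fraction` of the trait's regions (default 0.5, i.e. 3 of 5
     regions), which suppresses single-region flukes;
   * the term annotates at most `generality_max_fraction` of all genes
     (default 1%, strict above), which removes uninformative high-level
     terms.
   BH is applied within each trait's candidate set by default; the
   `global_correction` flag pools all trait×term tests instead. The two
   differ in what they control: per-trait correction bounds each trait's
   false-discovery rate, while only the global mode bounds the FDR of the
   pooled link table. Both modes are exercised by the test suite.

3. **Term sets to trait similarity.** Term–term similarity is Lin's
   measure, `2·IC(MICA) / (IC(t1) + IC(t2))`, with information content
   `IC(t) = −ln(annotated fraction)` in natural log (Lin is scale-invariant,
   so the base is a documentation choice only). "Ancestors" include the term
   itself, so the most informative common ancestor handles identical and
   nested pairs uniformly. Set-level similarity is the best-match average
   (BMA); we use the *symmetrized* form — the mean of the two directional
   best-match means — because a symmetric matrix is required downstream for
   the distance transform and clustering; the one-directional variant is
   available behind a flag. Two traits with identical term sets score
   exactly 1; because two distinct terms can also reach Lin similarity 1,
   the matrix additionally records a set-identity indicator so the two
   notions stay distinguishable. An alternative term-similarity (for
   example an interaction-adjusted measure) can be plugged in via
   `termsim_fun`; plain Lin is the default and the only measure this
   package claims to implement.

4. **Significance.** Two permutation schemes, both reproducible from one
   master seed through named substreams, and both using
   `p = (1 + #{null ≥ observed}) / (n_reps + 1)` — never exactly zero, and
   within one count of the plain `#/n` convention at the default 1,000
   replicates.
   * *Random regions*: each trait's regions are replaced by random genome
     placements of identical number and length (uniform over all valid
     chromosome/start positions; overlaps among sampled regions are
     allowed), and the **entire** pipeline — enrichment with identical
     filters, then similarity — is rerun through the same entry point as
     the observed analysis. The statistic is the count of trait pairs at or
     above a similarity threshold (defaults 1, 0.95, 0.9), per namespace
     and pooled.
   * *Shuffled links*: trait–term links are re-dealt keeping the number of
     traits, the global term multiset and each trait's link count fixed;
     duplicates within a trait are repaired by swaps (a link is a set
     membership). This null gives per-trait expected maxima of
     category-wise maximum similarity; BH at `linkage_fdr` (default 0.05)
     across links selects the significant trait–trait network.

5. **Reporting.** Similarities become distances by the linear transform
   `d = sim_max − sim` (with `sim_max` the largest off-diagonal similarity,
   so the closest observed pair sits at distance 0); complete-linkage
   clustering with deterministic lexicographic tie-breaking produces a
   dendrogram whose merge heights are the linkage distances themselves (no
   cophenetic rescaling); exports are Newick (branch length = parent height
   minus child height), SIF plus node/edge attribute tables, and long-form
   TSVs.

## The synthetic world

The package ships a generator instead of external data. It emulates the
shape of the published rice analysis at desk scale and makes the truth
known:

* ontology: one rooted DAG per namespace (default 200 terms, depth ≤ 5,
  ~10% of terms get a second parent to create diamonds);
* genome: 500 genes tiled over 5 chromosomes (3 kb genes, 2 kb gaps);
* annotations: Poisson(3) direct terms per gene per namespace, term usage
  following power-law weights (exponent 1.2), independent across genes (no
  linkage-disequilibrium structure — the pipeline never uses marker
  correlation);
* traits: 30 traits (10 per type); unplanted traits draw 3–6 random
  regions; planted traits get 4 regions each;
* planted signal: 5 groups of 2 traits share 4 leaf signal terms per
  namespace, carried by 5 dedicated genes (exactly 1% of the genome, so the
  signal sits on the keep side of the generality gate); each planted region
  is centered on a carrier with probability `planting_prob` (1 by default,
  0 for a pure null).

Three generator choices matter and were fixed from the published dataset's
proportions, not tuned to test outcomes:

* **Region size.** Published regions average ≈ 0.4% of the genome's genes;
  at 500 genes that is 2–4 genes per region (10–20 kb here). Early drafts
  used proportionally larger regions and showed a biologically real
  artifact: rare background terms on neighbors of carrier genes recur
  across regions and masquerade as signal.
* **Carrier separation.** Carrier genes are kept at least one maximal
  region length apart, so one region can never cover two causal loci.
* **Signal multiplicity.** Planted traits carry 4 signal terms per
  namespace, echoing the published scale of tens of links per trait rather
  than a single-term caricature; with a 1-link-per-trait world the realized
  false-link fraction of the emitted table hovers exactly at the nominal
  FDR, which is a knife edge rather than a test.

What a green planted-recovery test establishes: the gates jointly recover
recurring, specific, region-spanning signal and suppress background at
roughly the nominal FDR *in this idealized world*. What it does not
establish: behavior under linkage disequilibrium, annotation bias, or
correlated traits — none of which the generator models.

## Numerical and degenerate-case conventions

* Lin similarity of two effectively-root terms (IC sum 0) is defined as 0,
  keeping BMA finite; terms with zero annotated genes are excluded from
  similarity (their IC is undefined; enrichment can never emit them).
* The occurrence threshold is `ceiling(fraction · n_regions)` — 0.5 with 4
  regions means 2, with 5 regions means 3.
* The generality rule is strict: a term on exactly 1% of genes is kept.
* Fisher p-values with `k = 0` are exactly 1; bound violations are errors,
  not clamped.
* Linkage ties are broken toward the pair whose smallest member label sorts
  first; Newick children are ordered by smallest contained leaf, making
  exports byte-stable.
* Permutation p-values use the `+1` correction (see above), so a "perfectly
  significant" result at 1,000 replicates reports ≈ 0.001, matching the
  floor of the count-based convention.

## Known limitations

* The region-permutation p-value is *valid but conservative* when the pair
  count statistic is small and discrete. In a pure-null world the observed
  count at high thresholds is almost always 0, every permutation count ties
  it, and the p-value mass collects at 1 rather than spreading uniformly;
  the test suite documents this (the uniformity acceptance check is
  expected to fail for exactly this reason) and separately verifies the
  property that actually matters, `P(p ≤ α) ≤ α`.
* Per-trait BH (the default) does not bound the false-link rate of the
  pooled output table; use `global_correction = TRUE` when that table is
  the object of inference.
* Cross-namespace similarity is undefined by construction; BP and MF run
  as separate corpora end to end.
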