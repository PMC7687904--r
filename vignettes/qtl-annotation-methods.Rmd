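---
title: "Methods: LD-aware QTL annotation, TAD-based cis/trans labels, and cross-tissue sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD-aware QTL annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlannot)
library(data.table)
```

## The annotation model

The unit of annotation is the **QTL object**: the quadruple of variant,
gene, tissue and source study. Two summary-statistics rows that agree on
the quadruple describe the same putative QTL, whatever their reported
statistics; the package keys every store on this identity and treats a
**tissue-specific study** — one (source, tissue) pair — as the unit over
which "best" signals and sharing counts are defined. This matters because
public QTL corpora are heterogeneous: the same tissue is assayed by
several sources, sources disagree on tissue spelling, and some ship only
their own notion of significant associations. Ingestion therefore (i)
normalizes tissue names through an explicit, user-editable map that must
cover every raw spelling or fail loudly, (ii) records per dataset whether
significance is taken from the source or derived, and (iii) collapses
duplicate quadruples within a dataset to the smallest P, logging the
collision. The package deliberately performs **no statistical
meta-analysis** across studies; heterogeneous designs, genotyping
platforms and selection rules make naive pooling misleading, so the
output is an annotated catalogue, not a combined estimate.

### Significance

Datasets that do not declare their own rule get a family-wise error rate
(Bonferroni) threshold over all variant–gene tests,

$$ t = \frac{\alpha}{n_{\text{variants}} \times n_{\text{genes}}}, $$

with defaults $\alpha = 0.05$, $10^6$ variants and $5 \times 10^4$ genes
(roughly the protein-coding-plus-noncoding gene set without pseudogenes),
giving the study-wide level $t = 10^{-12}$. The boundary is inclusive
(`p <= t`): "passing a threshold" is read as reaching it, and an
exclusive rule would silently drop records whose P is reported exactly at
the level.

### Best signals and LD groups

Within each tissue-specific study the record(s) with minimal P are
flagged `is_best`. Exact P ties are **all** flagged: inventing a
tie-break (say, by rsID) would fabricate a distinction the data does not
support. `is_best_in_ld_group` asks the sharper question of whether a
record's variant beats every variant correlated with it: the **LD group**
of a variant is the variant plus all variants with pairwise
$r^2 > 0.2$ against it — pairwise to the seed, never a transitive
closure — and the record is flagged when its P is minimal among records
of group members in the same study. By default the comparison is
restricted to records of the *same gene*, since a QTL is a variant–gene
claim and comparing against a different gene's association answers a
different question; `per_gene = FALSE` switches to the gene-agnostic
reading. Variants absent from the LD reference form singleton groups and
are conservatively flagged (there is no evidence against them), with the
`no_ld_data` provenance available from the LD store.

Note the deliberate asymmetry between the two LD thresholds: LD-*group*
membership is strict (`r2 > 0.2`, a definition), while proxy search uses
an inclusive bound (`metric >= t`, a user-set cutoff where the natural
reading of "set a threshold of 0.8" includes 0.8 itself).

### LD computation

$r^2$ and $D'$ are computed from phased haplotypes by direct counting:
with allele-1 frequencies $p_A$, $p_B$ and joint frequency $p_{AB}$,

$$ D = p_{AB} - p_A p_B, \quad
   r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \quad
   D' = \frac{|D|}{D_{\max}}, $$

where $D_{\max} = \min(p_A(1-p_B),\,(1-p_A)p_B)$ for $D \ge 0$ and
$\min(p_A p_B,\,(1-p_A)(1-p_B))$ otherwise. Only phased input is
supported (no EM phasing); monomorphic variants have undefined LD and
raise an error the caller may turn into a skip. Pair computation is
restricted to a window (default 1 Mb) to bound the quadratic cost;
precomputed LD tables are accepted wherever a panel would be.

### Cis/trans and distances

Instead of a fixed distance cutoff, a record is **cis** when at least one
TAD interval contains both the variant position and the gene's anchor
point, and **trans** otherwise — including different chromosomes,
positions in TAD-free regions, and the empty-TAD limit in which
everything is trans. The anchor is the gene start; a strand-aware TSS
anchor is available (`strand_aware = TRUE`) but off by default so the
default behaviour has no hidden strand dependence. Overlapping TADs are
allowed; containment by *any* single TAD suffices. The per-record
distance column is 0 when the variant lies within the gene boundaries
and otherwise the signed kb offset from the nearest gene boundary
(positive downstream of the gene end, negative upstream of the start).
The distance *analysis* (below) instead measures from the gene start,
the anchor the sharing of regulatory signals is usually referenced to;
the two quantities are intentionally distinct columns.

Internally all coordinates are 1-based inclusive — the convention of the
IRanges/GenomicRanges containers the package stores intervals in — and
conversions happen only at the boundary (BED's 0-based half-open starts
gain 1 on read; GTF, VCF and summary TSVs pass through).

## Query workflow

Query text needs no fixed format: tokens split on any mix of commas,
semicolons and whitespace and are classified by regular expressions —
rsIDs (`rs` + digits), chromosomal positions (`chr` prefix optional,
build tag `:hg19`/`:hg38` optional, hg19 assumed otherwise), then gene
identifiers and symbols. Gene resolution prefers a stable id over a
primary symbol over a synonym; a synonym shared by several genes
resolves to the lexicographically smallest gene id with the alternatives
reported, a deterministic stand-in for a full term-to-gene
prioritization engine. Unresolvable tokens are reported, not fatal.

Variant queries optionally expand to **proxy variants** at an $r^2$ or
$D'$ threshold; each proxy row carries its index variant and LD metrics,
and a record reachable both directly and through a proxy is reported
once via its highest-$r^2$ route. Aggregation collapses rows onto
(index variant, gene), unioning tissues and keeping the best P — a
haplotype-block-centric view in which $\sum$ `n_merged` always equals
the number of input rows. Defaults of 50 query terms and 10,000 result
rows mirror common interactive limits and are plain arguments here.

## Explorative analyses

**Distances.** Per gene and tissue-specific study, the best (minimal P)
study-wide significant eQTL is selected and its signed base-pair offset
from the gene start recorded. Summaries report mean and median of
|distance| in kb — magnitudes, because the distribution is summarized on
a log scale where sign is a separate (retained) attribute — overall and
stratified by cis/trans. Records whose variant sits on another
chromosome carry no distance; they are counted in their stratum but
excluded from the moments.

**Sharing.** For each gene the best study-wide significant eQTLs of all
tissue-specific studies are pooled and partitioned into **eQTL LD
blocks** by single-linkage clustering over the pairwise graph with an
edge where $r^2$ exceeds the threshold. Single linkage is the standard
"block" notion and is directly testable against hand-computed
partitions; a pairwise-to-representative alternative would depend on an
arbitrary representative choice. The threshold ladder is
$r^2 > 0.6, 0.8, 0.9, 0.95$, $r^2 = 1$ (perfect proxies, within
$10^{-9}$), and "none" (every variant its own block — the strictest
partition). Each block is scored by the number of distinct
tissue-specific studies it represents and the gene is assigned the
maximum; the count is non-increasing as the ladder tightens. Variant
pairs with no LD data count as unlinked.

**Enrichment.** For each threshold, the top $k$ genes (default 100) by
maximum block count — ties at the $k$-th count resolved
deterministically by gene id — are tested for overlap with each
reference set (housekeeping genes; top-decile expressed genes, which
`top_expressed_genes()` derives from any expression matrix) by the
one-sided upper-tail hypergeometric test over the universe of genes with
at least one best study-wide significant eQTL. Benjamini–Hochberg
adjustment runs across the whole family of threshold × set tests (6 × 2
= 12 under the defaults), the widest defensible family for the reported
table.

## The synthetic test-bed

`fixture_spec()` / `synth_bundle()` generate every input dialect the
readers consume — per-source QTL TSVs with deliberately inconsistent
tissue spellings, a phased VCF, a TAD BED, gene and GWAS Catalog tables,
gene-set lists — plus a ground-truth sidecar. A single seeded stream
drives all randomness; equal seeds give byte-identical bundles.

What the generator emulates, and how the defaults were chosen once:

* **Study grid**: 4 sources × 5 tissues = 20 tissue-specific studies,
  30 genes with 4 local variants each — a desk-scale sketch of a
  multi-source corpus that keeps every end-to-end run in seconds.
* **Lead-eQTL distances**: log-normal with `meanlog = log(28000)`,
  `sdlog = 1.6`, i.e. median 28 kb and mean ≈ 101 kb — the scale real
  eQTL corpora show for best-signal-to-gene-start distances.
* **Significance**: planted significant records draw P log-uniformly in
  $[10^{-20}, t)$ and the rest in $(t, 1]$, so the sidecar's
  significance truth is exact by construction.
* **Sharing**: designated genes have their best eQTL recur in $m$
  studies (default 8/10/12) inside one planted LD block. Blocks are
  built deterministically — each member is the block seed with one
  distinct flipped haplotype, seed frequency drawn in 0.4–0.6 over 400
  haplotypes — giving member–seed $r^2 \approx 0.98$ and a member–member
  floor above 0.95, so single-linkage recovery of $m$ holds at every
  sub-unit threshold no matter which members surface as best, while
  $r^2 = 1$ grouping correctly splits them.
* **Enrichment**: the housekeeping reference list *is* the planted
  sharing set, so detection at BH FDR < 0.05 is the planted positive;
  type-I behaviour is assessed by drawing reference sets unrelated to
  the ranking, the exact null of the hypergeometric test.

What it does **not** emulate: coalescent population structure (haplotypes
are structured noise sufficient to hit $r^2$ targets), allele-frequency
spectra, overlapping genes, strand-specific annotation quirks, genuinely
confounded significance (e.g. winner's curse), or corpus scale. Green
tests therefore demonstrate the *mechanics* — flags, partitions, counts
and tests computed correctly under known truth — not that real-corpus
effect sizes or P values would be reproduced.

## Numerical and scale choices

* P-value comparisons are exact floating-point comparisons; ties are
  preserved, not broken.
* $r^2 = 1$ grouping uses a $10^{-9}$ tolerance against representation
  noise in LD tables.
* Property-style tests run at sizes where brute-force oracles stay
  exact and fast: LD against 2×2 counting oracles on 1,000 panels of
  8–64 haplotypes; flags and counts against loop-based recomputation on
  50 random stores of ≤ 140 records; hypergeometric P against
  binomial-coefficient enumeration on universes ≤ 20; sharing recovery
  on two full-scale bundles. The end-to-end pipeline at default fixture
  scale completes in well under a minute on one CPU.
* Degenerate inputs are defined, not special-cased: empty TAD sets label
  everything trans, empty stores give empty summaries, reference sets
  disjoint from the universe give overlap 0 and P = 1, and monomorphic
  variants raise rather than return NaN.

## Known limitations

* Only phased genotype input; no EM-based LD from unphased data.
* One genome build per store; no liftover (mixing builds is an error).
* The gene resolver is a deterministic exact-match cascade, not a
  full-text prioritization engine.
* Colocalization testing (e.g. posterior-probability methods) is out of
  scope; the TAD label is a structural proxy, and TAD boundaries are
  treated as cell-type invariant, which recent work suggests is only
  approximately true.
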