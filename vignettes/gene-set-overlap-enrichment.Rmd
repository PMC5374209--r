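---
title: "Gene-set overlap enrichment and literature co-citation with setlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set overlap enrichment and literature co-citation with setlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setlink)
```

## The analysis problem

Curated gene sets are the workhorse of database-enabled systems biology:
a disease perturbation database, a protein interactome, an organelle
proteome, a mechanism-specific protein network each reduce to a named set
of human Entrez gene identifiers, and the scientific question "are these
two bodies of evidence about the same biology?" reduces to asking whether
the two sets share more members than chance would allow. `setlink`
implements that workflow end to end: identifier normalization with
ortholog handling, first-neighbor expansion over protein-protein
interaction (PPI) networks, an exact overlap-enrichment engine with
per-query false-discovery-rate ranking, a gene-article-MeSH co-citation
index for literature surveys, and a planted-structure synthetic data
generator that makes every stage testable offline.

## The statistical model

Overlap significance is the one-sided Fisher exact test. For a universe
of $N$ genes, a query set of size $n_q$, a reference set of size $n_r$
and an observed overlap $k$, the p-value is the right tail of the
hypergeometric distribution,

$$ p = P(X \ge k) = \sum_{i=k}^{\min(n_q, n_r)}
   \frac{\binom{n_r}{i}\binom{N-n_r}{n_q-i}}{\binom{N}{n_q}}. $$

Only enrichment is tested; depletion is never of interest in this
workflow and the left tail is not offered.

One query is tested against an entire reference collection (hundreds to
thousands of sets), so p-values are adjusted by the Benjamini-Hochberg
step-up rule **within each query's test family** -- adjusting per query
rather than pooling across queries keeps each query's ranking
self-contained and matches how screening collections are used
iteratively. Results are reported as $-\log_{10}$ FDR and ranked by it;
ties break by descending overlap count, then reference name, so reports
are byte-reproducible. The conventional screening cutoff in this style
of analysis is $-\log_{10}\mathrm{FDR} \ge 10$; it is a reporting
threshold, not an inferential claim, because curated query and reference
sets are never independent -- the p-values are descriptive, and the
relative rank order and degree of overlap carry the interpretation.

### Numerical behaviour at extreme significance

Overlaps between large curated sets routinely produce p-values around
$10^{-100}$ to $10^{-300}$, past or near the double-precision underflow
threshold. `fisher_right_tail()` therefore works in log space: the first
tail term from `lchoose`, subsequent terms by multiplicative ratio
updates, the sum by log-sum-exp. The tail is always accumulated
directly, never as the complement of the left tail, because
$1 - (1 - 10^{-15})$ style cancellation would destroy exactly the values
this pipeline ranks by. BH adjustment has a log-space twin
(`bh_adjust_log()`), so `neg_log_fdr` is exact even where the reported
`fdr` double underflows to zero (documented behaviour below about
1e-308). Against brute-force enumeration the engine is accurate to
better than $10^{-12}$ relative error on an exhaustive small-universe
sweep, and against the independent `phyper(log.p = TRUE)` route to about
$10^{-12}$ absolute on the $-\log_{10}$ scale even at the $10^{-300}$
scale.

### The universe

The universe size $N$ is the one genuinely consequential free parameter:
inflating it inflates every significance. No single correct value exists
for mixed curated collections, so the package makes the choice explicit
rather than silent: the default is the union of all loaded sets, a fixed
integer (e.g. 20,000, roughly the human protein-coding complement) or an
explicit universe set can be supplied, and the resolved $N$ is recorded
in every report and run manifest. Printed FDR magnitudes from any
particular historical analysis depend on that analysis's private
reference collection and universe and are therefore treated as
non-reproducible reference values; the package's fixtures assert only
count and percentage arithmetic, which is exactly reproducible.

## Identifier normalization

Cross-species perturbation data are mapped to human Entrez IDs through a
user-supplied ortholog table. Three rules matter and are tested:

* a raw token with map entries contributes **all** of its mapped human
  orthologs (a fly gene with two closely related human paralogs yields
  both);
* unmapped tokens that already look like human identifiers are kept
  (integer IDs always; upper-cased symbols under the lenient policy);
* everything else is excluded and counted -- never silently dropped.

Normalization is idempotent, and miRNA identifiers live in a separate
namespace that is never intersected with protein-coding sets. The
`"<Name>_<size>"` naming convention is validated with a warning, not an
error, since restriction to a universe legitimately shrinks sets.

## Percentages and Venn regions

Printed overlap tables report integer "percent of set" columns.
`percent_of_set()` rounds to the nearest integer, half away from zero --
the rule consistent with every printed value we transcribe in the
packaged fixture (including the half-way cases 123/328 = 37.5% -> 38 and
119/400 = 29.75% -> 30). One fixture row (113/357 printed as 31 rather
than 32) is inconsistent with its own counts under any nearest-integer
rule; it is stored verbatim with a note flag and exempted from the
self-consistency sweep. Venn/Euler output is exact disjoint region
cardinalities (3 regions for two sets, 7 for three); rendering
area-proportional ellipses is out of scope, and a "neither" count is
defined only relative to an explicitly supplied frame set -- without a
frame it is `NA`, not zero.

## PPI neighborhoods

`expand_ppi()` builds first-neighbor sets around seed genes from a
HIPPIE-style edge list: undirected, canonicalized, deduplicated keeping
the maximum confidence score, self-loops dropped and counted. No score
threshold is applied by default -- mirroring curation practice of
imposing no selection criteria beyond the source databases -- and only
direct interactors are taken, never multi-hop expansion. Seeds are
included in their own neighborhood by default because published PPI set
sizes are not decomposable into seed-inclusive vs seed-exclusive
conventions; both behaviours are supported via `include_seeds`.
`merge_disease_set()` unions neighborhoods into disease-level sets with
per-gene provenance recording which seed contributed each member.

## Literature co-citation

The computable core of a literature survey is a join: articles citing
any member of a gene set (gene2pubmed-dialect links, taxon-filtered at
load) intersected with articles carrying a MeSH heading (a pre-extracted
two-column table; parsing PubMed XML is out of scope). Heading matching
is exact and case-insensitive after whitespace normalization, with no
MeSH-tree descendant expansion. `mesh_survey()` runs the join across a
heading list and ranks by article count -- the iterative,
human-in-the-loop term-selection step is deliberately left to the human;
the package only makes each round cheap.

## The synthetic-data generator

There is no public gold standard for this pipeline, so the generator
*defines* the conditions the tests certify:

* **Collections** -- a 20,000-gene universe; 100 reference sets of
  50-4,500 members sampled uniformly without replacement (the span from
  the smallest curated PPI sets to the largest protein databases;
  clamped for deliberately small test universes). Planted queries share
  exactly $\lceil \rho \, n_q n_r / N \rceil$ members with their target
  reference -- $\rho$ multiplies the null hypergeometric expectation,
  and exact-count construction keeps truth overlaps known exactly.
  Feasibility requires $\rho \cdot \max(n_q, n_r) \le N$, so the planted
  size defaults (queries 100-500, targets 200-1,500) sit in the feasible
  regime at $\rho = 10$; these are the scales of typical curated
  mechanism sets.
* **Corpora** -- per-gene citation propensities are Zipf-like
  (exponent 1.1), reproducing the heavy skew of real literature
  coverage; ~2,000 articles with Poisson(3) gene mentions and 1-3
  headings each. A boosted (set, heading) pair redirects gene draws of
  heading-carrying articles into the planted set with probability
  `min(0.9, boost * w0)` where `w0` is the set's baseline citation mass,
  so `boost = 0` is an exact independence null.
* **Graphs** -- random edges among non-hub nodes plus hubs wired to an
  exact configured degree, so neighborhood recovery is checkable member
  by member.

What the generator does **not** emulate: correlated set membership
(real curated sets share ascertainment bias), scale-free PPI topology,
and the gene-level dependence structure that makes real p-values
descriptive rather than inferential. Passing the recovery and
calibration suites therefore certifies the machinery, not the
inferential validity of any particular real-data application.

## Validation studies and problem sizes

The shipped suites run four simulation studies, sized to complete in a
few minutes on one core while keeping Monte-Carlo error small relative
to the margins tested:

* **Enumeration sweep** -- every valid contingency table with
  $N \le 30$ (about 50,000 tables) against direct
  binomial-coefficient enumeration, at $10^{-12}$ relative tolerance.
* **Null calibration** -- 500 uniform queries of size 100 against a
  100-set collection at $N = 20{,}000$: mean false-discovery proportion
  at FDR < 0.05 must stay within $0.05 + 3\,\mathrm{SE}$ (observed
  around 0.02).
* **Planted recovery** -- 100 seeds, one planted pair each at
  $\rho = 10$: recall@5 of the planted reference must be at least 0.95.
  A pilot at these sizes puts the planted overlap at roughly ten times
  its null expectation, which is far beyond the detection boundary, and
  observed recall is 1.
* **Co-citation recovery** -- 100 seeded corpora at boost 50: the
  planted (set, heading) pair must rank first in at least 95% of
  surveys; observed rate 1.

## Design choices worth knowing about

* `p_value` and `fdr` columns are plain doubles and underflow to 0
  below about 1e-308; `neg_log_p`/`neg_log_fdr` are the authoritative
  columns at extreme significance.
* The pipeline (`run_pipeline()`) is exposed as an R function driven by
  a plain list or YAML file, not a shell executable: its users script in
  R, and a function composes. Stage failures carry `[stage:...]` tags,
  partial outputs are removed, and the JSON manifest records input and
  output MD5s plus the resolved universe and reference family, so two
  runs with the same inputs and seed are byte-identical and every run's
  test family is explicit.
* Degenerate inputs fail loudly: empty normalization input, empty
  p-value vectors, impossible contingency tables, queries disjoint from
  the universe, universes smaller than a set. An absent MeSH heading, by
  contrast, is a valid empty survey outcome (flagged, warned, not an
  error).
* `summarize_overlaps()` and `relative_percent_table()` reproduce
  printed-table and bar-figure content as data; no graphics beyond a
  minimal `plot()` method on reports, since exact region counts and
  percent matrices are the analysis products.

## Known limitations

* BH across a curated collection controls FDR only under the usual
  positive-dependence conditions; with heavily overlapping reference
  sets the ranking remains sound but the nominal FDR is descriptive.
* Ortholog mapping quality is entirely inherited from the supplied map;
  no live identifier resolution is attempted.
* The co-citation join treats gene2pubmed links and MeSH indexing as
  co-equal evidence about an article; provenance differences between
  the two annotation pipelines are not modelled.
* Very large collections (tens of thousands of sets) would want an
  indexed membership matrix; the current implementation targets the
  hundreds-to-thousands scale of curated collections.
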