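---
title: "From CNV-region miRNAs to a disease gene network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CNV-region miRNAs to a disease gene network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgba)
```

`mirgba` chains five analyses: miRNA-density statistics for a genomic
region, integration of two target-prediction tools, gene-set enrichment
of the resulting target lists, construction of a guilt-by-association
disease network, and overlap tests between miRNA-mechanism target sets
and that network. This vignette records the statistical model behind
each stage, the parameters that matter, the numerical conventions, and
the design decisions that were genuinely open.

## Region miRNA density

The density statistic asks whether a query region (a recurrent deletion,
say) is unusually rich in miRNA genes. For every miRNA primary
transcript in the annotation we form a symmetric window around its
transcript start — `window_flank_bp` (default 1,300,000 bp, i.e. a
2.6 Mb window matching a typical deletion length) on either side,
clipped at position 1, never spanning chromosomes — and count the loci
fully contained in it. The reported percentile is the fraction of
windows with strictly fewer loci than the query region.

Three conventions needed fixing:

* **Containment.** A locus counts only when its whole interval lies in
  the window. A transcript-start-only mode (`start_only = TRUE`) is also
  provided, since at desk scale the two readings cannot be
  distinguished empirically; containment is the default because it is
  the natural reading of a transcript being "contained" in a window.
* **Self-comparison.** Windows centred on loci inside the query region
  are excluded from the percentile comparison by default
  (`exclude_region_loci`): the region should be compared against *other*
  loci, not its own cluster, whose windows are dense by construction.
* Every window contains at least its own centring locus, so window
  counts are always ≥ 1, and the percentile is monotone non-decreasing
  in the region count.

## Two-tool target integration

Prediction tools emit scores on incomparable scales and with opposite
polarities (for one tool smaller is stronger, for the other larger is
stronger). Scores are therefore mapped to percentiles *within each
tool's complete prediction table* — all putative targets of all miRNAs,
both mature arms pooled. The percentile of strength $s$ is

$$x' = \frac{\#\{\text{records with strength} \ge s\}}{\#\text{records}},$$

so smaller is stronger, values lie in $(0, 1]$, and a score exactly at
the top-10% boundary maps to exactly $0.10$. The max-tie convention
(ties share the largest applicable rank) is what makes that boundary
identity exact. Pooling both arms and all miRNAs in one percentile pool
is a deliberate reading of "all putative targets and all miRNAs"; a
per-arm pool would change values only marginally but would break the
boundary identity across arms.

Arm collapsing averages the −5p and −3p percentiles when a gene is
predicted for both mature forms of a locus; tool integration then keeps
only genes predicted by **both** tools (the conservative intersection —
a union would dilute the ranking with single-tool predictions whose
final score is not comparable) and averages the two tool percentiles
into the final score. Ranking is ascending in final score with ties
broken lexicographically by gene id, making every ranking deterministic
and permutation-invariant. Top-$k$ lists are prefix slices at
`topk_levels` (default 200, 400, 800); a miRNA with fewer targets than
$k$ contributes all of them, so its lists coincide.

## Functional enrichment and the consensus filter

Enrichment is tested against the background of *all* miRNAs' predicted
targets rather than the whole genome. This controls for functional bias
common to miRNA targets as a class (development, transcription), which
would otherwise dominate every test. For miRNA $i$ and gene-set $j$ the
2×2 table is:

|            | in $GS_j$ | in other sets only |
|------------|-----------|--------------------|
| targets of $i$ | a | b |
| other background | c | d |

Genes belonging to no gene-set contribute to no cell — the exclusion
happens inside the table rather than by pre-shrinking the background.
The p-value is the exact right tail $P(X \ge a)$ of the hypergeometric
distribution with all margins fixed (`stats::phyper` behind a single
shared routine, verified exhaustively against a `choose()`-based
enumeration oracle on all tables with margins ≤ 30).

Gene-sets are restricted to the background before sizing, and only sets
with 15–900 genes (bounds inclusive) are tested: larger sets are
uninformative, smaller ones inflate the multiple-testing burden. BH FDR
is applied per (miRNA, $k$-level) run across the gene-set collection.
The correction family was an open choice; per-run correction matches the
per-miRNA consensus logic, whereas a joint family across miRNAs would
couple unrelated runs. This is noted as a caveat rather than offered as
an option.

The consensus filter demands nominal $p \le 0.01$ in at least 2 of the
3 top-$k$ runs. A miRNA whose whole target list is shorter than the
smallest $k$ has a single (degenerate) run; it instead faces the
stricter single-run threshold $p \le 0.005$. "Short list" status is
triggered exactly when `n_targets < min(topk_levels)`. Surviving sets
are exported as an enrichment-map graph: edges connect sets whose
combined coefficient $\tfrac12 J + \tfrac12 O$ (Jaccard $J$, overlap
coefficient $O$ — the enrichment-map convention presupposed by the
conventional 0.225 threshold) meets `similarity_threshold`; the weights
are configurable. Nodes carry per-miRNA hit flags, a multi-miRNA flag,
and whether any contributing run reached `fdr_border` (0.25).

## Guilt-by-association network

Candidates from two independent sources (association-study genes and
rare-CNV genes) are merged by set union. Relevance to brain function is
encoded as three binary criteria per gene — expression, function,
mouse-phenotype — and candidates need ≥ 1 of 3 (`candidate_criteria_min`)
while all other genes need ≥ 2 of 3 (`partner_criteria_min`) to be
labeled brain-relevant. Genes without annotation meet 0 criteria and are
logged.

Interaction edges are cleaned at read time — self-loops dropped,
duplicate unordered pairs collapsed keeping the maximum weight, weights
below `edge_weight_min` (0.02, inclusive) removed — so every downstream
module can assume a simple weighted graph.

Each brain-relevant gene is scored additively over its first-degree
neighbors in the *full* weight-filtered network (scoring precedes
network construction): `score_candidate` (+2.5) per candidate neighbor,
`score_brain` (+0.5) per brain-relevant neighbor, `score_penalty` (−1)
otherwise. Genes scoring ≥ `retain_score_min` (1.5, inclusive) join the
candidates as eligible nodes; the final network is the induced edge set
among eligible nodes, and nodes left without edges are dropped — which
is why some candidates do not appear in the final network. Candidates
are eligible regardless of score, but receive the same additive score
for ranking purposes, so `rank_by_score()` yields one ranking over all
network genes (descending score, lexicographic ties).

## Mechanism sets and overlap testing

The region-miRNA mechanism set is the union of the region miRNAs'
top-`overlap_k` (default 200) targets. The microprocessor-dysregulation
set contains genes in the top-`overlap_k` lists of at least
`min_dysregulated_mirnas` (default 2) of the externally supplied
dysregulated miRNAs, minus the region set — the subtraction keeps the
two mechanisms disjoint so their overlap tests are not double counting.

The overlap test universe is all genes of the weight-filtered
interaction network. This was an open choice — the universe materially
affects the odds ratio — and it is the defensible default because both
the network genes and (after intersection) the mechanism genes live in
that space; out-of-universe mechanism genes are dropped and counted.
The p-value reuses the same one-tailed Fisher routine; the headline
odds ratio is the sample cross-product estimate $(a d)/(b c)$ (infinite
when $bc = 0$), with the conditional MLE from `stats::fisher.test`
reported alongside, since "point estimate" is ambiguous between the two.

## The synthetic-data generator

`synth_spec()` fixes the study conditions for all recovery testing. Its
defaults emulate the motivating study at desk scale: a 7-locus cluster
planted in a 2.6 Mb window on a background of genome-wide loci placed
uniformly per chromosome (background loci are kept off the planted
window so the region count is exactly the cluster size); ~2,000 genes;
two tools with 70% target agreement and opposite polarities (tool 1
normal-noise scores, smaller stronger; tool 2 uniform-based, larger
stronger), shared targets receiving positively correlated strengths via
a common latent draw; candidate lists of 35 and 107 genes sharing one
gene; relevance marginals (0.45, 0.16, 0.17) close to the fractions of
genes carried by brain expression/function/phenotype resources, with
candidates' marginals multiplied by `candidate_relevance_factor` (1.6) —
curated candidate lists are pre-screened for brain relevance, and the
factor reproduces a retention of roughly five of six candidates at the
1-of-3 filter; a geometric degree model with mean 6 (planted structure,
not topological realism, is what the tests need — no scale-free tail is
attempted); a fifth of edge weights below the 0.02 cutoff to exercise
the filter; and 40 designated core-partner genes that each receive
`core_density_boost` (8) extra candidate-directed edges and forced
relevance flags.

Planted gene-set enrichment redirects a stated fraction of a miRNA's
targets into a named set, placing them in the inter-tool shared block so
the conservative intersection retains the signal; a fraction that would
exceed the shared block or the set size is a configuration error rather
than a silent cap. Everything generated from a spec is a pure function
of the spec (seeded sub-streams per generator; the caller's RNG state is
untouched), and identical specs produce byte-identical file bundles.

What the generator does *not* emulate: realistic score distributions of
any actual tool, weight calibration of real interaction aggregators,
scale-free network topology, correlated relevance criteria, or linkage
between gene position and function. Passing recovery tests therefore
show that the pipeline's inference machinery detects the structure it is
specified to detect at realistic sizes — not that real data would yield
the original study's numbers, which depend on external resources
(annotation releases, prediction tables, interaction databases) this
package deliberately does not fetch.

## Numerical choices and degenerate inputs

* Percentiles use the max-tie convention; all-tied tables give every
  record percentile 1.
* All rankings break ties lexicographically by gene or set id; no
  output depends on input row order.
* `density_percentile` with an empty comparison set, enrichment with an
  empty background, and overlap universes smaller than their contents
  are errors, not NAs; malformed input files fail with line-numbered
  parse errors; structural violations (duplicate ids, overlapping
  candidate/brain sets) fail as validation errors. All package
  conditions carry classes (`mirgba_parse_error`,
  `mirgba_validation_error`, `mirgba_config_error`,
  `mirgba_computation_error`, `mirgba_stage_error`) so callers can
  discriminate.
* Thresholds are inclusive throughout (weight ≥ 0.02, sizes in
  [15, 900], score ≥ 1.5, combined similarity ≥ 0.225).
* The run manifest omits wall-clock timestamps so that identical inputs
  yield byte-identical outputs; determinism was judged more useful than
  provenance timestamps, which the filesystem already records.
* Genome builds are not interpreted: the annotation file is taken as
  truth and coordinates are 1-based inclusive everywhere.

## Problem sizes used by the test suite

The suite runs entirely on generated data: exhaustive Fisher
verification over all 2×2 tables with margins ≤ 30; guilt-by-association
recounts on one hundred 500-node graphs; quadratic density oracles on
200-locus fixtures; enrichment recovery over 20 seeds of a 7-miRNA,
1,500-gene, 25-set configuration with 300 targets per miRNA (planted
fraction 0.3 recovered by the consensus filter in ≥ 95% of seeds;
unplanted data flagged in ≤ 5% of pairs); and network-core recovery on
the 2,000-gene default spec. These sizes keep the full suite around half
a minute on one CPU while leaving each statistical check comfortably
powered.

## Known limitations

* The percentile pool, FDR family and overlap universe choices above
  are defensible but not uniquely determined; alternatives would change
  numbers at the margin.
* Only the stated additive scoring weights are implemented (they are
  configurable, but no alternative scheme is bundled).
* Enrichment-map rendering and any interactive visualization are out of
  scope; the package exports node/edge tables for external tools.
* Identifier mapping is a plain two-column substitution with dropped
  unmapped genes; no ontology-aware resolution is attempted.
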