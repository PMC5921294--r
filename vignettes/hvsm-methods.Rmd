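---
title: "Hierarchical vector space similarity from GO annotations: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical vector space similarity from GO annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvsm)
```

## The problem

Two gene products are functionally similar when their Gene Ontology (GO)
annotations are similar. The flat vector space model (VSM) encodes each gene
as a binary vector over all GO terms and takes the cosine

$$S_v(G_1,G_2)=\frac{v_1\cdot v_2}{|v_1||v_2|},$$

which is blind to the ontology: a gene annotated to *mitochondrial inner
membrane* and one annotated to *mitochondrial intermembrane space* share no
term and score exactly 0, although the DAG places the two terms next to each
other. The hierarchical vector space model implemented here fixes this by
expanding each gene's binary vector over its annotations' neighbourhood in
the DAG before taking the cosine, and by calibrating the result with a
certainty factor that reflects how much annotation evidence the pair rests
on.

## Vector expansion

A gene's vector starts with weight 1 on every directly annotated term. Two
relation stages follow — first `is_a`, then `part_of` — and within each
stage four steps run in order, with relation factor $w_{rel}$ equal to
$w_{is\_a}$ or $w_{part\_of}$:

1. **Parents.** Each direct parent of each annotated term is updated: a
   zero component becomes $w_{parent} \cdot w_{rel}$; a nonzero one is
   incremented by $w_{incre} \cdot w_{rel}$, capped at 1.
2. **Grandparents.** As step 1 with both the fresh value and the increment
   scaled by $w_{r\_g}$. The expansion deliberately stops two levels up:
   more distant ancestors say little about the gene.
3. **Common children.** Only terms that are direct children of two or more
   annotated terms receive weight (fresh value $w_{child} \cdot w_{rel}$,
   increment $w_{child} \cdot w_{incre} \cdot w_{rel}$): descendants are
   less informative than ancestors, so a lone child contributes nothing.
4. **Common grandchildren.** As step 3, scaled by $w_{r\_g}$.

Updates within a step see values written earlier in the same step, so when
$k$ annotated terms share a parent the parent receives one fresh value and
$k-1$ increments (with defaults: $0.5, \frac{2}{3}, \frac{5}{6}, 1, 1,
\dots$). Common children and grandchildren, by contrast, receive a single
update each once they qualify. Directly annotated terms are frozen at 1 —
the cap makes every update on them a no-op.

Two-step paths that mix relations (`is_a` then `part_of` or vice versa)
belong to the `part_of` stage: the `is_a` stage uses only pure `is_a`
two-step paths, so any path containing the weaker relation is weighted by
$w_{part\_of}$. The stages being sequential also answers what happens when
the `part_of` stage reaches a component the `is_a` stage already set: it is
nonzero, so it takes the increment branch.

### Contribution factors

| factor | default | meaning |
|---|---|---|
| $w_{is\_a}$ | 1 | weight of the specialisation relation |
| $w_{part\_of}$ | 0.7 | weight of the component-of relation (semantically weaker) |
| $w_{parent}$ | 0.5 | one-step ancestor contribution |
| $w_{child}$ | 0.2 | common-descendant contribution (< $w_{parent}$) |
| $w_{incre}$ | 1/6 | increment for repeatedly reached components |
| $w_{r\_g}$ | 0.5 | two-step contribution relative to one-step |

All six are unitless and restricted to $[0,1]$. `hvsm_params()` warns (but
does not fail) when the intended orderings $w_{is\_a}>w_{part\_of}$,
$w_{parent}>w_{child}$, $w_{r\_g}<1$ are violated, so full-cube parameter
sweeps remain possible. The `"cessm"` profile lowers $w_{child}$ to 0.05,
the setting used when exporting scores for CESSM-style protein-pair
collections, whose corpora are far larger and where common descendants
otherwise accumulate too much weight.

## Calibrated similarity

With $S_1, S_2$ the two genes' counts of *directly* annotated terms
(pre-expansion), the certainty factor is $\lambda = \ln(S_1+S_2)$ and the
similarity is

$$S_v(G_1,G_2)=\frac{\lambda\,(v_1\cdot v_2)}{|v_1||v_2|}.$$

Richly annotated pairs give more trustworthy cosines, so they are scaled
up. Consequences worth knowing:

* scores may exceed 1 (e.g. identical genes with $S\ge 2$ score
  $\ln 2S > 1$); the measure is built for rank-based use (ROC), where the
  logarithm's base is irrelevant;
* on an edgeless ontology the expansion is the identity and the score
  reduces exactly to $\ln(S_1+S_2)$ times the flat VSM cosine — the test
  suite asserts this reduction at $10^{-12}$;
* the computation uses only the union of nonzero components of the two
  sparse vectors, which equals the full-dimension value exactly.

## Sentinels and evaluation

Benchmark files routinely contain genes that the annotation set cannot
resolve. `pair_similarity()` and `score_dataset()` never abort a run: an
unresolvable gene yields the sentinel score −1, an internal computation
failure yields −2 (with a warning). `roc_auc()` ranks sentinels below every
real score, −1 above −2, so "complete" evaluations are well defined;
"partial" mode drops sentinel pairs first. When no sentinels exist the two
modes agree exactly.

The ROC sweep moves the threshold over distinct score values in descending
order; tied scores move as one block, producing a diagonal segment whose
trapezoidal area equals the Mann–Whitney rank statistic with ties counted
one half — the suite checks agreement at $10^{-10}$ on random score sets
with and without sentinels.

## Comparison measures

The package carries the classic measures it is meant to be compared
against, behind one dispatcher (`score_dataset(measure = ...)`): flat VSM,
Jaccard and Dice on the direct sets, Resnik, Lin, Jiang and Schlicker on
the most informative common ancestor (MICA) with MAX/AVG/BMA combination,
SimGIC on IC-weighted ancestor-extended sets, and IntelliGO. Conventions
fixed here because the surrounding literature leaves them open:

* the IC corpus is the loaded annotation set, with counts propagated to
  ancestors over both relations and probabilities normalised by the
  namespace root;
* Jiang's distance is reported as the bounded similarity
  $1/(1+\mathrm{dist})$;
* MICA search includes the term itself and uses both relations; ties are
  broken lexicographically (the IC value, which is all that matters, is
  tie-invariant);
* IntelliGO's term depth is the minimum edge distance from the root over
  both relations; among equally deep common ancestors the one minimising
  the connecting path is the LCA, then lexicographic order; evidence-code
  weights default to 1 and are configurable via `intelligo_config()`;
* the default gene-level combination for the term-based measures is MAX.

## The synthetic benchmark generator

Real evaluations of this method used curated interaction sets and archival
GO releases; the package instead ships a seeded generator
(`fixture_spec()`, `simulate_benchmark()`) so every pipeline stage is
testable offline. It emulates: a single-rooted acyclic ontology per
namespace with typed `is_a`/`part_of` edges (no `part_of` in MF), genes
annotated to small uniform-random term sets, and balanced positive/negative
pair sets where positives carry planted annotation relatedness. The DAG is
layered — term $k$ sits on layer $\lfloor\log_2 k\rfloor$ and draws 1–3
parents from the layer above — giving the geometric widening of real GO at
a miniature scale.

Signal modes:

* **shared-term** — positives share at least one direct annotation. Both
  flat and hierarchical cosines see this signal;
* **sibling-term** — positives share *no* term, but terms of the two genes
  have a common direct parent. This is precisely the situation the
  hierarchical expansion exists for: the flat cosine is 0 by construction,
  the expanded vectors overlap at the shared parent;
* **none** — positives are random pairs; any measure should score at
  chance (the suite requires AUC within 0.05 of 0.5 on 1,000 pairs).

Default sizes (200 terms, 100 genes, 2–6 terms per gene, 300+300 pairs)
keep a full generate–score–evaluate cycle under a second; the acceptance
script runs it at those sizes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: GO's term-depth and fan-out distributions, the
strong correlation of real annotation sets within protein families and
complexes, evidence-code composition, and annotation depth bias. One
consequence is measurable and worth stating plainly: under the pure
shared-term signal the flat VSM is essentially the matched detector (98% of
random negatives score exactly 0 while every positive is positive), so on
that benchmark VSM's AUC slightly exceeds the hierarchical model's, whose
expansion adds background similarity between random genes on a 200-term
ontology. The hierarchical model's advantage appears exactly where the
design predicts it: on the sibling-term benchmark the AUC gap over VSM is
roughly 0.2 (both numbers are recomputed by `scripts/acceptance.R`). On
real corpora both signal types mix, which is consistent with the modest
single-digit AUC improvements reported for hierarchy-aware measures.

## Numerical and degenerate-input choices

* Annotated terms, and neighbours within a step, are processed in sorted
  term-id order, making results independent of input order and exactly
  reproducible (the suite pins the expansion to a literal dense
  re-implementation, bit for bit, across random DAGs and parameter
  corners).
* Obsolete terms, non-hierarchical relationship types, and cross-namespace
  edges are dropped at OBO parse time; `alt_id` collisions keep the first
  mapping with a warning.
* NOT-qualified GAF rows are removed (standard practice), as are rows whose
  term is unknown after `alt_id` resolution; the namespace root is stripped
  from every gene's set, and genes left empty disappear — downstream they
  surface as sentinel −1, never as an exception.
* `certainty_factor()` requires both counts ≥ 1; an empty term set is a
  construction error, not a similarity of 0.
* Duplicate unordered pairs in a benchmark collapse to the first
  occurrence with a warning.
* Generator randomness derives from the spec's mandatory seed through
  per-artifact derived seeds; the caller's global RNG state is saved and
  restored.

## Known limitations

* Scores are not normalised to $[0,1]$; consumers needing calibrated
  probabilities must transform them.
* The expansion window is fixed at two levels up and down; deeper
  relatedness (e.g. cousins sharing a great-grandparent) is invisible.
* Cross-namespace composite scoring is out of scope: one namespace per
  run.
* IntelliGO here fixes depth/path conventions the original service left
  unspecified; exact numeric agreement with that service is not a goal.
* Weight learning is not provided; the defaults are published trade-off
  values and a manual sweep remains the calibration route.
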