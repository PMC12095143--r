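---
title: "Dosage-weighted prescription networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-weighted prescription networks: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosenet)
```

## The model

A multi-herb prescription is modeled as a four-layer multipartite graph:
botanical drugs connect to their bioactive metabolites, metabolites to the
protein targets they are known to bind, and targets found in a
disease-associated gene list to a single disease node. The classical
("non-dosage") analysis assigns weight 1 to every edge. `dosenet` builds a
second variant of the same graph in which each drug's edges carry its
*standardized dosage* — its gram dosage divided by the smallest gram dosage
in the prescription — so dosage information enters the topology-identical
network purely through edge weights.

Both variants are then read out identically:

1. **Weighted degree.** Each node's weighted degree is the sum of its
   incident edge weights (the ordinary degree when all weights are 1).
2. **Key targets.** Target-layer nodes whose weighted degree *strictly*
   exceeds the mean weighted degree of the target layer.
3. **Drug targets.** Key targets that are also disease-associated genes.
4. **Pathways.** Hypergeometric over-representation of the drug targets in
   a user-supplied gene-set collection, thresholded on the raw p-value and
   a minimum overlap count.

Differences between the two read-outs are summarized by four indicators:
Dedis (Euclidean distance between the standardized and all-ones dosage
vectors), DeSD (sample standard deviation of the standardized vector),
DeDT and DePy (1 − Jaccard similarity between the two drug-target and
enriched-pathway sets), plus metabolite-level analogues of the two input
indicators.

### Assumptions worth stating

- The component map (drug → metabolites → targets) is taken as given and
  complete; drug-likeness filtering is assumed to have happened upstream.
- Dosage acts multiplicatively and linearly along a drug's edges. No
  pharmacokinetic saturation, interaction or antagonism is modeled.
- A metabolite contributed by several drugs is assumed to act with their
  combined dose (see *Weight propagation* below).
- The disease is a single merged gene list; no per-disease-subtype
  structure.

## Key properties

Two exact consequences of the standardization anchor the test suite:

- **Null equivalence.** Equal dosages standardize to the all-ones vector,
  so the two pipelines coincide bit for bit and all indicators are exactly
  zero.
- **Scaling invariance.** Multiplying every dosage by k > 0 leaves the
  standardized vector (hence every prediction and indicator) unchanged:
  only dosage *ratios* matter. Doubling an entire prescription is
  invisible to the model by construction — a deliberate idealization.

A third, directional property links inputs to outputs: zero Dedis forces
zero DeDT and DePy, but positive Dedis does not force an output change
(a small dosage skew may leave every degree on the same side of the mean).
Dedis is therefore a necessary-not-sufficient signal of prediction change,
which is why it, and not DeSD, is the useful screening indicator.

## Tunable parameters

| parameter | where | default | rationale |
|---|---|---|---|
| `grams_per_fen` | `unit_conversion_table()` | 0.4 (Song–Yuan), 0.37 (Ming–Qing) g | dynastic metrology; shipped as versioned YAML so users can extend it |
| dynasty | prescription table | *required* | the two systems differ by 7.5%; silently defaulting would corrupt ratios. Mixed dynasties in one prescription are rejected; mixed units are fine |
| `propagate` | `build_network()` | `"sum"` | a metabolite contributed by two drugs carries both doses; `"max"` available for sensitivity analysis |
| `average` | `select_key_targets()` | `"targets"` | key targets are selected *among* targets, so the reference mean is the target layer; `"all"` (all nodes) available as a sensitivity option |
| `p_cutoff` | `enrich()` | 0.05 | raw-p threshold; no multiplicity correction by default (a BH option exists) to match common practice in prescription ORA |
| `min_genes` | `enrich()` | 10 | minimum *overlap* (enriched-gene) count, interpreted as such rather than as pathway size; desk-scale fixtures need it lowered (the worked example uses 2, synthetic ensembles 3) |
| `exact_limit` | `rank_sum_test()` | 12 | exact permutation p below this combined n (and no ties); above it, normal approximation with tie and continuity correction |

## Numerical choices

- **Standardization** is done in grams at full floating precision; no
  rounding before or after division. The minimum of a standardized vector
  is exactly 1 (division of the minimum by itself), and all components are
  ≥ 1.
- **SD denominator** is n − 1 (R's `sd()`), so DeSD of a two-drug vector
  `[1, r]` is `(r − 1)/√2`.
- **1 − Jaccard with two empty sets** is defined as 0: identical outputs
  mean no difference; the 0/0 case is otherwise undefined.
- **Metabolite-level indicators.** The metabolite dosage vector assigns
  each *distinct* metabolite the summed standardized dosages of its parent
  drugs (deduplicate-and-sum convention), in lexicographic metabolite
  order for reproducibility. Because a shared metabolite makes even the
  all-ones drug vector expand to components > 1, `compound_dedis` and
  `compound_desd` compare the weighted expansion against the expansion of
  the all-ones vector (not against a literal all-ones vector). For
  unshared metabolites the two readings coincide, and the null case is
  exactly zero either way.
- **Ties.** Key-target selection uses strict `>`, so degree ties at the
  mean are excluded (an all-equal target layer has no key targets).
  Enrichment ties in p are broken by pathway id for deterministic output.
- **Median splits** use R's midpoint convention for even n; items equal to
  the median are labeled "low"/"less".
- **Universe.** The enrichment background defaults to the union of all
  collection members, overridable; query genes outside it are dropped with
  a warning.

## The synthetic-data generator

No public corpus bundles prescriptions with curated metabolite/target maps
and a disease list in a self-contained way, so the package generates its
own: `synthetic_config()` defaults emulate the conditions the method is
meant for — 94 prescriptions of 3–9 drugs (median 6), standardized dosage
ratios up to 99 sampled on a log-uniform grid (so near-null and extreme
prescriptions both occur), a gene universe of 400 symbols of which 30% are
disease-associated, 25 pathways of 10–30 genes sampled with ~40% overlap
into the disease list, and 10% exact-null (equal-dosage) prescriptions.
All identifiers are synthetic (`G0001`, `P001_M003`, …) and everything is
deterministic under one seed.

Two dosage designs are provided:

- `"log_uniform"` (default): independent per-drug ratios. Input spread and
  input distance co-vary, and larger dosage skew reshuffles weighted
  degrees more — the *coupled* ensemble in which median-split grouping by
  Dedis shows stochastically larger DeDT in the high group.
- `"constant_spread"`: one high-dosage drug at ratio 1 + c·√k for k drugs
  (c ≈ 3 with ±10% jitter), which pins the sample SD of the dosage vector
  near c regardless of k while the Euclidean distance still varies with k.
  Grouping by DeSD in this ensemble carries no output signal — the
  construction that separates the two input indicators. Exact-null cases
  are omitted here (`null_fraction = 0`) because a null prescription has
  zero SD *and* zero Dedis, and would re-couple the split through the
  necessity property rather than through spread.

What the generator does **not** emulate: real metabolite sharing across
different herbs' chemistry, degree distributions of curated interactome
databases, relevance-scored disease associations, or GO's DAG structure.
Passing tests on synthetic ensembles therefore demonstrate the *internal*
behaviour of the method (invariances, coupling directions, thresholds),
not the biological validity of any particular prediction on real data.

## Problem sizes used in the checks

The shipped checks run the worked example exactly; null equivalence over
50–100 equal-dosage prescriptions; scaling invariance over 10
prescriptions × multipliers spanning 0.5–1000; oracle comparisons by
exhaustive enumeration (hypergeometric universes ≤ 12, rank-sum group
sizes ≤ 6, adjacency row sums on networks ≤ 20 nodes); 1,000 null
simulations for the rank-sum type-I rate; and the two 94-prescription
ensemble analyses described above. These sizes were chosen as the smallest
at which each property is exercised at its documented scale.

## Known limitations

- Predictions depend strongly on map completeness: a drug with few
  curated metabolites is structurally down-weighted irrespective of dose.
- The strict-mean key-target rule is a hard threshold; prescriptions whose
  degree distribution concentrates near the mean can flip predictions
  under tiny dosage perturbations.
- Absolute dosage (total mass) is invisible by design; the method speaks
  to composition, not magnitude.
- The enrichment step is deliberately generic (GMT in, hypergeometric
  out); it does not reproduce ontology-aware tooling output on real GO
  releases.
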