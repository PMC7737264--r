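---
title: "Area-taxonomy quality assurance: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-taxonomy quality assurance: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(areatax)
```

## The problem

Large biomedical terminologies (the NCI thesaurus, SNOMED CT, and their
relatives) define concepts through two kinds of links: hierarchical IS-A
(subsumption) edges, and *lateral relationships* — named, non-hierarchical
triples `(source, target, type)` such as *Biological Process Has Associated
Location*. Because lateral relationships carry most of a concept's
definitional content, *errors of omission* — relationships an editor should
have asserted but did not — quietly degrade the usefulness of the ontology
and mislead the classifiers that maintain it.

No algorithm can decide that a particular concept is missing a particular
relationship; that judgment needs a domain expert. What an algorithm *can*
do is concentrate expert attention on concepts with a high prior
probability of being under-modeled. This package implements one such
triage method built on the **area taxonomy**, an abstraction network that
partitions a hierarchy's concepts by their exact set of
lateral-relationship types.

## The method

1. **Area derivation.** Every concept is assigned to the *area* named by
   its set of relationship types (targets and multiplicity ignored). Areas
   are linked by *child-of* edges: area A is child-of area B when a root
   of A (a member with no IS-A parent inside A) has an IS-A parent in B.
   The *top area* is the area whose type set equals the hierarchy root's
   own set — the empty set for a full hierarchy, the subhierarchy root's
   inherited set for a subtaxonomy. Both cases follow one rule: the
   baseline is the root's type set.

2. **Top-area anomaly.** Concepts legitimately without relationships are
   few and general. A top area holding a large fraction of the hierarchy
   therefore signals widespread under-modeling. `top_area_metrics()` flags
   a top-area fraction inside a configurable band, 4%–90% by default. The
   lower cut reflects that published taxonomies with 1–2% top areas are
   unremarkable while ~4% and up have been judged disproportionate; the
   upper cut excludes hierarchies left almost entirely primitive on
   purpose (94–96% top areas), for which this kind of QA is not useful.

3. **Level prioritization.** When the top area is itself too large to
   review, concepts are ranked by *level*: the number of IS-A links on the
   longest path to the top-area root (root at level 0; multi-parent
   concepts take their longest path, computed in one topological pass).
   With `n` occupied levels, the *higher-indexed half* starts at level
   `floor((n + 1) / 2)`: 10 levels split into {0..4} and {5..9}, 11 levels
   into {0..5} and {6..10}. Deeper concepts accumulate intension and are
   more likely to be under-modeled, so review effort is best spent on the
   higher-indexed half, deepest levels first.

4. **Evaluation.** Audit verdicts are cross-tabulated — top area versus a
   control sample from other areas, or higher- versus lower-indexed-half
   levels — and tested with the two-tailed Fisher's exact test
   (`fisher_two_tailed()`), alongside per-level error tables
   (`level_error_table()`).

5. **Propagation.** A confirmed missing relationship `(C, R, D)` should
   also hold, with target D or a descendant of D, at every IS-A descendant
   of C. `classify_descendants()` partitions the descendants into
   `missing_same`, `already_correct` and `incorrect_target`;
   `apply_repairs()` adds the confirmed triples (and, with
   `inherit = TRUE`, the propagated copies) and returns a revised
   hierarchy whose re-derived taxonomy shows the structural effect of the
   corrections.

## Numerical and representational choices

- **Two-tailed Fisher.** The p-value is the sum of hypergeometric point
  probabilities (margins fixed) over all tables whose point probability is
  at most that of the observed table, compared with a relative tolerance
  of 1e-7 — the point-probability method as implemented by
  `stats::fisher.test()`, which the package wraps. A zero margin leaves
  nothing to condition on; the function returns 1 with a warning rather
  than erroring, so simulation sweeps that occasionally produce empty
  cells keep running. The test suite checks the wrapper against a full
  enumeration oracle on all tables with margins up to 12.

- **Percentages** are rounded half-up (`percent()`), not half-even, to
  match the convention of published audit tables; the number of decimals
  is a parameter because reports in this field mix one- and two-decimal
  conventions.

- **Area names** are canonical: types sorted in C-locale byte order,
  joined as `"{t1, t2, ...}"`. All orderings in the package (area tables,
  candidate tie-breaks, written TSVs) use the same locale-independent
  sort, so identical inputs give byte-identical outputs on any machine.

- **Levels are computed on the top-area-induced IS-A subgraph.** An IS-A
  parent outside the top area contributes no path. Under monotone
  inheritance this loses nothing (the top area is ancestor-closed); on
  non-monotone data the affected concepts are listed in the level map's
  `outside_parents` field, every area root of a disconnected top area is
  seeded at level 0, and the result is still well defined.

- **External targets.** Lateral triples may point into other hierarchies
  of the same ontology. Unknown target ids are kept as external references
  by default (`strict = TRUE` rejects them). For repair classification,
  "more specific than D" is resolved through the loaded IS-A closure when
  D is loaded; for an external D only exact equality counts as correct,
  and the classification is flagged accordingly.

- **Concept ids are opaque strings** and the only keys; names are
  metadata. Multiple parents are allowed; each loaded hierarchy has
  exactly one root (forests are loaded per hierarchy). The RF2 reader
  takes the "Is a" type identifier as a parameter (default `116680003`)
  and flattens role groups to types, which is all the area abstraction
  needs.

## The synthetic-data generator

Real releases cannot be redistributed, so validation runs on synthetic
hierarchies with known ground truth (`generate_truth()`, `plant_errors()`).

**Structure.** The generator grows a rooted DAG by random attachment:
each new concept takes one parent among earlier concepts with spare child
capacity (at most 6 children by default), plus a second parent with
probability 0.15. Parents are drawn with weight `0.65^depth`
(`depth_penalty`), which keeps hierarchies bushy near the root: at the
default 8,000 concepts this yields the 10–12 occupied top-area levels
seen in real hierarchies of a few thousand concepts, rather than the long
thin chains plain uniform attachment produces.

**Relationships.** Each concept inherits all ancestor triples and, per
relationship type (the seven role types of a biological-process hierarchy
by default), introduces a new triple with probability 0.03, its target
drawn from a small per-type external pool. Inheritance is materialized, so
type sets grow monotonically down the hierarchy and
`check_monotone_inheritance()` is empty by construction. Under these
defaults the (undamaged) top area holds roughly 20–45% of the concepts —
the anomalous regime the method targets, bracketed by the two studied
hierarchies (22% and 45%).

**Planted omissions.** An error model gives the probability `p(l)` that a
triple *introduced* at a level-`l` concept is omitted — mirroring an
editor failing to author an assertion. Inheritance is then
re-materialized from the surviving introductions, so the inherited copies
of an omitted assertion vanish from all descendants. `plant_errors`
records both the authoring-time omissions (`planted`) and the full
truth-minus-observed triple difference (`errors`, which additionally
contains the vanished inherited copies); the two coincide at the
introducing concepts by construction. The default `logistic_error_model()`
rises from 0.1 near the root to 0.7 at depth with its midpoint at level 5
— the lower/higher-half boundary of the hierarchies the generator
produces — so the increase spans the occupied levels.

**What the simulated reviewer sees.** In `recovery_experiment()` the
ground truth stands in for the human reviewer, and a concept is deemed
erroneous when one of its *own authored* assertions was omitted (the
planted set), not when it merely inherited the consequences of an
ancestor's omission. This choice is what makes the experiment a clean
test of the depth hypothesis: conditional on sitting in the observed top
area, whether a concept's own introductions were removed is independent
of its level when `p(l)` is constant, so the Fisher test's rejection rate
stays at its nominal size under a level-constant error model and rises
toward 1 under a level-increasing one. Had the reviewer flagged every
concept missing any triple relative to truth, deeper top-area concepts
would be structurally more error-prone even under constant rates (they
have more ancestors whose omissions they inherit), and the null would
never be exactly true. The inherited consequences are still fully
represented — they are what `classify_descendants()` and the impact
report quantify.

**Scale of the validation experiments.** The recovery experiment uses
8,000-concept hierarchies, which keep at least ~500 concepts in every
observed top area (the regime where half-splitting is meaningful) and
give the depth test over 90% power at the default effect; 100 runs are used
for the power check and 200 for the size check. One hundred seeded runs
take a few minutes on a single core.

**What the generator does not emulate.** Real missing-relationship errors
are not independent coin flips: editors omit related assertions in
batches, error rates differ by relationship type, and real top areas also
contain legitimately primitive subtrees curated as such on purpose. The
generator also draws targets from small pools and gives every type the
same introduction probability. Passing the recovery experiment therefore
shows that the pipeline detects level-concentrated omissions planted
under the stated model — it does not certify error rates on any real
release, and published area counts of specific releases (e.g., 37 or 97
areas) are only reproducible with those releases in hand.

## Limitations and open edges

- The method flags *candidates*; verdicts and correction targets come
  from human audit files. Nothing in the package invents a missing
  relationship.
- `incorrect_target` findings are reported, never auto-repaired: changing
  an existing assertion is curator work.
- Whether a relationship confirmed at concept C would have applied to all
  of C's children had it been authored higher up cannot be decided
  structurally; the package reports per-descendant classifications and
  leaves the judgment to the curator.
- Description-logic status (primitive vs fully defined) is invisible to
  the area abstraction and is not modeled.
- Audit files carry reviewer and stage columns so primary-review and
  confirmed-review analyses re-run from one file; the package applies no
  multiple-testing correction, matching how such audits are reported.
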