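# areatax

Quality assurance for biomedical ontologies, targeted at **missing lateral
relationships** — definitional links (NCIt "roles", SNOMED CT "attribute
relationships") that an editor should have asserted but did not.

Ontology curators cannot review hundreds of thousands of concepts. `areatax`
finds the concepts most worth their time using the **area taxonomy**, an
abstraction network that partitions a hierarchy's concepts into *areas* by
their exact set of lateral-relationship types, linked by *child-of* edges
derived from the IS-A hierarchy. Two structural signals drive the triage:

- **A disproportionately large top area.** The top area collects the
  concepts whose type set equals the hierarchy root's (the empty set for a
  full hierarchy). Legitimately relationship-free concepts are few and
  general, so a top area holding, say, 45% of a hierarchy indicates
  widespread under-modeling.
- **Depth within the top area.** The *level* of a top-area concept is the
  number of IS-A links on the longest path to the top-area root. With `n`
  occupied levels, the *higher-indexed half* (levels `⌊(n+1)/2⌋ … n−1`)
  holds the more complex concepts, where omissions concentrate: a 10-level
  top area splits into levels {0–4} vs {5–9}.

Audit outcomes are evaluated with two-tailed Fisher's exact tests on 2×2
contingency tables (top vs control areas; higher vs lower half) and
per-level error tables. Confirmed repairs `(C, R, D)` are propagated:
every IS-A descendant of C should carry relationship R with target D or a
descendant of D, and descendants are classified as `missing_same`,
`already_correct`, or `incorrect_target` before the revised hierarchy is
re-derived.

The package reads a native three-file TSV format and SNOMED CT RF2
snapshot subsets, exports Graphviz DOT diagrams of taxonomies, and ships a
synthetic-hierarchy generator with planted, level-dependent omission
errors so the whole pipeline is testable without any ontology download.

## Worked example

```r
library(areatax)

# a synthetic 5000-concept hierarchy with omissions planted at rates that
# rise with depth, as a stand-in for a real release
spec <- generator_spec(n_concepts = 5000, seed = 42)
pt <- plant_errors(generate_truth(spec), logistic_error_model(seed = 43))

t <- derive_taxonomy(pt$observed)
top_area_metrics(t)
#> top area: 1877 of 5000 concepts (37.5%) - ANOMALOUS [band 4%-90%]

lm <- compute_levels(t, pt$observed)
half_split(lm)
#> <half_split> n = 12: lower 0..5 | higher 6..11

head(prioritize_candidates(t, lm, pt$observed, scope = "higher"), 3)
#>   rank     id                   name level   half
#> 1    1 C04301 Synthetic concept 4301    11 higher
#> 2    2 C01595 Synthetic concept 1595    10 higher
#> 3    3 C02871 Synthetic concept 2871    10 higher
```

The top area holds over a third of the hierarchy — far above the few
percent a well-modeled hierarchy shows — so it is flagged as anomalous,
and the candidate list orders its concepts deepest-first for review.
Evaluating a (here: ground-truth) audit of the top area by level half:

```r
err <- unique(pt$planted$concept)
top <- t$areas[[t$top_area]]$members
aud <- audit_records(top, ifelse(top %in% err, "erroneous", "clean"),
                     missing_type = ifelse(top %in% err, "Location", NA))
ct <- build_half_contingency(aud, lm)
ct
#>        erroneous clean
#> lower         64   823
#> higher       115   875
fisher_two_tailed(ct)
#> [1] 0.001222675
```

Concepts in the deeper half are missing relationships significantly more
often — the depth signal the prioritization exploits.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/areatax.R derive --input ontology_dir --out reports/
Rscript inst/cli/areatax.R candidates --input ontology_dir --scope higher --out reports/
Rscript inst/cli/areatax.R render --input ontology_dir --out taxonomy.dot
```

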