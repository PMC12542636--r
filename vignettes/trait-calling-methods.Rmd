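---
title: "Rule-based metabolic trait calling: model, thresholds, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based metabolic trait calling: model, thresholds, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magtraits)
```

## The problem

Draft genomes binned from metagenomes (MAGs) are incomplete and sometimes
contaminated, yet most comparative studies must decide, genome by genome,
whether a metabolic capability is encoded. Calling a pathway from a single
marker gene inflates false positives (mis-binned or mis-annotated genes)
while demanding every enzyme of a pathway inflates false negatives (gene
dropout in incomplete assemblies). `magtraits` implements the standard
conservative compromise as an explicit, declarative rule engine so that
the criteria are inspectable, editable, and testable.

## The inference model

A trait rule is a requirement expression with four node kinds:

* **GENE** — a diagnostic gene, matched in a genome's annotation table by
  KO identifier (case-insensitive) or gene symbol (case-insensitive),
  with a per-gene `min_copies` threshold (default 1). A rule can be
  restricted to KO-only matching with its `ko_only` flag for tables whose
  symbols are unreliable.
* **COMPLEX** — a multi-subunit enzyme complex with a core-subunit list
  and a completeness threshold `min_fraction` in (0, 1]. The complex is
  satisfied iff the fraction of distinct core subunits found **strictly
  exceeds** `min_fraction`; only at `min_fraction = 1` does equality
  suffice. Under the default 1/2, a 4-subunit complex needs 3 subunits:
  exactly half must fail, because "more than 50% of the core subunits"
  is a strict majority. Copy numbers at or above a subunit's `min_copies`
  count the subunit as found once; extra copies never change a call.
* **ALL\_OF / ANY\_OF** — conjunction and disjunction over child nodes,
  arbitrarily nested.

Evaluation is monotone: the builtin rulebook contains no negation, so
adding annotations to a genome can only turn traits on, never off. The
test suite checks this property on 1,000 random subset/superset pairs and
checks the evaluator against an independent brute-force oracle (expansion
of each requirement tree into its minimal satisfying gene sets) on every
subset of each rule's vocabulary up to 12 genes.

Every call stores an evidence tree mirroring the requirement tree, with
per-node outcomes and per-complex subunit fractions; recomputing the
boolean from the evidence reproduces the call, which the tests assert.

## Quality tiers

Genomes are tiered before calling, following the usual CheckM conventions
for MAG collections:

| tier | rule |
|---|---|
| excluded | completeness < 50% **or** contamination ≥ 10% |
| high | completeness > 90% **and** contamination < 5% |
| medium | everything else retained |

Boundary semantics matter and are pinned by tests: completeness of exactly
50 is retained (medium), contamination of exactly 10 is excluded,
completeness of exactly 90 and contamination of exactly 5 are medium, not
high. Tiering annotates rather than deletes; excluded genomes are dropped
from the trait matrix unless `include_excluded = TRUE`, and a `drop` flag
removes them from the metadata table itself.

## The builtin rulebook

`builtin_rulebook()` ships 27 traits in nine functional categories. Points
where the underlying biology leaves the encoding genuinely open, and the
choices made:

* **Single-marker traits.** Although pathway presence generally requires
  multiple co-annotated diagnostic genes, some reported capabilities are
  single enzymes (alcohol dehydrogenase, formate dehydrogenase, xylose
  isomerase, cysteine synthase, nitrous-oxide reductase, cytochrome *b*).
  These are deliberate single-GENE rules; the exception is recorded per
  rule in its `notes`.
* **Complete respiratory chain.** The `respiratory_chain_complete` trait
  requires complexes I and II plus either terminal oxidase (aa3-type or
  bd-type) and intentionally does **not** require complex III: genomes of
  demonstrably aerobic organisms in this clade lack it, so requiring it
  would misclassify the lifestyle. Complex III remains available as its
  own trait.
* **Complex I core subunits.** No canonical subunit inventory exists for
  draft genomes; the default is the 11 subunits NuoA–NuoN excluding the
  NuoE/F/G input module (often absent or fused), and the set is a
  documented argument of `builtin_rulebook()`.
* **PEP carboxykinase.** The GTP-dependent (pckG) and ATP-dependent
  (pckA) forms are distinct GeneSpecs under an ANY\_OF, because the two
  forms partition across lineages.
* **RuBisCO.** The CBB rule accepts either RuBisCO subunit gene
  (`any_of(rbcL, rbcS)`) plus phosphoribulokinase, since form III
  enzymes have no small subunit; `rbcL` alone with `prk` therefore
  suffices.
* **Isocitrate dehydrogenase.** Any isoform symbolised `idh`/`IDH` (or
  KO K00031) counts; the literature does not restrict the isoform.
* **V/A-type ATPase.** The subunit inventory is not standardised; the
  default set (A, B, C, D, E, F, I, K) is a configurable argument.
* **KO identifiers** are best-effort configuration data: the primary
  identity is the gene symbol, and the shipped KO lists can be edited by
  saving (`save_rulebook()`, YAML canonical / JSON accepted) and
  reloading. `cs` (TCA citrate synthase) and `gltA` (rTCA citrate
  synthase) intentionally share K01647.

## Aggregation semantics

Subgroup summaries use a three-state encoding per (subgroup, trait):
`MAJOR` when the trait is present in at least half of the subgroup's
genomes — exactly 50% counts as MAJOR — `MINOR` when present in some but
fewer than half, and `ABSENT` when missing from all. The partition is
exhaustive and exclusive; the tests enumerate every (n_present, n_total)
with n_total ≤ 20.

The co-occurrence screen is descriptive: for two traits it reports the
2×2 contingency counts over genomes, the Jaccard index (0 when no genome
carries either trait), and a `mutually_exclusive` flag that is true iff no
genome carries both while each trait occurs at least once (an all-zero
column can never be "exclusive"). A hypergeometric lower-tail probability
of at most the observed joint count under independence is reported
alongside, but the flag is never gated on it — exclusivity here is a
pattern statement, not a hypothesis test.

Heatmap ordering uses agglomerative hierarchical clustering
(`stats::hclust`) of the 0/1 profiles. The default is Euclidean distance
with complete linkage — the defaults of the pheatmap-style tools these
figures are usually drawn with — and Jaccard distance (`stats::dist`
`"binary"`) with average linkage are offered as options since the
original figures' parameters are not stated. Two all-zero profiles are
defined to be at Jaccard distance 0 (the 0/0 case). Ordering is
deterministic for fixed input; distance ties resolve toward lower
original indices via the agglomeration order.

## The synthetic-data generator

The generator emulates a four-subgroup MAG collection with distinct
planted metabolic profiles; it produces the same TSV formats the ingest
module consumes, so every pipeline stage is exercised without downloads.
Modeling choices:

* **Dropout.** Each genome draws completeness uniformly from
  `completeness_range` (default 50–98%, the observed range in
  medium-to-high-quality MAG collections) and retains each gene of its
  subgroup's complement independently with probability
  completeness/100. This is the simplest model consistent with
  completeness as "fraction of the genome recovered"; it ignores
  linkage (neighboring genes dropping together on lost contigs), so real
  dropout is over-dispersed relative to it.
* **Contamination.** Foreign genes are drawn from the union of the other
  subgroups' complements, each injected independently with probability
  `contamination_rate` (default 0.05), mimicking cross-bin contamination.
  The *reported* contamination percentage in the metadata is drawn
  uniformly from `contamination_pct_range` (default 0–7.3%, below the
  exclusion threshold, as in a post-filter collection) independently of
  the injections: a marker-gene contamination estimate is not derivable
  from a diagnostic-gene list, and coupling the two would fabricate a
  precision the model does not have.
* **Profiles.** `generate_profiles()` samples distinct traits per
  subgroup and enforces two invariants: the subgroup's gene complement
  satisfies exactly its planted traits (closure — so recovery scoring is
  well-defined), and complements are pairwise disjoint across subgroups
  (so injected genes are guaranteed foreign) unless `allow_overlap =
  TRUE`. A consequence: composite traits whose complements imply other
  traits (e.g. `respiratory_chain_complete`, which contains complexes I,
  II and IV outright) can never be planted alone and are resampled away.
* **Seeding.** One root seed yields per-genome derived streams, so
  increasing the genome count never reshuffles earlier genomes; two runs
  from the same configuration are byte-identical through the entire
  simulate → call → summarize → evaluate pipeline, which the tests check
  at the artifact level.

Because retention is per-gene i.i.d., call sensitivity has closed forms:
a k-gene conjunction at retention *p* recovers with probability *pᵏ*, and
a k-subunit complex with strict-majority threshold with probability
P(Bin(k, p) > k/2) — e.g. 5/16 = 0.3125 for k = 4 at p = 0.5. The test
suite and the acceptance script hold the simulator to these forms within
three binomial standard errors at 2,000 genomes. Under zero
contamination, specificity for non-planted traits with disjoint gene sets
is exactly 1, and that is asserted exactly, not approximately.

What passing these tests does *not* show about real data: annotator
error (wrong KO assignments), symbol-vocabulary mismatches between
annotators and the rulebook, correlated dropout, and genuinely partial
pathways are all outside the simulation; the generator validates the
machinery, not the annotations.

## Numerical and interface choices

* Problem sizes in the default test run are chosen to keep the full
  suite near a minute: exhaustive enumeration is used wherever the space
  is ≤ 2¹² (complex thresholds, rule-vs-oracle equivalence, three-state
  classification), Monte Carlo (n = 2000, fixed seeds) where it is not.
* Degenerate inputs: a genome with zero annotation records yields an
  all-absent row plus a recorded annotation count of 0 (absence of
  evidence is distinguishable from evidence of absence downstream);
  single-item clustering returns the identity ordering with an empty
  merge history; an empty trait matrix is a stage error, not an empty
  artifact.
* Annotation merging: gene identity within a genome is the KO id when
  present, else the lowercased symbol; duplicate rows merge by summing
  copy numbers; rows blank in both identities are dropped with a
  warning. Genomes present in annotations but absent from the metadata
  are simply never called (rows are driven by the metadata table).
* Artifact contracts are fixed filenames (`trait_matrix.tsv`,
  `evidence.json`, `subgroup_summary.tsv`, `cooccurrence.tsv`,
  `ordering.json`, `truth.json`, `recovery.tsv`/`.json`, `run.log`) so
  downstream tooling and the tests can rely on them; TSVs never carry
  comment lines.

## Known limitations

* Calls are binary and completeness-agnostic: a 60%-complete genome is
  judged by the same rules as a 95%-complete one, so false negatives
  concentrate in low-completeness genomes (the simulator quantifies
  exactly this). No partial-credit or completeness-adjusted scores are
  produced by design.
* The rulebook matches annotations; it cannot rescue genes the annotator
  missed or mislabeled, and KO lists are only as good as their curation.
* Mutual exclusivity is descriptive; with few genomes the flag is
  unstable (one genome flips it), which is why the 2×2 counts and the
  hypergeometric tail are always reported alongside.
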