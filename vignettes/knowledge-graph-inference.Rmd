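---
title: "Knowledge-graph construction, rule-based closure and regulatory-candidate queries"
author: "regkb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph construction, rule-based closure and regulatory-candidate queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regkb)
```

## The model

`regkb` treats integrated biological knowledge as a typed directed graph:
nodes are CURIE-identified terms (ontology classes, proteins, genes,
pathways, reified interactions, modified residues, taxa; the category is a
pure function of the identifier namespace), and edges are
subject–predicate–object *statements* whose predicates are relation types
carrying inference-relevant attributes — transitivity, reflexivity,
declared superrelations, pairwise compositions, and *priority over
subsumption*. Each statement is tagged `asserted` (read from an input
file) or `inferred` (produced by a rule), and the `(subject, predicate,
object)` triple is unique: when the same triple arrives both ways, the
asserted version wins, so inference can never shadow direct evidence.

Construction proceeds protein-centrically. A small upper-level ontology
(about fifteen terms, single-rooted) glues together ontology fragments:
sub-domain fragments are carved out of a source ontology by reverse
reachability over `is_a`/`part_of` and linked under the 'Biological
Process' anchor with a single added `is_a` statement. Nested sub-domain
roots therefore give nested graphs — the narrower statement set is always
a subset of the wider one. *Core proteins* are those with at least one
Biological Process annotation to a seed term; one association round then
adds interaction partners, pathway co-members and orthologs of the core.
We deliberately do not iterate this round to a fixpoint: a single round
keeps the selection interpretable and the graph size bounded, and a
`rounds` argument exposes the wider variant for users who want it.
Population adds one asserted statement per record — `participates_in`,
`has_function`, `located_in` for the three annotation aspects,
`member_of_pathway`, `encoded_by` (gene nodes exist only when the protein
record supplies one), `has_modified_residue`, `in_taxon` — and reifies
each interaction as a node with two `has_participant` statements and one
`has_interaction_type` statement. Reification is what lets queries
distinguish a *direct interaction* (`MI:0407`) from a *physical
association* (`MI:0914`) partner.

Identifier hygiene is a filter, not a repair: records whose identifiers
cannot be mapped to a canonical protein CURIE are dropped and counted,
never guessed. Regulatory-edge target genes are the one exception — they
stay as upper-cased symbols when no gene mapping is available, because
curated TF–target resources are symbol-keyed.

## The closure

The total closure (graph name suffixed `-tc`) forward-chains five rules to
fixpoint. Termination is guaranteed because nodes and relations are fixed,
so the statement space is finite; the result is order-independent because
rules only ever *add* statements (set semantics, no negation or
retraction). Two semantics choices deserve comment:

* **Priority over subsumption** is implemented in both directions —
  object generalisation (`x r y ∧ y is_a z ⇒ x r z`) and subject
  specialisation (`w is_a x ∧ x r y ⇒ w r y`) — each independently
  toggleable and both on by default. Object generalisation is what makes
  an annotation to a specific process retrievable from every ancestor
  process (true-path-style propagation); subject specialisation is its
  mirror for class-level statements. Annotation relations
  (`participates_in`, `has_function`, `located_in`) carry the flag by
  default.
* **Reflexivity is domain-restricted**: only nodes already appearing in a
  statement of a reflexive relation gain the `x r x` loop. Universal
  reflexivity would add a quadratic bulk of loops with no query value.

Each inferred statement records the first rule that produced it; ties are
broken by the fixed application order (reflexivity, superrelation,
priority, transitivity, composition). The per-rule counts in a
`ClosureResult` are tabulated from these tags, so re-closing an already
closed graph is exactly idempotent. The fold increase
`(asserted + inferred) / asserted` is reported but is a property of the
input data, not of the method — hierarchy-rich graphs close harder, and
full-scale resource releases close harder than desk-scale fixtures. The
synthetic default closes around four-fold (see
`scripts/acceptance.R`); no particular factor is asserted as an
invariant beyond it exceeding 1 whenever a transitive hierarchy exists.

Relation metadata travels in a TSV config
(`inst/extdata/relations.tsv`): flags per relation, `;`-separated
superrelations, and compositions as `second>produces` pairs. The default
table ships one composition (`part_of ∘ part_of → part_of`) and the
`directly_*` sub-relations of the three annotation predicates, for sources
that distinguish direct from propagated assignments.

## Queries and provenance

Query templates are boolean trees over two selector atoms. A *term
selector* matches proteins linked by a predicate to a term or (by
default) any of its `is_a` descendants — the default mirrors querying the
closed graph, where descendant annotations have been propagated anyway. An
*interaction selector* matches co-participants of a reified interaction
with a given partner and/or type. The five built-in templates are fully
parameterised reconstructions of the published use-case queries; their
default bindings are the printed identifiers (CREB1 `UniProtKB:P16220`,
TCF7L2 `UniProtKB:Q9NQB0`, and the GO/MI/KEGG clause terms).

Two clause structures were genuinely open and are fixed as follows. Q4 is
*central term AND (union of degradation clauses)* — the use-case prose
asks for NFκB down-regulators *that also* have proteasomal-degradation
functions; a pure-union reading is exposed behind `q4Mode = "union"`. Q2
is the union of the two negative-regulation terms, with an optional
interacts-with-CREB1 conjunct (`q2InteractionConjunct`), since the source
material does not state whether the repressor query mirrored Q1's
interaction clauses.

Provenance partitioning evaluates a template three ways: on asserted
statements only, on inferred statements only, and on the full closure.
Hits are classed `asserted_only`, `both`, or `inferred_only`; the third
class is defined as *everything unreachable without inference* (closure
hits minus asserted hits), which also captures conjunctive matches that
mix asserted and inferred statements. The classes are disjoint and sum to
the closure hit count.

## What the synthetic generator emulates — and what it does not

`generateKB()` produces a complete fixture world from one seed: a
single-rooted random `is_a` DAG (each new term picks parents uniformly
among existing terms), background proteins with 1–3 annotations each,
typed interactions, pathway memberships, orthology pairs, gene/residue
info and regulatory edges — emitted in the same formats the readers
consume (GAF 2.x, PSI-MI TAB 2.5, OBO, TSV), so the generator also
exercises the I/O layer end-to-end. Defaults (60 terms, 40 proteins, 30
interactions, 5 pathways, 25 regulatory edges, 5 plants) keep a single
build-and-close cycle well under a second while leaving a multi-level
hierarchy for propagation to act on.

The real query-term anchors are injected as *leaves* of the synthetic DAG,
and background records never reference them. That separation is the load-
bearing design choice: planted regulators are the only proteins that can
satisfy a template, so recall and precision against the plant ledger are
exactly 1.0 whenever the engine is correct, and any chance match is a real
defect, not noise. Plants flagged *inferred-only* assert their term
clauses through `directly_*` sub-relations, which the built-in templates
cannot see until the superrelation rule fires — note that annotating a
descendant term would *not* be inferred-only here, because descendant-
aware selectors already match it on the asserted graph.

The generator does not emulate realistic annotation density, hub-like
interaction degree distributions, evidence-code structure, or expression
dynamics (expression evidence is boolean by design, as the prioritization
stage consumes calls, not measurements). Passing the planted-recovery
suites therefore demonstrates the correctness of integration, closure and
query logic — not robustness to the noise and incompleteness of real
resources, where precision depends on curation quality rather than graph
mechanics.

## Prioritization

Candidates from use-case queries are classified with strict precedence:
documented network members are `a` regardless of other evidence; among the
rest, expression-responsive candidates form `b1`, split into `b1i` (known
responsive to other stimuli — the most promising novel candidates) and
`b1j`; non-responsive candidates are `b_other`. Priorities are explicit
integers (0–3) so sorting is total and stable. Shared target genes are
`(novel, core, target)` joins over the regulatory-edge table; a target is
a *candidate* when expressed and responsive in the model system, and
*dual-supported* when its novel regulator is itself expressed. Gene
symbols match case-insensitively throughout, and absence from an evidence
table always means `FALSE`, never missing.

The packaged worked example (`table2Fixture()`, transcribed printed
values) drives the in-paper checks: 20 shared-target rows over 19 unique
genes, five candidate targets, two dual-supported.

## Numerical and degenerate-input choices

* Statement deduplication keys on `(s, p, o)` only; provenance resolves
  asserted-first. Merging is associative and commutative up to
  statement-set equality; conflicting relation metadata across merged
  graphs is an error, never silently resolved.
* All serialisations (OBO, N-Triples, fixture bundles) sort output
  lexicographically, so identical inputs produce byte-identical files.
* Empty inputs are legal everywhere: an empty OBO stream parses to an
  empty graph, an empty core set extends to an empty set, a rule with no
  eligible relations contributes nothing, and a closure without
  rule-bearing relations reports fold increase 1.0.
* Malformed reader rows are skipped and counted (`attr(x, "skipped")`),
  not repaired; schema mismatches in TSV tables name the missing columns.

## Test-suite problem sizes

The closure correctness battery compares the engine against an
independent dense-matrix naive-fixpoint oracle on 100 seeded random
graphs (10–200 nodes, up to 600 statements), checking set equality,
monotonicity and idempotence per seed, plus the closed-form transitive-
chain count `C(L+1,2) − L`. Planted retrieval runs all five templates
across 20 seeds each on 40-term/25-protein worlds. These sizes were chosen
to exercise multi-step propagation and all rule interactions while keeping
the whole suite comfortably fast on a laptop.

## Known limitations

* No OWL semantics beyond the five rules: no negation, cardinality,
  disjointness, or retraction/truth maintenance.
* The in-process store targets desk-scale graphs (10⁴–10⁵ statements);
  it is not a triple-store replacement and offers no SPARQL endpoint —
  N-Triples export is the hand-off point to one.
* Orthology is consumed, not predicted; differential-expression calling
  is out of scope (boolean responsiveness calls are inputs).
* Literature evidence (`b1i` flags) is an input table; no text mining.
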