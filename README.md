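# hypeval

Rule-based evaluation of biological event hypotheses against a curated
knowledge base, with ontology subsumption, logical score aggregation and
linked evaluation reports.

Molecular biologists phrase working hypotheses as combinations of typed
events — "Gal4p induces *GAL1* expression", "Gal2p transports galactose
into the cell" — and settling them against prior knowledge means
coordinating many partial, sometimes contradictory observations. `hypeval`
mechanizes that procedure for a knowledge base of molecular-event facts,
demonstrated on the yeast galactose (GAL) regulatory network. It is aimed
at computational biologists who want a transparent, fully inspectable
alternative to black-box scoring: every number in a report traces back to
a named rule applied to a specific fact.

## The model

A **fact** is an event record: one of seven event types (protein–protein
binding, protein–nucleic-acid binding, activation, inhibition, induction,
repression, transport), a relation verb, an actor and a target (CURIEs,
typed with CHEBI/SO ontology terms and annotated with GO functions), an
optional GO cellular location, a genetic perturbation context (`wt` =
wild type), an optional ECO evidence code, a source, and a negation flag
for events known *not* to occur.

A **hypothesis** is a tree of hypothesized events under n-ary AND/OR/XOR
operators, e.g. `e1 OR (e2 AND e3) OR (e4 AND e5 AND e6)`.

Each event type has an ordered **rule set** scoring how far a candidate
fact deviates from the ideal supporting observation. For induction:
actor typed protein/RNA (±1), target typed gene (±1), actor has
transcription factor activity (+1/0), location nucleus (±1), relation
"induce" (±1), event negated in the knowledge base (0/−2). The event
score is the best candidate's total as a fraction of the maximum
(here 5): candidates are facts matching the event's actor, target and
context, with type/relation/location deviations penalized rather than
filtered. An event with no candidate data is **undecidable**.

Scores aggregate bottom-up: AND sums (undecidable if any child is),
OR takes the maximum over decidable children (undecidable only if all
are), XOR passes through the single supported child (else 0). Entity and
type matching is subsumption-aware — a query restricted to "RNA" also
matches entities typed "messenger RNA" — via a reflexive-transitive is-a
store over GO/SO/CHEBI/ECO excerpts.

## Worked example

```r
library(hypeval)

fx <- build_gal_fixture()      # packaged GAL knowledge base + ontology
rulesets <- load_rulesets()    # shipped per-event-type rule sets

e1 <- hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "e1")
score_event(e1, fx$kb, rulesets, fx$store)
#> <event_score> e1: 4/5 = 0.8 (best fact hkb:f01)
#>   actor-type: yes -> +1
#>   target-type: yes -> +1
#>   actor-function: no -> +0
#>   location: yes -> +1
#>   relation: yes -> +1
#>   negation: yes -> +0
```

Gal4p is typed protein (+1), *GAL1* is a gene (+1), the fixture's Gal4p
carries no transcription-factor-activity annotation (0), the fact is
located in the nucleus (+1) with relation "induce" (+1) and is not
negated (0): 4 of 5 points, normalized **0.8**.

The worked six-event hypothesis `OR(e1, AND(e2, e3), AND(e4, e5, e6))`,
where e5 hypothesizes Gal80p inhibiting Gal4p under GAL3 over-expression
(a context with no data):

```r
h <- parse_hypothesis(gal_fixture_paths()[["induction_hypothesis"]])
evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
#> <evaluation_report> hqd:hypothesis-gal-induction
#>   overall: 1.6 (decidable)
#>   e1: 4/5 = 0.8 via hkb:f01
#>   e2: 4/5 = 0.8 via hkb:f02
#>   e3: 4/5 = 0.8 via hkb:f03
#>   e4: 4/5 = 0.8 via hkb:f03
#>   e5: undecidable
#>   e6: 4/5 = 0.8 via hkb:f04
```

The third branch is undecidable (AND with an undecidable conjunct), so
the overall score is the best decidable branch: e2 + e3 = **1.6**. The
single-event galactose-transport hypothesis scores exactly **1** (an
ideal candidate). Question answering uses the same matcher with unbound
variables:

```r
res <- query_events(
  event_pattern(event_type = "protein-nucleic-acid-binding",
                actor = ref_unbound("?a", "chebi:36080"),
                target = ref_instance("sgd:GAL1"), context = "wt"),
  fx$kb, fx$store)
res$bindings
#>           ?a fact_ids
#> 1  sgd:Mig1p  hkb:f07
#> 2 sgd:Spt15p  hkb:f08
#> 3  sgd:Gal4p  hkb:f09
```

— the three proteins known to bind the *GAL1* promoter in wild type.
Reports serialize to JSON (`report_to_json()`) and to linked N-Triples
(`report_to_ntriples()`) in which scores point at the facts behind them,
navigable in both directions.

A thin command-line wrapper ships at `inst/cli/hypeval`
(`evaluate | query | fixture | validate`); see `hypeval --help`.

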