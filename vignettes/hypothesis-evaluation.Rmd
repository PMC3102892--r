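---
title: "Rule-based evaluation of biological event hypotheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based evaluation of biological event hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hypeval)
```

## The problem

A molecular biologist's working hypothesis — "Gal4p induces *GAL1*
expression", "Gal2p transports galactose into the cell" — is rarely settled
by a single lookup. Evaluating it against what is already known means
finding candidate observations, judging how well each one matches the
hypothesized event (same participants? same relation? same cellular
compartment? contradicted anywhere?), and combining judgements across the
logical structure of a multi-part hypothesis. `hypeval` mechanizes this
procedure over a curated knowledge base of typed molecular events, using
the yeast galactose (GAL) regulatory network as its worked domain.

Three layers make up the package:

1. **A knowledge model.** Facts are event records with seven possible types
   (protein–protein binding, protein–nucleic-acid binding, activation,
   inhibition, induction, repression, transport), an actor, a target, an
   optional GO cellular-component location, a genetic perturbation context
   (`"wt"` = wild type), an optional ECO evidence code, a source citation,
   and a boolean negation flag asserting that the event does *not* occur
   under those conditions. Participants are entities identified by CURIEs,
   typed with CHEBI/SO terms and annotated with GO functions;
   `owl:sameAs` identifier groups are resolved to a canonical id at load
   time. A small ontology store answers reflexive–transitive is-a
   subsumption queries, so a query for "RNA" also retrieves entities typed
   "messenger RNA".
2. **A scoring engine.** Each event type has an ordered rule set; rules
   compare a candidate fact against the profile of the ideal supporting
   observation and award or subtract points. An event's score is the best
   candidate's point total as a fraction of the rule set's maximum.
3. **Logical aggregation.** Hypotheses are trees of events under n-ary
   AND / OR / XOR operators; event scores propagate bottom-up with explicit
   undecidability semantics.

## Scoring model

The induction ("induce") rule set is:

| rule           | condition                                              | true | false |
|----------------|--------------------------------------------------------|-----:|------:|
| actor-type     | actor typed protein (chebi:36080) or RNA (chebi:33697) |   +1 |    -1 |
| target-type    | target typed gene (so:0000236)                         |   +1 |    -1 |
| actor-function | actor has transcription factor activity (go:0003702)   |   +1 |     0 |
| location       | event located in the nucleus (go:0005634)              |   +1 |    -1 |
| relation       | relation verb is "induce"                              |   +1 |    -1 |
| negation       | fact's negation flag agrees with the claim             |    0 |    -2 |

The maximum is the sum of the positive contributions, `max(points_if_true,
0)` per rule — 5 here, since the negation rule can only penalize. The
actor-function rule's asymmetry (+1/0 rather than ±1) is preserved as
printed: a missing function annotation is weaker support, not
counter-evidence. An explicit contradiction (the event negated in the
knowledge base) costs 2 points, heavier than any single deviation.

```{r}
fx <- build_gal_fixture()
rulesets <- load_rulesets()
e1 <- hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "e1")
score_event(e1, fx$kb, rulesets, fx$store)
```

Only the induction rule set is grounded verbatim in its published source;
the other six event types are **reconstructions** built from the same
six-condition template with event-appropriate arguments (for transport:
transporter activity, membrane location, relation "transport"; and so on).
They are marked `"reconstructed"` in
`system.file("extdata", "rulesets-default.json", package = "hypeval")` and
are fully overridable through `load_rulesets()`. An `evidence_is` condition
is implemented for weighting ECO evidence codes but appears in no default
rule set, because the default knowledge base does not annotate evidence
consistently enough to support it.

### Candidate retrieval

Candidates for a hypothesized event are the facts whose **actor, target
and perturbation context** match; event type, relation, location and
negation are deliberately *not* filtered at retrieval. The relation rule
("+1 if the relation is 'induce', else −1") presupposes candidates whose
relation may differ from the hypothesized one — deviations are penalized by
rules, not silently excluded. Context matching is exact-token: an event
hypothesized under "GAL3 over-expressed" never matches wild-type data,
which is precisely what makes such an event undecidable when no data from
that perturbation exists. When several candidates exist, the
highest-scoring one is selected and linked to the event; ties break on the
lexicographically smallest fact id (C collation) for determinism.

### Undecidability and aggregation

An event with no candidates is **undecidable** — there is no data either
way — and undecidability propagates:

* **AND** (combined score): undecidable if *any* child is; otherwise the
  sum of child scores.
* **OR** (maximum score): undecidable only if *all* children are;
  otherwise the maximum over decidable children — decidable branches are
  simply preferred.
* **XOR** (exclusive): the source material states only the intent ("one of
  the events must be true, else they are both false"). The package's
  reading: a child is *supported* iff decidable with a positive score; the
  XOR is undecidable if any child is undecidable (a hidden second truth
  could falsify exclusivity), takes the supported child's score when
  exactly one child is supported, and is 0 otherwise. This is a design
  decision of this implementation, chosen as the deterministic reading
  closest to the stated intent.

The overall hypothesis score is the root aggregate's value, unnormalized —
a conjunction of two well-supported events scores 1.6, rewarding richer
hypotheses. Reports also carry a clearly auxiliary `mean_event_score`
(mean of decidable per-event scores), the alternative that would favour
simpler hypotheses instead; it plays no role in the headline score. A
decidable score can be negative when all candidates contradict the
hypothesis; values are reported unclamped.

```{r}
h <- parse_hypothesis(gal_fixture_paths()[["induction_hypothesis"]])
evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
```

### Hypothesized non-events

`negated_claim = TRUE` hypothesizes that an event does *not* occur. The
negation rule's polarity then flips: a negated fact (agreement) earns +2,
a plain fact (contradiction of the non-claim) earns −2, with all other
rules unchanged. So that scores remain fractions of an attainable maximum
in [−1, 1], the effective maximum for a negated claim adds the flipped
bonus (5 + 2 = 7 under the default sets). Both the flip and the adjusted
maximum are reconstructions — the source material discusses storing
negated facts but not scoring negated claims — and are documented here as
this package's choice.

## Exchange formats

* **Knowledge base**: a frozen 10-column TSV dialect (`fact_id`,
  `event_type`, `relation`, `actor`, `target`, `location`, `context`,
  `evidence`, `negated`, `source`; empty string = absent; context defaults
  to `wt`), chosen so that serialization round-trips bit-exactly; and a
  strict N-Triples form using a small `hq:` predicate vocabulary
  (`hq:event-type`, `hq:relation`, `hq:actor`, `hq:target`, `hq:location`,
  `hq:context`, `hq:evidence`, `hq:is-negated`, `hq:source`;
  `hq:has-type`/`hq:has-function`/`owl:sameAs` for entities). The
  published system's triple-store schema is not public, so this vocabulary
  is a documented reconstruction; unrecognized predicates are ignored with
  a count.
* **Ontology**: 3-column TSV (`id`, `label`, pipe-separated `parents`,
  optional `part_of`) or N-Triples with `rdfs:subClassOf`. Parthood is a
  separate edge layer queried by `has_part_transitive()`, never mixed into
  `is_a()` — mixing edge semantics would silently change rule outcomes.
  Dangling parents are auto-created as bare roots with a warning
  (ontology excerpts are routinely partial); cycles are a hard error.
* **Hypotheses**: JSON documents (schema shipped in `extdata/`), with an
  N-Triples serializer for linked-data parity. JSON was chosen as the
  authoring format because hand-writing RDF hypotheses is error-prone;
  operators are n-ary (≥ 2 children) as the worked three-child groups
  require. The `hq:` local names used in the hypothesis and report graphs
  are reconstructed from prose descriptions of the evaluation vocabulary
  and are labelled as such.
* **Reports**: JSON (full rule-by-rule detail) and N-Triples. In the
  linked-data form the evaluation instance `hq:is-about` the hypothesis
  and `hq:has-part` a single `hq:hypothesis-score`; operator nodes become
  `hq:combined-event-score` / `hq:maximum-event-score` /
  `hq:exclusive-event-score` nodes; each decidable `hq:event-score`
  `hq:is-about` its best supporting fact and `hq:has-part` its
  `hq:rule-score` nodes, so the graph is navigable from data to hypothesis
  and back. Report instance ids are deterministic hashes of (hypothesis
  id, knowledge-base digest, rule-set digest), so regenerated reports are
  reproducible; timestamps are UTC ISO-8601 and excluded from the id.

## The GAL fixture and the random generator

`build_gal_fixture()` loads the packaged GAL knowledge base: 13 entities
and 9 facts covering the induction circuit (Gal4p→GAL1, Gal3p→GAL2,
Gal4p→GAL7, Gal80p→GAL7, each 4/5 under the induce rules), a wild-type
Gal80p⊣Gal4p inhibition fact (deliberately *not* replicated under the
"GAL3 over-expressed" context, leaving that event undecidable), an ideal
galactose-transport fact for Gal2p, and the three GAL1-promoter binders
(Mig1p, Spt15p with evidence `eco:0000008`, Gal4p — evidence blanks
preserved as blanks). Annotations encode the worked scoring traces, not
curated SGD biology: most notably Gal4p carries no `go:0003702` function
annotation so the actor-function rule scores 0, although real Gal4p is of
course a transcription factor. The fixture is synthetic in that specific,
documented sense.

`gen_random_kb()` drives the property tests. Defaults (25 entities, 60
facts, negation rate 0.05, annotation completeness 0.7) are chosen as a
plausible small curated corpus: negated assertions are rare in curated
event data, and annotation coverage is substantial but incomplete. The
generator emulates the *structure* of real event data — typed
participants, partial annotations, occasional contradiction, a minority
non-wild-type context — but not its biology: entity identities, the
relation vocabulary outside the canonical verbs, and realistic annotation
correlations (e.g. transcription factors clustering in the nucleus) are
not modelled. Passing property tests therefore certify the engine's
algebra (oracle equivalence, monotonicity, round-trips), not biological
plausibility of conclusions on real corpora.

## Numerical and degenerate-input choices

* Scores are rationals computed in double precision; raw sums and maxima
  are integers, so normalized values like 0.8 and 1.6 are exact.
* CURIE prefixes are lower-cased on input; local parts are
  case-significant (Bio2RDF-style identifiers). All string ordering used
  for canonical ids, tie-breaks and serialization is C-collated,
  independent of the session locale.
* A fact and its negation may coexist; `validate_kb()` reports the pair
  as informational, never an error, since representing both assertions is
  the point of the negation flag.
* Empty knowledge bases are valid (all queries return empty; all events
  undecidable). Operator nodes require ≥ 2 children; single-child
  operators are schema errors rather than silently collapsed.
* The scoring invariant `raw ≤ max_score` holds for every decidable event,
  including negated claims via the effective-maximum adjustment.

## Problem sizes used by the test suite

The suite verifies subsumption against a brute-force BFS on random DAGs of
50 terms (all ordered pairs), query matching and event scoring against
exhaustive scans on random knowledge bases of up to 200 facts, and
aggregation against direct recursion on random trees of depth ≤ 4 — sizes
at which the independent oracles are unambiguous and the full suite runs
in seconds on a single CPU.

## Limitations

* No OWL reasoning (equivalence, restrictions, disjointness) and no
  loading of full GO/CHEBI releases; the ontology layer is an is-a /
  part-of excerpt store.
* No live SPARQL endpoint or HTTP dereferencing; the native pattern
  matcher implements the query-template semantics in-memory.
* Six of the seven default rule sets are reconstructions; users with
  better domain grounding should override them via `load_rulesets()`.
* Scoring is rule-based and empirical, not probabilistic; no uncertainty
  is attached to scores.
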