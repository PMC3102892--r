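fx <- build_gal_fixture()

test_that("match_entity honours instance identity and type subsumption", {
  kb <- fx$kb
  # an mRNA-typed entity satisfies a restriction to the more general RNA
  kb$entities[["sgd:Mrna1"]] <- list(
    id = "sgd:Mrna1", name = "mRNA1", types = "chebi:33699",
    functions = character(), same_as = character()
  )
  expect_true(match_entity(ref_type("chebi:33697"), kb$entities[["sgd:Mrna1"]],
                           fx$store, kb))
  expect_true(match_entity(ref_instance("sgd:Gal4p"), kb$entities[["sgd:Gal4p"]],
                           fx$store, kb))
  expect_false(match_entity(ref_instance("sgd:Gal4p"), kb$entities[["sgd:Gal80p"]],
                            fx$store, kb))
  # aliases compare equal to their canonical id
  expect_true(match_entity(ref_instance("sgd:S000006169gp"),
                           kb$entities[["sgd:Gal4p"]], fx$store, kb))
})

promoter_pattern <- function(actor_type = "chebi:36080") {
  event_pattern(
    event_type = "protein-nucleic-acid-binding",
    actor = ref_unbound("?a", actor_type),
    target = ref_instance("sgd:GAL1"),
    context = "wt",
    evidence = "?e"
  )
}

test_that("the GAL1 promoter-binding question returns its three known binders", {
  res <- query_events(promoter_pattern(), fx$kb, fx$store)
  expect_setequal(res$bindings[["?a"]], c("sgd:Mig1p", "sgd:Spt15p", "sgd:Gal4p"))
  # evidence variable: the Spt15p fact carries the curated-database code,
  # the other rows are blank
  expect_equal(res$bindings[["?e"]][res$bindings[["?a"]] == "sgd:Spt15p"],
               "eco:0000008")
  expect_equal(res$bindings[["?e"]][res$bindings[["?a"]] == "sgd:Mig1p"], "")
  tsv <- query_to_tsv(res)
  expect_equal(tsv[1], "Actor\tTarget\tPerturbation Context\tEvidence Type")
  expect_length(tsv, 4L)
})

test_that("an RNA-restricted actor matches none of the promoter binders", {
  res <- query_events(promoter_pattern("chebi:33697"), fx$kb, fx$store)
  expect_equal(nrow(res$facts), 0L)
  # agrees with an exhaustive scan
  expect_equal(oracle_query_fact_ids(promoter_pattern("chebi:33697"),
                                     fx$kb, fx$store), character(0))
})

test_that("any pattern on an empty KB returns an empty result", {
  kb <- kb_from_tables(fx$kb$entities, fx$kb$facts[0, ], fx$store)
  res <- query_events(promoter_pattern(), kb, fx$store)
  expect_equal(nrow(res$facts), 0L)
  expect_equal(nrow(res$bindings), 0L)
})

test_that("a fully-wildcard pattern is rejected", {
  expect_error(event_pattern(), "at least one")
})

test_that("candidate retrieval filters actor+target+context only", {
  e1 <- hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "e1")
  cands <- candidates_for(e1, fx$kb, fx$store)
  # includes the induction fact AND the promoter-binding fact for the same
  # pair: relation/event-type deviations are scored, not excluded
  expect_setequal(cands$fact_id, c("hkb:f01", "hkb:f09"))

  # context is exact-token: the over-expression context has no data even
  # though the same pair is attested in wild type
  e5 <- hyp_event("inhibition", "inhibit", "sgd:Gal80p", "sgd:Gal4p",
                  label = "e5", context = "GAL3 over-expressed")
  expect_equal(nrow(candidates_for(e5, fx$kb, fx$store)), 0L)

  # directional: swapping actor and target matches nothing
  rev <- hyp_event("induction", "induce", "sgd:GAL1", "sgd:Gal4p", label = "r")
  expect_equal(nrow(candidates_for(rev, fx$kb, fx$store)), 0L)

  # unbound refs cannot be scored
  ub <- hyp_event("induction", "induce", ref_unbound("?a"), "sgd:GAL1",
                  label = "u")
  expect_error(candidates_for(ub, fx$kb, fx$store), "unbound")
})

test_that("query matching equals a brute-force scan on random KBs", {
  withr::local_seed(11)
  patterns <- list(
    event_pattern(event_type = "transport"),
    event_pattern(relation = "bind", context = "wt"),
    event_pattern(actor = ref_unbound("?a", "chebi:36080"),
                  target = ref_unbound("?t", "so:0000236")),
    event_pattern(location = "go:0005575"),
    event_pattern(negated = TRUE),
    event_pattern(evidence = "eco:0000000", context = "wt"),
    event_pattern(event_type = "induction", target = ref_type("so:0000110"))
  )
  for (seed in 1:3) {
    kb <- gen_random_kb(fixture_spec(seed = seed, n_entities = 20,
                                     n_facts = 150, negation_rate = 0.2,
                                     annotation_completeness = 0.6),
                        fx$store)
    for (p in patterns) {
      got <- sort(query_events(p, kb, fx$store)$facts$fact_id)
      expect_identical(got, oracle_query_fact_ids(p, kb, fx$store))
    }
  }
})

test_that("widening a type restriction to an ancestor never shrinks results", {
  withr::local_seed(12)
  kb <- gen_random_kb(fixture_spec(seed = 5, n_facts = 120), fx$store)
  chains <- list(
    c("chebi:36080", "chebi:23367", "chebi:24431"),
    c("so:0000236", "so:0000110")
  )
  for (chain in chains) {
    prev <- character(0)
    for (ty in chain) {
      res <- query_events(
        event_pattern(target = ref_type(ty)), kb, fx$store
      )$facts$fact_id
      expect_true(all(prev %in% res))
      prev <- res
    }
  }
})

test_that("binding rows are deduplicated on the full tuple with witnesses", {
  # Gal4p acts on GAL1 in two facts (induction f01 and promoter binding
  # f09): one binding row for ?a = Gal4p, witnessed by both fact ids
  res <- query_events(
    event_pattern(actor = ref_unbound("?a"),
                  target = ref_instance("sgd:GAL1"), context = "wt"),
    fx$kb, fx$store
  )
  expect_equal(nrow(res$facts), 4L)
  expect_equal(nrow(res$bindings), 3L)
  gal4 <- res$bindings$fact_ids[res$bindings[["?a"]] == "sgd:Gal4p"]
  expect_equal(gal4, "hkb:f01,hkb:f09")
})
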