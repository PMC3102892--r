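fx <- build_gal_fixture()
rulesets <- load_rulesets()

e1 <- hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "e1")

test_that("the shipped default config has the printed induce rule set", {
  expect_setequal(names(rulesets),
                  c("protein-protein-binding", "protein-nucleic-acid-binding",
                    "activation", "inhibition", "induction", "repression",
                    "transport"))
  ind <- rulesets$induction
  expect_length(ind$rules, 6L)
  expect_equal(ind$max_score, 5L)
  expect_equal(ind$provenance, "verbatim")
  # every other set is flagged as a reconstruction
  for (nm in setdiff(names(rulesets), "induction")) {
    expect_equal(rulesets[[nm]]$provenance, "reconstructed")
  }
})

test_that("rule-set schema violations are rejected", {
  expect_error(load_rulesets(list(rulesets = list())), "rulesets")
  expect_error(
    load_rulesets(list(rulesets = list(list(event_type = "induction",
                                            rules = list())))),
    "empty rules"
  )
  expect_error(
    load_rulesets(list(rulesets = list(list(
      event_type = "induction",
      rules = list(list(id = "x", condition = "actor_smells_like",
                        args = list("a:1"), points_if_true = 1,
                        points_if_false = -1))
    )))),
    "condition"
  )
  # only-penalty rule sets have non-positive maximum
  expect_error(
    load_rulesets(list(rulesets = list(list(
      event_type = "induction",
      rules = list(list(id = "x", condition = "negated_in_kb", args = list(),
                        points_if_true = 0, points_if_false = -2))
    )))),
    "max_score"
  )
})

test_that("individual rules award the printed points on the e1 candidate", {
  fact <- as.list(fx$kb$facts[fx$kb$facts$fact_id == "hkb:f01", ])
  rules <- rulesets$induction$rules
  pts <- vapply(rules, function(r) {
    apply_rule(r, e1, fact, fx$kb, fx$store)$points
  }, 0L)
  # actor protein: +1; target gene: +1; no transcription-factor-activity
  # annotation: 0; nucleus: +1; relation induce: +1; not negated: 0
  expect_equal(pts, c(1L, 1L, 0L, 1L, 1L, 0L))

  negfact <- fact
  negfact$negated <- TRUE
  neg <- apply_rule(rules[[6]], e1, negfact, fx$kb, fx$store)
  expect_false(neg$fired)
  expect_equal(neg$points, -2L)
})

test_that("e1 scores 4 of 5 (0.8) and e5 is undecidable", {
  s <- score_event(e1, fx$kb, rulesets, fx$store)
  expect_equal(s$status, "decidable")
  expect_equal(s$raw, 4L)
  expect_equal(s$max_score, 5L)
  expect_equal(s$normalized, 0.8)
  expect_equal(s$best_fact, "hkb:f01")
  expect_length(s$rule_scores, 6L)

  e5 <- hyp_event("inhibition", "inhibit", "sgd:Gal80p", "sgd:Gal4p",
                  label = "e5", context = "GAL3 over-expressed")
  s5 <- score_event(e5, fx$kb, rulesets, fx$store)
  expect_equal(s5$status, "undecidable")
  expect_true(is.na(s5$raw) && is.na(s5$normalized) && is.na(s5$best_fact))
  expect_length(s5$rule_scores, 0L)
})

test_that("a missing rule set for the event type is an error", {
  expect_error(score_event(e1, fx$kb, rulesets["transport"], fx$store),
               "no rule set")
})

test_that("an ideal candidate normalizes to exactly 1", {
  ev <- hyp_event("transport", "transport", "sgd:Gal2p", "chebi:28260",
                  label = "t1")
  s <- score_event(ev, fx$kb, rulesets, fx$store)
  expect_equal(s$raw, s$max_score)
  expect_equal(s$normalized, 1)
})

test_that("a negated candidate matching rules 1,2,4,5 scores 2/5 = 0.4", {
  facts <- fx$kb$facts[fx$kb$facts$fact_id == "hkb:f01", ]
  facts$negated <- TRUE
  kb <- kb_from_tables(fx$kb$entities, facts, fx$store)
  s <- score_event(e1, kb, rulesets, fx$store)
  expect_equal(s$raw, 2L)
  expect_equal(s$normalized, 0.4)
})

test_that("overriding the actor-function rule to -1 lowers e1 to 0.6", {
  cfg <- jsonlite::fromJSON(default_rulesets_path(), simplifyVector = FALSE)
  idx <- which(vapply(cfg$rulesets, `[[`, "", "event_type") == "induction")
  cfg$rulesets[[idx]]$rules[[3]]$points_if_false <- -1
  rs2 <- load_rulesets(cfg)
  expect_equal(rs2$induction$max_score, 5L)
  s <- score_event(e1, fx$kb, rs2, fx$store)
  expect_equal(s$raw, 3L)
  expect_equal(s$normalized, 0.6)
})

test_that("a hypothesized non-event flips the negation rule's polarity", {
  facts <- fx$kb$facts[fx$kb$facts$fact_id == "hkb:f01", ]
  facts$negated <- TRUE
  kb <- kb_from_tables(fx$kb$entities, facts, fx$store)
  not_e1 <- hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1",
                      label = "n1", negated_claim = TRUE)
  s <- score_event(not_e1, kb, rulesets, fx$store)
  # rules 1,2,4,5 (+4), rule 3 (0), flipped negation bonus (+2) over an
  # effective maximum of 5 + 2
  expect_equal(s$raw, 6L)
  expect_equal(s$max_score, 7L)
  expect_equal(s$normalized, 6 / 7)
  # a plain supporting fact contradicts the non-event claim: rules 1,2,4,5
  # still award +4 but the agreement bonus becomes the -2 penalty
  s2 <- score_event(not_e1, fx$kb, rulesets, fx$store)
  expect_equal(s2$raw, 2L)
  expect_equal(s2$normalized, 2 / 7)
})

test_that("best-candidate selection is monotone in added facts", {
  withr::local_seed(21)
  for (seed in 1:3) {
    kb_full <- gen_random_kb(fixture_spec(seed = seed, n_entities = 10,
                                          n_facts = 40,
                                          negation_rate = 0.15,
                                          annotation_completeness = 0.5),
                             fx$store)
    kb_part <- kb_from_tables(kb_full$entities,
                              kb_full$facts[1:20, ], fx$store)
    for (i in 1:10) {
      f <- as.list(kb_part$facts[sample(nrow(kb_part$facts), 1L), ])
      ev <- hyp_event(f$event_type, f$relation, f$actor, f$target,
                      label = "m", context = f$context)
      before <- score_event(ev, kb_part, rulesets, fx$store)
      after <- score_event(ev, kb_full, rulesets, fx$store)
      expect_equal(after$status, "decidable")
      expect_gte(after$normalized, before$normalized)
    }
  }
})

test_that("event scoring equals a brute-force oracle on random KBs", {
  withr::local_seed(22)
  for (seed in 4:6) {
    kb <- gen_random_kb(fixture_spec(seed = seed, n_entities = 8,
                                     n_facts = 50, negation_rate = 0.2,
                                     annotation_completeness = 0.5),
                        fx$store)
    picks <- sample(nrow(kb$facts), 8L)
    for (i in picks) {
      f <- as.list(kb$facts[i, ])
      ev <- hyp_event(f$event_type, f$relation, f$actor, f$target,
                      label = "o", context = f$context,
                      negated_claim = stats::runif(1) < 0.3)
      got <- score_event(ev, kb, rulesets, fx$store)
      want <- oracle_score_event(ev, kb, rulesets[[f$event_type]], fx$store)
      expect_equal(got$status, want$status)
      if (got$status == "decidable") {
        expect_equal(got$raw, as.integer(want$raw))
        expect_equal(got$normalized, want$normalized)
        expect_equal(got$best_fact, want$best_fact)
        # raw never exceeds the effective maximum
        expect_lte(got$raw, got$max_score)
      }
    }
  }
})
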