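fx <- build_gal_fixture()
rulesets <- load_rulesets()

mk_scores <- function(...) as_event_scores(list(...))

test_that("operators aggregate as sum / max / exclusive pass-through", {
  two <- hyp_and(
    hyp_event("induction", "induce", "sgd:Gal3p", "sgd:GAL2", label = "e2"),
    hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL7", label = "e3")
  )
  agg <- aggregate_scores(two, mk_scores(
    e2 = list(status = "decidable", value = 0.8),
    e3 = list(status = "decidable", value = 0.8)
  ))
  expect_equal(agg$kind, "combined")
  expect_equal(agg$value, 1.6)

  three <- hyp_and(
    hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL7", label = "e4"),
    hyp_event("inhibition", "inhibit", "sgd:Gal80p", "sgd:Gal4p", label = "e5"),
    hyp_event("induction", "induce", "sgd:Gal80p", "sgd:GAL7", label = "e6")
  )
  agg2 <- aggregate_scores(three, mk_scores(
    e4 = list(status = "decidable", value = 0.8),
    e5 = list(status = "undecidable", value = NA_real_),
    e6 = list(status = "decidable", value = 0.8)
  ))
  expect_equal(agg2$status, "undecidable")
  expect_true(is.na(agg2$value))

  or3 <- hyp_or(
    hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "a"),
    hyp_event("induction", "induce", "sgd:Gal3p", "sgd:GAL2", label = "b"),
    hyp_event("induction", "induce", "sgd:Gal80p", "sgd:GAL7", label = "c")
  )
  agg3 <- aggregate_scores(or3, mk_scores(
    a = list(status = "decidable", value = 0.8),
    b = list(status = "decidable", value = 1.6),
    c = list(status = "undecidable", value = NA_real_)
  ))
  expect_equal(agg3$kind, "maximum")
  expect_equal(agg3$status, "decidable")
  expect_equal(agg3$value, 1.6)

  or2 <- hyp_or(
    hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "a"),
    hyp_event("induction", "induce", "sgd:Gal3p", "sgd:GAL2", label = "b")
  )
  agg4 <- aggregate_scores(or2, mk_scores(
    a = list(status = "undecidable", value = NA_real_),
    b = list(status = "undecidable", value = NA_real_)
  ))
  expect_equal(agg4$status, "undecidable")

  xor2 <- hyp_xor(
    hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "a"),
    hyp_event("induction", "induce", "sgd:Gal3p", "sgd:GAL2", label = "b")
  )
  # exactly one supported child: pass its score through
  agg5 <- aggregate_scores(xor2, mk_scores(
    a = list(status = "decidable", value = 0.8),
    b = list(status = "decidable", value = -0.2)
  ))
  expect_equal(agg5$kind, "exclusive")
  expect_equal(agg5$value, 0.8)
  # two supported children falsify an exclusive disjunction
  agg6 <- aggregate_scores(xor2, mk_scores(
    a = list(status = "decidable", value = 0.8),
    b = list(status = "decidable", value = 0.4)
  ))
  expect_equal(agg6$value, 0)

  expect_error(
    aggregate_scores(xor2, mk_scores(a = list(status = "decidable", value = 1))),
    "no score"
  )
})

test_that("aggregation equals direct recursion on random trees", {
  withr::local_seed(31)
  for (i in 1:25) {
    tree <- random_tree(3L)
    scores <- random_leaf_scores(tree)
    got <- aggregate_scores(tree, as_event_scores(scores))
    want <- oracle_aggregate(tree, scores)
    expect_equal(got$status, want$status)
    if (got$status == "decidable") expect_equal(got$value, unname(want$value))
  }
})

test_that("OR dominates children; AND and XOR are permutation-invariant", {
  withr::local_seed(32)
  for (i in 1:15) {
    tree <- random_tree(2L)
    scores <- random_leaf_scores(tree, p_undecidable = 0.15)
    agg <- aggregate_scores(tree, as_event_scores(scores))
    if (!inherits(tree, "hyp_event") && tree$operator == "OR" &&
        agg$status == "decidable") {
      for (ch in agg$children) {
        if (ch$status == "decidable") expect_gte(agg$value, ch$value)
      }
    }
    if (!inherits(tree, "hyp_event")) {
      perm <- tree
      perm$children <- rev(perm$children)
      agg_p <- aggregate_scores(perm, as_event_scores(scores))
      expect_equal(agg_p$status, agg$status)
      if (agg$status == "decidable") expect_equal(agg_p$value, agg$value)
    }
  }
})

test_that("the worked six-event hypothesis evaluates to 1.6 overall", {
  h <- parse_hypothesis(gal_fixture_paths()[["induction_hypothesis"]])
  r <- evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
  expect_equal(r$overall$status, "decidable")
  expect_equal(r$overall$value, 1.6)
  norm <- vapply(r$per_event, `[[`, 0, "normalized")
  expect_equal(unname(norm[c("e1", "e2", "e3", "e4", "e6")]),
               rep(0.8, 5))
  expect_equal(r$per_event$e5$status, "undecidable")
  # the third OR branch is undecidable, the winning branch is e2 AND e3
  expect_equal(r$overall$children[[3]]$status, "undecidable")
  expect_equal(r$overall$children[[2]]$value, 1.6)
  # every decidable event is linked to its best supporting fact
  expect_setequal(names(r$data_links), c("e1", "e2", "e3", "e4", "e6"))
})

test_that("the galactose-transport hypothesis evaluates to 1", {
  h <- parse_hypothesis(gal_fixture_paths()[["transport_hypothesis"]])
  r <- evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
  expect_equal(r$overall$value, 1)
  expect_equal(r$data_links$e1, "hkb:f06")
})

test_that("a leaf-only hypothesis with no candidate data is undecidable", {
  h <- hypothesis(hyp_event("induction", "induce", "sgd:Gal3p", "sgd:GAL7",
                            label = "e1", context = "gal80 deletion"))
  r <- evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
  expect_equal(r$overall$status, "undecidable")
  expect_length(r$data_links, 0L)
  expect_true(is.na(r$mean_event_score))
})

test_that("report identifiers are deterministic; timestamps are UTC ISO-8601", {
  h <- parse_hypothesis(gal_fixture_paths()[["transport_hypothesis"]])
  r1 <- evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
  r2 <- evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
  expect_equal(r1$report_id, r2$report_id)
  expect_match(r1$timestamp, "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$")
})

test_that("the N-Triples report links scores to hypothesis and data", {
  pm <- default_prefix_map()
  type_subjects <- function(tr, cls) {
    tr$subject[tr$predicate == hypeval:::RDF_TYPE &
                 tr$object == expand_curie(cls, pm)]
  }

  ht <- parse_hypothesis(gal_fixture_paths()[["transport_hypothesis"]])
  rt <- evaluate_hypothesis(ht, fx$kb, rulesets, fx$store)
  tr <- read_ntriples(report_to_ntriples(rt), text = TRUE)
  overall <- type_subjects(tr, "hq:hypothesis-score")
  expect_length(overall, 1L)
  val <- tr$object[tr$subject == overall &
                     tr$predicate == expand_curie("hq:has-value", pm)]
  expect_equal(as.numeric(val), 1)
  evs <- type_subjects(tr, "hq:event-score")
  expect_length(evs, 1L)
  expect_true(any(tr$subject == overall &
                    tr$predicate == expand_curie("hq:has-part", pm) &
                    tr$object == evs))
  # the event score points back at the supporting fact
  expect_true(any(tr$subject == evs &
                    tr$predicate == expand_curie("hq:is-about", pm) &
                    tr$object == expand_curie("hkb:f06", pm)))

  # worked hypothesis: one maximum node, two combined nodes, rule scores
  # only for scored events
  h6 <- parse_hypothesis(gal_fixture_paths()[["induction_hypothesis"]])
  r6 <- evaluate_hypothesis(h6, fx$kb, rulesets, fx$store)
  tr6 <- read_ntriples(report_to_ntriples(r6), text = TRUE)
  expect_length(type_subjects(tr6, "hq:maximum-event-score"), 1L)
  expect_length(type_subjects(tr6, "hq:combined-event-score"), 2L)
  expect_length(type_subjects(tr6, "hq:rule-score"), 5L * 6L)

  # an undecidable report has no rule-score nodes and an undecidable flag
  hu <- hypothesis(hyp_event("induction", "induce", "sgd:Gal3p", "sgd:GAL7",
                             label = "e1", context = "gal80 deletion"))
  ru <- evaluate_hypothesis(hu, fx$kb, rulesets, fx$store)
  tru <- read_ntriples(report_to_ntriples(ru), text = TRUE)
  expect_length(type_subjects(tru, "hq:rule-score"), 0L)
  st <- tru$object[tru$subject == type_subjects(tru, "hq:hypothesis-score") &
                     tru$predicate == expand_curie("hq:has-status", pm)]
  expect_equal(st, "undecidable")
})

test_that("N-Triples reports reload to the same overall value and status", {
  h <- parse_hypothesis(gal_fixture_paths()[["induction_hypothesis"]])
  r <- evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
  back <- read_report_ntriples(report_to_ntriples(r), text = TRUE)
  expect_equal(back$value, 1.6)
  expect_equal(back$status, "decidable")
})

test_that("the JSON report carries the score tree and auxiliary mean", {
  h <- parse_hypothesis(gal_fixture_paths()[["induction_hypothesis"]])
  r <- evaluate_hypothesis(h, fx$kb, rulesets, fx$store)
  doc <- jsonlite::fromJSON(report_to_json(r), simplifyVector = FALSE)
  expect_equal(doc$overall_score, 1.6)
  expect_equal(doc$overall_status, "decidable")
  expect_equal(doc$mean_event_score, 0.8)
  expect_equal(doc$score_tree$kind, "maximum")
  expect_length(doc$score_tree$children, 3L)
})
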