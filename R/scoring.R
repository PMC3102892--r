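#' Rule sets and event scoring
#'
#' Each event type has an ordered rule set. A rule names a condition
#' (`actor_is_a`, `target_is_a`, `actor_has_function`, `location_is`,
#' `relation_is`, `negated_in_kb`, `evidence_is`) with one or more CURIE or
#' token arguments, and the points awarded when the condition holds
#' (`points_if_true`) or fails (`points_if_false`, with `points_if_true >=
#' points_if_false`). Conditions assess how far a candidate fact deviates
#' from the ideal fact that would maximally support the hypothesized event;
#' an explicit contradiction (the event negated in the knowledge base)
#' carries a heavier penalty than other deviations. An event's score is the
#' best candidate's point sum expressed as a fraction of the rule set's
#' maximum, so scores are comparable across event types; when no candidate
#' exists, the event is *undecidable* rather than scored.
#'
#' The shipped induction ("induce") rule set awards: actor typed protein or
#' RNA (+1/-1); target typed gene (+1/-1); actor annotated with
#' transcription factor activity (+1/0); location nucleus (+1/-1); relation
#' "induce" (+1/-1); event negated in the knowledge base (0/-2) — maximum 5
#' points. The six other default rule sets are analogues built from the
#' same template and are marked `"reconstructed"` in the shipped
#' configuration; all are overridable via [load_rulesets()].
#'
#' @name scoring
NULL

RULE_CONDITIONS <- c("actor_is_a", "target_is_a", "actor_has_function",
                     "location_is", "relation_is", "negated_in_kb",
                     "evidence_is")

#' Path of the shipped default rule-set configuration
#' @return File path within the installed package.
#' @export
default_rulesets_path <- function() {
  system.file("extdata", "rulesets-default.json", package = "hypeval")
}

#' Load rule sets from a JSON configuration
#'
#' The configuration is an object with a `version` string and a `rulesets`
#' array; each rule set names an `event_type` and an ordered `rules` array
#' of `{id, condition, args, points_if_true, points_if_false}` objects.
#' The derived `max_score` is the sum over rules of
#' `max(points_if_true, 0)`, so a rule that can only penalize (such as the
#' negation rule, 0/-2) contributes nothing to the maximum.
#'
#' @param config Path to a JSON file or an already-parsed list. Defaults to
#'   the shipped configuration covering all seven event types.
#' @return Named list of `rule_set` objects keyed by event type, with a
#'   `version` attribute.
#' @export
load_rulesets <- function(config = default_rulesets_path()) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  if (is.null(config$rulesets) || !length(config$rulesets)) {
    stop(hy_schema_error("rule-set config has no 'rulesets' array"))
  }
  out <- list()
  for (rs in config$rulesets) {
    out[[rs$event_type]] <- build_ruleset(rs)
  }
  attr(out, "version") <- if (is.null(config$version)) "unversioned" else config$version
  out
}

build_ruleset <- function(rs) {
  if (is.null(rs$event_type) || !rs$event_type %in% EVENT_TYPES) {
    stop(hy_schema_error(sprintf(
      "rule set has unknown event_type '%s'",
      if (is.null(rs$event_type)) "<missing>" else rs$event_type
    )))
  }
  if (is.null(rs$rules) || length(rs$rules) == 0L) {
    stop(hy_schema_error(sprintf(
      "rule set for '%s' has an empty rules list", rs$event_type
    )))
  }
  rules <- lapply(rs$rules, function(r) {
    if (is.null(r$condition) || !r$condition %in% RULE_CONDITIONS) {
      stop(hy_schema_error(sprintf(
        "rule '%s': unknown condition '%s'",
        if (is.null(r$id)) "<unnamed>" else r$id,
        if (is.null(r$condition)) "<missing>" else r$condition
      )))
    }
    pt <- as.integer(r$points_if_true)
    pf <- as.integer(r$points_if_false)
    if (is.na(pt) || is.na(pf) || pt < pf) {
      stop(hy_schema_error(sprintf(
        "rule '%s': requires integer points with points_if_true >= points_if_false", r$id
      )))
    }
    list(
      id = r$id,
      condition = r$condition,
      args = curie_args(r$condition, unlist(r$args)),
      points_if_true = pt,
      points_if_false = pf
    )
  })
  max_score <- sum(vapply(rules, function(r) max(r$points_if_true, 0L), 0L))
  if (max_score <= 0L) {
    stop(hy_schema_error(sprintf(
      "rule set for '%s' has non-positive max_score %d", rs$event_type, max_score
    )))
  }
  structure(
    list(event_type = rs$event_type, rules = rules, max_score = max_score,
         provenance = if (is.null(rs$source)) "unspecified" else rs$source),
    class = "rule_set"
  )
}

curie_args <- function(condition, args) {
  if (condition %in% c("relation_is", "negated_in_kb")) return(as.character(args))
  curie_norm(as.character(args))
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %s: %d rules, max score %d (%s)\n",
              x$event_type, length(x$rules), x$max_score, x$provenance))
  for (r in x$rules) {
    cat(sprintf("  %s: %s(%s) %+d/%+d\n", r$id, r$condition,
                paste(r$args, collapse = ", "),
                r$points_if_true, r$points_if_false))
  }
  invisible(x)
}

#' Apply one rule to a candidate fact
#'
#' Evaluates the rule's condition against the fact (actor/target entity
#' types and functions via subsumption over the term store; location,
#' relation, evidence and negation flag directly) and returns the points
#' earned. The `negated_in_kb` condition holds when the fact's negation
#' flag agrees with the hypothesized claim: for an ordinary claim a
#' non-negated fact earns `points_if_true` (typically 0) and a negated fact
#' — an explicit contradiction — earns `points_if_false` (typically -2).
#' For a hypothesized non-event (`negated_claim = TRUE`) the polarity
#' flips: a negated fact earns `-points_if_false` (+2 under the default
#' rule) and a non-negated fact earns `points_if_false`.
#'
#' @param rule A rule (element of a `rule_set`'s `rules`).
#' @param event The [hyp_event()] being scored.
#' @param fact A candidate fact (one row of `kb$facts`, as a list or
#'   one-row data.frame).
#' @param kb A [knowledge_base].
#' @param store A [term_store].
#' @return A `rule_score`: list with `rule_id`, `points`, `fired` and
#'   `about` (the fact id).
#' @export
apply_rule <- function(rule, event, fact, kb, store) {
  fact <- as.list(fact)
  actor <- kb$entities[[fact$actor]]
  target <- kb$entities[[fact$target]]
  any_is_a <- function(terms, args) {
    length(terms) > 0L && any(vapply(
      terms,
      function(t) any(vapply(args, function(a) is_a_safe(t, a, store), TRUE)),
      TRUE
    ))
  }
  fired <- switch(
    rule$condition,
    actor_is_a = any_is_a(actor$types, rule$args),
    target_is_a = any_is_a(target$types, rule$args),
    actor_has_function = any_is_a(actor$functions, rule$args),
    location_is = !is.na(fact$location) && any_is_a(fact$location, rule$args),
    relation_is = fact$relation %in% rule$args,
    evidence_is = !is.na(fact$evidence) && any_is_a(fact$evidence, rule$args),
    negated_in_kb = fact$negated == isTRUE(event$negated_claim),
    stop(hy_schema_error(sprintf("unknown rule condition '%s'", rule$condition)))
  )
  points <- if (rule$condition == "negated_in_kb" && isTRUE(event$negated_claim)) {
    # flipped polarity for hypothesized non-events: agreement (a negated
    # fact) earns the mirror-image bonus of the contradiction penalty
    if (fired) -rule$points_if_false else rule$points_if_false
  } else {
    if (fired) rule$points_if_true else rule$points_if_false
  }
  list(rule_id = rule$id, points = points, fired = fired,
       about = fact$fact_id)
}

# Effective maximum for an event: the base max plus, for negated claims,
# the flipped negation bonus, keeping normalized scores within [-1, 1].
effective_max_score <- function(ruleset, event) {
  extra <- 0L
  if (isTRUE(event$negated_claim)) {
    for (r in ruleset$rules) {
      if (r$condition == "negated_in_kb") extra <- extra + abs(r$points_if_false)
    }
  }
  ruleset$max_score + extra
}

#' Score a hypothesized event against the knowledge base
#'
#' Retrieves candidates via [candidates_for()]; with no candidates the
#' event is `undecidable` (no raw, normalized or best-fact values).
#' Otherwise every rule of the event type's rule set is applied to every
#' candidate, the candidate with the maximal point sum is selected (ties
#' break on lexicographically smallest fact id), and the normalized score
#' is the raw sum divided by the rule set's maximum.
#'
#' @param event A [hyp_event()].
#' @param kb A [knowledge_base].
#' @param rulesets Named list from [load_rulesets()].
#' @param store A [term_store].
#' @return An `event_score`: list with `event_label`, `status`, `raw`,
#'   `normalized`, `max_score`, `best_fact` and `rule_scores`.
#' @export
score_event <- function(event, kb, rulesets, store) {
  ruleset <- rulesets[[event$event_type]]
  if (is.null(ruleset)) {
    stop(hy_schema_error(sprintf(
      "no rule set for event type '%s'", event$event_type
    )))
  }
  cands <- candidates_for(event, kb, store)
  if (nrow(cands) == 0L) {
    return(structure(
      list(event_label = event$label, status = "undecidable",
           raw = NA_integer_, normalized = NA_real_, max_score = NA_integer_,
           best_fact = NA_character_, rule_scores = list()),
      class = "event_score"
    ))
  }
  max_score <- effective_max_score(ruleset, event)
  best <- NULL
  for (i in seq_len(nrow(cands))) {
    fact <- as.list(cands[i, ])
    rs <- lapply(ruleset$rules, apply_rule, event = event, fact = fact,
                 kb = kb, store = store)
    raw <- sum(vapply(rs, `[[`, 0L, "points"))
    # ties break on lexicographically smallest fact id; candidates arrive
    # id-sorted from candidates_for, so strict improvement suffices
    if (is.null(best) || raw > best$raw) {
      best <- list(raw = raw, fact_id = fact$fact_id, rule_scores = rs)
    }
  }
  structure(
    list(
      event_label = event$label, status = "decidable",
      raw = as.integer(best$raw),
      normalized = best$raw / max_score,
      max_score = as.integer(max_score),
      best_fact = best$fact_id,
      rule_scores = best$rule_scores
    ),
    class = "event_score"
  )
}

#' @export
print.event_score <- function(x, ...) {
  if (x$status == "undecidable") {
    cat(sprintf("<event_score> %s: undecidable\n", x$event_label))
  } else {
    cat(sprintf("<event_score> %s: %d/%d = %.3g (best fact %s)\n",
                x$event_label, x$raw, x$max_score, x$normalized, x$best_fact))
    for (r in x$rule_scores) {
      cat(sprintf("  %s: %s -> %+d\n", r$rule_id,
                  if (r$fired) "yes" else "no", r$points))
    }
  }
  invisible(x)
}
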