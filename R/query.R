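#' Event patterns and subsumption-aware matching
#'
#' The query layer answers questions about single events, including
#' underspecified ones where participants are unbound variables ("which
#' proteins bind the GAL1 promoter in wild type?"). Matching is
#' subsumption-aware: a type restriction matches any entity annotated with
#' that type or a more specific descendant, and a pattern location matches
#' any fact location subsumed by it. Scalar pattern fields take a concrete
#' value, `NA` (wildcard), or a `"?var"` token, which acts as a wildcard
#' whose matched value is reported as a binding.
#'
#' @name query
NULL

#' Construct an event pattern
#'
#' @param event_type,relation,context Exact-match tokens, `NA` for wildcard,
#'   or a `"?var"` binding variable.
#' @param actor,target [entity_ref] objects (or bare CURIEs, promoted to
#'   instance references); use [ref_unbound()] for query variables.
#' @param location,evidence CURIE (matched up to subsumption), `NA`, or a
#'   `"?var"` binding variable.
#' @param negated `TRUE`/`FALSE`, or `NA` for wildcard.
#' @return An `event_pattern` object; at least one field must be
#'   non-wildcard.
#' @export
event_pattern <- function(event_type = NA, relation = NA,
                          actor = ref_unbound("?actor"),
                          target = ref_unbound("?target"),
                          location = NA, context = NA, evidence = NA,
                          negated = NA) {
  promote <- function(r) if (inherits(r, "entity_ref")) r else ref_instance(r)
  p <- structure(
    list(
      event_type = event_type, relation = relation,
      actor = promote(actor), target = promote(target),
      location = location, context = context, evidence = evidence,
      negated = negated
    ),
    class = "event_pattern"
  )
  constrained <- !is.na(p$event_type) || !is.na(p$relation) ||
    !is.na(p$location) || !is.na(p$context) || !is.na(p$evidence) ||
    !is.na(p$negated) ||
    p$actor$mode != "unbound" || !is.null(p$actor$type_curie) ||
    p$target$mode != "unbound" || !is.null(p$target$type_curie)
  if (!constrained) {
    stop(hy_schema_error("event pattern must constrain at least one field"))
  }
  p
}

is_var <- function(x) is.character(x) && !is.na(x) && startsWith(x, "?")

# Subsumption with auto-created-bare-root semantics: an unresolvable term
# only matches itself; an unresolvable ancestor restriction is an error.
is_a_safe <- function(term, ancestor, store) {
  term <- curie_norm(term)
  ancestor <- resolve_term(ancestor, store)
  if (term == ancestor) return(TRUE)
  if (is.null(store$terms[[term]])) return(FALSE)
  ancestor %in% store$ancestors[[term]]
}

#' Match an entity against an entity reference
#'
#' Instance references compare canonical ids (after `owl:sameAs`
#' resolution); type restrictions hold when some declared type of the
#' entity is subsumed by the restriction; unbound references match any
#' entity, subject to their optional type restriction.
#'
#' @param ref An [entity_ref].
#' @param entity An entity record from a [knowledge_base] (or an entity
#'   CURIE known to `kb`).
#' @param store A [term_store].
#' @param kb The [knowledge_base] owning the entity (used for canonical-id
#'   comparison of instance references).
#' @return Logical scalar.
#' @export
match_entity <- function(ref, entity, store, kb) {
  if (is.character(entity)) {
    id <- canonical_id(kb, entity)
    entity <- kb$entities[[id]]
    if (is.null(entity)) stop(hy_data_error(sprintf(
      "entity '%s' is not in the knowledge base", id
    )))
  }
  type_ok <- function(restriction) {
    any(vapply(entity$types, is_a_safe, TRUE, ancestor = restriction,
               store = store))
  }
  switch(ref$mode,
    instance = identical(canonical_id(kb, ref$value), entity$id),
    `type-restricted` = length(entity$types) > 0L && type_ok(ref$type_curie),
    unbound = is.null(ref$type_curie) ||
      (length(entity$types) > 0L && type_ok(ref$type_curie)),
    stop(hy_schema_error(sprintf("unknown entity_ref mode '%s'", ref$mode)))
  )
}

match_scalar <- function(pattern_value, fact_value, subsume = FALSE,
                         store = NULL) {
  if (is.na(pattern_value) || is_var(pattern_value)) return(TRUE)
  if (is.na(fact_value)) return(FALSE)
  if (subsume) is_a_safe(fact_value, pattern_value, store)
  else identical(pattern_value, fact_value)
}

fact_matches <- function(p, fact, kb, store) {
  if (!match_scalar(p$event_type, fact$event_type)) return(FALSE)
  if (!match_scalar(p$relation, fact$relation)) return(FALSE)
  if (!match_scalar(p$context, fact$context)) return(FALSE)
  if (!match_scalar(p$location, fact$location, subsume = TRUE, store = store)) return(FALSE)
  if (!match_scalar(p$evidence, fact$evidence, subsume = TRUE, store = store)) return(FALSE)
  if (!is.na(p$negated) && !identical(as.logical(p$negated), fact$negated)) return(FALSE)
  if (!match_entity(p$actor, kb$entities[[fact$actor]], store, kb)) return(FALSE)
  match_entity(p$target, kb$entities[[fact$target]], store, kb)
}

pattern_variables <- function(p) {
  vars <- character()
  if (p$actor$mode == "unbound") vars <- c(vars, actor = p$actor$variable)
  if (p$target$mode == "unbound") vars <- c(vars, target = p$target$variable)
  for (field in c("event_type", "relation", "location", "context", "evidence")) {
    if (is_var(p[[field]])) vars <- c(vars, stats::setNames(p[[field]], field))
  }
  vars
}

#' Query the knowledge base for matching events
#'
#' Scans the fact list, keeping facts that satisfy every non-wildcard
#' pattern field. Unbound variables are bound per matching fact; binding
#' rows are deduplicated on the full binding tuple, each row witnessed by
#' the ids of the facts that produced it. An empty result is a valid
#' answer.
#'
#' @param pattern An [event_pattern].
#' @param kb A [knowledge_base].
#' @param store A [term_store].
#' @return A `query_result`: list with `facts` (the matching fact rows) and
#'   `bindings` (data.frame of variable columns plus a `fact_ids` column of
#'   comma-separated witnessing fact ids).
#' @export
query_events <- function(pattern, kb, store) {
  facts <- kb$facts
  keep <- vapply(seq_len(nrow(facts)), function(i) {
    fact_matches(pattern, as.list(facts[i, ]), kb, store)
  }, TRUE)
  hits <- facts[keep, , drop = FALSE]
  rownames(hits) <- NULL

  vars <- pattern_variables(pattern)
  if (length(vars) && nrow(hits)) {
    bind_cols <- lapply(names(vars), function(field) {
      v <- hits[[field]]
      ifelse(is.na(v), "", v)
    })
    bindings <- as.data.frame(stats::setNames(bind_cols, vars),
                              check.names = FALSE, stringsAsFactors = FALSE)
    key <- do.call(paste, c(bindings, sep = "\r"))
    uniq <- !duplicated(key)
    witnesses <- vapply(key[uniq], function(k) {
      paste(c_sort(hits$fact_id[key == k]), collapse = ",")
    }, "")
    bindings <- bindings[uniq, , drop = FALSE]
    bindings$fact_ids <- unname(witnesses)
    rownames(bindings) <- NULL
  } else {
    bindings <- data.frame(fact_ids = hits$fact_id, stringsAsFactors = FALSE)
  }
  structure(list(pattern = pattern, facts = hits, bindings = bindings),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %d matching fact(s), %d binding row(s)\n",
              nrow(x$facts), nrow(x$bindings)))
  if (nrow(x$bindings)) print(x$bindings)
  invisible(x)
}

#' Export a query result as a TSV table
#'
#' Mirrors the promoter-binding result layout: one row per matching fact
#' with columns `Actor`, `Target`, `Perturbation Context` and
#' `Evidence Type` (actor/target as expanded IRIs, evidence as a CURIE,
#' blank when absent).
#'
#' @param result A `query_result`.
#' @param path Output path, or `NULL` to return the lines.
#' @param prefix_map CURIE prefix map for IRI expansion.
#' @return Invisibly (or visibly when `path` is `NULL`) the TSV lines.
#' @export
query_to_tsv <- function(result, path = NULL, prefix_map = default_prefix_map()) {
  f <- result$facts
  lines <- c(
    paste(c("Actor", "Target", "Perturbation Context", "Evidence Type"),
          collapse = "\t"),
    if (nrow(f)) paste(
      vapply(f$actor, expand_curie, "", prefix_map = prefix_map),
      vapply(f$target, expand_curie, "", prefix_map = prefix_map),
      f$context,
      ifelse(is.na(f$evidence), "", f$evidence),
      sep = "\t"
    )
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Retrieve scoring candidates for a hypothesized event
#'
#' Returns the facts whose actor and target match the event's entity
#' references and whose perturbation context equals the event's context
#' exactly (default `"wt"`). Event type, relation, location and negation
#' are deliberately NOT filtered here: deviations in those fields are
#' penalized by the scoring rules rather than excluded from consideration.
#' Exact context matching is what renders an event hypothesized under an
#' unobserved perturbation undecidable.
#'
#' @param event A [hyp_event()] whose actor and target are instance or
#'   type-restricted references (unbound variables are not allowed in
#'   scoring candidates).
#' @param kb A [knowledge_base].
#' @param store A [term_store].
#' @return Data.frame of candidate fact rows (possibly empty).
#' @export
candidates_for <- function(event, kb, store) {
  if (event$actor$mode == "unbound" || event$target$mode == "unbound") {
    stop(hy_schema_error(sprintf(
      "event '%s': unbound entity references cannot be scored", event$label
    )))
  }
  facts <- kb$facts
  rows <- if (event$actor$mode == "instance" && event$target$mode == "instance") {
    key <- paste(canonical_id(kb, event$actor$value),
                 canonical_id(kb, event$target$value),
                 event$context, sep = "\r")
    idx <- kb$indexes$by_actor_target_context[[key]]
    if (is.null(idx)) integer() else idx
  } else {
    which(vapply(seq_len(nrow(facts)), function(i) {
      f <- as.list(facts[i, ])
      f$context == event$context &&
        match_entity(event$actor, kb$entities[[f$actor]], store, kb) &&
        match_entity(event$target, kb$entities[[f$target]], store, kb)
    }, TRUE))
  }
  out <- facts[rows, , drop = FALSE]
  out <- out[order(out$fact_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
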