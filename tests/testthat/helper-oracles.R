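# Independent brute-force oracles used by the property tests. These
# deliberately avoid the package's subsumption/matching/aggregation code
# paths: reachability is a plain BFS over a parents mapping, matching and
# scoring are re-derived from first principles with loops.

# reflexive-transitive is-a reachability by breadth-first search
bfs_is_a <- function(term, ancestor, parents) {
  seen <- character()
  queue <- term
  while (length(queue)) {
    x <- queue[[1L]]
    queue <- queue[-1L]
    if (identical(x, ancestor)) return(TRUE)
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, parents[[x]])
  }
  FALSE
}

store_parents <- function(store) lapply(store$terms, `[[`, "parents")

# write a term table to a temp TSV and load it
load_terms_from_df <- function(df) {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  load_terms(tf)
}

# random DAG over n terms: parents only point to earlier terms
random_dag_df <- function(n, p_edge = 0.2) {
  ids <- sprintf("t:%03d", seq_len(n))
  parents <- vapply(seq_len(n), function(i) {
    if (i == 1L) return("")
    cand <- ids[seq_len(i - 1L)]
    sel <- cand[stats::runif(i - 1L) < p_edge]
    paste(sel, collapse = "|")
  }, "")
  data.frame(id = ids, label = ids, parents = parents,
             stringsAsFactors = FALSE)
}

gal_store <- function() build_gal_fixture()$store

# --- independent event-pattern matching -----------------------------------

oracle_ref_match <- function(ref, entity_id, kb, parents) {
  ent <- kb$entities[[entity_id]]
  ty_ok <- function(restriction) {
    any(vapply(ent$types, bfs_is_a, TRUE, ancestor = restriction,
               parents = parents))
  }
  if (ref$mode == "instance") {
    v <- ref$value
    hit <- kb$alias[v]
    if (!is.na(hit)) v <- unname(hit)
    identical(v, entity_id)
  } else if (ref$mode == "type-restricted") {
    length(ent$types) > 0L && ty_ok(ref$type_curie)
  } else {
    is.null(ref$type_curie) || (length(ent$types) > 0L && ty_ok(ref$type_curie))
  }
}

oracle_query_fact_ids <- function(pattern, kb, store) {
  parents <- store_parents(store)
  keep <- logical(nrow(kb$facts))
  for (i in seq_len(nrow(kb$facts))) {
    f <- as.list(kb$facts[i, ])
    ok <- TRUE
    scal <- function(pv, fv, subsume = FALSE) {
      if (is.na(pv) || startsWith(pv, "?")) return(TRUE)
      if (is.na(fv)) return(FALSE)
      if (subsume) bfs_is_a(fv, pv, parents) else identical(pv, fv)
    }
    ok <- ok && scal(pattern$event_type, f$event_type)
    ok <- ok && scal(pattern$relation, f$relation)
    ok <- ok && scal(pattern$context, f$context)
    ok <- ok && scal(pattern$location, f$location, subsume = TRUE)
    ok <- ok && scal(pattern$evidence, f$evidence, subsume = TRUE)
    if (!is.na(pattern$negated)) ok <- ok && identical(as.logical(pattern$negated), f$negated)
    ok <- ok && oracle_ref_match(pattern$actor, f$actor, kb, parents)
    ok <- ok && oracle_ref_match(pattern$target, f$target, kb, parents)
    keep[i] <- ok
  }
  sort(kb$facts$fact_id[keep])
}

# --- independent event scoring --------------------------------------------

oracle_score_event <- function(event, kb, ruleset, store) {
  parents <- store_parents(store)
  cand <- logical(nrow(kb$facts))
  for (i in seq_len(nrow(kb$facts))) {
    f <- as.list(kb$facts[i, ])
    cand[i] <- f$context == event$context &&
      oracle_ref_match(event$actor, f$actor, kb, parents) &&
      oracle_ref_match(event$target, f$target, kb, parents)
  }
  if (!any(cand)) return(list(status = "undecidable"))
  facts <- kb$facts[cand, , drop = FALSE]
  raws <- numeric(nrow(facts))
  for (i in seq_len(nrow(facts))) {
    f <- as.list(facts[i, ])
    actor <- kb$entities[[f$actor]]
    target <- kb$entities[[f$target]]
    pts <- 0L
    for (r in ruleset$rules) {
      any_of <- function(terms) {
        length(terms) > 0L && any(vapply(
          terms,
          function(t) any(vapply(r$args, function(a) bfs_is_a(t, a, parents), TRUE)),
          TRUE
        ))
      }
      fired <- switch(
        r$condition,
        actor_is_a = any_of(actor$types),
        target_is_a = any_of(target$types),
        actor_has_function = any_of(actor$functions),
        location_is = !is.na(f$location) && any_of(f$location),
        relation_is = f$relation %in% r$args,
        evidence_is = !is.na(f$evidence) && any_of(f$evidence),
        negated_in_kb = f$negated == isTRUE(event$negated_claim)
      )
      pts <- pts + if (r$condition == "negated_in_kb" && isTRUE(event$negated_claim)) {
        if (fired) -r$points_if_false else r$points_if_false
      } else {
        if (fired) r$points_if_true else r$points_if_false
      }
    }
    raws[i] <- pts
  }
  best <- which(raws == max(raws))
  best <- best[order(facts$fact_id[best])][1L]
  maxs <- sum(vapply(ruleset$rules, function(r) max(r$points_if_true, 0L), 0L))
  if (isTRUE(event$negated_claim)) {
    for (r in ruleset$rules) {
      if (r$condition == "negated_in_kb") maxs <- maxs + abs(r$points_if_false)
    }
  }
  list(status = "decidable", raw = raws[best],
       normalized = raws[best] / maxs, best_fact = facts$fact_id[best])
}

# --- independent aggregation ----------------------------------------------

# scores: named list with entries list(status=, value=)
oracle_aggregate <- function(node, scores) {
  if (inherits(node, "hyp_event")) return(scores[[node$label]])
  ch <- lapply(node$children, oracle_aggregate, scores = scores)
  st <- vapply(ch, `[[`, "", "status")
  vals <- vapply(ch, function(x) if (x$status == "decidable") x$value else NA_real_, 0)
  if (node$operator == "AND") {
    if (any(st == "undecidable")) list(status = "undecidable", value = NA_real_)
    else list(status = "decidable", value = sum(vals))
  } else if (node$operator == "OR") {
    if (all(st == "undecidable")) list(status = "undecidable", value = NA_real_)
    else list(status = "decidable", value = max(vals, na.rm = TRUE))
  } else {
    if (any(st == "undecidable")) return(list(status = "undecidable", value = NA_real_))
    pos <- sum(vals > 0)
    list(status = "decidable",
         value = if (pos == 1L) vals[vals > 0][[1L]] else 0)
  }
}

# random operator tree over synthetic leaf scores
random_tree <- function(depth, n_leaves_ctr = new.env()) {
  if (is.null(n_leaves_ctr$n)) n_leaves_ctr$n <- 0L
  mk <- function(d) {
    if (d == 0L || stats::runif(1) < 0.35) {
      n_leaves_ctr$n <- n_leaves_ctr$n + 1L
      hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1",
                label = paste0("e", n_leaves_ctr$n))
    } else {
      op <- sample(c("AND", "OR", "XOR"), 1L)
      kids <- lapply(seq_len(sample(2:4, 1L)), function(i) mk(d - 1L))
      do.call(switch(op, AND = hyp_and, OR = hyp_or, XOR = hyp_xor), kids)
    }
  }
  root <- mk(depth)
  if (inherits(root, "hyp_event")) root <- hyp_and(root, mk(0L))
  hypothesis(root, id = "hqd:random-tree")$root
}

random_leaf_scores <- function(node, p_undecidable = 0.25) {
  labs <- names(hypothesis_events(node))
  out <- lapply(labs, function(l) {
    if (stats::runif(1) < p_undecidable) list(status = "undecidable", value = NA_real_)
    else list(status = "decidable", value = round(stats::runif(1, -1, 1), 2))
  })
  names(out) <- labs
  out
}

# wrap plain (status, value) leaf scores as event_score objects
as_event_scores <- function(scores) {
  lapply(names(scores), function(l) {
    s <- scores[[l]]
    structure(
      list(event_label = l, status = s$status,
           raw = NA_integer_,
           normalized = if (s$status == "decidable") s$value else NA_real_,
           max_score = NA_integer_, best_fact = NA_character_,
           rule_scores = list()),
      class = "event_score"
    )
  }) |> stats::setNames(names(scores))
}
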