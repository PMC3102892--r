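#' Aggregating event scores through the hypothesis tree
#'
#' Operators combine child scores bottom-up: AND sums, OR selects the
#' maximum, XOR passes through the single supported child. Undecidability
#' propagates: an AND with any undecidable child is undecidable (a
#' conjunction cannot be settled while one conjunct has no data), an OR is
#' undecidable only when *every* child is — decidable branches are simply
#' preferred. For XOR a child counts as "supported" when it is decidable
#' with a positive score; the XOR is undecidable if any child is
#' undecidable, takes the supported child's value when exactly one child is
#' supported, and is 0 otherwise (zero or several supported children both
#' falsify an exclusive disjunction).
#'
#' @name aggregation
NULL

agg_node <- function(kind, status, value, children = list(),
                     event_score = NULL, label = NA_character_) {
  structure(
    list(kind = kind, status = status, value = value, children = children,
         event_score = event_score, label = label),
    class = "aggregate_score"
  )
}

KIND_BY_OPERATOR <- c(AND = "combined", OR = "maximum", XOR = "exclusive")

#' Aggregate event scores over a hypothesis tree
#'
#' @param node A `hypothesis_node` (typically `h$root`).
#' @param scores Named list of `event_score` objects covering every leaf
#'   label under `node` (from [score_event()]).
#' @return An `aggregate_score` tree: each node has a `kind` (`event`,
#'   `combined` for AND, `maximum` for OR, `exclusive` for XOR), a `status`
#'   (`decidable`/`undecidable`) and a `value` (`NA` when undecidable).
#' @export
aggregate_scores <- function(node, scores) {
  if (is_leaf(node)) {
    es <- scores[[node$label]]
    if (is.null(es)) {
      stop(hy_data_error(sprintf("no score provided for event '%s'", node$label)))
    }
    return(agg_node("event", es$status,
                    if (es$status == "decidable") es$normalized else NA_real_,
                    event_score = es, label = node$label))
  }
  children <- lapply(node$children, aggregate_scores, scores = scores)
  status <- vapply(children, `[[`, "", "status")
  values <- vapply(children, `[[`, 0, "value")
  kind <- KIND_BY_OPERATOR[[node$operator]]
  switch(
    node$operator,
    AND = {
      if (any(status == "undecidable")) {
        agg_node(kind, "undecidable", NA_real_, children)
      } else {
        agg_node(kind, "decidable", sum(values), children)
      }
    },
    OR = {
      dec <- status == "decidable"
      if (!any(dec)) agg_node(kind, "undecidable", NA_real_, children)
      else agg_node(kind, "decidable", max(values[dec]), children)
    },
    XOR = {
      if (any(status == "undecidable")) {
        agg_node(kind, "undecidable", NA_real_, children)
      } else {
        supported <- which(values > 0)
        val <- if (length(supported) == 1L) values[supported] else 0
        agg_node(kind, "decidable", val, children)
      }
    }
  )
}

#' @export
print.aggregate_score <- function(x, ...) {
  show <- function(n, indent) {
    pad <- strrep("  ", indent)
    val <- if (n$status == "decidable") format(n$value) else "undecidable"
    lab <- if (!is.na(n$label)) paste0(" [", n$label, "]") else ""
    cat(sprintf("%s%s%s: %s\n", pad, n$kind, lab, val))
    lapply(n$children, show, indent = indent + 1L)
  }
  show(x, 0L)
  invisible(x)
}

# Deterministic djb2-style string hash (hex), used for reproducible report
# instance identifiers.
string_digest <- function(x) {
  h <- 5381
  for (c in utf8ToInt(paste(x, collapse = "\r"))) {
    h <- (h * 33 + c) %% 2147483647
  }
  sprintf("%x", as.integer(h))
}

kb_digest <- function(kb) {
  facts <- kb$facts
  facts[is.na(facts)] <- ""
  string_digest(c(
    apply(facts, 1L, paste, collapse = "\t"),
    vapply(kb$entities, function(e) {
      paste(e$id, paste(e$types, collapse = "|"),
            paste(e$functions, collapse = "|"), sep = "\t")
    }, "")
  ))
}

rulesets_digest <- function(rulesets) {
  string_digest(vapply(rulesets, function(rs) {
    paste(rs$event_type, rs$max_score,
          paste(vapply(rs$rules, function(r) {
            paste(r$id, r$condition, paste(r$args, collapse = ","),
                  r$points_if_true, r$points_if_false)
          }, ""), collapse = ";"))
  }, ""))
}

#' Evaluate a hypothesis against a knowledge base
#'
#' Scores every hypothesized event independently with its event type's rule
#' set, aggregates through the operator tree bottom-up, and returns an
#' evaluation report linking the overall score, the per-event scores and
#' the best supporting facts. The overall score is the root aggregate's
#' value, unnormalized (sums over AND groups may exceed 1). The report also
#' carries `mean_event_score` — the mean of the decidable per-event
#' normalized scores — as a clearly auxiliary quantity for comparing
#' scoring schemes that favour simpler hypotheses.
#'
#' @param h A [hypothesis].
#' @param kb A [knowledge_base].
#' @param rulesets Named list from [load_rulesets()].
#' @param store A [term_store].
#' @return An `evaluation_report`: list with `hypothesis_id`, `title`,
#'   `overall` (`aggregate_score` tree), `per_event`, `data_links` (label
#'   -> best fact id for decidable events), `mean_event_score`,
#'   `ruleset_version`, `report_id` (deterministic hash of hypothesis, KB
#'   and rule-set content) and a UTC `timestamp`.
#' @export
evaluate_hypothesis <- function(h, kb, rulesets, store) {
  events <- hypothesis_events(h)
  missing_rs <- setdiff(
    unique(vapply(events, `[[`, "", "event_type")), names(rulesets)
  )
  if (length(missing_rs)) {
    stop(hy_schema_error(paste(
      "no rule set for event type(s):", paste(missing_rs, collapse = ", ")
    )))
  }
  scores <- lapply(events, score_event, kb = kb, rulesets = rulesets,
                   store = store)
  overall <- aggregate_scores(h$root, scores)
  decid <- vapply(scores, function(s) s$status == "decidable", TRUE)
  links <- vapply(scores[decid], `[[`, "", "best_fact")
  structure(
    list(
      hypothesis_id = h$id,
      title = h$title,
      overall = overall,
      per_event = scores,
      data_links = as.list(links),
      mean_event_score = if (any(decid)) {
        mean(vapply(scores[decid], `[[`, 0, "normalized"))
      } else NA_real_,
      ruleset_version = attr(rulesets, "version"),
      report_id = paste0(
        "hqd:evaluation-",
        string_digest(c(h$id, kb_digest(kb), rulesets_digest(rulesets)))
      ),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  val <- if (x$overall$status == "decidable") format(x$overall$value) else "undecidable"
  cat(sprintf("<evaluation_report> %s\n  overall: %s (%s)\n",
              x$hypothesis_id, val, x$overall$status))
  for (s in x$per_event) {
    cat(sprintf("  %s: %s\n", s$event_label,
                if (s$status == "decidable") {
                  sprintf("%d/%d = %.3g via %s", s$raw, s$max_score,
                          s$normalized, s$best_fact)
                } else "undecidable"))
  }
  invisible(x)
}

agg_to_list <- function(n) {
  out <- list(kind = n$kind, status = n$status)
  if (n$status == "decidable") out$value <- n$value
  if (n$kind == "event") {
    es <- n$event_score
    out$event <- list(
      label = es$event_label, status = es$status,
      raw = if (es$status == "decidable") es$raw else NULL,
      normalized = if (es$status == "decidable") es$normalized else NULL,
      max_score = if (es$status == "decidable") es$max_score else NULL,
      best_fact = if (es$status == "decidable") es$best_fact else NULL,
      rule_scores = lapply(es$rule_scores, function(r) {
        list(rule_id = r$rule_id, points = r$points, fired = r$fired,
             about = r$about)
      })
    )
  } else {
    out$children <- lapply(n$children, agg_to_list)
  }
  out
}

#' Serialize an evaluation report to JSON
#'
#' @param r An `evaluation_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(r, path = NULL) {
  doc <- list(
    report_id = r$report_id,
    hypothesis_id = r$hypothesis_id,
    title = r$title,
    overall_status = r$overall$status,
    overall_score = if (r$overall$status == "decidable") r$overall$value else NULL,
    mean_event_score = if (is.na(r$mean_event_score)) NULL else r$mean_event_score,
    ruleset_version = r$ruleset_version,
    timestamp = r$timestamp,
    score_tree = agg_to_list(r$overall),
    data_links = r$data_links
  )
  json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                        digits = NA, null = "null"))
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Serialize an evaluation report as linked N-Triples
#'
#' Emits the evaluation graph in the `hq:` vocabulary with `hqd:` instance
#' identifiers: the evaluation-data resource `hq:is-about` the hypothesis
#' and `hq:has-part` the overall hypothesis-score node; operator aggregates
#' become `hq:combined-event-score` (AND), `hq:maximum-event-score` (OR) or
#' `hq:exclusive-event-score` (XOR) nodes; leaf `hq:event-score` nodes
#' `hq:is-about` their best supporting fact and `hq:has-part` their
#' `hq:rule-score` nodes, which are in turn `hq:is-about` the fact they
#' were executed on. The graph is therefore navigable from data to
#' hypothesis and back.
#'
#' @param r An `evaluation_report`.
#' @param path Optional output path.
#' @param prefix_map CURIE prefix map for IRI expansion.
#' @return Character vector of N-Triples lines (invisibly when written).
#' @export
report_to_ntriples <- function(r, path = NULL, prefix_map = default_prefix_map()) {
  ex <- function(x) expand_curie(x, prefix_map)
  eval_iri <- ex(r$report_id)
  hyp_iri <- ex(r$hypothesis_id)
  out <- list(
    nt_triple(eval_iri, RDF_TYPE, hq_iri("evaluation-data", prefix_map)),
    nt_triple(eval_iri, hq_iri("is-about", prefix_map), hyp_iri)
  )
  add <- function(s, p, o, is_iri = TRUE, datatype = NA_character_) {
    out[[length(out) + 1L]] <<- nt_triple(s, hq_iri(p, prefix_map), o,
                                          object_is_iri = is_iri,
                                          datatype = datatype)
  }
  score_iri <- paste0(eval_iri, "-score")
  out[[length(out) + 1L]] <- nt_triple(score_iri, RDF_TYPE,
                                       hq_iri("hypothesis-score", prefix_map))
  add(eval_iri, "has-part", score_iri)
  add(score_iri, "is-about", hyp_iri)
  add(score_iri, "has-status", r$overall$status, is_iri = FALSE)
  if (r$overall$status == "decidable") {
    add(score_iri, "has-value", format(r$overall$value, scientific = FALSE),
        is_iri = FALSE, datatype = XSD_DECIMAL)
  }
  counter <- 0L
  class_of <- c(event = "event-score", combined = "combined-event-score",
                maximum = "maximum-event-score", exclusive = "exclusive-event-score")
  emit <- function(node, parent_iri) {
    counter <<- counter + 1L
    iri <- paste0(eval_iri, "-s", counter)
    out[[length(out) + 1L]] <<- nt_triple(iri, RDF_TYPE,
                                          hq_iri(class_of[[node$kind]], prefix_map))
    add(parent_iri, "has-part", iri)
    add(iri, "has-status", node$status, is_iri = FALSE)
    if (node$status == "decidable") {
      add(iri, "has-value", format(node$value, scientific = FALSE),
          is_iri = FALSE, datatype = XSD_DECIMAL)
    }
    if (node$kind == "event") {
      es <- node$event_score
      add(iri, "label", es$event_label, is_iri = FALSE)
      if (es$status == "decidable") {
        add(iri, "is-about", ex(es$best_fact))
        for (rs in es$rule_scores) {
          counter <<- counter + 1L
          riri <- paste0(eval_iri, "-s", counter)
          out[[length(out) + 1L]] <<- nt_triple(riri, RDF_TYPE,
                                                hq_iri("rule-score", prefix_map))
          add(iri, "has-part", riri)
          add(riri, "rule-id", rs$rule_id, is_iri = FALSE)
          add(riri, "has-value", as.character(rs$points), is_iri = FALSE,
              datatype = XSD_INTEGER)
          add(riri, "is-about", ex(rs$about))
        }
      }
    } else {
      for (ch in node$children) emit(ch, iri)
    }
  }
  emit(r$overall, score_iri)
  lines <- write_ntriples(do.call(rbind, out))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read back the headline result of an N-Triples report
#'
#' Parses a report produced by [report_to_ntriples()] and returns the
#' overall hypothesis score value and status, for round-trip verification
#' of the linked-data form.
#'
#' @param source Path or character vector of N-Triples lines (with
#'   `text = TRUE`).
#' @param text Interpret `source` as lines.
#' @param prefix_map CURIE prefix map.
#' @return List with `value` (numeric or `NA`) and `status`.
#' @export
read_report_ntriples <- function(source, text = FALSE,
                                 prefix_map = default_prefix_map()) {
  tr <- read_ntriples(source, text = text)
  score_class <- hq_iri("hypothesis-score", prefix_map)
  node <- tr$subject[tr$predicate == RDF_TYPE & tr$object == score_class]
  if (!length(node)) stop(hy_data_error("no hypothesis-score node in report"))
  mine <- tr[tr$subject == node[[1L]], , drop = FALSE]
  status <- mine$object[mine$predicate == hq_iri("has-status", prefix_map)]
  value <- mine$object[mine$predicate == hq_iri("has-value", prefix_map)]
  list(
    value = if (length(value)) as.numeric(value[[1L]]) else NA_real_,
    status = if (length(status)) status[[1L]] else NA_character_
  )
}
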