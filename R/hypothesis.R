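#' Hypotheses as logical event trees
#'
#' A hypothesis is a tree whose leaves are hypothesized events and whose
#' internal nodes are n-ary AND / OR / XOR operators (each with at least two
#' children), e.g. `OR(e1, AND(e2, e3), AND(e4, e5, e6))`. Each event names
#' an event type, a relation verb, actor and target entity references
#' (specific instances, type restrictions, or unbound variables for
#' question answering), and optionally a cellular location and a genetic
#' perturbation context (absent means wild type, `"wt"`). `negated_claim`
#' hypothesizes that the event does *not* occur.
#'
#' @name hypothesis
NULL

OPERATORS <- c("AND", "OR", "XOR")

#' Entity references
#'
#' `ref_instance()` names a specific entity; `ref_type()` restricts to any
#' entity with a declared type subsumed by `type_curie`; `ref_unbound()` is
#' a query variable (optionally type-restricted) that matches anything and
#' binds the matching entity id.
#'
#' @param curie Entity CURIE.
#' @param type_curie Ontology term CURIE restricting the entity type.
#' @param variable Variable token (conventionally `"?x"`).
#' @return An `entity_ref` object.
#' @export
ref_instance <- function(curie) {
  structure(list(mode = "instance", value = curie_norm(curie)),
            class = "entity_ref")
}

#' @rdname ref_instance
#' @export
ref_type <- function(type_curie) {
  structure(list(mode = "type-restricted", type_curie = curie_norm(type_curie)),
            class = "entity_ref")
}

#' @rdname ref_instance
#' @export
ref_unbound <- function(variable = "?x", type_curie = NULL) {
  structure(
    list(mode = "unbound", variable = variable,
         type_curie = if (is.null(type_curie)) NULL else curie_norm(type_curie)),
    class = "entity_ref"
  )
}

#' Construct a hypothesized event
#'
#' @param event_type One of the seven event types
#'   (`protein-protein-binding`, `protein-nucleic-acid-binding`,
#'   `activation`, `inhibition`, `induction`, `repression`, `transport`).
#' @param relation Relation verb token (e.g. `"induce"`).
#' @param actor,target [entity_ref] objects (bare CURIE strings are promoted
#'   to instance references).
#' @param label Event label, unique within a hypothesis; assigned
#'   automatically (`e1`, `e2`, ...) by [parse_hypothesis()] when absent.
#' @param location Optional GO cellular-component CURIE.
#' @param context Perturbation-context token; default `"wt"` (wild type).
#' @param negated_claim Hypothesize that the event does NOT occur.
#' @return A `hyp_event` object (also a valid leaf `hypothesis_node`).
#' @export
hyp_event <- function(event_type, relation, actor, target, label = NA_character_,
                      location = NULL, context = "wt", negated_claim = FALSE) {
  if (!event_type %in% EVENT_TYPES) {
    stop(hy_schema_error(sprintf("unknown event_type '%s'", event_type)))
  }
  promote <- function(r) if (inherits(r, "entity_ref")) r else ref_instance(r)
  structure(
    list(
      label = label, event_type = event_type, relation = relation,
      actor = promote(actor), target = promote(target),
      location = if (is.null(location)) NA_character_ else curie_norm(location),
      context = if (is.null(context) || is.na(context) || !nzchar(context)) "wt" else context,
      negated_claim = isTRUE(negated_claim)
    ),
    class = c("hyp_event", "hypothesis_node")
  )
}

#' Logical operator nodes
#'
#' @param ... Two or more `hypothesis_node` children (events or nested
#'   operator nodes).
#' @return An operator `hypothesis_node`.
#' @export
hyp_and <- function(...) hyp_operator("AND", list(...))

#' @rdname hyp_and
#' @export
hyp_or <- function(...) hyp_operator("OR", list(...))

#' @rdname hyp_and
#' @export
hyp_xor <- function(...) hyp_operator("XOR", list(...))

hyp_operator <- function(operator, children) {
  if (length(children) < 2L) {
    stop(hy_schema_error(sprintf(
      "%s node requires at least 2 children, got %d", operator, length(children)
    )))
  }
  ok <- vapply(children, inherits, TRUE, "hypothesis_node")
  if (!all(ok)) stop(hy_schema_error("operator children must be hypothesis nodes"))
  structure(list(operator = operator, children = children),
            class = c("hyp_group", "hypothesis_node"))
}

is_leaf <- function(node) inherits(node, "hyp_event")

#' Construct a hypothesis
#'
#' @param root A `hypothesis_node` (event leaf or operator tree).
#' @param id Hypothesis identifier (CURIE recommended).
#' @param title Free-text title.
#' @return A `hypothesis` object with labels assigned to unlabelled events.
#' @export
hypothesis <- function(root, id = "hqd:hypothesis-1", title = "") {
  if (!inherits(root, "hypothesis_node")) {
    stop(hy_schema_error("hypothesis root must be a hypothesis node"))
  }
  h <- structure(list(id = curie_norm(id), title = title, root = root),
                 class = "hypothesis")
  assign_labels(h)
}

assign_labels <- function(h) {
  counter <- 0L
  seen <- character()
  walk <- function(node) {
    if (is_leaf(node)) {
      counter <<- counter + 1L
      if (is.na(node$label) || !nzchar(node$label)) {
        node$label <- paste0("e", counter)
      }
      if (node$label %in% seen) {
        stop(hy_schema_error(sprintf("duplicate event label '%s'", node$label)))
      }
      seen <<- c(seen, node$label)
      node
    } else {
      node$children <- lapply(node$children, walk)
      node
    }
  }
  h$root <- walk(h$root)
  h
}

#' Collect the hypothesized events of a tree
#'
#' @param h A `hypothesis` or `hypothesis_node`.
#' @return Named list of `hyp_event` leaves, keyed by label, in document
#'   order.
#' @export
hypothesis_events <- function(h) {
  node <- if (inherits(h, "hypothesis")) h$root else h
  out <- list()
  walk <- function(n) {
    if (is_leaf(n)) out[[n$label]] <<- n else lapply(n$children, walk)
  }
  walk(node)
  out
}

#' @export
print.hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis> %s%s\n", x$id,
              if (nzchar(x$title)) paste0(": ", x$title) else ""))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is_leaf(node)) {
      cat(sprintf(
        "%s%s: %s %s %s -> %s [%s]%s\n", pad, node$label, node$event_type,
        describe_ref(node$actor), node$relation, describe_ref(node$target),
        node$context, if (node$negated_claim) " (negated claim)" else ""
      ))
    } else {
      cat(sprintf("%s%s\n", pad, node$operator))
      lapply(node$children, show, indent = indent + 1L)
    }
  }
  show(x$root, 1L)
  invisible(x)
}

describe_ref <- function(r) {
  switch(r$mode,
    instance = r$value,
    `type-restricted` = paste0("[a ", r$type_curie, "]"),
    unbound = paste0(r$variable,
                     if (!is.null(r$type_curie)) paste0(":", r$type_curie) else "")
  )
}

# ---- JSON document format -------------------------------------------------

ref_from_doc <- function(doc, where) {
  if (!is.list(doc)) stop(hy_schema_error(sprintf("%s: entity ref must be an object", where)))
  if (!is.null(doc$instance)) return(ref_instance(doc$instance))
  if (!is.null(doc$variable)) return(ref_unbound(doc$variable, doc$type))
  if (!is.null(doc$type)) return(ref_type(doc$type))
  stop(hy_schema_error(sprintf(
    "%s: entity ref needs one of 'instance', 'type', 'variable'", where
  )))
}

ref_to_doc <- function(r) {
  switch(r$mode,
    instance = list(instance = r$value),
    `type-restricted` = list(type = r$type_curie),
    unbound = c(list(variable = r$variable),
                if (!is.null(r$type_curie)) list(type = r$type_curie))
  )
}

node_from_doc <- function(doc) {
  if (!is.null(doc$event)) {
    ev <- doc$event
    for (req in c("event_type", "relation", "actor", "target")) {
      if (is.null(ev[[req]])) {
        stop(hy_schema_error(sprintf("event is missing required field '%s'", req)))
      }
    }
    hyp_event(
      event_type = ev$event_type,
      relation = ev$relation,
      actor = ref_from_doc(ev$actor, "actor"),
      target = ref_from_doc(ev$target, "target"),
      label = if (is.null(ev$label)) NA_character_ else ev$label,
      location = ev$location,
      context = if (is.null(ev$context)) "wt" else ev$context,
      negated_claim = isTRUE(ev$negated_claim)
    )
  } else if (!is.null(doc$operator)) {
    if (!doc$operator %in% OPERATORS) {
      stop(hy_schema_error(sprintf("unknown operator '%s'", doc$operator)))
    }
    if (is.null(doc$children) || length(doc$children) < 2L) {
      stop(hy_schema_error(sprintf(
        "%s node requires at least 2 children", doc$operator
      )))
    }
    hyp_operator(doc$operator, lapply(doc$children, node_from_doc))
  } else {
    stop(hy_schema_error("node must have either 'event' or 'operator'"))
  }
}

#' Parse a hypothesis document
#'
#' Reads the JSON exchange format (schema shipped at
#' `system.file("extdata", "hypothesis-schema.json", package = "hypeval")`):
#' an object with `id`, `title` and a `root` node, where a node is either
#' `{"event": {...}}` or `{"operator": "AND"|"OR"|"XOR", "children": [...]}`
#' with at least two children. Unlabelled events receive labels `e1`, `e2`,
#' ... in document order. All CURIEs are syntax-checked.
#'
#' @param doc Path to a JSON file, a JSON string, or an already-parsed list.
#' @return A [hypothesis] object.
#' @export
parse_hypothesis <- function(doc) {
  if (is.character(doc) && length(doc) == 1L) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  if (is.null(doc$root)) stop(hy_schema_error("hypothesis document has no 'root'"))
  h <- hypothesis(
    root = node_from_doc(doc$root),
    id = if (is.null(doc$id)) "hqd:hypothesis-1" else doc$id,
    title = if (is.null(doc$title)) "" else doc$title
  )
  check_curies(h)
  h
}

check_curies <- function(h) {
  for (ev in hypothesis_events(h)) {
    for (r in list(ev$actor, ev$target)) {
      v <- switch(r$mode, instance = r$value, `type-restricted` = r$type_curie,
                  unbound = r$type_curie)
      if (!is.null(v) && !is.na(v) && !is_curie(v)) {
        stop(hy_schema_error(sprintf(
          "event '%s': '%s' is not a valid CURIE", ev$label, v
        )))
      }
    }
    if (!is.na(ev$location) && !is_curie(ev$location)) {
      stop(hy_schema_error(sprintf(
        "event '%s': location '%s' is not a valid CURIE", ev$label, ev$location
      )))
    }
  }
  invisible(h)
}

node_to_doc <- function(node) {
  if (is_leaf(node)) {
    ev <- list(
      label = node$label,
      event_type = node$event_type,
      relation = node$relation,
      actor = ref_to_doc(node$actor),
      target = ref_to_doc(node$target)
    )
    if (!is.na(node$location)) ev$location <- node$location
    ev$context <- node$context
    if (node$negated_claim) ev$negated_claim <- TRUE
    list(event = ev)
  } else {
    list(operator = node$operator, children = lapply(node$children, node_to_doc))
  }
}

#' Serialize a hypothesis
#'
#' `format = "document"` emits the JSON exchange form, which round-trips
#' through [parse_hypothesis()] to an equal tree. `format = "ntriples"`
#' emits the linked-data form in the `hq:` vocabulary: the hypothesis
#' resource `hq:has-part` its root node, operator nodes carry an
#' `hq:operator` literal and `hq:has-part` their children, and each event
#' is an `hq:event` resource with its fields.
#'
#' @param h A [hypothesis].
#' @param format `"document"` or `"ntriples"`.
#' @param prefix_map CURIE prefix map for IRI expansion.
#' @return A character scalar (JSON) or character vector of N-Triples lines.
#' @export
serialize_hypothesis <- function(h, format = c("document", "ntriples"),
                                 prefix_map = default_prefix_map()) {
  format <- match.arg(format)
  if (format == "document") {
    doc <- list(id = h$id, title = h$title, root = node_to_doc(h$root))
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)))
  }
  ex <- function(x) expand_curie(x, prefix_map)
  hyp_iri <- ex(h$id)
  out <- list(nt_triple(hyp_iri, RDF_TYPE, hq_iri("hypothesis", prefix_map)))
  if (nzchar(h$title)) {
    out[[length(out) + 1L]] <- nt_triple(hyp_iri, RDFS_LABEL, h$title,
                                         object_is_iri = FALSE)
  }
  counter <- 0L
  emit <- function(node, parent_iri) {
    counter <<- counter + 1L
    iri <- paste0(hyp_iri, "-node-", counter)
    out[[length(out) + 1L]] <<- nt_triple(parent_iri, hq_iri("has-part", prefix_map), iri)
    if (is_leaf(node)) {
      out[[length(out) + 1L]] <<- nt_triple(iri, RDF_TYPE, hq_iri("event", prefix_map))
      add <- function(p, o, is_iri = FALSE, datatype = NA_character_) {
        out[[length(out) + 1L]] <<- nt_triple(iri, hq_iri(p, prefix_map), o,
                                              object_is_iri = is_iri,
                                              datatype = datatype)
      }
      add("label", node$label)
      add("event-type", node$event_type)
      add("relation", node$relation)
      emit_ref <- function(role, r) {
        switch(r$mode,
          instance = add(role, ex(r$value), is_iri = TRUE),
          `type-restricted` = add(paste0(role, "-type"), ex(r$type_curie), is_iri = TRUE),
          unbound = add(paste0(role, "-variable"), r$variable)
        )
      }
      emit_ref("actor", node$actor)
      emit_ref("target", node$target)
      if (!is.na(node$location)) add("location", ex(node$location), is_iri = TRUE)
      add("context", node$context)
      add("is-negated-claim", if (node$negated_claim) "true" else "false",
          datatype = XSD_BOOLEAN)
    } else {
      out[[length(out) + 1L]] <<- nt_triple(iri, RDF_TYPE, hq_iri("event-group", prefix_map))
      out[[length(out) + 1L]] <<- nt_triple(iri, hq_iri("operator", prefix_map),
                                            node$operator, object_is_iri = FALSE)
      for (ch in node$children) emit(ch, iri)
    }
  }
  emit(h$root, hyp_iri)
  write_ntriples(do.call(rbind, out))
}

#' Test two hypotheses for structural equality
#' @param a,b [hypothesis] objects.
#' @export
hypothesis_equal <- function(a, b) {
  identical(unserialize_canon(a), unserialize_canon(b))
}

unserialize_canon <- function(h) {
  jsonlite::fromJSON(serialize_hypothesis(h, "document"), simplifyVector = FALSE)
}
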