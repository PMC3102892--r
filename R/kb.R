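#' Event knowledge base
#'
#' A `knowledge_base` holds entities (gene products, genes, small molecules,
#' identified by CURIEs and typed with ontology terms) and event facts:
#' records of a (possibly negated) molecular event with an actor, a target,
#' an optional cellular location, a genetic perturbation context (`"wt"` for
#' wild type), an optional evidence code and a source citation. Facts are
#' indexed by actor, target and (actor, target, context) for candidate
#' retrieval. `owl:sameAs` identifier groups are resolved at load time to a
#' canonical id (the lexicographically smallest member).
#'
#' @name knowledge_base
NULL

EVENT_TYPES <- c(
  "protein-protein-binding", "protein-nucleic-acid-binding",
  "activation", "inhibition", "induction", "repression", "transport"
)

FACT_COLUMNS <- c(
  "fact_id", "event_type", "relation", "actor", "target",
  "location", "context", "evidence", "negated", "source"
)

empty_facts <- function() {
  data.frame(
    fact_id = character(), event_type = character(), relation = character(),
    actor = character(), target = character(), location = character(),
    context = character(), evidence = character(), negated = logical(),
    source = character(), stringsAsFactors = FALSE
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf(
    "<knowledge_base> %d entities (%d aliases), %d facts (%d negated)\n",
    length(x$entities), length(x$alias) - length(x$entities),
    nrow(x$facts), sum(x$facts$negated)
  ))
  invisible(x)
}

# Union-find identity resolution over declared ids and same_as mentions.
resolve_same_as <- function(entities) {
  ids <- names(entities)
  mentions <- unique(c(ids, unlist(lapply(entities, `[[`, "same_as"))))
  parent <- stats::setNames(mentions, mentions)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (e in entities) {
    for (al in e$same_as) {
      ra <- find(e$id); rb <- find(al)
      if (ra != rb) parent[[c_sort(c(ra, rb))[[2L]]]] <- c_min(c(ra, rb))
    }
  }
  roots <- vapply(mentions, find, "")
  # canonical = lexicographically smallest member of each group
  canonical <- vapply(split(mentions, roots), c_min, "")
  alias <- stats::setNames(canonical[roots], mentions)

  merged <- list()
  for (e in entities) {
    can <- alias[[e$id]]
    grp <- names(alias)[alias == can]
    if (is.null(merged[[can]])) {
      merged[[can]] <- list(
        id = can, name = e$name,
        types = e$types, functions = e$functions,
        same_as = c_sort(setdiff(grp, can))
      )
    } else {
      merged[[can]]$types <- c_sort(unique(c(merged[[can]]$types, e$types)))
      merged[[can]]$functions <- c_sort(unique(c(merged[[can]]$functions, e$functions)))
      if (!nzchar(merged[[can]]$name)) merged[[can]]$name <- e$name
    }
  }
  list(entities = merged[order(names(merged), method = "radix")], alias = alias)
}

build_indexes <- function(facts) {
  n <- nrow(facts)
  list(
    by_actor = split(seq_len(n), facts$actor),
    by_target = split(seq_len(n), facts$target),
    by_actor_target_context = split(
      seq_len(n),
      paste(facts$actor, facts$target, facts$context, sep = "\r")
    )
  )
}

#' Build a knowledge base from in-memory tables
#'
#' The programmatic constructor behind [load_kb()]: takes an entity list
#' (each element a list with `id`, `name`, `types`, `functions`, `same_as`)
#' and a fact data.frame in the frozen column order, resolves `same_as`
#' identity groups to canonical ids, canonicalizes fact actors/targets,
#' validates event types and entity references, and builds the indexes.
#'
#' @param entities List of entity records (or a data.frame with
#'   pipe-separated `types`, `functions`, `same_as` columns).
#' @param facts Data.frame with columns `fact_id`, `event_type`, `relation`,
#'   `actor`, `target`, `location`, `context`, `evidence`, `negated`,
#'   `source`. Empty strings in optional columns become `NA`; a missing
#'   context becomes `"wt"`.
#' @param store A [term_store]; ontology CURIEs used by entities and facts
#'   that do not resolve are reported by [validate_kb()], not rejected here.
#' @return A `knowledge_base` object.
#' @export
kb_from_tables <- function(entities, facts, store) {
  if (is.data.frame(entities)) entities <- entity_rows_to_list(entities)
  names(entities) <- vapply(entities, `[[`, "", "id")

  entities <- lapply(entities, function(e) {
    e$id <- curie_norm(e$id)
    e$types <- curie_norm(e$types)
    e$functions <- curie_norm(e$functions)
    e$same_as <- curie_norm(e$same_as)
    e
  })
  names(entities) <- vapply(entities, `[[`, "", "id")
  if (anyDuplicated(names(entities))) {
    stop(hy_data_error(sprintf(
      "duplicate entity id '%s'", names(entities)[duplicated(names(entities))][1L]
    )))
  }

  res <- resolve_same_as(entities)

  facts <- as.data.frame(facts, stringsAsFactors = FALSE)
  missing_cols <- setdiff(FACT_COLUMNS, names(facts))
  if (length(missing_cols)) {
    stop(hy_schema_error(paste(
      "fact table missing column(s):", paste(missing_cols, collapse = ", ")
    )))
  }
  facts <- facts[FACT_COLUMNS]
  for (col in c("location", "evidence", "source")) {
    facts[[col]][!is.na(facts[[col]]) & !nzchar(facts[[col]])] <- NA_character_
  }
  facts$context[is.na(facts$context) | !nzchar(facts$context)] <- "wt"
  if (is.character(facts$negated)) {
    facts$negated <- tolower(facts$negated) %in% c("true", "1", "yes")
  }
  facts$negated[is.na(facts$negated)] <- FALSE

  bad_type <- !(facts$event_type %in% EVENT_TYPES)
  if (any(bad_type)) {
    stop(hy_data_error(sprintf(
      "unknown event_type '%s' in fact '%s'",
      facts$event_type[bad_type][1L], facts$fact_id[bad_type][1L]
    )))
  }

  canon <- function(x) {
    x <- curie_norm(x)
    hit <- res$alias[x]
    unname(ifelse(is.na(hit), x, hit))
  }
  facts$actor <- canon(facts$actor)
  facts$target <- canon(facts$target)
  facts$location <- ifelse(is.na(facts$location), NA_character_,
                           curie_norm(facts$location))
  facts$evidence <- ifelse(is.na(facts$evidence), NA_character_,
                           curie_norm(facts$evidence))

  undeclared <- !(facts$actor %in% names(res$entities)) |
    !(facts$target %in% names(res$entities))
  if (any(undeclared)) {
    stop(hy_data_error(paste(
      "fact(s) reference undeclared entities:",
      paste(facts$fact_id[undeclared], collapse = ", ")
    )))
  }

  rownames(facts) <- NULL
  structure(
    list(
      entities = res$entities,
      alias = res$alias,
      facts = facts,
      indexes = build_indexes(facts),
      ignored_predicates = 0L
    ),
    class = "knowledge_base"
  )
}

entity_rows_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    list(
      id = df$id[i],
      name = if ("name" %in% names(df)) df$name[i] else "",
      types = split_pipe(df$types[i]),
      functions = if ("functions" %in% names(df)) split_pipe(df$functions[i]) else character(),
      same_as = if ("same_as" %in% names(df)) split_pipe(df$same_as[i]) else character()
    )
  })
}

#' Canonical entity id after identity resolution
#'
#' @param kb A [knowledge_base].
#' @param curie Entity CURIE or known alias.
#' @return The canonical CURIE of the identity group, or the normalized
#'   input if unknown to the knowledge base.
#' @export
canonical_id <- function(kb, curie) {
  curie <- curie_norm(curie)
  hit <- kb$alias[curie]
  unname(ifelse(is.na(hit), curie, hit))
}

#' Load a knowledge base from files
#'
#' Facts may come as the frozen 10-column TSV dialect (columns `fact_id`,
#' `event_type`, `relation`, `actor`, `target`, `location`, `context`,
#' `evidence`, `negated`, `source`) or as N-Triples using the `hq:` predicate
#' vocabulary (a reconstruction, documented in the package vignette;
#' unrecognized predicates are ignored and counted). Entities come as a TSV
#' (`id`, `name`, pipe-separated `types`, `functions`, `same_as`) or as
#' N-Triples.
#'
#' @param fact_source,entity_source File paths.
#' @param store A [term_store].
#' @param format `"tsv"`, `"ntriples"`, or `NULL` to infer per file from the
#'   extension.
#' @param prefix_map CURIE prefix map for N-Triples contraction.
#' @return A [knowledge_base].
#' @export
load_kb <- function(fact_source, entity_source, store, format = NULL,
                    prefix_map = default_prefix_map()) {
  fmt_of <- function(path) {
    if (!is.null(format)) format
    else if (grepl("\\.(nt|ntriples)$", path)) "ntriples" else "tsv"
  }
  ignored <- 0L
  facts <- if (fmt_of(fact_source) == "ntriples") {
    r <- read_facts_ntriples(fact_source, prefix_map)
    ignored <- ignored + r$ignored
    r$facts
  } else {
    read_facts_tsv(fact_source)
  }
  ents <- if (fmt_of(entity_source) == "ntriples") {
    r <- read_entities_ntriples(entity_source, prefix_map)
    ignored <- ignored + r$ignored
    r$entities
  } else {
    read_entities_tsv(entity_source)
  }
  kb <- kb_from_tables(ents, facts, store)
  kb$ignored_predicates <- ignored
  if (ignored > 0L) {
    message(sprintf("load_kb: ignored %d unrecognized N-Triples predicate occurrence(s)", ignored))
  }
  kb
}

read_facts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(FACT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(hy_schema_error(paste(
      "fact TSV missing column(s):", paste(missing_cols, collapse = ", ")
    )))
  }
  df
}

read_entities_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("id", "types") %in% names(df))) {
    stop(hy_schema_error("entity TSV must have at least columns id, types"))
  }
  df
}

hq_iri <- function(local, prefix_map = default_prefix_map()) {
  expand_curie(paste0("hq:", local), prefix_map)
}

FACT_PREDICATES <- c("event-type", "relation", "actor", "target", "location",
                     "context", "evidence", "is-negated", "source")

read_facts_ntriples <- function(path, prefix_map) {
  tr <- read_ntriples(path)
  pred_map <- stats::setNames(
    vapply(FACT_PREDICATES, hq_iri, "", prefix_map = prefix_map),
    FACT_PREDICATES
  )
  known <- c(pred_map, type = RDF_TYPE)
  ignored <- sum(!(tr$predicate %in% known))
  tr <- tr[tr$predicate %in% known, , drop = FALSE]
  subjects <- unique(tr$subject)
  ctr <- function(x) curie_norm(contract_iri(x, prefix_map))
  rows <- lapply(subjects, function(s) {
    mine <- tr[tr$subject == s, , drop = FALSE]
    get1 <- function(p, iri = FALSE) {
      v <- mine$object[mine$predicate == pred_map[[p]]]
      if (!length(v)) return(NA_character_)
      if (iri) ctr(v[[1L]]) else v[[1L]]
    }
    data.frame(
      fact_id = ctr(s),
      event_type = get1("event-type"),
      relation = get1("relation"),
      actor = get1("actor", iri = TRUE),
      target = get1("target", iri = TRUE),
      location = get1("location", iri = TRUE),
      context = get1("context"),
      evidence = get1("evidence", iri = TRUE),
      negated = identical(get1("is-negated"), "true"),
      source = get1("source"),
      stringsAsFactors = FALSE
    )
  })
  facts <- if (length(rows)) do.call(rbind, rows) else empty_facts()
  list(facts = facts[order(facts$fact_id, method = "radix"), , drop = FALSE], ignored = ignored)
}

ENTITY_PREDICATES <- c("has-type", "has-function")

read_entities_ntriples <- function(path, prefix_map) {
  tr <- read_ntriples(path)
  has_type <- hq_iri("has-type", prefix_map)
  has_fun <- hq_iri("has-function", prefix_map)
  known <- c(has_type, has_fun, RDFS_LABEL, OWL_SAMEAS, RDF_TYPE)
  ignored <- sum(!(tr$predicate %in% known))
  tr <- tr[tr$predicate %in% known, , drop = FALSE]
  ctr <- function(x) curie_norm(contract_iri(x, prefix_map))
  subjects <- unique(tr$subject)
  ents <- lapply(subjects, function(s) {
    mine <- tr[tr$subject == s, , drop = FALSE]
    lab <- mine$object[mine$predicate == RDFS_LABEL]
    list(
      id = ctr(s),
      name = if (length(lab)) lab[[1L]] else "",
      types = c_sort(vapply(mine$object[mine$predicate == has_type], ctr, "")),
      functions = c_sort(vapply(mine$object[mine$predicate == has_fun], ctr, "")),
      same_as = c_sort(vapply(mine$object[mine$predicate == OWL_SAMEAS], ctr, ""))
    )
  })
  list(entities = ents, ignored = ignored)
}

#' Serialize a knowledge base
#'
#' Writes the entity and fact tables in either the frozen TSV dialect or the
#' `hq:` N-Triples vocabulary. A TSV round trip through [load_kb()]
#' reproduces the fact multiset and entity map exactly.
#'
#' @param kb A [knowledge_base].
#' @param fact_path,entity_path Output file paths.
#' @param format `"tsv"` or `"ntriples"`.
#' @param prefix_map CURIE prefix map for IRI expansion.
#' @return Invisibly, the paths written.
#' @export
write_kb <- function(kb, fact_path, entity_path, format = c("tsv", "ntriples"),
                     prefix_map = default_prefix_map()) {
  format <- match.arg(format)
  if (format == "tsv") {
    facts <- kb$facts
    facts$negated <- ifelse(facts$negated, "true", "false")
    for (col in c("location", "evidence", "source")) {
      facts[[col]][is.na(facts[[col]])] <- ""
    }
    utils::write.table(facts, fact_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ents <- data.frame(
      id = names(kb$entities),
      name = vapply(kb$entities, `[[`, "", "name"),
      types = vapply(kb$entities, function(e) paste(e$types, collapse = "|"), ""),
      functions = vapply(kb$entities, function(e) paste(e$functions, collapse = "|"), ""),
      same_as = vapply(kb$entities, function(e) paste(e$same_as, collapse = "|"), ""),
      stringsAsFactors = FALSE
    )
    utils::write.table(ents, entity_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(write_ntriples(facts_to_triples(kb$facts, prefix_map)), fact_path)
    writeLines(write_ntriples(entities_to_triples(kb$entities, prefix_map)), entity_path)
  }
  invisible(c(fact_path, entity_path))
}

facts_to_triples <- function(facts, prefix_map) {
  ex <- function(x) expand_curie(x, prefix_map)
  out <- list()
  for (i in seq_len(nrow(facts))) {
    f <- facts[i, ]
    s <- ex(f$fact_id)
    out[[length(out) + 1L]] <- nt_triple(s, RDF_TYPE, hq_iri("event", prefix_map))
    add <- function(p, o, iri = TRUE, datatype = NA_character_) {
      out[[length(out) + 1L]] <<- nt_triple(s, hq_iri(p, prefix_map), o,
                                            object_is_iri = iri,
                                            datatype = datatype)
    }
    add("event-type", f$event_type, iri = FALSE)
    add("relation", f$relation, iri = FALSE)
    add("actor", ex(f$actor))
    add("target", ex(f$target))
    if (!is.na(f$location)) add("location", ex(f$location))
    add("context", f$context, iri = FALSE)
    if (!is.na(f$evidence)) add("evidence", ex(f$evidence))
    add("is-negated", if (f$negated) "true" else "false", iri = FALSE,
        datatype = XSD_BOOLEAN)
    if (!is.na(f$source)) add("source", f$source, iri = FALSE)
  }
  do.call(rbind, out)
}

entities_to_triples <- function(entities, prefix_map) {
  ex <- function(x) expand_curie(x, prefix_map)
  out <- list()
  for (e in entities) {
    s <- ex(e$id)
    out[[length(out) + 1L]] <- nt_triple(s, RDF_TYPE, hq_iri("entity", prefix_map))
    if (nzchar(e$name)) {
      out[[length(out) + 1L]] <- nt_triple(s, RDFS_LABEL, e$name, object_is_iri = FALSE)
    }
    for (ty in e$types) {
      out[[length(out) + 1L]] <- nt_triple(s, hq_iri("has-type", prefix_map), ex(ty))
    }
    for (fn in e$functions) {
      out[[length(out) + 1L]] <- nt_triple(s, hq_iri("has-function", prefix_map), ex(fn))
    }
    for (al in e$same_as) {
      out[[length(out) + 1L]] <- nt_triple(s, OWL_SAMEAS, ex(al))
    }
  }
  do.call(rbind, out)
}

#' Validate a knowledge base
#'
#' A pure reporting operation: returns a data.frame of diagnostics with
#' levels `"error"`, `"warning"` and `"info"`. Checked: duplicate fact ids;
#' actor/target references outside the entity map; ontology CURIEs (entity
#' types/functions, fact locations and evidence codes) that do not resolve
#' in the store; and fact/negation contradiction pairs — a fact and its
#' negation with otherwise identical fields are reported as an informational
#' pair, never an error, since the knowledge base deliberately permits
#' contradicting assertions about the same conditions.
#'
#' @param kb A [knowledge_base].
#' @param store Optional [term_store] for ontology-reference checks.
#' @return Data.frame with columns `level`, `code`, `message`.
#' @export
validate_kb <- function(kb, store = NULL) {
  diags <- list()
  note <- function(level, code, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      level = level, code = code, message = message, stringsAsFactors = FALSE
    )
  }
  facts <- kb$facts

  dup <- facts$fact_id[duplicated(facts$fact_id)]
  for (d in unique(dup)) note("error", "duplicate_fact_id", sprintf("duplicate fact id '%s'", d))

  for (col in c("actor", "target")) {
    bad <- !(facts[[col]] %in% names(kb$entities))
    for (i in which(bad)) {
      note("error", "dangling_entity_ref",
           sprintf("fact '%s' %s '%s' is not a declared entity",
                   facts$fact_id[i], col, facts[[col]][i]))
    }
  }

  if (!is.null(store)) {
    known <- term_ids(store)
    for (e in kb$entities) {
      for (t in setdiff(c(e$types, e$functions), known)) {
        note("warning", "dangling_term_ref",
             sprintf("entity '%s' references unresolvable term '%s'", e$id, t))
      }
    }
    locs <- stats::na.omit(unique(c(facts$location, facts$evidence)))
    for (t in setdiff(locs, known)) {
      note("warning", "dangling_term_ref",
           sprintf("fact field references unresolvable term '%s'", t))
    }
  }

  if (nrow(facts) > 1L) {
    key <- paste(facts$event_type, facts$relation, facts$actor, facts$target,
                 ifelse(is.na(facts$location), "", facts$location),
                 facts$context, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      grp <- facts[key == k, , drop = FALSE]
      if (length(unique(grp$negated)) == 2L) {
        note("info", "contradiction_pair",
             sprintf("facts {%s} assert and negate the same event conditions",
                     paste(grp$fact_id, collapse = ", ")))
      }
    }
  }

  if (!length(diags)) {
    return(data.frame(level = character(), code = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}
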