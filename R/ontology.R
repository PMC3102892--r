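#' Ontology term store with transitive subsumption
#'
#' A `term_store` holds ontology terms (GO / SO / CHEBI / ECO excerpts) as a
#' directed acyclic is-a graph, plus an optional part-of edge layer kept
#' strictly separate from is-a: mixing the two edge semantics would silently
#' change rule outcomes. The reflexive-transitive is-a closure is precomputed
#' at load time, so subsumption queries are O(1) lookups.
#'
#' @name term_store
NULL

new_term_store <- function(terms, prefix_map, dangling = character()) {
  structure(
    list(terms = terms, prefix_map = prefix_map, dangling = dangling,
         ancestors = NULL, part_ancestors = NULL),
    class = "term_store"
  )
}

#' @export
print.term_store <- function(x, ...) {
  cat(sprintf(
    "<term_store> %d terms, %d is-a edges, %d part-of edges\n",
    length(x$terms),
    sum(lengths(lapply(x$terms, `[[`, "parents"))),
    sum(lengths(lapply(x$terms, `[[`, "part_of")))
  ))
  invisible(x)
}

#' Load ontology terms
#'
#' Accepts either the 3-column TSV dialect (`id`, `label`, `parents` with
#' pipe-separated parent CURIEs; an optional 4th `part_of` column is
#' recognized) or N-Triples with `rdfs:subClassOf` is-a edges, `rdfs:label`
#' labels, and `hq:part-of` parthood edges. Parents that are referenced but
#' never defined are auto-created as bare root terms with a warning, so
#' partial ontology excerpts load cleanly. The parent relation must be
#' acyclic; a cycle is a hard error naming one member.
#'
#' @param source Path to a `.tsv`/`.nt` file (format sniffed from the
#'   extension unless `format` is given).
#' @param format One of `"tsv"`, `"ntriples"`, or `NULL` to infer.
#' @param prefix_map CURIE prefix map used for N-Triples contraction.
#' @return A [term_store] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tlabel\tparents",
#'              "chebi:33699\tmRNA\tchebi:33697",
#'              "chebi:33697\tRNA\tchebi:23367",
#'              "chebi:23367\tmolecular entity\t"), tf)
#' store <- load_terms(tf)
#' is_a("chebi:33699", "chebi:23367", store)
#' @export
load_terms <- function(source, format = NULL, prefix_map = default_prefix_map()) {
  if (is.null(format)) {
    format <- if (grepl("\\.(nt|ntriples)$", source)) "ntriples" else "tsv"
  }
  rows <- switch(
    format,
    tsv = read_term_tsv(source),
    ntriples = read_term_ntriples(source, prefix_map),
    stop(hy_schema_error(sprintf("unknown ontology format '%s'", format)))
  )
  build_term_store(rows, prefix_map)
}

read_term_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("id", "label", "parents") %in% names(df))) {
    stop(hy_schema_error("ontology TSV must have columns id, label, parents"))
  }
  if (!"part_of" %in% names(df)) df$part_of <- ""
  data.frame(
    id = df$id, label = df$label, parents = df$parents,
    part_of = df$part_of, stringsAsFactors = FALSE
  )
}

read_term_ntriples <- function(path, prefix_map) {
  tr <- read_ntriples(path)
  tr$s <- curie_norm(vapply(tr$subject, contract_iri, "", prefix_map = prefix_map))
  part_of_iri <- expand_curie("hq:part-of", prefix_map)
  ids <- unique(tr$s)
  rows <- lapply(ids, function(id) {
    mine <- tr[tr$s == id, , drop = FALSE]
    lab <- mine$object[mine$predicate == RDFS_LABEL]
    par <- mine$object[mine$predicate == RDFS_SUBCLASSOF]
    po <- mine$object[mine$predicate == part_of_iri]
    data.frame(
      id = id,
      label = if (length(lab)) lab[[1L]] else "",
      parents = paste(curie_norm(vapply(par, contract_iri, "", prefix_map = prefix_map)),
                      collapse = "|"),
      part_of = paste(curie_norm(vapply(po, contract_iri, "", prefix_map = prefix_map)),
                      collapse = "|"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1L]]
}

build_term_store <- function(rows, prefix_map) {
  rows$id <- curie_norm(rows$id)
  if (anyDuplicated(rows$id)) {
    stop(hy_schema_error(sprintf(
      "duplicate ontology term id '%s'", rows$id[duplicated(rows$id)][1L]
    )))
  }
  terms <- lapply(seq_len(nrow(rows)), function(i) {
    list(
      id = rows$id[i],
      label = rows$label[i],
      parents = curie_norm(split_pipe(rows$parents[i])),
      part_of = curie_norm(split_pipe(rows$part_of[i]))
    )
  })
  names(terms) <- rows$id

  referenced <- unique(unlist(lapply(terms, function(t) c(t$parents, t$part_of))))
  dangling <- setdiff(referenced, names(terms))
  if (length(dangling)) {
    warning(sprintf(
      "auto-creating %d dangling parent term(s) as bare roots: %s",
      length(dangling), paste(dangling, collapse = ", ")
    ), call. = FALSE)
    for (d in dangling) {
      terms[[d]] <- list(id = d, label = "", parents = character(),
                         part_of = character())
    }
  }

  store <- new_term_store(terms, prefix_map, dangling)
  store$ancestors <- closure_over(terms, "parents", check_acyclic = TRUE)
  store$part_ancestors <- closure_over(terms, "part_of", check_acyclic = TRUE)
  store
}

# Reflexive-transitive closure over one edge label; igraph does the DAG
# validation and reachability.
closure_over <- function(terms, field, check_acyclic = FALSE) {
  ids <- names(terms)
  edges <- do.call(rbind, lapply(terms, function(t) {
    ps <- t[[field]]
    if (length(ps)) cbind(t$id, ps) else NULL
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    out <- as.list(ids)
    names(out) <- ids
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (check_acyclic && !igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    member <- igraph::ends(g, cyc[[1L]])[1L]
    stop(hy_schema_error(sprintf(
      "cycle in ontology '%s' relation involving term '%s'", field, member
    )))
  }
  reach <- lapply(ids, function(v) {
    names(igraph::subcomponent(g, v, mode = "out"))
  })
  names(reach) <- ids
  reach
}

resolve_term <- function(curie, store) {
  curie <- curie_norm(curie)
  if (is.null(store$terms[[curie]])) {
    stop(hy_data_error(sprintf("CURIE '%s' does not resolve in the term store", curie)))
  }
  curie
}

#' Subsumption (is-a) test
#'
#' True iff `ancestor` is reachable from `term` through zero or more is-a
#' parent edges (reflexive and transitive), so a query for a general type
#' such as RNA also matches entities annotated with more specific types such
#' as messenger RNA.
#'
#' @param term,ancestor Term CURIEs; both must resolve in the store.
#' @param store A [term_store].
#' @return Logical scalar.
#' @export
is_a <- function(term, ancestor, store) {
  term <- resolve_term(term, store)
  ancestor <- resolve_term(ancestor, store)
  ancestor %in% store$ancestors[[term]]
}

#' Transitive parthood test
#'
#' Analogue of [is_a()] over the part-of edge layer; reflexive and
#' transitive. Kept separate from is-a so that rule evaluation semantics
#' never mix the two relations. Unused by the shipped default rule sets.
#'
#' @inheritParams is_a
#' @param whole Candidate whole term CURIE.
#' @export
has_part_transitive <- function(term, whole, store) {
  term <- resolve_term(term, store)
  whole <- resolve_term(whole, store)
  whole %in% store$part_ancestors[[term]]
}

term_ids <- function(store) names(store$terms)
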