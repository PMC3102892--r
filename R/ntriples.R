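# Minimal strict N-Triples subset: one triple per line, IRI subject and
# predicate, IRI or literal object (optional ^^<datatype> or @lang tag).
# Comments (#...) and blank lines are permitted. Blank nodes are not.

NT_LINE_RE <- paste0(
  "^\\s*<([^>]*)>\\s+<([^>]*)>\\s+",
  "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^>]*)>|@([A-Za-z0-9-]+))?)",
  "\\s*\\.\\s*$"
)

nt_unescape <- function(x) {
  x <- gsub("\\\\t", "\t", x)
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\r", "\r", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

nt_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\r", "\\\\r", x)
  gsub("\t", "\\\\t", x)
}

#' Parse an N-Triples file or character vector
#'
#' Supports the strict line-oriented subset used by the package's knowledge
#' base and report serializations: IRI subjects/predicates and IRI or literal
#' objects. Returns one row per triple with the object kind recorded.
#'
#' @param source File path, or a character vector of N-Triples lines when
#'   `text = TRUE`.
#' @param text Interpret `source` as literal lines rather than a path.
#' @return A data.frame with columns `subject`, `predicate`, `object`
#'   (IRIs or unescaped literal values), `object_is_iri` (logical) and
#'   `datatype` (IRI or `NA`).
#' @export
read_ntriples <- function(source, text = FALSE) {
  lines <- if (text) source else readLines(source, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(
      subject = character(), predicate = character(), object = character(),
      object_is_iri = logical(), datatype = character(),
      stringsAsFactors = FALSE
    ))
  }
  m <- regmatches(lines, regexec(NT_LINE_RE, lines, perl = TRUE))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop(hy_data_error(sprintf(
      "invalid N-Triples line: %s", lines[which(bad)[1L]]
    )))
  }
  parts <- do.call(rbind, lapply(m, function(g) g[-1L]))
  iri_obj <- nzchar(parts[, 3L])
  data.frame(
    subject = parts[, 1L],
    predicate = parts[, 2L],
    object = ifelse(iri_obj, parts[, 3L], nt_unescape(parts[, 4L])),
    object_is_iri = iri_obj,
    datatype = ifelse(!iri_obj & nzchar(parts[, 5L]), parts[, 5L], NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Serialize triples to N-Triples lines
#'
#' @param triples A data.frame as returned by [read_ntriples()] (the
#'   `datatype` column is optional).
#' @return Character vector of N-Triples lines.
#' @export
write_ntriples <- function(triples) {
  dt <- if ("datatype" %in% names(triples)) triples$datatype else rep(NA_character_, nrow(triples))
  obj <- ifelse(
    triples$object_is_iri,
    paste0("<", triples$object, ">"),
    paste0(
      "\"", nt_escape(triples$object), "\"",
      ifelse(is.na(dt), "", paste0("^^<", dt, ">"))
    )
  )
  paste0("<", triples$subject, "> <", triples$predicate, "> ", obj, " .")
}

nt_triple <- function(subject, predicate, object, object_is_iri = TRUE,
                      datatype = NA_character_) {
  data.frame(
    subject = subject, predicate = predicate, object = object,
    object_is_iri = object_is_iri, datatype = datatype,
    stringsAsFactors = FALSE
  )
}

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_SUBCLASSOF <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
OWL_SAMEAS <- "http://www.w3.org/2002/07/owl#sameAs"
XSD_BOOLEAN <- "http://www.w3.org/2001/XMLSchema#boolean"
XSD_DECIMAL <- "http://www.w3.org/2001/XMLSchema#decimal"
XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"
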