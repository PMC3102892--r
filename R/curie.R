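#' @keywords internal
"_PACKAGE"

#' Default CURIE prefix map
#'
#' Returns the prefix map shipped with the package, covering the namespaces
#' used by the GAL knowledge base and the evaluation vocabulary (`sgd:`,
#' `chebi:`, `go:`, `so:`, `eco:`, `hkb:`, `hq:`, `hqd:`). Prefixes are
#' lower-case; local parts are case-significant.
#'
#' @param path Optional path to a JSON prefix-map file (object of
#'   prefix -> namespace IRI). Defaults to the packaged map.
#' @return Named character vector mapping prefix to namespace IRI.
#' @export
default_prefix_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "prefixes.json", package = "hypeval")
  }
  pm <- jsonlite::fromJSON(path)
  out <- unlist(pm)
  names(out) <- tolower(names(out))
  out
}

# Normalize a CURIE: lower-case the prefix, keep the local part verbatim.
curie_norm <- function(x) {
  ifelse(
    grepl(":", x, fixed = TRUE),
    paste0(
      tolower(sub(":.*$", "", x)), ":",
      sub("^[^:]*:", "", x)
    ),
    x
  )
}

is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9._-]*:[^[:space:]]+$", x)
}

#' Expand a CURIE to a full IRI
#' @param curie CURIE string such as `"go:0005634"`.
#' @param prefix_map Named character vector (see [default_prefix_map()]).
#' @return Full IRI string.
#' @export
expand_curie <- function(curie, prefix_map = default_prefix_map()) {
  curie <- curie_norm(curie)
  prefix <- sub(":.*$", "", curie)
  local <- sub("^[^:]*:", "", curie)
  ns <- prefix_map[[prefix]]
  if (is.null(ns)) {
    stop(hy_data_error(sprintf("unknown CURIE prefix '%s' in '%s'", prefix, curie)))
  }
  paste0(ns, local)
}

#' Contract a full IRI to a CURIE
#'
#' Longest-namespace match wins. IRIs outside every registered namespace are
#' returned unchanged.
#' @inheritParams expand_curie
#' @param iri Full IRI string.
#' @export
contract_iri <- function(iri, prefix_map = default_prefix_map()) {
  ns <- prefix_map[order(nchar(prefix_map), decreasing = TRUE)]
  for (i in seq_along(ns)) {
    if (startsWith(iri, ns[[i]])) {
      return(paste0(names(ns)[i], ":", substring(iri, nchar(ns[[i]]) + 1L)))
    }
  }
  iri
}

# Locale-independent (C collation) string ordering, so canonical ids,
# tie-breaks and serialized output are identical across environments.
c_sort <- function(x) x[order(x, method = "radix")]

c_min <- function(x) c_sort(x)[[1L]]

# Condition constructors: schema/config problems vs data problems. The CLI
# maps these classes to distinct exit codes.
hy_schema_error <- function(msg) {
  errorCondition(msg, class = c("hy_schema_error", "hy_error"))
}

hy_data_error <- function(msg) {
  errorCondition(msg, class = c("hy_data_error", "hy_error"))
}
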