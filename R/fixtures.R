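#' The GAL-network worked knowledge base
#'
#' Loads the packaged knowledge base describing the yeast galactose (GAL)
#' regulatory system: the Gal4p/Gal3p/Gal80p induction circuit over the
#' GAL1/GAL2/GAL7 genes, galactose transport by Gal2p, and the three
#' proteins known to bind the GAL1 promoter in wild type (Mig1p, Spt15p
#' with a curated-database evidence code, and Gal4p). Annotations encode
#' the worked evaluation traces — for example Gal4p deliberately carries no
#' transcription-factor-activity function annotation, so the actor-function
#' rule scores 0 and each induction event scores 4 of 5 — and are synthetic
#' in that sense, not a dump of curated SGD biology.
#'
#' @return List with elements `kb` (a [knowledge_base]) and `store`
#'   (a [term_store]).
#' @examples
#' fx <- build_gal_fixture()
#' rs <- load_rulesets()
#' ev <- hyp_event("induction", "induce", "sgd:Gal4p", "sgd:GAL1", label = "e1")
#' score_event(ev, fx$kb, rs, fx$store)
#' @export
build_gal_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "hypeval")
  store <- load_terms(ext("gal_ontology.tsv"))
  kb <- load_kb(ext("gal_facts.tsv"), ext("gal_entities.tsv"), store)
  list(kb = kb, store = store)
}

#' Paths of the packaged GAL fixture and hypothesis documents
#' @return Named character vector of installed file paths.
#' @export
gal_fixture_paths <- function() {
  files <- c(
    ontology = "gal_ontology.tsv",
    entities = "gal_entities.tsv",
    facts = "gal_facts.tsv",
    induction_hypothesis = "gal-induction-hypothesis.json",
    transport_hypothesis = "gal-transport-hypothesis.json",
    rulesets = "rulesets-default.json",
    prefixes = "prefixes.json"
  )
  vapply(files, function(f) system.file("extdata", f, package = "hypeval"), "")
}

#' Specification for a random knowledge base
#'
#' @param seed Integer RNG seed; the same seed yields a byte-identical
#'   serialized knowledge base.
#' @param n_entities,n_facts Sizes (at least 2 entities when facts are
#'   requested).
#' @param negation_rate Probability a fact carries the negation flag.
#' @param annotation_completeness Probability that each optional,
#'   rule-relevant annotation (actor function, fact location, canonical
#'   relation verb, ideal target type) is present/ideal; at 1 every fact is
#'   an ideal candidate for its event type under the default rule sets.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, n_entities = 25L, n_facts = 60L,
                         negation_rate = 0.05, annotation_completeness = 0.7) {
  stopifnot(negation_rate >= 0, negation_rate <= 1,
            annotation_completeness >= 0, annotation_completeness <= 1)
  structure(
    list(seed = as.integer(seed), n_entities = as.integer(n_entities),
         n_facts = as.integer(n_facts), negation_rate = negation_rate,
         annotation_completeness = annotation_completeness),
    class = "fixture_spec"
  )
}

# Ideal fact profile per event type, mirroring the default rule sets.
IDEAL_PROFILE <- list(
  "protein-protein-binding" = list(
    target_type = "chebi:36080", fun = "go:0005515",
    location = "go:0005622", relation = "bind"
  ),
  "protein-nucleic-acid-binding" = list(
    target_type = "so:0000236", fun = "go:0003677",
    location = "go:0005634", relation = "bind"
  ),
  activation = list(
    target_type = "chebi:36080", fun = "go:0030234",
    location = "go:0005622", relation = "activate"
  ),
  inhibition = list(
    target_type = "chebi:36080", fun = "go:0004857",
    location = "go:0005622", relation = "inhibit"
  ),
  induction = list(
    target_type = "so:0000236", fun = "go:0003702",
    location = "go:0005634", relation = "induce"
  ),
  repression = list(
    target_type = "so:0000236", fun = "go:0016564",
    location = "go:0005634", relation = "repress"
  ),
  transport = list(
    target_type = "chebi:28260", fun = "go:0005215",
    location = "go:0016020", relation = "transport"
  )
)

#' Generate a random knowledge base
#'
#' Deterministic per seed. Entities are typed protein; facts draw an event
#' type uniformly from the seven types, with actors and targets sampled
#' from the entity pool (targets re-typed to the event type's ideal target
#' type with probability `annotation_completeness`, else left as protein).
#' Actor function, location and the canonical relation verb are each
#' ideal with probability `annotation_completeness` (otherwise absent or a
#' deviating value); the negation flag is set at `negation_rate`; a
#' minority of facts carry an evidence code or a non-wild-type context.
#' With `annotation_completeness = 1` and `negation_rate = 0` every fact is
#' an ideal candidate, so a single-event hypothesis built from any fact
#' scores exactly 1 under the default rule sets.
#'
#' @param spec A [fixture_spec()].
#' @param store A [term_store] containing the GAL fixture terms (e.g. from
#'   [build_gal_fixture()]).
#' @return A [knowledge_base].
#' @export
gen_random_kb <- function(spec, store) {
  if (spec$n_facts > 0L && spec$n_entities < 2L) {
    stop(hy_data_error("need at least 2 entities to generate facts"))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(spec$seed)

  p <- spec$annotation_completeness
  ids <- sprintf("rkb:ent%03d", seq_len(spec$n_entities))
  entities <- lapply(ids, function(id) {
    list(id = id, name = sub("^rkb:", "", id), types = "chebi:36080",
         functions = character(), same_as = character())
  })
  names(entities) <- ids

  rows <- vector("list", spec$n_facts)
  for (i in seq_len(spec$n_facts)) {
    etype <- sample(EVENT_TYPES, 1L)
    prof <- IDEAL_PROFILE[[etype]]
    pair <- sample(ids, 2L)
    actor <- pair[[1L]]; target <- pair[[2L]]
    if (stats::runif(1) < p) {
      entities[[target]]$types <-
        c_sort(unique(c(entities[[target]]$types, prof$target_type)))
    }
    if (stats::runif(1) < p) {
      entities[[actor]]$functions <-
        c_sort(unique(c(entities[[actor]]$functions, prof$fun)))
    }
    relation <- if (stats::runif(1) < p) prof$relation else "interact"
    location <- if (stats::runif(1) < p) prof$location else NA_character_
    context <- if (stats::runif(1) < 0.9) "wt" else "GAL3 over-expressed"
    evidence <- if (stats::runif(1) < 0.3) "eco:0000008" else NA_character_
    rows[[i]] <- data.frame(
      fact_id = sprintf("rkb:f%04d", i), event_type = etype,
      relation = relation, actor = actor, target = target,
      location = location, context = context, evidence = evidence,
      negated = stats::runif(1) < spec$negation_rate,
      source = "rkb:synthetic", stringsAsFactors = FALSE
    )
  }
  facts <- if (spec$n_facts > 0L) do.call(rbind, rows) else empty_facts()
  kb_from_tables(entities, facts, store)
}
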