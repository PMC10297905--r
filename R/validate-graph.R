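# Graph conformance against the ontology: declared predicates, union-aware
# domain/range checks for object properties, literal typing for datatype
# properties.

#' Validate a triple graph against an ontology schema
#'
#' Checks, per triple: the predicate is the type-assertion predicate or a
#' declared property (`UNDECLARED_PREDICATE`); for object properties,
#' the subject's asserted class is in the (possibly union) domain set
#' (`DOMAIN_VIOLATION`) and the object is an IRI whose asserted class is
#' the declared range or a subclass of it (`RANGE_VIOLATION`); for
#' datatype properties, the subject's class is in the domain set and the
#' literal's datatype matches the declared literal type
#' (`LITERAL_TYPE_MISMATCH`). Domain membership accepts subclasses of a
#' declared domain class. Untyped subjects of property triples violate
#' the domain check.
#'
#' @param graph An `rdf_graph`.
#' @param schema An `ehr_schema`.
#' @return Data frame of violations: `code`, `subject`, `predicate`,
#'   `object`, `message`; zero rows for a conformant graph.
#' @export
validate_graph <- function(graph, schema = build_mimic_schema()) {
  tr <- graph$triples
  base <- schema$base_iri
  empty <- data.frame(code = character(0), subject = character(0),
                      predicate = character(0), object = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  if (!nrow(tr)) return(empty)

  type_p <- paste0("<", RDF_TYPE, ">")
  is_type <- tr$p == type_p
  # subject -> asserted class(es), as local names
  tmap <- tr[is_type, c("s", "o")]
  tmap$class <- sub(paste0("^<", base, "([A-Za-z0-9_]+)>$"), "\\1", tmap$o)

  class_of <- function(terms) {
    # first asserted class per term (instances here carry exactly one)
    tmap$class[match(terms, tmap$s)]
  }

  op <- schema$object_properties
  dp <- schema$datatype_properties
  op_iri <- paste0("<", base, op$name, ">")
  dp_iri <- paste0("<", base, dp$name, ">")

  viol <- list()
  add <- function(code, rows, message) {
    if (!any(rows)) return()
    viol[[length(viol) + 1L]] <<- data.frame(
      code = code, subject = tr$s[rows], predicate = tr$p[rows],
      object = tr$o[rows], message = message, stringsAsFactors = FALSE)
  }

  known <- tr$p %in% c(type_p, op_iri, dp_iri)
  add("UNDECLARED_PREDICATE", !known, "predicate is not declared in the schema")

  # expand a ;-joined domain set to include declared subclasses
  expand_domains <- function(domains) {
    unique(unlist(lapply(split_set(domains), function(d)
      class_descendants(schema, d))))
  }

  is_lit <- startsWith(tr$o, "\"")
  subj_class <- class_of(tr$s)
  obj_class <- class_of(tr$o)

  for (i in seq_len(nrow(op))) {
    hit <- tr$p == op_iri[i]
    if (!any(hit)) next
    doms <- expand_domains(op$domains[i])
    rng <- class_descendants(schema, op$range[i])
    bad_dom <- hit & (is.na(subj_class) | !subj_class %in% doms)
    add("DOMAIN_VIOLATION", bad_dom,
        paste0("subject class not in domain of ", op$name[i],
               " {", op$domains[i], "}"))
    bad_rng <- hit & (is_lit | is.na(obj_class) | !obj_class %in% rng)
    add("RANGE_VIOLATION", bad_rng,
        paste0("object is not an instance of range ", op$range[i],
               " of ", op$name[i]))
  }

  lit_storage <- function(obj) {
    # storage type of an encoded literal term
    out <- rep(NA_character_, length(obj))
    lit <- startsWith(obj, "\"")
    dt <- rep("", length(obj))
    m <- regexpr("\\^\\^<[^>]*>$", obj)
    hasdt <- m > 0
    dt[hasdt] <- substr(obj[hasdt], m[hasdt] + 3L,
                        m[hasdt] + attr(m, "match.length")[hasdt] - 2L)
    out[lit & dt == XSD_INTEGER] <- "integer"
    out[lit & dt == XSD_DECIMAL] <- "decimal"
    out[lit & dt == XSD_DATETIME] <- "datetime"
    out[lit & dt == ""] <- "string"
    out
  }

  storage_for <- function(lt) {
    switch(lt, integer = "integer", decimal = "decimal",
           datetime = "datetime", "string")
  }

  for (i in seq_len(nrow(dp))) {
    hit <- tr$p == dp_iri[i]
    if (!any(hit)) next
    doms <- expand_domains(dp$domains[i])
    bad_dom <- hit & (is.na(subj_class) | !subj_class %in% doms)
    add("DOMAIN_VIOLATION", bad_dom,
        paste0("subject class not in domain of ", dp$name[i],
               " {", dp$domains[i], "}"))
    want <- storage_for(dp$literal_type[i])
    got <- lit_storage(tr$o)
    if (dp$literal_type[i] == "categorical") {
      # vocabulary resources under the base IRI are conformant objects;
      # out-of-vocabulary values fall back to plain strings
      ok <- hit & (startsWith(tr$o, paste0("<", base)) |
                     (!is.na(got) & got == "string"))
      add("LITERAL_TYPE_MISMATCH", hit & !ok,
          paste0("object of categorical property ", dp$name[i],
                 " is neither a vocabulary resource nor a string"))
    } else {
      bad_lit <- hit & (is.na(got) | got != want)
      add("LITERAL_TYPE_MISMATCH", bad_lit,
          paste0("literal type of ", dp$name[i], " is not ", want))
    }
  }

  if (length(viol)) {
    out <- do.call(rbind, viol)
    rownames(out) <- NULL
    out
  } else empty
}
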