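# Queryable store over a triple graph, plus the three cohort analyses:
# patients by ICD-9 diagnosis prefix, comorbid patients, and patients
# with repeated ICU admissions.

#' Load a triple graph into a queryable store
#'
#' @param graph An `rdf_graph`.
#' @return A `kg_handle` wrapping an immutable copy of the graph.
#' @export
kg_load <- function(graph) {
  stopifnot(inherits(graph, "rdf_graph"))
  structure(list(graph = graph, n = triple_count(graph)),
            class = "kg_handle")
}

#' @export
print.kg_handle <- function(x, ...) {
  cat("knowledge-graph store:", x$n, "triples\n")
  invisible(x)
}

#' Triple count of a loaded store
#' @param handle A `kg_handle`.
#' @export
kg_count <- function(handle) handle$n

#' Run a SPARQL query against a store
#'
#' Thin wrapper over [sparql_query()].
#'
#' @param handle A `kg_handle` (or an `rdf_graph`).
#' @param sparql Query text.
#' @export
kg_query <- function(handle, sparql) sparql_query(handle, sparql)

.patient_ids_from_iris <- function(iris) {
  vapply(iris, function(x) {
    u <- unmint_iri(x)
    if (is.null(u) || u$class != "Patient") NA_character_ else u$keys[1]
  }, "", USE.NAMES = FALSE)
}

.cohort_result <- function(patient_iris, counts = NULL) {
  o <- order(patient_iris)
  patient_iris <- patient_iris[o]
  if (!is.null(counts)) counts <- counts[o]
  structure(list(patients = patient_iris,
                 subject_ids = .patient_ids_from_iris(patient_iris),
                 counts = counts),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("cohort:", length(x$patients), "patient(s)\n")
  if (!is.null(x$counts)) cat("  with per-patient counts\n")
  invisible(x)
}

.iri_col <- function(res, var) {
  v <- as.character(as.data.frame(res)[[var]])
  sub("^<(.*)>$", "\\1", v)
}

.diagnosis_query <- function(path, code_prefix, exact) {
  filt <- if (exact) sprintf('FILTER(STR(?code) = "%s")', code_prefix)
          else sprintf('FILTER(STRSTARTS(STR(?code), "%s"))', code_prefix)
  body <- switch(path,
    admission = "?patient mc:HAS_ADMISSION ?adm .\n   ?adm mc:HAS_DIAGNOSIS ?dx .",
    icu = paste0("?patient mc:HAS_ADMISSION ?adm .\n   ",
                 "?adm mc:HAS_ICU_STAY ?icu .\n   ",
                 "?icu mc:HAS_DIAGNOSIS ?dx ."))
  sprintf("SELECT DISTINCT ?patient WHERE {\n   %s\n   ?dx mc:icd9_code ?code .\n   %s\n}",
          body, filt)
}

#' Patients carrying a diagnosis with a given ICD-9 code prefix
#'
#' Finds every patient linked - through their admissions or through the
#' ICU stays of those admissions - to at least one diagnosis whose ICD-9
#' code starts with `code_prefix`. The default prefix 250 selects
#' diabetes mellitus.
#'
#' @param handle A `kg_handle`.
#' @param code_prefix ICD-9 code prefix (non-empty); e.g. `"250"`
#'   diabetes, `"401"` essential hypertension.
#' @param exact Match the code exactly instead of by prefix.
#' @return An `ehr_cohort` with the patient IRI set and raw subject IDs.
#' @export
cohort_by_diagnosis <- function(handle, code_prefix = "250", exact = FALSE) {
  stopifnot(nzchar(code_prefix))
  iris <- unique(c(
    .iri_col(kg_query(handle, .diagnosis_query("admission", code_prefix, exact)),
             "patient"),
    .iri_col(kg_query(handle, .diagnosis_query("icu", code_prefix, exact)),
             "patient")))
  .cohort_result(iris)
}

#' Patients diagnosed with both of two conditions
#'
#' Intersection of two single-prefix diagnosis cohorts; defaults select
#' patients with both essential hypertension (401) and diabetes (250).
#'
#' @param handle A `kg_handle`.
#' @param prefix_a,prefix_b ICD-9 code prefixes.
#' @param exact Match codes exactly instead of by prefix.
#' @return An `ehr_cohort`.
#' @export
cohort_comorbid <- function(handle, prefix_a = "401", prefix_b = "250",
                            exact = FALSE) {
  a <- cohort_by_diagnosis(handle, prefix_a, exact)
  b <- cohort_by_diagnosis(handle, prefix_b, exact)
  .cohort_result(intersect(a$patients, b$patients))
}

#' Patients admitted to the ICU multiple times
#'
#' Counts distinct ICU stays per patient (through the admission link)
#' and keeps patients with at least `min_stays`; the default threshold
#' of 2 captures "multiple" ICU admissions.
#'
#' @param handle A `kg_handle`.
#' @param min_stays Minimum number of distinct ICU stays (>= 1).
#' @return An `ehr_cohort` with per-patient ICU-stay counts.
#' @export
cohort_multi_icu <- function(handle, min_stays = 2L) {
  min_stays <- as.integer(min_stays)
  if (is.na(min_stays) || min_stays < 1L)
    stop("min_stays must be an integer >= 1")
  q <- sprintf(paste0(
    "SELECT ?patient (COUNT(DISTINCT ?icu) AS ?n) WHERE {\n",
    "  ?patient mc:HAS_ADMISSION ?adm .\n",
    "  ?adm mc:HAS_ICU_STAY ?icu .\n",
    "} GROUP BY ?patient HAVING (COUNT(DISTINCT ?icu) >= %d)"), min_stays)
  df <- as.data.frame(kg_query(handle, q))
  iris <- sub("^<(.*)>$", "\\1", as.character(df$patient))
  counts <- as.integer(.term_natural(as.character(df$n)))
  names(counts) <- iris
  .cohort_result(iris, counts)
}
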