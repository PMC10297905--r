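# Ontology for MIMIC-III-shaped EHR data: class hierarchy, object
# properties (with union-of-classes domains) and the datatype-property
# catalogue derived from the core table schemas.

#' Base IRI under which all resources are minted
#' @keywords internal
EHR_BASE_IRI <- "http://mimicIII.com/base/"

#' Namespace prefix bound to the base IRI
#' @keywords internal
EHR_PREFIX <- "mc"

# Well-known vocabulary IRIs
RDF_TYPE  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDF_NS    <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS   <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS    <- "http://www.w3.org/2002/07/owl#"
XSD_NS    <- "http://www.w3.org/2001/XMLSchema#"

ROOT_MARKER <- "ROOT"

# ---------------------------------------------------------------------------
# Built-in class hierarchy.
# Abstract branch classes (Patient_Care, Codes, Events) have no source table.
# Event subclasses carry an _Event suffix and code-dictionary subclasses a
# _Code/_Item suffix so that every class has a unique identifier even where
# the published hierarchy reuses bare names across branches.
.ehr_classes <- function() {
  df <- function(...) as.data.frame(rbind(...), stringsAsFactors = FALSE)
  x <- df(
    c("Patient",            "ROOT",         "PATIENTS.CSV"),
    c("Admission",          "ROOT",         "ADMISSIONS.CSV"),
    c("CareGivers",         "ROOT",         "CAREGIVERS.CSV"),
    c("Patient_Care",       "ROOT",         ""),
    c("ICD_Diagnosis",      "Patient_Care", "DIAGNOSES_ICD.CSV"),
    c("ICD_Procedure",      "Patient_Care", "PROCEDURES_ICD.CSV"),
    c("Codes",              "ROOT",         ""),
    c("CPT_Code",           "Codes",        "D_CPT.CSV"),
    c("DRG_Code",           "Codes",        "DRGCODES.CSV"),
    c("ICD_Diagnosis_Code", "Codes",        "D_ICD_DIAGNOSES.CSV"),
    c("ICD_Procedure_Code", "Codes",        "D_ICD_PROCEDURES.CSV"),
    c("Lab_Item",           "Codes",        "D_LABITEMS.CSV"),
    c("Individual_Item",    "Codes",        "D_ITEMS.CSV"),
    c("ICU_Stays",          "ROOT",         "ICUSTAYS.CSV"),
    c("Events",             "ROOT",         ""),
    c("Chart_Event",        "Events",       "CHARTEVENTS.CSV"),
    c("CPT_Event",          "Events",       "CPTEVENTS.CSV"),
    c("Input_Event",        "Events",       "INPUTEVENTS_CV.CSV;INPUTEVENTS_MV.CSV"),
    c("Lab_Event",          "Events",       "LABEVENTS.CSV"),
    c("Microbiology_Event", "Events",       "MICROBIOLOGYEVENTS.CSV"),
    c("Note_Event",         "Events",       "NOTEEVENTS.CSV"),
    c("Output_Event",       "Events",       "OUTPUTEVENTS.CSV"),
    c("Transfers",          "ROOT",         "TRANSFERS.CSV"),
    c("Services",           "ROOT",         "SERVICES.CSV"),
    c("Prescription",       "ROOT",         "PRESCRIPTIONS.CSV"),
    c("Callout",            "ROOT",         "CALLOUT.CSV")
  )
  names(x) <- c("name", "parent", "source_tables")
  x$description <- class_descriptions()[x$name]
  x[, c("name", "parent", "description", "source_tables")]
}

class_descriptions <- function() {
  c(Patient            = "Patient demographics (gender, race, marital status, dates of birth/death)",
    Admission          = "Hospital admission episode with admit/discharge times and admission metadata",
    CareGivers         = "Care providers responsible for patient care",
    Patient_Care       = "Abstract branch for coded care records (ICD diagnoses and procedures)",
    ICD_Diagnosis      = "An ICD-9 coded diagnosis assigned during an admission",
    ICD_Procedure      = "An ICD-9 coded procedure performed during an admission",
    Codes              = "Abstract branch for code dictionaries",
    CPT_Code           = "Current Procedural Terminology code dictionary entry",
    DRG_Code           = "Diagnosis-related-group code dictionary entry",
    ICD_Diagnosis_Code = "ICD-9 diagnosis code dictionary entry",
    ICD_Procedure_Code = "ICD-9 procedure code dictionary entry",
    Lab_Item           = "Laboratory measurement dictionary entry",
    Individual_Item    = "Charted item dictionary entry",
    ICU_Stays          = "Intensive-care-unit stay with in/out times and care units",
    Events             = "Abstract branch for clinical and procedural event records",
    Chart_Event        = "Charted observation recorded at the bedside",
    CPT_Event          = "Billed CPT procedural event",
    Input_Event        = "Fluid/medication input event",
    Lab_Event          = "Laboratory measurement event",
    Microbiology_Event = "Microbiology culture/sensitivity event",
    Note_Event         = "Free-text clinical note (carried as an opaque literal)",
    Output_Event       = "Fluid output event",
    Transfers          = "Patient transfer between hospital locations",
    Services           = "Hospital service episode during an admission",
    Prescription       = "Medication order for an admission or ICU stay",
    Callout            = "Request for consultation / discharge call-out")
}

# ---------------------------------------------------------------------------
# The 19 object properties. Domains with more than one member are
# union-of-classes domains. Printed domain/range labels are reconciled to
# canonical class identifiers through ehr_class_aliases().
.ehr_object_properties <- function() {
  df <- function(...) as.data.frame(rbind(...), stringsAsFactors = FALSE)
  x <- df(
    c("HAS_ADMISSION",          "Patient",                                      "Admission",          "admissions.csv"),
    c("HAS_ICU_STAY",           "Admission",                                    "ICU_Stays",          "icustays.csv"),
    c("HAS_DIAGNOSIS",          "Admission;ICU_Stays",                          "ICD_Diagnosis",      "diagnoses_icd.csv"),
    c("HAS_PROCEDURE",          "Admission;ICU_Stays",                          "ICD_Procedure",      "procedures_icd.csv"),
    c("HAS_MEDICATION",         "Admission;ICU_Stays",                          "Prescription",       "prescriptions.csv"),
    c("HAS_LAB_EVENTS",         "Patient;Admission;ICU_Stays",                  "Lab_Event",          "labevents.csv"),
    c("HAS_NOTE",               "Patient;Admission;ICU_Stays",                  "Note_Event",         "noteevents.csv"),
    c("HAS_TRANSFER",           "Admission;ICU_Stays",                          "Transfers",          "transfers.csv"),
    c("HAS_SERVICE",            "Admission;ICU_Stays",                          "Services",           "services.csv"),
    c("HAS_LAB_ITEM",           "Lab_Event",                                    "Lab_Item",           "d_labitems.csv"),
    c("HAS_INDIVIDUAL_ITEM",    "Prescription;ICD_Procedure",                   "Individual_Item",    "d_items.csv"),
    c("HAS_CAREGIVER",          "Patient;Admission;ICU_Stays;ICD_Procedure",    "CareGivers",         "caregivers.csv"),
    c("HAS_CPT_CODE",           "ICD_Procedure",                                "CPT_Code",           "d_cpt.csv"),
    c("HAS_DRG_CODE",           "Admission",                                    "DRG_Code",           "drgcodes.csv"),
    c("HAS_ICU_PROCEDURE_CODE", "ICU_Stays",                                    "ICD_Procedure_Code", "d_icd_procedures.csv"),
    c("HAS_ICU_DIAGNOSIS_CODE", "ICU_Stays",                                    "ICD_Diagnosis_Code", "d_icd_diagnoses.csv"),
    c("HAS_PATIENT_CARE",       "Patient",                                      "Patient_Care",       "patients.csv"),
    c("HAS_ICD_DIAGNOSIS",      "Patient_Care",                                 "ICD_Diagnosis",      "diagnoses_icd.csv"),
    c("HAS_ICD_PROCEDURE",      "Patient_Care",                                 "ICD_Procedure",      "procedures_icd.csv")
  )
  names(x) <- c("name", "domains", "range", "source_table")
  x
}

#' Alias map reconciling published class labels to canonical identifiers
#'
#' The published class table and object-property table use inconsistent
#' labels for the same concept (`Diagnosis` vs the ICD diagnosis record
#' class, `Lab_Items` vs the lab dictionary class, singular/plural
#' variants, and bare names reused across branches). This map is the
#' single declared reconciliation from printed label to canonical class
#' identifier; it is data, not convention, so it can be inspected and
#' tested.
#'
#' @return Named character vector: printed label -> canonical class name.
#' @export
ehr_class_aliases <- function() {
  c("Patient Care"               = "Patient_Care",
    "Diagnosis"                  = "ICD_Diagnosis",
    "Procedure"                  = "ICD_Procedure",
    "Medication"                 = "Prescription",
    "ICU_Stay"                   = "ICU_Stays",
    "Lab_Events"                 = "Lab_Event",
    "Note_Events"                = "Note_Event",
    "Transfer"                   = "Transfers",
    "Service"                    = "Services",
    "Lab_Items"                  = "Lab_Item",
    "Individual Item"            = "Individual_Item",
    "Caregiver"                  = "CareGivers",
    "CPT Code"                   = "CPT_Code",
    "DRG Code"                   = "DRG_Code",
    "DRG Code in the Codes class" = "DRG_Code",
    "ICU Procedure"              = "ICD_Procedure_Code",
    "ICU Diagnosis Code"         = "ICD_Diagnosis_Code",
    "ICD Diagnosis"              = "ICD_Diagnosis",
    "ICD Procedure"              = "ICD_Procedure")
}

#' Resolve a (possibly aliased) class label to its canonical identifier
#' @param label Character vector of class labels.
#' @return Canonical class identifiers; labels already canonical pass through.
#' @export
resolve_class_alias <- function(label) {
  al <- ehr_class_aliases()
  out <- ifelse(label %in% names(al), unname(al[label]), label)
  unname(out)
}

# ---------------------------------------------------------------------------
# Datatype-property catalogue: one property per lowercased column name,
# with a set of domains and a set of TABLE.COLUMN sources (identifier
# columns such as subject_id recur across tables).
.ehr_datatype_properties <- function() {
  reg <- table_registry()
  cls <- table_class_map()
  rows <- list()
  for (tb in names(cls)) {
    ts <- reg[[tb]]
    for (i in seq_len(nrow(ts$columns))) {
      col <- ts$columns$name[i]
      rows[[length(rows) + 1L]] <- data.frame(
        name = tolower(col),
        domain = cls[[tb]],
        literal_type = ts$columns$literal_type[i],
        source = paste0(tb, ".", col),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  # collapse to one property per name with domain/source sets
  sp <- split(long, long$name)
  out <- do.call(rbind, lapply(sp, function(g) {
    lt <- unique(g$literal_type)
    data.frame(name = g$name[1],
               domains = paste(sort(unique(g$domain)), collapse = ";"),
               literal_type = if (length(lt) == 1L) lt else "string",
               sources = paste(sort(unique(g$source)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$name), ]
}

#' Build the built-in EHR ontology schema
#'
#' Constructs the full ontology for MIMIC-III-shaped EHR data: 26 classes
#' in a rooted hierarchy (abstract branches for coded patient care, code
#' dictionaries and clinical events), the 19 object properties linking
#' them (several with union-of-classes domains, e.g. `HAS_MEDICATION`
#' applies to either an admission or an ICU stay), and a datatype-property
#' catalogue covering every column of the core tables.
#'
#' @return An object of class `ehr_schema` with components `classes`,
#'   `object_properties`, `datatype_properties` (data frames; multi-valued
#'   domain/source fields are `;`-joined), `base_iri` and `prefix`.
#' @examples
#' sc <- build_mimic_schema()
#' subset(sc$object_properties, name == "HAS_MEDICATION")
#' @export
build_mimic_schema <- function() {
  schema <- structure(list(
    classes = .ehr_classes(),
    object_properties = .ehr_object_properties(),
    datatype_properties = .ehr_datatype_properties(),
    base_iri = EHR_BASE_IRI,
    prefix = EHR_PREFIX
  ), class = "ehr_schema")
  schema
}

#' @export
print.ehr_schema <- function(x, ...) {
  cat("EHR ontology schema\n")
  cat("  base IRI: ", x$base_iri, "  (prefix ", x$prefix, ":)\n", sep = "")
  cat("  classes:             ", nrow(x$classes), "\n", sep = "")
  cat("  object properties:   ", nrow(x$object_properties), "\n", sep = "")
  cat("  datatype properties: ", nrow(x$datatype_properties), "\n", sep = "")
  invisible(x)
}

split_set <- function(x) {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Ancestors of a class in the subclass hierarchy
#'
#' @param schema An `ehr_schema`.
#' @param class_name Class identifier.
#' @return Character vector of ancestors from immediate parent up to the
#'   `ROOT` marker (the top-level built-in class).
#' @export
class_ancestors <- function(schema, class_name) {
  cl <- schema$classes
  if (!class_name %in% cl$name) stop("undeclared class: ", class_name)
  out <- character(0)
  cur <- class_name
  while (TRUE) {
    parent <- cl$parent[match(cur, cl$name)]
    out <- c(out, parent)
    if (identical(parent, ROOT_MARKER)) break
    if (parent %in% out[-length(out)]) stop("cycle in class hierarchy at ", parent)
    cur <- parent
  }
  out
}

#' Classes subsumed by a class (itself plus all descendants)
#' @keywords internal
class_descendants <- function(schema, class_name) {
  cl <- schema$classes
  out <- class_name
  frontier <- class_name
  while (length(frontier)) {
    kids <- cl$name[cl$parent %in% frontier]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  out
}

#' Look up an object property definition
#'
#' @param schema An `ehr_schema`.
#' @param name Property name, e.g. `"HAS_ADMISSION"`.
#' @return List with `name`, `domains` (character vector), `range`,
#'   `source_table`, or `NULL` if absent.
#' @export
object_property <- function(schema, name) {
  op <- schema$object_properties
  i <- match(name, op$name)
  if (is.na(i)) return(NULL)
  list(name = op$name[i], domains = split_set(op$domains[i]),
       range = op$range[i], source_table = op$source_table[i])
}

#' Validate an ontology schema
#'
#' Structural validation: unique class and property names, every parent
#' and every property domain/range declared, subclass relation acyclic,
#' object- and datatype-property namespaces disjoint, and a single
#' literal type per datatype property.
#'
#' @param schema An `ehr_schema`.
#' @return Data frame of issues with columns `code`, `subject`, `message`;
#'   zero rows when the schema is valid.
#' @export
validate_schema <- function(schema) {
  issues <- list()
  add <- function(code, subject, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, subject = subject, message = message,
      stringsAsFactors = FALSE)
  }
  cl <- schema$classes
  dup <- unique(cl$name[duplicated(cl$name)])
  for (d in dup) add("DUPLICATE_NAME", d, "class name declared more than once")

  declared <- cl$name
  for (i in seq_len(nrow(cl))) {
    p <- cl$parent[i]
    if (!identical(p, ROOT_MARKER) && !p %in% declared)
      add("UNDECLARED_CLASS", cl$name[i], paste0("parent '", p, "' is not a declared class"))
  }

  # cycle detection by iterated leaf-stripping (Kahn) on the child->parent edges
  sub <- cl[cl$parent != ROOT_MARKER & cl$parent %in% declared, , drop = FALSE]
  nodes <- declared
  edges <- sub[, c("name", "parent")]
  repeat {
    has_child <- nodes %in% edges$parent
    leaves <- nodes[!has_child]
    if (!length(leaves)) break
    nodes <- setdiff(nodes, leaves)
    edges <- edges[!edges$name %in% leaves, , drop = FALSE]
    if (!nrow(edges)) break
  }
  if (nrow(edges))
    for (n in unique(edges$name))
      add("CYCLE", n, "class participates in a subclass cycle")

  op <- schema$object_properties
  dup <- unique(op$name[duplicated(op$name)])
  for (d in dup) add("DUPLICATE_NAME", d, "object property declared more than once")
  for (i in seq_len(nrow(op))) {
    doms <- split_set(op$domains[i])
    if (!length(doms)) add("EMPTY_DOMAIN", op$name[i], "object property has no domain")
    for (d in doms) if (!d %in% declared)
      add("UNDECLARED_CLASS", op$name[i], paste0("domain '", d, "' is not a declared class"))
    if (!op$range[i] %in% declared)
      add("UNDECLARED_CLASS", op$name[i], paste0("range '", op$range[i], "' is not a declared class"))
  }

  dp <- schema$datatype_properties
  dup <- unique(dp$name[duplicated(dp$name)])
  for (d in dup) add("DUPLICATE_NAME", d, "datatype property declared more than once")
  for (i in seq_len(nrow(dp))) {
    for (d in split_set(dp$domains[i])) if (!d %in% declared)
      add("UNDECLARED_CLASS", dp$name[i], paste0("domain '", d, "' is not a declared class"))
    if (!dp$literal_type[i] %in% LITERAL_TYPES)
      add("BAD_LITERAL_TYPE", dp$name[i], paste0("unknown literal type '", dp$literal_type[i], "'"))
  }

  shared <- intersect(op$name, dp$name)
  for (s in shared) add("NAMESPACE_CLASH", s, "name used as both object and datatype property")

  if (length(issues)) do.call(rbind, issues)
  else data.frame(code = character(0), subject = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}
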