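# Registry of the 26 MIMIC-III v1.4 CSV files. The core subset carries a
# full column catalogue (name, literal type, nullable); the remainder are
# registered by name and key columns only.

#' Literal types recognised by the mapper
#' @keywords internal
LITERAL_TYPES <- c("string", "integer", "decimal", "datetime", "code", "categorical")

# column spec shorthand: "NAME:t" with t in
#   i integer, d decimal, t datetime, s string, c code, g categorical
# "!" suffix marks a non-nullable column.
.parse_cols <- function(spec) {
  parts <- strsplit(spec, " ", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z0-9_]+):([idtscg])(!?)$", parts))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("bad column spec: ", paste(parts[bad], collapse = " "))
  tmap <- c(i = "integer", d = "decimal", t = "datetime",
            s = "string", c = "code", g = "categorical")
  data.frame(
    name = vapply(m, `[`, "", 2L),
    literal_type = unname(tmap[vapply(m, `[`, "", 3L)]),
    nullable = vapply(m, `[`, "", 4L) != "!",
    stringsAsFactors = FALSE)
}

.core_table_specs <- function() {
  list(
    PATIENTS = list(
      cols = "ROW_ID:i! SUBJECT_ID:c! GENDER:g! RACE:g MARITAL_STATUS:g DOB:t! DOD:t EXPIRE_FLAG:i!",
      pk = "SUBJECT_ID", fks = NULL),
    ADMISSIONS = list(
      cols = paste("ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! ADMITTIME:t! DISCHTIME:t!",
                   "DEATHTIME:t ADMISSION_TYPE:s! ADMISSION_LOCATION:s DISCHARGE_LOCATION:s",
                   "INSURANCE:s DIAGNOSIS:s HOSPITAL_EXPIRE_FLAG:i!"),
      pk = "HADM_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"))),
    ICUSTAYS = list(
      cols = paste("ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! ICUSTAY_ID:c! DBSOURCE:s",
                   "FIRST_CAREUNIT:s! LAST_CAREUNIT:s! INTIME:t! OUTTIME:t! LOS:d"),
      pk = "ICUSTAY_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID"))),
    DIAGNOSES_ICD = list(
      cols = "ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! SEQ_NUM:i! ICD9_CODE:c!",
      pk = "ROW_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID"))),
    PROCEDURES_ICD = list(
      cols = "ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! SEQ_NUM:i! ICD9_CODE:c!",
      pk = "ROW_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID"))),
    PRESCRIPTIONS = list(
      cols = paste("ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! ICUSTAY_ID:c STARTDATE:t!",
                   "ENDDATE:t DRUG_TYPE:s! DRUG:s! FORMULARY_DRUG_CD:c",
                   "DOSE_VAL_RX:s DOSE_UNIT_RX:s ROUTE:s"),
      pk = "ROW_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID"),
                 c("ICUSTAY_ID", "ICUSTAYS", "ICUSTAY_ID"))),
    LABEVENTS = list(
      cols = paste("ROW_ID:i! SUBJECT_ID:c! HADM_ID:c ITEMID:c! CHARTTIME:t!",
                   "VALUE:s VALUENUM:d VALUEUOM:s FLAG:s"),
      pk = "ROW_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID"),
                 c("ITEMID", "D_LABITEMS", "ITEMID"))),
    D_LABITEMS = list(
      cols = "ROW_ID:i! ITEMID:c! LABEL:s! FLUID:s CATEGORY:s LOINC_CODE:c",
      pk = "ITEMID", fks = NULL),
    D_ICD_DIAGNOSES = list(
      cols = "ROW_ID:i! ICD9_CODE:c! SHORT_TITLE:s! LONG_TITLE:s",
      pk = "ICD9_CODE", fks = NULL),
    CAREGIVERS = list(
      cols = "ROW_ID:i! CGID:c! LABEL:s DESCRIPTION:s",
      pk = "CGID", fks = NULL),
    TRANSFERS = list(
      cols = paste("ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! ICUSTAY_ID:c EVENTTYPE:s!",
                   "PREV_CAREUNIT:s CURR_CAREUNIT:s INTIME:t! OUTTIME:t"),
      pk = "ROW_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID"),
                 c("ICUSTAY_ID", "ICUSTAYS", "ICUSTAY_ID"))),
    SERVICES = list(
      cols = "ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! TRANSFERTIME:t! PREV_SERVICE:s CURR_SERVICE:s!",
      pk = "ROW_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID"))),
    CALLOUT = list(
      cols = paste("ROW_ID:i! SUBJECT_ID:c! HADM_ID:c! SUBMIT_WARDID:c CURR_WARDID:c",
                   "CALLOUT_SERVICE:s! REQUEST_TELE:i CALLOUT_STATUS:s! CALLOUT_OUTCOME:s",
                   "CREATETIME:t! OUTCOMETIME:t"),
      pk = "ROW_ID",
      fks = list(c("SUBJECT_ID", "PATIENTS", "SUBJECT_ID"),
                 c("HADM_ID", "ADMISSIONS", "HADM_ID")))
  )
}

# Non-core files: registered with key columns only.
.stub_table_specs <- function() {
  list(
    CHARTEVENTS        = "ROW_ID:i!",
    CPTEVENTS          = "ROW_ID:i!",
    DATETIMEEVENTS     = "ROW_ID:i!",
    D_CPT              = "ROW_ID:i!",
    D_ICD_PROCEDURES   = "ROW_ID:i! ICD9_CODE:c!",
    D_ITEMS            = "ROW_ID:i! ITEMID:c!",
    DRGCODES           = "ROW_ID:i!",
    INPUTEVENTS_CV     = "ROW_ID:i!",
    INPUTEVENTS_MV     = "ROW_ID:i!",
    MICROBIOLOGYEVENTS = "ROW_ID:i!",
    NOTEEVENTS         = "ROW_ID:i!",
    OUTPUTEVENTS       = "ROW_ID:i!",
    PROCEDUREEVENTS_MV = "ROW_ID:i!"
  )
}

#' Registry of the 26 MIMIC-III CSV files
#'
#' One `TableSchema` entry per file of the MIMIC-III v1.4 distribution.
#' Core tables (those the pipeline maps and the synthetic generator
#' populates) carry a full column catalogue with literal types and
#' nullability; the remaining files are registered by name and key
#' columns. File names are uppercase-canonical; the distribution's
#' MICROBIOLOGY events file is registered under its canonical name
#' `MICROBIOLOGYEVENTS`.
#'
#' @return Named list of `ehr_table_schema` objects, each with
#'   `file_name`, `columns` (data frame: name, literal_type, nullable),
#'   `primary_key`, `foreign_keys` (data frame: column, ref_table,
#'   ref_column) and `core` flag.
#' @examples
#' length(table_registry())  # 26
#' @export
table_registry <- function() {
  mk <- function(name, cols, pk, fks, core) {
    fk_df <- if (is.null(fks)) {
      data.frame(column = character(0), ref_table = character(0),
                 ref_column = character(0), stringsAsFactors = FALSE)
    } else {
      m <- do.call(rbind, fks)
      data.frame(column = m[, 1], ref_table = m[, 2], ref_column = m[, 3],
                 stringsAsFactors = FALSE)
    }
    structure(list(file_name = paste0(name, ".CSV"), table = name,
                   columns = .parse_cols(cols), primary_key = pk,
                   foreign_keys = fk_df, core = core),
              class = "ehr_table_schema")
  }
  core <- .core_table_specs()
  out <- lapply(names(core), function(n)
    mk(n, core[[n]]$cols, core[[n]]$pk, core[[n]]$fks, TRUE))
  names(out) <- names(core)
  stubs <- .stub_table_specs()
  out2 <- lapply(names(stubs), function(n) {
    pk <- .parse_cols(stubs[[n]])$name[1]
    mk(n, stubs[[n]], pk, NULL, FALSE)
  })
  names(out2) <- names(stubs)
  out <- c(out, out2)
  out[order(names(out))]
}

#' @export
print.ehr_table_schema <- function(x, ...) {
  cat(x$file_name, if (x$core) "(core)" else "(stub)",
      "- pk:", paste(x$primary_key, collapse = "+"),
      "-", nrow(x$columns), "columns\n")
  invisible(x)
}

#' Map from core table name to its ontology class
#' @keywords internal
table_class_map <- function() {
  c(PATIENTS        = "Patient",
    ADMISSIONS      = "Admission",
    ICUSTAYS        = "ICU_Stays",
    DIAGNOSES_ICD   = "ICD_Diagnosis",
    PROCEDURES_ICD  = "ICD_Procedure",
    PRESCRIPTIONS   = "Prescription",
    LABEVENTS       = "Lab_Event",
    D_LABITEMS      = "Lab_Item",
    D_ICD_DIAGNOSES = "ICD_Diagnosis_Code",
    CAREGIVERS      = "CareGivers",
    TRANSFERS       = "Transfers",
    SERVICES        = "Services",
    CALLOUT         = "Callout")
}

#' Export the table registry as JSON
#'
#' @param path Output file; when `NULL` the JSON text is returned.
#' @return Invisibly, the JSON text.
#' @export
registry_to_json <- function(path = NULL) {
  reg <- table_registry()
  doc <- lapply(reg, function(ts) list(
    file_name = ts$file_name,
    core = ts$core,
    primary_key = as.list(ts$primary_key),
    columns = ts$columns,
    foreign_keys = ts$foreign_keys))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
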