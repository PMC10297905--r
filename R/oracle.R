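# Independent ground-truth oracle over the raw CSV tables: direct scans
# and key joins, no RDF or SPARQL involved. Shares only the registry with
# the graph pipeline, so agreement between the two routes is evidence,
# not tautology.

#' Read a MIMIC-III-format CSV as character columns
#' @param path File path.
#' @return Data frame, all columns character, uppercase names.
#' @export
read_mimic_csv <- function(path) {
  if (!file.exists(path)) stop("missing table file: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0))
  names(df) <- toupper(trimws(names(df)))
  df
}

.oracle_read <- function(data_dir, table) {
  p <- .find_table_file(data_dir, table)
  if (is.null(p)) stop("missing table file: ", table)
  read_mimic_csv(p)
}

#' Direct-scan cohort oracle over the raw CSV tables
#'
#' Recomputes cohort membership by brute-force iteration over the CSV
#' files: `diagnosis_prefix` scans DIAGNOSES_ICD for codes starting with
#' `params$prefix`; `comorbid` intersects two prefix scans
#' (`params$prefix_a`, `params$prefix_b`); `multi_icu` group-counts
#' distinct ICUSTAY_IDs per patient and keeps those with at least
#' `params$min_stays`.
#'
#' @param data_dir Dataset directory.
#' @param cohort_kind One of `"diagnosis_prefix"`, `"comorbid"`,
#'   `"multi_icu"`.
#' @param params Named list of parameters (see above).
#' @return Sorted integer vector of SUBJECT_IDs.
#' @export
oracle_scan <- function(data_dir,
                        cohort_kind = c("diagnosis_prefix", "comorbid",
                                        "multi_icu"),
                        params = list()) {
  cohort_kind <- match.arg(cohort_kind)
  if (cohort_kind == "diagnosis_prefix") {
    prefix <- params$prefix %||% "250"
    dx <- .oracle_read(data_dir, "DIAGNOSES_ICD")
    hit <- startsWith(dx$ICD9_CODE, prefix)
    sort(unique(as.integer(dx$SUBJECT_ID[hit])))
  } else if (cohort_kind == "comorbid") {
    a <- oracle_scan(data_dir, "diagnosis_prefix",
                     list(prefix = params$prefix_a %||% "401"))
    b <- oracle_scan(data_dir, "diagnosis_prefix",
                     list(prefix = params$prefix_b %||% "250"))
    sort(intersect(a, b))
  } else {
    min_stays <- as.integer(params$min_stays %||% 2L)
    if (is.na(min_stays) || min_stays < 1L)
      stop("min_stays must be an integer >= 1")
    icu <- .oracle_read(data_dir, "ICUSTAYS")
    if (!nrow(icu)) return(integer(0))
    counts <- tapply(icu$ICUSTAY_ID, icu$SUBJECT_ID,
                     function(x) length(unique(x)))
    sort(as.integer(names(counts)[counts >= min_stays]))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check referential integrity and datetime ordering of a dataset
#'
#' Verifies the generator's structural guarantees on any dataset
#' directory: admission subjects exist in PATIENTS, ICU stays reference
#' valid admissions, diagnoses reference valid admissions,
#' `ADMITTIME <= DISCHTIME`, `INTIME <= OUTTIME`, and `DOB` precedes the
#' patient's first admission.
#'
#' @param data_dir Dataset directory.
#' @return Data frame of violations: `code`, `table`, `row`, `message`;
#'   zero rows when the dataset is consistent.
#' @export
check_dataset_integrity <- function(data_dir) {
  viol <- list()
  add <- function(code, table, rows, message) {
    if (!length(rows)) return()
    viol[[length(viol) + 1L]] <<- data.frame(
      code = code, table = table, row = rows, message = message,
      stringsAsFactors = FALSE)
  }
  pat <- .oracle_read(data_dir, "PATIENTS")
  adm <- .oracle_read(data_dir, "ADMISSIONS")
  icu <- .oracle_read(data_dir, "ICUSTAYS")
  dx <- .oracle_read(data_dir, "DIAGNOSES_ICD")

  add("ORPHAN_FK", "ADMISSIONS",
      which(!adm$SUBJECT_ID %in% pat$SUBJECT_ID),
      "SUBJECT_ID not present in PATIENTS")
  add("ORPHAN_FK", "ICUSTAYS",
      which(!icu$HADM_ID %in% adm$HADM_ID),
      "HADM_ID not present in ADMISSIONS")
  add("ORPHAN_FK", "ICUSTAYS",
      which(!icu$SUBJECT_ID %in% pat$SUBJECT_ID),
      "SUBJECT_ID not present in PATIENTS")
  add("ORPHAN_FK", "DIAGNOSES_ICD",
      which(!dx$HADM_ID %in% adm$HADM_ID),
      "HADM_ID not present in ADMISSIONS")

  t0 <- as.POSIXct(adm$ADMITTIME, tz = "UTC")
  t1 <- as.POSIXct(adm$DISCHTIME, tz = "UTC")
  add("DATE_ORDER", "ADMISSIONS", which(!is.na(t0) & !is.na(t1) & t0 > t1),
      "ADMITTIME after DISCHTIME")
  if (nrow(icu)) {
    i0 <- as.POSIXct(icu$INTIME, tz = "UTC")
    i1 <- as.POSIXct(icu$OUTTIME, tz = "UTC")
    add("DATE_ORDER", "ICUSTAYS", which(!is.na(i0) & !is.na(i1) & i0 > i1),
        "INTIME after OUTTIME")
  }
  if (nrow(adm) && nrow(pat)) {
    first_adm <- tapply(t0, adm$SUBJECT_ID, min)
    dob <- as.POSIXct(pat$DOB, tz = "UTC")
    fa <- first_adm[pat$SUBJECT_ID]
    bad <- which(!is.na(dob) & !is.na(fa) & dob >= fa)
    add("DATE_ORDER", "PATIENTS", bad, "DOB not before first ADMITTIME")
  }
  if (length(viol)) {
    out <- do.call(rbind, viol)
    rownames(out) <- NULL
    out
  } else data.frame(code = character(0), table = character(0),
                    row = integer(0), message = character(0),
                    stringsAsFactors = FALSE)
}

#' Inject a single known defect into a dataset
#'
#' Negative-test fixture generator: plants exactly one defect of the
#' stated kind at a seed-determined location and reports its coordinates
#' so tests can assert the downstream detection.
#'
#' @param data_dir Dataset directory (modified in place).
#' @param kind `"orphan_fk"` (an admission's SUBJECT_ID is repointed to a
#'   non-existent patient), `"bad_date_order"` (an admission's admit and
#'   discharge times are swapped) or `"duplicate_row"` (a diagnosis row
#'   is appended verbatim).
#' @param seed Integer seed selecting the location.
#' @return List describing the injected defect (`kind`, `table`, `row`,
#'   and old/new values where relevant).
#' @export
perturb_dataset <- function(data_dir,
                            kind = c("orphan_fk", "bad_date_order",
                                     "duplicate_row"),
                            seed = 1L) {
  kind <- match.arg(kind)
  target_table <- switch(kind, duplicate_row = "DIAGNOSES_ICD", "ADMISSIONS")
  path <- .find_table_file(data_dir, target_table)
  if (is.null(path)) stop("missing table file: ", target_table)
  df <- read_mimic_csv(path)
  if (!nrow(df)) stop("cannot perturb an empty ", target_table, " table")
  row <- .with_stream(seed, paste0("perturb-", kind),
                      sample.int(nrow(df), 1L))
  desc <- list(kind = kind, table = target_table, row = row)
  if (kind == "orphan_fk") {
    desc$column <- "SUBJECT_ID"
    desc$old <- df$SUBJECT_ID[row]
    desc$new <- "99999999"
    df$SUBJECT_ID[row] <- desc$new
  } else if (kind == "bad_date_order") {
    a <- df$ADMITTIME[row]; d <- df$DISCHTIME[row]
    if (identical(a, d)) stop("selected admission has equal times; cannot invert")
    df$ADMITTIME[row] <- d
    df$DISCHTIME[row] <- a
    desc$admittime <- d
    desc$dischtime <- a
  } else {
    df <- rbind(df, df[row, , drop = FALSE])
    desc$appended_at <- nrow(df)
  }
  .write_csv_canonical(df, path)
  desc
}
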