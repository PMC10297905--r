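# Seeded synthetic MIMIC-III-shaped dataset with planted cohorts.
#
# Cohorts are planted by exact count (floor(fraction * n)), so realized
# sizes are deterministic. Background diagnosis codes never start with a
# cohort family prefix, so cohort membership is exactly the planted set.
# Structural decisions (who is in which cohort, admissions per patient,
# ICU stays per patient) come from one "structure" stream; each table's
# field values come from a stream derived from (seed, table name), so
# adding a table never perturbs another table's content.

.hash_seed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (as.double(seed) %% 2147483647) * 48271) %% 2147483647)
}

.with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.hash_seed(seed, name))
  force(expr)
}

#' Default vocabularies for the synthetic generator
#'
#' The background ICD-9 pool deliberately avoids the diabetes (250) and
#' hypertension (401) families so that planted cohort membership is
#' exact.
#'
#' @return Named list of value pools.
#' @export
synth_vocab <- function() {
  list(
    gender = c("M", "F"),
    race = c("WHITE", "BLACK", "ASIAN", "HISPANIC", "OTHER"),
    marital_status = c("MARRIED", "SINGLE", "WIDOWED", "DIVORCED"),
    icd9_background = c("41401", "486", "5849", "42731", "5990", "2859",
                        "51881", "4280", "0389", "431", "5070", "2762",
                        "78552", "99592", "V4581"),
    icd9_diabetes = c("25000", "25002", "25040", "25060", "25011"),
    icd9_hypertension = c("4010", "4011", "4019"),
    icd9_procedures = c("3961", "9904", "0966", "3891", "8856"),
    drugs = c("Aspirin", "Metoprolol", "Insulin", "Furosemide", "Heparin",
              "Vancomycin", "Morphine", "Potassium Chloride"),
    lab_items = data.frame(
      ITEMID = as.character(50801:50810),
      LABEL = c("Glucose", "Creatinine", "Sodium", "Potassium", "Chloride",
                "Bicarbonate", "Hemoglobin", "Platelet Count", "Lactate",
                "White Blood Cells"),
      FLUID = "Blood", CATEGORY = "Chemistry",
      MEAN = c(120, 1.1, 140, 4.1, 102, 24, 11, 250, 1.8, 9),
      SD = c(30, 0.4, 4, 0.5, 4, 3, 2, 80, 0.9, 4),
      UOM = c("mg/dL", "mg/dL", "mEq/L", "mEq/L", "mEq/L", "mEq/L",
              "g/dL", "K/uL", "mmol/L", "K/uL"),
      stringsAsFactors = FALSE))
}

#' Specification for a synthetic EHR dataset
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_patients Number of patients (>= 0).
#' @param date_window Two datetimes (character) bounding admissions; the
#'   far-future default echoes the date-shifting used by de-identified
#'   ICU datasets.
#' @param mean_admissions_per_patient Mean admissions per patient (>= 1;
#'   each patient gets at least one).
#' @param icu_stay_probability Probability that a patient outside the
#'   multi-ICU cohort has a (single) ICU stay.
#' @param diabetes_fraction,hypertension_fraction,comorbid_fraction,multi_icu_fraction
#'   Cohort fractions; planting is by exact count (`floor(f * n)`), and
#'   the comorbid cohort is exactly the intersection of the diabetes and
#'   hypertension cohorts.
#' @param vocab Value pools; see [synth_vocab()].
#' @return A `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_patients = 100L,
                           date_window = c("2100-01-01 00:00:00",
                                           "2105-12-31 23:59:59"),
                           mean_admissions_per_patient = 1.4,
                           icu_stay_probability = 0.6,
                           diabetes_fraction = 0.10,
                           hypertension_fraction = 0.08,
                           comorbid_fraction = 0.03,
                           multi_icu_fraction = 0.10,
                           vocab = synth_vocab()) {
  fr <- c(diabetes_fraction, hypertension_fraction, comorbid_fraction,
          multi_icu_fraction, icu_stay_probability)
  if (any(fr < 0 | fr > 1)) stop("probabilities must lie in [0, 1]")
  if (comorbid_fraction > min(diabetes_fraction, hypertension_fraction))
    stop("comorbid_fraction must not exceed min(diabetes, hypertension)")
  if (mean_admissions_per_patient < 1)
    stop("mean_admissions_per_patient must be >= 1")
  w <- as.POSIXct(date_window, tz = "UTC")
  if (anyNA(w) || w[1] >= w[2]) stop("date_window start must precede end")
  n <- as.integer(n_patients)
  nd <- floor(diabetes_fraction * n)
  nh <- floor(hypertension_fraction * n)
  nc <- floor(comorbid_fraction * n)
  if (nd + (nh - nc) > n)
    stop("cohort fractions infeasible for n_patients")
  structure(list(seed = as.integer(seed), n_patients = n,
                 date_window = date_window,
                 mean_admissions_per_patient = mean_admissions_per_patient,
                 icu_stay_probability = icu_stay_probability,
                 diabetes_fraction = diabetes_fraction,
                 hypertension_fraction = hypertension_fraction,
                 comorbid_fraction = comorbid_fraction,
                 multi_icu_fraction = multi_icu_fraction,
                 vocab = vocab),
            class = "generator_spec")
}

.fmt_dt <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")
.fmt_d <- function(x) format(x, "%Y-%m-%d 00:00:00", tz = "UTC")

# canonical CSV writer: comma-separated, double-quote quoting only when
# needed, LF line endings
.write_csv_canonical <- function(df, path) {
  esc <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    needs <- grepl("[\",\n\r]", x)
    x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs]), "\"")
    x
  }
  header <- paste(names(df), collapse = ",")
  if (nrow(df)) {
    cols <- lapply(df, esc)
    body <- do.call(paste, c(cols, sep = ","))
    writeLines(c(header, body), path, sep = "\n")
  } else writeLines(header, path, sep = "\n")
  invisible(path)
}

#' Generate a synthetic MIMIC-III-shaped dataset
#'
#' Writes the core tables (with registry-conformant headers and full
#' referential integrity and datetime ordering) plus header-only stubs
#' for the remaining registry files, and a `manifest.json` recording the
#' exact planted cohort membership. Output is byte-identical for an
#' identical spec.
#'
#' @param spec A [generator_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the ground-truth manifest (also written as JSON).
#' @export
generate_ehr <- function(spec, out_dir) {
  stopifnot(inherits(spec, "generator_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  n <- spec$n_patients
  seed <- spec$seed
  vocab <- spec$vocab
  w0 <- as.POSIXct(spec$date_window[1], tz = "UTC")
  w1 <- as.POSIXct(spec$date_window[2], tz = "UTC")

  subject_ids <- if (n > 0) as.character(10000L + seq_len(n)) else character(0)

  nd <- floor(spec$diabetes_fraction * n)
  nh <- floor(spec$hypertension_fraction * n)
  nc <- floor(spec$comorbid_fraction * n)
  nm <- floor(spec$multi_icu_fraction * n)

  plan <- .with_stream(seed, "structure", {
    perm <- if (n > 0) sample.int(n) else integer(0)
    comorbid_ix <- perm[seq_len(nc)]
    diabetes_ix <- c(comorbid_ix, perm[seq_len(nd - nc) + nc])
    hyper_ix <- c(comorbid_ix, perm[seq_len(nh - nc) + nd])
    multi_ix <- if (n > 0) sample.int(n, nm) else integer(0)
    n_adm <- if (n > 0) 1L + stats::rpois(n, spec$mean_admissions_per_patient - 1) else integer(0)
    n_icu <- integer(n)
    if (n > 0) {
      n_icu[] <- stats::rbinom(n, 1L, spec$icu_stay_probability)
      n_icu[multi_ix] <- 2L + stats::rpois(length(multi_ix), 0.5)
    }
    # which of a patient's admissions each ICU stay / cohort code lands on
    icu_adm <- lapply(seq_len(n), function(i)
      if (n_icu[i] > 0) sample.int(n_adm[i], n_icu[i], replace = TRUE) else integer(0))
    dm_adm <- vapply(seq_len(n), function(i) sample.int(n_adm[i], 1L), 1L)
    ht_adm <- vapply(seq_len(n), function(i) sample.int(n_adm[i], 1L), 1L)
    n_bg_dx <- if (n > 0) 1L + stats::rpois(sum(n_adm), 1.0) else integer(0)
    list(comorbid_ix = comorbid_ix, diabetes_ix = diabetes_ix,
         hyper_ix = hyper_ix, multi_ix = multi_ix, n_adm = n_adm,
         n_icu = n_icu, icu_adm = icu_adm, dm_adm = dm_adm,
         ht_adm = ht_adm, n_bg_dx = n_bg_dx)
  })

  # ----- PATIENTS -------------------------------------------------------
  patients <- .with_stream(seed, "PATIENTS", {
    dob <- as.POSIXct("2030-01-01", tz = "UTC") +
      floor(stats::runif(n, 0, 50 * 365.25)) * 86400
    data.frame(
      ROW_ID = as.character(seq_len(n)),
      SUBJECT_ID = subject_ids,
      GENDER = sample(vocab$gender, n, replace = TRUE),
      RACE = sample(vocab$race, n, replace = TRUE),
      MARITAL_STATUS = sample(vocab$marital_status, n, replace = TRUE),
      DOB = if (n > 0) .fmt_d(dob) else character(0),
      DOD = rep("", n),
      EXPIRE_FLAG = rep("0", n),
      stringsAsFactors = FALSE)
  })

  # ----- ADMISSIONS -----------------------------------------------------
  total_adm <- sum(plan$n_adm)
  adm_patient <- rep(seq_len(n), plan$n_adm)   # patient index per admission
  admissions <- .with_stream(seed, "ADMISSIONS", {
    span <- as.double(difftime(w1, w0, units = "secs"))
    admit <- numeric(total_adm)
    for (i in seq_len(n)) {
      k <- plan$n_adm[i]
      admit[adm_patient == i] <- sort(stats::runif(k, 0, span * 0.9))
    }
    dur <- stats::runif(total_adm, 2, 20) * 86400
    admit_t <- w0 + round(admit)
    disch_t <- admit_t + round(dur)
    data.frame(
      ROW_ID = as.character(seq_len(total_adm)),
      SUBJECT_ID = subject_ids[adm_patient],
      HADM_ID = as.character(100000L + seq_len(total_adm)),
      ADMITTIME = .fmt_dt(admit_t),
      DISCHTIME = .fmt_dt(disch_t),
      DEATHTIME = rep("", total_adm),
      ADMISSION_TYPE = sample(c("EMERGENCY", "ELECTIVE", "URGENT"),
                              total_adm, replace = TRUE),
      ADMISSION_LOCATION = sample(c("EMERGENCY ROOM ADMIT",
                                    "PHYS REFERRAL/NORMAL DELI",
                                    "TRANSFER FROM HOSP/EXTRAM"),
                                  total_adm, replace = TRUE),
      DISCHARGE_LOCATION = sample(c("HOME", "SNF", "REHAB/DISTINCT PART HOSP"),
                                  total_adm, replace = TRUE),
      INSURANCE = sample(c("Medicare", "Private", "Medicaid", "Self Pay"),
                         total_adm, replace = TRUE),
      DIAGNOSIS = sample(c("CHEST PAIN", "PNEUMONIA", "SEPSIS",
                           "CONGESTIVE HEART FAILURE", "GI BLEED"),
                         total_adm, replace = TRUE),
      HOSPITAL_EXPIRE_FLAG = rep("0", total_adm),
      stringsAsFactors = FALSE)
  })
  # admission row indices per patient, in admission order
  adm_index <- split(seq_len(total_adm), factor(adm_patient, levels = seq_len(n)))
  adm_admit <- as.POSIXct(admissions$ADMITTIME, tz = "UTC")
  adm_disch <- as.POSIXct(admissions$DISCHTIME, tz = "UTC")

  # ----- ICUSTAYS -------------------------------------------------------
  stay_adm_row <- unlist(lapply(seq_len(n), function(i) {
    if (plan$n_icu[i] > 0) adm_index[[i]][plan$icu_adm[[i]]] else integer(0)
  }))
  total_icu <- length(stay_adm_row)
  icustays <- .with_stream(seed, "ICUSTAYS", {
    if (total_icu > 0) {
      dur <- as.double(adm_disch[stay_adm_row]) - as.double(adm_admit[stay_adm_row])
      f1 <- stats::runif(total_icu, 0.02, 0.45)
      f2 <- stats::runif(total_icu, 0.55, 0.95)
      intime <- adm_admit[stay_adm_row] + round(dur * f1)
      outtime <- adm_admit[stay_adm_row] + round(dur * f2)
      unit <- sample(c("MICU", "SICU", "CCU", "CSRU", "TSICU"),
                     total_icu, replace = TRUE)
      data.frame(
        ROW_ID = as.character(seq_len(total_icu)),
        SUBJECT_ID = admissions$SUBJECT_ID[stay_adm_row],
        HADM_ID = admissions$HADM_ID[stay_adm_row],
        ICUSTAY_ID = as.character(200000L + seq_len(total_icu)),
        DBSOURCE = sample(c("carevue", "metavision"), total_icu, replace = TRUE),
        FIRST_CAREUNIT = unit,
        LAST_CAREUNIT = unit,
        INTIME = .fmt_dt(intime),
        OUTTIME = .fmt_dt(outtime),
        LOS = sprintf("%.4f", (as.double(outtime) - as.double(intime)) / 86400),
        stringsAsFactors = FALSE)
    } else {
      data.frame(ROW_ID = character(0), SUBJECT_ID = character(0),
                 HADM_ID = character(0), ICUSTAY_ID = character(0),
                 DBSOURCE = character(0), FIRST_CAREUNIT = character(0),
                 LAST_CAREUNIT = character(0), INTIME = character(0),
                 OUTTIME = character(0), LOS = character(0),
                 stringsAsFactors = FALSE)
    }
  })

  # ----- DIAGNOSES_ICD --------------------------------------------------
  diagnoses <- .with_stream(seed, "DIAGNOSES_ICD", {
    rows <- list()
    bg_i <- 0L
    for (i in seq_len(n)) {
      for (k in seq_len(plan$n_adm[i])) {
        r <- adm_index[[i]][k]
        codes <- character(0)
        if (i %in% plan$diabetes_ix && plan$dm_adm[i] == k)
          codes <- c(codes, sample(vocab$icd9_diabetes, 1L))
        if (i %in% plan$hyper_ix && plan$ht_adm[i] == k)
          codes <- c(codes, sample(vocab$icd9_hypertension, 1L))
        bg_i <- bg_i + 1L
        nbg <- plan$n_bg_dx[bg_i]
        codes <- c(codes, sample(vocab$icd9_background,
                                 min(nbg, length(vocab$icd9_background))))
        rows[[length(rows) + 1L]] <- data.frame(
          SUBJECT_ID = subject_ids[i],
          HADM_ID = admissions$HADM_ID[r],
          SEQ_NUM = as.character(seq_along(codes)),
          ICD9_CODE = codes, stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(SUBJECT_ID = character(0), HADM_ID = character(0),
                           SEQ_NUM = character(0), ICD9_CODE = character(0),
                           stringsAsFactors = FALSE)
    cbind(data.frame(ROW_ID = as.character(seq_len(nrow(out))),
                     stringsAsFactors = FALSE), out)
  })

  # ----- PROCEDURES_ICD -------------------------------------------------
  procedures <- .with_stream(seed, "PROCEDURES_ICD", {
    npr <- stats::rbinom(total_adm, 2L, 0.4)
    idx <- rep(seq_len(total_adm), npr)
    total <- length(idx)
    sq <- unlist(lapply(npr[npr > 0], seq_len))
    data.frame(
      ROW_ID = as.character(seq_len(total)),
      SUBJECT_ID = admissions$SUBJECT_ID[idx],
      HADM_ID = admissions$HADM_ID[idx],
      SEQ_NUM = if (total) as.character(sq) else character(0),
      ICD9_CODE = if (total) sample(vocab$icd9_procedures, total, replace = TRUE)
                  else character(0),
      stringsAsFactors = FALSE)
  })

  # ----- PRESCRIPTIONS --------------------------------------------------
  prescriptions <- .with_stream(seed, "PRESCRIPTIONS", {
    npx <- stats::rbinom(total_adm, 3L, 0.6)
    idx <- rep(seq_len(total_adm), npx)
    total <- length(idx)
    if (total > 0) {
      stays_of_adm <- split(seq_len(total_icu), stay_adm_row)
      icustay <- vapply(idx, function(r) {
        st <- stays_of_adm[[as.character(r)]]
        if (!is.null(st) && length(st) && stats::runif(1) < 0.5)
          icustays$ICUSTAY_ID[st[sample.int(length(st), 1L)]]
        else ""
      }, "")
      start_off <- stats::runif(total, 0, 0.7)
      dur_d <- 1L + stats::rpois(total, 3)
      start_t <- adm_admit[idx] +
        round((as.double(adm_disch[idx]) - as.double(adm_admit[idx])) * start_off)
      drug <- sample(vocab$drugs, total, replace = TRUE)
      data.frame(
        ROW_ID = as.character(seq_len(total)),
        SUBJECT_ID = admissions$SUBJECT_ID[idx],
        HADM_ID = admissions$HADM_ID[idx],
        ICUSTAY_ID = icustay,
        STARTDATE = .fmt_d(start_t),
        ENDDATE = .fmt_d(start_t + dur_d * 86400),
        DRUG_TYPE = rep("MAIN", total),
        DRUG = drug,
        FORMULARY_DRUG_CD = toupper(substr(gsub(" ", "", drug), 1, 6)),
        DOSE_VAL_RX = as.character(sample(c(25, 50, 100, 250, 500), total,
                                          replace = TRUE)),
        DOSE_UNIT_RX = rep("mg", total),
        ROUTE = sample(c("PO", "IV"), total, replace = TRUE),
        stringsAsFactors = FALSE)
    } else {
      data.frame(ROW_ID = character(0), SUBJECT_ID = character(0),
                 HADM_ID = character(0), ICUSTAY_ID = character(0),
                 STARTDATE = character(0), ENDDATE = character(0),
                 DRUG_TYPE = character(0), DRUG = character(0),
                 FORMULARY_DRUG_CD = character(0), DOSE_VAL_RX = character(0),
                 DOSE_UNIT_RX = character(0), ROUTE = character(0),
                 stringsAsFactors = FALSE)
    }
  })

  # ----- LABEVENTS and D_LABITEMS --------------------------------------
  labitems <- vocab$lab_items
  d_labitems <- data.frame(
    ROW_ID = as.character(seq_len(nrow(labitems))),
    ITEMID = labitems$ITEMID, LABEL = labitems$LABEL,
    FLUID = labitems$FLUID, CATEGORY = labitems$CATEGORY,
    LOINC_CODE = rep("", nrow(labitems)), stringsAsFactors = FALSE)
  labevents <- .with_stream(seed, "LABEVENTS", {
    nlab <- 1L + stats::rpois(total_adm, 1.5)
    idx <- rep(seq_len(total_adm), nlab)
    total <- length(idx)
    if (total > 0) {
      it <- sample.int(nrow(labitems), total, replace = TRUE)
      off <- stats::runif(total, 0.05, 0.95)
      ct <- adm_admit[idx] +
        round((as.double(adm_disch[idx]) - as.double(adm_admit[idx])) * off)
      val <- round(stats::rnorm(total, labitems$MEAN[it], labitems$SD[it]), 1)
      val <- pmax(val, 0.1)
      data.frame(
        ROW_ID = as.character(seq_len(total)),
        SUBJECT_ID = admissions$SUBJECT_ID[idx],
        HADM_ID = admissions$HADM_ID[idx],
        ITEMID = labitems$ITEMID[it],
        CHARTTIME = .fmt_dt(ct),
        VALUE = sprintf("%g", val),
        VALUENUM = sprintf("%g", val),
        VALUEUOM = labitems$UOM[it],
        FLAG = ifelse(stats::runif(total) < 0.15, "abnormal", ""),
        stringsAsFactors = FALSE)
    } else {
      data.frame(ROW_ID = character(0), SUBJECT_ID = character(0),
                 HADM_ID = character(0), ITEMID = character(0),
                 CHARTTIME = character(0), VALUE = character(0),
                 VALUENUM = character(0), VALUEUOM = character(0),
                 FLAG = character(0), stringsAsFactors = FALSE)
    }
  })

  # ----- D_ICD_DIAGNOSES (dictionary over every code in the pools) -----
  all_codes <- sort(unique(c(vocab$icd9_background, vocab$icd9_diabetes,
                             vocab$icd9_hypertension)))
  d_icd <- data.frame(
    ROW_ID = as.character(seq_along(all_codes)),
    ICD9_CODE = all_codes,
    SHORT_TITLE = paste("Code", all_codes),
    LONG_TITLE = paste("Synthetic dictionary entry for ICD-9 code", all_codes),
    stringsAsFactors = FALSE)

  # ----- CAREGIVERS -----------------------------------------------------
  caregivers <- .with_stream(seed, "CAREGIVERS", {
    m <- max(6L, n %/% 20L)
    data.frame(
      ROW_ID = as.character(seq_len(m)),
      CGID = as.character(16170L + seq_len(m)),
      LABEL = sample(c("RN", "MD", "RT", "PharmD"), m, replace = TRUE),
      DESCRIPTION = rep("", m), stringsAsFactors = FALSE)
  })

  # ----- TRANSFERS ------------------------------------------------------
  transfers <- .with_stream(seed, "TRANSFERS", {
    adm_rows <- data.frame(
      SUBJECT_ID = admissions$SUBJECT_ID, HADM_ID = admissions$HADM_ID,
      ICUSTAY_ID = rep("", total_adm), EVENTTYPE = rep("admit", total_adm),
      PREV_CAREUNIT = rep("", total_adm), CURR_CAREUNIT = rep("", total_adm),
      INTIME = admissions$ADMITTIME, OUTTIME = admissions$DISCHTIME,
      stringsAsFactors = FALSE)
    icu_rows <- if (total_icu > 0) data.frame(
      SUBJECT_ID = icustays$SUBJECT_ID, HADM_ID = icustays$HADM_ID,
      ICUSTAY_ID = icustays$ICUSTAY_ID,
      EVENTTYPE = rep("transfer", total_icu),
      PREV_CAREUNIT = rep("", total_icu),
      CURR_CAREUNIT = icustays$FIRST_CAREUNIT,
      INTIME = icustays$INTIME, OUTTIME = icustays$OUTTIME,
      stringsAsFactors = FALSE) else NULL
    out <- rbind(adm_rows, icu_rows)
    cbind(data.frame(ROW_ID = as.character(seq_len(nrow(out))),
                     stringsAsFactors = FALSE), out)
  })

  # ----- SERVICES -------------------------------------------------------
  services <- .with_stream(seed, "SERVICES", {
    data.frame(
      ROW_ID = as.character(seq_len(total_adm)),
      SUBJECT_ID = admissions$SUBJECT_ID,
      HADM_ID = admissions$HADM_ID,
      TRANSFERTIME = admissions$ADMITTIME,
      PREV_SERVICE = rep("", total_adm),
      CURR_SERVICE = sample(c("MED", "SURG", "CMED", "NMED", "OMED"),
                            total_adm, replace = TRUE),
      stringsAsFactors = FALSE)
  })

  # ----- CALLOUT --------------------------------------------------------
  callout <- .with_stream(seed, "CALLOUT", {
    has <- stats::runif(total_adm) < 0.3
    idx <- which(has)
    total <- length(idx)
    create_t <- adm_disch[idx] - round(stats::runif(total, 0.5, 3) * 86400)
    data.frame(
      ROW_ID = as.character(seq_len(total)),
      SUBJECT_ID = admissions$SUBJECT_ID[idx],
      HADM_ID = admissions$HADM_ID[idx],
      SUBMIT_WARDID = as.character(sample(1:60, total, replace = TRUE)),
      CURR_WARDID = as.character(sample(1:60, total, replace = TRUE)),
      CALLOUT_SERVICE = sample(c("MED", "SURG", "CMED"), total, replace = TRUE),
      REQUEST_TELE = as.character(stats::rbinom(total, 1L, 0.4)),
      CALLOUT_STATUS = rep("Inactive", total),
      CALLOUT_OUTCOME = rep("Discharged", total),
      CREATETIME = if (total) .fmt_dt(create_t) else character(0),
      OUTCOMETIME = admissions$DISCHTIME[idx],
      stringsAsFactors = FALSE)
  })

  tables <- list(PATIENTS = patients, ADMISSIONS = admissions,
                 ICUSTAYS = icustays, DIAGNOSES_ICD = diagnoses,
                 PROCEDURES_ICD = procedures, PRESCRIPTIONS = prescriptions,
                 LABEVENTS = labevents, D_LABITEMS = d_labitems,
                 D_ICD_DIAGNOSES = d_icd, CAREGIVERS = caregivers,
                 TRANSFERS = transfers, SERVICES = services,
                 CALLOUT = callout)
  reg <- table_registry()
  for (tb in names(tables))
    .write_csv_canonical(tables[[tb]], file.path(out_dir, paste0(tb, ".csv")))
  # header-only stubs for the remaining registry files
  for (tb in setdiff(names(reg), names(tables))) {
    writeLines(paste(reg[[tb]]$columns$name, collapse = ","),
               file.path(out_dir, paste0(tb, ".csv")), sep = "\n")
  }

  manifest <- list(
    seed = seed,
    spec = list(n_patients = n,
                mean_admissions_per_patient = spec$mean_admissions_per_patient,
                icu_stay_probability = spec$icu_stay_probability,
                diabetes_fraction = spec$diabetes_fraction,
                hypertension_fraction = spec$hypertension_fraction,
                comorbid_fraction = spec$comorbid_fraction,
                multi_icu_fraction = spec$multi_icu_fraction,
                date_window = spec$date_window),
    row_counts = lapply(tables, nrow),
    cohorts = list(
      diabetes = sort(as.integer(subject_ids[plan$diabetes_ix])),
      hypertension = sort(as.integer(subject_ids[plan$hyper_ix])),
      comorbid = sort(as.integer(subject_ids[plan$comorbid_ix])),
      multi_icu = sort(as.integer(subject_ids[plan$multi_ix]))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a generated dataset's ground-truth manifest
#' @param data_dir Dataset directory.
#' @return The manifest list; cohort IDs as integer vectors.
#' @export
read_manifest <- function(data_dir) {
  jsonlite::read_json(file.path(data_dir, "manifest.json"),
                      simplifyVector = TRUE)
}
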