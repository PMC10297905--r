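# Row- and table-level CSV -> RDF mapping: emission rules, union-domain
# links, header validation, conservation, idempotence and closure.

.mc <- function(x) paste0("<http://mimicIII.com/base/", x, ">")
.rdf_type <- "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>"

test_that("a patient row maps to the hand-enumerated triples", {
  rules <- data.frame(column = c("GENDER", "DOB"),
                      property = c("gender", "dob"),
                      literal_type = c("categorical", "datetime"),
                      stringsAsFactors = FALSE)
  row <- c(SUBJECT_ID = "12345", GENDER = "M", DOB = "2050-01-01 00:00:00")

  # without key echo: type + gender + dob
  m3 <- table_mapping("PATIENTS", "Patient", "SUBJECT_ID", rules,
                      key_echo = FALSE)
  got3 <- map_row(m3, row)
  want3 <- data.frame(
    s = rep(.mc("Patient/12345"), 3),
    p = c(.rdf_type, .mc("gender"), .mc("dob")),
    o = c(.mc("Patient"), .mc("Male"),
          "\"2050-01-01T00:00:00\"^^<http://www.w3.org/2001/XMLSchema#dateTime>"),
    stringsAsFactors = FALSE)
  expect_setequal(paste(got3$s, got3$p, got3$o),
                  paste(want3$s, want3$p, want3$o))

  # key echo (the default) adds the subject_id literal: 4 triples
  m4 <- table_mapping("PATIENTS", "Patient", "SUBJECT_ID", rules)
  got4 <- map_row(m4, row)
  expect_equal(nrow(got4), 4L)
  expect_true(paste(.mc("Patient/12345"), .mc("subject_id"), "\"12345\"") %in%
                paste(got4$s, got4$p, got4$o))
})

test_that("admission rows link from their patient", {
  mp <- default_mappings()[["ADMISSIONS"]]
  row <- c(ROW_ID = "1", SUBJECT_ID = "12345", HADM_ID = "100001",
           ADMITTIME = "2101-01-01 10:00:00", DISCHTIME = "2101-01-05 09:00:00",
           DEATHTIME = "", ADMISSION_TYPE = "EMERGENCY",
           ADMISSION_LOCATION = "", DISCHARGE_LOCATION = "HOME",
           INSURANCE = "Private", DIAGNOSIS = "SEPSIS",
           HOSPITAL_EXPIRE_FLAG = "0")
  tr <- map_row(mp, row)
  expect_true(paste(.mc("Patient/12345"), .mc("HAS_ADMISSION"),
                    .mc("Admission/100001")) %in% paste(tr$s, tr$p, tr$o))
  # absent columns emit nothing
  expect_false(any(tr$p == .mc("deathtime")))
})

test_that("union-domain medication links follow the non-null context keys", {
  mp <- default_mappings()[["PRESCRIPTIONS"]]
  base_row <- c(ROW_ID = "7", SUBJECT_ID = "12345", HADM_ID = "100001",
                ICUSTAY_ID = "", STARTDATE = "2101-01-02 00:00:00",
                ENDDATE = "", DRUG_TYPE = "MAIN", DRUG = "Insulin",
                FORMULARY_DRUG_CD = "", DOSE_VAL_RX = "10",
                DOSE_UNIT_RX = "mg", ROUTE = "IV")
  # admission context only: exactly one link, from the Admission IRI
  tr <- map_row(mp, base_row)
  links <- tr[tr$p == .mc("HAS_MEDICATION"), ]
  expect_equal(nrow(links), 1L)
  expect_equal(links$s, .mc("Admission/100001"))
  expect_equal(links$o, .mc("Prescription/7"))
  # both contexts: two links, one per domain class
  row2 <- base_row
  row2["ICUSTAY_ID"] <- "200001"
  tr2 <- map_row(mp, row2)
  links2 <- tr2[tr2$p == .mc("HAS_MEDICATION"), ]
  expect_setequal(links2$s, c(.mc("Admission/100001"), .mc("ICU_Stays/200001")))
})

test_that("rows without their subject key are rejected", {
  mp <- default_mappings()[["PATIENTS"]]
  expect_error(map_row(mp, c(GENDER = "F")), "key column")
  expect_error(map_row(mp, c(SUBJECT_ID = "", GENDER = "F")), "key column")
})

test_that("header-only files map to empty graphs and mismatches error", {
  mp <- default_mappings()[["DIAGNOSES_ICD"]]
  f <- tempfile(fileext = ".csv")
  writeLines("ROW_ID,SUBJECT_ID,HADM_ID,SEQ_NUM,ICD9_CODE", f)
  res <- map_table(mp, f)
  expect_equal(triple_count(res$graph), 0L)
  expect_equal(res$report$rows_read, 0L)

  writeLines("ROW_ID,SUBJECT_ID,HADM_ID,SEQ_NUM", f)  # missing a column
  expect_error(map_table(mp, f), "ICD9_CODE")
  writeLines("ROW_ID,SUBJECT_ID,HADM_ID,SEQ_NUM,ICD9_CODE,EXTRA", f)
  expect_error(map_table(mp, f), "EXTRA")
  # column order and case are immaterial
  writeLines(c("icd9_code,row_id,subject_id,hadm_id,seq_num",
               "25000,1,10001,100001,1"), f)
  res2 <- map_table(mp, f)
  expect_equal(res2$report$rows_read, 1L)
  expect_true(paste(.mc("ICD_Diagnosis/1"), .mc("icd9_code"), "\"25000\"") %in%
                triple_set(res2$graph))
})

test_that("triples emitted follow the conservation formula", {
  fx <- shared_dataset()
  mps <- default_mappings()
  for (tb in c("PATIENTS", "ADMISSIONS", "ICUSTAYS", "DIAGNOSES_ICD",
               "PRESCRIPTIONS", "LABEVENTS")) {
    res <- map_table(mps[[tb]], file.path(fx$dir, paste0(tb, ".csv")))
    expect_equal(res$report$triples_emitted,
                 brute_force_triple_count(mps[[tb]],
                                          file.path(fx$dir, paste0(tb, ".csv"))),
                 label = tb)
  }
})

test_that("fully-populated rows emit exactly R*(1+C+L) triples", {
  # 3 rows, all columns populated, every link resolvable
  mp <- default_mappings()[["DIAGNOSES_ICD"]]
  f <- tempfile(fileext = ".csv")
  writeLines(c("ROW_ID,SUBJECT_ID,HADM_ID,SEQ_NUM,ICD9_CODE",
               "1,10001,100001,1,25000",
               "2,10001,100001,2,4019",
               "3,10002,100002,1,41401"), f)
  res <- map_table(mp, f)
  # C = 5 columns (key echo on), L = 1 admission link
  expect_equal(triple_count(res$graph), 3L * (1L + 5L + 1L))
})

test_that("duplicated rows collapse under set semantics", {
  mp <- default_mappings()[["DIAGNOSES_ICD"]]
  f <- tempfile(fileext = ".csv")
  writeLines(c("ROW_ID,SUBJECT_ID,HADM_ID,SEQ_NUM,ICD9_CODE",
               "1,10001,100001,1,25000",
               "1,10001,100001,1,25000"), f)
  res <- map_table(mp, f)
  expect_equal(triple_count(res$graph), 7L)
  expect_equal(res$report$rows_read, 2L)
})

test_that("dataset mapping is idempotent and closed over the schema", {
  fx <- shared_dataset()
  sg <- shared_graph()
  res2 <- map_dataset(fx$dir)
  expect_identical(triple_set(res2$graph), triple_set(sg$graph))

  sc <- build_mimic_schema()
  preds <- unique(sg$graph$triples$p)
  declared <- c(.rdf_type,
                .mc(sc$object_properties$name),
                .mc(sc$datatype_properties$name))
  expect_true(all(preds %in% declared))

  # every minted subject inverts to (class, keys)
  subj <- unique(sg$graph$triples$s)
  inv <- lapply(sub("^<(.*)>$", "\\1", subj[seq(1, length(subj), by = 97)]),
                unmint_iri)
  expect_false(any(vapply(inv, is.null, TRUE)))
  expect_true(all(vapply(inv, function(x) x$class %in% sc$classes$name, TRUE)))
})

test_that("a missing core table aborts dataset mapping", {
  fx <- shared_dataset()
  d2 <- file.path(tempdir(), "ehrkg-missing")
  unlink(d2, recursive = TRUE)
  dir.create(d2)
  for (f in setdiff(list.files(fx$dir), "PATIENTS.csv"))
    file.copy(file.path(fx$dir, f), file.path(d2, f))
  expect_error(map_dataset(d2), "PATIENTS")
})
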