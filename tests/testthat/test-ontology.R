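# Built-in schema structure: class hierarchy, the 19 object properties,
# the alias reconciliation, and structural validation.

test_that("built-in schema carries the published class hierarchy", {
  sc <- build_mimic_schema()
  expect_s3_class(sc, "ehr_schema")
  expect_identical(sc$base_iri, "http://mimicIII.com/base/")
  expect_identical(sc$prefix, "mc")
  expect_equal(nrow(validate_schema(sc)), 0L)
  # no duplicate class names after canonicalization
  expect_false(anyDuplicated(sc$classes$name) > 0)

  # branch structure: coded patient care, code dictionaries, events
  expect_setequal(sc$classes$name[sc$classes$parent == "Patient_Care"],
                  c("ICD_Diagnosis", "ICD_Procedure"))
  expect_setequal(sc$classes$name[sc$classes$parent == "Codes"],
                  c("CPT_Code", "DRG_Code", "ICD_Diagnosis_Code",
                    "ICD_Procedure_Code", "Lab_Item", "Individual_Item"))
  expect_setequal(sc$classes$name[sc$classes$parent == "Events"],
                  c("Chart_Event", "CPT_Event", "Input_Event", "Lab_Event",
                    "Microbiology_Event", "Note_Event", "Output_Event"))
  expect_equal(class_ancestors(sc, "Chart_Event"), c("Events", "ROOT"))
  expect_equal(class_ancestors(sc, "ICD_Diagnosis"), c("Patient_Care", "ROOT"))
})

test_that("object properties match the published table exactly", {
  sc <- build_mimic_schema()
  got <- sc$object_properties[order(sc$object_properties$name),
                              c("name", "domains", "range", "source_table")]
  rownames(got) <- NULL
  # independently transcribed property table (printed labels reconciled
  # through the declared alias map)
  want <- data.frame(rbind(
    c("HAS_ADMISSION", "Patient", "Admission", "admissions.csv"),
    c("HAS_CAREGIVER", "Patient;Admission;ICU_Stays;ICD_Procedure", "CareGivers", "caregivers.csv"),
    c("HAS_CPT_CODE", "ICD_Procedure", "CPT_Code", "d_cpt.csv"),
    c("HAS_DIAGNOSIS", "Admission;ICU_Stays", "ICD_Diagnosis", "diagnoses_icd.csv"),
    c("HAS_DRG_CODE", "Admission", "DRG_Code", "drgcodes.csv"),
    c("HAS_ICD_DIAGNOSIS", "Patient_Care", "ICD_Diagnosis", "diagnoses_icd.csv"),
    c("HAS_ICD_PROCEDURE", "Patient_Care", "ICD_Procedure", "procedures_icd.csv"),
    c("HAS_ICU_DIAGNOSIS_CODE", "ICU_Stays", "ICD_Diagnosis_Code", "d_icd_diagnoses.csv"),
    c("HAS_ICU_PROCEDURE_CODE", "ICU_Stays", "ICD_Procedure_Code", "d_icd_procedures.csv"),
    c("HAS_ICU_STAY", "Admission", "ICU_Stays", "icustays.csv"),
    c("HAS_INDIVIDUAL_ITEM", "Prescription;ICD_Procedure", "Individual_Item", "d_items.csv"),
    c("HAS_LAB_EVENTS", "Patient;Admission;ICU_Stays", "Lab_Event", "labevents.csv"),
    c("HAS_LAB_ITEM", "Lab_Event", "Lab_Item", "d_labitems.csv"),
    c("HAS_MEDICATION", "Admission;ICU_Stays", "Prescription", "prescriptions.csv"),
    c("HAS_NOTE", "Patient;Admission;ICU_Stays", "Note_Event", "noteevents.csv"),
    c("HAS_PATIENT_CARE", "Patient", "Patient_Care", "patients.csv"),
    c("HAS_PROCEDURE", "Admission;ICU_Stays", "ICD_Procedure", "procedures_icd.csv"),
    c("HAS_SERVICE", "Admission;ICU_Stays", "Services", "services.csv"),
    c("HAS_TRANSFER", "Admission;ICU_Stays", "Transfers", "transfers.csv")),
    stringsAsFactors = FALSE)
  names(want) <- c("name", "domains", "range", "source_table")
  expect_equal(nrow(got), 19L)
  expect_equal(got, want)

  # spot checks through the lookup interface
  p <- object_property(sc, "HAS_ADMISSION")
  expect_equal(p$domains, "Patient")
  expect_equal(p$range, "Admission")
  expect_equal(object_property(sc, "HAS_MEDICATION")$domains,
               c("Admission", "ICU_Stays"))
  expect_null(object_property(sc, "HAS_NOTHING"))
})

test_that("alias map reconciles printed labels to declared classes", {
  sc <- build_mimic_schema()
  al <- ehr_class_aliases()
  expect_true(all(al %in% sc$classes$name))
  expect_equal(resolve_class_alias("Diagnosis"), "ICD_Diagnosis")
  expect_equal(resolve_class_alias("Lab_Items"), "Lab_Item")
  expect_equal(resolve_class_alias("Patient"), "Patient")  # pass-through
  # every domain/range identifier resolves to a declared class (closure)
  used <- unique(c(unlist(strsplit(sc$object_properties$domains, ";")),
                   sc$object_properties$range,
                   unlist(strsplit(sc$datatype_properties$domains, ";"))))
  expect_true(all(used %in% sc$classes$name))
})

test_that("structural validation flags cycles and undeclared references", {
  sc <- build_mimic_schema()
  # subclass cycle
  bad <- sc
  bad$classes$parent[bad$classes$name == "Events"] <- "Chart_Event"
  iss <- validate_schema(bad)
  expect_true("CYCLE" %in% iss$code)
  # undeclared range (a typo'd class label)
  bad2 <- sc
  bad2$object_properties$range[1] <- "Diagnosi"
  iss2 <- validate_schema(bad2)
  expect_equal(sum(iss2$code == "UNDECLARED_CLASS"), 1L)
  expect_equal(iss2$subject[iss2$code == "UNDECLARED_CLASS"],
               sc$object_properties$name[1])
  # duplicate class name
  bad3 <- sc
  bad3$classes <- rbind(bad3$classes, bad3$classes[1, ])
  expect_true("DUPLICATE_NAME" %in% validate_schema(bad3)$code)
})

test_that("registry enumerates the 26 distribution files", {
  reg <- table_registry()
  expect_length(reg, 26L)
  expect_false(anyDuplicated(names(reg)) > 0)
  expect_true(all(names(reg) == toupper(names(reg))))
  expect_true("PATIENTS" %in% names(reg))
  expect_equal(reg$PATIENTS$primary_key, "SUBJECT_ID")
  expect_true("MICROBIOLOGYEVENTS" %in% names(reg))
  # files behind the published class table are all present
  for (tb in c("ADMISSIONS", "CAREGIVERS", "DIAGNOSES_ICD", "PROCEDURES_ICD",
               "D_CPT", "D_ICD_DIAGNOSES", "D_ICD_PROCEDURES", "DRGCODES",
               "ICUSTAYS", "CHARTEVENTS", "CPTEVENTS", "INPUTEVENTS_CV",
               "INPUTEVENTS_MV", "LABEVENTS", "NOTEEVENTS", "OUTPUTEVENTS",
               "TRANSFERS", "SERVICES", "PRESCRIPTIONS", "CALLOUT"))
    expect_true(tb %in% names(reg), label = tb)
  # primary keys exist and are non-nullable in core tables
  for (ts in reg[vapply(reg, function(x) x$core, TRUE)]) {
    i <- match(ts$primary_key, ts$columns$name)
    expect_false(anyNA(i), label = ts$file_name)
    expect_true(all(!ts$columns$nullable[i]), label = ts$file_name)
  }
})

test_that("registry JSON export round-trips through jsonlite", {
  path <- tempfile(fileext = ".json")
  registry_to_json(path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(doc, 26L)
  expect_true(doc$PATIENTS$core)
})
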