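# Synthetic generator: determinism, exact-count planting, referential
# integrity, oracle/manifest agreement, and the perturbation fixtures.

test_that("identical specs generate byte-identical datasets", {
  spec <- generator_spec(seed = 7L, n_patients = 10L)
  d1 <- file.path(tempdir(), "det1"); unlink(d1, recursive = TRUE)
  d2 <- file.path(tempdir(), "det2"); unlink(d2, recursive = TRUE)
  m1 <- generate_ehr(spec, d1)
  m2 <- generate_ehr(spec, d2)
  expect_identical(m1, m2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  }
  # all 26 registry files plus the manifest are present
  expect_setequal(list.files(d1),
                  c(paste0(names(table_registry()), ".csv"), "manifest.json"))
})

test_that("an empty population yields header-only tables", {
  d <- file.path(tempdir(), "zero"); unlink(d, recursive = TRUE)
  m <- generate_ehr(generator_spec(seed = 3L, n_patients = 0L), d)
  pts <- read_mimic_csv(file.path(d, "PATIENTS.csv"))
  expect_equal(nrow(pts), 0L)
  expect_length(m$cohorts$diabetes, 0L)
  expect_length(m$cohorts$multi_icu, 0L)
  expect_equal(nrow(check_dataset_integrity(d)), 0L)
})

test_that("cohorts are planted by exact count", {
  d <- file.path(tempdir(), "plant"); unlink(d, recursive = TRUE)
  m <- generate_ehr(generator_spec(seed = 42L, n_patients = 100L,
                                   diabetes_fraction = 0.2), d)
  expect_length(m$cohorts$diabetes, 20L)  # floor(0.2 * 100)
  expect_length(m$cohorts$hypertension, 8L)
  expect_length(m$cohorts$comorbid, 3L)
  expect_length(m$cohorts$multi_icu, 10L)
  # comorbid set is exactly the intersection
  expect_identical(m$cohorts$comorbid,
                   sort(intersect(m$cohorts$diabetes, m$cohorts$hypertension)))
  # every diabetes member has a 250-family code in the diagnosis file
  dx <- read_mimic_csv(file.path(d, "DIAGNOSES_ICD.csv"))
  with_dm <- sort(unique(as.integer(
    dx$SUBJECT_ID[startsWith(dx$ICD9_CODE, "250")])))
  expect_identical(with_dm, m$cohorts$diabetes)
  # every multi-ICU member has >= 2 ICU stay rows
  icu <- read_mimic_csv(file.path(d, "ICUSTAYS.csv"))
  stays <- tapply(icu$ICUSTAY_ID, as.integer(icu$SUBJECT_ID),
                  function(x) length(unique(x)))
  expect_true(all(stays[as.character(m$cohorts$multi_icu)] >= 2))
})

test_that("infeasible specs are rejected", {
  expect_error(generator_spec(comorbid_fraction = 0.5), "comorbid")
  expect_error(generator_spec(diabetes_fraction = 1.5), "probabilities")
  expect_error(generator_spec(date_window = c("2105-01-01", "2100-01-01")),
               "date_window")
  expect_error(generator_spec(mean_admissions_per_patient = 0.2), ">= 1")
})

test_that("integrity and oracle agreement hold across random specs", {
  for (seed in c(1L, 99L, 2024L)) {
    d <- file.path(tempdir(), paste0("prop", seed))
    unlink(d, recursive = TRUE)
    m <- generate_ehr(generator_spec(seed = seed, n_patients = 40L,
                                     diabetes_fraction = 0.15,
                                     hypertension_fraction = 0.10,
                                     comorbid_fraction = 0.05,
                                     multi_icu_fraction = 0.12), d)
    expect_equal(nrow(check_dataset_integrity(d)), 0L, label = seed)
    expect_identical(oracle_scan(d, "diagnosis_prefix", list(prefix = "250")),
                     m$cohorts$diabetes, label = seed)
    expect_identical(oracle_scan(d, "diagnosis_prefix", list(prefix = "401")),
                     m$cohorts$hypertension, label = seed)
    expect_identical(oracle_scan(d, "comorbid", list()),
                     m$cohorts$comorbid, label = seed)
    expect_identical(oracle_scan(d, "multi_icu", list(min_stays = 2)),
                     m$cohorts$multi_icu, label = seed)
    # oracle monotonicity in the stay threshold
    expect_true(all(oracle_scan(d, "multi_icu", list(min_stays = 2)) %in%
                      oracle_scan(d, "multi_icu", list(min_stays = 1))))
  }
})

test_that("each perturbation kind plants exactly one detectable defect", {
  mk <- function(name) {
    d <- file.path(tempdir(), name)
    unlink(d, recursive = TRUE)
    generate_ehr(generator_spec(seed = 7L, n_patients = 30L), d)
    d
  }
  # orphan foreign key -> one integrity violation at the stated row
  d <- mk("pert-fk")
  desc <- perturb_dataset(d, "orphan_fk", seed = 2)
  v <- check_dataset_integrity(d)
  expect_equal(nrow(v), 1L)
  expect_equal(v$code, "ORPHAN_FK")
  expect_equal(v$row, desc$row)

  # swapped admit/discharge -> one date-order violation
  d <- mk("pert-date")
  desc <- perturb_dataset(d, "bad_date_order", seed = 2)
  v <- check_dataset_integrity(d)
  expect_equal(nrow(v), 1L)
  expect_equal(v$code, "DATE_ORDER")
  expect_equal(v$table, "ADMISSIONS")

  # duplicated row -> triple count unchanged under set semantics
  d <- mk("pert-dup")
  mp <- default_mappings()[["DIAGNOSES_ICD"]]
  before <- map_table(mp, file.path(d, "DIAGNOSES_ICD.csv"))
  desc <- perturb_dataset(d, "duplicate_row", seed = 2)
  after <- map_table(mp, file.path(d, "DIAGNOSES_ICD.csv"))
  expect_equal(after$report$rows_read, before$report$rows_read + 1L)
  expect_identical(triple_set(after$graph), triple_set(before$graph))

  # perturbing an empty dataset is a fixture error
  d0 <- file.path(tempdir(), "pert-empty")
  unlink(d0, recursive = TRUE)
  generate_ehr(generator_spec(seed = 1L, n_patients = 0L), d0)
  expect_error(perturb_dataset(d0, "orphan_fk"), "empty")
})

test_that("manifest JSON round-trips through the reader", {
  fx <- shared_dataset()
  m <- read_manifest(fx$dir)
  expect_identical(sort(m$cohorts$diabetes), fx$manifest$cohorts$diabetes)
  expect_equal(m$spec$n_patients, 100L)
  expect_equal(m$seed, 42L)
})
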