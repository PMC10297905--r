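# Store loading and the three cohort analyses, checked set-exactly
# against the independent relational oracle and the generator manifest.

test_that("loading preserves the triple count and is independent", {
  sg <- shared_graph()
  h <- kg_load(sg$graph)
  expect_equal(kg_count(h), triple_count(sg$graph))
  h2 <- kg_load(sg$graph)
  expect_equal(kg_count(h2), kg_count(h))
  expect_equal(kg_count(kg_load(rdf_graph())), 0L)
})

test_that("diagnosis cohort equals oracle and manifest exactly", {
  fx <- shared_dataset()
  h <- kg_load(shared_graph()$graph)
  co <- cohort_by_diagnosis(h, "250")
  ids <- sort(as.integer(co$subject_ids))
  expect_identical(ids, fx$manifest$cohorts$diabetes)
  expect_identical(ids, oracle_scan(fx$dir, "diagnosis_prefix",
                                    list(prefix = "250")))
  # a prefix matching nothing yields the empty cohort
  expect_length(cohort_by_diagnosis(h, "999")$patients, 0L)
  expect_error(cohort_by_diagnosis(h, ""))
  # subset of the patients with any diagnosis at all
  any_dx <- unique(unlist(lapply(
    c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9", "V"),
    function(p) cohort_by_diagnosis(h, p)$patients)))
  expect_true(all(co$patients %in% any_dx))
})

test_that("exact-code matching restricts the prefix cohort", {
  h <- kg_load(shared_graph()$graph)
  fx <- shared_dataset()
  pre <- cohort_by_diagnosis(h, "4019")
  ex <- cohort_by_diagnosis(h, "4019", exact = TRUE)
  expect_setequal(ex$patients, pre$patients)  # 4019 is a complete code
  expect_length(cohort_by_diagnosis(h, "401", exact = TRUE)$patients,
                0L)  # the bare prefix is not itself a planted code
})

test_that("comorbid cohort is the intersection of its parts", {
  fx <- shared_dataset()
  h <- kg_load(shared_graph()$graph)
  cc <- cohort_comorbid(h, "401", "250")
  expect_identical(sort(as.integer(cc$subject_ids)),
                   fx$manifest$cohorts$comorbid)
  expect_identical(sort(as.integer(cc$subject_ids)),
                   oracle_scan(fx$dir, "comorbid",
                               list(prefix_a = "401", prefix_b = "250")))
  a <- cohort_by_diagnosis(h, "401")
  b <- cohort_by_diagnosis(h, "250")
  expect_setequal(cc$patients, intersect(a$patients, b$patients))
  expect_true(all(cc$patients %in% a$patients))
  expect_true(all(cc$patients %in% b$patients))
  # idempotent intersection
  same <- cohort_comorbid(h, "250", "250")
  expect_setequal(same$patients, b$patients)
})

test_that("multi-ICU cohort counts distinct stays and is antitone", {
  fx <- shared_dataset()
  h <- kg_load(shared_graph()$graph)
  mi <- cohort_multi_icu(h, 2)
  expect_identical(sort(as.integer(mi$subject_ids)),
                   fx$manifest$cohorts$multi_icu)
  expect_identical(sort(as.integer(mi$subject_ids)),
                   oracle_scan(fx$dir, "multi_icu", list(min_stays = 2)))
  expect_true(all(mi$counts >= 2))
  # min_stays = 1: everyone with any ICU stay
  one <- cohort_multi_icu(h, 1)
  expect_identical(sort(as.integer(one$subject_ids)),
                   oracle_scan(fx$dir, "multi_icu", list(min_stays = 1)))
  # antitone in the threshold
  three <- cohort_multi_icu(h, 3)
  expect_true(all(three$patients %in% mi$patients))
  expect_true(all(mi$patients %in% one$patients))
  expect_error(cohort_multi_icu(h, 0), "min_stays")
})
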