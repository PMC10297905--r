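# SPARQL-subset evaluator: pattern matching, filters, aggregates and the
# published query idioms.

.mc <- function(x) paste0("<http://mimicIII.com/base/", x, ">")
.rdf_type <- "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>"

.tiny_graph <- function() {
  rdf_graph(
    s = c(.mc("Patient/1"), .mc("Patient/1"), .mc("Patient/1"),
          .mc("Patient/2"), .mc("Patient/2"),
          .mc("ICD_Diagnosis/1"), .mc("ICD_Diagnosis/1"),
          .mc("ICD_Diagnosis/2"), .mc("ICD_Diagnosis/2")),
    p = c(.rdf_type, .mc("gender"), .mc("subject_id"),
          .rdf_type, .mc("gender"),
          .rdf_type, .mc("icd9_code"),
          .rdf_type, .mc("icd9_code")),
    o = c(.mc("Patient"), .mc("Male"), "\"1\"",
          .mc("Patient"), .mc("Female"),
          .mc("ICD_Diagnosis"), "\"41401\"",
          .mc("ICD_Diagnosis"), "\"25000\""))
}

test_that("a planted diagnosis code is found by the published query", {
  # plant exactly one matching row; oracle = direct scan of the fixture
  g <- .tiny_graph()
  res <- sparql_query(g, 'SELECT ?diagnosis WHERE { ?diagnosis mc:icd9_code "41401" }')
  expect_equal(nrow(res), 1L)
  expect_equal(as.data.frame(res)$diagnosis, .mc("ICD_Diagnosis/1"))
  # typographic quotes as printed are accepted
  res2 <- sparql_query(g, "SELECT ?diagnosis WHERE { ?diagnosis mc:icd9_code “41401” }")
  expect_equal(nrow(res2), 1L)
})

test_that("queries over the empty graph return no rows", {
  g <- rdf_graph()
  res <- sparql_query(g, "SELECT ?x WHERE { ?x a mc:Patient }")
  expect_equal(nrow(res), 0L)
})

test_that("conjunctive demographic patterns join correctly", {
  g <- .tiny_graph()
  res <- sparql_query(g, "SELECT ?patient WHERE {
    ?patient mc:gender mc:Male . ?patient a mc:Patient }")
  expect_equal(as.data.frame(res)$patient, .mc("Patient/1"))
  # default ':' prefix and 'a' keyword, as in the caregiver query idiom
  res2 <- sparql_query(g, "SELECT ?p WHERE { ?p rdf:type :Patient . ?p :gender :Female }")
  expect_equal(as.data.frame(res2)$p, .mc("Patient/2"))
})

test_that("FILTER comparisons, STRSTARTS and regex behave", {
  g <- .tiny_graph()
  res <- sparql_query(g, 'SELECT ?d WHERE {
    ?d mc:icd9_code ?c . FILTER(STRSTARTS(STR(?c), "250")) }')
  expect_equal(as.data.frame(res)$d, .mc("ICD_Diagnosis/2"))
  res2 <- sparql_query(g, 'SELECT ?d WHERE {
    ?d mc:icd9_code ?c . FILTER(regex(?c, "^4[0-9]+$")) }')
  expect_equal(as.data.frame(res2)$d, .mc("ICD_Diagnosis/1"))
  res3 <- sparql_query(g, 'SELECT ?d WHERE {
    ?d mc:icd9_code ?c . FILTER(?c != "41401" && !(?c = "99999")) }')
  expect_equal(as.data.frame(res3)$d, .mc("ICD_Diagnosis/2"))
  # numeric comparison on typed literals
  g2 <- rdf_graph(
    s = .mc(paste0("ICD_Diagnosis/", 1:3)),
    p = rep(.mc("seq_num"), 3),
    o = paste0("\"", c(1, 2, 10), "\"^^<http://www.w3.org/2001/XMLSchema#integer>"))
  res4 <- sparql_query(g2, "SELECT ?d WHERE { ?d mc:seq_num ?n . FILTER(?n >= 2) }")
  expect_setequal(as.data.frame(res4)$d, .mc(paste0("ICD_Diagnosis/", 2:3)))
})

test_that("aggregates agree with unaggregated row counts", {
  sg <- shared_graph()
  plain <- sparql_query(sg$graph,
    "SELECT ?p WHERE { ?p mc:HAS_ADMISSION ?a }")
  counted <- sparql_query(sg$graph,
    "SELECT (COUNT(?p) AS ?n) WHERE { ?p mc:HAS_ADMISSION ?a }")
  expect_equal(as.integer(result_values(counted)$n), nrow(plain))
  dcount <- sparql_query(sg$graph,
    "SELECT (COUNT(DISTINCT ?p) AS ?n) WHERE { ?p mc:HAS_ADMISSION ?a }")
  distinct <- sparql_query(sg$graph,
    "SELECT DISTINCT ?p WHERE { ?p mc:HAS_ADMISSION ?a }")
  expect_equal(as.integer(result_values(dcount)$n), nrow(distinct))
})

test_that("GROUP BY with HAVING reproduces a manual group-count", {
  sg <- shared_graph()
  res <- sparql_query(sg$graph, "SELECT ?p (COUNT(DISTINCT ?i) AS ?n) WHERE {
      ?p mc:HAS_ADMISSION ?a . ?a mc:HAS_ICU_STAY ?i .
    } GROUP BY ?p HAVING (COUNT(DISTINCT ?i) >= 2)")
  vals <- result_values(res)
  # manual recount from the unaggregated solutions
  raw <- as.data.frame(sparql_query(sg$graph,
    "SELECT ?p ?i WHERE { ?p mc:HAS_ADMISSION ?a . ?a mc:HAS_ICU_STAY ?i }"))
  manual <- tapply(raw$i, raw$p, function(x) length(unique(x)))
  manual <- manual[manual >= 2]
  expect_setequal(sub("^<(.*)>$", "\\1", vals$p),
                  sub("^<(.*)>$", "\\1", names(manual)))
  expect_equal(as.integer(vals$n[order(vals$p)]),
               as.integer(manual[order(names(manual))]))
})

test_that("ORDER BY, LIMIT and DISTINCT shape the solution sequence", {
  g <- .tiny_graph()
  res <- sparql_query(g, "SELECT ?c WHERE { ?d mc:icd9_code ?c } ORDER BY ?c")
  expect_equal(result_values(res)$c, c("25000", "41401"))
  res2 <- sparql_query(g, "SELECT ?c WHERE { ?d mc:icd9_code ?c } ORDER BY DESC(?c) LIMIT 1")
  expect_equal(result_values(res2)$c, "41401")
})

test_that("unsupported constructs and syntax errors are named", {
  g <- .tiny_graph()
  expect_error(sparql_query(g, "SELECT ?x WHERE { OPTIONAL { ?x a mc:Patient } }"),
               "OPTIONAL")
  expect_error(sparql_query(g, "ASK { ?x a mc:Patient }"), "SELECT")
  expect_error(sparql_query(g, "SELECT ?x WHERE { ?x a mc:Patient"),
               "unterminated")
  expect_error(sparql_query(g, "SELECT ?x WHERE { ?x zz:gender ?y }"),
               "prefix")
})

test_that("the evaluator agrees with an independent SPARQL engine", {
  # cross-check on a small mapped graph using the Python rdflib toolkit
  fx <- shared_dataset()
  mp <- default_mappings()[["DIAGNOSES_ICD"]]
  res <- map_table(mp, file.path(fx$dir, "DIAGNOSES_ICD.csv"))
  nt_file <- tempfile(fileext = ".nt")
  write_graph(res$graph, nt_file)
  q <- paste("PREFIX mc: <http://mimicIII.com/base/>",
             "SELECT DISTINCT ?d WHERE { ?d mc:icd9_code ?c .",
             'FILTER(STRSTARTS(STR(?c), "250")) }')
  py <- paste(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='nt')",
    sprintf("rows = g.query('''%s''')", q),
    "print('\\n'.join(sorted(str(r[0]) for r in rows)))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(py), shQuote(nt_file)),
                 stdout = TRUE)
  ours <- sort(sub("^<(.*)>$", "\\1",
                   as.data.frame(sparql_query(res$graph, q))$d))
  expect_equal(ours, out[nzchar(out)])
})
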