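# IRI minting, literals, categorical resources, and the triple graph's
# set semantics and canonical serialization.

test_that("IRI minting is deterministic, composite and invertible", {
  expect_identical(mint_iri("Patient", "12345"),
                   "http://mimicIII.com/base/Patient/12345")
  expect_identical(mint_iri("Patient", "12345"), mint_iri("Patient", "12345"))
  expect_identical(mint_iri("Lab_Event", c("12345", "50912")),
                   "http://mimicIII.com/base/Lab_Event/12345-50912")
  expect_error(mint_iri("Patient", ""), "non-empty")
  expect_error(mint_iri("Patient", c("1", "  ")), "non-empty")

  # inversion property over awkward key values, including the joiner
  set.seed(11)
  pool <- c(letters, LETTERS, 0:9, "-", "_", ".", "/", "%", " ", "é")
  for (i in 1:50) {
    keys <- replicate(sample(1:3, 1),
                      paste(sample(pool, sample(1:8, 1), replace = TRUE),
                            collapse = ""))
    keys <- vapply(keys, function(k) if (nzchar(trimws(k))) k else "x", "")
    iri <- mint_iri("Lab_Event", keys)
    back <- unmint_iri(iri)
    expect_equal(back$class, "Lab_Event")
    expect_equal(back$keys, unname(trimws(keys)))
  }
})

test_that("literal construction validates, normalises and skips absents", {
  expect_null(make_literal("", "string"))
  expect_null(make_literal("   ", "integer"))
  expect_null(make_literal("NULL", "datetime"))
  expect_null(make_literal("null", "code"))

  lit <- make_literal("41401", "code")
  expect_equal(lit, list(lexical = "41401", literal_type = "string"))
  expect_equal(make_literal("2101-10-20 19:08:00", "datetime")$lexical,
               "2101-10-20T19:08:00")
  expect_equal(make_literal("2101-10-20", "datetime")$lexical,
               "2101-10-20T00:00:00")
  expect_equal(make_literal("-17", "integer")$literal_type, "integer")
  expect_equal(make_literal("3.14", "decimal")$lexical, "3.14")
  expect_error(make_literal("abc", "integer"), "not an integer")
  expect_error(make_literal("1.2.3", "decimal"), "not a decimal")
  expect_error(make_literal("20-10-2101", "datetime"), "not a datetime")
})

test_that("categorical demographics become vocabulary resources", {
  expect_equal(categorical_resource("gender", "M"),
               "http://mimicIII.com/base/Male")
  expect_equal(categorical_resource("marital_status", "MARRIED"),
               "http://mimicIII.com/base/Married")
  expect_equal(categorical_resource("race", "WHITE"),
               "http://mimicIII.com/base/White")
  expect_equal(categorical_resource("gender", "m"),
               "http://mimicIII.com/base/Male")  # case-normalised
  expect_true(is.na(categorical_resource("race", "KLINGON")))
  expect_error(categorical_resource("dob", "x"), "not categorical")
})

test_that("triple graphs have set semantics", {
  s <- c("<http://mimicIII.com/base/Patient/1>",
         "<http://mimicIII.com/base/Patient/1>")
  p <- rep("<http://mimicIII.com/base/gender>", 2)
  o <- rep("<http://mimicIII.com/base/Male>", 2)
  g <- rdf_graph(s, p, o)
  expect_equal(triple_count(g), 1L)
  g2 <- graph_union(g, rdf_graph(s[1], p[1], o[1]))
  expect_equal(triple_count(g2), 1L)
})

test_that("graph serialization is canonical and round-trips", {
  g <- rdf_graph(
    s = c("<http://mimicIII.com/base/Patient/2>",
          "<http://mimicIII.com/base/Patient/1>",
          "<http://mimicIII.com/base/Patient/1>"),
    p = c("<http://mimicIII.com/base/subject_id>",
          "<http://mimicIII.com/base/dob>",
          "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>"),
    o = c("\"2\"",
          "\"2050-01-01T00:00:00\"^^<http://www.w3.org/2001/XMLSchema#dateTime>",
          "<http://mimicIII.com/base/Patient>"))
  for (fmt in c("ntriples", "turtle")) {
    doc <- serialize_graph(g, fmt)
    g2 <- parse_graph(doc, fmt)
    expect_identical(triple_set(g2), triple_set(g), label = fmt)
    expect_identical(doc, serialize_graph(g2, fmt), label = fmt)
  }
  # N-Triples: one sorted line per triple
  nt <- strsplit(serialize_graph(g, "ntriples"), "\n")[[1]]
  expect_length(nt, 3L)
  expect_identical(nt, sort(nt, method = "radix"))
  # empty graph serializes to an empty document
  expect_identical(serialize_graph(rdf_graph(), "ntriples"), "")
})

test_that("literals with embedded quoting survive the round trip", {
  g <- rdf_graph("<http://mimicIII.com/base/Note_Event/1>",
                 "<http://mimicIII.com/base/text>",
                 paste0("\"line one\\nsaid \\\"hi\\\", used \\\\ and\\ttab\""))
  g2 <- parse_graph(serialize_graph(g, "ntriples"), "ntriples")
  expect_identical(triple_set(g2), triple_set(g))
})

test_that("malformed documents report the offending line", {
  expect_error(parse_graph("<a> <b>\n", "ntriples"), "parse error")
  expect_error(parse_graph("<a> <b> <c> .\nnot a triple here .\n", "ntriples"),
               "line 2")
})
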