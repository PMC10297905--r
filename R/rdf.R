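# RDF primitives: IRI minting with percent-encoding, typed literals,
# and the duplicate-free triple graph with canonical serialization.
#
# Terms are held in their N-Triples lexical encoding throughout
# ("<iri>", '"lex"', '"lex"^^<datatype>'), which makes set semantics,
# joins and canonical output plain string operations.

XSD_INTEGER  <- paste0(XSD_NS, "integer")
XSD_DECIMAL  <- paste0(XSD_NS, "decimal")
XSD_DATETIME <- paste0(XSD_NS, "dateTime")

# RFC 3986 unreserved characters minus "-": the hyphen is the composite-key
# joiner, so it is encoded inside key values to keep minted IRIs invertible.
.IRI_SAFE <- c(LETTERS, letters, as.character(0:9), ".", "_", "~")

pct_encode <- function(x) {
  needs <- grepl("[^A-Za-z0-9._~]", x)
  if (!any(needs)) return(x)
  enc1 <- function(s) {
    b <- charToRaw(s)
    ch <- strsplit(rawToChar(b), "", useBytes = TRUE)[[1]]
    paste(ifelse(ch %in% .IRI_SAFE, ch,
                 paste0("%", toupper(as.character(b)))), collapse = "")
  }
  x[needs] <- vapply(x[needs], enc1, "", USE.NAMES = FALSE)
  x
}

pct_decode <- function(x) {
  vapply(x, utils::URLdecode, "", USE.NAMES = FALSE)
}

#' Mint a deterministic IRI for an entity
#'
#' Resources are minted as `{base}{ClassName}/{key1-key2-...}` with each
#' key value percent-encoded (including `-`, the joiner, so composite
#' keys are unambiguous and the template is invertible).
#'
#' @param entity_class Canonical ontology class name.
#' @param key_values Character vector of key values (all non-empty).
#' @param base Base IRI; defaults to the built-in base.
#' @return Absolute IRI text.
#' @examples
#' mint_iri("Patient", "12345")
#' mint_iri("Lab_Event", c("12345", "50912"))
#' @export
mint_iri <- function(entity_class, key_values, base = EHR_BASE_IRI) {
  key_values <- trimws(as.character(key_values))
  if (!length(key_values) || any(!nzchar(key_values)))
    stop("IRI minting requires non-empty key values (class ", entity_class, ")")
  paste0(base, entity_class, "/", paste(pct_encode(key_values), collapse = "-"))
}

# Vectorized minting over parallel key columns (list of equal-length
# character vectors). Returns NA where any key is empty.
mint_iri_vec <- function(entity_class, key_cols, base = EHR_BASE_IRI) {
  key_cols <- lapply(key_cols, function(k) trimws(as.character(k)))
  ok <- Reduce(`&`, lapply(key_cols, nzchar))
  enc <- lapply(key_cols, pct_encode)
  joined <- do.call(paste, c(enc, sep = "-"))
  out <- paste0(base, entity_class, "/", joined)
  out[!ok] <- NA_character_
  out
}

#' Invert a minted IRI back to (class, key values)
#'
#' @param iri IRI text produced by [mint_iri()].
#' @param base Base IRI.
#' @return List with `class` and `keys`, or `NULL` when the IRI does not
#'   match the minting template.
#' @export
unmint_iri <- function(iri, base = EHR_BASE_IRI) {
  if (!startsWith(iri, base)) return(NULL)
  local <- substring(iri, nchar(base) + 1L)
  m <- regexec("^([A-Za-z_][A-Za-z0-9_]*)/(.+)$", local)
  g <- regmatches(local, m)[[1]]
  if (!length(g)) return(NULL)
  list(class = g[2], keys = pct_decode(strsplit(g[3], "-", fixed = TRUE)[[1]]))
}

# ---------------------------------------------------------------------------
# Literals

.nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.nt_unescape <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

# Absence sentinel: empty, whitespace-only, or the string NULL (any case).
is_absent <- function(raw) {
  raw <- as.character(raw)
  is.na(raw) | !nzchar(trimws(raw)) | toupper(trimws(raw)) == "NULL"
}

#' Build a typed literal from a raw CSV value
#'
#' Empty, whitespace-only and `"NULL"` values are absent (returns `NULL`).
#' Datetimes written as `YYYY-MM-DD HH:MM:SS` are normalised to ISO 8601
#' (`T` separator); bare dates gain a midnight time. Integer and decimal
#' values are validated lexically. `code` and `categorical` values are
#' kept verbatim as string-typed literals.
#'
#' @param raw Raw field text.
#' @param literal_type One of `r paste(LITERAL_TYPES, collapse = ", ")`.
#' @return List with `lexical` and `literal_type` (the storage type:
#'   string, integer, decimal or datetime), or `NULL` when absent.
#' @export
make_literal <- function(raw, literal_type) {
  if (length(raw) != 1L) stop("make_literal is scalar; see the mapper for columns")
  if (is_absent(raw)) return(NULL)
  raw <- trimws(as.character(raw))
  lt <- match.arg(literal_type, LITERAL_TYPES)
  switch(lt,
    datetime = {
      lex <- normalize_datetime(raw)
      if (is.na(lex)) stop("not a datetime: '", raw, "'")
      list(lexical = lex, literal_type = "datetime")
    },
    integer = {
      if (!grepl("^[+-]?[0-9]+$", raw)) stop("not an integer: '", raw, "'")
      list(lexical = raw, literal_type = "integer")
    },
    decimal = {
      if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$", raw))
        stop("not a decimal: '", raw, "'")
      list(lexical = raw, literal_type = "decimal")
    },
    list(lexical = raw, literal_type = "string"))
}

normalize_datetime <- function(x) {
  out <- sub("^([0-9]{4}-[0-9]{2}-[0-9]{2}) ([0-9]{2}:[0-9]{2}:[0-9]{2})$",
             "\\1T\\2", x)
  bare <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", out)
  out[bare] <- paste0(out[bare], "T00:00:00")
  ok <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}$", out)
  out[!ok] <- NA_character_
  out
}

# Encoded literal term from lexical + storage type
literal_term <- function(lexical, storage_type) {
  dt <- switch(storage_type,
               integer = XSD_INTEGER, decimal = XSD_DECIMAL,
               datetime = XSD_DATETIME, NULL)
  core <- paste0("\"", .nt_escape(lexical), "\"")
  if (is.null(dt)) core else paste0(core, "^^<", dt, ">")
}

# Vectorized: encode a raw CSV column as literal terms; NA where absent.
# Invalid numeric/datetime lexicals yield NA with a warning count collected
# by the caller.
encode_literal_column <- function(raw, literal_type) {
  raw <- as.character(raw)
  absent <- is_absent(raw)
  raw <- trimws(raw)
  out <- rep(NA_character_, length(raw))
  bad <- rep(FALSE, length(raw))
  live <- !absent
  if (!any(live)) return(list(terms = out, bad = bad))
  v <- raw[live]
  res <- switch(literal_type,
    datetime = {
      lex <- normalize_datetime(v)
      list(lex = lex, dt = XSD_DATETIME, bad = is.na(lex))
    },
    integer = {
      okv <- grepl("^[+-]?[0-9]+$", v)
      list(lex = ifelse(okv, v, NA), dt = XSD_INTEGER, bad = !okv)
    },
    decimal = {
      okv <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$", v)
      list(lex = ifelse(okv, v, NA), dt = XSD_DECIMAL, bad = !okv)
    },
    list(lex = v, dt = NULL, bad = rep(FALSE, length(v)))
  )
  term <- ifelse(is.na(res$lex), NA_character_,
                 paste0("\"", .nt_escape(res$lex), "\"",
                        if (!is.null(res$dt)) paste0("^^<", res$dt, ">") else ""))
  out[live] <- term
  bad[live] <- res$bad
  list(terms = out, bad = bad)
}

#' Fixed vocabulary for the three categorical demographic fields
#'
#' @return Named list of named character vectors: raw value -> resource
#'   local name (e.g. gender `M` -> `Male`).
#' @export
categorical_vocab <- function() {
  list(
    gender = c(M = "Male", F = "Female"),
    race = c(WHITE = "White", BLACK = "Black", ASIAN = "Asian",
             HISPANIC = "Hispanic", OTHER = "Other", UNKNOWN = "Unknown"),
    marital_status = c(MARRIED = "Married", SINGLE = "Single",
                       WIDOWED = "Widowed", DIVORCED = "Divorced",
                       SEPARATED = "Separated", UNKNOWN = "Unknown"))
}

#' Resource IRI for a categorical demographic value
#'
#' Gender, race and marital status are modelled as resources under the
#' base IRI (e.g. `mc:Male`), matching the query idiom
#' `?patient mc:gender mc:Male`. Values outside the fixed vocabulary are
#' signalled so the mapper can fall back to a plain string literal.
#'
#' @param property One of `gender`, `race`, `marital_status`.
#' @param raw Raw field value.
#' @param base Base IRI.
#' @return IRI text, or `NA_character_` when the value is not in the
#'   vocabulary.
#' @examples
#' categorical_resource("gender", "M")
#' @export
categorical_resource <- function(property, raw, base = EHR_BASE_IRI) {
  vocab <- categorical_vocab()
  if (!property %in% names(vocab))
    stop("property '", property, "' is not categorical")
  key <- toupper(trimws(raw))
  hit <- unname(vocab[[property]][key])
  ifelse(is.na(hit), NA_character_, paste0(base, hit))
}

# ---------------------------------------------------------------------------
# Triple graph: duplicate-free set of encoded triples.

default_bindings <- function() {
  c(mc = EHR_BASE_IRI, rdf = RDF_NS, rdfs = RDFS_NS,
    owl = OWL_NS, xsd = XSD_NS)
}

#' Construct a triple graph
#'
#' @param s,p,o Equal-length character vectors of encoded terms
#'   (`<iri>` or N-Triples literal syntax). Duplicate triples collapse
#'   (set semantics).
#' @param bindings Named character vector of prefix -> namespace IRI.
#' @return An `rdf_graph`.
#' @export
rdf_graph <- function(s = character(0), p = character(0), o = character(0),
                      bindings = default_bindings()) {
  stopifnot(length(s) == length(p), length(p) == length(o))
  df <- data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(triples = df, bindings = bindings), class = "rdf_graph")
}

#' Number of triples in a graph
#' @param graph An `rdf_graph`.
#' @export
triple_count <- function(graph) nrow(graph$triples)

#' Union of triple graphs (set semantics)
#' @param ... `rdf_graph` objects.
#' @export
graph_union <- function(...) {
  gs <- list(...)
  df <- do.call(rbind, lapply(gs, function(g) g$triples))
  b <- do.call(c, lapply(gs, function(g) g$bindings))
  b <- b[!duplicated(names(b))]
  rdf_graph(df$s, df$p, df$o, bindings = b)
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("RDF graph:", nrow(x$triples), "triples,",
      length(x$bindings), "prefix bindings\n")
  invisible(x)
}

# canonical triple lines, C-locale sorted
.canonical_lines <- function(graph) {
  if (!nrow(graph$triples)) return(character(0))
  lines <- paste(graph$triples$s, graph$triples$p, graph$triples$o, ".")
  sort(lines, method = "radix")
}

# compact an <iri> term to prefix:local when the local part is a safe
# Turtle PN_LOCAL (no '/', no reserved chars); otherwise keep full form
.ttl_compact <- function(term, bindings) {
  out <- term
  is_iri <- startsWith(term, "<")
  iri <- substr(term[is_iri], 2L, nchar(term[is_iri]) - 1L)
  comp <- iri
  done <- rep(FALSE, length(iri))
  for (pfx in names(bindings)) {
    ns <- bindings[[pfx]]
    hit <- !done & startsWith(iri, ns)
    local <- substring(iri[hit], nchar(ns) + 1L)
    ok <- grepl("^[A-Za-z_][A-Za-z0-9_]*$", local)
    idx <- which(hit)[ok]
    comp[idx] <- paste0(pfx, ":", substring(iri[idx], nchar(ns) + 1L))
    done[idx] <- TRUE
  }
  out[is_iri][done] <- comp[done]
  # typed literals: compact the datatype IRI
  lit <- grepl("\\^\\^<", out)
  if (any(lit)) {
    for (pfx in names(bindings)) {
      ns <- bindings[[pfx]]
      out[lit] <- sub(paste0("\\^\\^<", ns, "([A-Za-z]+)>$"),
                      paste0("^^", pfx, ":\\1"), out[lit])
    }
  }
  out
}

#' Serialize a triple graph
#'
#' N-Triples output is canonical: one triple per line, lexicographically
#' sorted in the C locale, so serializing the same graph twice is
#' byte-identical. Turtle output carries the prefix block (including
#' `@prefix mc:`) and compacts IRIs to prefixed names where the local
#' part permits.
#'
#' @param graph An `rdf_graph`.
#' @param format `"ntriples"` or `"turtle"`.
#' @return Single character string (the document).
#' @export
serialize_graph <- function(graph, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  lines <- .canonical_lines(graph)
  if (format == "ntriples") {
    return(paste0(paste(lines, collapse = "\n"),
                  if (length(lines)) "\n" else ""))
  }
  b <- graph$bindings
  header <- paste0("@prefix ", names(b), ": <", unname(b), "> .")
  if (length(lines)) {
    parts <- .split_triple_lines(lines)
    body <- paste(.ttl_compact(parts$s, b), .ttl_compact(parts$p, b),
                  .ttl_compact(parts$o, b), ".")
  } else body <- character(0)
  paste0(paste(c(header, "", body), collapse = "\n"), "\n")
}

# split canonical "s p o ." lines back into term columns (vectorized;
# subjects and predicates never contain whitespace, literals may)
.split_triple_lines <- function(lines) {
  fail_at <- function(bad) {
    if (any(bad)) {
      i <- which(bad)[1]
      stop("parse error at line ", i, ": ", lines[i])
    }
  }
  sp1 <- regexpr("[ \t]", lines)
  fail_at(sp1 < 0)
  s <- substr(lines, 1L, sp1 - 1L)
  rest <- sub("^[ \t]+", "", substring(lines, sp1 + 1L))
  sp2 <- regexpr("[ \t]", rest)
  fail_at(sp2 < 0)
  p <- substr(rest, 1L, sp2 - 1L)
  o <- sub("^[ \t]+", "", substring(rest, sp2 + 1L))
  # strip the statement terminator
  term_ok <- grepl("[ \t]\\.[ \t]*$", o) | grepl("^[^\"]*\\.$", o)
  o <- sub("[ \t]*\\.[ \t]*$", "", o)
  nonlit <- "(<[^<>\"]*>|[A-Za-z][A-Za-z0-9_]*:[A-Za-z_][A-Za-z0-9_]*|a)"
  lit <- "\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^(?:<[^<>\"]*>|[A-Za-z]+:[A-Za-z]+))?"
  fail_at(!grepl(paste0("^", nonlit, "$"), s, perl = TRUE))
  fail_at(!grepl(paste0("^", nonlit, "$"), p, perl = TRUE))
  fail_at(!(grepl(paste0("^", nonlit, "$"), o, perl = TRUE) |
              grepl(paste0("^", lit, "$"), o, perl = TRUE)))
  list(s = s, p = p, o = o)
}

.expand_term <- function(term, bindings) {
  pn <- grepl("^[A-Za-z][A-Za-z0-9_]*:[A-Za-z_][A-Za-z0-9_]*$", term)
  if (any(pn)) {
    pfx <- sub(":.*$", "", term[pn])
    local <- sub("^[^:]*:", "", term[pn])
    ns <- bindings[pfx]
    if (anyNA(ns)) stop("undeclared prefix: ", unique(pfx[is.na(ns)])[1])
    term[pn] <- paste0("<", unname(ns), local, ">")
  }
  term[term == "a"] <- paste0("<", RDF_TYPE, ">")
  # expand prefixed datatype on literals
  lit <- grepl("\\^\\^[A-Za-z]+:[A-Za-z]+$", term)
  if (any(lit)) {
    dtp <- sub("^.*\\^\\^([A-Za-z]+):([A-Za-z]+)$", "\\1", term[lit])
    dtl <- sub("^.*\\^\\^([A-Za-z]+):([A-Za-z]+)$", "\\2", term[lit])
    ns <- bindings[dtp]
    if (anyNA(ns)) stop("undeclared prefix in datatype: ", unique(dtp[is.na(ns)])[1])
    term[lit] <- paste0(sub("\\^\\^[A-Za-z]+:[A-Za-z]+$", "", term[lit]),
                        "^^<", unname(ns), dtl, ">")
  }
  term
}

#' Parse an RDF document into a triple graph
#'
#' Accepts the line-oriented subset this package writes: N-Triples, or
#' Turtle restricted to `@prefix` declarations plus one triple per line.
#'
#' @param text Document text.
#' @param format `"ntriples"` or `"turtle"`.
#' @return An `rdf_graph`.
#' @export
parse_graph <- function(text, format = c("ntriples", "turtle")) {
  format <- match.arg(format)
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bindings <- if (format == "turtle") c() else default_bindings()
  is_pfx <- startsWith(lines, "@prefix")
  for (ln in lines[is_pfx]) {
    m <- regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_]*):\\s*<([^>]*)>\\s*\\.$", ln)
    g <- regmatches(ln, m)[[1]]
    if (!length(g)) stop("parse error: bad @prefix line: ", ln)
    bindings[g[2]] <- g[3]
  }
  body <- lines[!is_pfx]
  if (!length(body)) return(rdf_graph(bindings = if (length(bindings)) bindings else default_bindings()))
  parts <- tryCatch(.split_triple_lines(body), error = function(e) stop(conditionMessage(e)))
  if (!length(bindings)) bindings <- default_bindings()
  rdf_graph(.expand_term(parts$s, bindings),
            .expand_term(parts$p, bindings),
            .expand_term(parts$o, bindings),
            bindings = bindings)
}

#' Write a graph to a file
#' @param graph An `rdf_graph`.
#' @param path Output path; format inferred from extension (`.nt`, `.ttl`)
#'   unless given.
#' @param format Optional explicit format.
#' @export
write_graph <- function(graph, path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     nt = "ntriples", ttl = "turtle",
                     stop("cannot infer RDF format from extension: ", path))
  }
  cat(serialize_graph(graph, format), file = path)
  invisible(path)
}

#' Read a graph from a file
#' @param path Input path (`.nt` or `.ttl`).
#' @param format Optional explicit format.
#' @export
read_graph <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     nt = "ntriples", ttl = "turtle",
                     stop("cannot infer RDF format from extension: ", path))
  }
  parse_graph(paste(readLines(path, warn = FALSE), collapse = "\n"), format)
}
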