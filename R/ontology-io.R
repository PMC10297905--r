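# Ontology serialization. Two formats: Turtle (.ttl) and RDF/XML (.owl).
# Union-of-classes domains are emitted as owl:unionOf constructs. The
# catalogue annotations that the mapper needs (source tables, literal
# types, source columns) travel as annotation properties under the base
# IRI so that serialize -> parse is lossless.

.xsd_range_for <- function(literal_type) {
  switch(literal_type,
         integer = "integer", decimal = "decimal", datetime = "dateTime",
         "string")
}

.literal_type_from_range <- function(xsd_local, annotated) {
  if (nzchar(annotated)) annotated
  else switch(xsd_local, integer = "integer", decimal = "decimal",
              dateTime = "datetime", "string")
}

#' Serialize an ontology schema
#'
#' Deterministic output: classes, then object properties, then datatype
#' properties, each block sorted by name, with a fixed predicate order.
#' The prefix block binds `mc` to the schema base IRI.
#'
#' @param schema An `ehr_schema`; must pass [validate_schema()].
#' @param format `"turtle"` or `"rdfxml"`.
#' @return Document text.
#' @export
serialize_ontology <- function(schema, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  issues <- validate_schema(schema)
  if (nrow(issues))
    stop("schema fails validation (", nrow(issues), " issue(s)); first: ",
         issues$code[1], " on ", issues$subject[1])
  if (format == "turtle") .ontology_to_turtle(schema)
  else .ontology_to_rdfxml(schema)
}

.ontology_to_turtle <- function(schema) {
  b <- schema$base_iri
  q <- function(x) paste0("\"", .nt_escape(x), "\"")
  cls_ref <- function(name) {
    ifelse(name == ROOT_MARKER, "owl:Thing", paste0("mc:", name))
  }
  domain_ttl <- function(domains) {
    doms <- split_set(domains)
    if (length(doms) == 1L) cls_ref(doms)
    else paste0("[ a owl:Class ; owl:unionOf ( ",
                paste(cls_ref(doms), collapse = " "), " ) ]")
  }
  out <- c(
    paste0("@prefix mc: <", b, "> ."),
    paste0("@prefix owl: <", OWL_NS, "> ."),
    paste0("@prefix rdf: <", RDF_NS, "> ."),
    paste0("@prefix rdfs: <", RDFS_NS, "> ."),
    paste0("@prefix xsd: <", XSD_NS, "> ."),
    "",
    paste0("<", b, "> a owl:Ontology ."),
    "")
  cl <- schema$classes[order(schema$classes$name), ]
  for (i in seq_len(nrow(cl))) {
    stmt <- c(paste0("mc:", cl$name[i], " a owl:Class"),
              paste0("    rdfs:subClassOf ", cls_ref(cl$parent[i])),
              paste0("    rdfs:comment ", q(cl$description[i])))
    for (tb in split_set(cl$source_tables[i]))
      stmt <- c(stmt, paste0("    mc:sourceTable ", q(tb)))
    out <- c(out, paste0(paste(stmt, collapse = " ;\n"), " ."), "")
  }
  op <- schema$object_properties[order(schema$object_properties$name), ]
  for (i in seq_len(nrow(op))) {
    stmt <- c(paste0("mc:", op$name[i], " a owl:ObjectProperty"),
              paste0("    rdfs:domain ", domain_ttl(op$domains[i])),
              paste0("    rdfs:range mc:", op$range[i]),
              paste0("    mc:sourceTable ", q(op$source_table[i])))
    out <- c(out, paste0(paste(stmt, collapse = " ;\n"), " ."), "")
  }
  dp <- schema$datatype_properties[order(schema$datatype_properties$name), ]
  for (i in seq_len(nrow(dp))) {
    stmt <- c(paste0("mc:", dp$name[i], " a owl:DatatypeProperty"),
              paste0("    rdfs:domain ", domain_ttl(dp$domains[i])),
              paste0("    rdfs:range xsd:", .xsd_range_for(dp$literal_type[i])),
              paste0("    mc:literalType ", q(dp$literal_type[i])))
    for (src in split_set(dp$sources[i]))
      stmt <- c(stmt, paste0("    mc:sourceColumn ", q(src)))
    out <- c(out, paste0(paste(stmt, collapse = " ;\n"), " ."), "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

.xml_q <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.ontology_to_rdfxml <- function(schema) {
  b <- schema$base_iri
  ref <- function(name) {
    ifelse(name == ROOT_MARKER, paste0(OWL_NS, "Thing"), paste0(b, name))
  }
  domain_xml <- function(domains, indent) {
    doms <- split_set(domains)
    pad <- strrep(" ", indent)
    if (length(doms) == 1L)
      return(paste0(pad, "<rdfs:domain rdf:resource=\"", .xml_q(ref(doms)), "\"/>"))
    c(paste0(pad, "<rdfs:domain>"),
      paste0(pad, "  <owl:Class>"),
      paste0(pad, "    <owl:unionOf rdf:parseType=\"Collection\">"),
      paste0(pad, "      <owl:Class rdf:about=\"", .xml_q(ref(doms)), "\"/>"),
      paste0(pad, "    </owl:unionOf>"),
      paste0(pad, "  </owl:Class>"),
      paste0(pad, "</rdfs:domain>"))
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"", RDF_NS, "\""),
    paste0("         xmlns:rdfs=\"", RDFS_NS, "\""),
    paste0("         xmlns:owl=\"", OWL_NS, "\""),
    paste0("         xmlns:xsd=\"", XSD_NS, "\""),
    paste0("         xmlns:mc=\"", b, "\">"),
    paste0("  <owl:Ontology rdf:about=\"", b, "\"/>"))
  cl <- schema$classes[order(schema$classes$name), ]
  for (i in seq_len(nrow(cl))) {
    lines <- c(lines,
      paste0("  <owl:Class rdf:about=\"", .xml_q(paste0(b, cl$name[i])), "\">"),
      paste0("    <rdfs:subClassOf rdf:resource=\"", .xml_q(ref(cl$parent[i])), "\"/>"),
      paste0("    <rdfs:comment>", .xml_q(cl$description[i]), "</rdfs:comment>"),
      vapply(split_set(cl$source_tables[i]), function(tb)
        paste0("    <mc:sourceTable>", .xml_q(tb), "</mc:sourceTable>"), ""),
      "  </owl:Class>")
  }
  op <- schema$object_properties[order(schema$object_properties$name), ]
  for (i in seq_len(nrow(op))) {
    lines <- c(lines,
      paste0("  <owl:ObjectProperty rdf:about=\"", .xml_q(paste0(b, op$name[i])), "\">"),
      domain_xml(op$domains[i], 4L),
      paste0("    <rdfs:range rdf:resource=\"", .xml_q(paste0(b, op$range[i])), "\"/>"),
      paste0("    <mc:sourceTable>", .xml_q(op$source_table[i]), "</mc:sourceTable>"),
      "  </owl:ObjectProperty>")
  }
  dp <- schema$datatype_properties[order(schema$datatype_properties$name), ]
  for (i in seq_len(nrow(dp))) {
    lines <- c(lines,
      paste0("  <owl:DatatypeProperty rdf:about=\"", .xml_q(paste0(b, dp$name[i])), "\">"),
      domain_xml(dp$domains[i], 4L),
      paste0("    <rdfs:range rdf:resource=\"", XSD_NS,
             .xsd_range_for(dp$literal_type[i]), "\"/>"),
      paste0("    <mc:literalType>", .xml_q(dp$literal_type[i]), "</mc:literalType>"),
      vapply(split_set(dp$sources[i]), function(src)
        paste0("    <mc:sourceColumn>", .xml_q(src), "</mc:sourceColumn>"), ""),
      "  </owl:DatatypeProperty>")
  }
  paste0(paste(c(lines, "</rdf:RDF>"), collapse = "\n"), "\n")
}

#' Parse an ontology document
#'
#' Inverse of [serialize_ontology()] on its image. Structural issues in
#' the parsed schema (e.g. a property referencing an undeclared class)
#' are attached as the `"issues"` attribute rather than raised, so a
#' damaged but syntactically well-formed document can be inspected.
#'
#' @param text Document text.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return An `ehr_schema`; `attr(, "issues")` holds the validation
#'   report.
#' @export
parse_ontology <- function(text, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  schema <- if (format == "turtle") .ontology_from_turtle(text)
            else .ontology_from_rdfxml(text)
  attr(schema, "issues") <- validate_schema(schema)
  schema
}

# collect "subject pred obj ; pred obj ... ." statements (our writer never
# splits a bracketed object across lines)
.ttl_statements <- function(lines) {
  stmts <- list()
  buf <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "@prefix")) next
    buf <- c(buf, ln)
    if (grepl("\\.$", ln)) {
      stmts[[length(stmts) + 1L]] <- paste(buf, collapse = " ")
      buf <- character(0)
    }
  }
  if (length(buf)) stop("parse error: truncated statement: ", buf[1])
  stmts
}

.ontology_from_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pfx <- grep("^@prefix", trimws(lines), value = TRUE)
  bindings <- c()
  for (ln in pfx) {
    g <- regmatches(ln, regexec(
      "^@prefix\\s+([A-Za-z][A-Za-z0-9_]*):\\s*<([^>]*)>\\s*\\.$", trimws(ln)))[[1]]
    if (!length(g)) stop("parse error: bad @prefix line")
    bindings[g[2]] <- g[3]
  }
  if (!"mc" %in% names(bindings)) stop("parse error: no mc prefix binding")
  base <- unname(bindings["mc"])
  unq <- function(x) .nt_unescape(sub("^\"(.*)\"$", "\\1", x))
  cls_name <- function(ref) {
    if (ref == "owl:Thing") ROOT_MARKER else sub("^mc:", "", ref)
  }
  parse_domain <- function(obj) {
    if (grepl("owl:unionOf", obj)) {
      inner <- sub("^.*\\(\\s*(.*?)\\s*\\).*$", "\\1", obj)
      paste(vapply(strsplit(inner, "\\s+")[[1]], cls_name, ""), collapse = ";")
    } else cls_name(obj)
  }
  classes <- list(); oprops <- list(); dprops <- list()
  # split on ';' only outside brackets/parens/strings
  split_po <- function(stmt) {
    chars <- strsplit(stmt, "")[[1]]
    depth <- 0L; inq <- FALSE
    cut <- integer(0)
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "\"" && (i == 1 || chars[i - 1] != "\\")) inq <- !inq
      if (!inq) {
        if (ch %in% c("[", "(")) depth <- depth + 1L
        else if (ch %in% c("]", ")")) depth <- depth - 1L
        else if (ch == ";" && depth == 0L) cut <- c(cut, i)
      }
    }
    starts <- c(1L, cut + 1L)
    ends <- c(cut - 1L, length(chars))
    trimws(substring(stmt, starts, ends))
  }
  for (stmt in .ttl_statements(lines)) {
    stmt <- sub("\\s*\\.$", "", stmt)
    parts <- split_po(stmt)
    head <- parts[1]
    hg <- regmatches(head, regexec("^(\\S+)\\s+a\\s+(\\S+)$", head))[[1]]
    if (!length(hg)) {
      # e.g. "<base> a owl:Ontology" handled by the same regex; anything
      # else is unexpected
      stop("parse error: bad statement head: ", head)
    }
    subj <- hg[2]; kind <- hg[3]
    if (kind == "owl:Ontology") next
    name <- sub("^mc:", "", subj)
    po <- lapply(parts[-1], function(p) {
      g <- regmatches(p, regexec("^(\\S+)\\s+(.*)$", p))[[1]]
      c(g[2], g[3])
    })
    preds <- vapply(po, `[`, "", 1L)
    objs <- vapply(po, `[`, "", 2L)
    get1 <- function(p) { i <- match(p, preds); if (is.na(i)) "" else objs[i] }
    getall <- function(p) objs[preds == p]
    if (kind == "owl:Class") {
      classes[[length(classes) + 1L]] <- data.frame(
        name = name,
        parent = cls_name(get1("rdfs:subClassOf")),
        description = unq(get1("rdfs:comment")),
        source_tables = paste(vapply(getall("mc:sourceTable"), unq, ""),
                              collapse = ";"),
        stringsAsFactors = FALSE)
    } else if (kind == "owl:ObjectProperty") {
      oprops[[length(oprops) + 1L]] <- data.frame(
        name = name,
        domains = parse_domain(get1("rdfs:domain")),
        range = cls_name(get1("rdfs:range")),
        source_table = unq(get1("mc:sourceTable")),
        stringsAsFactors = FALSE)
    } else if (kind == "owl:DatatypeProperty") {
      xsd_local <- sub("^xsd:", "", get1("rdfs:range"))
      dprops[[length(dprops) + 1L]] <- data.frame(
        name = name,
        domains = parse_domain(get1("rdfs:domain")),
        literal_type = .literal_type_from_range(xsd_local, unq(get1("mc:literalType"))),
        sources = paste(vapply(getall("mc:sourceColumn"), unq, ""),
                        collapse = ";"),
        stringsAsFactors = FALSE)
    } else stop("parse error: unknown declaration kind ", kind)
  }
  .assemble_schema(classes, oprops, dprops, base)
}

.ontology_from_rdfxml <- function(text) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(text)),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
  ns <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS)
  onto <- xml2::xml_find_first(doc, "/rdf:RDF/owl:Ontology", ns)
  if (inherits(onto, "xml_missing")) stop("parse error: no owl:Ontology node")
  base <- xml2::xml_attr(onto, "about")
  local <- function(iri) {
    if (identical(iri, paste0(OWL_NS, "Thing"))) ROOT_MARKER
    else sub(paste0("^", base), "", iri, fixed = FALSE)
  }
  node_domain <- function(node) {
    doms <- xml2::xml_find_all(node, "./rdfs:domain", ns)
    res <- xml2::xml_attr(doms, "resource", ns = character(0))
    if (length(doms) && !is.na(res[1]) && nzchar(res[1])) return(local(res[1]))
    members <- xml2::xml_find_all(
      node, "./rdfs:domain/owl:Class/owl:unionOf/owl:Class", ns)
    paste(vapply(xml2::xml_attr(members, "about"), local, ""), collapse = ";")
  }
  txt_all <- function(node, tag) {
    kids <- xml2::xml_find_all(node, paste0("./*[local-name()='", tag, "']"))
    vapply(kids, xml2::xml_text, "")
  }
  txt1 <- function(node, tag) {
    v <- txt_all(node, tag); if (length(v)) v[1] else ""
  }
  res1 <- function(node, xp) {
    n <- xml2::xml_find_first(node, xp, ns)
    if (inherits(n, "xml_missing")) "" else xml2::xml_attr(n, "resource")
  }
  classes <- lapply(xml2::xml_find_all(doc, "/rdf:RDF/owl:Class", ns), function(n) {
    data.frame(
      name = local(xml2::xml_attr(n, "about")),
      parent = local(res1(n, "./rdfs:subClassOf")),
      description = txt1(n, "comment"),
      source_tables = paste(txt_all(n, "sourceTable"), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  oprops <- lapply(xml2::xml_find_all(doc, "/rdf:RDF/owl:ObjectProperty", ns), function(n) {
    data.frame(
      name = local(xml2::xml_attr(n, "about")),
      domains = node_domain(n),
      range = local(res1(n, "./rdfs:range")),
      source_table = txt1(n, "sourceTable"),
      stringsAsFactors = FALSE)
  })
  dprops <- lapply(xml2::xml_find_all(doc, "/rdf:RDF/owl:DatatypeProperty", ns), function(n) {
    xsd_local <- sub(paste0("^", XSD_NS), "", res1(n, "./rdfs:range"))
    data.frame(
      name = local(xml2::xml_attr(n, "about")),
      domains = node_domain(n),
      literal_type = .literal_type_from_range(xsd_local, txt1(n, "literalType")),
      sources = paste(txt_all(n, "sourceColumn"), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  .assemble_schema(classes, oprops, dprops, base)
}

.assemble_schema <- function(classes, oprops, dprops, base) {
  bind_sorted <- function(rows) {
    if (!length(rows)) return(NULL)
    df <- do.call(rbind, rows)
    df <- df[order(df$name), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  structure(list(
    classes = bind_sorted(classes),
    object_properties = bind_sorted(oprops),
    datatype_properties = bind_sorted(dprops),
    base_iri = base,
    prefix = "mc"), class = "ehr_schema")
}

#' Compare two schemas up to row order
#'
#' @param a,b `ehr_schema` objects.
#' @return `TRUE` when both declare the same classes, properties, base
#'   IRI and prefix (component rows compared after sorting by name).
#' @export
schema_equal <- function(a, b) {
  canon <- function(df) {
    df <- df[order(df$name), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  isTRUE(all.equal(canon(a$classes), canon(b$classes))) &&
    isTRUE(all.equal(canon(a$object_properties), canon(b$object_properties))) &&
    isTRUE(all.equal(canon(a$datatype_properties), canon(b$datatype_properties))) &&
    identical(a$base_iri, b$base_iri) &&
    identical(a$prefix, b$prefix)
}
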