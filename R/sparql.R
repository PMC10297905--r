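# SPARQL-subset evaluator over an in-memory triple graph.
#
# Supported: PREFIX declarations, SELECT [DISTINCT] with variables or
# (COUNT([DISTINCT] ?x|*) AS ?v), basic graph patterns with ';' and ','
# abbreviations, FILTER with comparisons, !/&&/||, STR, STRSTARTS and
# REGEX, GROUP BY / HAVING / ORDER BY / LIMIT. Solution semantics follow
# the standard for this subset; unsupported constructs raise an error
# naming the construct.

# ---------------------------------------------------------------------------
# Tokenizer

.SPARQL_TOKEN_RE <- paste0(
  "(\"(?:[^\"\\\\]|\\\\.)*\")",                          # 1 string
  "|(<[^<>\\s]*>)",                                        # 2 iriref
  "|(\\?[A-Za-z_][A-Za-z0-9_]*)",                          # 3 var
  "|((?:[A-Za-z][A-Za-z0-9_.-]*)?:[A-Za-z0-9_][A-Za-z0-9_.-]*",  # 4 pname
  "|(?:[A-Za-z][A-Za-z0-9_.-]*)?:)",                             #   or ns-only
  "|([+-]?[0-9]+(?:\\.[0-9]+)?)",                          # 5 number
  "|([A-Za-z][A-Za-z0-9_]*)",                              # 6 name/keyword
  "|(\\^\\^|&&|\\|\\||!=|<=|>=|=|<|>|!|[{}().,;*])"        # 7 operator
)

sparql_tokens <- function(text) {
  # normalise typographic quotes, strip comments outside strings
  text <- gsub("“|”", "\"", text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- vapply(lines, function(ln) {
    # cut at the first # that is not inside a string literal
    chars <- strsplit(ln, "")[[1]]
    inq <- FALSE
    for (i in seq_along(chars)) {
      if (chars[i] == "\"" && (i == 1 || chars[i - 1] != "\\")) inq <- !inq
      if (chars[i] == "#" && !inq) return(substr(ln, 1, i - 1))
    }
    ln
  }, "", USE.NAMES = FALSE)
  text <- paste(lines, collapse = "\n")
  m <- gregexpr(.SPARQL_TOKEN_RE, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(type = character(0), text = character(0)))
  toks <- regmatches(text, gregexpr(.SPARQL_TOKEN_RE, text, perl = TRUE))[[1]]
  # verify no stray characters between tokens
  covered <- sum(attr(m, "match.length"))
  residue <- gsub("\\s", "", text)
  if (nchar(gsub("\\s", "", paste(toks, collapse = ""))) != nchar(residue))
    stop("SPARQL syntax error: unrecognised characters in query")
  type <- vapply(toks, function(tk) {
    if (startsWith(tk, "\"")) "string"
    else if (startsWith(tk, "<") && endsWith(tk, ">") && nchar(tk) > 1 &&
             !tk %in% c("<=", ">=")) "iriref"
    else if (startsWith(tk, "?")) "var"
    else if (grepl("^(?:[A-Za-z][A-Za-z0-9_.-]*)?:", tk)) "pname"
    else if (grepl("^[+-]?[0-9]", tk)) "number"
    else if (grepl("^[A-Za-z]", tk)) "name"
    else "op"
  }, "", USE.NAMES = FALSE)
  data.frame(type = type, text = toks, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Parser (cursor over the token table)

.new_cursor <- function(toks) new.env(parent = emptyenv()) |>
  (function(e) { e$toks <- toks; e$i <- 1L; e })()

.peek <- function(cur, k = 0L) {
  i <- cur$i + k
  if (i > nrow(cur$toks)) list(type = "eof", text = "")
  else list(type = cur$toks$type[i], text = cur$toks$text[i])
}
.advance <- function(cur) { cur$i <- cur$i + 1L; invisible(NULL) }
.expect <- function(cur, text) {
  tk <- .peek(cur)
  if (!identical(toupper(tk$text), toupper(text)))
    stop("SPARQL syntax error: expected '", text, "' but found '",
         tk$text, "'")
  .advance(cur)
}
.at_kw <- function(cur, kw) {
  tk <- .peek(cur)
  tk$type == "name" && toupper(tk$text) == kw
}

.pfx_key <- function(nm) if (nzchar(nm)) nm else "._default"

parse_sparql <- function(text, prefixes = c()) {
  toks <- sparql_tokens(text)
  cur <- .new_cursor(toks)
  # pre-bound prefixes; the default (:) prefix is stored under "._default"
  # because R cannot index a named vector by the empty string
  pfx <- c(mc = EHR_BASE_IRI, rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS,
           xsd = XSD_NS, ._default = EHR_BASE_IRI, prefixes)
  repeat {
    if (.at_kw(cur, "PREFIX")) {
      .advance(cur)
      tk <- .peek(cur)
      if (tk$type != "pname")
        stop("SPARQL syntax error: bad PREFIX declaration")
      nm <- .pfx_key(sub(":.*$", "", tk$text))
      .advance(cur)
      iri <- .peek(cur)
      if (iri$type != "iriref") stop("SPARQL syntax error: PREFIX needs an IRI")
      pfx[nm] <- substr(iri$text, 2, nchar(iri$text) - 1)
      .advance(cur)
    } else if (.at_kw(cur, "BASE")) {
      .advance(cur); .advance(cur)
    } else break
  }
  if (!.at_kw(cur, "SELECT"))
    stop("unsupported SPARQL form: only SELECT queries are supported")
  .advance(cur)
  distinct <- FALSE
  if (.at_kw(cur, "DISTINCT")) { distinct <- TRUE; .advance(cur) }
  if (.at_kw(cur, "REDUCED"))
    stop("unsupported SPARQL construct: REDUCED")
  proj <- list()
  star <- FALSE
  repeat {
    tk <- .peek(cur)
    if (tk$type == "var") {
      proj[[length(proj) + 1L]] <- list(kind = "var",
                                        name = substring(tk$text, 2))
      .advance(cur)
    } else if (tk$type == "op" && tk$text == "*") {
      star <- TRUE; .advance(cur)
    } else if (tk$type == "op" && tk$text == "(") {
      .advance(cur)
      agg <- .parse_expr(cur, pfx)
      .expect(cur, "AS")
      v <- .peek(cur)
      if (v$type != "var") stop("SPARQL syntax error: AS needs a variable")
      proj[[length(proj) + 1L]] <- list(kind = "agg", expr = agg,
                                        name = substring(v$text, 2))
      .advance(cur)
      .expect(cur, ")")
    } else break
  }
  if (.at_kw(cur, "WHERE")) .advance(cur)
  .expect(cur, "{")
  patterns <- list()
  filters <- list()
  repeat {
    tk <- .peek(cur)
    if (tk$type == "op" && tk$text == "}") { .advance(cur); break }
    if (tk$type == "eof") stop("SPARQL syntax error: unterminated group pattern")
    if (.at_kw(cur, "FILTER")) {
      .advance(cur)
      filters[[length(filters) + 1L]] <- .parse_filter(cur, pfx)
      tk <- .peek(cur)
      if (tk$type == "op" && tk$text == ".") .advance(cur)
      next
    }
    if (tk$type == "name" &&
        toupper(tk$text) %in% c("OPTIONAL", "UNION", "MINUS", "GRAPH",
                                "SERVICE", "BIND", "VALUES"))
      stop("unsupported SPARQL construct: ", toupper(tk$text))
    patterns <- c(patterns, .parse_triples_same_subject(cur, pfx))
    tk <- .peek(cur)
    if (tk$type == "op" && tk$text == ".") .advance(cur)
  }
  group_by <- character(0)
  having <- NULL
  order_by <- NULL
  limit <- NULL
  repeat {
    if (.at_kw(cur, "GROUP")) {
      .advance(cur); .expect(cur, "BY")
      repeat {
        tk <- .peek(cur)
        if (tk$type != "var") break
        group_by <- c(group_by, substring(tk$text, 2))
        .advance(cur)
      }
    } else if (.at_kw(cur, "HAVING")) {
      .advance(cur)
      having <- .parse_filter(cur, pfx)
    } else if (.at_kw(cur, "ORDER")) {
      .advance(cur); .expect(cur, "BY")
      dir <- "asc"
      if (.at_kw(cur, "ASC") || .at_kw(cur, "DESC")) {
        dir <- tolower(.peek(cur)$text); .advance(cur)
        .expect(cur, "(")
        tk <- .peek(cur); .advance(cur); .expect(cur, ")")
        order_by <- list(var = substring(tk$text, 2), dir = dir)
      } else {
        tk <- .peek(cur)
        if (tk$type != "var") stop("SPARQL syntax error: ORDER BY needs a variable")
        .advance(cur)
        order_by <- list(var = substring(tk$text, 2), dir = dir)
      }
    } else if (.at_kw(cur, "LIMIT")) {
      .advance(cur)
      limit <- as.integer(.peek(cur)$text)
      .advance(cur)
    } else break
  }
  if (.peek(cur)$type != "eof")
    stop("SPARQL syntax error: trailing tokens from '", .peek(cur)$text, "'")
  list(projection = proj, star = star, distinct = distinct,
       patterns = patterns, filters = filters, group_by = group_by,
       having = having, order_by = order_by, limit = limit)
}

.term_from_token <- function(cur, pfx) {
  tk <- .peek(cur)
  if (tk$type == "var") {
    .advance(cur)
    return(list(kind = "var", name = substring(tk$text, 2)))
  }
  if (tk$type == "iriref") {
    .advance(cur)
    return(list(kind = "const", term = tk$text))
  }
  if (tk$type == "pname") {
    .advance(cur)
    nm <- sub(":.*$", "", tk$text)
    local <- sub("^[^:]*:", "", tk$text)
    ns <- pfx[.pfx_key(nm)]
    if (is.na(ns)) stop("SPARQL error: undeclared prefix '", nm, ":'")
    return(list(kind = "const", term = paste0("<", unname(ns), local, ">")))
  }
  if (tk$type == "name" && tk$text == "a") {
    .advance(cur)
    return(list(kind = "const", term = paste0("<", RDF_TYPE, ">")))
  }
  if (tk$type == "string") {
    .advance(cur)
    lex <- .nt_unescape(substr(tk$text, 2, nchar(tk$text) - 1))
    dt <- NULL
    nxt <- .peek(cur)
    if (nxt$type == "op" && nxt$text == "^^") {
      .advance(cur)
      dtk <- .peek(cur)
      if (dtk$type == "iriref") dt <- substr(dtk$text, 2, nchar(dtk$text) - 1)
      else if (dtk$type == "pname") {
        nm <- sub(":.*$", "", dtk$text)
        dt <- paste0(unname(pfx[nm]), sub("^[^:]*:", "", dtk$text))
      } else stop("SPARQL syntax error: bad datatype")
      .advance(cur)
    }
    term <- paste0("\"", .nt_escape(lex), "\"",
                   if (!is.null(dt) && dt != paste0(XSD_NS, "string"))
                     paste0("^^<", dt, ">") else "")
    return(list(kind = "const", term = term))
  }
  if (tk$type == "number") {
    .advance(cur)
    dt <- if (grepl("\\.", tk$text)) XSD_DECIMAL else XSD_INTEGER
    return(list(kind = "const", term = paste0("\"", tk$text, "\"^^<", dt, ">"),
                numeric = as.numeric(tk$text)))
  }
  stop("SPARQL syntax error: unexpected token '", tk$text, "'")
}

# subject (verb objectList (';' verb objectList)*)
.parse_triples_same_subject <- function(cur, pfx) {
  subj <- .term_from_token(cur, pfx)
  out <- list()
  repeat {
    verb <- .term_from_token(cur, pfx)
    repeat {
      obj <- .term_from_token(cur, pfx)
      out[[length(out) + 1L]] <- list(s = subj, p = verb, o = obj)
      tk <- .peek(cur)
      if (tk$type == "op" && tk$text == ",") { .advance(cur); next }
      break
    }
    tk <- .peek(cur)
    if (tk$type == "op" && tk$text == ";") {
      .advance(cur)
      nxt <- .peek(cur)
      if (nxt$type == "op" && nxt$text %in% c(".", "}")) break
      next
    }
    break
  }
  out
}

.parse_filter <- function(cur, pfx) {
  tk <- .peek(cur)
  if (tk$type == "op" && tk$text == "(") {
    .advance(cur)
    e <- .parse_expr(cur, pfx)
    .expect(cur, ")")
    e
  } else .parse_expr(cur, pfx)
}

.parse_expr <- function(cur, pfx) {
  e <- .parse_and(cur, pfx)
  repeat {
    tk <- .peek(cur)
    if (tk$type == "op" && tk$text == "||") {
      .advance(cur)
      e <- list(kind = "or", lhs = e, rhs = .parse_and(cur, pfx))
    } else return(e)
  }
}

.parse_and <- function(cur, pfx) {
  e <- .parse_rel(cur, pfx)
  repeat {
    tk <- .peek(cur)
    if (tk$type == "op" && tk$text == "&&") {
      .advance(cur)
      e <- list(kind = "and", lhs = e, rhs = .parse_rel(cur, pfx))
    } else return(e)
  }
}

.parse_rel <- function(cur, pfx) {
  e <- .parse_unary(cur, pfx)
  tk <- .peek(cur)
  if (tk$type == "op" && tk$text %in% c("=", "!=", "<", ">", "<=", ">=")) {
    .advance(cur)
    return(list(kind = "cmp", op = tk$text, lhs = e,
                rhs = .parse_unary(cur, pfx)))
  }
  e
}

.parse_unary <- function(cur, pfx) {
  tk <- .peek(cur)
  if (tk$type == "op" && tk$text == "!") {
    .advance(cur)
    return(list(kind = "not", arg = .parse_unary(cur, pfx)))
  }
  if (tk$type == "op" && tk$text == "(") {
    .advance(cur)
    e <- .parse_expr(cur, pfx)
    .expect(cur, ")")
    return(e)
  }
  if (tk$type == "name") {
    kw <- toupper(tk$text)
    if (kw %in% c("STRSTARTS", "STR", "REGEX", "COUNT")) {
      .advance(cur)
      .expect(cur, "(")
      distinct <- FALSE
      args <- list()
      if (kw == "COUNT") {
        if (.at_kw(cur, "DISTINCT")) { distinct <- TRUE; .advance(cur) }
        tk2 <- .peek(cur)
        if (tk2$type == "op" && tk2$text == "*") {
          args <- list(list(kind = "star"))
          .advance(cur)
        } else args <- list(.parse_expr(cur, pfx))
      } else {
        repeat {
          args[[length(args) + 1L]] <- .parse_expr(cur, pfx)
          tk2 <- .peek(cur)
          if (tk2$type == "op" && tk2$text == ",") { .advance(cur); next }
          break
        }
      }
      .expect(cur, ")")
      return(list(kind = "call", fn = kw, args = args, distinct = distinct))
    }
    if (kw %in% c("BOUND", "EXISTS", "NOT", "IF", "COALESCE", "SUM", "AVG",
                  "MIN", "MAX", "SAMPLE", "LANG", "DATATYPE"))
      stop("unsupported SPARQL construct: ", kw)
  }
  .term_from_token(cur, pfx)
}

# ---------------------------------------------------------------------------
# Evaluation

# natural (comparison) value of a column of encoded terms
.term_natural <- function(x) {
  lit <- !is.na(x) & startsWith(x, "\"")
  lex <- x
  # strip datatype then quotes
  lex[lit] <- sub("\\^\\^<[^>]*>$", "", x[lit])
  lex[lit] <- .nt_unescape(substr(lex[lit], 2, nchar(lex[lit]) - 1))
  iri <- !is.na(x) & startsWith(x, "<")
  lex[iri] <- substr(x[iri], 2, nchar(x[iri]) - 1)
  numeric_dt <- grepl("\\^\\^<[^>]*(integer|decimal|double)>$", x)
  if (any(lit) && all(numeric_dt[lit])) {
    out <- rep(NA_real_, length(x))
    out[lit] <- as.numeric(lex[lit])
    if (!any(iri)) return(out)
  }
  lex
}

.eval_expr <- function(ast, df, agg_fun = NULL) {
  n <- nrow(df)
  rec <- function(a) {
    switch(a$kind,
      var = {
        if (!a$name %in% names(df))
          stop("SPARQL error: unbound variable ?", a$name, " in expression")
        df[[a$name]]
      },
      const = if (!is.null(a$numeric)) rep(a$numeric, n)
              else rep(a$term, n),
      and = rec(a$lhs) & rec(a$rhs),
      or = rec(a$lhs) | rec(a$rhs),
      not = !rec(a$arg),
      cmp = {
        l <- .coerce_operand(rec(a$lhs))
        r <- .coerce_operand(rec(a$rhs))
        if (is.numeric(l) || is.numeric(r)) {
          l <- suppressWarnings(as.numeric(.as_lexical(l)))
          r <- suppressWarnings(as.numeric(.as_lexical(r)))
        } else { l <- .as_lexical(l); r <- .as_lexical(r) }
        switch(a$op, "=" = l == r, "!=" = l != r, "<" = l < r,
               ">" = l > r, "<=" = l <= r, ">=" = l >= r)
      },
      call = {
        if (a$fn == "COUNT") {
          if (is.null(agg_fun))
            stop("SPARQL error: COUNT outside an aggregate context")
          agg_fun(a)
        } else if (a$fn == "STR") {
          .as_lexical(rec(a$args[[1]]))
        } else if (a$fn == "STRSTARTS") {
          startsWith(.as_lexical(rec(a$args[[1]])),
                     .as_lexical(rec(a$args[[2]])))
        } else if (a$fn == "REGEX") {
          pat <- .as_lexical(rec(a$args[[2]]))[1]
          flags <- if (length(a$args) >= 3)
            .as_lexical(rec(a$args[[3]]))[1] else ""
          grepl(pat, .as_lexical(rec(a$args[[1]])),
                ignore.case = grepl("i", flags), perl = TRUE)
        } else stop("unsupported function: ", a$fn)
      },
      stop("unsupported expression node: ", a$kind))
  }
  rec(ast)
}

# lexical/IRI text for STR() and string comparisons
.as_lexical <- function(x) {
  if (is.numeric(x)) return(x)
  enc <- grepl("^[\"<]", x)
  out <- x
  if (any(enc)) out[enc] <- .term_natural(x[enc])
  out
}

.coerce_operand <- function(x) {
  if (is.numeric(x) || is.logical(x)) return(x)
  nat <- .term_natural(ifelse(grepl("^[\"<]", x), x, paste0("\"", x, "\"")))
  nat
}

# match one triple pattern against the store; returns a solution df
.match_pattern <- function(tr, pat) {
  keep <- rep(TRUE, nrow(tr))
  for (pos in c("s", "p", "o")) {
    t <- pat[[pos]]
    if (t$kind == "const") keep <- keep & tr[[pos]] == t$term
  }
  sub <- tr[keep, , drop = FALSE]
  var_pos <- list()
  for (pos in c("s", "p", "o")) {
    t <- pat[[pos]]
    if (t$kind == "var") var_pos[[pos]] <- t$name
  }
  # repeated variable within one pattern: positions must agree
  vnames <- unlist(var_pos)
  if (anyDuplicated(vnames)) {
    for (v in unique(vnames[duplicated(vnames)])) {
      ps <- names(var_pos)[vnames == v]
      eq <- Reduce(`&`, lapply(ps[-1], function(p2) sub[[ps[1]]] == sub[[p2]]))
      sub <- sub[eq, , drop = FALSE]
    }
  }
  if (!length(var_pos)) {
    # fully ground pattern: acts as an existence test
    return(data.frame(row.names = seq_len(min(1L, nrow(sub)))))
  }
  cols <- list()
  for (pos in names(var_pos)) cols[[var_pos[[pos]]]] <- sub[[pos]]
  out <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

.join_solutions <- function(a, b) {
  # zero-column frames are existence tests: empty kills all solutions
  if (!ncol(a)) return(if (nrow(a)) b else b[0, , drop = FALSE])
  if (!ncol(b)) return(if (nrow(b)) a else a[0, , drop = FALSE])
  common <- intersect(names(a), names(b))
  if (length(common)) {
    merge(a, b, by = common, sort = FALSE)
  } else {
    merge(a, b, by = NULL)  # cross product
  }
}

#' Evaluate a SPARQL query over a triple graph
#'
#' @param graph An `rdf_graph` or `kg_handle` from [kg_load()].
#' @param sparql Query text. The `mc:` prefix (and `rdf:`, `rdfs:`,
#'   `owl:`, `xsd:`, plus a default `:` bound to the base IRI) are
#'   pre-declared.
#' @return An `ehr_result`: data frame of encoded term bindings, one
#'   column per projected variable, with attribute `variables`.
#' @examples
#' g <- rdf_graph(
#'   s = "<http://mimicIII.com/base/ICD_Diagnosis/1>",
#'   p = "<http://mimicIII.com/base/icd9_code>",
#'   o = "\"41401\"")
#' sparql_query(g, 'SELECT ?d WHERE { ?d mc:icd9_code "41401" }')
#' @export
sparql_query <- function(graph, sparql) {
  if (inherits(graph, "kg_handle")) graph <- graph$graph
  q <- parse_sparql(sparql)
  tr <- graph$triples

  # join order: most selective (fewest matches) first
  sols <- lapply(q$patterns, function(p) .match_pattern(tr, p))
  if (length(sols)) {
    ord <- order(vapply(sols, nrow, 1L))
    sol <- Reduce(.join_solutions, sols[ord])
  } else {
    sol <- data.frame()
  }
  if ("..exists.." %in% names(sol)) sol$..exists.. <- NULL

  for (f in q$filters) {
    if (!nrow(sol)) break
    keep <- .eval_expr(f, sol)
    keep[is.na(keep)] <- FALSE
    sol <- sol[keep, , drop = FALSE]
  }

  has_agg <- any(vapply(q$projection, function(p) p$kind == "agg", TRUE)) ||
    length(q$group_by) || !is.null(q$having)

  if (has_agg) {
    sol <- .aggregate_solutions(sol, q)
  } else {
    vars <- if (q$star) names(sol)
            else vapply(q$projection, function(p) p$name, "")
    missing <- setdiff(vars, names(sol))
    for (m in missing) sol[[m]] <- rep(NA_character_, nrow(sol))
    sol <- sol[, vars, drop = FALSE]
  }
  if (q$distinct && nrow(sol)) sol <- sol[!duplicated(sol), , drop = FALSE]
  if (!is.null(q$order_by) && nrow(sol)) {
    v <- .term_natural(as.character(sol[[q$order_by$var]]))
    o <- order(v, decreasing = q$order_by$dir == "desc", method = "radix")
    sol <- sol[o, , drop = FALSE]
  }
  if (!is.null(q$limit)) sol <- utils::head(sol, q$limit)
  rownames(sol) <- NULL
  structure(sol, variables = names(sol), class = c("ehr_result", "data.frame"))
}

.aggregate_solutions <- function(sol, q) {
  gb <- q$group_by
  agg_names <- vapply(q$projection, function(p)
    if (p$kind == "agg") p$name else p$name, "")
  if (!nrow(sol)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(agg_names)),
                                  agg_names), check.names = FALSE)
    # an ungrouped COUNT over an empty solution is 0
    if (!length(gb)) {
      vals <- lapply(q$projection, function(p)
        if (p$kind == "agg") "\"0\"^^<http://www.w3.org/2001/XMLSchema#integer>"
        else NA_character_)
      out <- as.data.frame(setNames(vals, agg_names), check.names = FALSE)
    }
    return(out)
  }
  key <- if (length(gb)) do.call(paste, c(sol[gb], sep = "\r")) else
    rep("all", nrow(sol))
  groups <- split(seq_len(nrow(sol)), key)
  make_agg_fun <- function(g) {
    function(a) {
      if (a$fn != "COUNT") stop("unsupported aggregate: ", a$fn)
      arg <- a$args[[1]]
      if (identical(arg$kind, "star")) {
        n <- length(g)
      } else {
        v <- sol[[arg$name]][g]
        v <- v[!is.na(v)]
        n <- if (a$distinct) length(unique(v)) else length(v)
      }
      n
    }
  }
  rows <- lapply(groups, function(g) {
    af <- make_agg_fun(g)
    vals <- lapply(q$projection, function(p) {
      if (p$kind == "agg") {
        n <- .eval_expr(p$expr, sol[g[1], , drop = FALSE], agg_fun = af)
        paste0("\"", format(n, scientific = FALSE), "\"^^<", XSD_INTEGER, ">")
      } else {
        if (length(gb) && !p$name %in% gb)
          stop("SPARQL error: projected variable ?", p$name,
               " is neither grouped nor aggregated")
        sol[[p$name]][g[1]]
      }
    })
    ok <- TRUE
    if (!is.null(q$having)) {
      af2 <- make_agg_fun(g)
      hv <- .eval_expr(q$having, sol[g[1], , drop = FALSE], agg_fun = af2)
      ok <- isTRUE(as.logical(hv[1]))
    }
    if (!ok) return(NULL)
    as.data.frame(setNames(vals, agg_names), check.names = FALSE,
                  stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(as.data.frame(setNames(rep(list(character(0)), length(agg_names)),
                                  agg_names), check.names = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decode an encoded result to display values
#'
#' IRIs become their IRI text, literals their lexical form.
#'
#' @param result An `ehr_result` (or any data frame of encoded terms).
#' @return Data frame of plain character (or numeric, for aggregate)
#'   columns.
#' @export
result_values <- function(result) {
  out <- as.data.frame(result, check.names = FALSE)
  for (j in seq_along(out)) {
    v <- .term_natural(as.character(out[[j]]))
    out[[j]] <- v
  }
  class(out) <- "data.frame"
  out
}

#' @export
print.ehr_result <- function(x, ...) {
  cat("SPARQL result:", nrow(x), "solution(s),",
      "variables:", paste(attr(x, "variables"), collapse = ", "), "\n")
  print(utils::head(result_values(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}
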