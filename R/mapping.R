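# CSV -> RDF mapping. Each core table has a recipe: the class its rows
# instantiate, the key columns that mint the subject IRI, per-column
# literal rules, and foreign-key link rules that attach the row to its
# patient/admission/ICU-stay context through the declared object
# properties. Union-domain properties emit one link per non-null context
# key (an admission-linked and an ICU-linked triple can coexist).

#' Construct a table mapping
#'
#' @param table Registry table name (e.g. `"ADMISSIONS"`).
#' @param subject_class Ontology class its rows instantiate.
#' @param subject_key_columns Columns minting the subject IRI.
#' @param column_rules Data frame with `column`, `property`,
#'   `literal_type`; one triple per non-absent value.
#' @param link_rules List of link rules, each a list with `direction`
#'   (`"in"`: context entity -> row subject, `"out"`: row subject ->
#'   target), `property` (object property name), `other_class`, and
#'   `key_columns` (columns of this table holding the other entity's
#'   key). A rule is applied per row only when all its key columns are
#'   non-null.
#' @param key_echo Emit the subject key columns as datatype-property
#'   literals too (default `TRUE`), so queries can filter on raw
#'   identifiers.
#' @param row_filter Optional predicate `function(df) logical` on raw
#'   rows.
#' @return An `ehr_table_mapping`.
#' @export
table_mapping <- function(table, subject_class, subject_key_columns,
                          column_rules, link_rules = list(),
                          key_echo = TRUE, row_filter = NULL) {
  stopifnot(length(subject_key_columns) >= 1L)
  structure(list(table = table, subject_class = subject_class,
                 subject_key_columns = subject_key_columns,
                 column_rules = column_rules, link_rules = link_rules,
                 key_echo = key_echo, row_filter = row_filter),
            class = "ehr_table_mapping")
}

.link <- function(direction, property, other_class, key_columns) {
  list(direction = direction, property = property,
       other_class = other_class, key_columns = key_columns)
}

#' Built-in mappings for the core tables
#'
#' One mapping per core table: every column becomes a datatype-property
#' literal (keys echoed by default), and foreign keys become object-
#' property links per the ontology's declared domains. For properties
#' with union domains the link is emitted from each context whose key is
#' present (e.g. a prescription with both `HADM_ID` and `ICUSTAY_ID`
#' links from the admission and from the ICU stay).
#'
#' @param schema An `ehr_schema` (defaults to the built-in schema).
#' @return Named list of `ehr_table_mapping` objects.
#' @export
default_mappings <- function(schema = build_mimic_schema()) {
  reg <- table_registry()
  cls <- table_class_map()
  links <- list(
    ADMISSIONS = list(.link("in", "HAS_ADMISSION", "Patient", "SUBJECT_ID")),
    ICUSTAYS = list(.link("in", "HAS_ICU_STAY", "Admission", "HADM_ID")),
    DIAGNOSES_ICD = list(.link("in", "HAS_DIAGNOSIS", "Admission", "HADM_ID")),
    PROCEDURES_ICD = list(.link("in", "HAS_PROCEDURE", "Admission", "HADM_ID")),
    PRESCRIPTIONS = list(
      .link("in", "HAS_MEDICATION", "Admission", "HADM_ID"),
      .link("in", "HAS_MEDICATION", "ICU_Stays", "ICUSTAY_ID")),
    LABEVENTS = list(
      .link("in", "HAS_LAB_EVENTS", "Patient", "SUBJECT_ID"),
      .link("in", "HAS_LAB_EVENTS", "Admission", "HADM_ID"),
      .link("out", "HAS_LAB_ITEM", "Lab_Item", "ITEMID")),
    TRANSFERS = list(
      .link("in", "HAS_TRANSFER", "Admission", "HADM_ID"),
      .link("in", "HAS_TRANSFER", "ICU_Stays", "ICUSTAY_ID")),
    SERVICES = list(.link("in", "HAS_SERVICE", "Admission", "HADM_ID"))
  )
  out <- list()
  for (tb in names(cls)) {
    ts <- reg[[tb]]
    keys <- ts$primary_key
    cols <- ts$columns[!ts$columns$name %in% keys, , drop = FALSE]
    rules <- data.frame(column = cols$name,
                        property = tolower(cols$name),
                        literal_type = cols$literal_type,
                        stringsAsFactors = FALSE)
    out[[tb]] <- table_mapping(
      table = tb, subject_class = unname(cls[[tb]]),
      subject_key_columns = keys, column_rules = rules,
      link_rules = if (tb %in% names(links)) links[[tb]] else list())
  }
  out
}

# effective column rules: key echo prepends the subject key columns
.effective_column_rules <- function(mapping) {
  rules <- mapping$column_rules
  if (mapping$key_echo) {
    reg <- table_registry()[[mapping$table]]
    keys <- mapping$subject_key_columns
    lt <- reg$columns$literal_type[match(keys, reg$columns$name)]
    lt[is.na(lt)] <- "code"
    rules <- rbind(data.frame(column = keys, property = tolower(keys),
                              literal_type = lt, stringsAsFactors = FALSE),
                   rules)
  }
  rules[!duplicated(rules$column), , drop = FALSE]
}

# Vectorized mapping of a block of raw rows (character data frame with
# canonical uppercase names). Returns triples plus per-block stats.
.map_chunk <- function(mapping, df, schema) {
  n <- nrow(df)
  stats <- list(rows_read = n, rows_skipped = 0L, coercion_warnings = 0L,
                unmapped_values = 0L)
  if (!n) {
    return(list(triples = data.frame(s = character(0), p = character(0),
                                     o = character(0)), stats = stats))
  }
  if (!is.null(mapping$row_filter)) {
    keep <- mapping$row_filter(df)
    stats$rows_skipped <- stats$rows_skipped + sum(!keep)
    df <- df[keep, , drop = FALSE]
    n <- nrow(df)
  }
  keys <- mapping$subject_key_columns
  missing_cols <- setdiff(keys, names(df))
  if (length(missing_cols))
    stop("table ", mapping$table, ": key column(s) missing: ",
         paste(missing_cols, collapse = ", "))
  key_vals <- lapply(keys, function(k) df[[k]])
  key_ok <- Reduce(`&`, lapply(key_vals, function(v) !is_absent(v)))
  stats$rows_skipped <- stats$rows_skipped + sum(!key_ok)
  df <- df[key_ok, , drop = FALSE]
  n <- nrow(df)
  if (!n) {
    return(list(triples = data.frame(s = character(0), p = character(0),
                                     o = character(0)), stats = stats))
  }
  base <- schema$base_iri
  subj <- mint_iri_vec(mapping$subject_class,
                       lapply(keys, function(k) df[[k]]), base)
  type_p <- paste0("<", RDF_TYPE, ">")
  class_iri <- paste0("<", base, mapping$subject_class, ">")
  ss <- list(paste0("<", subj, ">"))
  pp <- list(rep(type_p, n))
  oo <- list(rep(class_iri, n))

  vocab <- categorical_vocab()
  rules <- .effective_column_rules(mapping)
  for (i in seq_len(nrow(rules))) {
    col <- rules$column[i]
    if (!col %in% names(df)) next
    raw <- df[[col]]
    pred <- paste0("<", base, rules$property[i], ">")
    if (rules$literal_type[i] == "categorical" &&
        rules$property[i] %in% names(vocab)) {
      live <- !is_absent(raw)
      if (!any(live)) next
      res <- categorical_resource(rules$property[i], raw[live], base)
      unmapped <- is.na(res)
      stats$unmapped_values <- stats$unmapped_values + sum(unmapped)
      obj <- ifelse(unmapped,
                    paste0("\"", .nt_escape(trimws(raw[live])), "\""),
                    paste0("<", res, ">"))
      ss <- c(ss, list(paste0("<", subj[live], ">")))
      pp <- c(pp, list(rep(pred, sum(live))))
      oo <- c(oo, list(obj))
    } else {
      enc <- encode_literal_column(raw, rules$literal_type[i])
      stats$coercion_warnings <- stats$coercion_warnings + sum(enc$bad)
      live <- !is.na(enc$terms)
      if (!any(live)) next
      ss <- c(ss, list(paste0("<", subj[live], ">")))
      pp <- c(pp, list(rep(pred, sum(live))))
      oo <- c(oo, list(enc$terms[live]))
    }
  }

  for (lr in mapping$link_rules) {
    kc <- lr$key_columns
    if (!all(kc %in% names(df))) next
    other <- mint_iri_vec(lr$other_class, lapply(kc, function(k) df[[k]]), base)
    live <- !is.na(other)
    if (!any(live)) next
    pred <- paste0("<", base, lr$property, ">")
    if (lr$direction == "in") {
      ss <- c(ss, list(paste0("<", other[live], ">")))
      oo <- c(oo, list(paste0("<", subj[live], ">")))
    } else {
      ss <- c(ss, list(paste0("<", subj[live], ">")))
      oo <- c(oo, list(paste0("<", other[live], ">")))
    }
    pp <- c(pp, list(rep(pred, sum(live))))
  }
  list(triples = data.frame(s = unlist(ss), p = unlist(pp), o = unlist(oo),
                            stringsAsFactors = FALSE),
       stats = stats)
}

#' Map one raw row to triples
#'
#' Emits the type assertion, one literal triple per non-absent column
#' rule (categorical demographics as vocabulary resources), and one link
#' triple per link rule whose key columns are non-null.
#'
#' @param mapping An `ehr_table_mapping`.
#' @param row Named character vector or single-row data frame.
#' @param schema An `ehr_schema`.
#' @return Data frame of encoded triples (`s`, `p`, `o`).
#' @export
map_row <- function(mapping, row, schema = build_mimic_schema()) {
  if (!is.data.frame(row)) {
    row <- as.data.frame(as.list(row), stringsAsFactors = FALSE,
                         check.names = FALSE)
  }
  names(row) <- toupper(names(row))
  keys <- mapping$subject_key_columns
  missing_key <- !keys %in% names(row) |
    vapply(keys, function(k) if (k %in% names(row)) is_absent(row[[k]]) else TRUE,
           TRUE)
  if (any(missing_key))
    stop("row is missing subject key column(s): ",
         paste(keys[missing_key], collapse = ", "))
  res <- .map_chunk(mapping, row, schema)
  res$triples[!duplicated(res$triples), , drop = FALSE]
}

# read and canonicalize a CSV header, validating it against the registry
.check_header <- function(header, table) {
  ts <- table_registry()[[table]]
  if (is.null(ts)) stop("unknown table: ", table)
  got <- toupper(trimws(header))
  want <- ts$columns$name
  missing <- setdiff(want, got)
  extra <- setdiff(got, want)
  if (length(missing) || length(extra))
    stop("header mismatch for ", table,
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  got
}

#' Map a CSV file to a triple graph
#'
#' Streams the file in chunks (constant memory in the number of rows per
#' chunk); the header must match the registry schema for the mapped
#' table, order-insensitively. Duplicate rows collapse under the graph's
#' set semantics.
#'
#' @param mapping An `ehr_table_mapping`.
#' @param csv_path Path to the CSV file.
#' @param schema An `ehr_schema`.
#' @param chunk_size Rows per chunk.
#' @return List with `graph` (an `rdf_graph`) and `report` (rows read,
#'   rows skipped, triples emitted, warning counts).
#' @export
map_table <- function(mapping, csv_path, schema = build_mimic_schema(),
                      chunk_size = 20000L) {
  con <- file(csv_path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  header_line <- readLines(con, n = 1L, warn = FALSE)
  if (!length(header_line)) stop("empty file: ", csv_path)
  header <- .check_header(
    scan(text = header_line, what = "", sep = ",", quote = "\"",
         quiet = TRUE), mapping$table)
  stats <- list(rows_read = 0L, rows_skipped = 0L,
                coercion_warnings = 0L, unmapped_values = 0L)
  parts <- list()
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (!length(lines)) break
    df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                          header = FALSE, col.names = header,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "\"")
    names(df) <- header
    res <- .map_chunk(mapping, df, schema)
    for (fld in names(stats)) stats[[fld]] <- stats[[fld]] + res$stats[[fld]]
    parts[[length(parts) + 1L]] <- res$triples
  }
  all_t <- if (length(parts)) do.call(rbind, parts)
           else data.frame(s = character(0), p = character(0), o = character(0))
  g <- rdf_graph(all_t$s, all_t$p, all_t$o)
  report <- c(list(table = mapping$table), stats,
              list(triples_emitted = triple_count(g)))
  list(graph = g, report = report)
}

# locate a registry table's file in a directory (.csv or .CSV)
.find_table_file <- function(dir, table) {
  for (nm in paste0(table, c(".csv", ".CSV"))) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Map a dataset directory to one triple graph
#'
#' Maps every core table present in `dir` and unions the per-table
#' graphs. All core tables covered by `mappings` must be present.
#'
#' @param dir Directory of MIMIC-III-format CSV files.
#' @param schema An `ehr_schema`.
#' @param mappings Named list of table mappings (default
#'   [default_mappings()]).
#' @return List with `graph` and `report` (named list of per-table
#'   reports).
#' @export
map_dataset <- function(dir, schema = build_mimic_schema(),
                        mappings = default_mappings(schema)) {
  paths <- lapply(names(mappings), function(tb) .find_table_file(dir, tb))
  names(paths) <- names(mappings)
  absent <- names(paths)[vapply(paths, is.null, TRUE)]
  if (length(absent))
    stop("dataset is missing required core table file(s): ",
         paste(absent, collapse = ", "))
  graphs <- list()
  reports <- list()
  for (tb in names(mappings)) {
    res <- map_table(mappings[[tb]], paths[[tb]], schema)
    graphs[[tb]] <- res$graph
    reports[[tb]] <- res$report
  }
  g <- do.call(graph_union, unname(graphs))
  list(graph = g, report = reports)
}
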