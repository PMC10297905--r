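# Shared fixtures: one small synthetic dataset (and its mapped graph)
# built once per test run and cached; plus an independent brute-force
# triple-count oracle used by the conservation tests.

.fixture_env <- new.env(parent = emptyenv())

# small dataset used by most unit tests
shared_dataset <- function() {
  if (is.null(.fixture_env$dir)) {
    dir <- file.path(tempdir(), "ehrkg-fixture-small")
    unlink(dir, recursive = TRUE)
    manifest <- generate_ehr(generator_spec(seed = 42L, n_patients = 100L), dir)
    .fixture_env$dir <- dir
    .fixture_env$manifest <- manifest
  }
  list(dir = .fixture_env$dir, manifest = .fixture_env$manifest)
}

shared_graph <- function() {
  if (is.null(.fixture_env$graph)) {
    fx <- shared_dataset()
    res <- map_dataset(fx$dir)
    .fixture_env$graph <- res$graph
    .fixture_env$map_report <- res$report
  }
  list(graph = .fixture_env$graph, report = .fixture_env$map_report)
}

# acceptance-scale dataset (seed 42, 1000 patients), built lazily
acceptance_dataset <- function() {
  if (is.null(.fixture_env$acc_dir)) {
    dir <- file.path(tempdir(), "ehrkg-fixture-acceptance")
    unlink(dir, recursive = TRUE)
    manifest <- generate_ehr(generator_spec(seed = 42L, n_patients = 1000L), dir)
    res <- map_dataset(dir)
    .fixture_env$acc_dir <- dir
    .fixture_env$acc_manifest <- manifest
    .fixture_env$acc_graph <- res$graph
    .fixture_env$acc_report <- res$report
  }
  list(dir = .fixture_env$acc_dir, manifest = .fixture_env$acc_manifest,
       graph = .fixture_env$acc_graph, report = .fixture_env$acc_report)
}

# Independent conservation oracle: expected triple count for one table by
# direct row iteration over the raw CSV (no mapper code involved beyond
# reading the mapping's declared rules).
brute_force_triple_count <- function(mapping, csv_path) {
  df <- utils::read.csv(csv_path, colClasses = "character",
                        check.names = FALSE, na.strings = character(0))
  names(df) <- toupper(names(df))
  mat <- as.matrix(df)
  absent <- function(v) !nzchar(trimws(v)) | toupper(trimws(v)) == "NULL"
  keys <- mapping$subject_key_columns
  if (!nrow(mat)) return(0L)
  key_ok <- !Reduce(`|`, lapply(keys, function(k) absent(mat[, k])))
  sig <- apply(mat, 1, paste, collapse = "\r")
  accepted <- key_ok & !duplicated(sig)   # duplicate rows collapse
  mat <- mat[accepted, , drop = FALSE]
  cnt <- rep(1L, nrow(mat))               # type assertion per accepted row
  cols <- mapping$column_rules$column
  if (mapping$key_echo) cols <- unique(c(keys, cols))
  for (cl in intersect(cols, colnames(mat)))
    cnt <- cnt + as.integer(!absent(mat[, cl]))
  for (lr in mapping$link_rules) {
    if (all(lr$key_columns %in% colnames(mat))) {
      ok <- !Reduce(`|`, lapply(lr$key_columns, function(k) absent(mat[, k])))
      cnt <- cnt + as.integer(ok)
    }
  }
  sum(cnt)
}

triple_set <- function(graph) {
  sort(paste(graph$triples$s, graph$triples$p, graph$triples$o))
}
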