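---
title: "Building and querying an EHR knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and querying an EHR knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrkg)
```

## The problem and the model

Critical-care EHR datasets in the MIMIC-III mould arrive as ~26 CSV
tables tied together by three identifiers: a patient (`SUBJECT_ID`), a
hospital admission (`HADM_ID`) and an ICU stay (`ICUSTAY_ID`). `ehrkg`
re-expresses these records as an RDF graph in which every row is a
resource, every column value a typed literal or vocabulary resource, and
every foreign key a semantic link declared in an ontology. A cohort
question then reads as a graph pattern rather than a join plan.

The ontology has three abstract branches besides the core
patient/admission/ICU classes: `Patient_Care` (ICD-9 coded diagnosis and
procedure records), `Codes` (code dictionaries: CPT, DRG, ICD-9
dictionaries, lab and charted item catalogues) and `Events` (chart, CPT,
input, lab, microbiology, note and output events). Nineteen object
properties connect the branches. Where a record can legitimately hang
off more than one context — a medication ordered during an admission or
during an ICU stay — the property declares a *union* domain, and the
mapper emits one link per context whose key is present, so both
admission-level and ICU-level views of the same prescription coexist.

Two labelling conventions required decisions the source material leaves
open. First, the published class listing reuses bare names (a CPT entry
appears both as an event and as a code), so event subclasses carry an
`_Event` suffix and dictionary subclasses a `_Code`/`_Item` suffix;
the printed labels are reconciled through a declared, test-covered alias
map (`ehr_class_aliases()`). Second, the property catalogue names a
"Drug" code class but sources it from the DRG (diagnosis-related group)
file; we model it as `DRG_Code` and treat the label as a naming slip.
Similarly, the `HAS_PATIENT_CARE` source is listed as a lowercase
singular "patient" file and is resolved to `PATIENTS.CSV` via the alias
map.

## IRIs, literals, and the mapping recipe

Every resource is minted as `{base}{Class}/{key1-key2-...}` under the
base IRI `http://mimicIII.com/base/` (prefix `mc`). Key values are
percent-encoded; the hyphen joiner is itself encoded inside values, so
composite keys are unambiguous and `unmint_iri()` recovers `(class,
keys)` exactly. Minting is pure string construction, hence deterministic
across runs and machines.

Per-table recipes (`default_mappings()`) drive the emission. For each
accepted row: one `rdf:type` assertion; one literal triple per non-null
column (the subject's own key columns are echoed as literals by default,
so queries can filter on raw identifiers such as `mc:cgid "16175"`); one
link triple per resolvable foreign-key rule. Nulls are the empty string,
whitespace, or the sentinel `NULL` in any case. Datetimes in the
`YYYY-MM-DD HH:MM:SS` dialect are normalised to ISO 8601 with a `T`
separator; integers and decimals are validated lexically and carried
with XSD datatypes; codes and identifiers stay plain string literals.
The three demographic fields (gender, race, marital status) map through
a fixed vocabulary to resources (`mc:Male`, `mc:White`, `mc:Married`);
out-of-vocabulary values fall back to a string literal and are counted
as warnings rather than dropped. These two conventions — codes as
strings, demographics as resources — reproduce both query idioms used in
the source material's printed examples.

One modelling divergence from the real distribution is deliberate:
gender, race and marital status are Patient-level attributes here
(the real data records ethnicity and marital status per admission),
because the demographic cohort queries the package targets are phrased
against patients. The divergence is confined to the `PATIENTS` table
schema and documented in its registry entry.

A note on mechanism: the original pipeline this package re-implements
produced its triples through interactive GUI tooling (spreadsheet-style
mapping screens feeding SPARQL `CONSTRUCT` templates over a federation
endpoint). `ehrkg` computes the same triples by direct in-process
mapping; the semantics, not the mechanism, are preserved.

## Graph container and serialization

Triples are held set-semantically (duplicate insertion is a no-op) in
their N-Triples term encoding, which makes joins and canonicalisation
plain string operations. Canonical N-Triples output is one triple per
line, sorted lexicographically in the C locale — serialising the same
graph twice is byte-identical, which the determinism tests rely on.
Turtle output adds the prefix block and compacts names where the local
part is a safe `PN_LOCAL`; the parser accepts the line-oriented subset
the package writes. Ontology documents additionally use
`owl:unionOf` constructs for union domains, and carry the column
catalogue (source tables, literal types) as annotation properties under
the base IRI so that serialize → parse is lossless in both Turtle and
RDF/XML.

## The SPARQL subset

The in-package evaluator supports `SELECT` (with `DISTINCT` and
`COUNT`/`COUNT DISTINCT` aggregates), basic graph patterns with `;` and
`,` abbreviations, `FILTER` with comparisons, boolean connectives,
`STR`, `STRSTARTS` and `regex`, plus `GROUP BY`, `HAVING`, `ORDER BY`
and `LIMIT`. Unsupported constructs (`OPTIONAL`, `UNION`, `BIND`,
`SERVICE`, ...) raise errors naming the construct rather than silently
misevaluating. Basic graph patterns are evaluated by per-pattern
matching followed by natural joins, most-selective pattern first;
filters apply to the joined solution set. Comparisons are numeric when a
typed numeric literal is involved and lexical otherwise. Typographic
quotation marks are normalised to ASCII before tokenising, so query text
copied from typeset documents runs unchanged.

The three cohort operations are SPARQL routes, not relational
shortcuts: `cohort_by_diagnosis()` unions the admission path
(`?patient mc:HAS_ADMISSION ?adm . ?adm mc:HAS_DIAGNOSIS ?dx`) with the
ICU-stay path, matching the union-domain declaration for diagnosis
links; `cohort_comorbid()` intersects two single-prefix cohorts; and
`cohort_multi_icu()` group-counts distinct ICU stays per patient with a
`HAVING` threshold. "Multiple ICU admissions" means at least two
distinct `ICUSTAY_ID`s, not two hospitalisations. Since the named
conditions are never tied to concrete codes in the source material, the
package adopts the standard ICD-9-CM chapter prefixes — `250` for
diabetes mellitus, `401` for essential hypertension — both overridable,
with an `exact` flag for full-code matching.

```{r cohort-demo}
dir <- file.path(tempdir(), "vignette-demo")
manifest <- generate_ehr(generator_spec(seed = 1, n_patients = 100), dir)
g <- map_dataset(dir)$graph
h <- kg_load(g)
cohort_comorbid(h, "401", "250")$subject_ids
```

## The synthetic generator and what it does (not) show

The generator emulates the shape of the MIMIC-III v1.4 distribution at
desk scale: 13 core tables are populated (patients, admissions, ICU
stays, ICD-9 diagnoses and procedures, prescriptions, lab events and
their dictionary, the diagnosis dictionary, caregivers, transfers,
services, call-outs); the remaining registry files are written as
header-only stubs. Structural guarantees hold by construction for every
seed: referential integrity across all key columns, `ADMITTIME ≤
DISCHTIME`, `INTIME ≤ OUTTIME` within the admission window, and `DOB`
(drawn in 2030–2080) strictly before the first admission (window
2100–2105, echoing the far-future date-shifting convention of
de-identified ICU data).

Key generator decisions:

* **Exact-count planting.** Cohort sizes are `floor(fraction × n)`, not
  Bernoulli draws, so expected counts are deterministic; the comorbid
  cohort is constructed as exactly the intersection of the diabetes and
  hypertension cohorts, and background diagnosis codes never start with
  `250` or `401`, so planted membership is recoverable without
  tolerance. Default fractions — diabetes 0.10, hypertension 0.08,
  comorbid 0.03, multi-ICU 0.10 — define the reference study conditions
  used throughout the tests and the acceptance script.
* **Per-table streams.** Structural decisions come from one seeded
  stream, field values from streams derived from `(seed, table name)`;
  adding a table never perturbs another's content, and identical specs
  produce byte-identical files.
* **Realism envelope.** Admission counts are `1 + Poisson(mean − 1)`
  (default mean 1.4 per patient), non-cohort patients have at most one
  ICU stay (probability 0.6), multi-ICU members `2 + Poisson(0.5)` stays.
  Lab values are Gaussian around item-typical means; drugs, units and
  care units are small realistic vocabularies. Everyone survives:
  mortality fields are present but empty/zero.

What passing tests on this data *do* show: the mapping emits exactly the
declared triples (conservation), the graph conforms to the ontology, the
SPARQL route and an independent relational route agree set-exactly on
every cohort, and the whole pipeline is reproducible byte-for-byte. What
they do *not* show: robustness to the messiness of real EHR exports
(clinical free text, inconsistent code formats, genuinely missing
demographics, million-row event tables) or the clinical validity of the
ontology — no terminology binding (SNOMED CT, LOINC) is attempted.

## Numerical and engineering choices

* Mapping streams CSVs in 20,000-row chunks with vectorised per-chunk
  emission; memory is bounded by chunk size, not file size. Embedded
  newlines inside quoted fields are not supported (none of the mapped
  core tables carry them).
* `validate_graph()` treats a subclass instance as satisfying a
  superclass domain (the hierarchy is honoured), and an untyped subject
  of any property triple as a domain violation — that is exactly how a
  dangling foreign key surfaces after mapping.
* Reference problem sizes: unit tests run on a shared 100-patient
  dataset (~18k triples); the acceptance script and the headline
  oracle-equivalence test use 1000 patients (~178k triples), which maps
  in a few seconds and validates in under ten.
* Ties and ordering: wherever output order is observable (serialised
  triples, ontology blocks, manifest ID arrays) it is sorted
  lexicographically or numerically, never insertion-ordered, so diffs
  are stable.

## Known limitations

The SPARQL subset has no `OPTIONAL`/`UNION` (the cohort union is taken
in R); blank nodes are excluded by design (every entity has an
invertible IRI); the Turtle parser reads the package's own line-oriented
dialect rather than full Turtle; and the relational oracle shares the
table registry with the pipeline — deliberately its only shared code —
so registry errors would affect both routes; the generator manifest is
the third, fully independent witness guarding against that.
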