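---
title: "From archetype constraints to executable data quality rules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From archetype constraints to executable data quality rules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqrgen)
```

## The problem and the method

Rule-based data quality assessment of EHR data expresses each quality
requirement as an executable query whose result rows are violations. In an
openEHR clinical data repository the knowledge those rules need already
exists in machine-readable form: archetypes constrain, attribute by
attribute, what well-formed data looks like. `dqrgen` operationalizes a
four-step procedure:

1. **Keyword identification.** Five ADL keywords carry quality semantics —
   `existence`, `occurrences`, `cardinality`, `defining_code` and `matches`
   — and each maps to a sub-dimension of Kahn's harmonized data-quality
   framework: mandatory existence to *completeness*; occurrences and
   count-bounded cardinality to *relational conformance*;
   uniqueness-flagged cardinality to *uniqueness plausibility*; code sets,
   value sets, ranges and units to *value conformance*. One reference-model
   feature joins them: the Entry classes (INSTRUCTION, ACTION, OBSERVATION,
   …) encode the stage of a clinical event, so a declared ordering of Entry
   types expresses *temporal plausibility* (a request must not postdate its
   execution). Two Kahn sub-dimensions — computational conformance and
   atemporal plausibility — have no generating keyword; rules in those
   sub-dimensions can only be supplied externally.

2. **Template design.** Each keyword has a fixed SQL skeleton with
   placeholders for the select column, the table and the violation
   predicate (`template_registry()` in the source; `select_template()`
   chooses per constraint). All skeletons share one contract: *returned
   rows are violations*.

3. **Constraint retrieval.** `parse_archetype()` parses the archetype's
   definition section (a pragmatic ADL 1.4 subset) into a node tree and
   `extract_constraints()` emits one record per constraint clause, with the
   verbatim source text kept as provenance. `normalize_constraint()` then
   strips the notation SQL cannot use: `|0.0..1000.0|` becomes the
   violation predicate `column < 0 OR column > 1000`, quoted members become
   escaped `NOT IN` lists, a designated unit becomes an inequality test.

4. **Conversion.** `generate_rules()` resolves each constraint's attribute
   through the declarative archetype-relational mapping
   (`(archetype_id, node_path, role) → (table, column)`) and fills the
   template. Every rule keeps full provenance (archetype, path, keyword,
   raw constraint text) and a deterministic identifier, so regeneration
   from identical inputs is byte-identical.

Evaluation against a reference rule set (`compare_rules()`) is two-aspect:
pairs must return identical violation row multisets on a probe dataset
*and* have equal canonical normalized query forms; `coverage()` divides
agreeing pairs by the reference count, per dimension and overall.

## Assumptions

- The repository is relational and each constrained attribute is bound to
  exactly one column; the mapping file declares that binding explicitly
  (the mapping is input, never inferred).
- One rule is emitted per constraint, not per attribute: a node carrying a
  range and a units constraint yields two rules.
- Violation semantics are row-oriented; group rules (occurrences,
  cardinality) report one violating *group* per offending key.

## Design choices the source material left open

- **Interval inclusivity.** Interval bounds are inclusive unless explicitly
  prefixed `>` or `<`: a value is a violation only strictly below the lower
  or strictly above the upper bound. This matches the final rendered rule
  (`< 0`, `> 1000`) for `|0.0..1000.0|`.
- **Disjunction, not conjunction.** Pseudocode for range and cardinality
  checks is sometimes printed with `AND` between the two sides
  (`value < 0 and value > 1000`), which no row can satisfy. The violation
  predicate is implemented as the disjunction; the conjunction is treated
  as an erratum and the corrected form is what semantic agreement is tested
  against.
- **NULL semantics.** NULL (and empty-string) values are completeness
  findings only; range, set and units predicates never flag them. This is
  native SQL comparison behaviour — `NULL < 0` is not true — so generated
  SQL needs no explicit guard, and it keeps per-dimension counts additive
  (one defect, one dimension).
- **Empty-value tokens.** The completeness template tests
  `IS NULL OR = ''` and accepts a configurable list of additional
  null-equivalent tokens (`'-'`, `'NA'`, …), since real repositories encode
  missingness inconsistently.
- **Vacuous constraints.** Optional existence (`0..1`) generates no rule —
  it expresses no requirement — and the same ruling extends to any count
  interval with no finite bound (e.g. occurrences `0..*`): there is no
  violating condition to test.
- **Grouping keys.** Occurrences/cardinality rules need a partition key
  that the ADL text does not name. The mapping's KEY-role column for the
  table supplies it; a table without one makes such constraints a
  skip-with-reason, never a guess.
- **Kahn → CARSES crosswalk.** The assessment standard's dimensions are
  configuration, not code (`default_crosswalk()`, overridable via YAML):
  completeness→completeness, terminology-code conformance→consistency,
  range/value/units conformance→conformity, temporal
  plausibility→timeliness, relational conformance and uniqueness
  plausibility→UNMATCHED. The default reproduces the packaged count
  fixture's partition; other standards can remap.
- **Pair matching before agreement.** Nothing in the procedure dictates how
  generated and reference rules are paired. Candidates are matched on
  (table, select-column set, dimension), ties broken by smallest edit
  distance between normalized forms, each reference rule matched at most
  once. The matching is logged per pair.
- **Temporal joins.** The temporal template compares with strict `>`
  (equal timestamps are not violations) and takes its join keys from the
  declared temporal link, since the pseudocode-level template names no join
  condition.
- **The count fixture.** The packaged evaluation fixture uses the
  per-dimension table (208/212, 47/87, 45/45, 11/22; overall 311/366),
  whose arithmetic is internally consistent (311/366 = 84.97%). A
  differently printed overall agreement figure of 319 exists in the source
  material's summary; it is not reproducible from the per-dimension counts
  and is not used.

## Numerical conventions

- Percentages are rounded half-up to two decimals (`round_half_up()`),
  not banker's rounding; 84.9726… prints as 84.97.
- SQL rendering is byte-stable: fixed keyword casing, double-quoted
  identifiers taken verbatim (no case folding), set members sorted before
  inlining, predicate order fixed (lower bound before upper).
- Canonical SQL normalization (for semantic equality) case-folds keywords
  and identifiers, strips identifier quoting and table aliases, rewrites
  `!=` to `<>`, renders numbers canonically (`0.0` ≡ `0`), sorts select and
  group-by lists, IN-list members, conjuncts and disjuncts. It is
  deliberately conservative: predicates that differ in operator or operand
  never normalize to the same form.
- Degenerate inputs: a single-point interval `|0..0|` is legal (violations
  are values ≠ 0 on either side); an empty value set is a normalization
  error; a fully unbounded interval is vacuous; coverage over a dimension
  with zero reference rules is an error rather than 0 or 100.

## The synthetic-data generator

`synth_spec()`/`generate_bundle()` emulate an archetype-shaped repository
end to end: archetypes in the supported ADL subset, a mapping that resolves
every constraint, one table per archetype, and a defect ground truth. The
defaults are the package's study conditions: 3 archetypes (an
INSTRUCTION/ACTION pair sharing record keys plus an OBSERVATION), 8
constraints per archetype covering every template class, 300 rows per
table, and per-class defect rates of 1–3% — the order of magnitude one
expects of structured-field defects in operational EHR data, and enough
rows that every class draws a nonzero count at the default sizes.

Defects are injected non-overlapping per cell, so ground truth is exact:
missing values and out-of-range/bad-code/bad-unit replacements touch
disjoint cells of columns that carry exactly one constraint each; extra
occurrences and duplicate list members are injected as *added rows* that
are clean in every column except the targeted group column (other group
columns are NULL in added rows so group counts elsewhere are untouched);
temporal inversions swap request/execution timestamps of keys that no
row-adding defect touches. Consequently each generated rule's violation
count must equal one class's injected count exactly — the recovery
property the tests assert.

What the generator does **not** emulate: clinically realistic value
distributions (values are uniform within bounds, defects uniform in a
margin beyond the violated bound), correlated or overlapping defects,
multi-valued nodes with bespoke column layouts, or free-text content.
Passing tests therefore demonstrate that the constraint logic, SQL
generation and counting are correct — not that the rules would capture
every defect mode of a production repository.

## Problem sizes in the test suite

Unit tests run on bundles of 20–120 rows. The end-to-end property suite
uses five seeds at 1,000–2,000 rows per table (≈24 rules each), checking
SQL-vs-oracle row-set equality, exact defect recovery, byte-identical
regeneration, parser round-trips and template-class coverage; the whole
suite completes in well under a minute on a single CPU. These sizes were
chosen because every property under test is scale-invariant: the checks
are exact equalities, not statistical estimates, so larger tables add
runtime but no evidence.

## Known limitations

- The ADL subset excludes ADL 2, specialization, slots, templates and the
  rules/expression-language section; archetypes outside the subset fail
  fast with a location rather than parsing partially.
- Rules span one table (plus the declared temporal joins); multi-element
  clinical logic and semantic checks of free text are out of scope.
- The SQL dialect is the embedded engine's (SQLite, ANSI-leaning quoting).
  Rendered rules are portable in structure but not guaranteed verbatim
  against every RDBMS.
- Semantic equality is normalization-based: two queries that are logically
  equivalent but structurally different (e.g. `NOT (x >= 0 AND x <= 10)`)
  are not recognized as equal — the result-equality aspect on a probe
  dataset is the backstop for such pairs.
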