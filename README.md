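# dqrgen — automatic data quality rules from openEHR archetypes

Secondary use of electronic health record (EHR) data — research, decision
support, quality reporting — is only as trustworthy as the data's quality,
and the standard way to assess that quality is a battery of **data quality
rules (DQRs)**: executable queries whose returned rows are violations.
Writing hundreds of such rules by hand is slow, expert-bound and hard to
standardize. In an openEHR-based clinical data repository, however, most of
the knowledge the rules need is already machine-readable: every archetype
states, in the Archetype Definition Language (ADL), which attributes are
mandatory, what ranges and units a quantity admits, which terminology codes
are allowed, and how often a node may occur.

`dqrgen` turns that constraint knowledge into executable SQL rules. It is
aimed at informaticians running data-quality assessment over
archetype-modeled relational repositories, and at anyone studying automated
DQR creation.

## What it does

1. **Parse** a pragmatic subset of ADL 1.4 and extract every quality
   constraint: `existence`, `occurrences`, `cardinality` (with the `unique`
   flag), value intervals `|a..b|`, value sets, terminology code lists and
   unit designations — the five quality-related ADL keywords.
2. **Classify** each constraint against Kahn's harmonized data-quality
   framework (value/relational conformance, completeness,
   uniqueness/temporal plausibility) and map it onto the dimensions of an
   assessment standard (by default CARSES: completeness, consistency,
   timeliness, conformity) via a configurable crosswalk.
3. **Instantiate** SQL templates through a declarative archetype-relational
   mapping (`mapping.yaml`): each rule is a `SELECT` whose rows violate the
   constraint, e.g. an interval `|0.0..1000.0|` on a mapped magnitude
   becomes

   ```sql
   SELECT "diastolic_blood_pressure_value" FROM "blood_pressure"
   WHERE "diastolic_blood_pressure_value" < 0
      OR "diastolic_blood_pressure_value" > 1000
   ```

   One reference-model feature adds a further rule class: Entry types order
   the stages of a clinical event, so a declared INSTRUCTION→ACTION link
   yields a temporal-plausibility rule (`request_time > execution_time`).
4. **Execute** rule sets read-only on an embedded SQLite database (or CSV
   tables) and report violation counts per rule and per dimension. A
   brute-force row-wise oracle re-evaluates every rule without the SQL
   engine for equivalence testing.
5. **Evaluate** a generated rule set against a reference (expert) rule set
   by two-aspect agreement — identical violation row sets on a probe
   dataset *and* semantically equal canonical query forms — and compute
   coverage per dimension:

   `coverage = 100 × (# generated rules in agreement) / (# reference rules)`

A seeded synthetic-data generator emits archetypes, mappings, and tables
with labeled injected defects (missing values, out-of-range values, bad
codes/units, duplicated list members, extra occurrences, inverted
request/execution timestamps), so the whole pipeline is testable without
any external data.

## Worked example

```r
library(dqrgen)

wx <- fixture_worked_example()          # blood-pressure archetype + mapping + 3-row table
model <- parse_archetype(wx$adl)
model
#> <archetype_model> openEHR-EHR-OBSERVATION.blood_pressure.v1
#>   entry type: OBSERVATION
#>   concept:    Blood pressure
#>   nodes:      5 (2 constrained)

rules <- generate_rules(model, wx$mapping)
rules$sql_text[1]
#> [1] "SELECT \"diastolic_blood_pressure_value\" FROM \"blood_pressure\"
#>      WHERE \"diastolic_blood_pressure_value\" < 0 OR
#>      \"diastolic_blood_pressure_value\" > 1000"

ds <- dq_dataset(wx$tables)             # values -5, 500, 1500
execute_rule(rules[1, ], ds)$violations
#> [1] 2
dq_disconnect(ds)
```

The two violations are the hand-checkable ones: −5 falls below the lower
bound 0 and 1500 exceeds the upper bound 1000; 500 passes.

Coverage arithmetic on the packaged per-dimension count fixture:

```r
fx <- fixture_table6()
coverage(fx$coverage_counts, auto_tally = fx$auto_tally)
#> <coverage_summary>
#>   completeness    208 /  212  =   98.11%
#>   conformity       47 /   87  =   54.02%
#>   consistency      45 /   45  =  100.00%
#>   timeliness       11 /   22  =   50.00%
#>   overall         311 /  366  =   84.97%
```

meaning, e.g., that 311 of 366 reference rules are matched by agreeing
generated rules overall, and every consistency requirement is covered.

## Command line

A thin CLI wraps the same functions (`inst/cli/dqr.R`):

```sh
Rscript inst/cli/dqr.R simulate --seed 42 --out bundle/
Rscript inst/cli/dqr.R parse    --archetypes bundle/ --out constraints.jsonl
Rscript inst/cli/dqr.R generate --archetypes bundle/ --mapping bundle/mapping.yaml --out rules/
Rscript inst/cli/dqr.R run      --rules rules/rules.jsonl --db bundle/data.sqlite --out report.json
Rscript inst/cli/dqr.R evaluate --fixture table6 --out coverage.json
```

## Scope and limitations

- ADL 2, archetype specialization/slots, templates (OET/OPT) and the ADL
  rules/expression-language section are out of scope.
- No rules are produced for computational conformance or atemporal
  plausibility: no ADL keyword or RM feature expresses them.
- Multi-element clinical-logic constraints and free-text (NLP) completeness
  checks are not representable as single generated rules.
- The relational schema is declared, not derived: the mapping file states
  whatever tables and columns exist.

See `vignettes/dqrgen-methods.Rmd` for the full account of the method,
design choices and numerical conventions.
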