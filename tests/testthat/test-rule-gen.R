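# Constraint normalization, rule instantiation, canonical SQL rendering.

test_that("normalization strips ADL notation into violation predicates", {
  rng <- list(keyword = "MATCHES_RANGE", payload = parse_interval("|0..1000|"))
  expect_equal(normalize_constraint(rng)$sql,
               "{column} < 0 OR {column} > 1000")
  # exclusive bounds shift the comparators
  exc <- list(keyword = "MATCHES_RANGE", payload = parse_interval("|>0..<1000|"))
  expect_equal(normalize_constraint(exc)$sql,
               "{column} <= 0 OR {column} >= 1000")
  # one-sided interval: the unbounded side contributes nothing
  lo <- list(keyword = "MATCHES_RANGE", payload = parse_interval("|0..|"))
  expect_equal(normalize_constraint(lo)$sql, "{column} < 0")

  lit <- list(keyword = "MATCHES_UNITS",
              payload = structure(list(value = "mm[Hg]"), class = "adl_literal"))
  expect_equal(normalize_constraint(lit)$sql, "{column} <> 'mm[Hg]'")

  vs <- list(keyword = "MATCHES_VALUE",
             payload = structure(list(values = c("Mr", "Dr", "Mrs", "Miss")),
                                 class = "adl_valueset"))
  expect_equal(normalize_constraint(vs)$sql,
               "{column} NOT IN ('Dr', 'Miss', 'Mr', 'Mrs')")
  # literals are escaped
  esc <- list(keyword = "MATCHES_VALUE",
              payload = structure(list(values = c("O'Neil", "X")),
                                  class = "adl_valueset"))
  expect_match(normalize_constraint(esc)$sql, "'O''Neil'", fixed = TRUE)

  ex <- list(keyword = "EXISTENCE", payload = parse_interval("(1..1)"))
  expect_equal(normalize_constraint(ex)$sql,
               "{column} IS NULL OR {column} = ''")
  ex2 <- normalize_constraint(ex, null_tokens = c("NA", "-"))
  expect_match(ex2$sql, "IN \\('-', 'NA'\\)")

  occ <- list(keyword = "OCCURRENCES", payload = parse_interval("(1..1)"))
  expect_equal(normalize_constraint(occ)$sql,
               "COUNT({column}) < 1 OR COUNT({column}) > 1")

  empty <- list(keyword = "DEFINING_CODE",
                payload = structure(list(codes = character(0)),
                                    class = "adl_codeset"))
  expect_error(normalize_constraint(empty), class = "dqr_normalize_error")
})

test_that("the worked example instantiates the printed range rule (OR-corrected)", {
  s <- worked_example_setup()
  on.exit(dq_disconnect(s$ds))
  range_rule <- s$rules[s$rules$template_id == "range_out_of_bounds", ]
  expect_equal(nrow(range_rule), 1)
  expect_equal(range_rule$table_name, "blood_pressure")
  expect_equal(range_rule$eval_spec[[1]]$column, "diastolic_blood_pressure_value")
  expect_equal(range_rule$eval_spec[[1]]$lower, 0)
  expect_equal(range_rule$eval_spec[[1]]$upper, 1000)
  expect_equal(
    range_rule$sql_text,
    paste0('SELECT "diastolic_blood_pressure_value" FROM "blood_pressure" ',
           'WHERE "diastolic_blood_pressure_value" < 0 OR ',
           '"diastolic_blood_pressure_value" > 1000')
  )
  # provenance points back at the extracted constraint
  expect_equal(range_rule$raw_text, "magnitude matches {|0.0..1000.0|}")
  expect_equal(range_rule$kahn_subdimension, "VALUE_CONFORMANCE")
  expect_equal(range_rule$carses_dimension, "CONFORMITY")
})

test_that("group rules require a KEY mapping and report skips with reasons", {
  adl <- make_archetype(c("occ_1 occurrences matches {1..1}",
                          "item_2 existence matches {1..1}"))
  model <- parse_archetype(adl)
  entries <- data.frame(
    archetype_id = model$archetype_id,
    node_path = c("/data/occ_1", "/data/item_2"),
    table_name = "t", column_name = c("occ_1", "item_2"),
    role = "VALUE", stringsAsFactors = FALSE
  )
  # no KEY column: the occurrences rule is skipped, the existence rule is not
  rules <- generate_rules(model, mapping_table(entries))
  expect_equal(nrow(rules), 1)
  skips <- attr(rules, "skips")
  expect_equal(nrow(skips), 1)
  expect_match(skips$reason, "KEY")
  expect_true(skips$template_eligible)

  # with a KEY column both rules generate
  entries2 <- rbind(entries, data.frame(
    archetype_id = model$archetype_id, node_path = "/key", table_name = "t",
    column_name = "record_key", role = "KEY", stringsAsFactors = FALSE
  ))
  rules2 <- generate_rules(model, mapping_table(entries2))
  expect_equal(nrow(rules2), 2)
  expect_match(rules2$sql_text[rules2$template_id == "occurrences_count"],
               'GROUP BY "record_key" HAVING', fixed = TRUE)
})

test_that("generation is deterministic and conserves constraint counts", {
  bundle <- generate_bundle(synth_spec(seed = 21, rows_per_table = 20))
  r1 <- generate_rules(bundle$models, bundle$mapping)
  r2 <- generate_rules(bundle$models, bundle$mapping)
  expect_identical(r1$rule_id, r2$rule_id)
  expect_identical(r1$sql_text, r2$sql_text)
  # re-rendering from the structured form reproduces the stored SQL
  for (i in seq_len(nrow(r1))) {
    expect_identical(render_sql(r1[i, , drop = FALSE]), r1$sql_text[i])
  }
  # count conservation: rules + eligible skips = eligible constraints + links
  eligible <- 0
  for (model in bundle$models) {
    cs <- extract_constraints(model)
    for (i in seq_len(nrow(cs))) {
      if (!is.null(select_template(cs[i, , drop = FALSE]))) eligible <- eligible + 1
    }
  }
  skips <- attr(r1, "skips")
  expect_equal(nrow(r1) + sum(skips$template_eligible),
               eligible + length(bundle$mapping$temporal_links))
  # Kahn sub-dimension matches classification of the provenance constraint
  for (i in seq_len(nrow(r1))) {
    if (r1$keyword[i] == "TEMPORAL_PAIR") next
    model <- bundle$models[[which(vapply(bundle$models, function(m)
      m$archetype_id, "") == r1$archetype_id[i])]]
    cs <- extract_constraints(model)
    row <- cs[cs$node_path == r1$node_path[i], , drop = FALSE]
    expect_equal(r1$kahn_subdimension[i],
                 classify_constraint(row[1, , drop = FALSE]))
  }
})

test_that("generated SQL parses in the embedded engine and rules round-trip JSONL", {
  bundle <- generate_bundle(synth_spec(seed = 22, rows_per_table = 20))
  rules <- generate_rules(bundle$models, bundle$mapping)
  expect_gt(nrow(rules), 0)
  ds <- dq_dataset(bundle$tables)
  on.exit(dq_disconnect(ds))
  for (i in seq_len(nrow(rules))) {
    expect_no_error(execute_rule(rules[i, , drop = FALSE], ds))
  }
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(back$rule_id, rules$rule_id)
  expect_equal(back$sql_text, rules$sql_text)
  expect_equal(back$carses_dimension, rules$carses_dimension)
  # a re-read rule still executes and still matches its oracle
  r <- back[1, , drop = FALSE]
  expect_identical(violation_signature(execute_rule(r, ds)$rows),
                   violation_signature(oracle_evaluate(r, ds$tables)))
  # .sql export carries one statement per rule with provenance headers
  sqlp <- withr::local_tempfile(fileext = ".sql")
  write_rules_sql(rules, sqlp)
  txt <- readLines(sqlp)
  expect_equal(sum(grepl("^-- ", txt)), nrow(rules))
})
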