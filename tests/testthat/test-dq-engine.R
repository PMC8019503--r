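# Rule execution, the brute-force oracle, and assessment reports.

test_that("the range rule flags exactly the hand-evaluated violations", {
  s <- worked_example_setup()
  on.exit(dq_disconnect(s$ds))
  range_rule <- s$rules[s$rules$template_id == "range_out_of_bounds", ]
  res <- execute_rule(range_rule, s$ds)
  # values {-5, 500, 1500}: -5 < 0 and 1500 > 1000 violate; 500 does not
  expect_equal(res$violations, 2)
  expect_equal(res$rows_examined, 3)
  expect_setequal(res$rows[[1]], c(-5, 1500))
  # units all equal mm[Hg]: clean
  units_rule <- s$rules[s$rules$template_id == "units_not_equal", ]
  expect_equal(execute_rule(units_rule, s$ds)$violations, 0)
})

test_that("execution errors name the missing identifier and reports continue", {
  s <- worked_example_setup()
  on.exit(dq_disconnect(s$ds))
  broken <- s$rules[1, , drop = FALSE]
  broken$eval_spec[[1]]$table <- "no_such_table"
  err <- tryCatch(execute_rule(broken, s$ds), error = function(e) conditionMessage(e))
  expect_match(err, "no_such_table")
  mixed <- rbind(s$rules, broken)
  report <- run_assessment(mixed, s$ds)
  expect_equal(sum(!is.na(report$per_rule$error)), 1)
  expect_equal(sum(is.na(report$per_rule$error)), nrow(s$rules))
})

test_that("zero rules yield an empty report with zeroed aggregates", {
  s <- worked_example_setup()
  on.exit(dq_disconnect(s$ds))
  report <- run_assessment(s$rules[0, , drop = FALSE], s$ds)
  expect_equal(nrow(report$per_rule), 0)
  expect_equal(nrow(report$by_carses), 0)
})

test_that("a temporal link with one inverted request/execution pair yields one violation", {
  tables <- list(
    req = data.frame(record_key = 1:4,
                     request_time = c("2024-01-01 08:00:00", "2024-01-01 09:00:00",
                                      "2024-01-01 12:00:00", "2024-01-01 11:00:00"),
                     stringsAsFactors = FALSE),
    act = data.frame(record_key = 1:4,
                     execution_time = c("2024-01-01 08:30:00", "2024-01-01 09:30:00",
                                        "2024-01-01 11:00:00", "2024-01-01 11:00:00"),
                     stringsAsFactors = FALSE)
  )
  mp <- mapping_table(NULL, list(list(
    earlier_table = "req", earlier_time_column = "request_time",
    later_table = "act", later_time_column = "execution_time",
    join_pairs = list(c("record_key", "record_key")),
    earlier_entry_type = "INSTRUCTION", later_entry_type = "ACTION"
  )))
  rules <- generate_rules(list(), mp)
  expect_equal(nrow(rules), 1)
  expect_equal(rules$kahn_subdimension, "TEMPORAL_PLAUSIBILITY")
  expect_equal(rules$carses_dimension, "TIMELINESS")
  ds <- dq_dataset(tables)
  on.exit(dq_disconnect(ds))
  res <- execute_rule(rules, ds)
  # only pair 3 has request after execution; equal timestamps (pair 4) pass
  expect_equal(res$violations, 1)
  expect_equal(res$rows_examined, 4)
  expect_identical(violation_signature(res$rows),
                   violation_signature(oracle_evaluate(rules, tables)))
})

test_that("NULL values are completeness findings, never range/value violations", {
  adl <- make_archetype(c("item_1 existence matches {1..1}",
                          "meas_2 matches {|0..10|}"))
  model <- parse_archetype(adl)
  entries <- data.frame(
    archetype_id = model$archetype_id,
    node_path = c("/data/item_1", "/data/meas_2"),
    table_name = "t", column_name = c("item_1", "meas_2"),
    role = "VALUE", stringsAsFactors = FALSE
  )
  rules <- generate_rules(model, mapping_table(entries))
  tables <- list(t = data.frame(item_1 = c("a", NA, ""),
                                meas_2 = c(5, NA, 20), stringsAsFactors = FALSE))
  ds <- dq_dataset(tables)
  on.exit(dq_disconnect(ds))
  cmp <- rules[rules$template_id == "existence_not_empty", ]
  rng <- rules[rules$template_id == "range_out_of_bounds", ]
  expect_equal(execute_rule(cmp, ds)$violations, 2)   # NA and ""
  expect_equal(execute_rule(rng, ds)$violations, 1)   # only 20; NA not flagged
  expect_identical(violation_signature(execute_rule(rng, ds)$rows),
                   violation_signature(oracle_evaluate(rng, ds$tables)))
})

test_that("adding a violating row never decreases a rule's violation count", {
  s <- worked_example_setup()
  range_rule <- s$rules[s$rules$template_id == "range_out_of_bounds", ]
  before <- execute_rule(range_rule, s$ds)$violations
  dq_disconnect(s$ds)
  t2 <- s$wx$tables
  t2$blood_pressure <- rbind(t2$blood_pressure,
                             data.frame(record_key = 4,
                                        diastolic_blood_pressure_value = -100,
                                        diastolic_blood_pressure_units = "mm[Hg]"))
  ds2 <- dq_dataset(t2)
  on.exit(dq_disconnect(ds2))
  expect_gte(execute_rule(range_rule, ds2)$violations, before)
  expect_equal(execute_rule(range_rule, ds2)$violations, before + 1)
})

test_that("uniqueness rules flag exactly the duplicated key/value groups", {
  adl <- make_archetype("uniq_1 cardinality matches {0..*; unique}")
  model <- parse_archetype(adl)
  entries <- data.frame(
    archetype_id = model$archetype_id,
    node_path = c("/data/uniq_1", "/key"),
    table_name = "t", column_name = c("uniq_1", "k"),
    role = c("VALUE", "KEY"), stringsAsFactors = FALSE
  )
  rules <- generate_rules(model, mapping_table(entries))
  tables <- list(t = data.frame(k = c(1, 1, 1, 2, 2),
                                uniq_1 = c("a", "a", "b", "a", "c"),
                                stringsAsFactors = FALSE))
  ds <- dq_dataset(tables)
  on.exit(dq_disconnect(ds))
  res <- execute_rule(rules, ds)
  # only (k=1, 'a') appears twice within one key group
  expect_equal(res$violations, 1)
  expect_identical(violation_signature(res$rows),
                   violation_signature(oracle_evaluate(rules, tables)))
})

test_that("datasets load identically from data frames, CSV directories and SQLite", {
  bundle <- generate_bundle(synth_spec(seed = 9, rows_per_table = 30))
  rules <- generate_rules(bundle$models, bundle$mapping)
  dir <- withr::local_tempdir()
  write_bundle(bundle, dir)

  ds_mem <- dq_dataset(bundle$tables)
  csv_dir <- file.path(dir, "csv"); dir.create(csv_dir)
  for (f in list.files(dir, pattern = "\\.csv$", full.names = TRUE)) {
    file.copy(f, csv_dir)
  }
  ds_csv <- dq_dataset(csv_dir)
  ds_sql <- dq_dataset(file.path(dir, "data.sqlite"))
  on.exit({dq_disconnect(ds_mem); dq_disconnect(ds_csv); dq_disconnect(ds_sql)})

  for (i in seq_len(nrow(rules))) {
    r <- rules[i, , drop = FALSE]
    sig <- violation_signature(execute_rule(r, ds_mem)$rows)
    expect_identical(violation_signature(execute_rule(r, ds_csv)$rows), sig,
                     info = r$rule_id)
    expect_identical(violation_signature(execute_rule(r, ds_sql)$rows), sig,
                     info = r$rule_id)
  }
})
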