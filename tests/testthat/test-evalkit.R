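# SQL normalization, two-aspect agreement, coverage arithmetic, proportions.

test_that("normalization canonicalizes quoting, case, numbers and disjunct order", {
  expect_identical(
    normalize_sql('SELECT "x" FROM "t" WHERE "x" > 10 OR "x" < 0.0'),
    normalize_sql("select x from t where x < 0 or x > 10")
  )
  expect_identical(
    normalize_sql("SELECT a FROM t WHERE a NOT IN ('b', 'a', 'c')"),
    normalize_sql('SELECT "a" FROM "t" WHERE "a" NOT IN (\'c\', \'a\', \'b\')')
  )
  expect_identical(
    normalize_sql("SELECT a FROM t WHERE a != 'x'"),
    normalize_sql("SELECT a FROM t WHERE a <> 'x'")
  )
  # aliases are stripped and replaced by the table they alias
  expect_identical(
    normalize_sql("SELECT e.t1 FROM req e JOIN act l ON e.k = l.k WHERE e.t1 > l.t2"),
    normalize_sql('SELECT "req"."t1" FROM "req" JOIN "act" ON "req"."k" = "act"."k" WHERE "req"."t1" > "act"."t2"')
  )
  # genuinely different predicates stay different
  expect_false(identical(
    normalize_sql("SELECT a FROM t WHERE a < 0"),
    normalize_sql("SELECT a FROM t WHERE a <= 0")
  ))
})

test_that("two-aspect agreement requires result equality and semantic equality", {
  s <- worked_example_setup()
  on.exit(dq_disconnect(s$ds))
  auto <- s$rules
  range_i <- which(auto$template_id == "range_out_of_bounds")

  # textually identical rules agree
  expert_same <- auto[range_i, , drop = FALSE]
  expert_same$rule_id <- "expert_same"
  agr <- compare_rules(auto, expert_same, s$ds)
  expect_true(all(agr$pairs$agree))

  # reordered disjuncts still agree: oracle check by expanding both
  # predicates over the probe rows
  expert_re <- expert_same
  expert_re$rule_id <- "expert_reordered"
  expert_re$sql_text <- paste0(
    "Select diastolic_blood_pressure_value From blood_pressure ",
    "Where diastolic_blood_pressure_value > 1000.0 or ",
    "diastolic_blood_pressure_value < 0.0")
  v <- s$wx$tables$blood_pressure$diastolic_blood_pressure_value
  oracle_a <- (v < 0) | (v > 1000)
  oracle_b <- (v > 1000.0) | (v < 0.0)
  expect_identical(oracle_a, oracle_b)
  agr2 <- compare_rules(auto, expert_re, s$ds)
  expect_true(all(agr2$pairs$result_equal))
  expect_true(all(agr2$pairs$semantically_equal))

  # a range rule and a not-null rule on the same column disagree: the probe
  # row 500 is in range but present
  expert_diff <- expert_same
  expert_diff$rule_id <- "expert_notnull"
  expert_diff$sql_text <- paste0(
    "SELECT diastolic_blood_pressure_value FROM blood_pressure WHERE ",
    "diastolic_blood_pressure_value IS NULL")
  expert_diff$eval_spec <- list(NULL)
  agr3 <- compare_rules(auto, expert_diff, s$ds)
  expect_false(any(agr3$pairs$agree))

  # agreement is invariant to pair order within the candidate set
  agr4 <- compare_rules(auto[rev(seq_len(nrow(auto))), ], expert_same, s$ds)
  expect_equal(sum(agr4$pairs$agree), sum(agr$pairs$agree))
})

test_that("rules failing on the probe dataset are non-agreeing with a reason", {
  s <- worked_example_setup()
  on.exit(dq_disconnect(s$ds))
  expert_bad <- s$rules[s$rules$template_id == "range_out_of_bounds", , drop = FALSE]
  expert_bad$rule_id <- "expert_bad"
  expert_bad$sql_text <- paste0(
    "SELECT diastolic_blood_pressure_value FROM blood_pressure ",
    "WHERE no_such_column < 0")
  expert_bad$eval_spec <- list(NULL)
  agr <- compare_rules(s$rules, expert_bad, s$ds)
  expect_false(any(agr$pairs$agree))
  expect_match(agr$pairs$note[1], "execution failed")
})

test_that("coverage reproduces the published per-dimension percentages", {
  fx <- fixture_table6()
  cov <- coverage(fx$coverage_counts, auto_tally = fx$auto_tally)
  pd <- cov$per_dimension
  expect_equal(pd$coverage_pct[pd$dimension == "COMPLETENESS"], 98.11)
  expect_equal(pd$coverage_pct[pd$dimension == "CONSISTENCY"], 100.00)
  expect_equal(pd$coverage_pct[pd$dimension == "CONFORMITY"], 54.02)
  expect_equal(pd$coverage_pct[pd$dimension == "TIMELINESS"], 50.00)
  expect_equal(cov$overall$n_agree, 311)
  expect_equal(cov$overall$n_expert, 366)
  expect_equal(cov$overall$coverage_pct, 84.97)
})

test_that("coverage is scale-free, bounded and undefined on empty dimensions", {
  counts <- data.frame(dimension = c("A", "B"), n_agree = c(3, 7),
                       n_expert = c(10, 14), stringsAsFactors = FALSE)
  c1 <- coverage(counts)
  counts_k <- counts; counts_k$n_agree <- counts$n_agree * 5
  counts_k$n_expert <- counts$n_expert * 5
  expect_equal(coverage(counts_k)$per_dimension$coverage_pct,
               c1$per_dimension$coverage_pct)
  expect_true(all(c1$per_dimension$coverage_pct >= 0 &
                  c1$per_dimension$coverage_pct <= 100))
  expect_equal(coverage(data.frame(dimension = "A", n_agree = 0,
                                   n_expert = 8))$overall$coverage_pct, 0)
  expect_equal(coverage(data.frame(dimension = "A", n_agree = 45,
                                   n_expert = 45))$overall$coverage_pct, 100)
  expect_error(coverage(data.frame(dimension = "A", n_agree = 0, n_expert = 0)),
               class = "dqr_coverage_error")
  expect_error(coverage(data.frame(dimension = "A", n_agree = 9, n_expert = 3)),
               class = "dqr_coverage_error")
})

test_that("dimension breakdown uses half-up rounding and reports UNMATCHED", {
  fx <- fixture_table6()
  bd <- dimension_breakdown(fx$auto_tally)
  expect_equal(bd$pct[bd$dimension == "COMPLETENESS"], 57.94)
  expect_equal(bd$pct[bd$dimension == "UNMATCHED"], 8.91)
  expect_equal(bd$pct[bd$dimension == "CONFORMITY"], 13.09)
  expect_equal(bd$pct[bd$dimension == "TIMELINESS"], 3.06)
  expect_equal(sum(bd$n), 359)
  # shares sum to 100 within rounding
  expect_lt(abs(sum(bd$pct) - 100), 0.05)
  # single-rule set
  expect_equal(dimension_breakdown(c(COMPLETENESS = 1))$pct, 100)
})

test_that("coverage computed from an agreement result tallies per dimension", {
  s <- worked_example_setup()
  on.exit(dq_disconnect(s$ds))
  expert <- s$rules
  expert$rule_id <- paste0("expert_", seq_len(nrow(expert)))
  agr <- compare_rules(s$rules, expert, s$ds)
  cov <- coverage(agr, expert)
  expect_equal(cov$overall$n_expert, nrow(expert))
  expect_equal(cov$overall$n_agree, nrow(expert))
  expect_equal(cov$overall$coverage_pct, 100)
})
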