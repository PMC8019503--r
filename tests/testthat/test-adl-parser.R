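# ADL subset parsing: archetype structure, constraint extraction, the
# interval micro-grammar, and the canonical round-trip.

test_that("the blood-pressure archetype parses with entry type and quantity node", {
  wx <- fixture_worked_example()
  model <- parse_archetype(wx$adl)
  expect_s3_class(model, "archetype_model")
  expect_equal(model$archetype_id, "openEHR-EHR-OBSERVATION.blood_pressure.v1")
  expect_equal(model$entry_type, "OBSERVATION")
  expect_equal(model$concept_name, "Blood pressure")
  expect_true("/data/Diastolic/value/magnitude" %in% node_paths(model))

  cs <- extract_constraints(model)
  expect_equal(nrow(cs), 2)
  expect_equal(cs$keyword, c("MATCHES_RANGE", "MATCHES_UNITS"))
  # raw constraint text is verbatim from the source
  for (raw in cs$raw_text) expect_true(grepl(raw, model$source, fixed = TRUE))
  iv <- cs$payload[[1]]
  expect_equal(c(iv$lower, iv$upper), c(0, 1000))
  expect_true(iv$lower_included && iv$upper_included)
})

test_that("entry type is derived from the archetype identifier", {
  ids <- c("openEHR-EHR-OBSERVATION.blood_pressure.v1" = "OBSERVATION",
           "openEHR-EHR-INSTRUCTION.request-lab_test.v1" = "INSTRUCTION",
           "openEHR-EHR-ADMIN_ENTRY.admission.v1" = "ADMIN_ENTRY",
           "openEHR-DEMOGRAPHIC-PERSON.person.v1" = "DEMOGRAPHIC",
           "openEHR-EHR-CLUSTER.specimen.v1" = "CLUSTER",
           "openEHR-EHR-SOMETHING_ELSE.x.v1" = "OTHER")
  for (id in names(ids)) {
    model <- parse_archetype(make_archetype("item_1 existence matches {1..1}",
                                            archetype_id = id,
                                            root_type = "ITEM_TREE"))
    expect_equal(model$entry_type, unname(ids[id]), info = id)
  }
})

test_that("an empty definition body yields a model with zero constraint nodes", {
  adl <- paste(c(
    "archetype (adl_version=1.4)",
    "    openEHR-EHR-OBSERVATION.empty.v1",
    "",
    "definition",
    "    OBSERVATION[at0000] matches { }"
  ), collapse = "\n")
  model <- parse_archetype(adl)
  expect_equal(length(node_paths(model)), 0)
  expect_equal(nrow(extract_constraints(model)), 0)
})

test_that("malformed input fails fast with location information", {
  expect_error(parse_archetype("no sections here"), class = "dqr_structure_error")
  expect_error(
    parse_archetype(paste("archetype", "    openEHR-EHR-OBSERVATION.x.v1",
                          "concept", "    [at0000]", sep = "\n")),
    class = "dqr_structure_error"
  )
  bad <- make_archetype("meas_1 matches {|0..10|")   # unbalanced brace
  expect_error(parse_archetype(bad), class = "dqr_parse_error")
  bad2 <- make_archetype("meas_1 matches {@bogus}")
  err <- tryCatch(parse_archetype(bad2), error = function(e) conditionMessage(e))
  expect_match(err, "line [0-9]+", all = FALSE)
})

test_that("every constraint kind extracts with the expected keyword and payload", {
  adl <- make_archetype(c(
    "item_1 existence matches {1..1}",
    "note_2 existence matches {0..1}",
    "meas_3 matches {|0.5..99.5|}",
    "code_4 matches {[local::at0010, at0011]}",
    "class_5 matches {'Dr', 'Miss', 'Mrs', 'Mr'}",
    "method_6 matches {\"auscultation\"}",
    "q7 matches {",
    "    units matches {\"mm[Hg]\"}",
    "}",
    "occ_8 occurrences matches {1..1}",
    "list_9 cardinality matches {0..*; unique}",
    "list_10 cardinality matches {2..5}"
  ))
  cs <- extract_constraints(parse_archetype(adl))
  expect_equal(cs$keyword,
               c("EXISTENCE", "EXISTENCE", "MATCHES_RANGE", "DEFINING_CODE",
                 "MATCHES_VALUE", "MATCHES_VALUE", "MATCHES_UNITS",
                 "OCCURRENCES", "CARDINALITY", "CARDINALITY"))
  expect_equal(cs$payload[[4]]$codes, c("at0010", "at0011"))
  expect_equal(cs$payload[[5]]$values, c("Dr", "Miss", "Mrs", "Mr"))
  expect_equal(cs$payload[[6]]$value, "auscultation")
  expect_equal(cs$node_path[7], "/data/q7/units")
  expect_true(cs$payload[[9]]$unique_flag)
  expect_false(cs$payload[[10]]$unique_flag)
  expect_equal(c(cs$payload[[10]]$lower, cs$payload[[10]]$upper), c(2, 5))
  # document order is preserved
  expect_equal(cs$attribute_name[1:3], c("item_1", "note_2", "meas_3"))
})

test_that("interval micro-grammar handles bounds, exclusivity and flags", {
  iv <- parse_interval("|0.0..1000|")
  expect_equal(c(iv$lower, iv$upper), c(0, 1000))
  expect_true(iv$lower_included && iv$upper_included)

  # degenerate single-point interval
  iv0 <- parse_interval("|0..0|")
  expect_equal(c(iv0$lower, iv0$upper), c(0, 0))

  # exclusive bounds, checked against an independent string-scanning oracle
  raw <- "|>0..<1000|"
  nums <- as.numeric(regmatches(raw, gregexpr("[0-9]+(\\.[0-9]+)?", raw))[[1]])
  ivx <- parse_interval(raw)
  expect_equal(c(ivx$lower, ivx$upper), nums)
  expect_equal(grepl(">", raw, fixed = TRUE), !ivx$lower_included)
  expect_equal(grepl("<", raw, fixed = TRUE), !ivx$upper_included)

  # unbounded sides and flags
  expect_true(parse_interval("|..100|")$lower_unbounded)
  expect_true(parse_interval("|5..|")$upper_unbounded)
  expect_true(parse_interval("(0..*; unique)")$unique_flag)
  expect_true(parse_interval("(..unique)")$unique_flag)
  expect_true(parse_interval("(2..5)")$upper_included)

  # malformed intervals carry the raw text in the error
  expect_error(parse_interval("|17|"), class = "dqr_interval_error")
  expect_error(parse_interval("|a..b|"), class = "dqr_interval_error")
  expect_error(parse_interval("|9..1|"), class = "dqr_interval_error")
})

test_that("interval parsing is idempotent through canonical rendering", {
  cases <- c("|0.0..1000|", "|>0..<1000|", "|..100|", "|5..|",
             "(0..*; unique)", "(2..5)", "|0..0|")
  for (raw in cases) {
    iv <- parse_interval(raw)
    expect_equal(parse_interval(render_interval(iv)), iv, info = raw)
  }
})

test_that("constraints round-trip through canonical serialization", {
  adl <- make_archetype(c(
    "item_1 existence matches {1..1}",
    "meas_2 matches {|0..50|}",
    "code_3 matches {[local::at0010, at0011, at0012]}",
    "class_4 matches {'A', 'B', 'C'}",
    "occ_5 occurrences matches {1..1}"
  ))
  cs <- extract_constraints(parse_archetype(adl))
  rt <- extract_constraints(parse_archetype(constraints_to_adl(cs)))
  expect_equal(constraint_fields(rt)[c("node_path", "attribute_name",
                                       "keyword", "payload")],
               constraint_fields(cs)[c("node_path", "attribute_name",
                                       "keyword", "payload")])
  # serialization reaches a fixpoint
  expect_identical(constraints_to_adl(rt), constraints_to_adl(cs))
})

test_that("generated archetypes parse to the generator's ground truth", {
  for (seed in c(11, 12)) {
    bundle <- generate_bundle(synth_spec(seed = seed, rows_per_table = 20))
    for (i in seq_along(bundle$models)) {
      model <- bundle$models[[i]]
      cs <- extract_constraints(model)
      census <- bundle$ground_truth$constraint_census[[model$archetype_id]]
      got <- table(cs$keyword)
      expect_equal(as.integer(got[names(census)]), unname(census),
                   info = paste(seed, model$archetype_id))
      # every raw_text occurs verbatim in the emitted source
      src <- bundle$archetypes[[model$archetype_id]]
      for (raw in cs$raw_text) expect_true(grepl(raw, src, fixed = TRUE))
      # round-trip on generator output preserves the full constraint list
      rt <- extract_constraints(parse_archetype(constraints_to_adl(cs)))
      expect_equal(constraint_fields(rt)[c("node_path", "keyword", "payload")],
                   constraint_fields(cs)[c("node_path", "keyword", "payload")])
    }
  }
})
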