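# Shared helpers: tiny archetypes built in code and comparison utilities.

# A minimal archetype with one constraint clause per supplied line.
make_archetype <- function(clauses,
                           archetype_id = "openEHR-EHR-OBSERVATION.test_obs.v1",
                           root_type = "OBSERVATION") {
  paste(c(
    "archetype (adl_version=1.4)",
    paste0("    ", archetype_id),
    "",
    "concept",
    "    [at0000]",
    "",
    "definition",
    paste0("    ", root_type, "[at0000] matches {"),
    "        data[at0001] matches {",
    paste0("            ", clauses),
    "        }",
    "    }"
  ), collapse = "\n")
}

# Constraint-list equality on the semantically meaningful fields.
constraint_fields <- function(cs) {
  list(
    node_path = cs$node_path,
    attribute_name = cs$attribute_name,
    keyword = cs$keyword,
    payload = lapply(cs$payload, unclass),
    raw_text = cs$raw_text
  )
}

# Fresh dataset per test; callers must dq_disconnect().
worked_example_setup <- function() {
  wx <- fixture_worked_example()
  model <- parse_archetype(wx$adl)
  rules <- generate_rules(model, wx$mapping)
  ds <- dq_dataset(wx$tables, id = "worked_example")
  list(wx = wx, model = model, rules = rules, ds = ds)
}
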