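#' @title Packaged fixtures
#'
#' @description
#' Two small fixtures accompany the package: a minimal blood-pressure
#' archetype with its mapping and a three-row table (the canonical worked
#' example of turning a magnitude interval constraint into an executable
#' range rule), and the published per-dimension agreement/reference counts
#' of a full-scale evaluation of this approach against the CARSES
#' requirements, as machine-readable input for the coverage arithmetic.
#' @name fixtures
NULL

#' Blood-pressure worked example
#'
#' A diastolic blood-pressure magnitude constrained to the interval
#' `|0.0..1000.0|` with units `mm[Hg]`, mapped to table `blood_pressure`,
#' column `diastolic_blood_pressure_value` (units column
#' `diastolic_blood_pressure_units`), plus a three-row probe table with
#' values -5, 500 and 1500 -- of which exactly two violate the range rule.
#'
#' @return list with `adl` (archetype source), `mapping` (a
#'   `mapping_table`) and `tables` (named list with the `blood_pressure`
#'   data frame).
#' @export
fixture_worked_example <- function() {
  adl <- paste(c(
    "archetype (adl_version=1.4)",
    "    openEHR-EHR-OBSERVATION.blood_pressure.v1",
    "",
    "concept",
    "    [at0000]",
    "",
    "definition",
    "    OBSERVATION[at0000] matches {    -- Blood pressure",
    "        data[at0001] matches {",
    "            ELEMENT[at0004] matches {    -- Diastolic",
    "                value matches {",
    "                    magnitude matches {|0.0..1000.0|}",
    "                    units matches {\"mm[Hg]\"}",
    "                }",
    "            }",
    "        }",
    "    }",
    "",
    "ontology",
    "    term_definitions = <",
    "        [\"at0000\"] = <\"Blood pressure\">",
    "        [\"at0001\"] = <\"structure\">",
    "        [\"at0004\"] = <\"Diastolic\">",
    "    >"
  ), collapse = "\n")

  entries <- data.frame(
    archetype_id = rep("openEHR-EHR-OBSERVATION.blood_pressure.v1", 3),
    node_path = c("/data/Diastolic/value/magnitude",
                  "/data/Diastolic/value/units",
                  "/record_key"),
    table_name = rep("blood_pressure", 3),
    column_name = c("diastolic_blood_pressure_value",
                    "diastolic_blood_pressure_units",
                    "record_key"),
    role = c("VALUE", "UNITS", "KEY"),
    stringsAsFactors = FALSE
  )

  tables <- list(blood_pressure = data.frame(
    record_key = 1:3,
    diastolic_blood_pressure_value = c(-5, 500, 1500),
    diastolic_blood_pressure_units = rep("mm[Hg]", 3),
    stringsAsFactors = FALSE
  ))

  list(adl = adl, mapping = mapping_table(entries), tables = tables)
}

#' Published per-dimension agreement and reference counts
#'
#' The machine-readable counts of a full-scale evaluation of automatically
#' created rules against 366 expert-created rules covering the CARSES
#' requirements: per-dimension agreement/reference pairs (completeness
#' 208/212, conformity 47/87, consistency 45/45, timeliness 11/22; overall
#' 311/366) and the composition of the 359 generated rules (208
#' completeness, 47 conformity, 61 consistency, 11 timeliness, 32 matching
#' no dimension of the standard).
#'
#' @return list with `coverage_counts` (data frame `dimension`, `n_agree`,
#'   `n_expert`), `auto_tally` and `expert_tally` (named count vectors).
#' @export
fixture_table6 <- function() {
  list(
    coverage_counts = data.frame(
      dimension = c("COMPLETENESS", "CONFORMITY", "CONSISTENCY", "TIMELINESS"),
      n_agree = c(208L, 47L, 45L, 11L),
      n_expert = c(212L, 87L, 45L, 22L),
      stringsAsFactors = FALSE
    ),
    auto_tally = c(COMPLETENESS = 208, CONFORMITY = 47, CONSISTENCY = 61,
                   TIMELINESS = 11, UNMATCHED = 32),
    expert_tally = c(COMPLETENESS = 212, CONFORMITY = 87, CONSISTENCY = 45,
                     TIMELINESS = 22)
  )
}
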