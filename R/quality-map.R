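#' @title Quality-keyword registry: Kahn sub-dimensions and rule templates
#'
#' @description
#' Five ADL keywords carry data-quality knowledge: `cardinality`,
#' `occurrences`, `existence`, `defining_code` and `matches` (the last split
#' here by payload into range, value/value-set and units constraints). Each
#' maps to a sub-dimension of Kahn's harmonized data-quality framework and
#' to an SQL rule template whose returned rows are violations. One
#' reference-model feature adds a further template: the Entry classes
#' (INSTRUCTION, ACTION, OBSERVATION, ...) encode the stage of a clinical
#' event, so a declared ordering of Entry types yields a
#' temporal-plausibility template (request time must not follow execution
#' time). Computational conformance and atemporal plausibility have no
#' generating keyword and can only appear on externally supplied rules.
#' @name quality-map
NULL

#' Closed enumerations used throughout the package
#'
#' @return character vector of the enumeration's levels.
#' @export
kahn_subdimensions <- function() {
  c("VALUE_CONFORMANCE", "RELATIONAL_CONFORMANCE", "COMPUTATIONAL_CONFORMANCE",
    "COMPLETENESS", "UNIQUENESS_PLAUSIBILITY", "ATEMPORAL_PLAUSIBILITY",
    "TEMPORAL_PLAUSIBILITY")
}

#' @rdname kahn_subdimensions
#' @export
carses_dimensions <- function() {
  c("COMPLETENESS", "CONSISTENCY", "TIMELINESS", "CONFORMITY", "UNMATCHED")
}

#' @rdname kahn_subdimensions
#' @export
constraint_keywords <- function() {
  c("CARDINALITY", "OCCURRENCES", "EXISTENCE", "DEFINING_CODE",
    "MATCHES_VALUE", "MATCHES_RANGE", "MATCHES_UNITS")
}

#' @rdname kahn_subdimensions
#' @export
entry_types <- function() {
  c("ADMIN_ENTRY", "OBSERVATION", "EVALUATION", "INSTRUCTION", "ACTION",
    "DEMOGRAPHIC", "CLUSTER", "OTHER")
}

new_rule_template <- function(template_id, keyword, kahn_subdimension, skeleton) {
  structure(
    list(
      template_id = template_id,
      keyword = keyword,
      kahn_subdimension = kahn_subdimension,
      skeleton = skeleton,
      violation_semantics = "returned rows violate the constraint"
    ),
    class = "rule_template"
  )
}

# The fixed registry. Skeleton placeholders: {table}, {column}, {columns},
# {key}, {predicate}, {codeset}, {link}. Every skeleton holds exactly one
# SELECT; rows returned are violations.
template_registry <- function() {
  list(
    existence_not_empty = new_rule_template(
      "existence_not_empty", "EXISTENCE", "COMPLETENESS",
      "SELECT {column} FROM {table} WHERE {predicate}"
    ),
    occurrences_count = new_rule_template(
      "occurrences_count", "OCCURRENCES", "RELATIONAL_CONFORMANCE",
      "SELECT {key} FROM {table} GROUP BY {key} HAVING {predicate}"
    ),
    cardinality_bounds = new_rule_template(
      "cardinality_bounds", "CARDINALITY", "RELATIONAL_CONFORMANCE",
      "SELECT {key} FROM {table} GROUP BY {key} HAVING {predicate}"
    ),
    cardinality_unique = new_rule_template(
      "cardinality_unique", "CARDINALITY", "UNIQUENESS_PLAUSIBILITY",
      "SELECT {key}, {column} FROM {table} WHERE {column} IS NOT NULL GROUP BY {key}, {column} HAVING COUNT(*) > 1"
    ),
    code_not_in_set = new_rule_template(
      "code_not_in_set", "DEFINING_CODE", "VALUE_CONFORMANCE",
      "SELECT {column} FROM {table} WHERE {predicate}"
    ),
    value_not_in_set = new_rule_template(
      "value_not_in_set", "MATCHES_VALUE", "VALUE_CONFORMANCE",
      "SELECT {column} FROM {table} WHERE {predicate}"
    ),
    value_not_equal = new_rule_template(
      "value_not_equal", "MATCHES_VALUE", "VALUE_CONFORMANCE",
      "SELECT {column} FROM {table} WHERE {predicate}"
    ),
    range_out_of_bounds = new_rule_template(
      "range_out_of_bounds", "MATCHES_RANGE", "VALUE_CONFORMANCE",
      "SELECT {column} FROM {table} WHERE {predicate}"
    ),
    units_not_equal = new_rule_template(
      "units_not_equal", "MATCHES_UNITS", "VALUE_CONFORMANCE",
      "SELECT {column} FROM {table} WHERE {predicate}"
    ),
    temporal_order = new_rule_template(
      "temporal_order", "TEMPORAL_PAIR", "TEMPORAL_PLAUSIBILITY",
      "SELECT e.{earlier_time}, l.{later_time} FROM {earlier_table} e JOIN {later_table} l ON {link} WHERE e.{earlier_time} > l.{later_time}"
    )
  )
}

#' Classify a constraint against Kahn's data-quality framework
#'
#' Mandatory-or-optional existence maps to completeness; occurrences and
#' count-bounded cardinality to relational conformance; uniqueness-flagged
#' cardinality to uniqueness plausibility; code sets, value sets/literals,
#' ranges and units to value conformance.
#'
#' @param constraint one row of a `dqr_constraints` data frame (a data frame
#'   with one row, or a list with `keyword` and `payload`).
#' @return a Kahn sub-dimension name (see [kahn_subdimensions()]).
#' @export
classify_constraint <- function(constraint) {
  c <- as_constraint_row(constraint)
  kw <- c$keyword
  if (!kw %in% constraint_keywords()) {
    stop_dqr("unknown constraint keyword: ", kw, class = "dqr_classify_error")
  }
  switch(kw,
    EXISTENCE = "COMPLETENESS",
    OCCURRENCES = "RELATIONAL_CONFORMANCE",
    CARDINALITY = if (isTRUE(c$payload$unique_flag)) "UNIQUENESS_PLAUSIBILITY"
                  else "RELATIONAL_CONFORMANCE",
    DEFINING_CODE = ,
    MATCHES_VALUE = ,
    MATCHES_RANGE = ,
    MATCHES_UNITS = "VALUE_CONFORMANCE"
  )
}

as_constraint_row <- function(constraint) {
  if (is.data.frame(constraint)) {
    stopifnot(nrow(constraint) == 1)
    list(
      keyword = constraint$keyword[[1]],
      payload = constraint$payload[[1]],
      attribute_name = if ("attribute_name" %in% names(constraint))
        constraint$attribute_name[[1]] else NA_character_,
      archetype_id = if ("archetype_id" %in% names(constraint))
        constraint$archetype_id[[1]] else NA_character_,
      node_path = if ("node_path" %in% names(constraint))
        constraint$node_path[[1]] else NA_character_,
      raw_text = if ("raw_text" %in% names(constraint))
        constraint$raw_text[[1]] else NA_character_
    )
  } else {
    constraint
  }
}

#' Select the rule template for a constraint
#'
#' Returns the unique registry template for the keyword/payload combination,
#' or `NULL` when the constraint generates no rule: optional existence
#' (`0..1`) expresses no requirement, and an interval with no finite bound
#' (e.g. occurrences `0..*` without a uniqueness flag) has no violating
#' condition.
#'
#' @inheritParams classify_constraint
#' @return a `rule_template` or `NULL`.
#' @export
select_template <- function(constraint) {
  c <- as_constraint_row(constraint)
  reg <- template_registry()
  switch(c$keyword,
    EXISTENCE = {
      iv <- c$payload
      mandatory <- !iv$lower_unbounded && iv$lower >= 1
      if (mandatory) reg$existence_not_empty else NULL
    },
    OCCURRENCES = {
      if (occurrence_bounds_vacuous(c$payload)) NULL else reg$occurrences_count
    },
    CARDINALITY = {
      if (isTRUE(c$payload$unique_flag)) reg$cardinality_unique
      else if (occurrence_bounds_vacuous(c$payload)) NULL
      else reg$cardinality_bounds
    },
    DEFINING_CODE = reg$code_not_in_set,
    MATCHES_VALUE = {
      if (inherits(c$payload, "adl_valueset")) reg$value_not_in_set
      else reg$value_not_equal
    },
    MATCHES_RANGE = {
      if (c$payload$lower_unbounded && c$payload$upper_unbounded) NULL
      else reg$range_out_of_bounds
    },
    MATCHES_UNITS = reg$units_not_equal,
    stop_dqr("unknown constraint keyword: ", c$keyword,
             class = "dqr_classify_error")
  )
}

# Count bounds admit every group size >= 0: nothing to check.
occurrence_bounds_vacuous <- function(iv) {
  lower_free <- iv$lower_unbounded || iv$lower <= 0
  upper_free <- iv$upper_unbounded
  lower_free && upper_free
}

#' Default ordering of Entry types within a clinical event
#'
#' A clinical event moves through the Entry classes of the reference model:
#' an INSTRUCTION (request) precedes the ACTION that executes it and the
#' OBSERVATION that records its result. Each declared pair yields a
#' temporal-plausibility rule.
#'
#' @return data frame with columns `earlier`, `later`.
#' @export
default_temporal_pairs <- function() {
  data.frame(
    earlier = c("INSTRUCTION", "INSTRUCTION"),
    later = c("ACTION", "OBSERVATION"),
    stringsAsFactors = FALSE
  )
}

#' Temporal-plausibility template for an Entry-type ordering
#'
#' @param earlier,later Entry type names (see [entry_types()]).
#' @param pairs declared orderings, a data frame with columns
#'   `earlier`/`later`; defaults to [default_temporal_pairs()].
#' @return the `temporal_order` `rule_template`.
#' @export
temporal_pair_template <- function(earlier, later, pairs = default_temporal_pairs()) {
  stopifnot(is.data.frame(pairs), all(c("earlier", "later") %in% names(pairs)))
  declared <- any(pairs$earlier == earlier & pairs$later == later)
  if (!declared) {
    stop_dqr("undeclared temporal pair: (", earlier, ", ", later, ")",
             class = "dqr_config_error")
  }
  template_registry()$temporal_order
}

#' Default crosswalk from Kahn sub-dimensions to CARSES dimensions
#'
#' CARSES (the Chinese Application-Level Ranking Standard for EHR Systems)
#' states quality requirements over four dimensions: completeness,
#' consistency, timeliness and conformity. The crosswalk is configuration,
#' not code: alternative assessment standards can remap. The default sends
#' completeness to completeness, terminology-code conformance to
#' consistency, range/value/units conformance to conformity, temporal
#' plausibility to timeliness, and the relational-conformance /
#' uniqueness-plausibility rules (which CARSES does not address) to
#' UNMATCHED.
#'
#' @return a data frame with columns `kahn_subdimension`, `payload_kind`
#'   (`"*"` for any) and `carses_dimension`.
#' @export
default_crosswalk <- function() {
  data.frame(
    kahn_subdimension = c(
      "COMPLETENESS",
      "VALUE_CONFORMANCE", "VALUE_CONFORMANCE",
      "TEMPORAL_PLAUSIBILITY",
      "RELATIONAL_CONFORMANCE", "UNIQUENESS_PLAUSIBILITY",
      "COMPUTATIONAL_CONFORMANCE", "ATEMPORAL_PLAUSIBILITY"
    ),
    payload_kind = c("*", "codeset", "*", "*", "*", "*", "*", "*"),
    carses_dimension = c(
      "COMPLETENESS", "CONSISTENCY", "CONFORMITY", "TIMELINESS",
      "UNMATCHED", "UNMATCHED", "UNMATCHED", "UNMATCHED"
    ),
    stringsAsFactors = FALSE
  )
}

payload_kind_of <- function(payload) {
  if (is.null(payload)) return("none")
  if (inherits(payload, "adl_interval")) "interval"
  else if (inherits(payload, "adl_codeset")) "codeset"
  else if (inherits(payload, "adl_valueset")) "valueset"
  else if (inherits(payload, "adl_literal")) "literal"
  else "none"
}

#' Map a Kahn sub-dimension (plus constraint payload) to a CARSES dimension
#'
#' @param kahn a Kahn sub-dimension name.
#' @param constraint the generating constraint (or `NULL` for externally
#'   supplied rules); only its payload kind matters.
#' @param crosswalk crosswalk table, defaults to [default_crosswalk()].
#'   Specific payload-kind rows take precedence over `"*"` rows.
#' @return a CARSES dimension name.
#' @export
crosswalk_to_carses <- function(kahn, constraint = NULL,
                                crosswalk = default_crosswalk()) {
  pk <- if (is.null(constraint)) "none"
        else payload_kind_of(as_constraint_row(constraint)$payload)
  hits <- crosswalk[crosswalk$kahn_subdimension == kahn, , drop = FALSE]
  if (!nrow(hits)) return("UNMATCHED")
  exact <- hits[hits$payload_kind == pk, , drop = FALSE]
  if (nrow(exact)) return(exact$carses_dimension[1])
  star <- hits[hits$payload_kind == "*", , drop = FALSE]
  if (nrow(star)) return(star$carses_dimension[1])
  "UNMATCHED"
}

#' Read / write a crosswalk configuration
#'
#' @param path YAML file with a `crosswalk:` list of
#'   `{kahn, payload_kind, carses}` entries.
#' @return crosswalk data frame (see [default_crosswalk()]).
#' @export
read_crosswalk <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$crosswalk %||% cfg
  data.frame(
    kahn_subdimension = vapply(entries, function(e) e$kahn, ""),
    payload_kind = vapply(entries, function(e) e$payload_kind %||% "*", ""),
    carses_dimension = vapply(entries, function(e) e$carses, ""),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_crosswalk
#' @param crosswalk crosswalk data frame to write.
#' @export
write_crosswalk <- function(crosswalk, path) {
  entries <- lapply(seq_len(nrow(crosswalk)), function(i) {
    list(kahn = crosswalk$kahn_subdimension[i],
         payload_kind = crosswalk$payload_kind[i],
         carses = crosswalk$carses_dimension[i])
  })
  yaml::write_yaml(list(crosswalk = entries), path)
  invisible(path)
}
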