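#' @title Seeded synthetic archetype/data bundles with labeled defects
#'
#' @description
#' The generator emulates an archetype-based clinical data repository at
#' desk scale: it emits archetypes in the supported ADL subset, the mapping
#' that binds every constrained attribute to a table/column, relational
#' tables whose clean values satisfy every constraint, and a ground truth of
#' injected quality defects. Defects are mutually non-overlapping per cell
#' (and per join pair), so per-class injected counts are exactly the
#' violation counts the generated rules must recover. Value distributions
#' are deliberately simple -- uniform within bounds, defects uniform in a
#' margin beyond the violated bound -- since only the constraint logic, not
#' clinical realism, is under test.
#' @name synthdata
NULL

DEFECT_CLASSES <- c("MISSING", "OUT_OF_RANGE", "BAD_CODE", "BAD_UNITS",
                    "DUPLICATE_KEY", "EXTRA_OCCURRENCE", "TEMPORAL_INVERSION")

#' Specification of a synthetic bundle
#'
#' @param n_archetypes number of archetypes (tables). With the default 3,
#'   the first two form a linked INSTRUCTION/ACTION pair so every template
#'   class (including temporal plausibility) is exercised.
#' @param constraints_per_archetype constraints per archetype (minimum 4;
#'   the guaranteed kinds are distributed first, seeded draws pad the rest).
#' @param rows_per_table rows per table before defect injection.
#' @param defect_rates named vector of per-class injection probabilities
#'   (classes: `r paste(DEFECT_CLASSES, collapse=", ")`).
#' @param keyword_mix weights over the padding constraint keywords
#'   (EXISTENCE, MATCHES_RANGE, DEFINING_CODE, MATCHES_VALUE, MATCHES_UNITS).
#' @param seed integer seed; together with the other fields it fully
#'   determines every emitted byte.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_archetypes = 3,
                       constraints_per_archetype = 8,
                       rows_per_table = 300,
                       defect_rates = c(MISSING = 0.03, OUT_OF_RANGE = 0.03,
                                        BAD_CODE = 0.02, BAD_UNITS = 0.02,
                                        DUPLICATE_KEY = 0.01,
                                        EXTRA_OCCURRENCE = 0.01,
                                        TEMPORAL_INVERSION = 0.02),
                       keyword_mix = c(EXISTENCE = 0.35, MATCHES_RANGE = 0.25,
                                       DEFINING_CODE = 0.15,
                                       MATCHES_VALUE = 0.15,
                                       MATCHES_UNITS = 0.10),
                       seed = 1L) {
  rates <- c(MISSING = 0, OUT_OF_RANGE = 0, BAD_CODE = 0, BAD_UNITS = 0,
             DUPLICATE_KEY = 0, EXTRA_OCCURRENCE = 0, TEMPORAL_INVERSION = 0)
  rates[names(defect_rates)] <- defect_rates
  if (any(rates < 0 | rates > 1)) {
    stop_dqr("defect rates must lie in [0, 1]", class = "dqr_spec_error")
  }
  if (n_archetypes < 1 || constraints_per_archetype < 4 || rows_per_table < 10) {
    stop_dqr("infeasible synthetic spec", class = "dqr_spec_error")
  }
  structure(
    list(n_archetypes = as.integer(n_archetypes),
         constraints_per_archetype = as.integer(constraints_per_archetype),
         rows_per_table = as.integer(rows_per_table),
         defect_rates = rates,
         keyword_mix = keyword_mix / sum(keyword_mix),
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Constraint kinds the generator can emit. "Group" kinds (counted per key)
# are limited to one per table so that row-adding defect classes stay
# non-overlapping.
SYNTH_GROUP_KINDS <- c("occurrences", "cardinality_bounds", "cardinality_unique")
SYNTH_CELL_KINDS <- c("existence", "existence_optional", "range", "code",
                      "valueset", "literal", "units")

synth_entry_types <- function(n) {
  base <- c("INSTRUCTION", "ACTION", "OBSERVATION")
  extra <- c("EVALUATION", "ADMIN_ENTRY", "OBSERVATION", "CLUSTER")
  if (n <= 3) base[seq_len(n)]
  else c(base, extra[((seq_len(n - 3) - 1) %% length(extra)) + 1])
}

# Deterministic constraint plan: guaranteed kinds round-robin, then seeded
# padding from the keyword mix.
synth_plan <- function(spec) {
  n <- spec$n_archetypes
  plans <- rep(list(character(0)), n)
  for (i in seq_along(SYNTH_CELL_KINDS)) {
    a <- ((i - 1) %% n) + 1
    plans[[a]] <- c(plans[[a]], SYNTH_CELL_KINDS[i])
  }
  for (i in seq_len(min(n, length(SYNTH_GROUP_KINDS)))) {
    plans[[i]] <- c(plans[[i]], SYNTH_GROUP_KINDS[i])
  }
  pad_kinds <- c(EXISTENCE = "existence", MATCHES_RANGE = "range",
                 DEFINING_CODE = "code", MATCHES_VALUE = "valueset",
                 MATCHES_UNITS = "units")
  mix <- spec$keyword_mix[names(pad_kinds)]
  mix[is.na(mix)] <- 0
  for (a in seq_len(n)) {
    while (length(plans[[a]]) < spec$constraints_per_archetype) {
      kw <- sample(names(pad_kinds), 1, prob = mix)
      plans[[a]] <- c(plans[[a]], pad_kinds[[kw]])
    }
    plans[[a]] <- plans[[a]][seq_len(spec$constraints_per_archetype)]
  }
  plans
}

synth_codesets <- function(k) sprintf("at%04d", 10 + seq_len(k))

# Build one archetype's constraint inventory: attribute names, payload
# parameters, canonical clause text, node paths, column names.
synth_archetype_plan <- function(kinds, arch_index) {
  rows <- list()
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    attr <- switch(kind,
      existence = sprintf("item_%02d", i),
      existence_optional = sprintf("note_%02d", i),
      range = sprintf("meas_%02d", i),
      code = sprintf("code_%02d", i),
      valueset = sprintf("class_%02d", i),
      literal = sprintf("method_%02d", i),
      units = sprintf("qty_%02d", i),
      occurrences = sprintf("occ_%02d", i),
      cardinality_bounds = sprintf("list_%02d", i),
      cardinality_unique = sprintf("uniq_%02d", i)
    )
    params <- switch(kind,
      existence = list(interval = "1..1"),
      existence_optional = list(interval = "0..1"),
      range = {
        lo <- (arch_index - 1) * 10
        hi <- lo + 100 + i
        list(lower = lo, upper = hi)
      },
      code = list(terminology = "local", codes = synth_codesets(3 + (i %% 3))),
      valueset = list(values = c("A", "B", "C", "D")[seq_len(3 + (i %% 2))]),
      literal = list(value = sprintf("method_%d", arch_index)),
      units = list(value = c("mm[Hg]", "mg", "mmol/l", "/min")[((i - 1) %% 4) + 1]),
      occurrences = list(interval = "1..1"),
      cardinality_bounds = list(lower = 0, upper = 2),
      cardinality_unique = list()
    )
    node_path <- if (kind == "units") paste0("/data/", attr, "/units")
                 else paste0("/data/", attr)
    column <- if (kind == "units") paste0(attr, "_units") else attr
    rows[[i]] <- list(kind = kind, attr = attr, node_path = node_path,
                      column = column, params = params)
  }
  rows
}

synth_clause_text <- function(item) {
  p <- item$params
  switch(item$kind,
    existence = paste0(item$attr, " existence matches {", p$interval, "}"),
    existence_optional = paste0(item$attr, " existence matches {", p$interval, "}"),
    range = paste0(item$attr, " matches {|",
                   format_num(p$lower), "..", format_num(p$upper), "|}"),
    code = paste0(item$attr, " matches {[", p$terminology, "::",
                  paste(p$codes, collapse = ", "), "]}"),
    valueset = paste0(item$attr, " matches {",
                      paste(paste0("'", p$values, "'"), collapse = ", "), "}"),
    literal = paste0(item$attr, " matches {\"", p$value, "\"}"),
    units = paste0(item$attr, " matches {\n                units matches {\"",
                   p$value, "\"}\n            }"),
    occurrences = paste0(item$attr, " occurrences matches {", p$interval, "}"),
    cardinality_bounds = paste0(item$attr, " cardinality matches {",
                                format_num(p$lower), "..",
                                format_num(p$upper), "}"),
    cardinality_unique = paste0(item$attr, " cardinality matches {0..*; unique}")
  )
}

synth_adl_text <- function(archetype_id, concept, entry_type, items) {
  root_type <- if (entry_type %in% c("DEMOGRAPHIC", "OTHER")) "ITEM_TREE" else entry_type
  clauses <- vapply(items, synth_clause_text, "")
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
    "    }",
    "",
    "ontology",
    "    term_definitions = <",
    paste0("        [\"at0000\"] = <\"", concept, "\">"),
    "    >"
  ), collapse = "\n")
}

#' Generate a synthetic archetype/mapping/data bundle
#'
#' @param spec a [synth_spec()].
#' @return object of class `synth_bundle`: list with `archetypes` (named
#'   character vector of ADL sources), `models` (parsed archetypes),
#'   `mapping` (a `mapping_table` resolving every constraint), `tables`
#'   (named list of data frames with injected defects), `ground_truth`
#'   (list: `defects` data frame `(table, row_key, column, defect_class)`,
#'   `census` per-class tallies, `constraint_census` per-keyword counts per
#'   archetype), and the `spec`.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)

  n_arch <- spec$n_archetypes
  n_rows <- spec$rows_per_table
  entry_types <- synth_entry_types(n_arch)
  plans <- synth_plan(spec)

  concepts <- sprintf("synthetic_%s_%d", tolower(entry_types), seq_len(n_arch))
  archetype_ids <- sprintf("openEHR-EHR-%s.%s.v1", entry_types, concepts)
  table_names <- concepts

  archetypes <- character(0)
  map_entries <- list()
  tables <- list()
  defects <- list()
  constraint_census <- list()

  add_defect <- function(table, row_key, column, class) {
    defects[[length(defects) + 1L]] <<- data.frame(
      table = table, row_key = row_key, column = column,
      defect_class = class, stringsAsFactors = FALSE
    )
  }

  # Temporal link between the first two archetypes (INSTRUCTION -> ACTION).
  has_link <- n_arch >= 2 && entry_types[1] == "INSTRUCTION" &&
    entry_types[2] == "ACTION"
  inverted_keys <- integer(0)
  if (has_link) {
    k <- stats::rbinom(1, n_rows, spec$defect_rates[["TEMPORAL_INVERSION"]])
    inverted_keys <- sort(sample.int(n_rows, k))
  }
  # times shared between the two linked tables
  base_minutes <- cumsum(5 + sample.int(30, n_rows, replace = TRUE))
  delta_minutes <- 1 + sample.int(120, n_rows, replace = TRUE)
  origin <- as.POSIXct("2024-01-01 06:00:00", tz = "UTC")
  fmt_time <- function(mins) format(origin + mins * 60, "%Y-%m-%d %H:%M:%S")
  request_time <- fmt_time(base_minutes)
  execution_time <- fmt_time(base_minutes + delta_minutes)
  if (length(inverted_keys)) {
    tmp <- request_time[inverted_keys]
    request_time[inverted_keys] <- execution_time[inverted_keys]
    execution_time[inverted_keys] <- tmp
    for (key in inverted_keys) {
      add_defect(table_names[1], key, "request_time", "TEMPORAL_INVERSION")
    }
  }

  for (a in seq_len(n_arch)) {
    items <- synth_archetype_plan(plans[[a]], a)
    archetypes[archetype_ids[a]] <- synth_adl_text(
      archetype_ids[a], concepts[a], entry_types[a], items
    )

    kw_of_kind <- c(existence = "EXISTENCE", existence_optional = "EXISTENCE",
                    range = "MATCHES_RANGE", code = "DEFINING_CODE",
                    valueset = "MATCHES_VALUE", literal = "MATCHES_VALUE",
                    units = "MATCHES_UNITS", occurrences = "OCCURRENCES",
                    cardinality_bounds = "CARDINALITY",
                    cardinality_unique = "CARDINALITY")
    census_kw <- table(kw_of_kind[plans[[a]]])
    constraint_census[[archetype_ids[a]]] <-
      stats::setNames(as.integer(census_kw), names(census_kw))

    # mapping: KEY + one entry per constrained attribute
    map_entries[[length(map_entries) + 1L]] <- data.frame(
      archetype_id = archetype_ids[a], node_path = "/record_key",
      table_name = table_names[a], column_name = "record_key", role = "KEY",
      stringsAsFactors = FALSE
    )
    for (item in items) {
      role <- switch(item$kind, code = "CODE", units = "UNITS", "VALUE")
      map_entries[[length(map_entries) + 1L]] <- data.frame(
        archetype_id = archetype_ids[a], node_path = item$node_path,
        table_name = table_names[a], column_name = item$column, role = role,
        stringsAsFactors = FALSE
      )
    }

    # clean table
    df <- data.frame(record_key = seq_len(n_rows))
    for (item in items) {
      p <- item$params
      df[[item$column]] <- switch(item$kind,
        existence = ,
        existence_optional = sprintf("v%05d", sample.int(99999, n_rows, replace = TRUE)),
        range = round(stats::runif(n_rows, p$lower, p$upper), 2),
        code = sample(p$codes, n_rows, replace = TRUE),
        valueset = sample(p$values, n_rows, replace = TRUE),
        literal = rep(p$value, n_rows),
        units = rep(p$value, n_rows),
        occurrences = sprintf("o%05d", sample.int(99999, n_rows, replace = TRUE)),
        cardinality_bounds = sprintf("m%05d", sample.int(99999, n_rows, replace = TRUE)),
        cardinality_unique = sprintf("u_%d_%06d", a, seq_len(n_rows))
      )
    }
    if (a == 1 && has_link) df$request_time <- request_time
    if (a == 2 && has_link) df$execution_time <- execution_time

    # keys eligible for row-adding defects: keep clear of temporal inversions
    reserved <- if (a <= 2 && has_link) inverted_keys else integer(0)
    free_keys <- setdiff(seq_len(n_rows), reserved)

    group_cols <- vapply(
      items[vapply(items, function(x) x$kind %in% SYNTH_GROUP_KINDS, TRUE)],
      function(x) x$column, ""
    )

    extra_rows <- list()
    # Added rows are clean everywhere except the target group column, so the
    # injection is visible to exactly one rule: non-target group columns are
    # NULL (not counted), cell columns get fresh in-constraint values, and
    # timestamps are copied from the (non-inverted) base key.
    make_added_row <- function(base_key, target_item, same_value) {
      row <- df[df$record_key == base_key, , drop = FALSE][1, , drop = FALSE]
      for (item in items) {
        if (item$column == target_item$column) next
        p <- item$params
        row[[item$column]] <- if (item$column %in% group_cols) NA else
          switch(item$kind,
            existence = ,
            existence_optional = sprintf("v%05d", sample.int(99999, 1)),
            range = round((p$lower + p$upper) / 2, 2),
            code = p$codes[1],
            valueset = p$values[1],
            literal = p$value,
            units = p$value,
            NA
          )
      }
      if (!same_value) {
        # fresh member for the target group column (extra occurrence)
        row[[target_item$column]] <- switch(target_item$kind,
          occurrences = sprintf("o_add_%05d", sample.int(99999, 1)),
          cardinality_bounds = sprintf("m_add_%05d", sample.int(99999, 1)),
          cardinality_unique = sprintf("u_add_%05d", sample.int(99999, 1))
        )
      }
      row
    }

    for (item in items) {
      p <- item$params
      if (item$kind %in% c("existence")) {
        k <- stats::rbinom(1, n_rows, spec$defect_rates[["MISSING"]])
        if (k > 0) {
          idx <- sort(sample.int(n_rows, k))
          empty_as_blank <- stats::runif(k) < 0.5
          df[[item$column]][idx] <- ifelse(empty_as_blank, "", NA)
          for (key in idx) add_defect(table_names[a], key, item$column, "MISSING")
        }
      } else if (item$kind == "range") {
        k <- stats::rbinom(1, n_rows, spec$defect_rates[["OUT_OF_RANGE"]])
        if (k > 0) {
          idx <- sort(sample.int(n_rows, k))
          margin <- (p$upper - p$lower) * 0.5
          above <- stats::runif(k) < 0.5
          vals <- ifelse(above,
                         round(p$upper + 0.01 + stats::runif(k, 0, margin), 2),
                         round(p$lower - 0.01 - stats::runif(k, 0, margin), 2))
          df[[item$column]][idx] <- vals
          for (key in idx) add_defect(table_names[a], key, item$column, "OUT_OF_RANGE")
        }
      } else if (item$kind == "code") {
        k <- stats::rbinom(1, n_rows, spec$defect_rates[["BAD_CODE"]])
        if (k > 0) {
          idx <- sort(sample.int(n_rows, k))
          df[[item$column]][idx] <- sprintf("bad%04d", sample.int(9999, k, replace = TRUE))
          for (key in idx) add_defect(table_names[a], key, item$column, "BAD_CODE")
        }
      } else if (item$kind == "units") {
        k <- stats::rbinom(1, n_rows, spec$defect_rates[["BAD_UNITS"]])
        if (k > 0) {
          idx <- sort(sample.int(n_rows, k))
          df[[item$column]][idx] <- "unknown_unit"
          for (key in idx) add_defect(table_names[a], key, item$column, "BAD_UNITS")
        }
      } else if (item$kind %in% c("occurrences", "cardinality_bounds")) {
        k <- stats::rbinom(1, length(free_keys),
                           spec$defect_rates[["EXTRA_OCCURRENCE"]])
        if (k > 0) {
          keys <- sort(free_keys[sample.int(length(free_keys), k)])
          free_keys <- setdiff(free_keys, keys)
          n_extra <- if (item$kind == "occurrences") 1L else as.integer(p$upper)
          for (key in keys) {
            for (r in seq_len(n_extra)) {
              extra_rows[[length(extra_rows) + 1L]] <-
                make_added_row(key, item, same_value = FALSE)
            }
            add_defect(table_names[a], key, item$column, "EXTRA_OCCURRENCE")
          }
        }
      } else if (item$kind == "cardinality_unique") {
        k <- stats::rbinom(1, length(free_keys),
                           spec$defect_rates[["DUPLICATE_KEY"]])
        if (k > 0) {
          keys <- sort(free_keys[sample.int(length(free_keys), k)])
          free_keys <- setdiff(free_keys, keys)
          for (key in keys) {
            extra_rows[[length(extra_rows) + 1L]] <-
              make_added_row(key, item, same_value = TRUE)
            add_defect(table_names[a], key, item$column, "DUPLICATE_KEY")
          }
        }
      }
    }

    if (length(extra_rows)) df <- rbind(df, do.call(rbind, extra_rows))
    df <- df[order(df$record_key), , drop = FALSE]
    rownames(df) <- NULL
    tables[[table_names[a]]] <- df
  }

  links <- list()
  if (has_link) {
    links <- list(list(
      earlier_table = table_names[1], earlier_time_column = "request_time",
      later_table = table_names[2], later_time_column = "execution_time",
      join_pairs = list(c("record_key", "record_key")),
      earlier_entry_type = "INSTRUCTION", later_entry_type = "ACTION"
    ))
    map_entries[[length(map_entries) + 1L]] <- data.frame(
      archetype_id = archetype_ids[1], node_path = "/time",
      table_name = table_names[1], column_name = "request_time", role = "TIME",
      stringsAsFactors = FALSE
    )
    map_entries[[length(map_entries) + 1L]] <- data.frame(
      archetype_id = archetype_ids[2], node_path = "/time",
      table_name = table_names[2], column_name = "execution_time", role = "TIME",
      stringsAsFactors = FALSE
    )
  }

  mapping <- mapping_table(do.call(rbind, map_entries), links)
  defects_df <- if (length(defects)) do.call(rbind, defects) else data.frame(
    table = character(0), row_key = integer(0), column = character(0),
    defect_class = character(0), stringsAsFactors = FALSE
  )
  census <- stats::setNames(
    vapply(DEFECT_CLASSES, function(cl) sum(defects_df$defect_class == cl), 0L),
    DEFECT_CLASSES
  )

  models <- lapply(archetypes, parse_archetype)

  structure(
    list(archetypes = archetypes, models = unname(models), mapping = mapping,
         tables = tables,
         ground_truth = list(defects = defects_df, census = census,
                             constraint_census = constraint_census),
         spec = spec),
    class = "synth_bundle"
  )
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("<synth_bundle> seed ", x$spec$seed, ": ", length(x$archetypes),
      " archetype(s), ", length(x$tables), " table(s), ",
      nrow(x$ground_truth$defects), " injected defect(s)\n", sep = "")
  invisible(x)
}

#' Expected violation count per generated rule
#'
#' Joins a rule set to the bundle's ground truth: every rule kind recovers
#' one defect class (completeness -> MISSING, range -> OUT_OF_RANGE, code ->
#' BAD_CODE, units -> BAD_UNITS, occurrences/cardinality counts ->
#' EXTRA_OCCURRENCE, uniqueness -> DUPLICATE_KEY, temporal ->
#' TEMPORAL_INVERSION); value-set/literal rules have no injected class and
#' expect zero.
#'
#' @param bundle a `synth_bundle`.
#' @param rules rules generated from the bundle.
#' @return data frame `(rule_id, defect_class, expected)`.
#' @export
expected_rule_violations <- function(bundle, rules) {
  defects <- bundle$ground_truth$defects
  out <- lapply(seq_len(nrow(rules)), function(i) {
    spec <- rules$eval_spec[[i]]
    cl <- switch(spec$kind,
      not_empty = "MISSING", range = "OUT_OF_RANGE",
      not_in = if (rules$keyword[i] == "DEFINING_CODE") "BAD_CODE" else NA,
      not_equal = if (rules$keyword[i] == "MATCHES_UNITS") "BAD_UNITS" else NA,
      count_bounds = "EXTRA_OCCURRENCE", unique_dup = "DUPLICATE_KEY",
      temporal = "TEMPORAL_INVERSION", NA
    )
    expected <- if (is.na(cl)) 0L else if (spec$kind == "temporal") {
      sum(defects$defect_class == cl & defects$table == spec$earlier_table)
    } else {
      sum(defects$defect_class == cl & defects$table == spec$table &
            defects$column == spec$column)
    }
    data.frame(rule_id = rules$rule_id[i],
               defect_class = if (is.na(cl)) "NONE" else cl,
               expected = expected, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a bundle to disk
#'
#' Emits `.adl` archetype files, `mapping.yaml`, one CSV per table, an
#' SQLite database `data.sqlite`, and `ground_truth.json`. Output is
#' byte-identical for identical spec and seed (the SQLite file aside, whose
#' binary layout is engine-internal).
#'
#' @param bundle a `synth_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aid in names(bundle$archetypes)) {
    writeLines(bundle$archetypes[[aid]], file.path(dir, paste0(aid, ".adl")),
               useBytes = TRUE)
  }
  save_mapping(bundle$mapping, file.path(dir, "mapping.yaml"))
  for (tn in names(bundle$tables)) {
    utils::write.csv(bundle$tables[[tn]], file.path(dir, paste0(tn, ".csv")),
                     row.names = FALSE)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), file.path(dir, "data.sqlite"))
  for (tn in names(bundle$tables)) DBI::dbWriteTable(con, tn, bundle$tables[[tn]],
                                                     overwrite = TRUE)
  DBI::dbDisconnect(con)
  jsonlite::write_json(
    list(defects = bundle$ground_truth$defects,
         census = as.list(bundle$ground_truth$census),
         constraint_census = bundle$ground_truth$constraint_census,
         seed = bundle$spec$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
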