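#' @title Instantiating data quality rules
#'
#' @description
#' A data quality rule (DQR) is an executable SQL query whose returned rows
#' are violations. Rules are produced by filling a registry template with
#' (a) the table/column binding resolved through the archetype-relational
#' mapping and (b) the normalized constraint: interval bounds become
#' out-of-range comparisons (disjunction of the two sides -- a conjunction
#' would be unsatisfiable), value and code sets become `NOT IN` lists with
#' sorted, escaped members, and single literals become inequality tests.
#' NULL values are deliberately not value-conformance violations (SQL
#' comparison semantics already skip them); missingness is the completeness
#' template's job, which keeps per-dimension counts additive.
#' @name rule-gen
NULL

#' Normalize a constraint into an SQL violation predicate
#'
#' Strips the ADL notation (`|`, `..`, braces, quotes) and renders the
#' *violation* condition with a `{column}` placeholder: an interval
#' `|0..1000|` (inclusive) becomes `{column} < 0 OR {column} > 1000`,
#' explicit exclusive bounds (`>a`, `<b`) shift the comparison to `<=` /
#' `>=`, unbounded sides contribute nothing; value/code sets become
#' `{column} NOT IN (...)` over sorted members; a literal becomes
#' `{column} <> '...'`. Mandatory existence becomes the null-or-empty test,
#' extended by any configured null-equivalent tokens. Occurrences and
#' count-bounded cardinality yield a `HAVING` predicate on
#' `COUNT({column})`.
#'
#' @param constraint one row of a `dqr_constraints` data frame.
#' @param null_tokens extra strings treated as empty values by the
#'   completeness template (e.g. `"-"`, `"NA"`).
#' @return object of class `dqr_predicate`: list with `sql` (the predicate
#'   with `{column}` placeholders), `kind` and the normalized parameters.
#' @export
normalize_constraint <- function(constraint, null_tokens = character(0)) {
  c <- as_constraint_row(constraint)
  kw <- c$keyword
  pl <- c$payload

  if (kw %in% c("DEFINING_CODE", "MATCHES_VALUE") &&
      inherits(pl, c("adl_codeset", "adl_valueset"))) {
    members <- if (inherits(pl, "adl_codeset")) pl$codes else pl$values
    if (!length(members)) {
      stop_dqr("empty value/code set cannot be normalized",
               class = "dqr_normalize_error")
    }
    members <- sort(members, method = "radix")
    return(new_predicate(
      sql = paste0("{column} NOT IN (",
                   paste(quote_literal(members), collapse = ", "), ")"),
      kind = "not_in", members = members
    ))
  }

  if (kw %in% c("MATCHES_VALUE", "MATCHES_UNITS") && inherits(pl, "adl_literal")) {
    return(new_predicate(
      sql = paste0("{column} <> ", quote_literal(pl$value)),
      kind = "not_equal", literal = pl$value
    ))
  }

  if (kw == "MATCHES_RANGE") {
    parts <- character(0)
    if (!pl$lower_unbounded) {
      op <- if (pl$lower_included) "<" else "<="
      parts <- c(parts, paste0("{column} ", op, " ", format_num(pl$lower)))
    }
    if (!pl$upper_unbounded) {
      op <- if (pl$upper_included) ">" else ">="
      parts <- c(parts, paste0("{column} ", op, " ", format_num(pl$upper)))
    }
    if (!length(parts)) {
      stop_dqr("fully unbounded interval has no violating condition",
               class = "dqr_normalize_error")
    }
    return(new_predicate(
      sql = paste(parts, collapse = " OR "), kind = "range",
      lower = pl$lower, upper = pl$upper,
      lower_included = pl$lower_included, upper_included = pl$upper_included,
      lower_unbounded = pl$lower_unbounded, upper_unbounded = pl$upper_unbounded
    ))
  }

  if (kw == "EXISTENCE") {
    sql <- "{column} IS NULL OR {column} = ''"
    if (length(null_tokens)) {
      sql <- paste0(sql, " OR {column} IN (",
                    paste(quote_literal(sort(null_tokens, method = "radix")),
                          collapse = ", "), ")")
    }
    return(new_predicate(sql = sql, kind = "not_empty", null_tokens = null_tokens))
  }

  if (kw %in% c("OCCURRENCES", "CARDINALITY")) {
    if (isTRUE(pl$unique_flag)) {
      return(new_predicate(sql = "COUNT(*) > 1", kind = "unique_dup"))
    }
    parts <- character(0)
    if (!pl$lower_unbounded && pl$lower > 0) {
      parts <- c(parts, paste0("COUNT({column}) < ", format_num(pl$lower)))
    }
    if (!pl$upper_unbounded) {
      parts <- c(parts, paste0("COUNT({column}) > ", format_num(pl$upper)))
    }
    if (!length(parts)) {
      stop_dqr("count bounds admit every group size; nothing to normalize",
               class = "dqr_normalize_error")
    }
    return(new_predicate(
      sql = paste(parts, collapse = " OR "), kind = "count_bounds",
      lower = pl$lower, upper = pl$upper,
      lower_unbounded = pl$lower_unbounded, upper_unbounded = pl$upper_unbounded
    ))
  }

  stop_dqr("cannot normalize constraint with keyword ", kw,
           class = "dqr_normalize_error")
}

new_predicate <- function(sql, kind, ...) {
  structure(list(sql = sql, kind = kind, ...), class = "dqr_predicate")
}

# Which mapping role a keyword's column binding uses.
role_for_keyword <- function(keyword) {
  switch(keyword,
    DEFINING_CODE = "CODE",
    MATCHES_UNITS = "UNITS",
    "VALUE"
  )
}

## ---------------------------------------------------------------------------
## Rule construction and rendering
## ---------------------------------------------------------------------------

empty_rules <- function() {
  out <- data.frame(
    rule_id = character(0), sql_text = character(0), template_id = character(0),
    keyword = character(0), kahn_subdimension = character(0),
    carses_dimension = character(0), archetype_id = character(0),
    node_path = character(0), raw_text = character(0),
    table_name = character(0), stringsAsFactors = FALSE
  )
  out$eval_spec <- list()
  class(out) <- c("dqr_rules", "data.frame")
  out
}

rule_row <- function(rule_id, sql_text, template_id, keyword, kahn, carses,
                     archetype_id, node_path, raw_text, table_name, eval_spec) {
  out <- data.frame(
    rule_id = rule_id, sql_text = sql_text, template_id = template_id,
    keyword = keyword, kahn_subdimension = kahn, carses_dimension = carses,
    archetype_id = archetype_id, node_path = node_path, raw_text = raw_text,
    table_name = table_name, stringsAsFactors = FALSE
  )
  out$eval_spec <- list(eval_spec)
  out
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Render a rule's canonical SQL from its structured form
#'
#' Rendering is byte-stable: fixed keyword casing, double-quoted
#' identifiers, sorted set members, deterministic predicate order.
#'
#' @param rule one rule (a one-row `dqr_rules` data frame or a list with an
#'   `eval_spec` element).
#' @return SQL text (character scalar).
#' @export
render_sql <- function(rule) {
  spec <- if (is.data.frame(rule)) rule$eval_spec[[1]] else rule$eval_spec
  render_sql_spec(spec)
}

render_sql_spec <- function(spec) {
  tq <- quote_ident(spec$table)
  switch(spec$kind,
    not_empty = ,
    not_in = ,
    not_equal = ,
    range = {
      cq <- quote_ident(spec$column)
      pred <- gsub("{column}", cq, spec$predicate_sql, fixed = TRUE)
      paste0("SELECT ", cq, " FROM ", tq, " WHERE ", pred)
    },
    count_bounds = {
      kq <- quote_ident(spec$key)
      cq <- quote_ident(spec$column)
      pred <- gsub("{column}", cq, spec$predicate_sql, fixed = TRUE)
      paste0("SELECT ", kq, " FROM ", tq, " GROUP BY ", kq, " HAVING ", pred)
    },
    unique_dup = {
      kq <- quote_ident(spec$key)
      cq <- quote_ident(spec$column)
      paste0("SELECT ", kq, ", ", cq, " FROM ", tq, " WHERE ", cq,
             " IS NOT NULL GROUP BY ", kq, ", ", cq, " HAVING COUNT(*) > 1")
    },
    temporal = {
      et <- quote_ident(spec$earlier_time)
      lt <- quote_ident(spec$later_time)
      join <- paste(vapply(spec$join_pairs, function(jp) {
        paste0("e.", quote_ident(jp[1]), " = l.", quote_ident(jp[2]))
      }, ""), collapse = " AND ")
      paste0("SELECT e.", et, ", l.", lt, " FROM ", quote_ident(spec$earlier_table),
             " e JOIN ", quote_ident(spec$later_table), " l ON ", join,
             " WHERE e.", et, " > l.", lt)
    },
    stop_dqr("unknown rule kind: ", spec$kind, class = "dqr_render_error")
  )
}

#' Generate data quality rules from parsed archetypes and a mapping
#'
#' One rule per template-eligible constraint with a resolvable binding,
#' plus one temporal-plausibility rule per declared temporal link.
#' Optional-existence and vacuous constraints carry no template; constraints
#' whose attribute (or required grouping key) is unmapped are skipped with a
#' reason. Output order is deterministic: archetype order, then document
#' order, then temporal rules.
#'
#' @param models an `archetype_model` or list of them.
#' @param mapping a `mapping_table` (its `temporal_links` drive the temporal
#'   rules).
#' @param pairs declared Entry-type orderings for temporal links
#'   (see [default_temporal_pairs()]).
#' @param crosswalk Kahn-to-CARSES crosswalk (see [default_crosswalk()]).
#' @param null_tokens extra null-equivalent strings for completeness rules.
#' @return a `dqr_rules` data frame; attribute `"skips"` holds the
#'   generation report (one row per skipped constraint, with `reason` and
#'   whether the constraint was template-eligible).
#' @export
generate_rules <- function(models, mapping, pairs = default_temporal_pairs(),
                           crosswalk = default_crosswalk(),
                           null_tokens = character(0)) {
  if (inherits(models, "archetype_model")) models <- list(models)
  stopifnot(inherits(mapping, "mapping_table"))

  rules <- list()
  skips <- list()
  add_skip <- function(aid, path, keyword, reason, eligible) {
    skips[[length(skips) + 1L]] <<- data.frame(
      archetype_id = aid, node_path = path, keyword = keyword,
      reason = reason, template_eligible = eligible, stringsAsFactors = FALSE
    )
  }

  for (model in models) {
    cs <- extract_constraints(model)
    if (!nrow(cs)) next
    for (i in seq_len(nrow(cs))) {
      row <- cs[i, , drop = FALSE]
      tpl <- select_template(row)
      if (is.null(tpl)) {
        add_skip(row$archetype_id, row$node_path, row$keyword,
                 "no template: optional or vacuous constraint", FALSE)
        next
      }
      kahn <- classify_constraint(row)
      role <- role_for_keyword(row$keyword)
      binding <- tryCatch(
        resolve_mapping(mapping, row$archetype_id, row$node_path, role),
        dqr_resolve_error = function(e) NULL
      )
      if (is.null(binding)) {
        add_skip(row$archetype_id, row$node_path, row$keyword,
                 paste0("unmapped attribute (role ", role, ")"), TRUE)
        next
      }
      pred <- normalize_constraint(row, null_tokens = null_tokens)

      needs_key <- pred$kind %in% c("count_bounds", "unique_dup")
      key <- if (needs_key) key_column_for(mapping, binding$table_name) else NULL
      if (needs_key && is.null(key)) {
        add_skip(row$archetype_id, row$node_path, row$keyword,
                 paste0("no KEY-role column mapped for table ",
                        binding$table_name), TRUE)
        next
      }

      eval_spec <- c(
        list(kind = pred$kind, table = binding$table_name,
             column = binding$column_name, key = key,
             predicate_sql = pred$sql),
        pred[setdiff(names(pred), c("sql", "kind"))]
      )
      sql <- render_sql_spec(eval_spec)
      carses <- crosswalk_to_carses(kahn, row, crosswalk)
      rid <- paste0(tpl$template_id, "__", sanitize_id(row$archetype_id), "__",
                    sanitize_id(sub("^/", "", row$node_path)))
      rules[[length(rules) + 1L]] <- rule_row(
        rid, sql, tpl$template_id, row$keyword, kahn, carses,
        row$archetype_id, row$node_path, row$raw_text, binding$table_name,
        eval_spec
      )
    }
  }

  for (lk in mapping$temporal_links) {
    tpl <- temporal_pair_template(lk$earlier_entry_type %||% "INSTRUCTION",
                                  lk$later_entry_type %||% "ACTION",
                                  pairs = pairs)
    eval_spec <- list(
      kind = "temporal",
      table = lk$earlier_table,
      earlier_table = lk$earlier_table, earlier_time = lk$earlier_time_column,
      later_table = lk$later_table, later_time = lk$later_time_column,
      join_pairs = lk$join_pairs
    )
    sql <- render_sql_spec(eval_spec)
    carses <- crosswalk_to_carses(tpl$kahn_subdimension, NULL, crosswalk)
    rid <- paste0("temporal_order__", sanitize_id(lk$earlier_table), "__",
                  sanitize_id(lk$later_table))
    rules[[length(rules) + 1L]] <- rule_row(
      rid, sql, tpl$template_id, "TEMPORAL_PAIR", tpl$kahn_subdimension,
      carses, NA_character_,
      paste0(lk$earlier_table, "->", lk$later_table),
      paste0(lk$earlier_time_column, " > ", lk$later_time_column),
      lk$earlier_table, eval_spec
    )
  }

  out <- if (length(rules)) {
    res <- do.call(rbind, rules)
    class(res) <- c("dqr_rules", "data.frame")
    res
  } else {
    empty_rules()
  }
  if (anyDuplicated(out$rule_id)) {
    dup <- out$rule_id[duplicated(out$rule_id)]
    out$rule_id <- make.unique(out$rule_id, sep = "__c")
  }
  attr(out, "skips") <- if (length(skips)) do.call(rbind, skips) else
    data.frame(archetype_id = character(0), node_path = character(0),
               keyword = character(0), reason = character(0),
               template_eligible = logical(0), stringsAsFactors = FALSE)
  out
}

#' @export
print.dqr_rules <- function(x, ...) {
  cat("<dqr_rules> ", nrow(x), " rule(s)\n", sep = "")
  if (nrow(x)) {
    tab <- table(x$kahn_subdimension)
    for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
  skips <- attr(x, "skips")
  if (!is.null(skips) && nrow(skips)) {
    cat("  skipped constraints: ", nrow(skips), "\n", sep = "")
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Rule set I/O (JSON lines and .sql)
## ---------------------------------------------------------------------------

#' Write / read a rule set as JSON lines
#'
#' One JSON object per line; reference (expert) rule sets use the same
#' format, so they are first-class citizens of the pipeline. Objects carry
#' at minimum `rule_id`, `sql_text` and `carses_dimension`; rules written by
#' [generate_rules()] also carry provenance and the structured evaluation
#' spec.
#'
#' @param rules a `dqr_rules` data frame.
#' @param path output `.jsonl` file.
#' @export
write_rules <- function(rules, path) {
  lines <- vapply(seq_len(nrow(rules)), function(i) {
    obj <- list(
      rule_id = rules$rule_id[i],
      sql_text = rules$sql_text[i],
      template_id = rules$template_id[i],
      keyword = rules$keyword[i],
      kahn_subdimension = rules$kahn_subdimension[i],
      carses_dimension = rules$carses_dimension[i],
      archetype_id = rules$archetype_id[i],
      node_path = rules$node_path[i],
      raw_text = rules$raw_text[i],
      table_name = rules$table_name[i],
      eval_spec = rules$eval_spec[[i]]
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @return `read_rules()` returns a `dqr_rules` data frame.
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_rules())
  rows <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    spec <- obj$eval_spec
    if (!is.null(spec) && !is.null(spec$join_pairs)) {
      spec$join_pairs <- lapply(spec$join_pairs, as.character)
    }
    rule_row(
      obj$rule_id %||% NA_character_, obj$sql_text %||% NA_character_,
      obj$template_id %||% NA_character_, obj$keyword %||% NA_character_,
      obj$kahn_subdimension %||% NA_character_,
      obj$carses_dimension %||% NA_character_,
      obj$archetype_id %||% NA_character_, obj$node_path %||% NA_character_,
      obj$raw_text %||% NA_character_, obj$table_name %||% NA_character_,
      spec
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dqr_rules", "data.frame")
  out
}

#' Write a rule set as an SQL script
#'
#' One statement per rule with a comment header carrying provenance.
#'
#' @inheritParams write_rules
#' @export
write_rules_sql <- function(rules, path) {
  blocks <- vapply(seq_len(nrow(rules)), function(i) {
    paste0(
      "-- ", rules$rule_id[i], " | ",
      rules$kahn_subdimension[i], " -> ", rules$carses_dimension[i], " | ",
      rules$archetype_id[i], ":", rules$node_path[i], " | ",
      rules$raw_text[i], "\n",
      rules$sql_text[i], ";"
    )
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}
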