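#' @title Executing rules and reporting
#'
#' @description
#' Rules run read-only against an embedded SQLite database. A dataset can be
#' an existing SQLite file, a directory of CSV tables (loaded into an
#' ephemeral in-memory database), or a named list of data frames. Every
#' dataset keeps an in-memory copy of its tables so that the brute-force
#' row-wise oracle -- an evaluator of the rule's semantic predicate that
#' never touches the SQL engine -- can be run against the same data for
#' equivalence testing.
#' @name dq-engine
NULL

#' Open a dataset for quality assessment
#'
#' @param x a named list of data frames, a path to an SQLite database file,
#'   or a path to a directory of `.csv` files (one table per file, named
#'   after the file).
#' @param id dataset identifier used in reports.
#' @return an object of class `dq_dataset` (holds a DBI connection plus
#'   in-memory copies of the tables). Close with [dq_disconnect()].
#' @export
dq_dataset <- function(x, id = "dataset") {
  if (is.character(x) && length(x) == 1) {
    if (dir.exists(x)) {
      files <- sort(list.files(x, pattern = "\\.csv$", full.names = TRUE))
      tables <- lapply(files, function(f) {
        utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
      })
      names(tables) <- sub("\\.csv$", "", basename(files))
      return(dq_dataset(tables, id = id))
    }
    if (file.exists(x)) {
      con <- DBI::dbConnect(RSQLite::SQLite(), x)
      tables <- stats::setNames(
        lapply(DBI::dbListTables(con), function(t) DBI::dbReadTable(con, t)),
        DBI::dbListTables(con)
      )
      return(structure(list(con = con, tables = tables, id = id),
                       class = "dq_dataset"))
    }
    stop_dqr("no such dataset: ", x, class = "dqr_dataset_error")
  }
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  for (nm in names(x)) DBI::dbWriteTable(con, nm, as.data.frame(x[[nm]]))
  structure(list(con = con, tables = x, id = id), class = "dq_dataset")
}

#' @rdname dq_dataset
#' @param ds a `dq_dataset`.
#' @export
dq_disconnect <- function(ds) {
  if (inherits(ds, "dq_dataset")) DBI::dbDisconnect(ds$con)
  invisible(NULL)
}

#' @export
print.dq_dataset <- function(x, ...) {
  cat("<dq_dataset> ", x$id, ": ", length(x$tables), " table(s)\n", sep = "")
  invisible(x)
}

check_rule_schema <- function(rule_spec, ds) {
  tabs <- DBI::dbListTables(ds$con)
  need_tables <- if (rule_spec$kind == "temporal") {
    c(rule_spec$earlier_table, rule_spec$later_table)
  } else rule_spec$table
  for (t in need_tables) {
    if (!t %in% tabs) {
      stop_dqr("missing table: ", t, class = "dqr_execution_error")
    }
  }
  cols_needed <- switch(rule_spec$kind,
    temporal = NULL,
    count_bounds = c(rule_spec$key, rule_spec$column),
    unique_dup = c(rule_spec$key, rule_spec$column),
    rule_spec$column
  )
  if (!is.null(cols_needed)) {
    have <- DBI::dbListFields(ds$con, rule_spec$table)
    miss <- setdiff(cols_needed, have)
    if (length(miss)) {
      stop_dqr("missing column: ", rule_spec$table, ".", miss[1],
               class = "dqr_execution_error")
    }
  }
  if (rule_spec$kind == "temporal") {
    et <- DBI::dbListFields(ds$con, rule_spec$earlier_table)
    lt <- DBI::dbListFields(ds$con, rule_spec$later_table)
    need_e <- c(rule_spec$earlier_time,
                vapply(rule_spec$join_pairs, `[`, "", 1))
    need_l <- c(rule_spec$later_time,
                vapply(rule_spec$join_pairs, `[`, "", 2))
    miss <- c(setdiff(need_e, et), setdiff(need_l, lt))
    if (length(miss)) {
      stop_dqr("missing column: ", miss[1], class = "dqr_execution_error")
    }
  }
  invisible(TRUE)
}

#' Execute one rule against a dataset
#'
#' @param rule a one-row `dqr_rules` data frame (or list with `sql_text` and
#'   optionally `eval_spec`).
#' @param ds a `dq_dataset`.
#' @return list with `rows` (the violating rows as returned by the query),
#'   `violations` (their count) and `rows_examined` (rows of the target
#'   table, or join pairs for a temporal rule).
#' @export
execute_rule <- function(rule, ds) {
  stopifnot(inherits(ds, "dq_dataset"))
  sql <- if (is.data.frame(rule)) rule$sql_text[[1]] else rule$sql_text
  spec <- if (is.data.frame(rule)) rule$eval_spec[[1]] else rule$eval_spec

  if (!is.null(spec) && !is.null(spec$kind)) {
    check_rule_schema(spec, ds)
    rows_examined <- if (spec$kind == "temporal") {
      join <- paste(vapply(spec$join_pairs, function(jp) {
        paste0("e.", quote_ident(jp[1]), " = l.", quote_ident(jp[2]))
      }, ""), collapse = " AND ")
      DBI::dbGetQuery(ds$con, paste0(
        "SELECT COUNT(*) AS n FROM ", quote_ident(spec$earlier_table),
        " e JOIN ", quote_ident(spec$later_table), " l ON ", join))$n[1]
    } else {
      DBI::dbGetQuery(ds$con, paste0(
        "SELECT COUNT(*) AS n FROM ", quote_ident(spec$table)))$n[1]
    }
  } else {
    st <- sql_structure(sql)
    if (is.na(st$table) || !st$table %in% tolower(DBI::dbListTables(ds$con))) {
      if (is.na(st$table) || !st$table %in% DBI::dbListTables(ds$con)) {
        stop_dqr("missing table: ", st$table, class = "dqr_execution_error")
      }
    }
    rows_examined <- DBI::dbGetQuery(ds$con, paste0(
      "SELECT COUNT(*) AS n FROM ", quote_ident(st$table)))$n[1]
  }

  rows <- DBI::dbGetQuery(ds$con, sql)
  list(rows = rows, violations = nrow(rows), rows_examined = rows_examined)
}

#' Brute-force row-wise oracle for a rule
#'
#' Evaluates the rule's semantic predicate directly on in-memory tables,
#' row by row (or pair by pair over the declared join), without the SQL
#' engine. Output is comparable to [execute_rule()] via
#' [violation_signature()]. Supported rule shapes are the ones the
#' generator emits; anything else raises an oracle-unsupported error.
#'
#' @param rule a one-row `dqr_rules` data frame carrying an `eval_spec`.
#' @param tables named list of data frames (e.g. `ds$tables`).
#' @return data frame of violating rows (column layout mirrors the SQL
#'   result).
#' @export
oracle_evaluate <- function(rule, tables) {
  spec <- if (is.data.frame(rule)) rule$eval_spec[[1]] else rule$eval_spec
  if (is.null(spec) || is.null(spec$kind)) {
    stop_dqr("rule carries no structured form; oracle unsupported",
             class = "dqr_oracle_error")
  }

  get_table <- function(nm) {
    if (!nm %in% names(tables)) {
      stop_dqr("missing table: ", nm, class = "dqr_oracle_error")
    }
    tables[[nm]]
  }

  if (spec$kind == "temporal") {
    e <- get_table(spec$earlier_table)
    l <- get_table(spec$later_table)
    by_e <- vapply(spec$join_pairs, `[`, "", 1)
    by_l <- vapply(spec$join_pairs, `[`, "", 2)
    merged <- merge(e, l, by.x = by_e, by.y = by_l,
                    suffixes = c(".__e", ".__l"))
    ecol <- if (spec$earlier_time %in% names(merged)) spec$earlier_time
            else paste0(spec$earlier_time, ".__e")
    lcol <- if (spec$later_time %in% names(merged)) spec$later_time
            else paste0(spec$later_time, ".__l")
    ev <- merged[[ecol]]
    lv <- merged[[lcol]]
    bad <- !is.na(ev) & !is.na(lv) & ev > lv
    out <- data.frame(a = ev[bad], b = lv[bad], stringsAsFactors = FALSE)
    names(out) <- c(spec$earlier_time, spec$later_time)
    return(out)
  }

  df <- get_table(spec$table)
  col <- df[[spec$column]]

  if (spec$kind == "not_empty") {
    bad <- is.na(col) | as.character(col) == "" |
      (length(spec$null_tokens %||% character(0)) > 0 &
         as.character(col) %in% (spec$null_tokens %||% character(0)))
    out <- data.frame(v = col[bad], stringsAsFactors = FALSE)
    names(out) <- spec$column
    return(out)
  }
  if (spec$kind == "not_in") {
    bad <- !is.na(col) & !(as.character(col) %in% spec$members)
    out <- data.frame(v = col[bad], stringsAsFactors = FALSE)
    names(out) <- spec$column
    return(out)
  }
  if (spec$kind == "not_equal") {
    bad <- !is.na(col) & as.character(col) != spec$literal
    out <- data.frame(v = col[bad], stringsAsFactors = FALSE)
    names(out) <- spec$column
    return(out)
  }
  if (spec$kind == "range") {
    v <- suppressWarnings(as.numeric(col))
    bad <- rep(FALSE, length(v))
    if (!isTRUE(spec$lower_unbounded)) {
      bad <- bad | (if (isTRUE(spec$lower_included)) v < spec$lower else v <= spec$lower)
    }
    if (!isTRUE(spec$upper_unbounded)) {
      bad <- bad | (if (isTRUE(spec$upper_included)) v > spec$upper else v >= spec$upper)
    }
    bad[is.na(v)] <- FALSE
    out <- data.frame(v = col[bad], stringsAsFactors = FALSE)
    names(out) <- spec$column
    return(out)
  }
  if (spec$kind == "count_bounds") {
    key <- df[[spec$key]]
    counts <- tapply(!is.na(col), key, sum)
    bad <- rep(FALSE, length(counts))
    if (!isTRUE(spec$lower_unbounded) && spec$lower > 0) {
      bad <- bad | counts < spec$lower
    }
    if (!isTRUE(spec$upper_unbounded)) bad <- bad | counts > spec$upper
    keys <- names(counts)[bad]
    # restore the key's original type where possible
    kv <- key[match(keys, as.character(key))]
    out <- data.frame(k = kv, stringsAsFactors = FALSE)
    names(out) <- spec$key
    return(out)
  }
  if (spec$kind == "unique_dup") {
    keep <- !is.na(col)
    key <- df[[spec$key]][keep]
    val <- col[keep]
    grp <- paste(as.character(key), as.character(val), sep = "\r")
    tab <- table(grp)
    bad_grp <- names(tab)[tab > 1]
    idx <- match(bad_grp, grp)
    out <- data.frame(k = key[idx], v = val[idx], stringsAsFactors = FALSE)
    names(out) <- c(spec$key, spec$column)
    return(out)
  }
  stop_dqr("oracle unsupported for rule kind ", spec$kind,
           class = "dqr_oracle_error")
}

#' Canonical multiset signature of a violation row set
#'
#' Sorts columns by name and rows lexicographically so that the SQL result
#' and the oracle result can be compared as multisets.
#'
#' @param rows data frame of violating rows.
#' @return character vector (one element per row, sorted).
#' @export
violation_signature <- function(rows) {
  if (!nrow(rows)) return(character(0))
  rows <- rows[, sort(names(rows)), drop = FALSE]
  vals <- lapply(rows, function(v) {
    if (is.numeric(v)) format_num(as.numeric(v)) else as.character(v)
  })
  sig <- do.call(paste, c(vals, sep = "\r"))
  sort(sig, method = "radix")
}

#' Run a full assessment
#'
#' Executes every rule; individual rule failures are recorded per rule and
#' the run continues. Aggregates are reported by CARSES dimension and by
#' Kahn sub-dimension.
#'
#' @param rules a `dqr_rules` data frame.
#' @param ds a `dq_dataset`.
#' @param seed optional seed recorded in the metadata when the dataset is
#'   synthetic.
#' @return an object of class `dqa_report` with elements `dataset_id`,
#'   `per_rule`, `by_carses`, `by_kahn`, `run_metadata`.
#' @export
run_assessment <- function(rules, ds, seed = NULL) {
  per_rule <- data.frame(
    rule_id = character(0), carses_dimension = character(0),
    kahn_subdimension = character(0), rows_examined = numeric(0),
    violations = numeric(0), error = character(0), stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(rules))) {
    res <- tryCatch(
      execute_rule(rules[i, , drop = FALSE], ds),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      per_rule <- rbind(per_rule, data.frame(
        rule_id = rules$rule_id[i], carses_dimension = rules$carses_dimension[i],
        kahn_subdimension = rules$kahn_subdimension[i],
        rows_examined = NA_real_, violations = NA_real_,
        error = conditionMessage(res), stringsAsFactors = FALSE
      ))
    } else {
      per_rule <- rbind(per_rule, data.frame(
        rule_id = rules$rule_id[i], carses_dimension = rules$carses_dimension[i],
        kahn_subdimension = rules$kahn_subdimension[i],
        rows_examined = res$rows_examined, violations = res$violations,
        error = NA_character_, stringsAsFactors = FALSE
      ))
    }
  }

  agg <- function(by) {
    ok <- per_rule[is.na(per_rule$error), , drop = FALSE]
    if (!nrow(ok)) {
      return(data.frame(dimension = character(0), n_rules = numeric(0),
                        violations = numeric(0), stringsAsFactors = FALSE))
    }
    sp <- split(ok, ok[[by]])
    data.frame(
      dimension = names(sp),
      n_rules = vapply(sp, nrow, 0),
      violations = vapply(sp, function(d) sum(d$violations), 0),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }

  structure(
    list(
      dataset_id = ds$id,
      per_rule = per_rule,
      by_carses = agg("carses_dimension"),
      by_kahn = agg("kahn_subdimension"),
      run_metadata = list(
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        engine = paste0("dqrgen ", as.character(utils::packageVersion("dqrgen"))),
        seed = seed
      )
    ),
    class = "dqa_report"
  )
}

#' @export
print.dqa_report <- function(x, ...) {
  cat("<dqa_report> dataset: ", x$dataset_id, "\n", sep = "")
  cat("  rules executed: ", sum(is.na(x$per_rule$error)), " / ",
      nrow(x$per_rule), "\n", sep = "")
  cat("  total violations: ",
      sum(x$per_rule$violations, na.rm = TRUE), "\n", sep = "")
  if (nrow(x$by_carses)) {
    for (i in seq_len(nrow(x$by_carses))) {
      cat("  ", x$by_carses$dimension[i], ": ", x$by_carses$violations[i],
          " violation(s) over ", x$by_carses$n_rules[i], " rule(s)\n", sep = "")
    }
  }
  invisible(x)
}

#' Write an assessment report
#'
#' @param report a `dqa_report`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(dataset_id = report$dataset_id, per_rule = report$per_rule,
           by_carses = report$by_carses, by_kahn = report$by_kahn,
           run_metadata = report$run_metadata),
      json_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_rule, csv_path, row.names = FALSE)
  }
  invisible(report)
}
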