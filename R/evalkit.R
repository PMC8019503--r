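#' @title Coverage evaluation against a reference rule set
#'
#' @description
#' A generated rule set is evaluated against a reference (expert-created)
#' rule set in two aspects: (1) both rules are executed on the same probe
#' dataset and must return identical violation row multisets; (2) their
#' expressions must be semantically consistent, tested as equality of
#' canonical normalized query forms (see [normalize_sql()]). A pair is in
#' agreement only if it agrees on both aspects. Coverage is the number of
#' agreeing rules divided by the total number of reference rules, expressed
#' as a percentage, overall and per quality dimension.
#' @name evalkit
NULL

rule_field <- function(rules, i, field) {
  v <- rules[[field]]
  if (is.null(v)) NA_character_ else v[[i]]
}

rule_match_key <- function(rules) {
  n <- nrow(rules)
  vapply(seq_len(n), function(i) {
    st <- sql_structure(rules$sql_text[[i]])
    tbl <- rule_field(rules, i, "table_name")
    if (is.na(tbl)) tbl <- st$table
    paste(tolower(tbl), paste(st$columns, collapse = ","),
          rule_field(rules, i, "carses_dimension"), sep = "|")
  }, "")
}

#' Two-aspect agreement between generated and reference rules
#'
#' Candidate pairs are matched on (table, select-column set, CARSES
#' dimension); ties are broken by closest normalized-text distance. Each
#' reference rule is matched to at most one generated rule. For every pair,
#' `result_equal` compares violation row multisets on the probe dataset,
#' `semantically_equal` compares canonical normalized forms, and
#' `agree` requires both. A rule that fails to execute on the probe dataset
#' makes its pair non-agreeing, with the reason recorded.
#'
#' @param auto generated rules (`dqr_rules`).
#' @param expert reference rules in the same format (e.g. [read_rules()]).
#' @param probe_ds a `dq_dataset` both rule sets can execute on.
#' @return an object of class `agreement_result`: list with `pairs` (data
#'   frame: `auto_rule_id`, `expert_rule_id`, `result_equal`,
#'   `semantically_equal`, `agree`, `note`), `unmatched_auto`,
#'   `unmatched_expert`.
#' @export
compare_rules <- function(auto, expert, probe_ds) {
  akey <- rule_match_key(auto)
  ekey <- rule_match_key(expert)
  anorm <- vapply(auto$sql_text, normalize_sql, "", USE.NAMES = FALSE)
  enorm <- vapply(expert$sql_text, normalize_sql, "", USE.NAMES = FALSE)

  exec_sig <- function(rules, i) {
    tryCatch({
      res <- execute_rule(rules[i, , drop = FALSE], probe_ds)
      list(ok = TRUE, sig = violation_signature(res$rows))
    }, error = function(e) list(ok = FALSE, sig = conditionMessage(e)))
  }

  auto_used <- rep(FALSE, nrow(auto))
  pairs <- list()
  for (j in seq_len(nrow(expert))) {
    cand <- which(akey == ekey[j] & !auto_used)
    if (!length(cand)) next
    if (length(cand) > 1) {
      d <- utils::adist(enorm[j], anorm[cand])[1, ]
      cand <- cand[order(d)]
    }
    i <- cand[1]
    auto_used[i] <- TRUE

    sem <- identical(anorm[i], enorm[j])
    ra <- exec_sig(auto, i)
    re <- exec_sig(expert, j)
    if (ra$ok && re$ok) {
      res_eq <- identical(ra$sig, re$sig)
      note <- NA_character_
    } else {
      res_eq <- FALSE
      note <- paste0("execution failed: ",
                     if (!ra$ok) ra$sig else re$sig)
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      auto_rule_id = auto$rule_id[i], expert_rule_id = expert$rule_id[j],
      result_equal = res_eq, semantically_equal = sem,
      agree = res_eq && sem, note = note, stringsAsFactors = FALSE
    )
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else data.frame(
    auto_rule_id = character(0), expert_rule_id = character(0),
    result_equal = logical(0), semantically_equal = logical(0),
    agree = logical(0), note = character(0), stringsAsFactors = FALSE
  )
  structure(
    list(
      pairs = pairs_df,
      unmatched_auto = auto$rule_id[!auto_used],
      unmatched_expert = setdiff(expert$rule_id, pairs_df$expert_rule_id)
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> ", nrow(x$pairs), " pair(s), ",
      sum(x$pairs$agree), " in agreement; ",
      length(x$unmatched_auto), " auto / ",
      length(x$unmatched_expert), " reference rule(s) unmatched\n", sep = "")
  invisible(x)
}

#' Coverage of a reference rule set
#'
#' Coverage is `100 * n_agree / n_expert` (the number of generated rules in
#' agreement with reference rules over the total number of reference
#' rules), rounded half-up to two decimals, computed overall and per
#' dimension. A dimension with zero reference rules has undefined coverage
#' and raises an error.
#'
#' @param agreement an `agreement_result` from [compare_rules()], or a data
#'   frame of pre-tallied counts with columns `dimension`, `n_agree`,
#'   `n_expert` (e.g. `fixture_table6()$coverage_counts`).
#' @param expert the reference rule set (`dqr_rules`); not needed when
#'   `agreement` is a counts data frame.
#' @param auto_tally optional named vector of generated-rule counts per
#'   dimension (for the proportions block); computed from `agreement` pairs
#'   when omitted and available.
#' @return an object of class `coverage_summary`: list with `per_dimension`
#'   (dimension, n_agree, n_expert, coverage_pct), `overall` and
#'   `proportions` (per-dimension share of the generated rule set, when a
#'   tally is available).
#' @export
coverage <- function(agreement, expert = NULL, auto_tally = NULL) {
  if (is.data.frame(agreement) &&
      all(c("dimension", "n_agree", "n_expert") %in% names(agreement))) {
    counts <- agreement
  } else if (inherits(agreement, "agreement_result")) {
    if (is.null(expert)) {
      stop_dqr("reference rule set required to tally coverage",
               class = "dqr_coverage_error")
    }
    dims <- expert$carses_dimension
    agree_ids <- agreement$pairs$expert_rule_id[agreement$pairs$agree]
    dim_levels <- unique(dims)
    counts <- data.frame(
      dimension = dim_levels,
      n_agree = vapply(dim_levels, function(d) {
        sum(expert$rule_id[dims == d] %in% agree_ids)
      }, 0),
      n_expert = vapply(dim_levels, function(d) sum(dims == d), 0),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    stop_dqr("agreement must be an agreement_result or a counts data frame",
             class = "dqr_coverage_error")
  }

  if (any(counts$n_expert == 0)) {
    stop_dqr("coverage undefined for dimension(s) with zero reference rules: ",
             paste(counts$dimension[counts$n_expert == 0], collapse = ", "),
             class = "dqr_coverage_error")
  }
  if (any(counts$n_agree > counts$n_expert)) {
    stop_dqr("agreement count exceeds reference count",
             class = "dqr_coverage_error")
  }

  counts$coverage_pct <- round_half_up(100 * counts$n_agree / counts$n_expert, 2)
  overall <- list(
    n_agree = sum(counts$n_agree),
    n_expert = sum(counts$n_expert),
    coverage_pct = round_half_up(100 * sum(counts$n_agree) / sum(counts$n_expert), 2)
  )

  proportions <- NULL
  if (!is.null(auto_tally)) {
    proportions <- dimension_breakdown(auto_tally)
  }

  structure(
    list(per_dimension = counts, overall = overall, proportions = proportions),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat("<coverage_summary>\n")
  for (i in seq_len(nrow(x$per_dimension))) {
    cat(sprintf("  %-14s %4d / %4d  =  %6.2f%%\n",
                tolower(x$per_dimension$dimension[i]),
                x$per_dimension$n_agree[i], x$per_dimension$n_expert[i],
                x$per_dimension$coverage_pct[i]))
  }
  cat(sprintf("  %-14s %4d / %4d  =  %6.2f%%\n", "overall",
              x$overall$n_agree, x$overall$n_expert, x$overall$coverage_pct))
  invisible(x)
}

#' Per-dimension composition of a rule set
#'
#' Shares are percentages of the whole rule set, half-up rounded to two
#' decimals; the UNMATCHED bucket (rules addressing no dimension of the
#' assessment standard) is reported explicitly.
#'
#' @param auto a `dqr_rules` data frame, or a named numeric vector of
#'   per-dimension counts.
#' @return data frame with columns `dimension`, `n`, `pct`.
#' @export
dimension_breakdown <- function(auto) {
  tally <- if (is.data.frame(auto)) {
    tab <- table(auto$carses_dimension)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    auto
  }
  total <- sum(tally)
  data.frame(
    dimension = names(tally),
    n = as.numeric(tally),
    pct = if (total > 0) round_half_up(100 * as.numeric(tally) / total, 2)
          else rep(0, length(tally)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
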