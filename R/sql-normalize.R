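#' @title Canonical SQL normalization
#'
#' @description
#' Semantic comparison of two rules' expressions works on a canonical
#' normalized form of the restricted SELECT dialect this package emits:
#' keywords and identifiers case-folded, identifier quoting stripped,
#' `!=` rewritten to `<>`, numbers rendered canonically (so `0.0` equals
#' `0`), table aliases replaced by the table they alias, the select and
#' group-by lists sorted, `IN`-list members sorted, and the boolean
#' structure of `WHERE`/`HAVING`/`ON` flattened with conjuncts and
#' disjuncts sorted. Two rules whose normalized forms are byte-equal are
#' treated as semantically equal; the normalization is deliberately
#' conservative (it never merges genuinely different predicates).
#' @name sql-normalize
NULL

SQL_KEYWORDS <- c(
  "select", "from", "where", "group", "by", "having", "order", "join",
  "inner", "left", "right", "outer", "on", "and", "or", "not", "in", "is",
  "null", "count", "distinct", "as", "exists", "between", "like", "case",
  "when", "then", "else", "end", "asc", "desc", "union", "all"
)

sql_tokenize <- function(sql) {
  pattern <- paste0(
    "'(?:[^']|'')*'",                  # string literal
    "|\"(?:[^\"]|\"\")*\"",            # quoted identifier
    "|-?[0-9]+(?:\\.[0-9]+)?",         # number
    "|[A-Za-z_][A-Za-z0-9_]*",         # word
    "|<>|<=|>=|!=|=|<|>",              # comparison operators
    "|[(),.;*]"                        # punctuation
  )
  m <- gregexpr(pattern, sql, perl = TRUE)[[1]]
  if (m[1] == -1) return(character(0))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  substring(sql, starts, starts + lens - 1L)
}

canon_token <- function(tok) {
  c1 <- substr(tok, 1, 1)
  if (c1 == "'") return(tok)                                  # string literal
  if (c1 == '"') {                                            # quoted ident
    inner <- gsub('""', '"', substr(tok, 2, nchar(tok) - 1L))
    return(tolower(inner))
  }
  if (tok == "!=") return("<>")
  if (grepl("^-?[0-9]", tok)) {
    v <- suppressWarnings(as.numeric(tok))
    if (!is.na(v)) return(format_num(v))
  }
  if (grepl("^[A-Za-z_]", tok)) return(tolower(tok))
  tok
}

# Split a token vector at depth-0 occurrences of a separator token.
split_top_level <- function(tokens, sep) {
  depth <- 0L
  groups <- list()
  cur <- character(0)
  for (tok in tokens) {
    if (tok == "(") depth <- depth + 1L
    if (tok == ")") depth <- depth - 1L
    if (depth == 0L && tok %in% sep) {
      groups[[length(groups) + 1L]] <- cur
      cur <- character(0)
    } else {
      cur <- c(cur, tok)
    }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

# Remove parentheses wrapping an entire expression.
strip_outer_parens <- function(tokens) {
  while (length(tokens) >= 2 && tokens[1] == "(" && tokens[length(tokens)] == ")") {
    depth <- 0L
    wraps <- TRUE
    for (i in seq_along(tokens)) {
      if (tokens[i] == "(") depth <- depth + 1L
      if (tokens[i] == ")") depth <- depth - 1L
      if (depth == 0L && i < length(tokens)) { wraps <- FALSE; break }
    }
    if (!wraps) break
    tokens <- tokens[-c(1L, length(tokens))]
  }
  tokens
}

# Sort the members of every depth-1 IN (...) list.
normalize_in_lists <- function(tokens) {
  i <- 1L
  out <- character(0)
  n <- length(tokens)
  while (i <= n) {
    if (tokens[i] == "in" && i < n && tokens[i + 1L] == "(") {
      depth <- 1L
      j <- i + 2L
      while (j <= n && depth > 0L) {
        if (tokens[j] == "(") depth <- depth + 1L
        if (tokens[j] == ")") depth <- depth - 1L
        j <- j + 1L
      }
      inner <- tokens[seq.int(i + 2L, j - 2L)]
      members <- vapply(split_top_level(inner, ","), paste, "", collapse = " ")
      members <- sort(members, method = "radix")
      out <- c(out, "in", "(", paste(members, collapse = " , "), ")")
      i <- j
    } else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

# Canonical boolean expression: strip outer parens, sort AND-conjuncts
# within each OR-disjunct, sort disjuncts.
normalize_bool_expr <- function(tokens) {
  tokens <- strip_outer_parens(tokens)
  tokens <- normalize_in_lists(tokens)
  disjuncts <- split_top_level(tokens, "or")
  parts <- vapply(disjuncts, function(d) {
    conjuncts <- split_top_level(d, "and")
    strs <- vapply(conjuncts, function(cj) {
      paste(strip_outer_parens(trimws_tokens(cj)), collapse = " ")
    }, "")
    paste(sort(strs, method = "radix"), collapse = " and ")
  }, "")
  paste(sort(parts, method = "radix"), collapse = " or ")
}

trimws_tokens <- function(tokens) tokens[nzchar(tokens)]

# Resolve "FROM t a" / "JOIN t2 b" aliases: returns list(tokens, alias_map).
resolve_aliases <- function(tokens) {
  alias_map <- character(0)
  n <- length(tokens)
  drop <- logical(n)
  i <- 1L
  while (i <= n) {
    if (tokens[i] %in% c("from", "join") && i + 1L <= n) {
      tbl <- tokens[i + 1L]
      j <- i + 2L
      if (j <= n && tokens[j] == "as") { drop[j] <- TRUE; j <- j + 1L }
      if (j <= n && grepl("^[a-z_][a-z0-9_]*$", tokens[j]) &&
          !tokens[j] %in% SQL_KEYWORDS) {
        alias_map[tokens[j]] <- tbl
        drop[j] <- TRUE
      }
    }
    i <- i + 1L
  }
  tokens <- tokens[!drop]
  # replace alias tokens that qualify a column (alias . col)
  if (length(alias_map)) {
    n <- length(tokens)
    for (i in seq_len(n)) {
      if (i < n && tokens[i + 1L] == "." && tokens[i] %in% names(alias_map)) {
        tokens[i] <- alias_map[[tokens[i]]]
      }
    }
  }
  tokens
}

#' Normalize an SQL rule expression to canonical form
#'
#' @param sql SQL text in the package's restricted SELECT dialect.
#' @return canonical single-line lower-case form (character scalar).
#' @examples
#' normalize_sql('SELECT "x" FROM "t" WHERE "x" > 10 OR "x" < 0') ==
#'   normalize_sql("select x from t where x < 0.0 or x > 10")
#' @export
normalize_sql <- function(sql) {
  tokens <- vapply(sql_tokenize(sql), canon_token, "", USE.NAMES = FALSE)
  tokens <- tokens[tokens != ";"]
  tokens <- resolve_aliases(tokens)

  clause_words <- c("select", "from", "where", "group", "having", "order")
  idx <- which(tokens %in% clause_words)
  # `group by` / `order by`: treat the keyword position only
  if (!length(idx) || tokens[idx[1]] != "select") {
    # not a SELECT statement: return flat canonical join
    return(paste(tokens, collapse = " "))
  }
  bounds <- c(idx, length(tokens) + 1L)
  pieces <- list()
  for (k in seq_along(idx)) {
    word <- tokens[idx[k]]
    body <- if (bounds[k + 1L] - 1L >= idx[k] + 1L) {
      tokens[seq.int(idx[k] + 1L, bounds[k + 1L] - 1L)]
    } else character(0)
    pieces[[length(pieces) + 1L]] <- list(word = word, body = body)
  }

  out <- character(0)
  for (pc in pieces) {
    word <- pc$word
    body <- pc$body
    if (word == "select") {
      items <- vapply(split_top_level(body, ","), paste, "", collapse = " ")
      out <- c(out, "select", paste(sort(trimws(items), method = "radix"),
                                    collapse = " , "))
    } else if (word == "from") {
      # normalize ON conditions inside the from clause
      on_idx <- which(body == "on")
      if (length(on_idx)) {
        pre <- body[seq_len(on_idx[1])]
        cond <- body[seq.int(on_idx[1] + 1L, length(body))]
        out <- c(out, "from", paste(pre[-length(pre)], collapse = " "), "on",
                 normalize_bool_expr(cond))
      } else {
        out <- c(out, "from", paste(body, collapse = " "))
      }
    } else if (word %in% c("where", "having")) {
      out <- c(out, word, normalize_bool_expr(body))
    } else if (word == "group") {
      body <- body[body != "by"]
      items <- vapply(split_top_level(body, ","), paste, "", collapse = " ")
      out <- c(out, "group by", paste(sort(trimws(items), method = "radix"),
                                      collapse = " , "))
    } else {
      out <- c(out, word, paste(body, collapse = " "))
    }
  }
  paste(out, collapse = " ")
}

#' Extract table and column set from a restricted-dialect SELECT
#'
#' Used to pair externally supplied rules (which may carry only SQL text)
#' with generated rules for agreement testing.
#'
#' @param sql SQL text.
#' @return list with `table` (first FROM table, unquoted) and `columns`
#'   (sorted unique column identifiers appearing in the SELECT list).
#' @export
sql_structure <- function(sql) {
  raw <- sql_tokenize(sql)
  tokens <- vapply(raw, canon_token, "", USE.NAMES = FALSE)
  from_pos <- which(tokens == "from")[1]
  table <- if (!is.na(from_pos) && from_pos < length(tokens)) {
    tokens[from_pos + 1L]
  } else NA_character_

  sel_pos <- which(tokens == "select")[1]
  cols <- character(0)
  if (!is.na(sel_pos) && !is.na(from_pos) && from_pos > sel_pos + 1L) {
    body <- tokens[seq.int(sel_pos + 1L, from_pos - 1L)]
    items <- split_top_level(body, ",")
    for (item in items) {
      words <- item[grepl("^[a-z_][a-z0-9_]*$", item) & !item %in% SQL_KEYWORDS]
      # for qualified a.b references keep the final component
      if (length(words)) cols <- c(cols, words[length(words)])
    }
  }
  list(table = table, columns = sort(unique(cols), method = "radix"))
}
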