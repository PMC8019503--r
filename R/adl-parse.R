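#' @title Parsing a pragmatic subset of ADL 1.4
#'
#' @description
#' Archetypes are constraint-based definitions of clinical concepts written
#' in the Archetype Definition Language (ADL). The quality knowledge a data
#' quality rule needs lives in the `definition` (cADL) section: existence,
#' occurrences and cardinality clauses, value intervals, value sets,
#' terminology code lists and unit designations. This parser supports exactly
#' that subset (plus the header, concept and ontology sections needed to
#' identify the archetype and resolve at-codes to names); the ADL 2 syntax,
#' specialisation, templates and the rules/expression-language section are
#' out of scope.
#'
#' Parsing is single-pass, deterministic and fail-fast: input outside the
#' supported subset raises an error naming the line, column and offending
#' construct.
#' @name adl-parsing
NULL

## ---------------------------------------------------------------------------
## Tokenizer
## ---------------------------------------------------------------------------

# Token classes: COMMENT (dropped), STRING, NUMBER, IDENT, DOTDOT, COLONCOLON,
# and single-character symbols. Offsets are 1-based positions in `src`.
adl_tokenize <- function(src, base_offset = 0L) {
  pattern <- paste0(
    "--[^\n]*",                         # trailing comment
    "|\"[^\"]*\"",                      # double-quoted string
    "|'[^']*'",                         # single-quoted string
    "|\\.\\.",                          # interval separator
    "|::",                              # terminology namespace separator
    "|-?[0-9]+(?:\\.[0-9]+)?",          # number
    "|[A-Za-z_][A-Za-z0-9_.\\-]*",      # identifier (incl. at-codes)
    "|[{}\\[\\]()|;,=<>*!/]"            # structural symbols
  )
  m <- gregexpr(pattern, src, perl = TRUE)[[1]]
  if (m[1] == -1) {
    texts <- character(0); starts <- integer(0); lens <- integer(0)
  } else {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    texts <- substring(src, starts, starts + lens - 1L)
  }

  # Everything not matched must be whitespace, otherwise the construct is
  # unsupported -- report the first offending character with line/column.
  covered <- rep(FALSE, nchar(src))
  for (i in seq_along(starts)) {
    covered[starts[i]:(starts[i] + lens[i] - 1L)] <- TRUE
  }
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  bad <- which(!covered & !grepl("^[ \t\r\n]$", chars))
  if (length(bad)) {
    lc <- offset_linecol(src, bad[1])
    stop_dqr("unsupported character '", chars[bad[1]], "' at line ", lc[1],
             ", column ", lc[2], class = "dqr_parse_error")
  }

  type <- vapply(texts, function(t) {
    c1 <- substr(t, 1, 1)
    if (startsWith(t, "--")) "COMMENT"
    else if (c1 == '"' || c1 == "'") "STRING"
    else if (t == "..") "DOTDOT"
    else if (t == "::") "COLONCOLON"
    else if (grepl("^-?[0-9]", t)) "NUMBER"
    else if (grepl("^[A-Za-z_]", t)) "IDENT"
    else "SYM"
  }, character(1), USE.NAMES = FALSE)

  keep <- type != "COMMENT"
  lc <- t(vapply(starts[keep], function(s) offset_linecol(src, s), integer(2)))
  data.frame(
    type = type[keep],
    text = texts[keep],
    start = starts[keep] + base_offset,
    end = starts[keep] + lens[keep] - 1L + base_offset,
    line = if (length(starts[keep])) lc[, 1] else integer(0),
    col = if (length(starts[keep])) lc[, 2] else integer(0),
    stringsAsFactors = FALSE
  )
}

offset_linecol <- function(src, offset) {
  prefix <- substr(src, 1L, offset)
  line <- lengths(regmatches(prefix, gregexpr("\n", prefix, fixed = TRUE))) + 1L
  last_nl <- max(c(0L, gregexpr("\n", prefix, fixed = TRUE)[[1]]))
  col <- offset - last_nl
  c(as.integer(line), as.integer(col))
}

## ---------------------------------------------------------------------------
## Parser state helpers
## ---------------------------------------------------------------------------

new_parser <- function(tokens, src) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env$src <- src
  env
}

p_peek <- function(p, ahead = 0L) {
  i <- p$pos + ahead
  if (i > nrow(p$tokens)) NULL else p$tokens[i, ]
}

p_next <- function(p) {
  tok <- p_peek(p)
  if (is.null(tok)) {
    stop_dqr("unexpected end of definition section", class = "dqr_parse_error")
  }
  p$pos <- p$pos + 1L
  tok
}

p_expect <- function(p, text = NULL, type = NULL, what = NULL) {
  tok <- p_next(p)
  ok <- (is.null(text) || tok$text == text) && (is.null(type) || tok$type == type)
  if (!ok) {
    stop_dqr("expected ", what %||% text %||% type, " but found '", tok$text,
             "' at line ", tok$line, ", column ", tok$col,
             class = "dqr_parse_error")
  }
  tok
}

p_error <- function(p, tok, msg) {
  stop_dqr(msg, " at line ", tok$line, ", column ", tok$col,
           class = "dqr_parse_error")
}

## ---------------------------------------------------------------------------
## Top-level parse
## ---------------------------------------------------------------------------

#' Parse an archetype written in the supported ADL 1.4 subset
#'
#' @param adl ADL source text (single string, possibly with newlines) or the
#'   path to a UTF-8 `.adl` file.
#' @return An object of class `archetype_model`: a list with elements
#'   `archetype_id`, `entry_type` (one of `ADMIN_ENTRY`, `OBSERVATION`,
#'   `EVALUATION`, `INSTRUCTION`, `ACTION`, `DEMOGRAPHIC`, `CLUSTER`,
#'   `OTHER`, derived from the reference-model segment of the identifier),
#'   `concept_name`, `nodes` (the constraint-node tree), `ontology`
#'   (named character vector of at-code terms) and `source`.
#' @examples
#' wx <- fixture_worked_example()
#' model <- parse_archetype(wx$adl)
#' model$entry_type
#' @export
parse_archetype <- function(adl) {
  src <- read_adl_text(adl)
  sections <- split_sections(src)

  if (is.na(sections["definition"])) {
    stop_dqr("archetype has no definition section", class = "dqr_structure_error")
  }

  archetype_id <- parse_header_id(sections, src)
  ontology <- parse_ontology(section_text(sections, "ontology", src))

  def_start <- section_body_start(sections, "definition")
  def_text <- section_text(sections, "definition", src)
  tokens <- adl_tokenize(def_text, base_offset = def_start - 1L)
  p <- new_parser(tokens, src)

  root <- parse_cadl_node(p, path = "", ontology = ontology, is_root = TRUE)
  if (!is.null(p_peek(p))) {
    tok <- p_peek(p)
    p_error(p, tok, paste0("trailing content '", tok$text, "' after definition root"))
  }

  concept_name <- ont_lookup(ontology, "at0000") %||% concept_segment(archetype_id)

  structure(
    list(
      archetype_id = archetype_id,
      entry_type = entry_type_from_id(archetype_id),
      concept_name = concept_name,
      nodes = root,
      ontology = ontology,
      source = src
    ),
    class = "archetype_model"
  )
}

read_adl_text <- function(adl) {
  if (length(adl) == 1 && !grepl("\n", adl) && file.exists(adl)) {
    adl <- paste(readLines(adl, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  paste(adl, collapse = "\n")
}

# Sections begin at column 1 with a known keyword. Returns named integer
# vector of section header start offsets (NA when absent).
split_sections <- function(src) {
  keys <- c("archetype", "concept", "language", "description", "definition",
            "ontology", "terminology")
  starts <- rep(NA_integer_, length(keys))
  names(starts) <- keys
  m <- gregexpr("(?m)^(archetype|concept|language|description|definition|ontology|terminology)\\b",
                src, perl = TRUE)[[1]]
  if (m[1] != -1) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      key <- substring(src, m[i], m[i] + lens[i] - 1L)
      if (is.na(starts[key])) starts[key] <- as.integer(m[i])
    }
  }
  if (is.na(starts["archetype"])) {
    stop_dqr("missing 'archetype' header section", class = "dqr_structure_error")
  }
  starts
}

section_bounds <- function(sections, name, src) {
  start <- sections[name]
  if (is.na(start)) return(NULL)
  later <- sections[!is.na(sections) & sections > start]
  end <- if (length(later)) min(later) - 1L else nchar(src)
  c(start, end)
}

# Offset of the first character after the section keyword line.
section_body_start <- function(sections, name) {
  sections[[name]] + nchar(name)
}

section_text <- function(sections, name, src) {
  b <- section_bounds(sections, name, src)
  if (is.null(b)) return("")
  body_start <- section_body_start(sections, name)
  substr(src, body_start, b[2])
}

parse_header_id <- function(sections, src) {
  hdr <- section_text(sections, "archetype", src)
  # drop a parenthesised adl_version annotation if present
  hdr <- sub("^\\s*\\(adl_version\\s*=\\s*[0-9.]+\\s*\\)", "", hdr)
  lines <- strsplit(hdr, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop_dqr("archetype header carries no archetype id", class = "dqr_structure_error")
  }
  id <- lines[1]
  if (!grepl("^[A-Za-z][A-Za-z0-9_+-]*(-[A-Za-z0-9_]+)+\\.[A-Za-z0-9_.-]+$", id)) {
    stop_dqr("malformed archetype id: '", id, "'", class = "dqr_structure_error")
  }
  id
}

entry_type_from_id <- function(archetype_id) {
  qualified <- strsplit(archetype_id, ".", fixed = TRUE)[[1]][1]
  segs <- strsplit(qualified, "-", fixed = TRUE)[[1]]
  known <- c("ADMIN_ENTRY", "OBSERVATION", "EVALUATION", "INSTRUCTION",
             "ACTION", "CLUSTER")
  if (length(segs) >= 2 && toupper(segs[2]) == "DEMOGRAPHIC") return("DEMOGRAPHIC")
  rm_class <- toupper(paste(segs[-(1:2)], collapse = "_"))
  if (length(segs) >= 3 && rm_class %in% known) rm_class else "OTHER"
}

concept_segment <- function(archetype_id) {
  parts <- strsplit(archetype_id, ".", fixed = TRUE)[[1]]
  if (length(parts) >= 2) parts[2] else archetype_id
}

ont_lookup <- function(ontology, code) {
  if (length(ontology) && code %in% names(ontology)) ontology[[code]] else NULL
}

# Ontology term definitions of the form ["at0000"] = <"Blood pressure">.
parse_ontology <- function(txt) {
  if (!nzchar(txt)) return(stats::setNames(character(0), character(0)))
  m <- gregexpr('\\[\\"(at[0-9.]+)\\"\\]\\s*=\\s*<\\"([^\"]*)\\"', txt, perl = TRUE)[[1]]
  out <- character(0)
  if (m[1] != -1) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      piece <- substring(txt, m[i], m[i] + lens[i] - 1L)
      code <- sub('^\\[\\"(at[0-9.]+)\\"\\].*$', "\\1", piece)
      term <- sub('^.*<\\"([^\"]*)\\".*$', "\\1", piece)
      out[code] <- term
    }
  }
  out
}

## ---------------------------------------------------------------------------
## cADL node parsing
## ---------------------------------------------------------------------------

is_rm_type_name <- function(name) grepl("^[A-Z][A-Z0-9_]*$", name)

# Parses one node: IDENT [ '[' atcode ']' ] clause* where a plain
# `matches { ... }` clause may hold a payload (interval / strings / code
# list) or nested child nodes.
parse_cadl_node <- function(p, path, ontology, is_root = FALSE) {
  name_tok <- p_expect(p, type = "IDENT", what = "a node or attribute name")
  name <- name_tok$text

  atcode <- NA_character_
  if (!is.null(p_peek(p)) && p_peek(p)$text == "[") {
    p_next(p)
    code_tok <- p_expect(p, type = "IDENT", what = "an at-code")
    atcode <- code_tok$text
    p_expect(p, "]")
  }

  component <- if (is_rm_type_name(name)) {
    if (!is.na(atcode)) (ont_lookup(ontology, atcode) %||% atcode) else name
  } else name
  node_path <- if (is_root) "" else paste0(path, "/", component)

  node <- list(
    name = name,
    atcode = atcode,
    node_path = node_path,
    constraints = list(),
    children = list()
  )

  first_clause <- TRUE
  repeat {
    tok <- p_peek(p)
    if (is.null(tok) || tok$type != "IDENT") break

    if (tok$text %in% c("existence", "occurrences", "cardinality") &&
        !is.null(p_peek(p, 1L)) && p_peek(p, 1L)$text == "matches") {
      kw_tok <- p_next(p)
      p_expect(p, "matches")
      open <- p_expect(p, "{")
      close <- scan_balanced(p, "{", "}")
      raw_inside <- substr(p$src, open$end + 1L, close$start - 1L)
      node$constraints[[length(node$constraints) + 1L]] <- list(
        clause = kw_tok$text,
        payload_kind = "interval",
        payload = parse_interval(trimws(raw_inside)),
        raw_start = if (first_clause) name_tok$start else kw_tok$start,
        raw_end = close$end
      )
      first_clause <- FALSE
    } else if (tok$text == "matches") {
      m_tok <- p_next(p)
      p_expect(p, "{")
      inner <- p_peek(p)
      if (is.null(inner)) p_error(p, m_tok, "unterminated matches block")

      if (inner$text == "|") {
        # interval payload |a..b|
        open_pipe <- p_next(p)
        close_pipe <- scan_until_pipe(p)
        close <- p_expect(p, "}")
        raw <- substr(p$src, open_pipe$start, close_pipe$end)
        node$constraints[[length(node$constraints) + 1L]] <- list(
          clause = "matches",
          payload_kind = "interval",
          payload = parse_interval(raw),
          raw_start = if (first_clause) name_tok$start else m_tok$start,
          raw_end = close$end
        )
      } else if (inner$text == "[") {
        payload <- parse_code_list(p)
        close <- p_expect(p, "}")
        node$constraints[[length(node$constraints) + 1L]] <- list(
          clause = "matches",
          payload_kind = "codeset",
          payload = payload,
          raw_start = if (first_clause) name_tok$start else m_tok$start,
          raw_end = close$end
        )
      } else if (inner$type == "STRING" || inner$type == "NUMBER") {
        payload <- parse_literal_list(p)
        close <- p_expect(p, "}")
        node$constraints[[length(node$constraints) + 1L]] <- list(
          clause = "matches",
          payload_kind = if (length(payload$values) > 1L) "valueset" else "literal",
          payload = payload,
          raw_start = if (first_clause) name_tok$start else m_tok$start,
          raw_end = close$end
        )
      } else if (inner$type == "IDENT") {
        # nested child nodes
        while (!is.null(p_peek(p)) && p_peek(p)$text != "}") {
          child <- parse_cadl_node(p, path = node_path, ontology = ontology)
          node$children[[length(node$children) + 1L]] <- child
        }
        p_expect(p, "}")
      } else if (inner$text == "}") {
        p_next(p)  # empty matches block: structural, no constraint
      } else {
        p_error(p, inner, paste0("unsupported matches payload starting with '",
                                 inner$text, "'"))
      }
      first_clause <- FALSE
    } else {
      break
    }
  }

  node
}

# Consume tokens until the matching close brace; returns the closing token.
scan_balanced <- function(p, open_sym, close_sym) {
  depth <- 1L
  repeat {
    tok <- p_next(p)
    if (tok$text == open_sym) depth <- depth + 1L
    if (tok$text == close_sym) {
      depth <- depth - 1L
      if (depth == 0L) return(tok)
    }
  }
}

scan_until_pipe <- function(p) {
  repeat {
    tok <- p_next(p)
    if (tok$text == "|") return(tok)
  }
}

# [local::at0001, at0002] or [ICD10::I10, I11]
parse_code_list <- function(p) {
  p_expect(p, "[")
  term_tok <- p_expect(p, type = "IDENT", what = "a terminology id")
  p_expect(p, "::", what = "'::'")
  codes <- character(0)
  repeat {
    tok <- p_next(p)
    if (!tok$type %in% c("IDENT", "NUMBER")) {
      p_error(p, tok, paste0("expected a code but found '", tok$text, "'"))
    }
    codes <- c(codes, tok$text)
    nxt <- p_next(p)
    if (nxt$text == "]") break
    if (nxt$text != ",") p_error(p, nxt, "expected ',' or ']' in code list")
  }
  if (anyDuplicated(codes)) {
    stop_dqr("duplicate codes in code list: ",
             paste(codes[duplicated(codes)], collapse = ", "),
             class = "dqr_parse_error")
  }
  list(terminology = term_tok$text, codes = codes)
}

# 'Dr', 'Miss' / "mm[Hg]" / bare numbers
parse_literal_list <- function(p) {
  values <- character(0)
  quote_char <- NULL
  repeat {
    tok <- p_next(p)
    if (tok$type == "STRING") {
      if (is.null(quote_char)) quote_char <- substr(tok$text, 1, 1)
      values <- c(values, substr(tok$text, 2, nchar(tok$text) - 1L))
    } else if (tok$type == "NUMBER") {
      values <- c(values, tok$text)
    } else {
      p_error(p, tok, paste0("expected a literal but found '", tok$text, "'"))
    }
    nxt <- p_peek(p)
    if (is.null(nxt)) stop_dqr("unterminated literal list", class = "dqr_parse_error")
    if (nxt$text == ",") { p_next(p); next }
    break
  }
  if (anyDuplicated(values)) {
    stop_dqr("duplicate members in value set", class = "dqr_parse_error")
  }
  list(values = values, quote = quote_char %||% "\"")
}

## ---------------------------------------------------------------------------
## Interval micro-grammar
## ---------------------------------------------------------------------------

#' Parse an ADL interval constraint
#'
#' Handles the interval notations used by occurrences, existence,
#' cardinality and quantity-magnitude constraints: `|a..b|`, `|>a..<b|`,
#' `|..b|`, `|a..|`, `(a..b)`, `{0..*}`, `(..unique)` and the
#' semicolon-separated cardinality flags (`unique`, `ordered`,
#' `unordered`). `*` (or an absent bound) marks an unbounded side. Bounds
#' are inclusive unless prefixed `>` (lower) or `<` (upper).
#'
#' @param raw interval text, with or without the `|`, `(` or `{` delimiters.
#' @return An object of class `adl_interval` with fields `lower`, `upper`,
#'   `lower_included`, `upper_included`, `lower_unbounded`,
#'   `upper_unbounded`, `unique_flag`.
#' @examples
#' parse_interval("|0.0..1000|")
#' parse_interval("(0..*; unique)")
#' @export
parse_interval <- function(raw) {
  s <- trimws(raw)
  orig <- s
  # strip one layer of |...|, (...) or {...}
  if (grepl("^\\|.*\\|$", s)) s <- substr(s, 2, nchar(s) - 1L)
  else if (grepl("^\\(.*\\)$", s)) s <- substr(s, 2, nchar(s) - 1L)
  else if (grepl("^\\{.*\\}$", s)) s <- substr(s, 2, nchar(s) - 1L)
  s <- trimws(s)

  unique_flag <- FALSE
  if (grepl(";", s, fixed = TRUE)) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    s <- trimws(parts[1])
    flags <- trimws(parts[-1])
    bad <- setdiff(flags, c("unique", "ordered", "unordered", ""))
    if (length(bad)) {
      stop_dqr("unknown cardinality flag '", bad[1], "' in '", orig, "'",
               class = "dqr_interval_error")
    }
    unique_flag <- "unique" %in% flags
  }
  # the (..unique) shorthand: uniqueness with no count bounds
  if (grepl("^\\.\\.\\s*unique$", s)) {
    s <- ".."
    unique_flag <- TRUE
  }

  if (!grepl("..", s, fixed = TRUE)) {
    stop_dqr("malformed interval '", orig, "': missing '..' separator",
             class = "dqr_interval_error")
  }
  halves <- strsplit(s, "..", fixed = TRUE)[[1]]
  if (length(halves) > 2) {
    stop_dqr("malformed interval '", orig, "': more than one '..'",
             class = "dqr_interval_error")
  }
  lo_txt <- trimws(if (length(halves) >= 1) halves[1] else "")
  hi_txt <- trimws(if (length(halves) == 2) halves[2] else "")

  lower_included <- !startsWith(lo_txt, ">")
  upper_included <- !startsWith(hi_txt, "<")
  lo_txt <- sub("^>", "", lo_txt)
  hi_txt <- sub("^<", "", hi_txt)

  parse_bound <- function(txt, side) {
    if (txt == "" || txt == "*") return(NA_real_)
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v)) {
      stop_dqr("malformed interval '", orig, "': non-numeric ", side,
               " bound '", txt, "'", class = "dqr_interval_error")
    }
    v
  }
  lower <- parse_bound(lo_txt, "lower")
  upper <- parse_bound(hi_txt, "upper")
  lower_unbounded <- is.na(lower)
  upper_unbounded <- is.na(upper)
  if (!lower_unbounded && !upper_unbounded && lower > upper) {
    stop_dqr("malformed interval '", orig, "': lower bound exceeds upper",
             class = "dqr_interval_error")
  }

  structure(
    list(
      lower = lower, upper = upper,
      lower_included = if (lower_unbounded) FALSE else lower_included,
      upper_included = if (upper_unbounded) FALSE else upper_included,
      lower_unbounded = lower_unbounded,
      upper_unbounded = upper_unbounded,
      unique_flag = unique_flag
    ),
    class = "adl_interval"
  )
}

#' Render an interval in canonical ADL notation
#'
#' Inverse of [parse_interval()]: `parse_interval(render_interval(x))` is
#' equal to `x`.
#'
#' @param iv an `adl_interval`.
#' @param delim delimiter style: `"pipes"` (`|a..b|`), `"braces"` (bare
#'   `a..b`, for occurrences blocks) or `"parens"`.
#' @return character scalar.
#' @export
render_interval <- function(iv, delim = c("pipes", "braces", "parens")) {
  delim <- match.arg(delim)
  lo <- if (iv$lower_unbounded) "*" else
    paste0(if (!iv$lower_included) ">" else "", format_num(iv$lower))
  hi <- if (iv$upper_unbounded) "*" else
    paste0(if (!iv$upper_included) "<" else "", format_num(iv$upper))
  core <- paste0(lo, "..", hi)
  if (iv$unique_flag) core <- paste0(core, "; unique")
  switch(delim,
    pipes = paste0("|", core, "|"),
    parens = paste0("(", core, ")"),
    braces = core
  )
}

## ---------------------------------------------------------------------------
## Constraint extraction
## ---------------------------------------------------------------------------

#' Extract quality constraints from a parsed archetype
#'
#' Walks the definition tree in document order and emits one row per
#' constraint clause. Keywords follow the five quality-related ADL keywords
#' (cardinality, occurrences, existence, defining_code, matches), with the
#' `matches` family split by payload: value range, value set / literal, and
#' units designation (a literal on an attribute named `units`). Terminology
#' code lists are reported as `DEFINING_CODE` regardless of attribute name.
#'
#' @param model an `archetype_model` from [parse_archetype()].
#' @return A data frame of class `dqr_constraints` with columns
#'   `archetype_id`, `node_path`, `attribute_name`, `keyword`, `payload`
#'   (list column of `adl_interval` / value-set / code-set / literal
#'   payloads) and `raw_text` (verbatim constraint substring of the source).
#' @export
extract_constraints <- function(model) {
  stopifnot(inherits(model, "archetype_model"))
  rows <- list()

  walk <- function(node) {
    for (con in node$constraints) {
      keyword <- constraint_keyword(node, con)
      payload <- constraint_payload(con)
      rows[[length(rows) + 1L]] <<- list(
        archetype_id = model$archetype_id,
        node_path = node$node_path,
        attribute_name = node$name,
        keyword = keyword,
        payload = payload,
        raw_text = substr(model$source, con$raw_start, con$raw_end)
      )
    }
    for (child in node$children) walk(child)
  }
  walk(model$nodes)

  out <- data.frame(
    archetype_id = vapply(rows, `[[`, "", "archetype_id"),
    node_path = vapply(rows, `[[`, "", "node_path"),
    attribute_name = vapply(rows, `[[`, "", "attribute_name"),
    keyword = vapply(rows, `[[`, "", "keyword"),
    raw_text = vapply(rows, `[[`, "", "raw_text"),
    stringsAsFactors = FALSE
  )
  out$payload <- lapply(rows, `[[`, "payload")
  out <- out[, c("archetype_id", "node_path", "attribute_name", "keyword",
                 "payload", "raw_text")]
  class(out) <- c("dqr_constraints", "data.frame")
  out
}

constraint_keyword <- function(node, con) {
  switch(con$clause,
    existence = "EXISTENCE",
    occurrences = "OCCURRENCES",
    cardinality = "CARDINALITY",
    matches = switch(con$payload_kind,
      interval = "MATCHES_RANGE",
      codeset = "DEFINING_CODE",
      valueset = "MATCHES_VALUE",
      literal = if (identical(node$name, "units")) "MATCHES_UNITS" else "MATCHES_VALUE"
    )
  )
}

constraint_payload <- function(con) {
  if (con$payload_kind == "interval") return(con$payload)
  if (con$payload_kind == "codeset") {
    return(structure(con$payload, class = "adl_codeset"))
  }
  if (con$payload_kind == "valueset") {
    return(structure(list(values = con$payload$values, quote = con$payload$quote),
                     class = "adl_valueset"))
  }
  structure(list(value = con$payload$values[[1]], quote = con$payload$quote),
            class = "adl_literal")
}

#' All node paths of a parsed archetype
#'
#' @param model an `archetype_model`.
#' @param constrained_only if `TRUE`, only paths of nodes that carry at
#'   least one quality constraint.
#' @return character vector of slash-separated paths (document order).
#' @export
node_paths <- function(model, constrained_only = FALSE) {
  out <- character(0)
  walk <- function(node) {
    if (nzchar(node$node_path) &&
        (!constrained_only || length(node$constraints) > 0)) {
      out <<- c(out, node$node_path)
    }
    for (child in node$children) walk(child)
  }
  walk(model$nodes)
  out
}

#' @export
print.archetype_model <- function(x, ...) {
  cat("<archetype_model> ", x$archetype_id, "\n", sep = "")
  cat("  entry type: ", x$entry_type, "\n", sep = "")
  cat("  concept:    ", x$concept_name, "\n", sep = "")
  cat("  nodes:      ", length(node_paths(x)), " (",
      length(node_paths(x, constrained_only = TRUE)), " constrained)\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Canonical serialization (round-trip support)
## ---------------------------------------------------------------------------

render_payload <- function(payload) {
  if (inherits(payload, "adl_interval")) {
    return(render_interval(payload, "pipes"))
  }
  if (inherits(payload, "adl_codeset")) {
    return(paste0("[", payload$terminology, "::",
                  paste(payload$codes, collapse = ", "), "]"))
  }
  if (inherits(payload, "adl_valueset")) {
    q <- payload$quote %||% "'"
    return(paste(paste0(q, payload$values, q), collapse = ", "))
  }
  q <- payload$quote %||% "\""
  paste0(q, payload$value, q)
}

# One canonical clause, e.g. `existence matches {1..1}` or
# `matches {|0..1000|}` (without the attribute-name prefix).
render_constraint_clause <- function(keyword, payload) {
  switch(keyword,
    EXISTENCE = paste0("existence matches {", render_interval(payload, "braces"), "}"),
    OCCURRENCES = paste0("occurrences matches {", render_interval(payload, "braces"), "}"),
    CARDINALITY = paste0("cardinality matches {", render_interval(payload, "braces"), "}"),
    MATCHES_RANGE = paste0("matches {", render_payload(payload), "}"),
    DEFINING_CODE = paste0("matches {", render_payload(payload), "}"),
    MATCHES_VALUE = paste0("matches {", render_payload(payload), "}"),
    MATCHES_UNITS = paste0("matches {", render_payload(payload), "}")
  )
}

#' Serialize constraints back to canonical ADL text
#'
#' Rebuilds a definition tree from the slash-separated node paths and emits
#' a minimal archetype in the supported subset, such that
#' [parse_archetype()] + [extract_constraints()] on the output reproduces
#' the constraint list (canonical round-trip). Path components must be plain
#' identifiers.
#'
#' @param constraints a `dqr_constraints` data frame.
#' @param archetype_id archetype identifier for the emitted header; defaults
#'   to the constraints' own id.
#' @return ADL source text (character scalar).
#' @export
constraints_to_adl <- function(constraints,
                               archetype_id = constraints$archetype_id[1]) {
  stopifnot(nrow(constraints) > 0)
  root_type <- entry_type_from_id(archetype_id)
  if (root_type %in% c("DEMOGRAPHIC", "OTHER")) root_type <- "ITEM_TREE"

  # tree of environments keyed by path component
  root <- new_node_env()
  for (i in seq_len(nrow(constraints))) {
    comps <- strsplit(sub("^/", "", constraints$node_path[i]), "/", fixed = TRUE)[[1]]
    if (any(!grepl("^[A-Za-z_][A-Za-z0-9_]*$", comps))) {
      stop_dqr("cannot serialize path with non-identifier components: ",
               constraints$node_path[i], class = "dqr_serialize_error")
    }
    env <- root
    for (comp in comps) env <- child_env(env, comp)
    env$clauses[[length(env$clauses) + 1L]] <-
      render_constraint_clause(constraints$keyword[i], constraints$payload[[i]])
  }

  lines <- c(
    "archetype (adl_version=1.4)",
    paste0("    ", archetype_id),
    "",
    "concept",
    "    [at0000]",
    "",
    "definition",
    paste0("    ", root_type, "[at0000] matches {"),
    render_node_env(root, indent = 8L),
    "    }"
  )
  paste(lines, collapse = "\n")
}

new_node_env <- function() {
  env <- new.env(parent = emptyenv())
  env$children <- list()
  env$order <- character(0)
  env$clauses <- list()
  env
}

child_env <- function(env, comp) {
  if (is.null(env$children[[comp]])) {
    env$children[[comp]] <- new_node_env()
    env$order <- c(env$order, comp)
  }
  env$children[[comp]]
}

render_node_env <- function(env, indent) {
  pad <- strrep(" ", indent)
  out <- character(0)
  for (comp in env$order) {
    child <- env$children[[comp]]
    clause_txt <- if (length(child$clauses)) {
      paste(unlist(child$clauses), collapse = " ")
    } else ""
    if (length(child$order)) {
      head <- if (nzchar(clause_txt)) paste0(pad, comp, " ", clause_txt, " matches {")
              else paste0(pad, comp, " matches {")
      out <- c(out, head, render_node_env(child, indent + 4L), paste0(pad, "}"))
    } else {
      out <- c(out, paste0(pad, comp, " ", clause_txt))
    }
  }
  out
}
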