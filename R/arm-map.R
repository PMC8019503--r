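#' @title Archetype-relational mapping (ARM)
#'
#' @description
#' In an archetype-based clinical data repository every archetype attribute
#' has a corresponding table and column. That correspondence is declared
#' here in an explicit mapping file (YAML or JSON) rather than derived:
#' one entry per `(archetype_id, node_path, role)` binding, where `role`
#' distinguishes the value column, an accompanying units column, a
#' terminology-code column, a timestamp column, and the grouping key used
#' by occurrences/cardinality rules. Temporal links between Entry tables
#' (request vs execution) are declared alongside, including the join keys
#' that the temporal rule template needs.
#' @name arm-map
NULL

MAPPING_ROLES <- c("VALUE", "UNITS", "CODE", "TIME", "KEY")

#' Construct a mapping table from entries
#'
#' @param entries data frame with columns `archetype_id`, `node_path`,
#'   `table_name`, `column_name`, `role`.
#' @param temporal_links list of temporal links, each a list with
#'   `earlier_table`, `earlier_time_column`, `later_table`,
#'   `later_time_column`, `join_pairs` (list of 2-element character
#'   vectors) and optionally `earlier_entry_type` / `later_entry_type`.
#' @return an object of class `mapping_table`.
#' @export
mapping_table <- function(entries, temporal_links = list()) {
  required <- c("archetype_id", "node_path", "table_name", "column_name", "role")
  if (is.null(entries) || !nrow(entries)) {
    entries <- data.frame(archetype_id = character(0), node_path = character(0),
                          table_name = character(0), column_name = character(0),
                          role = character(0), stringsAsFactors = FALSE)
  }
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    stop_dqr("mapping entries lack required fields: ",
             paste(missing, collapse = ", "), class = "dqr_mapping_error")
  }
  bad_role <- setdiff(unique(entries$role), MAPPING_ROLES)
  if (length(bad_role)) {
    stop_dqr("invalid mapping role(s): ", paste(bad_role, collapse = ", "),
             class = "dqr_mapping_error")
  }
  key <- paste(entries$archetype_id, entries$node_path, entries$role, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- entries[duplicated(key), , drop = FALSE]
    stop_dqr("duplicate mapping entries for: ",
             paste(unique(paste0(dup$archetype_id, ":", dup$node_path, " [",
                                 dup$role, "]")), collapse = "; "),
             class = "dqr_mapping_error")
  }
  for (lk in temporal_links) {
    need <- c("earlier_table", "earlier_time_column", "later_table",
              "later_time_column", "join_pairs")
    miss <- setdiff(need, names(lk))
    if (length(miss)) {
      stop_dqr("temporal link lacks fields: ", paste(miss, collapse = ", "),
               class = "dqr_mapping_error")
    }
    if (!length(lk$join_pairs)) {
      stop_dqr("temporal link has no join pairs (",
               lk$earlier_table, " -> ", lk$later_table, ")",
               class = "dqr_mapping_error")
    }
  }
  structure(
    list(entries = entries[, required, drop = FALSE], temporal_links = temporal_links),
    class = "mapping_table"
  )
}

#' Load an archetype-relational mapping from YAML or JSON
#'
#' The file holds an `entries:` list (each with `archetype_id`,
#' `node_path`, `table`, `column`, `role`) and an optional
#' `temporal_links:` list (each with `earlier_table`,
#' `earlier_time_column`, `later_table`, `later_time_column`, `join` as a
#' list of `[earlier_key, later_key]` pairs, and optional
#' `earlier_entry_type` / `later_entry_type`).
#'
#' @param path mapping file (`.yaml`/`.yml` or `.json`).
#' @return a `mapping_table`.
#' @export
load_mapping <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  mapping_from_config(cfg)
}

mapping_from_config <- function(cfg) {
  entries_cfg <- cfg$entries %||% list()
  need <- function(e, field, alt = NULL) {
    v <- e[[field]] %||% (if (!is.null(alt)) e[[alt]] else NULL)
    if (is.null(v)) {
      stop_dqr("mapping entry missing field '", field, "': ",
               paste(unlist(e), collapse = " / "), class = "dqr_mapping_error")
    }
    as.character(v)
  }
  entries <- data.frame(
    archetype_id = vapply(entries_cfg, need, "", field = "archetype_id"),
    node_path = vapply(entries_cfg, need, "", field = "node_path"),
    table_name = vapply(entries_cfg, need, "", field = "table", alt = "table_name"),
    column_name = vapply(entries_cfg, need, "", field = "column", alt = "column_name"),
    role = toupper(vapply(entries_cfg, function(e) as.character(e$role %||% "VALUE"), "")),
    stringsAsFactors = FALSE
  )
  links <- lapply(cfg$temporal_links %||% list(), function(lk) {
    list(
      earlier_table = as.character(lk$earlier_table),
      earlier_time_column = as.character(lk$earlier_time_column),
      later_table = as.character(lk$later_table),
      later_time_column = as.character(lk$later_time_column),
      join_pairs = lapply(lk$join %||% lk$join_pairs, function(jp) as.character(unlist(jp))),
      earlier_entry_type = as.character(lk$earlier_entry_type %||% "INSTRUCTION"),
      later_entry_type = as.character(lk$later_entry_type %||% "ACTION")
    )
  })
  mapping_table(entries, links)
}

#' Save a mapping to YAML
#'
#' Round-trips through [load_mapping()] without loss.
#'
#' @param mapping a `mapping_table`.
#' @param path output file path (`.yaml`).
#' @export
save_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "mapping_table"))
  e <- mapping$entries
  entries <- lapply(seq_len(nrow(e)), function(i) {
    list(archetype_id = e$archetype_id[i], node_path = e$node_path[i],
         table = e$table_name[i], column = e$column_name[i], role = e$role[i])
  })
  links <- lapply(mapping$temporal_links, function(lk) {
    list(earlier_table = lk$earlier_table,
         earlier_time_column = lk$earlier_time_column,
         later_table = lk$later_table,
         later_time_column = lk$later_time_column,
         join = lapply(lk$join_pairs, as.list),
         earlier_entry_type = lk$earlier_entry_type %||% "INSTRUCTION",
         later_entry_type = lk$later_entry_type %||% "ACTION")
  })
  yaml::write_yaml(list(entries = entries, temporal_links = links), path)
  invisible(path)
}

#' Resolve an archetype attribute to its table/column binding
#'
#' Exact-match lookup on `(archetype_id, node_path, role)`; no fuzzy
#' resolution.
#'
#' @param mapping a `mapping_table`.
#' @param archetype_id archetype identifier.
#' @param node_path slash-separated attribute path.
#' @param role one of `VALUE`, `UNITS`, `CODE`, `TIME`, `KEY`.
#' @return list with `table_name` and `column_name`.
#' @export
resolve_mapping <- function(mapping, archetype_id, node_path, role = "VALUE") {
  stopifnot(inherits(mapping, "mapping_table"))
  e <- mapping$entries
  hit <- which(e$archetype_id == archetype_id & e$node_path == node_path &
               e$role == role)
  if (!length(hit)) {
    stop_dqr("unmapped attribute: ", archetype_id, ":", node_path,
             " [", role, "]", class = "dqr_resolve_error")
  }
  list(table_name = e$table_name[hit[1]], column_name = e$column_name[hit[1]])
}

# The KEY-role column for a table (grouping key for occurrences/cardinality
# rules); NULL when the table declares none.
key_column_for <- function(mapping, table_name) {
  e <- mapping$entries
  hit <- which(e$table_name == table_name & e$role == "KEY")
  if (!length(hit)) NULL else e$column_name[hit[1]]
}

#' @export
print.mapping_table <- function(x, ...) {
  cat("<mapping_table> ", nrow(x$entries), " entries, ",
      length(x$temporal_links), " temporal link(s)\n", sep = "")
  invisible(x)
}
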