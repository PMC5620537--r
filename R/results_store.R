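#' Relational PSM results store
#'
#' A single-file (or in-memory) SQLite database holding one row per
#' peptide-spectrum match in a canonical worksheet schema, with Mascot-style
#' column headers. Column shortcuts (`varmods`, `peptide`, `score`, ...) are
#' expanded before query execution.
#'
#' Canonical columns: `Run`, `Scan`, `Peptide Sequence`,
#' `Variable Modifications`, `Charge`, `Peptide Score`, `Engine`,
#' `Protein Accessions`, `Precursor MZ`, `RT`.
#'
#' @param path SQLite file path, or `":memory:"` (default).
#' @return An `mz_results_db` handle.
#' @export
results_db <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  if (!"psms" %in% DBI::dbListTables(con)) {
    DBI::dbExecute(con, paste0(
      'CREATE TABLE psms ("Run" TEXT, "Scan" INTEGER, "Peptide Sequence" TEXT, ',
      '"Variable Modifications" TEXT, "Charge" INTEGER, "Peptide Score" REAL, ',
      '"Engine" TEXT, "Protein Accessions" TEXT, "Precursor MZ" REAL, "RT" REAL)'
    ))
  }
  structure(list(con = con, path = path), class = "mz_results_db")
}

#' @export
print.mz_results_db <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM psms")$n
  cat(sprintf("<mz_results_db> %s  %d PSM(s)\n", x$path, n))
  invisible(x)
}

#' @rdname results_db
#' @param db An `mz_results_db`.
#' @export
results_close <- function(db) {
  DBI::dbDisconnect(db$con)
  invisible(NULL)
}

RESULTS_COLUMNS <- c("Run", "Scan", "Peptide Sequence", "Variable Modifications",
                     "Charge", "Peptide Score", "Engine", "Protein Accessions",
                     "Precursor MZ", "RT")

COLUMN_SHORTCUTS <- c(
  varmods   = "Variable Modifications",
  mods      = "Variable Modifications",
  peptide   = "Peptide Sequence",
  seq       = "Peptide Sequence",
  score     = "Peptide Score",
  accessions = "Protein Accessions",
  proteins  = "Protein Accessions",
  mz        = "Precursor MZ"
)

SQL_KEYWORDS <- c("AND", "AS", "ASC", "BETWEEN", "BY", "COUNT", "DESC",
                  "DISTINCT", "FROM", "GROUP", "HAVING", "IN", "IS", "LIKE",
                  "LIMIT", "MAX", "MIN", "NOT", "NULL", "OR", "ORDER",
                  "SELECT", "SUM", "WHERE")

ENGINES <- c("mascot", "xtandem", "comet", "proteome_discoverer", "internal")

#' Import search results
#'
#' Reads PSM rows from delimited text (TSV/CSV with a header row in the
#' canonical worksheet dialect) or pepXML, keeping only top-ranked hits by
#' default. Combined multi-run files keep their per-run basenames so rows can
#' later be re-linked to raw scans.
#'
#' @param db An `mz_results_db`.
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"pepxml"`.
#' @param keep_all_ranks Import all ranked hits from pepXML (default: rank 1
#'   only).
#' @return `db`, invisibly; use [results_query()] to inspect.
#' @export
import_results <- function(db, path, format = c("auto", "tsv", "csv", "pepxml"),
                           keep_all_ranks = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "mzc_data_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv",
                     pepxml = "pepxml", xml = "pepxml",
                     abort(paste0("unknown results format: .", ext), class = "mzc_data_error"))
  }
  rows <- switch(format,
    tsv = read_results_delim(path, "\t"),
    csv = read_results_delim(path, ","),
    pepxml = read_pepxml(path, keep_all_ranks = keep_all_ranks)
  )
  if (nrow(rows)) {
    names(rows) <- RESULTS_COLUMNS
    DBI::dbWriteTable(db$con, "psms", as.data.frame(rows), append = TRUE)
  }
  invisible(db)
}

read_results_delim <- function(path, sep) {
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(RESULTS_COLUMNS, names(df))
  if (length(missing)) {
    abort(paste0("results file lacks required column(s): ",
                 paste(missing, collapse = ", ")), class = "mzc_data_error")
  }
  df <- df[, RESULTS_COLUMNS]
  # enforce canonical column types (an all-empty mods column must stay character)
  chr_cols <- c("Run", "Peptide Sequence", "Variable Modifications", "Engine",
                "Protein Accessions")
  for (cc in chr_cols) {
    v <- as.character(df[[cc]])
    v[is.na(v)] <- ""
    df[[cc]] <- v
  }
  df$Scan <- as.integer(df$Scan)
  df$Charge <- as.integer(df$Charge)
  for (nc in c("Peptide Score", "Precursor MZ", "RT")) df[[nc]] <- as.numeric(df[[nc]])
  as_tibble(df)
}

read_pepxml <- function(path, keep_all_ranks = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("malformed pepXML: ",
                                                   conditionMessage(e)),
                                            class = "mzc_data_error"))
  ns <- c(p = "http://regis-web.systemsbiology.net/pepXML")
  has_ns <- length(xml2::xml_ns(doc)) > 0 &&
    any(grepl("pepXML", unlist(xml2::xml_ns(doc))))
  xp <- function(node, q) {
    if (has_ns) xml2::xml_find_all(node, gsub("//", "//p:", q), ns)
    else xml2::xml_find_all(node, q)
  }
  runs <- xp(doc, "//msms_run_summary")
  out <- purrr::map_dfr(runs, function(rn) {
    base <- basename(xml2::xml_attr(rn, "base_name"))
    eng <- xml2::xml_attr(xp(rn, ".//search_summary"), "search_engine")
    eng <- if (length(eng) && !is.na(eng[1]) && eng[1] %in% ENGINES) eng[1] else "internal"
    queries <- xp(rn, ".//spectrum_query")
    purrr::map_dfr(queries, function(q) {
      hits <- xp(q, ".//search_hit")
      if (!keep_all_ranks) {
        rank <- as.integer(xml2::xml_attr(hits, "hit_rank"))
        hits <- hits[is.na(rank) | rank == 1L]
      }
      purrr::map_dfr(hits, function(h) {
        mods <- xp(h, ".//mod_aminoacid_mass")
        vm <- if (length(mods)) {
          pos <- as.integer(xml2::xml_attr(mods, "position"))
          lab <- xml2::xml_attr(mods, "label")
          if (all(is.na(lab))) {
            dm <- as.numeric(xml2::xml_attr(mods, "massdiff"))
            lab <- vapply(dm, label_for_delta, character(1))
          }
          paste(sprintf("%d:%s", pos, lab), collapse = ", ")
        } else ""
        sc <- xp(h, ".//search_score")
        score <- NA_real_
        if (length(sc)) {
          nm <- xml2::xml_attr(sc, "name")
          v <- as.numeric(xml2::xml_attr(sc, "value"))
          score <- if ("score" %in% nm) v[match("score", nm)] else v[1]
        }
        tibble(
          Run = base,
          Scan = as.integer(xml2::xml_attr(q, "start_scan")),
          `Peptide Sequence` = xml2::xml_attr(h, "peptide"),
          `Variable Modifications` = vm,
          Charge = as.integer(xml2::xml_attr(q, "assumed_charge")),
          `Peptide Score` = score,
          Engine = eng,
          `Protein Accessions` = xml2::xml_attr(h, "protein"),
          `Precursor MZ` = {
            nm <- as.numeric(xml2::xml_attr(q, "precursor_neutral_mass"))
            z <- as.integer(xml2::xml_attr(q, "assumed_charge"))
            (nm + z * PROTON_MASS) / z
          },
          RT = as.numeric(xml2::xml_attr(q, "retention_time_sec")) / 60
        )
      })
    })
  })
  out
}

label_for_delta <- function(delta, tol = 0.001) {
  v <- mod_vocabulary()
  i <- which(abs(v$delta - delta) <= tol)
  if (length(i)) v$label[i[1]] else sprintf("%+.5f", delta)
}

# expand column shortcuts in a SQL fragment, outside quoted strings
expand_shortcuts <- function(sql) {
  # alternate chunks inside/outside single-quoted literals; rewrite outside only
  chunks <- strsplit(sql, "'", fixed = TRUE)[[1]]
  n_quotes <- lengths(regmatches(sql, gregexpr("'", sql, fixed = TRUE)))
  while (length(chunks) < n_quotes + 1L) chunks <- c(chunks, "")
  for (i in seq_along(chunks)) {
    if (i %% 2 == 1) {  # outside quotes
      for (k in names(COLUMN_SHORTCUTS)) {
        chunks[i] <- gsub(paste0("\\b", k, "\\b"),
                          paste0('"', COLUMN_SHORTCUTS[[k]], '"'),
                          chunks[i], ignore.case = TRUE)
      }
    }
  }
  paste(chunks, collapse = "'")
}

#' Query the results store
#'
#' Read-only relational access: `expression` must be a single SELECT
#' statement. Column shortcuts are expanded first (`varmods` becomes the
#' quoted `"Variable Modifications"` column, `peptide` the
#' `"Peptide Sequence"` column, and so on); syntax errors from SQLite are
#' surfaced verbatim.
#'
#' @param db An `mz_results_db`.
#' @param expression SQL SELECT text against table `psms`.
#' @return Result rows as a tibble.
#' @export
results_query <- function(db, expression) {
  stopifnot(inherits(db, "mz_results_db"))
  sql <- expand_shortcuts(expression)
  first <- toupper(sub("^\\s*", "", sql))
  if (!startsWith(first, "SELECT")) {
    abort("results store is read-only: only SELECT statements are accepted",
          class = "mzc_data_error")
  }
  as_tibble(DBI::dbGetQuery(db$con, sql))
}

#' Autocomplete a partial query
#'
#' Completions for the token under the cursor: SQL keywords first, then
#' column shortcuts, then canonical column names — case-insensitive prefix
#' match, alphabetical within each group.
#'
#' @param db An `mz_results_db` (columns are read from it; `NULL` uses the
#'   canonical schema).
#' @param fragment Partial query text.
#' @param cursor Cursor position (defaults to end of fragment).
#' @return Character vector of ranked completions.
#' @export
results_complete <- function(db = NULL, fragment = "", cursor = nchar(fragment)) {
  before <- substr(fragment, 1, cursor)
  tok <- regmatches(before, regexpr("[A-Za-z_][A-Za-z0-9_]*$", before))
  prefix <- if (length(tok)) tolower(tok) else ""
  cols <- RESULTS_COLUMNS
  if (!is.null(db)) {
    cols <- tryCatch(DBI::dbListFields(db$con, "psms"), error = function(e) RESULTS_COLUMNS)
  }
  pick <- function(x) sort(x[startsWith(tolower(x), prefix)])
  c(pick(SQL_KEYWORDS), pick(names(COLUMN_SHORTCUTS)), pick(cols))
}

# distinct (run, scan) pairs that have a sequence assignment
results_matched_scans <- function(db) {
  df <- DBI::dbGetQuery(db$con, 'SELECT DISTINCT "Run" AS run, "Scan" AS scan FROM psms')
  as_tibble(df)
}

#' Fetch the matched MS/MS spectrum for a PSM row
#'
#' Re-links a results row to its raw scan through the run cache: the PSM
#' inspection loop (combine with [annotate_spectrum()] to view the assigned
#' fragment ions on the spectrum).
#'
#' @param db An `mz_results_db` (unused for the lookup itself; kept for the
#'   record-centric call signature).
#' @param record A one-row tibble or list with `Run` and `Scan` fields.
#' @param cache An `mz_run_cache`.
#' @param run_paths Named character vector: run basename -> mzML path.
#' @return The `mz_spectrum` the PSM was matched to.
#' @export
psm_to_scan <- function(db, record, cache, run_paths) {
  base <- strip_mz_ext(as.character(record$Run[[1]]))
  names(run_paths) <- strip_mz_ext(names(run_paths))
  if (!base %in% names(run_paths)) {
    abort(paste0("raw run file not available for basename '", base, "'"),
          class = "mzc_data_error")
  }
  run <- cache_get(cache, run_paths[[base]])
  get_scan(run, as.integer(record$Scan[[1]]))
}

#' Export the PSM table as canonical TSV
#'
#' @param db An `mz_results_db`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_results <- function(db, path) {
  df <- results_query(db, "SELECT * FROM psms")
  header <- paste(names(df), collapse = "\t")
  cells <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  body <- do.call(paste, c(cells, sep = "\t"))
  write_atomic(c(header, body), path)
}
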