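# Tab-separated readers/writers for the formats the pipeline touches:
# coding dictionaries (coding19.txt style), TRUD-style mapping tables,
# gp_clinical-style event tables, and the pipeline's own mapping output.
# All files are UTF-8 TSV with header rows.

KNOWN_STATUS <- c("E", "G", "D", "A", "R")

read_tsv_raw <- function(path) {
  utils::read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    quote = "", fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rb_error(sprintf("%s: missing required column(s): %s",
                     what, paste(missing, collapse = ", ")),
             "schema_error")
  }
  invisible(df)
}

#' Read a coding dictionary (code + description TSV)
#'
#' Parses a UK Biobank-style coding file: tab-separated with header
#' columns `coding` and `meaning` (optionally `parent`). Row order is
#' preserved; all concepts are marked active.
#'
#' @param path Path to the TSV file.
#' @param system Code-system label for the resulting ontology.
#' @return An [ontology()].
#' @export
read_coding_table <- function(path, system = "ICD10") {
  df <- read_tsv_raw(path)
  require_columns(df, c("coding", "meaning"), "coding table")
  dup <- duplicated(df$coding)
  if (any(dup)) {
    rb_error(sprintf("duplicate coding value(s): %s",
                     paste(unique(df$coding[dup]), collapse = ", ")),
             "duplicate_key_error")
  }
  parent <- if ("parent" %in% names(df)) {
    ifelse(nzchar(df$parent), df$parent, NA_character_)
  } else {
    rep(NA_character_, nrow(df))
  }
  ontology(system, df$coding, df$meaning, active = TRUE, parent_code = parent)
}

#' Write an ontology back out as a coding table
#'
#' @param ont An [ontology()].
#' @param path Output path.
#' @export
write_coding_table <- function(ont, path) {
  df <- data.frame(coding = ont$concepts$code,
                   meaning = ont$concepts$description,
                   stringsAsFactors = FALSE)
  if (any(!is.na(ont$concepts$parent_code))) {
    df$parent <- ifelse(is.na(ont$concepts$parent_code), "",
                        ont$concepts$parent_code)
  }
  write_tsv_utf8(df, path)
  invisible(path)
}

write_tsv_utf8 <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, con, useBytes = TRUE)
}

#' Read a TRUD-style mapping table
#'
#' Tab-separated with required columns `read_code`, `target_code`,
#' `target_system`; optional columns `read_version`, `mapping_status`,
#' `refine_flag`, `add_code_flag`, `element_num`, `block_num`,
#' `provenance`. Blank flag cells stay blank (`""`). Rows are returned in
#' file order. Unknown mapping-status characters are kept but listed in
#' the parse report attached as attribute `"report"`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of mapping entries with attribute `"report"`
#'   (a list with element `unknown_status`).
#' @export
read_mapping_table <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("read_code", "target_code", "target_system"),
                  "mapping table")
  opt <- c("read_version", "mapping_status", "refine_flag", "add_code_flag",
           "provenance")
  for (col in opt) if (!col %in% names(df)) df[[col]] <- rep("", nrow(df))
  for (col in c("element_num", "block_num")) {
    if (!col %in% names(df)) df[[col]] <- rep("", nrow(df))
    raw <- trimws(df[[col]])
    bad <- nzchar(raw) & !grepl("^[0-9]+$", raw)
    if (any(bad)) {
      rb_error(sprintf("non-integer %s at row(s): %s", col,
                       paste(which(bad), collapse = ", ")),
               "parse_error")
    }
    df[[col]] <- ifelse(nzchar(raw), suppressWarnings(as.integer(raw)),
                        NA_integer_)
  }
  df$target_system <- as_code_system(df$target_system)
  df <- df[c("read_code", "read_version", "target_code", "target_system",
             "mapping_status", "refine_flag", "add_code_flag",
             "element_num", "block_num", "provenance")]
  unknown <- nzchar(df$mapping_status) & !(df$mapping_status %in% KNOWN_STATUS)
  report <- list(
    n_rows = nrow(df),
    unknown_status = df$read_code[unknown]
  )
  attr(df, "report") <- report
  df
}

#' Write a mapping table
#'
#' @param entries Mapping-entry data frame (as from [read_mapping_table()]).
#' @param path Output path.
#' @export
write_mapping_table <- function(entries, path) {
  out <- entries
  for (col in c("element_num", "block_num")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
  }
  write_tsv_utf8(out, path)
  invisible(path)
}

#' Retrieve the parse report attached to a parsed table
#'
#' @param x An object returned by one of the readers.
#' @return The report list, or `NULL` if none was attached.
#' @export
parse_report <- function(x) attr(x, "report")

parse_event_date <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  alt <- as.Date(x, format = "%d/%m/%Y")
  d[is.na(d)] <- alt[is.na(d)]
  # reject partially matched garbage like "2010-13-45"
  d
}

#' Read a gp_clinical-style clinical event table
#'
#' Expects tab-separated columns `eid`, `data_provider`, `event_dt`,
#' `read_2`, `read_3` (extra columns such as the free-text `value` fields
#' are ignored). Rows with both Read columns empty are dropped and
#' counted; rows whose date fails to parse (ISO `YYYY-MM-DD` or
#' `DD/MM/YYYY`) are dropped and listed. Counts are attached as the
#' `"report"` attribute.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `eid`, `data_provider` (integer),
#'   `event_dt` (`Date`), `read_2`, `read_3` (`NA` where absent), with
#'   attribute `"report"`.
#' @export
read_events <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("eid", "data_provider", "event_dt",
                        "read_2", "read_3"), "events table")
  df <- df[c("eid", "data_provider", "event_dt", "read_2", "read_3")]
  r2 <- trimws(df$read_2)
  r3 <- trimws(df$read_3)
  no_code <- !nzchar(r2) & !nzchar(r3)
  dates <- parse_event_date(trimws(df$event_dt))
  bad_date <- is.na(dates) & !no_code
  keep <- !no_code & !bad_date
  out <- data.frame(
    eid = df$eid[keep],
    data_provider = as.integer(df$data_provider[keep]),
    event_dt = dates[keep],
    read_2 = ifelse(nzchar(r2[keep]), r2[keep], NA_character_),
    read_3 = ifelse(nzchar(r3[keep]), r3[keep], NA_character_),
    stringsAsFactors = FALSE
  )
  attr(out, "report") <- list(
    n_rows = nrow(df),
    n_dropped_no_code = sum(no_code),
    n_dropped_bad_date = sum(bad_date),
    bad_date_rows = which(bad_date)
  )
  out
}

# Doubles are serialized with %.17g so write -> read is the identity.
fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write pipeline mapping records
#'
#' Emits a TSV with one row per (Read code, target) pair and header
#' `read_code, read_version, target_code, target_system, method,
#' similarity, review_needed`. Writing then re-reading with
#' [read_mapping_records()] reproduces the records exactly.
#'
#' @param records Mapping-record data frame (long form, one row per
#'   target; `target_code` is `NA` for explicitly unmapped codes).
#' @param path Output path.
#' @export
write_mapping_records <- function(records, path) {
  cols <- c("read_code", "read_version", "target_code", "target_system",
            "method", "similarity", "review_needed")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    rb_error(sprintf("records missing column(s): %s",
                     paste(missing, collapse = ", ")), "schema_error")
  }
  out <- data.frame(
    read_code = records$read_code,
    read_version = records$read_version,
    target_code = ifelse(is.na(records$target_code), "",
                         records$target_code),
    target_system = ifelse(is.na(records$target_system), "",
                           records$target_system),
    method = records$method,
    similarity = fmt_num(records$similarity),
    review_needed = ifelse(records$review_needed, "TRUE", "FALSE"),
    stringsAsFactors = FALSE
  )
  write_tsv_utf8(out, path)
  invisible(path)
}

#' Read pipeline mapping records written by [write_mapping_records()]
#'
#' @param path Path to the TSV file.
#' @return Mapping-record data frame.
#' @export
read_mapping_records <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("read_code", "read_version", "target_code",
                        "target_system", "method", "similarity",
                        "review_needed"), "mapping records")
  data.frame(
    read_code = df$read_code,
    read_version = df$read_version,
    target_code = ifelse(nzchar(df$target_code), df$target_code,
                         NA_character_),
    target_system = ifelse(nzchar(df$target_system), df$target_system,
                           NA_character_),
    method = df$method,
    similarity = ifelse(nzchar(df$similarity), as.numeric(df$similarity),
                        NA_real_),
    review_needed = df$review_needed == "TRUE",
    stringsAsFactors = FALSE
  )
}
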