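#' Supported code systems
#'
#' The eight coding systems the toolkit knows about. Anything else is
#' rejected at parse time.
#'
#' @format Character vector of system identifiers.
#' @export
CODE_SYSTEMS <- c("READ2", "READ3", "ICD9", "ICD10", "ICD10CM",
                  "ICDO3", "SNOMED", "OPCS4")

# Typed conditions so callers can test on class rather than message text.
rb_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "readbridge_error", "error"),
                      call = call))
}

#' Validate code-system labels
#'
#' @param x Character vector of code-system labels.
#' @return `x`, upper-cased, if every element is a known system.
#' @export
as_code_system <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad <- !(x %in% CODE_SYSTEMS)
  if (any(bad)) {
    rb_error(sprintf("unknown code system(s): %s",
                     paste(unique(x[bad]), collapse = ", ")),
             "unknown_system_error")
  }
  x
}

#' Normalize a Read code to its canonical 5-character form
#'
#' Read v2 and CTV3 codes are stored as exactly 5 characters, right-padded
#' with dots (`"G2y"` becomes `"G2y.."`), matching the convention of the
#' TRUD dictionaries. An optional `"2/"` or `"3/"` version prefix is
#' stripped; if present it must agree with `version`.
#'
#' @param raw Character vector of raw Read codes.
#' @param version `"READ2"` or `"READ3"`.
#' @return Character vector of 5-character dot-padded codes.
#' @examples
#' normalize_read_code("3/G2y", "READ3")  # "G2y.."
#' normalize_read_code("J570", "READ2")   # "J570."
#' @export
normalize_read_code <- function(raw, version = c("READ2", "READ3")) {
  version <- match.arg(version)
  x <- trimws(as.character(raw))
  if (length(x) == 0L) return(character(0))
  if (any(is.na(x) | !nzchar(x))) {
    rb_error("empty Read code after trimming", "malformed_code_error")
  }
  pref <- substr(x, 1L, 2L)
  pref_version <- ifelse(pref == "2/", "READ2",
                         ifelse(pref == "3/", "READ3", NA_character_))
  has_pref <- !is.na(pref_version)
  conflict <- has_pref & pref_version != version
  if (any(conflict)) {
    rb_error(sprintf("Read version prefix conflicts with version=%s: %s",
                     version, paste(x[conflict], collapse = ", ")),
             "version_conflict_error")
  }
  x[has_pref] <- substring(x[has_pref], 3L)
  n <- nchar(x)
  if (any(n > 5L)) {
    rb_error(sprintf("Read code longer than 5 characters: %s",
                     paste(x[n > 5L], collapse = ", ")),
             "malformed_code_error")
  }
  if (any(n == 0L)) {
    rb_error("empty Read code after prefix stripping", "malformed_code_error")
  }
  paste0(x, strrep(".", 5L - n))
}

#' Classify a Read code as disease-related or not
#'
#' A code counts as disease-related when it already maps into ICD via a
#' lookup table, or when it sits in a disease chapter of the Read
#' hierarchy, i.e. its first character is an uppercase letter A-Z.
#'
#' @param code Character vector of normalized 5-character Read codes.
#' @param has_icd_lookup Logical vector: does the code have an ICD lookup
#'   entry? Recycled against `code`.
#' @return Character vector, `"DISEASE"` or `"NON_DISEASE"`.
#' @export
classify_read_domain <- function(code, has_icd_lookup = FALSE) {
  code <- as.character(code)
  first <- substr(code, 1L, 1L)
  disease <- has_icd_lookup | (first %in% LETTERS)
  ifelse(disease, "DISEASE", "NON_DISEASE")
}

#' Canonicalize ICD codes (strip dots)
#'
#' ICD-10 codes are stored dotless (`"A87.9"` becomes `"A879"`).
#'
#' @param code Character vector of ICD codes.
#' @return Dotless upper-cased codes.
#' @export
normalize_icd10 <- function(code) {
  x <- gsub(".", "", trimws(as.character(code)), fixed = TRUE)
  if (any(is.na(x) | !nzchar(x))) {
    rb_error("empty ICD code", "malformed_code_error")
  }
  x
}

#' Truncate ICD-10 codes to a fixed prefix width
#'
#' Automated-mapping comparisons are limited to the first characters of
#' the ICD-10 code (4 by default).
#'
#' @param code Character vector of canonical (dotless) ICD codes.
#' @param width Positive integer prefix width.
#' @return `code` truncated to at most `width` characters.
#' @export
truncate_icd10 <- function(code, width = 4L) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) {
    rb_error("width must be a positive integer", "argument_error")
  }
  x <- normalize_icd10(code)
  substr(x, 1L, width)
}

#' Agreement level between two ICD-10 codes
#'
#' Compares an automatically mapped code with a manually mapped one:
#' `EXACT` when identical, `PREFIX4` when the first four characters agree
#' (and both codes have at least four characters), `PREFIX3` when the
#' first three agree, else `MISMATCH`. Levels are mutually exclusive and
#' ordered `EXACT > PREFIX4 > PREFIX3 > MISMATCH`.
#'
#' @param auto_code,manual_code Character vectors of canonical ICD-10
#'   codes (recycled to a common length).
#' @return Character vector of agreement levels.
#' @export
match_level <- function(auto_code, manual_code) {
  a <- normalize_icd10(auto_code)
  b <- normalize_icd10(manual_code)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- rep("MISMATCH", n)
  out[substr(a, 1L, 3L) == substr(b, 1L, 3L)] <- "PREFIX3"
  p4 <- substr(a, 1L, 4L) == substr(b, 1L, 4L) & nchar(a) >= 4L & nchar(b) >= 4L
  out[p4] <- "PREFIX4"
  out[a == b] <- "EXACT"
  out
}

MATCH_LEVELS <- c(MISMATCH = 0L, PREFIX3 = 1L, PREFIX4 = 2L, EXACT = 3L)

match_level_rank <- function(level) unname(MATCH_LEVELS[level])

#' Construct an ontology (a coding dictionary)
#'
#' A lightweight container for one code system's concepts: code,
#' description, activity status and optional parent. Codes must be unique
#' and every non-missing parent must itself be a stored concept.
#'
#' @param system A single code-system label (see [CODE_SYSTEMS]).
#' @param codes Character vector of concept codes (no internal whitespace).
#' @param descriptions Character vector of concept descriptions.
#' @param active Logical vector (recycled), concept activity status.
#' @param parent_code Optional character vector of parent codes
#'   (`NA` where absent), referring to codes in the same ontology.
#' @return An object of class `"ontology"`.
#' @export
ontology <- function(system, codes, descriptions, active = TRUE,
                     parent_code = NA_character_) {
  system <- as_code_system(system)
  if (length(system) != 1L) rb_error("system must be scalar", "argument_error")
  codes <- as.character(codes)
  descriptions <- as.character(descriptions)
  if (length(codes) != length(descriptions)) {
    rb_error("codes and descriptions differ in length", "argument_error")
  }
  if (any(grepl("[[:space:]]", codes))) {
    rb_error("concept codes must not contain whitespace", "malformed_code_error")
  }
  dup <- duplicated(codes)
  if (any(dup)) {
    rb_error(sprintf("duplicate codes in ontology: %s",
                     paste(unique(codes[dup]), collapse = ", ")),
             "duplicate_key_error")
  }
  concepts <- data.frame(
    code = codes,
    description = descriptions,
    active = rep_len(as.logical(active), length(codes)),
    parent_code = rep_len(as.character(parent_code), length(codes)),
    stringsAsFactors = FALSE
  )
  dangling <- !is.na(concepts$parent_code) &
    !(concepts$parent_code %in% concepts$code)
  if (any(dangling)) {
    rb_error(sprintf("dangling parent code(s): %s",
                     paste(unique(concepts$parent_code[dangling]),
                           collapse = ", ")),
             "dangling_parent_error")
  }
  structure(list(system = system, concepts = concepts), class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %s: %d concepts\n", x$system, nrow(x$concepts)))
  if (nrow(x$concepts)) {
    print(utils::head(x$concepts, 5L), row.names = FALSE)
    if (nrow(x$concepts) > 5L) cat(sprintf("... and %d more\n",
                                           nrow(x$concepts) - 5L))
  }
  invisible(x)
}

#' @export
length.ontology <- function(x) nrow(x$concepts)

# Description lookup; NA for unknown codes.
ontology_description <- function(ont, code) {
  ont$concepts$description[match(code, ont$concepts$code)]
}

ontology_has <- function(ont, code) code %in% ont$concepts$code

#' Count unique Read codes per version and in total
#'
#' Corpus bookkeeping used by run reports: unique Read2 plus unique Read3
#' codes, with the total computed by summation.
#'
#' @param codes Data frame with columns `read_code` and `read_version`.
#' @return Named list with `n_read2`, `n_read3` and `n_total`.
#' @export
corpus_summary <- function(codes) {
  stopifnot(is.data.frame(codes),
            all(c("read_code", "read_version") %in% names(codes)))
  n2 <- length(unique(codes$read_code[codes$read_version == "READ2"]))
  n3 <- length(unique(codes$read_code[codes$read_version == "READ3"]))
  list(n_read2 = n2, n_read3 = n3, n_total = n2 + n3)
}
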