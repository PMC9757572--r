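# Cross-mapping Read codes to ICD-10 through SNOMED CT-style tables:
# Read3 -> concept resolution, inactive-concept replacement chains,
# concept -> ICD-10 reference-set lookup, Read2 non-mappability, and the
# broad/narrow selection policies for ambiguous one-to-many choices.

#' Read a SNOMED-style concept table
#'
#' Tab-separated columns: `concept_id`, `description`, `active`
#' (`TRUE`/`FALSE` or `1`/`0`), `replaced_by` (blank when none) and
#' `parents` (`|`-separated concept ids, blank when none). Active
#' concepts must not carry a replacement.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `"snomed_concepts"`.
#' @export
read_snomed_concepts <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("concept_id", "description", "active"),
                  "snomed concepts")
  for (col in c("replaced_by", "parents")) {
    if (!col %in% names(df)) df[[col]] <- ""
  }
  snomed_concepts(data.frame(
    concept_id = df$concept_id,
    description = df$description,
    active = df$active %in% c("TRUE", "true", "1"),
    replaced_by = ifelse(nzchar(df$replaced_by), df$replaced_by,
                         NA_character_),
    parents = df$parents,
    stringsAsFactors = FALSE
  ))
}

#' Validate and class a SNOMED-style concept store
#'
#' @param df Data frame with columns `concept_id`, `description`,
#'   `active` (logical), `replaced_by` (`NA` when none), `parents`
#'   (`|`-separated string, `""` when none).
#' @return The data frame with class `"snomed_concepts"` prepended.
#' @export
snomed_concepts <- function(df) {
  require_columns(df, c("concept_id", "description", "active",
                        "replaced_by", "parents"), "snomed concepts")
  dup <- duplicated(df$concept_id)
  if (any(dup)) {
    rb_error(sprintf("duplicate concept id(s): %s",
                     paste(unique(df$concept_id[dup]), collapse = ", ")),
             "duplicate_key_error")
  }
  bad <- df$active & !is.na(df$replaced_by)
  if (any(bad)) {
    rb_error(sprintf("active concept(s) carry replaced_by: %s",
                     paste(df$concept_id[bad], collapse = ", ")),
             "schema_error")
  }
  class(df) <- c("snomed_concepts", class(df))
  df
}

#' Write a concept table
#' @param concepts A `"snomed_concepts"` data frame.
#' @param path Output path.
#' @export
write_snomed_concepts <- function(concepts, path) {
  out <- data.frame(
    concept_id = concepts$concept_id,
    description = concepts$description,
    active = ifelse(concepts$active, "TRUE", "FALSE"),
    replaced_by = ifelse(is.na(concepts$replaced_by), "",
                         concepts$replaced_by),
    parents = concepts$parents,
    stringsAsFactors = FALSE
  )
  write_tsv_utf8(out, path)
  invisible(path)
}

#' Read a Read3 -> SNOMED concept map (TSV: read_code, concept_id)
#' @param path Path to the TSV file.
#' @return Data frame with columns `read_code`, `concept_id`.
#' @export
read_read3_map <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("read_code", "concept_id"), "read3 map")
  df[c("read_code", "concept_id")]
}

#' Read a SNOMED -> ICD-10 reference set (TSV: concept_id, icd10_code)
#' @param path Path to the TSV file.
#' @return Data frame with columns `concept_id`, `icd10_code`.
#' @export
read_icd10_refset <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("concept_id", "icd10_code"), "icd10 refset")
  df[c("concept_id", "icd10_code")]
}

#' Look up the SNOMED concept for a Read3 code
#'
#' @param code A single normalized Read3 code.
#' @param map Read3 map data frame (`read_code`, `concept_id`).
#' @return The concept id, or `NA` when the code is absent.
#' @export
read3_to_snomed <- function(code, map) {
  stopifnot(length(code) == 1L)
  hit <- map$concept_id[map$read_code == code]
  if (length(hit)) hit[1L] else NA_character_
}

#' Resolve an inactive SNOMED concept through its replacement chain
#'
#' Active concepts are returned as-is. Inactive concepts with a
#' `replaced_by` chain are followed (transitively, cycle-safe) to the
#' first active concept. Inactive concepts without a replacement are
#' returned unchanged and flagged for review — never silently treated
#' as resolved.
#'
#' @param concept_id A single concept id present in `concepts`.
#' @param concepts A `"snomed_concepts"` store.
#' @return List with `concept_id` (the resolved id), `resolved`
#'   (logical: a replacement was followed) and `review` (logical:
#'   inactive with no replacement).
#' @export
resolve_inactive <- function(concept_id, concepts) {
  stopifnot(length(concept_id) == 1L)
  chain <- character(0)
  cur <- concept_id
  repeat {
    row <- match(cur, concepts$concept_id)
    if (is.na(row)) {
      rb_error(sprintf("concept not in registry: %s", cur),
               "unknown_code_error")
    }
    if (concepts$active[row]) {
      return(list(concept_id = cur,
                  resolved = length(chain) > 0L, review = FALSE))
    }
    nxt <- concepts$replaced_by[row]
    if (is.na(nxt)) {
      return(list(concept_id = cur, resolved = FALSE, review = TRUE))
    }
    if (cur %in% chain) {
      rb_error(sprintf("replacement chain cycle: %s",
                       paste(c(chain, cur), collapse = " -> ")),
               "cycle_error")
    }
    chain <- c(chain, cur)
    cur <- nxt
  }
}

#' ICD-10 targets of a SNOMED concept from the reference set
#'
#' @param concept_id A single concept id.
#' @param refset Reference-set data frame (`concept_id`, `icd10_code`).
#' @return Character vector of ICD-10 codes in table order (empty when
#'   the concept has no entry).
#' @export
snomed_to_icd10 <- function(concept_id, refset) {
  stopifnot(length(concept_id) == 1L)
  refset$icd10_code[refset$concept_id == concept_id]
}

#' Cross-map Read codes to ICD-10 through SNOMED
#'
#' Composes [read3_to_snomed()], [resolve_inactive()] and
#' [snomed_to_icd10()] for Read3 codes. Read2 codes have no automated
#' path into SNOMED and come back `READ2_UNMAPPABLE` unless a manual
#' override supplies a concept. The summary reports the fractions of
#' missing SNOMED concepts, inactive-resolved concepts, missing ICD-10
#' entries (over both the found-in-SNOMED and all-Read3 denominators)
#' and unmappable Read2 codes.
#'
#' @param codes Data frame with columns `read_code`, `read_version`.
#' @param concepts A `"snomed_concepts"` store.
#' @param read3_map Read3 map data frame.
#' @param refset ICD-10 reference set data frame.
#' @param overrides Optional data frame (`read_code`, `concept_id`) of
#'   manual Read -> SNOMED assignments (the only path for Read2).
#' @return An object of class `"crossmap_result"`: list with `records`
#'   (one row per code: `snomed_id`, `snomed_status`, `icd10_codes`
#'   `|`-collapsed, `icd10_status`) and `summary`.
#' @export
crossmap <- function(codes, concepts, read3_map, refset, overrides = NULL) {
  n <- nrow(codes)
  snomed_id <- rep(NA_character_, n)
  snomed_status <- rep(NA_character_, n)
  icd10_codes <- rep("", n)
  review <- rep(FALSE, n)
  for (i in seq_len(n)) {
    code <- codes$read_code[i]
    ov <- if (!is.null(overrides)) {
      h <- overrides$concept_id[overrides$read_code == code]
      if (length(h)) h[1L] else NA_character_
    } else NA_character_
    if (codes$read_version[i] == "READ2" && is.na(ov)) {
      snomed_status[i] <- "READ2_UNMAPPABLE"
      next
    }
    cid <- if (!is.na(ov)) ov else read3_to_snomed(code, read3_map)
    if (is.na(cid)) {
      snomed_status[i] <- "MISSING"
      next
    }
    res <- resolve_inactive(cid, concepts)
    snomed_id[i] <- res$concept_id
    snomed_status[i] <- if (res$resolved) "INACTIVE_RESOLVED" else "DIRECT"
    review[i] <- res$review
    icd10_codes[i] <- paste(snomed_to_icd10(res$concept_id, refset),
                            collapse = "|")
  }
  records <- data.frame(
    read_code = codes$read_code,
    read_version = codes$read_version,
    snomed_id = snomed_id,
    snomed_status = snomed_status,
    icd10_codes = icd10_codes,
    icd10_status = ifelse(nzchar(icd10_codes), "MAPPED", "MISSING"),
    review_needed = review,
    stringsAsFactors = FALSE
  )
  is_r3 <- codes$read_version == "READ3"
  n_r3 <- sum(is_r3)
  found <- is_r3 & records$snomed_status %in% c("DIRECT", "INACTIVE_RESOLVED")
  summary <- list(
    n_codes = n,
    n_read2 = sum(!is_r3),
    n_read3 = n_r3,
    frac_read2_unmappable =
      if (n) sum(records$snomed_status == "READ2_UNMAPPABLE") / n else 0,
    frac_snomed_missing =
      if (n_r3) sum(is_r3 & records$snomed_status == "MISSING") / n_r3 else 0,
    frac_inactive_resolved =
      if (sum(found)) sum(records$snomed_status[found] ==
                            "INACTIVE_RESOLVED") / sum(found) else 0,
    frac_icd10_missing_of_found =
      if (sum(found)) sum(records$icd10_status[found] == "MISSING") /
        sum(found) else 0,
    frac_icd10_missing_of_read3 =
      if (n_r3) sum(is_r3 & records$icd10_status == "MISSING") / n_r3 else 0
  )
  structure(list(records = records, summary = summary),
            class = "crossmap_result")
}

#' @export
print.crossmap_result <- function(x, ...) {
  s <- x$summary
  cat("<crossmap_result>\n")
  cat(sprintf("  %d codes (%d Read2, %d Read3)\n", s$n_codes, s$n_read2,
              s$n_read3))
  cat(sprintf("  SNOMED missing: %.1f%% of Read3; inactive resolved: %.1f%%\n",
              100 * s$frac_snomed_missing, 100 * s$frac_inactive_resolved))
  cat(sprintf("  ICD-10 missing: %.1f%% of found (%.1f%% of all Read3)\n",
              100 * s$frac_icd10_missing_of_found,
              100 * s$frac_icd10_missing_of_read3))
  invisible(x)
}

#' Write crossmap records as TSV
#' @param result A `"crossmap_result"`.
#' @param path Output path.
#' @export
write_crossmap_records <- function(result, path) {
  out <- result$records
  out$snomed_id <- ifelse(is.na(out$snomed_id), "", out$snomed_id)
  out$review_needed <- ifelse(out$review_needed, "TRUE", "FALSE")
  write_tsv_utf8(out, path)
  invisible(path)
}

snomed_parents <- function(concepts, id) {
  p <- concepts$parents[match(id, concepts$concept_id)]
  if (is.na(p) || !nzchar(p)) character(0)
  else strsplit(p, "|", fixed = TRUE)[[1L]]
}

snomed_ancestors <- function(concepts, id) {
  seen <- character(0)
  frontier <- snomed_parents(concepts, id)
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    if (!length(new)) break
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, snomed_parents,
                                     concepts = concepts)))
  }
  seen
}

#' Select among candidate concepts by broad/narrow policy
#'
#' When several SNOMED concepts could represent a source term, the
#' `"BROAD"` policy picks the smallest sufficiently general one: the
#' candidate that is an ancestor of all others if such exists, otherwise
#' the candidate with the fewest ancestors. The `"NARROW"` policy picks
#' the most specific: the candidate with the most ancestors. Ties break
#' by ascending concept id so selection is deterministic.
#'
#' @param candidate_ids Non-empty character vector of concept ids.
#' @param concepts A `"snomed_concepts"` store holding the hierarchy.
#' @param policy `"BROAD"` or `"NARROW"`.
#' @return A single concept id.
#' @export
select_by_policy <- function(candidate_ids, concepts,
                             policy = c("BROAD", "NARROW")) {
  policy <- match.arg(toupper(policy[1L]), c("BROAD", "NARROW"))
  if (!length(candidate_ids)) {
    rb_error("candidate set is empty", "argument_error")
  }
  candidate_ids <- unique(candidate_ids)
  if (length(candidate_ids) == 1L) return(candidate_ids)
  anc <- lapply(candidate_ids, snomed_ancestors, concepts = concepts)
  names(anc) <- candidate_ids
  if (policy == "BROAD") {
    covers_all <- vapply(candidate_ids, function(id) {
      all(vapply(setdiff(candidate_ids, id),
                 function(o) id %in% anc[[o]], logical(1)))
    }, logical(1))
    if (any(covers_all)) {
      return(sort(candidate_ids[covers_all])[1L])
    }
    n_anc <- lengths(anc)
    pool <- candidate_ids[n_anc == min(n_anc)]
    return(sort(pool)[1L])
  }
  n_anc <- lengths(anc)
  pool <- candidate_ids[n_anc == max(n_anc)]
  sort(pool)[1L]
}
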