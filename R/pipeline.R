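# The automated mapping workflow: lookup-table mapping, ICD-9 -> ICD-10
# bridging, fuzzy mapping of unmapped disease terms, dual-target
# detection, the "unspecified leaf" preference rule, and flag-based
# refinement of one-to-many lookup mappings.

ICD_SYSTEMS <- c("ICD9", "ICD10", "ICD10CM")

empty_records <- function() {
  data.frame(read_code = character(0), read_version = character(0),
             target_code = character(0), target_system = character(0),
             method = character(0), similarity = numeric(0),
             review_needed = logical(0), stringsAsFactors = FALSE)
}

new_records <- function(read_code, read_version, target_code, target_system,
                        method, similarity = NA_real_,
                        review_needed = FALSE) {
  n <- length(target_code)
  data.frame(read_code = rep_len(read_code, n),
             read_version = rep_len(read_version, n),
             target_code = target_code,
             target_system = rep_len(target_system, n),
             method = rep_len(method, n),
             similarity = rep_len(similarity, n),
             review_needed = rep_len(review_needed, n),
             stringsAsFactors = FALSE)
}

#' Map Read codes through lookup tables
#'
#' Attaches, for every input code with at least one mapping entry, all
#' matching targets in table order (full one-to-many mappings are
#' preserved). Codes mapping to both an ICD system and OPCS4 are listed
#' in the `dual_target` side report; codes without any entry are listed
#' in `unmapped`.
#'
#' @param codes Data frame with columns `read_code`, `read_version`
#'   (normalized codes).
#' @param entries Mapping-entry data frame (see [read_mapping_table()]).
#' @return List with `records` (mapping-record data frame, method
#'   `"LOOKUP"`), `unmapped` (data frame of codes without entries) and
#'   `dual_target` (character vector of codes with both ICD and OPCS4
#'   targets).
#' @export
map_via_lookups <- function(codes, entries) {
  stopifnot(is.data.frame(codes),
            all(c("read_code", "read_version") %in% names(codes)))
  use_version <- "read_version" %in% names(entries) &&
    any(nzchar(entries$read_version))
  ck <- if (use_version) paste(codes$read_code, codes$read_version)
        else codes$read_code
  ek <- if (use_version) paste(entries$read_code, entries$read_version)
        else entries$read_code
  rec_list <- vector("list", nrow(codes))
  dual <- character(0)
  mapped <- logical(nrow(codes))
  for (i in seq_len(nrow(codes))) {
    idx <- which(ek == ck[i])
    if (!length(idx)) next
    mapped[i] <- TRUE
    sys <- entries$target_system[idx]
    if (any(sys %in% ICD_SYSTEMS) && any(sys == "OPCS4")) {
      dual <- c(dual, codes$read_code[i])
    }
    rec_list[[i]] <- new_records(codes$read_code[i], codes$read_version[i],
                                 entries$target_code[idx], sys, "LOOKUP")
  }
  records <- if (any(mapped)) do.call(rbind, rec_list[mapped])
             else empty_records()
  list(records = records,
       unmapped = codes[!mapped, , drop = FALSE],
       dual_target = unique(dual))
}

#' Re-map an ICD-9 code to ICD-10
#'
#' Uses the ICD-9 -> ICD-10 bridge table when it has entries for the
#' code; otherwise falls back to the best description match of the ICD-9
#' description against the ICD-10 dictionary via trigram search, flagged
#' for review when the score falls below `threshold`.
#'
#' @param icd9_code A single canonical ICD-9 code.
#' @param icd9_dict,icd10_dict [ontology()] objects.
#' @param bridge Optional mapping-entry data frame whose `read_code`
#'   column holds ICD-9 codes and `target_code` the ICD-10 targets.
#' @param index Optional pre-built trigram index over `icd10_dict`
#'   (built on the fly if omitted).
#' @param threshold Review threshold for the fuzzy fallback.
#' @return Data frame with columns `target_code`, `similarity`,
#'   `review_needed` (zero rows when no candidate is found).
#' @export
remap_icd9_to_icd10 <- function(icd9_code, icd9_dict, icd10_dict,
                                bridge = NULL, index = NULL,
                                threshold = 0.8) {
  stopifnot(length(icd9_code) == 1L)
  if (!ontology_has(icd9_dict, icd9_code)) {
    rb_error(sprintf("ICD-9 code not in dictionary: %s", icd9_code),
             "unknown_code_error")
  }
  if (!is.null(bridge)) {
    idx <- which(bridge$read_code == icd9_code)
    if (length(idx)) {
      return(data.frame(target_code = bridge$target_code[idx],
                        similarity = NA_real_, review_needed = FALSE,
                        stringsAsFactors = FALSE))
    }
  }
  if (is.null(index)) index <- build_trigram_index(icd10_dict)
  desc <- ontology_description(icd9_dict, icd9_code)
  hit <- search_index(index, desc, top_k = 1L, threshold = threshold)
  if (!nrow(hit)) {
    return(data.frame(target_code = character(0), similarity = numeric(0),
                      review_needed = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(target_code = hit$code, similarity = hit$score,
             review_needed = hit$review_needed, stringsAsFactors = FALSE)
}

high_level_source <- function(desc) {
  d <- tolower(desc)
  grepl("nos", d, fixed = TRUE) || grepl("unspecified", d, fixed = TRUE) ||
    grepl("other", d, fixed = TRUE) || grepl("\\.{3}$|…$", trimws(desc))
}

#' Prefer an "unspecified" leaf over a 3-character ICD-10 category
#'
#' When a high-level source description (containing "NOS", "unspecified",
#' "other", or a trailing ellipsis) maps to a 3-character ICD-10
#' category, and that category has exactly one child whose description
#' contains "unspecified", the child is returned instead — e.g. "Viral
#' meningitis NOS" goes to the "Viral meningitis, unspecified" leaf
#' rather than the category. In every other case the candidate is
#' returned unchanged.
#'
#' @param candidate A single ICD-10 code present in `icd10_dict`.
#' @param icd10_dict An [ontology()] of ICD-10 concepts.
#' @param source_desc Description of the source (Read) concept.
#' @return An ICD-10 code.
#' @export
prefer_unspecified_child <- function(candidate, icd10_dict, source_desc) {
  stopifnot(length(candidate) == 1L)
  if (nchar(candidate) != 3L || !high_level_source(source_desc)) {
    return(candidate)
  }
  cpt <- icd10_dict$concepts
  kids <- if (any(!is.na(cpt$parent_code))) {
    cpt[!is.na(cpt$parent_code) & cpt$parent_code == candidate, ]
  } else {
    cpt[startsWith(cpt$code, candidate) & nchar(cpt$code) > 3L, ]
  }
  unspec <- kids[grepl("unspecified", tolower(kids$description)), ]
  if (nrow(unspec) == 1L) unspec$code else candidate
}

#' Fuzzy-map unmapped disease codes to ICD-10
#'
#' For each code without a lookup entry but classified as
#' disease-related, takes the top trigram-search candidate over the
#' ICD-10 dictionary (after the unspecified-leaf preference), records
#' the similarity score, and flags the code for review when the score
#' falls below `threshold`. Codes with no candidate at all are returned
#' unmapped with `review_needed = TRUE`.
#'
#' @param codes Data frame with columns `read_code`, `read_version`,
#'   `description`.
#' @param icd10_index Trigram index over the ICD-10 dictionary.
#' @param icd10_dict The matching [ontology()] (for the unspecified-leaf
#'   rule); may be `NULL` to skip that rule.
#' @param threshold Review threshold (default 0.8).
#' @return Mapping-record data frame with method `"FUZZY"`.
#' @export
map_unmapped_disease_codes <- function(codes, icd10_index, icd10_dict = NULL,
                                       threshold = 0.8) {
  out <- vector("list", nrow(codes))
  for (i in seq_len(nrow(codes))) {
    hit <- search_index(icd10_index, codes$description[i], top_k = 1L,
                        threshold = threshold)
    if (!nrow(hit)) {
      out[[i]] <- new_records(codes$read_code[i], codes$read_version[i],
                              NA_character_, NA_character_, "FUZZY",
                              NA_real_, TRUE)
    } else {
      target <- hit$code[1L]
      if (!is.null(icd10_dict)) {
        target <- prefer_unspecified_child(target, icd10_dict,
                                           codes$description[i])
      }
      out[[i]] <- new_records(codes$read_code[i], codes$read_version[i],
                              target, icd10_index$system, "FUZZY",
                              hit$score[1L], hit$score[1L] < threshold)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_records()
}

qualifying_flags <- function(entries) {
  s <- entries$mapping_status
  s == "E" | s == "G" |
    (s %in% c("D", "A") & entries$refine_flag == "C" &
       entries$add_code_flag == "C")
}

#' Refine lookup mappings using TRUD-style flags
#'
#' Under `"FULL"`, records pass through unchanged. Under `"REFINED"`,
#' only targets whose mapping entry carries status `E`, `G`, or status
#' `D`/`A` with refine flag `C` and add-code flag `C` survive; status
#' `R` ("requires checking") and every other flag combination is
#' excluded, and codes left with zero targets are dropped and counted.
#' `"HYBRID"` keeps the refined targets where at least one survives and
#' falls back to the full record otherwise.
#'
#' @param records Mapping-record data frame whose targets all have flag
#'   entries in `entries`.
#' @param entries Mapping-entry data frame carrying the flags.
#' @param strategy `"FULL"`, `"REFINED"` or `"HYBRID"`.
#' @return List with `records`, `n_excluded` (codes dropped, REFINED
#'   only), `excluded_fraction`, and `excluded_codes`.
#' @export
apply_flag_refinement <- function(records,
                                  strategy = c("HYBRID", "FULL", "REFINED"),
                                  entries) {
  strategy <- match.arg(toupper(strategy[1L]),
                        c("HYBRID", "FULL", "REFINED"))
  n_codes <- length(unique(records$read_code))
  if (strategy == "FULL" || !nrow(records)) {
    return(list(records = records, n_excluded = 0L,
                excluded_fraction = 0, excluded_codes = character(0),
                strategy = strategy))
  }
  rk <- paste(records$read_code, records$target_code)
  ek <- paste(entries$read_code, entries$target_code)
  pos <- match(rk, ek)
  if (anyNA(pos)) {
    miss <- rk[is.na(pos)][1L]
    rb_error(sprintf("no flag entry for mapping pair: %s", miss),
             "flag_lookup_error")
  }
  keep <- qualifying_flags(entries[pos, , drop = FALSE])
  surviving <- unique(records$read_code[keep])
  if (strategy == "REFINED") {
    refined <- records[keep, , drop = FALSE]
    excluded <- setdiff(unique(records$read_code), surviving)
    rownames(refined) <- NULL
    return(list(records = refined, n_excluded = length(excluded),
                excluded_fraction = length(excluded) / n_codes,
                excluded_codes = excluded, strategy = strategy))
  }
  # HYBRID: refined rows where the code kept >= 1 target, full otherwise
  hybrid <- records[keep | !(records$read_code %in% surviving), ,
                    drop = FALSE]
  rownames(hybrid) <- NULL
  list(records = hybrid, n_excluded = 0L, excluded_fraction = 0,
       excluded_codes = character(0), strategy = strategy,
       n_fallback_full = n_codes - length(surviving))
}

#' Run the full automated curation pipeline
#'
#' Deterministic composition of the workflow stages: lookup mapping,
#' ICD-9 -> ICD-10 bridging of codes mapped to ICD-9 only, disease
#' classification of unmapped codes, trigram fuzzy mapping of the
#' unmapped disease terms, and flag-based refinement of the lookup
#' records under the chosen strategy. Identical inputs and configuration
#' give identical output.
#'
#' @param codes Data frame with columns `read_code`, `read_version` and
#'   optionally `description` (needed for fuzzy mapping).
#' @param lookup Mapping-entry data frame (the Read -> ICD lookup).
#' @param icd10_dict ICD-10 [ontology()].
#' @param icd9_dict Optional ICD-9 [ontology()] (enables bridging).
#' @param bridge Optional ICD-9 -> ICD-10 bridge table (see
#'   [remap_icd9_to_icd10()]).
#' @param strategy Refinement strategy: `"HYBRID"` (default), `"FULL"`
#'   or `"REFINED"`.
#' @param threshold Fuzzy review threshold (default 0.8).
#' @return An object of class `"curation_result"`: a list with `records`
#'   (mapping-record data frame) and `report` (per-stage counts, review
#'   queue, dual targets, excluded fraction).
#' @export
run_pipeline <- function(codes, lookup, icd10_dict, icd9_dict = NULL,
                         bridge = NULL,
                         strategy = c("HYBRID", "FULL", "REFINED"),
                         threshold = 0.8) {
  strategy <- match.arg(toupper(strategy[1L]),
                        c("HYBRID", "FULL", "REFINED"))
  if (!"description" %in% names(codes)) codes$description <- NA_character_
  icd10_index <- build_trigram_index(icd10_dict)

  lk <- map_via_lookups(codes, lookup)
  records <- lk$records

  # Bridge codes whose lookup targets are all ICD-9.
  n_bridged <- 0L
  if (!is.null(icd9_dict) && nrow(records)) {
    by_code <- split(seq_len(nrow(records)), records$read_code)
    drop_rows <- integer(0)
    bridged <- list()
    for (code in names(by_code)) {
      rows <- by_code[[code]]
      if (!all(records$target_system[rows] == "ICD9")) next
      pieces <- lapply(rows, function(r) {
        icd9 <- records$target_code[r]
        if (!ontology_has(icd9_dict, icd9)) return(NULL)
        rm <- remap_icd9_to_icd10(icd9, icd9_dict, icd10_dict,
                                  bridge = bridge, index = icd10_index,
                                  threshold = threshold)
        if (!nrow(rm)) return(NULL)
        new_records(records$read_code[r], records$read_version[r],
                    rm$target_code, "ICD10", "ICD9_BRIDGE",
                    rm$similarity, rm$review_needed)
      })
      pieces <- pieces[!vapply(pieces, is.null, logical(1))]
      if (length(pieces)) {
        drop_rows <- c(drop_rows, rows)
        bridged <- c(bridged, pieces)
        n_bridged <- n_bridged + 1L
      }
    }
    if (length(bridged)) {
      records <- rbind(records[-drop_rows, , drop = FALSE],
                       do.call(rbind, bridged))
    }
  }

  # Fuzzy-map unmapped disease codes (those with descriptions).
  un <- lk$unmapped
  domain <- classify_read_domain(un$read_code, has_icd_lookup = FALSE)
  disease <- un[domain == "DISEASE" & !is.na(un$description), , drop = FALSE]
  fuzzy <- map_unmapped_disease_codes(disease, icd10_index, icd10_dict,
                                      threshold = threshold)
  n_nondisease <- sum(domain == "NON_DISEASE")

  # Flag refinement applies to the lookup records (which carry flags).
  is_lookup <- records$method == "LOOKUP"
  ref <- apply_flag_refinement(records[is_lookup, , drop = FALSE],
                               strategy = strategy, entries = lookup)
  records <- rbind(ref$records, records[!is_lookup, , drop = FALSE], fuzzy)
  rownames(records) <- NULL

  cs <- corpus_summary(codes)
  report <- list(
    n_input = nrow(codes),
    n_read2 = cs$n_read2,
    n_read3 = cs$n_read3,
    n_total = cs$n_total,
    n_lookup = length(unique(records$read_code[records$method == "LOOKUP"])),
    n_bridged = n_bridged,
    n_fuzzy = length(unique(records$read_code[records$method == "FUZZY"])),
    n_unmapped_nondisease = n_nondisease,
    dual_target = lk$dual_target,
    n_dual_target = length(lk$dual_target),
    review_queue = unique(records$read_code[records$review_needed %in% TRUE]),
    n_excluded = ref$n_excluded,
    excluded_fraction = ref$excluded_fraction,
    excluded_codes = ref$excluded_codes,
    strategy = strategy,
    threshold = threshold
  )
  structure(list(records = records, report = report),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  r <- x$report
  cat("<curation_result>\n")
  cat(sprintf("  input codes: %d (Read2 %d + Read3 %d = %d unique)\n",
              r$n_input, r$n_read2, r$n_read3, r$n_total))
  cat(sprintf("  mapped: %d lookup, %d bridged, %d fuzzy; %d non-disease ignored\n",
              r$n_lookup, r$n_bridged, r$n_fuzzy, r$n_unmapped_nondisease))
  cat(sprintf("  strategy %s: %d codes excluded (%.1f%%); %d in review queue; %d dual-target\n",
              r$strategy, r$n_excluded, 100 * r$excluded_fraction,
              length(r$review_queue), r$n_dual_target))
  invisible(x)
}

#' Write a curation result to disk
#'
#' Writes the mapping records as TSV (see [write_mapping_records()]) and,
#' optionally, the run report as a key-value TSV. Byte-identical for
#' identical results.
#'
#' @param result A `"curation_result"`.
#' @param records_path Output path for the mapping TSV.
#' @param report_path Optional output path for the report TSV.
#' @export
write_curation_result <- function(result, records_path, report_path = NULL) {
  write_mapping_records(result$records, records_path)
  if (!is.null(report_path)) {
    r <- result$report
    flat <- vapply(r, function(v) paste(format(v, digits = 15),
                                        collapse = "|"), character(1))
    write_tsv_utf8(data.frame(key = names(flat), value = unname(flat),
                              stringsAsFactors = FALSE), report_path)
  }
  invisible(result)
}
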