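# Seeded generators for synthetic dictionaries, mapping tables,
# SNOMED-style tables and clinical event streams, with a gold standard
# recording the ground truth of every generated code. The fixtures
# emulate the *structure* of the upstream artifacts (5-character
# dot-padded Read codes, capital-letter disease chapters, ICD-10
# category/leaf shape, TRUD flag vocabulary, one-to-many blocks,
# inactive SNOMED concepts, injected wrong targets) — not the clinical
# epidemiology of real primary-care data.

WORD_BANK <- c(
  "chronic", "acute", "benign", "malignant", "neoplasm", "polyp",
  "disease", "disorder", "syndrome", "infection", "inflammation",
  "stenosis", "ulcer", "cyst", "fracture", "allergy", "dermatitis",
  "skin", "bone", "joint", "liver", "kidney", "lung", "heart", "ear",
  "eye", "colon", "rectum", "bladder", "thyroid", "nerve", "muscle",
  "viral", "bacterial", "fungal", "hereditary", "metabolic", "vascular"
)

QUALIFIER_BANK <- c("of skin", "of bone", "acute", "chronic", "localized",
                    "diffuse", "congenital", "acquired", "benign",
                    "malignant", "recurrent", "secondary")

ADMIN_BANK <- c("blood pressure screening", "occupation recorded",
                "medication review", "telephone consultation",
                "smoking status", "immunisation given",
                "laboratory test requested", "referral letter sent",
                "height measured", "weight measured")

#' Configuration for the synthetic-fixture generators
#'
#' Bundles every knob of the generators with validation. A fixed `seed`
#' makes all downstream outputs byte-identical across runs; the
#' sub-generators derive their streams from `seed` by fixed offsets so
#' adding a generator never perturbs existing fixtures.
#'
#' @param n_read_codes Total Read codes (split evenly Read2/Read3).
#' @param disease_fraction Fraction starting with a capital letter
#'   (the disease chapters of the Read hierarchy).
#' @param n_icd10 Number of ICD-10 leaf concepts.
#' @param flag_mix Proportions over the flag classes `E`, `G`, `DCC`
#'   (`D|C|C`), `ACC` (`A|C|C`), `R` and `other`; must sum to 1.
#' @param one_to_many_rate Fraction of mapped codes given 2-4 targets
#'   grouped with element/block numbers.
#' @param injected_error_rate Fraction of mapped codes given an extra
#'   wrong target from an unrelated ICD-10 chapter (status `R` with
#'   probability 0.9).
#' @param lookup_coverage Fraction of disease codes that get lookup
#'   entries at all (the rest exercise the fuzzy path).
#' @param inactive_snomed_rate Fraction of mapped SNOMED concepts that
#'   are inactive with replacement chains (default 0.42, the reported
#'   magnitude for CTV3 codes).
#' @param refset_missing_rate Fraction of active concepts without an
#'   ICD-10 reference-set entry (default 0.434, the reported magnitude).
#' @param snomed_missing_rate Fraction of Read3 codes absent from the
#'   concept map (default 18/790, the reported magnitude).
#' @param n_patients Number of distinct participants in the event
#'   stream.
#' @param events_per_patient Events per participant.
#' @param seed Master integer seed.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_read_codes = 200L,
                           disease_fraction = 0.6,
                           n_icd10 = 80L,
                           flag_mix = c(E = 0.45, G = 0.15, DCC = 0.10,
                                        ACC = 0.10, R = 0.10,
                                        other = 0.10),
                           one_to_many_rate = 0.15,
                           injected_error_rate = 0.05,
                           lookup_coverage = 0.85,
                           inactive_snomed_rate = 0.42,
                           refset_missing_rate = 0.434,
                           snomed_missing_rate = 18 / 790,
                           n_patients = 300L,
                           events_per_patient = 5L,
                           seed = 1L) {
  rates <- c(disease_fraction, one_to_many_rate, injected_error_rate,
             lookup_coverage, inactive_snomed_rate, refset_missing_rate,
             snomed_missing_rate)
  if (any(rates < 0 | rates > 1)) {
    rb_error("all rates must lie in [0, 1]", "argument_error")
  }
  if (!setequal(names(flag_mix), c("E", "G", "DCC", "ACC", "R", "other"))) {
    rb_error("flag_mix must name E, G, DCC, ACC, R, other",
             "argument_error")
  }
  if (abs(sum(flag_mix) - 1) > 1e-8) {
    rb_error("flag_mix proportions must sum to 1", "argument_error")
  }
  structure(list(n_read_codes = as.integer(n_read_codes),
                 disease_fraction = disease_fraction,
                 n_icd10 = as.integer(n_icd10),
                 flag_mix = flag_mix,
                 one_to_many_rate = one_to_many_rate,
                 injected_error_rate = injected_error_rate,
                 lookup_coverage = lookup_coverage,
                 inactive_snomed_rate = inactive_snomed_rate,
                 refset_missing_rate = refset_missing_rate,
                 snomed_missing_rate = snomed_missing_rate,
                 n_patients = as.integer(n_patients),
                 events_per_patient = as.integer(events_per_patient),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

rand_desc <- function(n_words = 2L) {
  paste(sample(WORD_BANK, n_words), collapse = " ")
}

# Unique 5-character dot-padded Read codes with a controlled fraction of
# capital-letter (disease-chapter) first characters.
gen_read_codes <- function(n, disease_fraction) {
  pool_rest <- c(LETTERS, letters, as.character(0:9))
  codes <- character(0)
  disease <- logical(0)
  while (length(codes) < n) {
    m <- n - length(codes)
    is_dis <- stats::runif(m) < disease_fraction
    first <- ifelse(is_dis, sample(LETTERS, m, replace = TRUE),
                    sample(as.character(0:9), m, replace = TRUE))
    len <- sample(2:5, m, replace = TRUE)
    body <- vapply(len - 1L, function(k) {
      paste(sample(pool_rest, k, replace = TRUE), collapse = "")
    }, character(1))
    cand <- paste0(first, body, strrep(".", 5L - len))
    keep <- !duplicated(cand) & !(cand %in% codes)
    codes <- c(codes, cand[keep])
    disease <- c(disease, is_dis[keep])
  }
  list(codes = codes, disease = disease)
}

#' Generate synthetic Read2/Read3/ICD-10 ontologies
#'
#' ICD-10 concepts come as 3-character categories each with 1-5
#' 4-character children, one of them an "unspecified" leaf with
#' probability 0.8; exactly `n_icd10` leaves are produced. Read codes
#' are 5-character dot-padded, with `disease_fraction` of them in
#' capital-letter chapters; disease descriptions overlap lexically with
#' ICD-10 leaf descriptions (half copied verbatim, a third mutated) so
#' trigram similarity spans the full range. Deterministic under the
#' config seed.
#'
#' @param config A [fixture_config()].
#' @return List with elements `read2`, `read3`, `icd10` (each an
#'   [ontology()]).
#' @export
generate_ontologies <- function(config) {
  set.seed(config$seed)
  n_leaf <- config$n_icd10

  # ICD-10: draw categories until their children cover n_leaf leaves.
  cat_pool <- as.vector(outer(LETTERS, sprintf("%02d", 0:99), paste0))
  cat_pool <- sample(cat_pool)
  cats <- character(0); cat_desc <- character(0)
  leaf_code <- character(0); leaf_desc <- character(0)
  leaf_parent <- character(0)
  i <- 0L
  while (length(leaf_code) < n_leaf) {
    i <- i + 1L
    cc <- cat_pool[i]
    cd <- rand_desc(sample(2:3, 1L))
    k <- sample(1:5, 1L)
    has_unspec <- stats::runif(1) < 0.8
    digits <- as.character(seq_len(k) - 1L)
    descs <- paste(cd, sample(QUALIFIER_BANK, k, replace = TRUE))
    if (has_unspec) {
      digits[k] <- "9"
      descs[k] <- paste0(cd, ", unspecified")
    }
    cats <- c(cats, cc); cat_desc <- c(cat_desc, cd)
    leaf_code <- c(leaf_code, paste0(cc, digits))
    leaf_desc <- c(leaf_desc, descs)
    leaf_parent <- c(leaf_parent, rep(cc, k))
  }
  keep <- seq_len(n_leaf)
  leaf_code <- leaf_code[keep]; leaf_desc <- leaf_desc[keep]
  leaf_parent <- leaf_parent[keep]
  used <- cats %in% leaf_parent
  icd10 <- ontology("ICD10",
                    c(cats[used], leaf_code),
                    c(cat_desc[used], leaf_desc),
                    parent_code = c(rep(NA_character_, sum(used)),
                                    leaf_parent))

  # Read codes: half Read2, half Read3.
  n3 <- ceiling(config$n_read_codes / 2)
  n2 <- config$n_read_codes - n3
  mk_read <- function(n, system) {
    g <- gen_read_codes(n, config$disease_fraction)
    desc <- character(n)
    for (j in seq_len(n)) {
      if (g$disease[j]) {
        u <- stats::runif(1)
        base <- sample(leaf_desc, 1L)
        desc[j] <- if (u < 0.5) {
          base
        } else if (u < 0.8) {
          # mutate: drop or append one word
          w <- strsplit(base, " ", fixed = TRUE)[[1L]]
          if (length(w) > 1L && stats::runif(1) < 0.5) {
            paste(w[-sample(length(w), 1L)], collapse = " ")
          } else {
            paste(c(w, sample(WORD_BANK, 1L)), collapse = " ")
          }
        } else {
          rand_desc(3L)
        }
      } else {
        desc[j] <- sample(ADMIN_BANK, 1L)
      }
    }
    ontology(system, g$codes, desc)
  }
  list(read2 = mk_read(n2, "READ2"), read3 = mk_read(n3, "READ3"),
       icd10 = icd10)
}

draw_flags <- function(n, flag_mix) {
  cls <- sample(names(flag_mix), n, replace = TRUE, prob = flag_mix)
  status <- character(n); refine <- character(n); add <- character(n)
  for (i in seq_len(n)) {
    f <- switch(cls[i],
                E = c("E", "", ""),
                G = c("G", "", ""),
                DCC = c("D", "C", "C"),
                ACC = c("A", "C", "C"),
                R = c("R", "", ""),
                other = c(sample(c("D", "A"), 1L), "P", "M"))
    status[i] <- f[1L]; refine[i] <- f[2L]; add[i] <- f[3L]
  }
  data.frame(class = cls, mapping_status = status, refine_flag = refine,
             add_code_flag = add, stringsAsFactors = FALSE)
}

#' Generate a synthetic lookup mapping table with gold standard
#'
#' Disease Read codes receive lookup entries (with probability
#' `lookup_coverage`); flag combinations follow `flag_mix`; a
#' `one_to_many_rate` fraction gets 2-4 sibling targets grouped by
#' element/block numbers; an `injected_error_rate` fraction additionally
#' receives a wrong target drawn from an unrelated ICD-10 chapter,
#' carrying status `R` with probability 0.9 — the mechanism behind
#' prevalence inflation. The gold standard records, for every generated
#' Read code, its true targets and any injected error.
#'
#' @param config A [fixture_config()].
#' @param onts Output of [generate_ontologies()].
#' @return List with `entries` (mapping-entry data frame) and `gold`
#'   (one row per Read code).
#' @export
generate_mapping_tables <- function(config, onts) {
  set.seed(config$seed + 1L)
  leaves <- onts$icd10$concepts[!is.na(onts$icd10$concepts$parent_code), ]
  all_codes <- rbind(
    data.frame(read_code = onts$read2$concepts$code, read_version = "READ2",
               stringsAsFactors = FALSE),
    data.frame(read_code = onts$read3$concepts$code, read_version = "READ3",
               stringsAsFactors = FALSE)
  )
  disease <- substr(all_codes$read_code, 1L, 1L) %in% LETTERS
  covered <- disease & stats::runif(nrow(all_codes)) < config$lookup_coverage

  entries <- list()
  gold <- list()
  for (i in seq_len(nrow(all_codes))) {
    rc <- all_codes$read_code[i]; rv <- all_codes$read_version[i]
    if (!covered[i]) {
      gold[[i]] <- data.frame(read_code = rc, read_version = rv,
                              covered = FALSE, true_targets = "",
                              n_targets = 0L, injected_wrong = FALSE,
                              wrong_target = "", wrong_status = "",
                              stringsAsFactors = FALSE)
      next
    }
    ti <- sample(nrow(leaves), 1L)
    true_code <- leaves$code[ti]
    targets <- true_code
    if (stats::runif(1) < config$one_to_many_rate) {
      sibs <- setdiff(leaves$code[leaves$parent_code ==
                                    leaves$parent_code[ti]], true_code)
      extra <- min(length(sibs), sample(1:3, 1L))
      if (extra > 0L) targets <- c(true_code, sample(sibs, extra))
    }
    k <- length(targets)
    fl <- draw_flags(1L, config$flag_mix)
    ent <- data.frame(
      read_code = rc, read_version = rv, target_code = targets,
      target_system = "ICD10",
      mapping_status = fl$mapping_status,
      refine_flag = fl$refine_flag, add_code_flag = fl$add_code_flag,
      element_num = if (k > 1L) seq_len(k) else NA_integer_,
      block_num = if (k > 1L) 1L else NA_integer_,
      provenance = "UKB_LOOKUP", stringsAsFactors = FALSE
    )
    inj <- stats::runif(1) < config$injected_error_rate
    wrong_code <- ""; wrong_status <- ""
    if (inj) {
      other <- leaves$code[substr(leaves$code, 1L, 1L) !=
                             substr(true_code, 1L, 1L)]
      if (length(other)) {
        wrong_code <- sample(other, 1L)
        wrong_status <- if (stats::runif(1) < 0.9) "R" else "G"
        ent <- rbind(ent, data.frame(
          read_code = rc, read_version = rv, target_code = wrong_code,
          target_system = "ICD10", mapping_status = wrong_status,
          refine_flag = "", add_code_flag = "",
          element_num = NA_integer_, block_num = NA_integer_,
          provenance = "UKB_LOOKUP", stringsAsFactors = FALSE
        ))
      } else {
        inj <- FALSE
      }
    }
    entries[[i]] <- ent
    gold[[i]] <- data.frame(read_code = rc, read_version = rv,
                            covered = TRUE,
                            true_targets = paste(targets, collapse = "|"),
                            n_targets = k, injected_wrong = inj,
                            wrong_target = wrong_code,
                            wrong_status = wrong_status,
                            stringsAsFactors = FALSE)
  }
  entries <- entries[!vapply(entries, is.null, logical(1))]
  list(entries = if (length(entries)) do.call(rbind, entries)
                 else NULL,
       gold = do.call(rbind, gold))
}

#' Generate SNOMED-style concept, map and reference-set tables
#'
#' Each Read3 code maps to a concept unless dropped at
#' `snomed_missing_rate`; a fraction `inactive_snomed_rate` of mapped
#' concepts is inactive with an acyclic replacement chain of length 1-2
#' ending in an active concept; a fraction `refset_missing_rate` of the
#' final active concepts lacks an ICD-10 reference-set entry. Concepts
#' hang under a handful of generic root concepts so hierarchy-based
#' selection policies are exercisable. All outcomes are recorded in the
#' gold standard.
#'
#' @param config A [fixture_config()].
#' @param read3_codes Character vector of Read3 codes.
#' @param icd10_codes Character vector of ICD-10 codes to draw refset
#'   targets from.
#' @return List with `concepts` (a `"snomed_concepts"`), `read3_map`,
#'   `refset`, `gold`.
#' @export
generate_snomed_tables <- function(config, read3_codes, icd10_codes) {
  set.seed(config$seed + 2L)
  n <- length(read3_codes)
  roots <- data.frame(
    concept_id = as.character(10001:10005),
    description = paste("clinical finding group", 1:5),
    active = TRUE, replaced_by = NA_character_, parents = "",
    stringsAsFactors = FALSE
  )
  id_pool <- as.character(sample(100000:999999, 4L * max(n, 1L)))
  next_id <- 0L
  take_id <- function() {
    next_id <<- next_id + 1L
    id_pool[next_id]
  }
  concepts <- list(); map <- list(); refset <- list(); gold <- list()
  for (i in seq_len(n)) {
    rc <- read3_codes[i]
    if (stats::runif(1) < config$snomed_missing_rate) {
      gold[[i]] <- data.frame(read_code = rc, concept_id = "",
                              inactive = FALSE, chain_len = 0L,
                              final_concept = "", has_refset = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    desc <- rand_desc(2L)
    root <- sample(roots$concept_id, 1L)
    inactive <- stats::runif(1) < config$inactive_snomed_rate
    if (inactive) {
      chain_len <- sample(1:2, 1L)
      ids <- vapply(seq_len(chain_len + 1L), function(j) take_id(),
                    character(1))
      for (j in seq_len(chain_len)) {
        concepts[[length(concepts) + 1L]] <- data.frame(
          concept_id = ids[j], description = paste(desc, "(retired)"),
          active = FALSE, replaced_by = ids[j + 1L], parents = root,
          stringsAsFactors = FALSE)
      }
      final <- ids[chain_len + 1L]
      concepts[[length(concepts) + 1L]] <- data.frame(
        concept_id = final, description = desc, active = TRUE,
        replaced_by = NA_character_, parents = root,
        stringsAsFactors = FALSE)
      first <- ids[1L]
    } else {
      chain_len <- 0L
      first <- final <- take_id()
      concepts[[length(concepts) + 1L]] <- data.frame(
        concept_id = first, description = desc, active = TRUE,
        replaced_by = NA_character_, parents = root,
        stringsAsFactors = FALSE)
    }
    map[[length(map) + 1L]] <- data.frame(read_code = rc,
                                          concept_id = first,
                                          stringsAsFactors = FALSE)
    has_refset <- stats::runif(1) >= config$refset_missing_rate
    if (has_refset && length(icd10_codes)) {
      k <- sample(1:2, 1L)
      refset[[length(refset) + 1L]] <- data.frame(
        concept_id = final,
        icd10_code = sample(icd10_codes, min(k, length(icd10_codes))),
        stringsAsFactors = FALSE)
    }
    gold[[i]] <- data.frame(read_code = rc, concept_id = first,
                            inactive = inactive, chain_len = chain_len,
                            final_concept = final,
                            has_refset = has_refset,
                            stringsAsFactors = FALSE)
  }
  concepts <- rbind(roots, if (length(concepts)) do.call(rbind, concepts))
  list(concepts = snomed_concepts(concepts),
       read3_map = if (length(map)) do.call(rbind, map)
                   else data.frame(read_code = character(0),
                                   concept_id = character(0)),
       refset = if (length(refset)) do.call(rbind, refset)
                else data.frame(concept_id = character(0),
                                icd10_code = character(0)),
       gold = do.call(rbind, gold))
}

#' Generate a synthetic clinical event stream
#'
#' `n_patients` distinct participants each get `events_per_patient`
#' events. Codes are drawn from a seeded categorical distribution in
#' which one designated "common" code (the first disease code, standing
#' in for a high-frequency diagnosis such as osteoarthritis) receives
#' 30% of the probability mass, reproducing the conditions under which
#' an erroneous one-to-many mapping inflates prevalence. Dates fall in
#' 1990-2017.
#'
#' @param config A [fixture_config()].
#' @param codes Data frame with columns `read_code`, `read_version`.
#' @return Event data frame (`eid`, `data_provider`, `event_dt`,
#'   `read_2`, `read_3`) plus attribute `"common_code"`.
#' @export
generate_events <- function(config, codes) {
  set.seed(config$seed + 3L)
  if (config$n_patients == 0L || !nrow(codes)) {
    out <- data.frame(eid = character(0), data_provider = integer(0),
                      event_dt = as.Date(character(0)),
                      read_2 = character(0), read_3 = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "common_code") <- NA_character_
    return(out)
  }
  disease <- which(substr(codes$read_code, 1L, 1L) %in% LETTERS)
  common <- if (length(disease)) disease[1L] else 1L
  prob <- rep((1 - 0.3) / max(nrow(codes) - 1L, 1L), nrow(codes))
  prob[common] <- if (nrow(codes) > 1L) 0.3 else 1
  n_ev <- config$n_patients * config$events_per_patient
  pick <- sample(nrow(codes), n_ev, replace = TRUE, prob = prob)
  days <- sample(as.integer(as.Date("2017-12-31") -
                              as.Date("1990-01-01")), n_ev,
                 replace = TRUE)
  out <- data.frame(
    eid = as.character(rep(1000L + seq_len(config$n_patients),
                           each = config$events_per_patient)),
    data_provider = sample(1:4, n_ev, replace = TRUE),
    event_dt = as.Date("1990-01-01") + days,
    read_2 = ifelse(codes$read_version[pick] == "READ2",
                    codes$read_code[pick], NA_character_),
    read_3 = ifelse(codes$read_version[pick] == "READ3",
                    codes$read_code[pick], NA_character_),
    stringsAsFactors = FALSE
  )
  attr(out, "common_code") <- codes$read_code[common]
  out
}

#' Generate and write a complete fixture set
#'
#' Runs all four generators and writes every table as TSV under `dir`:
#' coding dictionaries (`read2.tsv`, `read3.tsv`, `icd10.tsv`), the
#' lookup `mapping.tsv`, SNOMED-style `snomed_concepts.tsv`,
#' `read3_map.tsv`, `refset.tsv`, the `events.tsv` stream, and the gold
#' standards (`gold_mapping.tsv`, `gold_snomed.tsv`). Identical configs
#' produce byte-identical files.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
generate_fixtures <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  onts <- generate_ontologies(config)
  maps <- generate_mapping_tables(config, onts)
  sn <- generate_snomed_tables(
    config, onts$read3$concepts$code,
    onts$icd10$concepts$code[!is.na(onts$icd10$concepts$parent_code)])
  codes <- maps$gold[c("read_code", "read_version")]
  events <- generate_events(config, codes)

  p <- function(f) file.path(dir, f)
  write_coding_table(onts$read2, p("read2.tsv"))
  write_coding_table(onts$read3, p("read3.tsv"))
  write_coding_table(onts$icd10, p("icd10.tsv"))
  write_mapping_table(maps$entries, p("mapping.tsv"))
  write_snomed_concepts(sn$concepts, p("snomed_concepts.tsv"))
  write_tsv_utf8(sn$read3_map, p("read3_map.tsv"))
  write_tsv_utf8(sn$refset, p("refset.tsv"))
  ev <- events
  ev$event_dt <- format(ev$event_dt, "%Y-%m-%d")
  ev$read_2 <- ifelse(is.na(ev$read_2), "", ev$read_2)
  ev$read_3 <- ifelse(is.na(ev$read_3), "", ev$read_3)
  write_tsv_utf8(ev, p("events.tsv"))
  write_tsv_utf8(maps$gold, p("gold_mapping.tsv"))
  write_tsv_utf8(sn$gold, p("gold_snomed.tsv"))
  invisible(stats::setNames(
    file.path(dir, c("read2.tsv", "read3.tsv", "icd10.tsv", "mapping.tsv",
                     "snomed_concepts.tsv", "read3_map.tsv", "refset.tsv",
                     "events.tsv", "gold_mapping.tsv", "gold_snomed.tsv")),
    c("read2", "read3", "icd10", "mapping", "snomed_concepts",
      "read3_map", "refset", "events", "gold_mapping", "gold_snomed")))
}

#' Synthetic prevalence-inflation scenario
#'
#' Reconstructs, at desk scale, the mechanism by which an erroneous
#' one-to-many lookup mapping inflates apparent disease prevalence: two
#' common osteoarthritis Read codes carry a wrong extra target in the
#' E70 chapter (amino-acid metabolism disorders) with mapping status
#' `R`, so full mapping classifies every osteoarthritis patient as an
#' E70 case while refined mapping removes the wrong target and recovers
#' the true count.
#'
#' @param seed Integer seed for event dates/providers.
#' @param n_osteo Number of osteoarthritis patients (default 500).
#' @param n_true Number of genuine E70 patients (default 5).
#' @return List with `codes`, `entries`, `events`,
#'   `true_e70_patients` and `wrong_prefix` (`"E70"`).
#' @export
generate_inflation_scenario <- function(seed = 1L, n_osteo = 500L,
                                        n_true = 5L) {
  set.seed(seed)
  codes <- data.frame(
    read_code = c("XE1DV", "N05..", "C351."),
    read_version = c("READ3", "READ2", "READ2"),
    description = c("Osteoarthritis", "Osteoarthritis and allied disorders",
                    "Disorder of aromatic amino-acid metabolism"),
    stringsAsFactors = FALSE
  )
  entries <- data.frame(
    read_code = c("XE1DV", "XE1DV", "N05..", "N05..", "C351."),
    read_version = c("READ3", "READ3", "READ2", "READ2", "READ2"),
    target_code = c("M190", "E702", "M190", "E702", "E702"),
    target_system = "ICD10",
    mapping_status = c("E", "R", "E", "R", "E"),
    refine_flag = "", add_code_flag = "",
    element_num = NA_integer_, block_num = NA_integer_,
    provenance = "UKB_LOOKUP", stringsAsFactors = FALSE
  )
  n <- n_osteo + n_true
  osteo_code <- sample(c("XE1DV", "N05.."), n_osteo, replace = TRUE)
  code <- c(osteo_code, rep("C351.", n_true))
  is_r3 <- code == "XE1DV"
  events <- data.frame(
    eid = as.character(1000L + seq_len(n)),
    data_provider = sample(1:4, n, replace = TRUE),
    event_dt = as.Date("1990-01-01") +
      sample(10000L, n, replace = TRUE),
    read_2 = ifelse(is_r3, NA_character_, code),
    read_3 = ifelse(is_r3, code, NA_character_),
    stringsAsFactors = FALSE
  )
  list(codes = codes, entries = entries, events = events,
       true_e70_patients = as.integer(n_true), wrong_prefix = "E70")
}
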