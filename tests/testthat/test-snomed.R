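toy_concepts <- function() {
  snomed_concepts(data.frame(
    concept_id = c("26079004", "609558009", "111", "222", "333",
                   "900", "901"),
    description = c("Tremor", "Essential tremor (disorder)",
                    "Old concept", "Mid concept", "Current concept",
                    "Cycle a", "Cycle b"),
    active = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    replaced_by = c(NA, NA, "222", "333", NA, "901", "900"),
    parents = c("", "26079004", "", "", "", "", ""),
    stringsAsFactors = FALSE
  ))
}

test_that("concept stores reject duplicate ids and active replacements", {
  expect_s3_class(toy_concepts(), "snomed_concepts")
  expect_error(snomed_concepts(data.frame(
    concept_id = c("1", "1"), description = "x", active = TRUE,
    replaced_by = NA_character_, parents = "",
    stringsAsFactors = FALSE)), class = "duplicate_key_error")
  expect_error(snomed_concepts(data.frame(
    concept_id = "1", description = "x", active = TRUE,
    replaced_by = "2", parents = "", stringsAsFactors = FALSE)),
    class = "schema_error")
})

test_that("read3 lookup reports missing codes at the fixture's rate", {
  # 790 codes of which 18 are absent from the concept map
  codes <- sprintf("X%04d", 1:790)
  map <- data.frame(read_code = codes[-(1:18)],
                    concept_id = as.character(1:772),
                    stringsAsFactors = FALSE)
  found <- vapply(codes, read3_to_snomed, character(1), map = map)
  expect_identical(sum(is.na(found)), 18L)
  expect_identical(read3_to_snomed("X0020", map), "2")
})

test_that("inactive concepts resolve through chains, never silently", {
  cs <- toy_concepts()
  act <- resolve_inactive("333", cs)
  expect_identical(act$concept_id, "333")
  expect_false(act$resolved)

  chain <- resolve_inactive("111", cs)
  expect_identical(chain$concept_id, "333")
  expect_true(chain$resolved)
  expect_false(chain$review)

  orphan <- snomed_concepts(data.frame(
    concept_id = "5", description = "x", active = FALSE,
    replaced_by = NA_character_, parents = "", stringsAsFactors = FALSE))
  res <- resolve_inactive("5", orphan)
  expect_false(res$resolved)
  expect_true(res$review)

  expect_error(resolve_inactive("900", cs), class = "cycle_error")
  expect_error(resolve_inactive("nope", cs), class = "unknown_code_error")
})

test_that("refset lookup preserves table order and counts misses", {
  refset <- data.frame(concept_id = c("333", "333", "222"),
                       icd10_code = c("G250", "G251", "Z999"),
                       stringsAsFactors = FALSE)
  expect_identical(snomed_to_icd10("333", refset), c("G250", "G251"))
  expect_identical(snomed_to_icd10("26079004", refset), character(0))
})

test_that("crossmap composes the stages with a self-consistent summary", {
  cs <- toy_concepts()
  map <- data.frame(read_code = c("F131.", "X1111", "X2222"),
                    concept_id = c("26079004", "111", "333"),
                    stringsAsFactors = FALSE)
  refset <- data.frame(concept_id = c("26079004", "333"),
                       icd10_code = c("G25", "G250"),
                       stringsAsFactors = FALSE)
  codes <- data.frame(
    read_code = c("F131.", "X1111", "X2222", "X9999", "N05.."),
    read_version = c("READ3", "READ3", "READ3", "READ3", "READ2"),
    stringsAsFactors = FALSE)
  cm <- crossmap(codes, cs, map, refset)
  r <- cm$records
  expect_identical(r$snomed_status[r$read_code == "N05.."],
                   "READ2_UNMAPPABLE")
  expect_identical(r$snomed_status[r$read_code == "X9999"], "MISSING")
  expect_identical(r$snomed_status[r$read_code == "X1111"],
                   "INACTIVE_RESOLVED")
  expect_identical(r$icd10_codes[r$read_code == "X1111"], "G250")
  expect_identical(r$icd10_status[r$read_code == "F131."], "MAPPED")
  # summary fractions equal direct recounts over the record list
  is_r3 <- r$read_version == "READ3"
  found <- is_r3 & r$snomed_status %in% c("DIRECT", "INACTIVE_RESOLVED")
  expect_equal(cm$summary$frac_snomed_missing,
               sum(is_r3 & r$snomed_status == "MISSING") / sum(is_r3))
  expect_equal(cm$summary$frac_inactive_resolved,
               sum(r$snomed_status[found] == "INACTIVE_RESOLVED") /
                 sum(found))
  expect_equal(cm$summary$frac_icd10_missing_of_found,
               sum(r$icd10_status[found] == "MISSING") / sum(found))
  # a manual override is the only automated path for Read2
  ov <- crossmap(codes, cs, map, refset,
                 overrides = data.frame(read_code = "N05..",
                                        concept_id = "26079004"))
  expect_identical(
    ov$records$snomed_status[ov$records$read_code == "N05.."], "DIRECT")
})

test_that("broad/narrow policies pick general vs specific concepts", {
  cs <- toy_concepts()
  cand <- c("26079004", "609558009")
  expect_identical(select_by_policy(cand, cs, "BROAD"), "26079004")
  expect_identical(select_by_policy(cand, cs, "NARROW"), "609558009")
  expect_identical(select_by_policy("333", cs, "BROAD"), "333")
  expect_identical(select_by_policy("333", cs, "NARROW"), "333")
  expect_error(select_by_policy(character(0), cs, "BROAD"),
               class = "argument_error")
  # mutually unrelated candidates with equal ancestor counts: policies
  # coincide on the deterministic tie-break
  flat <- snomed_concepts(data.frame(
    concept_id = c("30", "10", "20"), description = "x", active = TRUE,
    replaced_by = NA_character_, parents = "", stringsAsFactors = FALSE))
  ids <- c("30", "10", "20")
  expect_identical(select_by_policy(ids, flat, "BROAD"),
                   select_by_policy(ids, flat, "NARROW"))
  expect_identical(select_by_policy(ids, flat, "BROAD"), "10")
})

test_that("thinned-refset crossmapping loses more codes than direct mapping", {
  cfg <- fixture_config(n_read_codes = 200, seed = 47,
                        refset_missing_rate = 0.434)
  onts <- generate_ontologies(cfg)
  maps <- generate_mapping_tables(cfg, onts)
  sn <- generate_snomed_tables(
    cfg, onts$read3$concepts$code,
    onts$icd10$concepts$code[!is.na(onts$icd10$concepts$parent_code)])
  gold3 <- maps$gold[maps$gold$read_version == "READ3" &
                       maps$gold$covered, ]
  codes3 <- gold3[c("read_code", "read_version")]
  # direct: a code errs when its lookup targets miss every true target
  recs <- map_via_lookups(codes3, maps$entries)$records
  direct_err <- mean(vapply(seq_len(nrow(gold3)), function(i) {
    truth <- strsplit(gold3$true_targets[i], "|", fixed = TRUE)[[1]]
    got <- recs$target_code[recs$read_code == gold3$read_code[i]]
    !any(truth %in% got)
  }, logical(1)))
  cm <- crossmap(codes3, sn$concepts, sn$read3_map, sn$refset)
  cross_err <- mean(vapply(seq_len(nrow(gold3)), function(i) {
    truth <- strsplit(gold3$true_targets[i], "|", fixed = TRUE)[[1]]
    row <- cm$records[cm$records$read_code == gold3$read_code[i], ]
    got <- strsplit(row$icd10_codes, "|", fixed = TRUE)[[1]]
    !any(truth %in% got)
  }, logical(1)))
  expect_lte(direct_err, cross_err)
})

test_that("snomed tables round-trip through their TSV formats", {
  cs <- toy_concepts()
  f <- tempfile(fileext = ".tsv")
  write_snomed_concepts(cs, f)
  back <- read_snomed_concepts(f)
  expect_identical(back$concept_id, cs$concept_id)
  expect_identical(back$active, cs$active)
  expect_identical(back$replaced_by, cs$replaced_by)
})
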