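test_that("fixture config validates its rates and proportions", {
  expect_s3_class(fixture_config(), "fixture_config")
  expect_error(fixture_config(disease_fraction = 1.2),
               class = "argument_error")
  expect_error(fixture_config(flag_mix = c(E = 1)),
               class = "argument_error")
  expect_error(fixture_config(flag_mix = c(E = 0.5, G = 0.2, DCC = 0.1,
                                           ACC = 0.1, R = 0.1,
                                           other = 0.2)),
               class = "argument_error")
})

test_that("generated ontologies honour the configured shapes", {
  cfg <- fixture_config(n_read_codes = 100, n_icd10 = 50, seed = 3)
  onts <- generate_ontologies(cfg)
  leaves <- onts$icd10$concepts[!is.na(onts$icd10$concepts$parent_code), ]
  expect_identical(nrow(leaves), 50L)
  expect_true(all(nchar(leaves$code) == 4L))
  expect_true(all(leaves$parent_code %in% onts$icd10$concepts$code))
  expect_true(all(nchar(onts$read2$concepts$code) == 5L))
  expect_true(all(nchar(onts$read3$concepts$code) == 5L))

  all_disease <- generate_ontologies(fixture_config(
    n_read_codes = 40, disease_fraction = 1, seed = 5))
  firsts <- substr(c(all_disease$read2$concepts$code,
                     all_disease$read3$concepts$code), 1, 1)
  expect_true(all(firsts %in% LETTERS))
})

test_that("gold standard covers every code once and tracks injections", {
  cfg <- fixture_config(n_read_codes = 120, injected_error_rate = 0.1,
                        seed = 8)
  onts <- generate_ontologies(cfg)
  maps <- generate_mapping_tables(cfg, onts)
  gold <- maps$gold
  all_codes <- c(onts$read2$concepts$code, onts$read3$concepts$code)
  expect_setequal(gold$read_code, all_codes)
  expect_false(any(duplicated(gold$read_code)))
  # every injected error is recoverable and present in the entries
  inj <- gold[gold$injected_wrong, ]
  expect_gt(nrow(inj), 0)
  for (i in seq_len(nrow(inj))) {
    hit <- maps$entries$read_code == inj$read_code[i] &
      maps$entries$target_code == inj$wrong_target[i]
    expect_identical(sum(hit), 1L)
    expect_identical(maps$entries$mapping_status[hit], inj$wrong_status[i])
  }

  clean <- generate_mapping_tables(
    fixture_config(n_read_codes = 60, injected_error_rate = 0, seed = 8),
    onts)
  expect_false(any(clean$gold$injected_wrong))
})

test_that("an all-E flag mix makes refined mapping equal full mapping", {
  cfg <- fixture_config(n_read_codes = 80, seed = 13,
                        injected_error_rate = 0,
                        flag_mix = c(E = 1, G = 0, DCC = 0, ACC = 0,
                                     R = 0, other = 0))
  onts <- generate_ontologies(cfg)
  maps <- generate_mapping_tables(cfg, onts)
  codes <- maps$gold[c("read_code", "read_version")]
  recs <- map_via_lookups(codes, maps$entries)$records
  refined <- apply_flag_refinement(recs, "REFINED", maps$entries)$records
  expect_identical(refined, recs)
})

test_that("snomed tables realise the configured inactive/missing rates", {
  cfg <- fixture_config(seed = 21, inactive_snomed_rate = 0.42,
                        refset_missing_rate = 0.434)
  r3 <- sprintf("X%04d", 1:790)
  icd <- sprintf("A%02d%d", 1:50, 0)
  sn <- generate_snomed_tables(cfg, r3, icd)
  gold <- sn$gold
  expect_identical(nrow(gold), 790L)
  mapped <- gold[nzchar(gold$concept_id), ]
  # realised rates sit near the configured magnitudes
  expect_lt(abs(mean(gold$concept_id == "") - 18 / 790), 0.02)
  expect_lt(abs(mean(mapped$inactive) - 0.42), 0.06)
  expect_lt(abs(mean(!mapped$has_refset) - 0.434), 0.06)
  # chains resolve to the recorded final concept, no cycles possible
  for (i in which(mapped$inactive)[1:10]) {
    res <- resolve_inactive(mapped$concept_id[i], sn$concepts)
    expect_identical(res$concept_id, mapped$final_concept[i])
    expect_true(res$resolved)
  }
  none <- generate_snomed_tables(
    fixture_config(seed = 21, inactive_snomed_rate = 0,
                   snomed_missing_rate = 0), r3[1:50], icd)
  expect_false(any(none$gold$inactive))
})

test_that("event streams have the configured shape", {
  cfg <- fixture_config(n_patients = 40, events_per_patient = 3, seed = 2)
  onts <- generate_ontologies(cfg)
  codes <- data.frame(
    read_code = c(onts$read2$concepts$code, onts$read3$concepts$code),
    read_version = rep(c("READ2", "READ3"),
                       c(length(onts$read2), length(onts$read3))),
    stringsAsFactors = FALSE)
  ev <- generate_events(cfg, codes)
  expect_identical(nrow(ev), 120L)
  expect_identical(length(unique(ev$eid)), 40L)
  expect_true(all(!is.na(ev$read_2) | !is.na(ev$read_3)))
  expect_true(all(ev$event_dt >= as.Date("1990-01-01") &
                    ev$event_dt <= as.Date("2017-12-31")))
  expect_identical(nrow(generate_events(
    fixture_config(n_patients = 0, seed = 2), codes)), 0L)

  # a single-code universe: its true prevalence is every patient
  one <- data.frame(read_code = "A56..", read_version = "READ2",
                    stringsAsFactors = FALSE)
  ev1 <- generate_events(cfg, one)
  recs <- data.frame(read_code = "A56..", read_version = "READ2",
                     target_code = "B069", target_system = "ICD10",
                     method = "LOOKUP", similarity = NA_real_,
                     review_needed = FALSE, stringsAsFactors = FALSE)
  expect_identical(prevalence_count(ev1, recs, "B06"), 40L)
})

test_that("identical configs write byte-identical fixture sets", {
  cfg <- fixture_config(n_read_codes = 60, n_patients = 30, seed = 99)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- generate_fixtures(cfg, d1)
  p2 <- generate_fixtures(cfg, d2)
  expect_identical(names(p1), names(p2))
  expect_identical(md5_of(p1), md5_of(p2))
  # and the files parse back through the package's own readers
  ont <- read_coding_table(p1[["icd10"]], system = "ICD10")
  expect_gt(length(ont), 0)
  tab <- read_mapping_table(p1[["mapping"]])
  expect_gt(nrow(tab), 0)
  ev <- read_events(p1[["events"]])
  expect_identical(nrow(ev), 150L)
  cs <- read_snomed_concepts(p1[["snomed_concepts"]])
  expect_s3_class(cs, "snomed_concepts")
})
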