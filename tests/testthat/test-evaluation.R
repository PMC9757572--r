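test_that("quality categories follow the curator decision tree", {
  perfect <- assign_quality_category("A080",
                                     annotation = list(precise = TRUE))
  expect_identical(perfect$label, "PERFECT")
  expect_identical(perfect$group, "NO_ISSUE")

  combo <- assign_quality_category(c("K620", "K621"))
  expect_identical(combo$label, "MULTIPLE_COMBINATION")
  expect_identical(combo$group, "MULTIPLE")

  block <- assign_quality_category("H80-H83")
  expect_identical(block$label, "MULTIPLE_BLOCK")

  morph <- assign_quality_category(c("C413", "8812/3"),
                                   systems = c("ICD10CM", "ICDO3"))
  expect_identical(morph$label, "MULTIPLE_MORPHOLOGY")

  unspec <- assign_quality_category(
    "B069", annotation = list(unspecified = TRUE))
  expect_identical(unspec$label, "IMPRECISE_UNSPECIFIED")
  expect_identical(unspec$group, "IMPRECISE")

  closest <- assign_quality_category(
    "R739", annotation = list(closest_only = TRUE))
  expect_identical(closest$label, "IMPRECISE_CLOSEST")

  general <- assign_quality_category("C413")
  expect_identical(general$label, "IMPRECISE_GENERAL")
})

test_that("agreement classification has the fixed precedence", {
  expect_identical(compare_mappings("A080", "A080"), "EXACT")
  expect_identical(compare_mappings(c("A080", "J108", "J118"), "A080"),
                   "PARTIAL_MULTI")
  expect_identical(compare_mappings(character(0), "Z91012"),
                   "MISSING_OR_INCORRECT")
  expect_identical(compare_mappings(NA_character_, "Z91012"),
                   "MISSING_OR_INCORRECT")
  expect_identical(compare_mappings("X999", "A080", "ICDO3"),
                   "MORPHOLOGY")
  # four-character agreement with a more specific manual choice
  expect_identical(compare_mappings("W540", "W540XXA"), "MATCH4")
  # three-character category agreement only
  expect_identical(compare_mappings("I158", "I159"), "MATCH3")
  # neither category agrees
  expect_identical(compare_mappings("T781", "Z910"), "NEAR_MISS")
  # self-comparison is exact for any non-empty record
  set.seed(31)
  pool <- c("A080", "B069", "W540XXA", "K620", "I158")
  for (i in 1:20) {
    tgt <- sample(pool, sample(1:3, 1))
    expect_identical(compare_mappings(tgt, tgt), "EXACT")
  }
})

test_that("flat-prior credible intervals behave as Beta posteriors", {
  ci <- proportion_ci(0, 10)
  expect_identical(ci$pct, 0)
  expect_gte(ci$lower, 0)
  expect_lte(ci$upper, 100)
  expect_true(ci$lower <= ci$pct + 1e-12 && ci$pct <= ci$upper)
  # interval width shrinks as n grows at fixed k/n
  w <- function(k, n) {
    x <- proportion_ci(k, n); x$upper - x$lower
  }
  expect_true(w(10, 100) > w(100, 1000))
  expect_true(w(100, 1000) > w(1000, 10000))
  expect_error(proportion_ci(5, 4), class = "argument_error")
  expect_error(proportion_ci(1, 10, level = 1), class = "argument_error")
})

test_that("quality reports order rows and check count consistency", {
  one <- quality_report(rep("PERFECT", 4))
  expect_identical(one$pct, 100)
  expect_identical(one$count, 4L)

  rep1 <- quality_report(c(PERFECT = 796, IMPRECISE_GENERAL = 413,
                           MULTIPLE_COMBINATION = 36,
                           MULTIPLE_MORPHOLOGY = 27,
                           IMPRECISE_CLOSEST = 16, MULTIPLE_BLOCK = 15,
                           IMPRECISE_UNSPECIFIED = 10))
  expect_identical(rep1$count[1], 796L)
  expect_true(all(diff(rep1$count) <= 0))
  expect_identical(rep1$group[rep1$label == "PERFECT"], "NO_ISSUE")
  # percentages sum to 100 up to rounding slack
  expect_lt(abs(sum(rep1$pct) - 100), 0.1 * nrow(rep1))
  # half-up vs truncate differ exactly where the third decimal demands
  tr <- quality_report(c(PERFECT = 796, IMPRECISE_GENERAL = 413,
                         MULTIPLE_COMBINATION = 36,
                         MULTIPLE_MORPHOLOGY = 27,
                         IMPRECISE_CLOSEST = 16, MULTIPLE_BLOCK = 15,
                         IMPRECISE_UNSPECIFIED = 10),
                       rounding = "truncate")
  expect_identical(
    tr$pct[tr$label == "IMPRECISE_GENERAL"], 31.4)    # 31.45... truncated
  expect_identical(
    rep1$pct[rep1$label == "IMPRECISE_GENERAL"], 31.5) # and rounded up

  expect_error(quality_report(c(A = 10, B = 5), n = 20),
               class = "consistency_error")
})

test_that("prevalence counts distinct participants under a mapping", {
  empty <- data.frame(eid = character(0), data_provider = integer(0),
                      event_dt = as.Date(character(0)),
                      read_2 = character(0), read_3 = character(0))
  recs <- data.frame(read_code = "XE1DV", read_version = "READ3",
                     target_code = "E702", target_system = "ICD10",
                     method = "LOOKUP", similarity = NA_real_,
                     review_needed = FALSE, stringsAsFactors = FALSE)
  expect_identical(prevalence_count(empty, recs, "E70"), 0L)

  # five qualifying events for one patient still count once
  ev <- data.frame(eid = rep("1001", 5), data_provider = 1L,
                   event_dt = as.Date("2010-01-01") + 0:4,
                   read_2 = NA_character_, read_3 = "XE1DV",
                   stringsAsFactors = FALSE)
  expect_identical(prevalence_count(ev, recs, "E70"), 1L)
  expect_identical(prevalence_count(ev, recs, "E702"), 1L)
  expect_identical(prevalence_count(ev, recs, "M19"), 0L)
})

test_that("inflation collapses from full to refined mapping", {
  sc <- generate_inflation_scenario(seed = 13, n_osteo = 200, n_true = 4)
  recs <- map_via_lookups(sc$codes, sc$entries)$records
  full <- apply_flag_refinement(recs, "FULL", sc$entries)$records
  refined <- apply_flag_refinement(recs, "REFINED", sc$entries)$records
  n_full <- prevalence_count(sc$events, full, sc$wrong_prefix)
  n_refined <- prevalence_count(sc$events, refined, sc$wrong_prefix)
  expect_identical(n_full, 204L)
  expect_identical(n_refined, sc$true_e70_patients)
})
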