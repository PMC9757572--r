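# Mapping-quality audit: quality categories for manual mappings,
# agreement classes for automated-vs-manual comparison, flat-prior
# Bayesian credible intervals for proportions, summary reports, and the
# prevalence-inflation diagnostic.

QUALITY_LABELS <- c("PERFECT", "IMPRECISE_GENERAL", "MULTIPLE_COMBINATION",
                    "MULTIPLE_MORPHOLOGY", "IMPRECISE_CLOSEST",
                    "MULTIPLE_BLOCK", "IMPRECISE_UNSPECIFIED")

AGREEMENT_LABELS <- c("EXACT", "MATCH4", "MATCH3", "PARTIAL_MULTI",
                      "NEAR_MISS", "MISSING_OR_INCORRECT", "MORPHOLOGY")

#' Quality group of a quality-category label
#'
#' `PERFECT` is `NO_ISSUE`; the `IMPRECISE_*` labels (curators could not
#' find a precise one-to-one mapping) are `IMPRECISE`; the `MULTIPLE_*`
#' labels (one-to-many mapping) are `MULTIPLE`.
#'
#' @param label Character vector of quality-category labels.
#' @return Character vector of groups (`NA` for non-quality labels).
#' @export
quality_group <- function(label) {
  out <- rep(NA_character_, length(label))
  out[label == "PERFECT"] <- "NO_ISSUE"
  out[startsWith(label, "IMPRECISE_")] <- "IMPRECISE"
  out[startsWith(label, "MULTIPLE_")] <- "MULTIPLE"
  out
}

#' Assign a quality category to one manual mapping
#'
#' Deterministic decision tree over the curator's verdict: morphology
#' targets (ICD-O-3) take precedence, then multi-code combinations, then
#' 3-character block/range targets; a single precise target is
#' `PERFECT`; otherwise the imprecision is attributed to an
#' "unspecified"/"uncomplicated" qualifier, a closest-available-only
#' choice, or (by default) a more general target.
#'
#' @param targets Character vector of mapped target codes (a block
#'   range like `"H80-H83"` counts as a block).
#' @param systems Code systems of the targets (recycled; `"ICDO3"`
#'   triggers the morphology category).
#' @param annotation Named list of curator verdict flags: `precise`,
#'   `combination`, `morphology`, `block`, `unspecified`,
#'   `closest_only` (all default `FALSE`; `combination` defaults to
#'   `TRUE` when there are two or more targets).
#' @return List with `label` and `group`.
#' @export
assign_quality_category <- function(targets, systems = "ICD10CM",
                                    annotation = list()) {
  systems <- rep_len(as.character(systems), length(targets))
  flag <- function(name, default = FALSE) {
    v <- annotation[[name]]
    if (is.null(v)) default else isTRUE(v)
  }
  label <-
    if (flag("morphology") || any(systems == "ICDO3")) {
      "MULTIPLE_MORPHOLOGY"
    } else if (length(targets) >= 2L &&
               flag("combination", default = TRUE)) {
      "MULTIPLE_COMBINATION"
    } else if (flag("block") || any(grepl("-", targets, fixed = TRUE))) {
      "MULTIPLE_BLOCK"
    } else if (flag("precise")) {
      "PERFECT"
    } else if (flag("unspecified")) {
      "IMPRECISE_UNSPECIFIED"
    } else if (flag("closest_only")) {
      "IMPRECISE_CLOSEST"
    } else {
      "IMPRECISE_GENERAL"
    }
  list(label = label, group = quality_group(label))
}

#' Compare an automated mapping against a manual one
#'
#' Classifies the agreement between the automated and manual target sets
#' for one Read code, with a fixed precedence so classification is a
#' function: `MORPHOLOGY` (manual uses ICD-O-3) > `MISSING_OR_INCORRECT`
#' (no automated targets) > `EXACT` (identical sets) > `MATCH4` (every
#' target agrees on the first four characters) > `PARTIAL_MULTI`
#' (several automated targets, some agreeing and some plainly wrong) >
#' `MATCH3` (agreement only at the three-character category) >
#' `NEAR_MISS`.
#'
#' @param auto Character vector of automated target codes (may be empty
#'   or `NA` for unmapped).
#' @param manual Character vector of manual target codes (non-empty).
#' @param manual_systems Code systems of the manual targets (recycled).
#' @return A single agreement-class label.
#' @export
compare_mappings <- function(auto, manual, manual_systems = "ICD10CM") {
  manual_systems <- rep_len(as.character(manual_systems), length(manual))
  if (any(manual_systems == "ICDO3")) return("MORPHOLOGY")
  auto <- auto[!is.na(auto)]
  if (!length(auto)) return("MISSING_OR_INCORRECT")
  a <- normalize_icd10(auto)
  m <- normalize_icd10(manual)
  if (setequal(a, m)) return("EXACT")
  ranks <- outer(a, m, function(x, y) match_level_rank(match_level(x, y)))
  auto_best <- apply(ranks, 1L, max)
  manual_best <- apply(ranks, 2L, max)
  if (all(manual_best >= 2L) && all(auto_best >= 2L)) return("MATCH4")
  if (length(a) > 1L && any(auto_best >= 2L) && any(auto_best == 0L)) {
    return("PARTIAL_MULTI")
  }
  if (all(manual_best >= 1L) && all(auto_best >= 1L)) return("MATCH3")
  "NEAR_MISS"
}

#' Flat-prior Bayesian credible interval for a proportion
#'
#' Equal-tailed credible interval for a binomial proportion under a
#' uniform Beta(1, 1) prior: the posterior is Beta(k + 1, n - k + 1) and
#' the bounds are its (1 - level)/2 and 1 - (1 - level)/2 quantiles,
#' reported on the percentage scale.
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials (recycled against `k`).
#' @param level Credible level in (0, 1), default 0.95.
#' @return Object of class `"proportion_ci"`: data frame with columns
#'   `k`, `n`, `pct`, `lower`, `upper`, `level` (percent scale, full
#'   precision).
#' @examples
#' proportion_ci(796, 1313)  # 60.6% [58.0, 63.2]
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1) {
    rb_error("level must lie strictly between 0 and 1", "argument_error")
  }
  len <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  if (any(is.na(k) | is.na(n) | n < 1 | k < 0 | k > n)) {
    rb_error("require 0 <= k <= n and n >= 1", "argument_error")
  }
  alpha <- (1 - level) / 2
  pct <- 100 * k / n
  # at k = 0 or k = n the flat prior pulls the equal-tailed interval off
  # the point estimate; clamp so the interval always contains pct
  out <- data.frame(
    k = k, n = n,
    pct = pct,
    lower = pmin(100 * stats::qbeta(alpha, k + 1, n - k + 1), pct),
    upper = pmax(100 * stats::qbeta(1 - alpha, k + 1, n - k + 1), pct),
    level = level
  )
  class(out) <- c("proportion_ci", class(out))
  out
}

#' @export
print.proportion_ci <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.1f-%.1f%%)\n",
                x$k[i], x$n[i], x$pct[i], 100 * x$level[i],
                x$lower[i], x$upper[i]))
  }
  invisible(x)
}

#' Round a percentage to one decimal under a declared mode
#'
#' `"half-up"` rounds 0.05 upward; `"truncate"` drops everything past
#' the first decimal (some published tables truncate rather than round).
#'
#' @param x Numeric vector of percentages.
#' @param mode `"half-up"` (default) or `"truncate"`.
#' @return Rounded values.
#' @export
round_pct <- function(x, mode = c("half-up", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "half-up") floor(x * 10 + 0.5) / 10
  else floor(x * 10 + 1e-9) / 10
}

#' Summary table of quality categories or agreement classes
#'
#' Counts per label with percentage (one decimal, rounding mode
#' disclosed) and flat-prior 95% credible interval. Rows are ordered by
#' descending count, ties broken by label.
#'
#' @param x Either a character vector of per-item labels, or a named
#'   numeric vector of counts.
#' @param n Total (defaults to `length(x)` resp. `sum(x)`); when counts
#'   are supplied it must equal their sum.
#' @param rounding `"half-up"` or `"truncate"`.
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `label`, `count`, `pct`, `ci_lower`,
#'   `ci_upper`, `group`.
#' @export
quality_report <- function(x, n = NULL, rounding = c("half-up", "truncate"),
                           level = 0.95) {
  rounding <- match.arg(rounding)
  if (is.character(x)) {
    if (!length(x)) rb_error("no assessments supplied", "argument_error")
    counts <- table(x)
    counts <- stats::setNames(as.integer(counts), names(counts))
    if (is.null(n)) n <- length(x)
  } else {
    counts <- x
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      rb_error("counts must be named by label", "argument_error")
    }
    if (is.null(n)) n <- sum(counts)
  }
  if (sum(counts) != n) {
    rb_error(sprintf("counts sum to %d but n = %d", sum(counts), n),
             "consistency_error")
  }
  ci <- proportion_ci(unname(counts), n, level = level)
  out <- data.frame(
    label = names(counts),
    count = as.integer(counts),
    pct = round_pct(ci$pct, rounding),
    ci_lower = round_pct(ci$lower, rounding),
    ci_upper = round_pct(ci$upper, rounding),
    group = quality_group(names(counts)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$label), ]
  rownames(out) <- NULL
  attr(out, "rounding") <- rounding
  out
}

#' Count distinct participants whose events map into an ICD-10 prefix
#'
#' The prevalence-inflation diagnostic: a participant qualifies when at
#' least one of their clinical events carries a Read code whose mapped
#' targets include an ICD-10/ICD-10-CM code starting with the given
#' prefix. Comparing the count under full vs refined mapping exposes
#' inflation from erroneous one-to-many mappings.
#'
#' @param events Event data frame (see [read_events()]).
#' @param records Mapping-record data frame.
#' @param icd10_prefix Target prefix, e.g. `"E70"`.
#' @return Integer count of distinct `eid`s.
#' @export
prevalence_count <- function(events, records, icd10_prefix) {
  stopifnot(length(icd10_prefix) == 1L)
  w <- nchar(icd10_prefix)
  hit <- !is.na(records$target_code) &
    records$target_system %in% c("ICD10", "ICD10CM") &
    substr(gsub(".", "", records$target_code, fixed = TRUE), 1L, w) ==
      icd10_prefix
  keys <- unique(paste(records$read_code[hit], records$read_version[hit]))
  qual <- (!is.na(events$read_2) & paste(events$read_2, "READ2") %in% keys) |
    (!is.na(events$read_3) & paste(events$read_3, "READ3") %in% keys)
  length(unique(events$eid[qual]))
}
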