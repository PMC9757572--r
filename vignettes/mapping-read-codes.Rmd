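---
title: "Mapping Read codes to ICD-10 and SNOMED CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Read codes to ICD-10 and SNOMED CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readbridge)
```

## The problem

UK primary-care (GP) clinical events are recorded in Read v2 and CTV3
(Read v3) codes — 5-character hierarchical codes retired in favour of
SNOMED CT. Integrating GP events with hospital-inpatient data, cancer
registries, or any ICD-coded source requires mapping Read codes into
ICD-10/ICD-10-CM. Public lookup tables cover most disease codes but
carry one-to-many mappings whose wrong branches can inflate apparent
disease prevalence by orders of magnitude; the remainder needs
description-based matching and manual review. `readbridge` implements
this curation workflow as composable, deterministic, fully testable
pieces, with synthetic fixtures standing in for the access-restricted
source dictionaries.

## Code conventions

Read codes are normalized to exactly 5 characters, right-padded with
dots (`"G2y"` → `"G2y.."`), the convention of the upstream
dictionaries; an optional `2/`/`3/` version prefix is stripped and
checked. Raw extracts differ in whether short codes arrive padded, so
`normalize_read_code()` accepts both and is idempotent. ICD codes are
stored dotless (`"A87.9"` → `"A879"`), and comparisons are
case-sensitive, since Read codes are case-significant. A Read code
counts as *disease-related* when it either already maps into ICD via a
lookup, or its first character is a capital letter (the disease
chapters of the Read hierarchy); the lookup criterion dominates because
some clearly clinical codes (e.g. chronic hyperglycaemia under the
test-result chapter `66...`) live outside the letter chapters.

## Lookup mapping and flag refinement

`map_via_lookups()` attaches every lookup target in table order —
one-to-many blocks intact — because discarding alternatives silently
would hide exactly the errors the toolkit is meant to expose. Codes
mapping to both an ICD system and OPCS4 (procedure coding) are
reported as dual-target rather than resolved.

Lookup entries carry TRUD-style flags: a mapping status (`E` exact,
`G` target more general, `D` default, `A` alternative, `R` requires
checking), a refine flag and an add-code flag. *Refined* mapping keeps
only targets flagged `E`, `G`, or `D`/`A` with both qualifier flags
`C` ("completely refined", "complete"); everything else — including
blank flags — is treated as non-qualifying, since no other combination
is documented as reliable. Refinement is evaluated per target, not per
block, and can only ever remove targets (a property the test suite
asserts over a thousand random fixtures). The *hybrid* strategy falls
back to the full record when refinement would leave a code with
nothing, trading some precision for coverage.

## Trigram fuzzy matching

Codes without lookup entries but classified as disease-related are
mapped by description. Descriptions are normalized (lower-case,
punctuation runs collapsed to single spaces) and decomposed into
character trigrams, each word padded with two leading and one trailing
space — the dominant trigram-index convention, which weights word
starts more heavily than ends. The similarity of two descriptions is
the Jaccard coefficient of their trigram sets: the canonical set-based
trigram score, bounded in [0, 1], symmetric, and equal to 1 on
normalization-identical strings. Scores are reproducible bit-for-bit;
ties are broken by ascending code so search results are deterministic.

The index (`build_trigram_index()`) inverts trigrams to concept codes
so a query touches only concepts sharing at least one trigram; the
test suite proves index search identical to a brute-force scan over
hundreds of random dictionaries. The default review threshold is 0.80:
candidates scoring below it are *flagged* for manual review, never
dropped, which keeps the review queue an explicit artifact instead of
an interactive step. 0.80 is the conventional operating point trading
match accuracy against curation burden; it is a parameter everywhere
it appears.

One mapping heuristic deserves note: when a high-level source
description (containing "NOS", "unspecified", "other", or a trailing
ellipsis) lands on a 3-character ICD-10 category that has exactly one
"unspecified" child, the child is preferred (`A87` "Viral meningitis"
→ `A879` "Viral meningitis, unspecified" for "Viral meningitis NOS").
The rationale: had the condition carried a specific qualifier, the
recording clinician would have used a more specific source code. With
two or more "unspecified" children the choice is ambiguous and the
category is kept.

## Cross-mapping through SNOMED CT

Read3 codes resolve to SNOMED-style concepts through a concept map;
Read2 codes have no automated path (they predate SNOMED's Read3
lineage), so only a manual-override table can map them. Inactive
concepts are resolved by following `replaced_by` chains transitively
with cycle detection; an inactive concept without a replacement is
returned unchanged and flagged for review — automated resolution
stands in for a curator's judgement and must never silently claim
success. ICD-10 targets then come from a concept→ICD-10 reference set,
and the summary reports missing-ICD-10 fractions over both plausible
denominators (concepts found, and all Read3 inputs), since either can
be the quantity of interest.

When several concepts could represent one source term,
`select_by_policy()` implements the two defensible conventions: the
**broad** policy takes the smallest sufficiently general concept (an
ancestor of all the others if one exists, else the candidate with the
fewest ancestors in the transitive parent closure), robust for
prevalence summaries; the **narrow** policy takes the concept with the
most ancestors, most informative but prone to over-commitment. Ties
break by ascending concept id.

## Evaluation statistics

Manual-mapping audits classify each code by a deterministic decision
tree into seven quality categories in three groups — perfect match
(no issue), imprecise (more general / closest available / unspecified
qualifier), and multiple (combinations, ICD-O-3 morphology, block
ranges). Automated-vs-manual comparisons are classified by fixed
precedence (morphology > missing > exact > 4-character match >
partial multi-target > 3-character match > near miss) so that
classification is a function; 4-character agreement requires both
codes to have at least 4 characters, so a 3-character category never
spuriously "4-matches".

Uncertainty on proportions uses the Bayesian credible interval under a
flat Beta(1, 1) prior: the posterior for *k* of *n* is
Beta(*k* + 1, *n* − *k* + 1) and the bounds are its equal-tailed
2.5%/97.5% quantiles. Equal-tailed (rather than highest-density)
quantiles are used because they are the standard reporting convention
for binomial audits. At the boundaries *k* = 0 or *k* = *n* the
equal-tailed interval does not contain the point estimate, so the
interval is clamped to include it. Report percentages are rounded to
one decimal; because published tables sometimes truncate rather than
round, `quality_report()` offers both modes (`half-up` default,
`truncate`) and discloses which was used.

```{r ci}
proportion_ci(c(796, 439), 1313)
```

The prevalence-inflation diagnostic counts distinct participants with
at least one event whose mapped targets fall under an ICD-10 prefix.
Comparing the count under full vs refined mapping exposes wrong
one-to-many branches: in the bundled synthetic scenario, two common
osteoarthritis codes carry an erroneous `E702` target with status `R`,
so full mapping classifies every osteoarthritis patient as having an
amino-acid-metabolism disorder while refined mapping recovers the true
count exactly.

## The synthetic generators

All fixtures are generated in code from a `fixture_config()`; a single
master seed drives every sub-generator through fixed offsets, so
outputs are byte-identical across runs and adding a generator never
perturbs existing fixtures. The generators emulate the *structure* of
the upstream artifacts:

* ICD-10 dictionaries with 3-character categories, 1–5 children each,
  and an "unspecified" leaf with probability 0.8;
* dot-padded 5-character Read codes, a configurable fraction in
  capital-letter disease chapters (default 0.6), with descriptions
  drawn from a word bank at controlled lexical overlap with the ICD-10
  descriptions (half verbatim, a third mutated by one word) so trigram
  scores span [0, 1] meaningfully;
* lookup tables whose flag mix defaults to 45% `E`, 15% `G`, 10% each
  `D|C|C`, `A|C|C`, `R` and partially-refined combinations, with 15%
  one-to-many blocks and 85% lookup coverage of disease codes;
* injected wrong targets (default 5% of mapped codes) drawn from an
  unrelated ICD-10 chapter, carrying status `R` with probability 0.9 —
  deliberately not 1.0, so refined mapping removes most but not all
  errors and tests can distinguish refinement from oracle-perfect
  behaviour;
* SNOMED-style tables with 42% inactive concepts (replacement chains
  of length 1–2, acyclic), 43.4% of concepts lacking ICD-10 reference
  entries, and 18/790 of Read3 codes absent from the concept map —
  the reported magnitudes of these phenomena in real CTV3 data;
* event streams in which one designated common code takes 30% of the
  probability mass, reproducing the conditions for prevalence
  inflation.

Every generated code is covered exactly once by a gold standard
recording its true targets and any injected error, so tests can score
recovery exactly. The fixtures target structural fidelity, not
clinical realism: passing tests demonstrate that the algorithms behave
correctly on data with these shapes, not that any particular real-world
mapping is correct — the curation judgement itself remains with human
reviewers, and the toolkit's job is to queue the right items for them.

## Problem sizes and numerical choices

The default study conditions are 200 Read codes, 80 ICD-10 leaves, 300
patients with 5 events each, and the rates above; the property checks
run 1,000 refinement fixtures of 30 codes, 200 random dictionaries of
up to 50 concepts for the search-oracle equivalence, and 200
replicates of *n* = 1000 for credible-interval coverage at injected
imprecision rates of 0.1 and 0.3 — sizes chosen so the full suite
exercises every claim at meaningful scale while running in about a
minute. Dates parse from ISO `YYYY-MM-DD` or `DD/MM/YYYY` (the two
dialects seen in GP extracts); malformed event rows are dropped and
counted rather than fatal, since raw GP data arrives minimally
cleaned. Run reports count distinct Read codes with at least one
target, deduplicated across lookup sources.

## Known limitations

* The trigram scorer is a clean-room design: it honours the published
  contract of pre-indexed trigram search with a [0, 1] score and a 0.8
  review threshold, but no claim is made that its scores equal those
  of any proprietary matcher.
* Procedure coding (OPCS) is detected (dual-target report) but not
  mapped; free-text values, prescriptions and registration tables are
  out of scope.
* ICD-O-3 morphology is represented only as a category flag with
  pass-through codes.
* Broad/narrow selection uses ancestor counts as the specificity
  proxy; with very flat synthetic hierarchies the tie-break by id does
  most of the work.
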