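# Character-trigram fuzzy matching over concept descriptions.
#
# The index is built once per ontology (trigram postings + per-concept
# trigram sets), so queries only touch concepts that share at least one
# trigram with the query. The similarity score is the Jaccard coefficient
# of the padded trigram sets: the canonical set-based trigram similarity,
# bounded in [0,1] and equal to 1 on normalization-identical strings.

#' Normalize free text for trigram matching
#'
#' Lower-cases, collapses every run of non-alphanumeric characters to a
#' single space, and strips leading/trailing space.
#'
#' @param s Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(s) {
  s <- tolower(as.character(s))
  s <- gsub("[^[:alnum:]]+", " ", s)
  trimws(s)
}

#' Trigram set of a normalized string
#'
#' Each whitespace-delimited token is padded with two leading and one
#' trailing space, and all contiguous 3-character substrings are
#' collected. The result is the set (unique) union over tokens; empty
#' input gives an empty set.
#'
#' @param s A single already-normalized string (see [normalize_text()]).
#' @return Character vector of distinct trigrams.
#' @export
trigrams <- function(s) {
  stopifnot(length(s) == 1L)
  toks <- strsplit(s, " ", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  out <- unlist(lapply(toks, function(t) {
    p <- paste0("  ", t, " ")
    n <- nchar(p)
    substring(p, seq_len(n - 2L), seq_len(n - 2L) + 2L)
  }), use.names = FALSE)
  unique(out)
}

#' Trigram similarity of two strings
#'
#' Jaccard coefficient of the trigram sets of the normalized inputs:
#' `|T(a) n T(b)| / |T(a) u T(b)|`. Two empty strings score 1; exactly
#' one empty scores 0. Symmetric by construction.
#'
#' @param a,b Character scalars (normalization is applied internally).
#' @return Similarity in `[0, 1]`.
#' @export
trigram_similarity <- function(a, b) {
  ta <- trigrams(normalize_text(a))
  tb <- trigrams(normalize_text(b))
  if (!length(ta) && !length(tb)) return(1)
  if (!length(ta) || !length(tb)) return(0)
  inter <- length(intersect(ta, tb))
  inter / (length(ta) + length(tb) - inter)
}

# Content fingerprint so indexes can be tied back to the dictionary they
# were built from.
rb_fingerprint <- function(ont) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, open = "wb")
  writeLines(c(ont$system,
               paste(ont$concepts$code, ont$concepts$description,
                     ont$concepts$active, sep = "\t")),
             con, useBytes = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

#' Build a trigram index over an ontology
#'
#' Pre-computes, for every concept, the trigram set of its normalized
#' description, plus an inverted postings map from trigram to concept
#' codes. Search over the index returns exactly what a brute-force scan
#' of all concepts would.
#'
#' @param ont An [ontology()] with unique codes.
#' @return An object of class `"trigram_index"`.
#' @export
build_trigram_index <- function(ont) {
  stopifnot(inherits(ont, "ontology"))
  codes <- ont$concepts$code
  sets <- lapply(ont$concepts$description,
                 function(d) trigrams(normalize_text(d)))
  names(sets) <- codes
  postings <- if (length(codes)) {
    split(rep(codes, lengths(sets)), unlist(sets, use.names = FALSE))
  } else {
    list()
  }
  descriptions <- stats::setNames(ont$concepts$description, codes)
  structure(list(system = ont$system,
                 postings = postings,
                 trigram_sets = sets,
                 descriptions = descriptions,
                 built_from = rb_fingerprint(ont)),
            class = "trigram_index")
}

#' @export
print.trigram_index <- function(x, ...) {
  cat(sprintf("<trigram_index> %s: %d concepts, %d distinct trigrams\n",
              x$system, length(x$trigram_sets), length(x$postings)))
  invisible(x)
}

#' Fuzzy search a trigram index
#'
#' Scores every concept sharing at least one trigram with the query by
#' Jaccard similarity, sorts by descending score with ties broken by
#' ascending code, and returns at most `top_k` candidates. Candidates
#' scoring below `threshold` are flagged `review_needed`, never silently
#' dropped; zero-score concepts are omitted.
#'
#' @param index A [build_trigram_index()] result.
#' @param query Query text (raw; normalized internally).
#' @param top_k Maximum number of candidates (default 5).
#' @param threshold Review threshold in `[0, 1]` (default 0.8, the
#'   operating point below which matches go to manual review).
#' @return Data frame with columns `code`, `description`, `score`,
#'   `review_needed`, ordered best-first.
#' @export
search_index <- function(index, query, top_k = 5L, threshold = 0.8) {
  stopifnot(inherits(index, "trigram_index"))
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) {
    rb_error("top_k must be a positive integer", "argument_error")
  }
  if (threshold < 0 || threshold > 1) {
    rb_error("threshold must lie in [0, 1]", "argument_error")
  }
  empty <- data.frame(code = character(0), description = character(0),
                      score = numeric(0), review_needed = logical(0),
                      stringsAsFactors = FALSE)
  tq <- trigrams(normalize_text(query))
  if (!length(tq)) return(empty)
  hits <- unlist(index$postings[intersect(tq, names(index$postings))],
                 use.names = FALSE)
  if (!length(hits)) return(empty)
  inter <- table(hits)
  codes <- names(inter)
  inter <- as.integer(inter)
  union <- length(tq) + lengths(index$trigram_sets[codes]) - inter
  score <- inter / union
  ord <- order(-score, codes)
  codes <- codes[ord]
  score <- score[ord]
  keep <- seq_len(min(top_k, length(codes)))
  data.frame(
    code = codes[keep],
    description = unname(index$descriptions[codes[keep]]),
    score = score[keep],
    review_needed = score[keep] < threshold,
    stringsAsFactors = FALSE
  )
}
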