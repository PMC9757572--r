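# Shared helpers: independent brute-force oracles and tiny in-code
# fixtures used across test files.

# Brute-force fuzzy scan: score every concept with the pairwise
# similarity function, drop zero scores, sort by descending score with
# ties by ascending code. The index-based search must reproduce this.
brute_force_search <- function(ont, query, top_k = 5L) {
  scores <- vapply(ont$concepts$description,
                   function(d) trigram_similarity(query, d), numeric(1))
  df <- data.frame(code = ont$concepts$code, score = unname(scores),
                   stringsAsFactors = FALSE)
  df <- df[df$score > 0, , drop = FALSE]
  df <- df[order(-df$score, df$code), , drop = FALSE]
  head(df, top_k)
}

# Independent trigram enumeration: explicit per-character loop.
oracle_trigrams <- function(s) {
  s <- trimws(gsub("[^[:alnum:]]+", " ", tolower(s)))
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  out <- character(0)
  for (tok in toks) {
    p <- paste0("  ", tok, " ")
    for (i in seq_len(nchar(p) - 2L)) {
      out <- c(out, substr(p, i, i + 2L))
    }
  }
  unique(out)
}

# Small ICD-10 dictionary with category/leaf structure.
toy_icd10 <- function() {
  ontology(
    "ICD10",
    codes = c("A87", "A879", "A870", "B06", "B069", "K62",
              "K620", "K621"),
    descriptions = c("Viral meningitis", "Viral meningitis, unspecified",
                     "Enteroviral meningitis", "Rubella",
                     "Rubella without complication", "Diseases of anus",
                     "Anal polyp", "Rectal polyp"),
    parent_code = c(NA, "A87", "A87", NA, "B06", NA, "K62", "K62")
  )
}

random_ontology <- function(n, seed) {
  set.seed(seed)
  bank <- c("acute", "chronic", "benign", "malignant", "polyp", "ulcer",
            "skin", "bone", "liver", "kidney", "viral", "bacterial",
            "disease", "disorder", "infection", "unspecified")
  codes <- sprintf("C%03d", seq_len(n))
  desc <- vapply(seq_len(n), function(i) {
    paste(sample(bank, sample(1:4, 1), replace = TRUE), collapse = " ")
  }, character(1))
  ontology("ICD10", codes, desc)
}

write_lines_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

md5_of <- function(paths) unname(tools::md5sum(paths))
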