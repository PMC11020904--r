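.lexicon_sources <- c("semantic_type", "wordnet", "custom")

#' Construct a hypernym lexicon from a data frame
#'
#' A lexicon maps lowercased terms to candidate hypernym phrases, each tagged
#' with its source (a terminology semantic-type label, a WordNet-style
#' hypernym, or a custom entry). Duplicate (term, hypernym) pairs collapse to
#' one candidate; a hypernym equal to its own term is rejected.
#'
#' @param x A data frame with columns `term`, `hypernym`, `source` and
#'   optionally `semantic_type`.
#' @return A tibble of class `medsim_lexicon`.
#' @export
as_lexicon <- function(x) {
  if (inherits(x, "medsim_lexicon")) return(x)
  needed <- c("term", "hypernym", "source")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    abort("A lexicon needs columns term, hypernym, source.",
          class = "medsimplify_bad_input")
  }
  lex <- tibble::tibble(
    term = tolower(trimws(as.character(x$term))),
    hypernym = tolower(trimws(as.character(x$hypernym))),
    source = as.character(x$source),
    semantic_type = if ("semantic_type" %in% names(x)) {
      as.character(x$semantic_type)
    } else {
      NA_character_
    }
  )
  validate_lexicon_rows(lex)
  lex <- dplyr::distinct(lex, .data$term, .data$hypernym, .keep_all = TRUE)
  class(lex) <- c("medsim_lexicon", class(tibble::tibble()))
  lex
}

validate_lexicon_rows <- function(lex, line = NULL) {
  where <- function(i) {
    if (is.null(line)) paste0("row ", i) else paste0("line ", line[i])
  }
  bad <- which(!nzchar(lex$term) | !nzchar(lex$hypernym))
  if (length(bad) > 0) {
    abort(paste0("Empty term or hypernym at ", where(bad[1]), "."),
          class = "medsimplify_bad_lexicon")
  }
  bad <- which(lex$hypernym == lex$term)
  if (length(bad) > 0) {
    abort(paste0("Hypernym equals its own term ('", lex$term[bad[1]],
                 "') at ", where(bad[1]), "."),
          class = "medsimplify_bad_lexicon")
  }
  bad <- which(!lex$source %in% .lexicon_sources)
  if (length(bad) > 0) {
    abort(paste0("Unknown source tag '", lex$source[bad[1]], "' at ",
                 where(bad[1]), "; expected one of ",
                 paste(.lexicon_sources, collapse = ", "), "."),
          class = "medsimplify_bad_lexicon")
  }
  invisible(lex)
}

#' Read and write hypernym lexicons in TSV form
#'
#' The on-disk dialect is UTF-8 TSV with a required header
#' `term<TAB>hypernym<TAB>source<TAB>semantic_type`; lines starting with `#`
#' are comments. `semantic_type` may be empty. Malformed rows raise an error
#' naming the offending line.
#'
#' @param path File path.
#' @return `read_lexicon()` returns a `medsim_lexicon` tibble.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Lexicon file not found: ", path), class = "medsimplify_io_error")
  }
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    abort("Lexicon file is empty.", class = "medsimplify_bad_lexicon")
  }
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  expected <- c("term", "hypernym", "source", "semantic_type")
  if (!identical(header, expected)) {
    abort(paste0("Lexicon header must be '", paste(expected, collapse = "\\t"),
                 "' (line ", keep[1], ")."),
          class = "medsimplify_bad_lexicon")
  }
  data_idx <- keep[-1]
  if (length(data_idx) == 0) {
    abort("Lexicon file has a header but no entries.",
          class = "medsimplify_bad_lexicon")
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L | n_fields > 4L)
  if (length(bad) > 0) {
    abort(paste0("Malformed lexicon row at line ", data_idx[bad[1]],
                 ": expected 3-4 tab-separated fields, got ",
                 n_fields[bad[1]], "."),
          class = "medsimplify_bad_lexicon")
  }
  raw <- tibble::tibble(
    term = purrr::map_chr(fields, 1),
    hypernym = purrr::map_chr(fields, 2),
    source = purrr::map_chr(fields, 3),
    semantic_type = purrr::map_chr(fields, ~ if (length(.x) >= 4) .x[[4]] else NA_character_)
  )
  validate_lexicon_rows(
    dplyr::mutate(raw, term = tolower(trimws(.data$term)),
                  hypernym = tolower(trimws(.data$hypernym))),
    line = data_idx)
  as_lexicon(raw)
}

#' @rdname read_lexicon
#' @param lex A `medsim_lexicon` (or compatible data frame).
#' @export
write_lexicon <- function(lex, path) {
  lex <- as_lexicon(lex)
  st <- ifelse(is.na(lex$semantic_type), "", lex$semantic_type)
  lines <- c("term\thypernym\tsource\tsemantic_type",
             paste(lex$term, lex$hypernym, lex$source, st, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

char_ngrams <- function(x, n = 3L, pad = "#") {
  padded <- paste0(strrep(pad, n - 1L), tolower(x), strrep(pad, n - 1L))
  purrr::map(padded, function(p) {
    k <- nchar(p) - n + 1L
    substring(p, seq_len(k), seq_len(k) + n - 1L)
  })
}

#' Build a character n-gram TF-IDF index over lexicon terms
#'
#' Each term is padded with two boundary markers per side (so prefixes and
#' suffixes get their own grams), decomposed into character 3-grams (spaces
#' inside multi-word terms are retained), and represented as an
#' L2-normalized TF-IDF profile with `IDF = ln(N / df)` computed over the
#' lexicon terms as documents. A single-term lexicon degenerates (all IDF
#' zero); the index then falls back to raw term-frequency profiles.
#'
#' @param lex A `medsim_lexicon`.
#' @param n Gram size (default 3).
#' @return An object of class `medsim_ngram_index`.
#' @export
build_ngram_index <- function(lex, n = 3L) {
  lex <- as_lexicon(lex)
  terms <- sort(unique(lex$term))
  grams <- char_ngrams(terms, n = n)
  vocab <- sort(unique(unlist(grams)))
  triplets <- dplyr::count(
    tibble::tibble(
      i = rep(seq_along(terms), lengths(grams)),
      j = match(unlist(grams), vocab)),
    .data$i, .data$j, name = "tf")
  tf <- Matrix::sparseMatrix(i = triplets$i, j = triplets$j, x = triplets$tf,
                             dims = c(length(terms), length(vocab)))
  df <- Matrix::colSums(tf > 0)
  idf <- log(length(terms) / df)
  weighting <- if (all(idf == 0)) "tf" else "tfidf"
  w <- if (weighting == "tfidf") tf %*% Matrix::Diagonal(x = idf) else tf
  w <- normalize_rows(w)
  structure(
    list(terms = terms, vocab = vocab, n = n, idf = idf,
         weights = w, weighting = weighting),
    class = "medsim_ngram_index")
}

normalize_rows <- function(m) {
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1  # all-zero profiles stay zero
  Matrix::Diagonal(x = 1 / norms) %*% m
}

#' @export
print.medsim_ngram_index <- function(x, ...) {
  cat("<medsim_ngram_index> ", length(x$terms), " terms, ",
      length(x$vocab), " character ", x$n, "-grams (", x$weighting, ")\n",
      sep = "")
  invisible(x)
}

#' Fuzzy-match query strings against indexed lexicon terms
#'
#' Cosine similarity between the query's character n-gram profile and every
#' indexed term profile, using the index's IDF weights (query grams unseen in
#' the lexicon contribute nothing). Returns the top `k` terms with similarity
#' at or above `min_sim`, in descending similarity with lexicographic
#' tie-breaking; a query sharing no gram with any term returns zero rows.
#'
#' @param query Character vector of query strings (matched lowercased).
#' @param index A `medsim_ngram_index`.
#' @param k Maximum matches per query.
#' @param min_sim Minimum cosine similarity to report. Default 0.4; the
#'   gate is configurable because no universal cutoff exists for fuzzy
#'   terminology lookup.
#' @return A tibble with columns `query`, `term`, `similarity`, `rank`.
#' @export
#' @examples
#' lex <- as_lexicon(tibble::tibble(
#'   term = c("lymphoma", "histamine"), hypernym = c("cancer", "amine"),
#'   source = "wordnet"))
#' idx <- build_ngram_index(lex)
#' match_term("histamin", idx)
match_term <- function(query, index, k = 5L, min_sim = 0.4) {
  if (!inherits(index, "medsim_ngram_index")) {
    abort("`index` must be a medsim_ngram_index.", class = "medsimplify_bad_input")
  }
  if (length(query) == 0 || any(!nzchar(query))) {
    abort("`query` must be non-empty.", class = "medsimplify_bad_input")
  }
  q <- tolower(query)
  grams <- char_ngrams(q, n = index$n)
  idx_list <- purrr::map(grams, ~ match(.x, index$vocab))
  trip <- tibble::tibble(
    i = rep(seq_along(q), lengths(idx_list)),
    j = unlist(idx_list))
  trip <- dplyr::count(dplyr::filter(trip, !is.na(.data$j)),
                       .data$i, .data$j, name = "tf")
  qm <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$tf,
                             dims = c(length(q), length(index$vocab)))
  if (index$weighting == "tfidf") {
    qm <- qm %*% Matrix::Diagonal(x = index$idf)
  }
  qm <- normalize_rows(qm)
  sims <- as.matrix(qm %*% Matrix::t(index$weights))
  out <- purrr::map(seq_along(q), function(i) {
    s <- sims[i, ]
    sel <- which(s >= min_sim & s > 0)
    if (length(sel) == 0) return(NULL)
    ord <- sel[order(-s[sel], index$terms[sel])]
    ord <- head(ord, k)
    tibble::tibble(query = query[i], term = index$terms[ord],
                   similarity = s[ord], rank = seq_along(ord))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(query = character(), term = character(),
                          similarity = numeric(), rank = integer())
  }
  res
}

#' Total syllable count of a phrase
#'
#' Sums [count_syllables()] over the word tokens of each phrase.
#'
#' @param phrase Character vector of phrases.
#' @return Integer vector.
#' @export
phrase_syllables <- function(phrase) {
  words <- stringr::str_extract_all(phrase, "[A-Za-z0-9]+")
  vapply(words, function(w) {
    if (length(w) == 0) return(0L)
    as.integer(sum(count_syllables(w)))
  }, integer(1))
}

#' Select the simplest hypernym for a term
#'
#' Among all candidate hypernym phrases recorded for `term` (across all
#' sources), returns the one with the fewest total syllables; ties break to
#' fewer characters, then lexicographically. This is the "least amount of
#' syllables" selection rule of the substitution pipeline.
#'
#' @param term A term present in the lexicon.
#' @param lex A `medsim_lexicon`.
#' @param counter Syllable-counting function used on candidate words
#'   (defaults to [count_syllables()]).
#' @return A single hypernym phrase.
#' @export
#' @examples
#' lex <- as_lexicon(tibble::tibble(
#'   term = "lymphoma", hypernym = c("cancer", "neoplastic process"),
#'   source = c("wordnet", "semantic_type")))
#' select_hypernym("lymphoma", lex)  # "cancer"
select_hypernym <- function(term, lex, counter = count_syllables) {
  lex <- as_lexicon(lex)
  cand <- lex[lex$term == tolower(term), ]
  if (nrow(cand) == 0) {
    abort(paste0("Term not in lexicon: '", term, "'."),
          class = "medsimplify_lookup_miss")
  }
  syl <- vapply(cand$hypernym, function(p) {
    w <- stringr::str_extract_all(p, "[A-Za-z0-9]+")[[1]]
    if (length(w) == 0) 0L else as.integer(sum(counter(w)))
  }, integer(1))
  ord <- order(syl, nchar(cand$hypernym), cand$hypernym)
  cand$hypernym[ord[1]]
}
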