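#' Tokenize a definition into sentences and word tokens
#'
#' Deterministic, convention-fixed tokenization feeding every readability
#' metric. Sentences end at runs of terminal punctuation (`.`, `!`, `?`).
#' Word tokens are maximal alphanumeric runs, so hyphenated compounds split
#' into one token per component ("non-covalently" gives "non" and
#' "covalently") and punctuation never counts towards word totals. Each token
#' carries its character offsets into the raw string, its character count and
#' its syllable count.
#'
#' No abbreviation-aware sentence splitting is attempted: biomedical
#' definitions are short and the corpora this package targets avoid ambiguous
#' periods.
#'
#' @param text A single non-empty string (UTF-8 plain text).
#' @return An object of class `tokenized_text`: a list with `raw_text` and a
#'   `tokens` tibble (columns `sentence`, `token`, `start`, `end`, `chars`,
#'   `syllables`).
#' @seealso [count_syllables()], [text_stats()]
#' @export
#' @examples
#' tt <- tokenize("Lymphoma is a type of cancer.")
#' nrow(tt$tokens)      # 6 word tokens
#' max(tt$tokens$sentence)  # 1 sentence
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single non-NA string.",
          class = "medsimplify_bad_input")
  }
  if (!nzchar(trimws(text))) {
    abort("Cannot tokenize empty or whitespace-only text.",
          class = "medsimplify_empty_input")
  }
  loc <- stringr::str_locate_all(text, "[A-Za-z0-9]+")[[1]]
  if (nrow(loc) == 0L) {
    abort("Text contains no word tokens.", class = "medsimplify_empty_input")
  }
  token <- stringr::str_sub(text, loc[, 1], loc[, 2])
  term_end <- stringr::str_locate_all(text, "[.!?]+")[[1]][, 2]
  # a token belongs to sentence 1 + number of terminators strictly before it
  sent_raw <- findInterval(loc[, 1] - 1L, term_end) + 1L
  sentence <- match(sent_raw, unique(sent_raw))
  tokens <- tibble::tibble(
    sentence  = sentence,
    token     = token,
    start     = as.integer(loc[, 1]),
    end       = as.integer(loc[, 2]),
    chars     = nchar(token),
    syllables = count_syllables(token)
  )
  structure(list(raw_text = text, tokens = tokens), class = "tokenized_text")
}

#' @export
print.tokenized_text <- function(x, ...) {
  cat("<tokenized_text> ", max(x$tokens$sentence), " sentence(s), ",
      nrow(x$tokens), " word token(s)\n", sep = "")
  cat(substr(x$raw_text, 1, 70),
      if (nchar(x$raw_text) > 70) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Reassemble a tokenized text into a canonical surface string
#'
#' Joins tokens with single spaces and terminates every sentence with a
#' period. Re-tokenizing the result reproduces the same token sequence, which
#' is the idempotence property the test suite asserts.
#'
#' @param x A `tokenized_text`.
#' @return A single string.
#' @export
detokenize <- function(x) {
  stopifnot(inherits(x, "tokenized_text"))
  sents <- split(x$tokens$token, x$tokens$sentence)
  paste0(paste(vapply(sents, paste, "", collapse = " "), collapse = ". "), ".")
}

#' Count syllables in a word token
#'
#' Rule-based counting: the number of maximal vowel-letter runs
#' (`a e i o u y`), minus one for a terminal silent "e" (unless that would
#' reach zero), plus one for a terminal consonant + "le" cluster, floored at
#' one. Tokens without vowel letters (such as "h4") count as one syllable;
#' digits count as characters but never as vowels. This is the fixed
#' convention behind every grade-level formula in the package; published
#' grade levels computed under other syllabification conventions can differ.
#'
#' @param word Character vector of non-empty alphanumeric tokens.
#' @return Integer vector of syllable counts, all >= 1.
#' @export
#' @examples
#' count_syllables(c("a", "cancer", "histamine", "h4", "table"))
count_syllables <- function(word) {
  if (length(word) == 0L) return(integer(0))
  if (any(is.na(word)) || any(!nzchar(word))) {
    abort("`word` must contain non-empty tokens.", class = "medsimplify_bad_input")
  }
  w <- tolower(word)
  n <- stringr::str_count(w, "[aeiouy]+")
  silent_e <- stringr::str_detect(w, "e$") & n > 1L
  n[silent_e] <- n[silent_e] - 1L
  cons_le <- stringr::str_detect(w, "[^aeiouy]le$")
  n[cons_le] <- n[cons_le] + 1L
  pmax(n, 1L)
}

#' Aggregate token counts for the readability formulas
#'
#' Sums word, sentence, character and syllable counts over a tokenized text;
#' `n_complex_words` counts tokens with three or more syllables (the Gunning
#' Fog "complex word"). Characters are letters and digits inside word tokens
#' only. The data-frame method computes the same statistics per corpus row.
#'
#' @param x A `tokenized_text`, a character vector of texts, or a corpus data
#'   frame with `id` and `text` columns.
#' @param ... Passed between methods.
#' @return A tibble with columns `n_words`, `n_sentences`, `n_chars`,
#'   `n_syllables`, `n_complex_words` (one row per input text; the data-frame
#'   method prepends the `id` column).
#' @export
#' @examples
#' text_stats(tokenize("Lymphoma is a type of cancer."))
text_stats <- function(x, ...) UseMethod("text_stats")

#' @rdname text_stats
#' @export
text_stats.tokenized_text <- function(x, ...) {
  tk <- x$tokens
  tibble::tibble(
    n_words         = nrow(tk),
    n_sentences     = max(tk$sentence),
    n_chars         = sum(tk$chars),
    n_syllables     = sum(tk$syllables),
    n_complex_words = sum(tk$syllables >= 3L)
  )
}

#' @rdname text_stats
#' @export
text_stats.character <- function(x, ...) {
  purrr::map_dfr(x, function(s) text_stats(tokenize(s)))
}

#' @rdname text_stats
#' @param id,text Column names holding definition ids and raw text.
#' @export
text_stats.data.frame <- function(x, id = "id", text = "text", ...) {
  check_corpus(x, id = id, text = text)
  dplyr::bind_cols(tibble::tibble(id = x[[id]]), text_stats(x[[text]]))
}

check_corpus <- function(x, id = "id", text = "text") {
  missing_cols <- setdiff(c(id, text), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Corpus is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "medsimplify_bad_input")
  }
  invisible(x)
}

#' Read and write JSONL definition corpora
#'
#' One JSON object per line with fields `id` and `text`.
#'
#' @param path File path.
#' @return `read_corpus()` returns a tibble with columns `id` and `text`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Corpus file not found: ", path), class = "medsimplify_io_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("Corpus file is empty.", class = "medsimplify_io_error")
  }
  recs <- purrr::map(lines, jsonlite::fromJSON)
  bad <- which(!purrr::map_lgl(recs, ~ all(c("id", "text") %in% names(.x))))
  if (length(bad) > 0) {
    abort(paste0("Corpus line ", bad[1], " lacks id/text fields."),
          class = "medsimplify_io_error")
  }
  tibble::tibble(
    id   = purrr::map_chr(recs, ~ as.character(.x$id)),
    text = purrr::map_chr(recs, ~ as.character(.x$text))
  )
}

#' @rdname read_corpus
#' @param corpus A corpus tibble with `id` and `text` columns.
#' @export
write_corpus <- function(corpus, path) {
  check_corpus(corpus)
  lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(id = corpus$id[i], text = corpus$text[i]),
                     auto_unbox = TRUE)
  })
  readr::write_lines(lines, path)
  invisible(path)
}
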