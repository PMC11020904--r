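#' Classic readability formulas
#'
#' Closed-form readability scores computed from a table of per-definition
#' text statistics (see [text_stats()]). All four are vectorized over rows
#' and are always computed per definition, never on pooled corpus counts.
#'
#' * `fks()` — Flesch-Kincaid Reading Ease,
#'   `206.835 - 1.015 W/S - 84.6 Y/W` (higher = easier; nominally 0-100 but
#'   not clamped).
#' * `fkg()` — Flesch-Kincaid Grade, `0.39 W/S + 11.8 Y/W - 15.59`.
#' * `ari()` — Automated Readability Index, `4.71 C/W + 0.5 W/S - 21.43`.
#' * `gfi()` — Gunning Fog Index, `0.4 (W/S + 100 X/W)`,
#'   where `X` counts words with >= 3 syllables.
#'
#' `W`, `S`, `C`, `Y` are word, sentence, character and syllable counts.
#' Rows with zero words or sentences yield `NA`.
#'
#' @param stats A data frame with columns `n_words`, `n_sentences`,
#'   `n_chars`, `n_syllables`, `n_complex_words`.
#' @return A numeric vector, one value per row of `stats`.
#' @export
#' @examples
#' st <- text_stats("The cat sat on the mat and then it slept.")
#' fks(st); fkg(st); ari(st); gfi(st)
fks <- function(stats) {
  check_stats(stats, c("n_words", "n_sentences", "n_syllables"))
  with_valid(stats, 206.835 -
    1.015 * stats$n_words / stats$n_sentences -
    84.6 * stats$n_syllables / stats$n_words)
}

#' @rdname fks
#' @export
fkg <- function(stats) {
  check_stats(stats, c("n_words", "n_sentences", "n_syllables"))
  with_valid(stats, 0.39 * stats$n_words / stats$n_sentences +
    11.8 * stats$n_syllables / stats$n_words - 15.59)
}

#' @rdname fks
#' @export
ari <- function(stats) {
  check_stats(stats, c("n_words", "n_sentences", "n_chars"))
  with_valid(stats, 4.71 * stats$n_chars / stats$n_words +
    0.5 * stats$n_words / stats$n_sentences - 21.43)
}

#' @rdname fks
#' @export
gfi <- function(stats) {
  check_stats(stats, c("n_words", "n_sentences", "n_complex_words"))
  with_valid(stats, 0.4 * (stats$n_words / stats$n_sentences +
    100 * stats$n_complex_words / stats$n_words))
}

check_stats <- function(stats, cols) {
  if (!is.data.frame(stats) || !all(cols %in% names(stats))) {
    abort(paste0("`stats` must be a data frame with columns: ",
                 paste(cols, collapse = ", ")),
          class = "medsimplify_bad_input")
  }
  invisible(stats)
}

with_valid <- function(stats, value) {
  ifelse(stats$n_words >= 1 & stats$n_sentences >= 1, value, NA_real_)
}

#' Round a grade level for display
#'
#' Grade metrics are reported unrounded throughout; this helper applies the
#' half-up integer rounding conventionally used when quoting "nth grade".
#'
#' @param grade Numeric vector of grade levels.
#' @return Integer vector.
#' @export
round_grade <- function(grade) as.integer(floor(grade + 0.5))

#' Measure of Textual Lexical Diversity (MTLD)
#'
#' Bidirectional MTLD: scan the (lowercased) token sequence accumulating a
#' running type-token ratio; each time the ratio drops below `ttr_threshold`
#' a factor is completed and counting restarts. The trailing partial segment
#' contributes `(1 - TTR) / (1 - threshold)` of a factor. The score in one
#' direction is token count divided by total factors; the reported value is
#' the mean of the forward and reverse passes. If either pass accrues zero
#' factors (e.g. all tokens distinct) the measure is undefined and `NA` is
#' returned.
#'
#' @param tokens Character vector of word tokens (>= 1), or a
#'   `tokenized_text`.
#' @param ttr_threshold Type-token ratio at which a factor completes.
#'   Default 0.72, the standard published value.
#' @return A single numeric value, or `NA` when undefined.
#' @export
#' @examples
#' mtld(rep(c("a", "b", "a"), 4))  # 3
#' mtld(rep("a", 4))               # 2
mtld <- function(tokens, ttr_threshold = 0.72) {
  if (inherits(tokens, "tokenized_text")) tokens <- tokens$tokens$token
  if (length(tokens) == 0L) {
    abort("MTLD needs at least one token.", class = "medsimplify_empty_input")
  }
  toks <- tolower(tokens)
  f_fwd <- mtld_factors(toks, ttr_threshold)
  f_rev <- mtld_factors(rev(toks), ttr_threshold)
  if (f_fwd <= 0 || f_rev <= 0) return(NA_real_)
  mean(c(length(toks) / f_fwd, length(toks) / f_rev))
}

mtld_factors <- function(toks, thr) {
  factors <- 0
  seen <- character(0)
  n_seg <- 0L
  for (tk in toks) {
    n_seg <- n_seg + 1L
    if (!(tk %in% seen)) seen <- c(seen, tk)
    ttr <- length(seen) / n_seg
    if (ttr < thr) {
      factors <- factors + 1
      seen <- character(0)
      n_seg <- 0L
    }
  }
  if (n_seg > 0L) {
    ttr <- length(seen) / n_seg
    factors <- factors + (1 - ttr) / (1 - thr)
  }
  factors
}

#' Per-definition readability table
#'
#' Tokenizes every definition in a corpus and returns one row per definition
#' with its text statistics, the four readability formulas and MTLD. This is
#' the table the evaluation harness pairs pre/post.
#'
#' @param corpus A data frame with `id` and `text` columns.
#' @param id,text Column names.
#' @return A tibble: `id`, the [text_stats()] columns, `fks`, `fkg`, `ari`,
#'   `gfi`, `mtld`.
#' @export
#' @examples
#' readability(tibble::tibble(id = "d1", text = "Lymphoma is a type of cancer."))
readability <- function(corpus, id = "id", text = "text") {
  check_corpus(corpus, id = id, text = text)
  na_row <- tibble::tibble(
    n_words = NA_integer_, n_sentences = NA_integer_, n_chars = NA_integer_,
    n_syllables = NA_integer_, n_complex_words = NA_integer_,
    fks = NA_real_, fkg = NA_real_, ari = NA_real_, gfi = NA_real_,
    mtld = NA_real_)
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    tryCatch({
      tt <- tokenize(corpus[[text]][i])
      st <- text_stats(tt)
      dplyr::mutate(st,
        fks  = fks(st),  fkg = fkg(st), ari = ari(st), gfi = gfi(st),
        mtld = mtld(tt$tokens$token))
    }, error = function(e) na_row)  # unscorable definitions keep their id, all NA
  })
  dplyr::bind_cols(tibble::tibble(id = corpus[[id]]), dplyr::bind_rows(rows))
}
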