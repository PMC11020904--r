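#' Score the lexical complexity of word tokens
#'
#' Deterministic default scorer standing behind the pipeline's pluggable
#' complexity interface. Words on the common-word list score 0; any other
#' word scores `0.25 * max(0, syllables - 1) + 0.05 * max(0, length - 4)`,
#' clamped to `[0, 1]`. The scale is calibrated so that everyday two-syllable
#' words stay below the 0.65 decision threshold while longer Latinate
#' vocabulary crosses it ("cancer" scores 0.35, "histamine" 0.75).
#'
#' @param word Character vector of word tokens.
#' @param common_words Words that always score 0 (default
#'   [common_word_list()]).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' score_complexity(c("and", "cancer", "histamine"))
score_complexity <- function(word, common_words = common_word_list()) {
  syl <- count_syllables(word)
  len <- nchar(word)
  score <- 0.25 * pmax(0, syl - 1) + 0.05 * pmax(0, len - 4)
  score <- pmin(1, pmax(0, score))
  score[tolower(word) %in% tolower(common_words)] <- 0
  score
}

empty_spans <- function() {
  tibble::tibble(
    sentence = integer(), token_start = integer(), token_end = integer(),
    surface = character(), char_start = integer(), char_end = integer(),
    complexity_score = numeric(), matched_term = character(),
    similarity = numeric(), hypernym = character())
}

#' Identify complex, biomedical target spans
#'
#' Scans each sentence left to right for token n-grams (up to `max_span`
#' tokens, non-overlapping) that pass both gates of the substitution rule:
#' the span must fuzzy-match a lexicon term at or above `min_sim` (the
#' "biomedical" gate, dictionary-based recognition via [match_term()]) and
#' its maximum per-token complexity score must reach `threshold` (the
#' "complex" gate; the span maximum favours recall on multi-word terms).
#' Overlaps resolve by match quality: the highest-similarity window claims
#' its tokens first (ties: leftmost, then longest), so a loose window can
#' neither widen a span past its matched term nor swallow a neighbouring
#' exact term. Span edges must themselves have a positive complexity score,
#' so common or trivially short tokens can sit inside a span but never
#' start or end one.
#'
#' @param x A `tokenized_text`.
#' @param lex A `medsim_lexicon`.
#' @param index Optional prebuilt [build_ngram_index()] for `lex`.
#' @param threshold Complexity decision threshold, default 0.65.
#' @param min_sim Fuzzy-match gate passed to [match_term()].
#' @param max_span Maximum tokens per span (default 3).
#' @param common_words Passed to [score_complexity()].
#' @return A tibble of target spans: `sentence`, `token_start`/`token_end`
#'   (0-based, half-open), `surface`, `char_start`/`char_end` (1-based
#'   offsets into the raw text), `complexity_score`, `matched_term`,
#'   `similarity`, `hypernym`.
#' @export
identify_targets <- function(x, lex, index = NULL, threshold = 0.65,
                             min_sim = 0.4, max_span = 3L,
                             common_words = common_word_list()) {
  stopifnot(inherits(x, "tokenized_text"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.",
          class = "medsimplify_bad_input")
  }
  lex <- as_lexicon(lex)
  if (is.null(index)) index <- build_ngram_index(lex)
  tk <- x$tokens
  tk$score <- score_complexity(tk$token, common_words)
  # pass 1: enumerate windows passing the edge and complexity gates
  sent_v <- integer(0); i_v <- integer(0); j_v <- integer(0)
  surf_v <- character(0); cs_v <- integer(0); ce_v <- integer(0)
  score_v <- numeric(0); query_v <- character(0)
  for (s in unique(tk$sentence)) {
    st <- tk[tk$sentence == s, ]
    n <- nrow(st)
    low <- tolower(st$token)
    for (i in seq_len(n)) {
      if (st$score[i] <= 0) next
      for (len in seq_len(min(max_span, n - i + 1L))) {
        j <- i + len - 1L
        if (st$score[j] <= 0) next
        span_score <- max(st$score[i:j])
        if (span_score < threshold) next
        sent_v <- c(sent_v, s); i_v <- c(i_v, i); j_v <- c(j_v, j)
        surf_v <- c(surf_v, paste(st$token[i:j], collapse = " "))
        cs_v <- c(cs_v, st$start[i]); ce_v <- c(ce_v, st$end[j])
        score_v <- c(score_v, span_score)
        query_v <- c(query_v, paste(low[i:j], collapse = " "))
      }
    }
  }
  if (length(i_v) == 0) return(empty_spans())
  cand <- tibble::tibble(sentence = sent_v, i = i_v, j = j_v,
                         surface = surf_v, char_start = cs_v, char_end = ce_v,
                         complexity_score = score_v, query = query_v)
  # one batched fuzzy lookup for all windows (the biomedical gate)
  hits <- match_term(unique(cand$query), index, k = 1L, min_sim = min_sim)
  cand <- dplyr::inner_join(cand, hits[, c("query", "term", "similarity")],
                            by = "query")
  if (nrow(cand) == 0) return(empty_spans())
  # pass 2: overlap resolution. Best-matching windows claim their tokens
  # first (ties: leftmost, then longest), so a strong exact term is never
  # swallowed by a looser window that happens to start earlier.
  # Similarities are rounded so exact matches tie regardless of float noise.
  ord <- order(-round(cand$similarity, 9), cand$sentence, cand$i,
               -(cand$j - cand$i))
  keep <- integer(0)
  for (r in ord) {
    clash <- keep[cand$sentence[keep] == cand$sentence[r] &
                    cand$i[keep] <= cand$j[r] & cand$j[keep] >= cand$i[r]]
    if (length(clash) == 0) keep <- c(keep, r)
  }
  out <- cand[sort(keep), ]
  # one hypernym lookup per distinct matched term
  hyp_map <- vapply(unique(out$term), function(t) select_hypernym(t, lex),
                    character(1))
  tibble::tibble(
    sentence = out$sentence,
    token_start = out$i - 1L, token_end = out$j,
    surface = out$surface,
    char_start = out$char_start, char_end = out$char_end,
    complexity_score = out$complexity_score,
    matched_term = out$term, similarity = out$similarity,
    hypernym = unname(hyp_map[out$term]))
}

#' Substitute hypernyms into a text
#'
#' Replaces each target span with its selected hypernym, right-to-left so
#' character offsets stay valid, with three surface repairs: a preceding
#' indefinite article is re-agreed to the replacement's initial letter
#' (vowel -> "an"), case preserved; sentence-initial capitalization is
#' transferred to the replacement; and whitespace is normalized. No other
#' grammar repair is attempted — rule-based simplifiers deliberately leave
#' residual inflection artifacts rather than risk altering meaning.
#'
#' @param x A `tokenized_text`.
#' @param spans A span tibble from [identify_targets()] (non-overlapping).
#' @return An object of class `medsim_simplified`: list with `original`,
#'   `text`, and a `substitutions` tibble (`from`, `to`, `repairs`,
#'   `char_start`, `char_end`); `from`/`to` give the exact replaced and
#'   inserted strings so recorded substitutions replay to `text`.
#' @export
substitute_spans <- function(x, spans) {
  stopifnot(inherits(x, "tokenized_text"))
  if (nrow(spans) > 0) {
    ord <- order(spans$char_start)
    spans <- spans[ord, ]
    if (any(spans$char_start[-1] <= spans$char_end[-nrow(spans)])) {
      abort("Target spans overlap.", class = "medsimplify_overlap")
    }
  }
  text <- x$raw_text
  tk <- x$tokens
  recs <- list()
  for (r in rev(seq_len(nrow(spans)))) {
    sp <- spans[r, ]
    repairs <- character(0)
    replacement <- sp$hypernym
    rep_start <- sp$char_start
    rep_end <- sp$char_end
    prev <- tk[tk$sentence == sp$sentence & tk$end < sp$char_start, ]
    article_handled <- FALSE
    if (nrow(prev) > 0) {
      prev <- prev[nrow(prev), ]
      if (tolower(prev$token) %in% c("a", "an")) {
        wants_an <- grepl("^[aeiou]", tolower(replacement))
        art <- if (wants_an) "an" else "a"
        if (art != tolower(prev$token)) {
          if (grepl("^[A-Z]", prev$token)) {
            art <- paste0(toupper(substr(art, 1, 1)), substr(art, 2, nchar(art)))
          }
          replacement <- paste(art, replacement)
          rep_start <- prev$start
          repairs <- c(repairs, "article")
          article_handled <- TRUE
        }
      }
    }
    if (!article_handled) {
      sent_first <- min(tk$start[tk$sentence == sp$sentence])
      if (sp$char_start == sent_first &&
          grepl("^[A-Z]", substr(x$raw_text, sp$char_start, sp$char_start))) {
        replacement <- paste0(toupper(substr(replacement, 1, 1)),
                              substr(replacement, 2, nchar(replacement)))
        repairs <- c(repairs, "capitalization")
      }
    }
    recs[[length(recs) + 1L]] <- tibble::tibble(
      from = substr(x$raw_text, rep_start, rep_end),
      to = replacement,
      repairs = list(repairs),
      char_start = rep_start, char_end = rep_end)
    text <- paste0(substr(text, 1, rep_start - 1L), replacement,
                   substr(text, rep_end + 1L, nchar(text)))
  }
  normalized <- trimws(gsub("[ \t]+", " ", text))
  subs <- if (length(recs) == 0) {
    tibble::tibble(from = character(), to = character(), repairs = list(),
                   char_start = integer(), char_end = integer())
  } else {
    dplyr::arrange(dplyr::bind_rows(rev(recs)), .data$char_start)
  }
  if (!identical(normalized, text) && nrow(subs) > 0) {
    subs$repairs <- purrr::map(subs$repairs, ~ unique(c(.x, "whitespace")))
  }
  structure(list(original = x$raw_text, text = normalized,
                 substitutions = subs),
            class = "medsim_simplified")
}

# Replays recorded substitutions against the original string; used by the
# test suite to assert provenance completeness.
replay_substitutions <- function(original, subs) {
  text <- original
  if (nrow(subs) > 0) {
    for (r in rev(order(subs$char_start))) {
      text <- paste0(substr(text, 1, subs$char_start[r] - 1L), subs$to[r],
                     substr(text, subs$char_end[r] + 1L, nchar(text)))
    }
  }
  trimws(gsub("[ \t]+", " ", text))
}

#' @export
print.medsim_simplified <- function(x, ...) {
  cat("<medsim_simplified> ", nrow(x$substitutions), " substitution(s)\n",
      "original:   ", x$original, "\n",
      "simplified: ", x$text, "\n", sep = "")
  invisible(x)
}

#' Simplify every definition in a corpus
#'
#' Runs tokenize -> identify targets -> substitute for each corpus row with
#' per-definition error isolation: a definition that fails (for instance an
#' empty text) is recorded in the failure log with its reason and the run
#' continues, mirroring the partial-loss behaviour of batch simplification
#' pipelines. The whole pass is deterministic.
#'
#' @param corpus A data frame with `id` and `text` columns.
#' @param lex A `medsim_lexicon`.
#' @param threshold,min_sim,max_span,common_words Passed to
#'   [identify_targets()].
#' @param quiet Suppress the summary message.
#' @return A tibble of class `medsim_simplified_corpus`: columns `id`,
#'   `original`, `simplified`, `n_substitutions`, `substitutions`
#'   (list-column of per-definition records). The failure log is attached as
#'   attribute `"failures"` and available via [failures()].
#' @export
simplify_corpus <- function(corpus, lex, threshold = 0.65, min_sim = 0.4,
                            max_span = 3L, common_words = common_word_list(),
                            quiet = FALSE) {
  check_corpus(corpus)
  if (nrow(corpus) < 1) {
    abort("Corpus must contain at least one definition.",
          class = "medsimplify_bad_input")
  }
  lex <- as_lexicon(lex)
  index <- build_ngram_index(lex)
  results <- vector("list", nrow(corpus))
  fails <- list()
  for (i in seq_len(nrow(corpus))) {
    id_i <- corpus$id[i]
    res <- tryCatch({
      tt <- tokenize(corpus$text[i])
      spans <- identify_targets(tt, lex, index = index, threshold = threshold,
                                min_sim = min_sim, max_span = max_span,
                                common_words = common_words)
      out <- substitute_spans(tt, spans)
      tibble::tibble(id = id_i, original = corpus$text[i],
                     simplified = out$text,
                     n_substitutions = nrow(out$substitutions),
                     substitutions = list(out$substitutions))
    }, error = function(e) {
      fails[[length(fails) + 1L]] <<- tibble::tibble(
        id = id_i, reason = conditionMessage(e))
      NULL
    })
    results[[i]] <- res
  }
  out <- dplyr::bind_rows(results)
  failures <- if (length(fails) == 0) {
    tibble::tibble(id = character(), reason = character())
  } else {
    dplyr::bind_rows(fails)
  }
  if (!quiet) {
    inform(paste0("Simplified ", nrow(out), " of ", nrow(corpus),
                  " definitions (", nrow(failures), " failed, ",
                  sum(out$n_substitutions > 0), " with substitutions)."))
  }
  attr(out, "failures") <- failures
  class(out) <- c("medsim_simplified_corpus", class(tibble::tibble()))
  out
}

#' Failure log of a corpus simplification run
#'
#' @param x A `medsim_simplified_corpus`.
#' @return A tibble with columns `id`, `reason`.
#' @export
failures <- function(x) {
  stopifnot(inherits(x, "medsim_simplified_corpus"))
  attr(x, "failures")
}

#' Extract the simplified corpus as plain id/text rows
#'
#' @param x A `medsim_simplified_corpus`.
#' @return A tibble with columns `id`, `text` (the simplified texts),
#'   directly usable by [readability()] and [write_corpus()].
#' @export
simplified_corpus <- function(x) {
  stopifnot(inherits(x, "medsim_simplified_corpus"))
  tibble::tibble(id = x$id, text = x$simplified)
}

#' Write simplification results as JSONL
#'
#' One record per definition:
#' `{"id", "text", "substitutions": [{"from", "to", "repairs"}]}`.
#'
#' @param x A `medsim_simplified_corpus`.
#' @param path Output path.
#' @export
write_simplified <- function(x, path) {
  stopifnot(inherits(x, "medsim_simplified_corpus"))
  lines <- purrr::map_chr(seq_len(nrow(x)), function(i) {
    subs <- x$substitutions[[i]]
    jsonlite::toJSON(list(
      id = x$id[i], text = x$simplified[i],
      substitutions = purrr::map(seq_len(nrow(subs)), function(r) {
        list(from = subs$from[r], to = subs$to[r],
             repairs = as.list(subs$repairs[[r]]))
      })), auto_unbox = TRUE)
  })
  readr::write_lines(lines, path)
  invisible(path)
}
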