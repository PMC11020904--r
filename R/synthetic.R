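# Syllable inventory for pseudo-biomedical terms. Vowel "e" and "y" are
# deliberately excluded so count_syllables() returns exactly the number of
# concatenated CV syllables (no silent-e or consonant-le adjustments).
.cv_consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
.cv_vowels <- c("a", "i", "o", "u")

cv_word <- function(n_syllables) {
  paste0(paste0(sample(.cv_consonants, n_syllables, replace = TRUE),
                sample(.cv_vowels, n_syllables, replace = TRUE)),
        collapse = "")
}

#' Generate a synthetic definition corpus with a matched hypernym lexicon
#'
#' Seeded generator of definition-like texts emulating the shape of
#' terminology glossary entries (about 3 sentences and 30 words per
#' definition under the defaults): common monosyllabic filler words
#' (the fixed [common_word_list()]) interspersed with pseudo-biomedical
#' complex terms built by consonant-vowel syllable concatenation (3-6
#' syllables). Every complex term gets a lexicon entry whose hypernym is a
#' CV word with `hypernym_syllable_gap` fewer syllables (floored at 1), so
#' substitution provably reduces syllable counts. Some terms additionally
#' carry a second, longer candidate to exercise minimal-syllable selection.
#'
#' `failure_injection_rate` blanks out exactly `ceiling(rate * n)` records
#' (empty text), emulating definitions lost to processing error so pair
#' alignment and failure logging can be tested.
#'
#' Three independent RNG streams (vocabulary, text, failure injection) are
#' derived from the master seed, so changing one artifact never perturbs the
#' others. The same seed always yields byte-identical output.
#'
#' @param n_definitions Number of definitions.
#' @param seed Master seed (integer).
#' @param mean_sentences Mean sentences per definition (default 3).
#' @param mean_words_per_sentence Mean words per sentence (default 10).
#' @param complex_term_density Probability that a word slot holds a complex
#'   term rather than filler (default 0.2).
#' @param hypernym_syllable_gap How many syllables shorter the hypernym is
#'   than its term (>= 1, default 2).
#' @param failure_injection_rate Fraction of records to blank (default 0).
#' @param n_terms Size of the complex-term vocabulary (default 50).
#' @return A list with `corpus` (tibble `id`, `text`), `lexicon`
#'   (`medsim_lexicon`), and `terms` (tibble `term`, `syllables`,
#'   `hypernym`, `hypernym_syllables`).
#' @export
#' @examples
#' g <- gen_corpus(5, seed = 1)
#' g$corpus$text[1]
gen_corpus <- function(n_definitions, seed, mean_sentences = 3,
                       mean_words_per_sentence = 10,
                       complex_term_density = 0.2,
                       hypernym_syllable_gap = 2L,
                       failure_injection_rate = 0,
                       n_terms = 50L) {
  stopifnot(n_definitions >= 1, mean_sentences >= 1,
            mean_words_per_sentence >= 1,
            complex_term_density >= 0, complex_term_density <= 1,
            hypernym_syllable_gap >= 1,
            failure_injection_rate >= 0, failure_injection_rate <= 1)
  streams <- withr::with_seed(as.integer(seed),
                              sample.int(.Machine$integer.max - 1L, 3L))

  vocab <- withr::with_seed(streams[1], {
    terms <- character(0)
    syl <- integer(0)
    while (length(terms) < n_terms) {
      s <- sample(3:6, 1)
      w <- cv_word(s)
      if (!(w %in% terms) && !(w %in% .common_words)) {
        terms <- c(terms, w)
        syl <- c(syl, s)
      }
    }
    # Hypernyms are capped at 3 syllables so they always score below the
    # default 0.65 complexity threshold: substitution can never re-flag its
    # own output, and simplification is idempotent by construction.
    hyp_syl <- pmax(1L, pmin(3L, syl - as.integer(hypernym_syllable_gap)))
    hyper <- vapply(hyp_syl, function(h) {
      repeat {
        w <- cv_word(h)
        if (!(w %in% terms)) return(w)
      }
    }, character(1))
    extra <- purrr::map2(syl, hyp_syl, function(s, h) {
      if (stats::runif(1) < 0.3 && s - 1L > h) cv_word(min(s - 1L, h + 1L)) else NA_character_
    })
    tibble::tibble(term = terms, syllables = syl, hypernym = hyper,
                   hypernym_syllables = hyp_syl,
                   extra_hypernym = unlist(extra))
  })

  lex_df <- dplyr::bind_rows(
    tibble::tibble(term = vocab$term, hypernym = vocab$hypernym,
                   source = "semantic_type", semantic_type = "synthetic process"),
    dplyr::filter(
      tibble::tibble(term = vocab$term, hypernym = vocab$extra_hypernym,
                     source = "wordnet", semantic_type = NA_character_),
      !is.na(.data$hypernym)))
  lexicon <- as_lexicon(lex_df)

  corpus <- withr::with_seed(streams[2], {
    texts <- vapply(seq_len(n_definitions), function(i) {
      n_sent <- 1L + stats::rpois(1, max(0, mean_sentences - 1))
      sents <- vapply(seq_len(n_sent), function(s) {
        n_w <- 1L + stats::rpois(1, max(0, mean_words_per_sentence - 1))
        words <- vapply(seq_len(n_w), function(k) {
          if (stats::runif(1) < complex_term_density) {
            sample(vocab$term, 1)
          } else {
            sample(.common_words, 1)
          }
        }, character(1))
        words[1] <- paste0(toupper(substr(words[1], 1, 1)),
                           substr(words[1], 2, nchar(words[1])))
        paste0(paste(words, collapse = " "), ".")
      }, character(1))
      paste(sents, collapse = " ")
    }, character(1))
    tibble::tibble(id = sprintf("def%05d", seq_len(n_definitions)), text = texts)
  })

  if (failure_injection_rate > 0) {
    k <- ceiling(failure_injection_rate * n_definitions)
    corpus <- withr::with_seed(streams[3], {
      idx <- sample.int(n_definitions, k)
      corpus$text[idx] <- ""
      corpus
    })
  }

  list(corpus = corpus, lexicon = lexicon,
       terms = vocab[, c("term", "syllables", "hypernym", "hypernym_syllables")])
}

#' Generate random projective dependency trees with known MDD
#'
#' Writes-ready CoNLL-U token tables for `n_trees` single-sentence documents
#' plus a sidecar of true mean dependency distances computed directly from
#' the generated arc structure (independently of the CoNLL-U reader, so the
#' pair serves as an oracle for [mdd()]). Trees are projective by
#' construction: a head is drawn inside each contiguous segment and the
#' left/right remainders attach recursively. Each sentence ends with a
#' punctuation token attached to the root and tagged `PUNCT`, which both the
#' sidecar and [mdd()] exclude.
#'
#' @param n_trees Number of trees/documents.
#' @param seed Integer seed.
#' @param mean_length Mean words per sentence (default 10; minimum 2).
#' @param tree `"random"` projective trees or `"chain"` (each word attaches
#'   to its predecessor, so true MDD is exactly 1).
#' @return A list with `tokens` (tibble as from [read_conllu()]) and
#'   `sidecar` (tibble `doc_id`, `mdd`, `n_arcs`).
#' @export
gen_conllu <- function(n_trees, seed, mean_length = 10,
                       tree = c("random", "chain")) {
  tree <- match.arg(tree)
  stopifnot(n_trees >= 1, mean_length >= 2)
  withr::with_seed(as.integer(seed), {
    docs <- vector("list", n_trees)
    side <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      n <- max(2L, 1L + stats::rpois(1, mean_length - 1))
      heads <- integer(n)
      if (tree == "chain") {
        heads <- c(0L, seq_len(n - 1L))
      } else {
        rec <- function(lo, hi, parent) {
          if (lo > hi) return()
          r <- if (lo == hi) lo else sample(lo:hi, 1)
          heads[r] <<- parent
          rec(lo, r - 1L, r)
          rec(r + 1L, hi, r)
        }
        rec(1L, n, 0L)
      }
      root <- which(heads == 0L)
      doc_id <- sprintf("tree%04d", t)
      forms <- sample(.common_words, n, replace = TRUE)
      docs[[t]] <- tibble::tibble(
        doc_id = doc_id, sent_id = paste0(doc_id, "-1"),
        token_id = c(seq_len(n), n + 1L),
        form = c(forms, "."),
        upos = c(rep("NOUN", n), "PUNCT"),
        head = c(heads, root),
        deprel = c(ifelse(heads == 0L, "root", "dep"), "punct"))
      dist <- abs(seq_len(n) - heads)[heads != 0L]
      side[[t]] <- tibble::tibble(doc_id = doc_id, mdd = mean(dist),
                                  n_arcs = length(dist))
    }
    list(tokens = dplyr::bind_rows(docs), sidecar = dplyr::bind_rows(side))
  })
}

#' Sample definitions without replacement
#'
#' Uniform seeded subsampling of a corpus, honouring an optional exclusion
#' list (e.g. ids already used for training).
#'
#' @param corpus A corpus tibble (`id`, `text`).
#' @param n Sample size.
#' @param seed Integer seed.
#' @param exclude Character vector of ids to exclude before sampling.
#' @return A corpus tibble with `n` rows.
#' @export
sample_corpus <- function(corpus, n, seed, exclude = NULL) {
  check_corpus(corpus)
  pool <- corpus[!corpus$id %in% exclude, ]
  if (n > nrow(pool)) {
    abort(paste0("Requested ", n, " definitions but only ", nrow(pool),
                 " are available after exclusions."),
          class = "medsimplify_bad_input")
  }
  withr::with_seed(as.integer(seed), pool[sample.int(nrow(pool), n), ])
}
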