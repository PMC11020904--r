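write_lex_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("lexicon TSV loading groups, deduplicates and validates", {
  path <- write_lex_lines(c(
    "term\thypernym\tsource\tsemantic_type",
    "# a comment line",
    "lymphoma\tcancer\twordnet\t",
    "lymphoma\tneoplastic process\tsemantic_type\tNeoplastic Process",
    "histamine\tamine\twordnet\t"))
  lex <- read_lexicon(path)
  expect_s3_class(lex, "medsim_lexicon")
  expect_equal(length(unique(lex$term)), 2L)
  expect_equal(nrow(lex), 3L)

  # duplicated rows collapse to a single candidate
  dup <- write_lex_lines(c(
    "term\thypernym\tsource\tsemantic_type",
    "lymphoma\tcancer\twordnet\t",
    "lymphoma\tcancer\twordnet\t"))
  expect_equal(nrow(read_lexicon(dup)), 1L)
})

test_that("malformed lexicons fail with the offending line named", {
  self <- write_lex_lines(c(
    "term\thypernym\tsource\tsemantic_type",
    "cancer\tcancer\twordnet\t"))
  expect_error(read_lexicon(self), "line 2", class = "medsimplify_bad_lexicon")

  short <- write_lex_lines(c(
    "term\thypernym\tsource\tsemantic_type",
    "lymphoma\tcancer\twordnet\t",
    "histamine\tamine"))
  expect_error(read_lexicon(short), "line 3", class = "medsimplify_bad_lexicon")

  badsrc <- write_lex_lines(c(
    "term\thypernym\tsource\tsemantic_type",
    "lymphoma\tcancer\tumls\t"))
  expect_error(read_lexicon(badsrc), "line 2", class = "medsimplify_bad_lexicon")

  empty <- write_lex_lines(character(0))
  expect_error(read_lexicon(empty), class = "medsimplify_bad_lexicon")
  header_only <- write_lex_lines("term\thypernym\tsource\tsemantic_type")
  expect_error(read_lexicon(header_only), class = "medsimplify_bad_lexicon")
})

test_that("ngram profiles use two-marker padding and handle degeneracy", {
  single <- as_lexicon(tibble::tibble(term = "abc", hypernym = "x",
                                      source = "custom"))
  idx <- build_ngram_index(single)
  expect_setequal(idx$vocab, c("##a", "#ab", "abc", "bc#", "c##"))
  # single-term lexicon: all IDF zero, falls back to raw term frequency
  expect_equal(idx$weighting, "tf")
  m <- match_term("abc", idx, min_sim = 0.99)
  expect_equal(m$term, "abc")
  expect_equal(m$similarity, 1.0)

  # terms sharing no gram have zero cosine: neither matches the other
  disjoint <- as_lexicon(tibble::tibble(
    term = c("aaaa", "zzzz"), hypernym = c("x", "y"), source = "custom"))
  idx2 <- build_ngram_index(disjoint)
  m2 <- match_term("aaaa", idx2, k = 5, min_sim = 0)
  expect_false("zzzz" %in% m2$term)
})

test_that("fuzzy matching agrees with a brute-force cosine scan", {
  lex <- toy_lexicon()
  idx <- build_ngram_index(lex)

  exact <- match_term("histamine receptor", idx)
  expect_equal(exact$term[1], "histamine receptor")
  expect_equal(exact$similarity[1], 1.0)

  got <- match_term(c("histamin", "lymphona", "receptor histamine"),
                    idx, k = 6, min_sim = 0.1)
  want <- oracle_match(c("histamin", "lymphona", "receptor histamine"),
                       unique(lex$term), k = 6, min_sim = 0.1)
  expect_equal(canonical_ranking(as.data.frame(got)),
               canonical_ranking(want), tolerance = 1e-9)
  expect_equal(got$term[got$query == "histamin" & got$rank == 1], "histamine")

  # no shared gram with any indexed term: empty result
  expect_equal(nrow(match_term("qqqq", idx)), 0L)
})

test_that("lexicon write/read round trip reproduces identical rankings", {
  lex <- gen_corpus(1, seed = 77, n_terms = 30)$lexicon
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  lex2 <- read_lexicon(path)
  queries <- c(head(unique(lex$term), 5), "zanopira")
  m1 <- match_term(queries, build_ngram_index(lex), k = 10, min_sim = 0)
  m2 <- match_term(queries, build_ngram_index(lex2), k = 10, min_sim = 0)
  expect_equal(m1, m2)
})

test_that("hypernym selection minimizes syllables with stated tie-breaks", {
  lex <- toy_lexicon()
  expect_equal(select_hypernym("lymphoma", lex), "cancer")  # 2 < 5 syllables
  expect_equal(select_hypernym("histamine", lex), "amine")  # single candidate

  tie <- as_lexicon(tibble::tibble(
    term = "tumour", hypernym = c("growth", "mass"), source = "wordnet"))
  expect_equal(select_hypernym("tumour", tie), "mass")  # 1 = 1 syl, 4 < 6 chars

  expect_error(select_hypernym("absent", lex),
               class = "medsimplify_lookup_miss")

  # minimality over a generated lexicon: never more syllables than any candidate
  gl <- gen_corpus(1, seed = 13, n_terms = 25)$lexicon
  for (t in unique(gl$term)) {
    chosen <- select_hypernym(t, gl)
    expect_true(phrase_syllables(chosen) <=
                  min(phrase_syllables(gl$hypernym[gl$term == t])))
  }
})
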