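stats_row <- function(w, s, chars = 4 * w, syl = w, cx = 0) {
  tibble::tibble(n_words = w, n_sentences = s, n_chars = chars,
                 n_syllables = syl, n_complex_words = cx)
}

test_that("readability formulas reproduce closed-form hand values", {
  expect_equal(fks(stats_row(10, 1, syl = 10)), 112.085)
  expect_equal(fks(stats_row(10, 1, syl = 20)), 27.485)
  expect_equal(fkg(stats_row(10, 1, syl = 10)), 0.11)
  expect_equal(fkg(stats_row(10, 1, syl = 30)), 23.71)
  expect_equal(ari(stats_row(10, 1, chars = 40)), 2.41)
  expect_equal(ari(stats_row(10, 1, chars = 80)), 21.25)
  expect_equal(gfi(stats_row(10, 1)), 4.0)
  expect_equal(gfi(stats_row(10, 1, cx = 2)), 12.0)
})

test_that("formula monotonicities hold", {
  base <- stats_row(10, 1, syl = 15)
  more <- stats_row(10, 1, syl = 30)
  expect_lt(fks(more), fks(base))               # more syllables, harder
  expect_gt(fkg(more), fkg(base))               # FKS and FKG move oppositely
  expect_lt(ari(stats_row(10, 1, chars = 30)),
            ari(stats_row(10, 1, chars = 50)))  # shorter words, lower ARI
  # swapping one complex word for a simple one lowers GFI by exactly 40/W
  w <- 25
  expect_equal(gfi(stats_row(w, 2, cx = 5)) - gfi(stats_row(w, 2, cx = 4)),
               40 / w)
})

test_that("degenerate statistics yield NA rather than scores", {
  empty <- stats_row(0, 0)
  expect_true(is.na(fks(empty)))
  expect_true(is.na(fkg(empty)))
  expect_true(is.na(ari(empty)))
  expect_true(is.na(gfi(empty)))
})

test_that("MTLD reproduces hand-stepped factor counts and invariances", {
  expect_equal(mtld(rep(c("a", "b", "a"), 4)), 3.0)
  expect_equal(mtld(rep("a", 4)), 2.0)
  expect_true(is.na(mtld(letters[1:12])))  # all distinct: zero factors
  expect_error(mtld(character(0)), class = "medsimplify_empty_input")

  # case invariance
  toks <- c("The", "the", "THE", "dog", "DOG", "the", "dog", "cat", "the",
            "dog", "cat", "rat")
  expect_equal(mtld(toks), mtld(tolower(toks)))

  # palindromic sequences score identically reversed
  pal <- c("a", "b", "c", "b", "a", "a", "b", "c", "b", "a")
  expect_equal(mtld(pal), mtld(rev(pal)))
})

test_that("MDD pools arcs, ignores labels and excludes punctuation", {
  tok <- function(id, upos, head, deprel = "dep") {
    tibble::tibble(doc_id = "d", sent_id = "d-1", token_id = id,
                   form = "w", upos = upos, head = head, deprel = deprel)
  }
  one_arc <- dplyr::bind_rows(tok(1, "NOUN", 2), tok(2, "VERB", 0, "root"))
  expect_equal(mdd(one_arc)$mdd, 1.0)

  # arc distances {1, 2, 3} pooled
  g <- tibble::tibble(doc_id = "d", sent_id = "d-1", token_id = 1:4,
                      form = "w", upos = "NOUN",
                      head = c(2L, 0L, 1L, 1L), deprel = "dep")
  expect_equal(mdd(g)$mdd, 2.0)

  # relation labels are irrelevant
  g2 <- dplyr::mutate(g, deprel = c("nsubj", "root", "obj", "obl"))
  expect_equal(mdd(g2)$mdd, mdd(g)$mdd)

  # punctuation-dependent arcs never change the value
  g3 <- dplyr::bind_rows(g, tibble::tibble(
    doc_id = "d", sent_id = "d-1", token_id = 5L, form = ".",
    upos = "PUNCT", head = 2L, deprel = "punct"))
  expect_equal(mdd(g3)$mdd, mdd(g)$mdd)

  # adjacent-only tree has MDD 1 regardless of length
  n <- 12
  chain <- tibble::tibble(doc_id = "d", sent_id = "d-1", token_id = 1:n,
                          form = "w", upos = "NOUN",
                          head = c(0L, 1:(n - 1)), deprel = "dep")
  expect_equal(mdd(chain)$mdd, 1.0)

  # a document with no qualifying arc is undefined
  root_only <- tok(1, "NOUN", 0, "root")
  expect_true(is.na(mdd(root_only)$mdd))
})

test_that("CoNLL-U files round trip and malformed lines are named", {
  g <- gen_conllu(5, seed = 21)
  path <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(g$tokens, path)
  back <- read_conllu(path)
  expect_equal(as.data.frame(back), as.data.frame(g$tokens))

  # multiword ranges and empty nodes are skipped, not parsed
  lines <- c("# sent_id = x-1",
             "1-2\tdel\t_\tX\t_\t_\t_\t_\t_\t_",
             "1\tdel\t_\tNOUN\t_\t_\t2\tdep\t_\t_",
             "2\tla\t_\tNOUN\t_\t_\t0\troot\t_\t_", "")
  p2 <- withr::local_tempfile(fileext = ".conllu")
  writeLines(lines, p2)
  expect_equal(nrow(read_conllu(p2)), 2L)

  p3 <- withr::local_tempfile(fileext = ".conllu")
  writeLines(c("1\tword\tonly\tfour", ""), p3)
  expect_error(read_conllu(p3), "line 1", class = "medsimplify_io_error")
})

test_that("readability table is per definition and robust to bad rows", {
  corpus <- tibble::tibble(
    id = c("d1", "d2", "d3"),
    text = c("Lymphoma is a type of cancer.", "", "The cat sat."))
  rb <- readability(corpus)
  expect_equal(nrow(rb), 3L)
  expect_true(is.na(rb$fks[2]))  # unscorable row keeps its id
  st1 <- text_stats(tokenize(corpus$text[1]))
  expect_equal(rb$fks[1], fks(st1))
  expect_equal(rb$gfi[3], gfi(text_stats(tokenize("The cat sat."))))
})

test_that("display rounding is half-up", {
  expect_equal(round_grade(c(13.5, 13.49, 0.5, -0.4)), c(14L, 13L, 1L, 0L))
})
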