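test_that("exact Wilcoxon matches hand-enumerated sign patterns", {
  w5 <- wilcoxon_signed_rank(rep(0, 5), 1:5)
  expect_equal(w5$statistic, 15)
  expect_equal(w5$p_value, 0.0625)   # 2/32
  expect_equal(w5$method, "exact")

  w6 <- wilcoxon_signed_rank(rep(0, 6), 1:6)
  expect_equal(w6$statistic, 21)
  expect_equal(w6$p_value, 0.03125)  # 2/64

  # antisymmetry: swapping pre and post maps W to n(n+1)/2 - W, same p
  pre <- c(3, 1, 4, 1, 5, 9, 2, 6)
  post <- c(2, 7, 1, 8, 2, 8, 1, 8)
  a <- wilcoxon_signed_rank(pre, post)
  b <- wilcoxon_signed_rank(post, pre)
  n <- a$n_used
  expect_equal(b$statistic, n * (n + 1) / 2 - a$statistic)
  expect_equal(b$p_value, a$p_value)

  expect_error(wilcoxon_signed_rank(1:4, 1:4),
               class = "medsimplify_degenerate")
})

test_that("exact Wilcoxon agrees with independent references", {
  # untied case: stats::wilcox.test computes the same exact two-sided p
  withr::with_seed(42, {
    for (rep_i in 1:20) {
      n <- sample(4:12, 1)
      pre <- rnorm(n)
      post <- pre + rnorm(n)
      ours <- wilcoxon_signed_rank(pre, post)
      ref <- stats::wilcox.test(post, pre, paired = TRUE, exact = TRUE,
                                correct = FALSE)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  })
  # tied case: brute-force enumeration is the oracle
  withr::with_seed(43, {
    for (rep_i in 1:20) {
      n <- sample(3:11, 1)
      pre <- sample(0:4, n, replace = TRUE)
      post <- sample(0:4, n, replace = TRUE)
      if (all(post == pre)) post[1] <- post[1] + 1
      ours <- wilcoxon_signed_rank(pre, post)
      want <- oracle_wsr(pre, post)
      expect_equal(ours$statistic, want$W)
      expect_equal(ours$p_value, want$p, tolerance = 1e-12)
    }
  })
})

test_that("normal approximation tracks the exact tail at moderate n", {
  withr::with_seed(7, {
    for (rep_i in 1:10) {
      pre <- rnorm(25)
      post <- pre + rnorm(25, mean = 0.3)
      exact <- wilcoxon_signed_rank(pre, post, exact_limit = 30)
      approx <- wilcoxon_signed_rank(pre, post, exact_limit = 10)
      expect_equal(approx$method, "normal_approx")
      expect_lt(abs(approx$p_value - exact$p_value), 0.01)
    }
  })
})

test_that("pair alignment keeps the defined intersection and logs drops", {
  pre <- tibble::tibble(id = c("a", "b", "c"), value = 1:3)
  post <- tibble::tibble(id = c("a", "c"), value = c(4, 6))
  al <- align_pairs(pre, post, quiet = TRUE)
  expect_equal(al$id, c("a", "c"))
  expect_equal(nrow(attr(al, "dropped")), 1L)
  expect_equal(attr(al, "dropped")$id, "b")

  # identical id sets: nothing dropped
  al2 <- align_pairs(pre, dplyr::mutate(pre, value = value + 1), quiet = TRUE)
  expect_equal(nrow(attr(al2, "dropped")), 0L)

  # undefined values drop their id too
  post_na <- tibble::tibble(id = c("a", "b", "c"), value = c(4, NA, 6))
  al3 <- align_pairs(pre, post_na, quiet = TRUE)
  expect_equal(al3$id, c("a", "c"))

  expect_error(
    align_pairs(pre, tibble::tibble(id = "z", value = 1), quiet = TRUE),
    class = "medsimplify_empty_intersection")
})

test_that("paired delta report summarises per metric with stars", {
  paired <- tibble::tibble(
    metric = "fks", id = as.character(1:8),
    pre = c(1, 2, 3, 4, 5, 6, 7, 8), post = c(3, 4, 5, 6, 7, 8, 9, 10))
  rep1 <- paired_deltas(paired, boot_ci = FALSE)
  expect_equal(rep1$mean_delta, 2)
  expect_equal(rep1$iqr_delta, 0)
  expect_equal(rep1$statistic, 36)           # all positive ranks
  expect_equal(rep1$p_value, 2 / 256)
  expect_equal(rep1$stars, "**")

  # undefined entries are excluded and counted
  paired_na <- dplyr::bind_rows(paired, tibble::tibble(
    metric = "mtld", id = c("1", "2", "3"),
    pre = c(10, NA, 12), post = c(11, 5, NA)))
  rep2 <- paired_deltas(paired_na, boot_ci = FALSE)
  expect_equal(rep2$n_excluded[rep2$metric == "mtld"], 2L)
  expect_equal(rep2$n_used[rep2$metric == "mtld"], 1L)

  # all-zero differences flag a degenerate row instead of erroring
  same <- tibble::tibble(metric = "fkg", id = c("1", "2"),
                         pre = c(1, 2), post = c(1, 2))
  rep3 <- paired_deltas(same, boot_ci = FALSE)
  expect_true(rep3$degenerate)
  expect_equal(rep3$stars, "")

  # bootstrap CI brackets the mean shift and is seed-reproducible
  shifted <- tibble::tibble(metric = "m", id = as.character(1:40),
                            pre = rep(0, 40), post = seq(0.5, 2, length.out = 40))
  r1 <- paired_deltas(shifted, boot_ci = TRUE, boot_n = 500, seed = 5)
  r2 <- paired_deltas(shifted, boot_ci = TRUE, boot_n = 500, seed = 5)
  expect_equal(r1$ci_lower, r2$ci_lower)
  expect_true(r1$ci_lower < mean(shifted$post) & r1$ci_upper > 0)
})

test_that("significance stars follow the three printed tiers", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.004, NA)),
               c("", "*", "**", "***", ""))
})

test_that("Cohen's kappa matches closed forms and an external reference", {
  expect_equal(cohens_kappa(c(1, 2, 1, 2, 3), c(1, 2, 1, 2, 3))$kappa, 1)
  expect_equal(cohens_kappa(c(1, 1, 2, 2), c(1, 2, 1, 2))$kappa, 0)

  # consistent relabeling leaves kappa unchanged
  r1 <- c(1, 2, 3, 1, 2, 3, 1, 1)
  r2 <- c(1, 2, 2, 1, 3, 3, 2, 1)
  relab <- c("x", "y", "z")
  expect_equal(cohens_kappa(relab[r1], relab[r2])$kappa,
               cohens_kappa(r1, r2)$kappa)

  # contingency-table input equals raw-vector input
  tab <- table(factor(r1, levels = 1:3), factor(r2, levels = 1:3))
  expect_equal(cohens_kappa(tab)$kappa, cohens_kappa(r1, r2)$kappa)

  # both raters constant and identical: undefined
  expect_true(is.na(cohens_kappa(rep(1, 4), rep(1, 4))$kappa))

  # cross-check against e1071's implementation
  skip_if_not_installed("e1071")
  expect_equal(cohens_kappa(r1, r2)$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)

  # band labels at the published thresholds
  expect_equal(kappa_band(c(-0.1, 0.1, 0.3, 0.5, 0.7, 0.9)),
               c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect"))
})

test_that("Likert rating comparison is pairwise, paired and exact", {
  ids <- sprintf("t%02d", 1:10)
  base <- tibble::tibble(id = ids, system = "B", metric = "clarity",
                         score = rep(c(2, 3), 5))
  up <- dplyr::mutate(base, system = "A", score = score + 1)
  cmp <- rating_compare(dplyr::bind_rows(base, up))
  expect_equal(nrow(cmp), 1L)
  expect_gt(cmp$mean_a, cmp$mean_b)
  expect_equal(cmp$p_value, 2 / 1024)  # n=10, all signs one way

  # identical systems: degenerate, not an error
  twin <- dplyr::mutate(base, system = "A")
  cmp2 <- rating_compare(dplyr::bind_rows(base, twin))
  expect_true(cmp2$degenerate)

  # three systems give three pairwise rows per metric
  third <- dplyr::mutate(base, system = "C", score = pmin(5, score + 2))
  cmp3 <- rating_compare(dplyr::bind_rows(base, up, third))
  expect_equal(nrow(cmp3), 3L)

  expect_error(rating_compare(dplyr::mutate(base, score = 7)),
               class = "medsimplify_bad_input")
})
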