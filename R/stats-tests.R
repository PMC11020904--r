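#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences `post - pre`. Zero
#' differences are discarded (Wilcoxon's treatment, not Pratt's); absolute
#' differences are ranked with average ranks for ties; the statistic `W` is
#' the sum of positive ranks. For `n <= exact_limit` non-zero pairs the
#' p-value is exact, from the full distribution of `W` over all `2^n`
#' equiprobable sign assignments (computed by convolution, valid under
#' ties); otherwise a normal approximation with continuity and tie
#' correction is used. The two-sided p is `min(1, 2 min(P(W<=w), P(W>=w)))`.
#'
#' @param pre,post Equal-length numeric vectors of paired observations.
#'   Pairs with missing values are dropped.
#' @param exact_limit Largest `n` for which the exact distribution is
#'   enumerated (default 25).
#' @return An object of class `medsim_wsr`: list with `statistic`,
#'   `p_value`, `n_used`, `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 5, 7, 9))  # W = 15
wilcoxon_signed_rank <- function(pre, post, exact_limit = 25L) {
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have equal length.",
          class = "medsimplify_bad_input")
  }
  ok <- stats::complete.cases(pre, post)
  d <- (post - pre)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("All paired differences are zero (or missing): test is degenerate.",
          class = "medsimplify_degenerate")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- wsr_exact_p(r, W)
    method <- "exact"
  } else {
    p <- wsr_normal_p(r, W, d)
    method <- "normal_approx"
  }
  structure(list(statistic = W, p_value = p, n_used = n, method = method),
            class = "medsim_wsr")
}

# Exact two-sided p over all 2^n sign assignments. Doubled ranks are
# integers even with average-rank ties, so the null distribution of 2W is a
# convolution over {0, 2r_i}.
wsr_exact_p <- function(r, W) {
  w2 <- as.integer(round(2 * r))
  total <- sum(w2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (w in w2) {
    idx <- (w + 1):(total + 1)
    f[idx] <- f[idx] + f[idx - w]
  }
  n <- length(r)
  target <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(target + 1)]) / 2^n
  p_ge <- sum(f[(target + 1):(total + 1)]) / 2^n
  min(1, 2 * min(p_le, p_ge))
}

wsr_normal_p <- function(r, W, d) {
  n <- length(d)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(1)
  cc <- if (W > mu) 0.5 else if (W < mu) -0.5 else 0
  z <- (W - mu - cc) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.medsim_wsr <- function(x, ...) {
  cat("Wilcoxon signed-rank test (two-sided, ", x$method, ")\n",
      "W = ", format(x$statistic), ", p = ", format(x$p_value),
      ", n = ", x$n_used, "\n", sep = "")
  invisible(x)
}

#' Significance stars for benchmark tables
#'
#' Three tiers: `*` p < 0.05, `**` p < 0.01, `***` p < 0.005.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels (empty string when n.s. or NA).
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p)  ~ "",
    p < 0.005 ~ "***",
    p < 0.01  ~ "**",
    p < 0.05  ~ "*",
    TRUE      ~ ""
  )
}

#' Cohen's kappa for two raters
#'
#' Unweighted chance-corrected agreement
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal products. Accepts two equal-length categorical vectors or a
#' square contingency table. When both raters are constant and identical
#' (`p_e = 1`) kappa is undefined and `NA` is returned.
#'
#' @param r1 First rater's labels, or a contingency table/matrix.
#' @param r2 Second rater's labels (ignored when `r1` is a table).
#' @return An object of class `medsim_kappa`: list with `kappa`, `p_o`,
#'   `p_e`, `n`, and the conventional agreement `band` (slight/fair/moderate/
#'   substantial/almost perfect).
#' @export
#' @examples
#' cohens_kappa(c(1, 1, 2, 2), c(1, 2, 1, 2))$kappa  # 0
cohens_kappa <- function(r1, r2 = NULL) {
  if (is.table(r1) || is.matrix(r1)) {
    tab <- as.matrix(r1)
    if (nrow(tab) != ncol(tab)) {
      abort("Contingency table must be square (same categories per rater).",
            class = "medsimplify_bad_input")
    }
  } else {
    if (is.null(r2) || length(r1) != length(r2) || length(r1) < 1) {
      abort("Need two equal-length rating vectors of length >= 1.",
            class = "medsimplify_bad_input")
    }
    lev <- sort(unique(c(as.character(r1), as.character(r2))))
    tab <- table(factor(as.character(r1), levels = lev),
                 factor(as.character(r2), levels = lev))
    tab <- as.matrix(tab)
  }
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e >= 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = n,
                 band = kappa_band(kappa)),
            class = "medsim_kappa")
}

#' Agreement band for a kappa value
#'
#' Conventional interpretation thresholds: below 0 poor, 0-0.20 slight,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, above 0.80
#' almost perfect.
#'
#' @param kappa Numeric vector.
#' @return Character vector of band labels.
#' @export
kappa_band <- function(kappa) {
  dplyr::case_when(
    is.na(kappa)  ~ NA_character_,
    kappa < 0     ~ "poor",
    kappa <= 0.20 ~ "slight",
    kappa <= 0.40 ~ "fair",
    kappa <= 0.60 ~ "moderate",
    kappa <= 0.80 ~ "substantial",
    TRUE          ~ "almost perfect"
  )
}

#' @export
print.medsim_kappa <- function(x, ...) {
  cat("Cohen's kappa = ", format(x$kappa), " (", x$band %||% "undefined",
      "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Pairwise comparison of Likert ratings across systems
#'
#' For every metric and unordered pair of systems, runs a two-sided paired
#' Wilcoxon signed-rank test on ratings aligned by text id, and reports mean
#' ratings so systems can be ranked. If a `rater` column is present, ratings
#' are first averaged over raters within id x system x metric. Pairs whose
#' differences are all zero are flagged `degenerate` rather than erroring.
#'
#' @param ratings A data frame with columns `id`, `system`, `metric`,
#'   `score` (Likert 1-5) and optionally `rater`.
#' @return A tibble with one row per metric and system pair: `metric`,
#'   `system_a`, `system_b`, `n`, `mean_a`, `mean_b`, `statistic`,
#'   `p_value`, `stars`, `degenerate`.
#' @export
rating_compare <- function(ratings) {
  needed <- c("id", "system", "metric", "score")
  if (!is.data.frame(ratings) || !all(needed %in% names(ratings))) {
    abort("`ratings` needs columns id, system, metric, score.",
          class = "medsimplify_bad_input")
  }
  if (!all(ratings$score %in% 1:5 | (ratings$score >= 1 & ratings$score <= 5))) {
    abort("Likert scores must lie in [1, 5].", class = "medsimplify_bad_input")
  }
  rt <- dplyr::summarise(
    dplyr::group_by(ratings, .data$id, .data$system, .data$metric),
    score = mean(.data$score), .groups = "drop")
  systems <- sort(unique(rt$system))
  if (length(systems) < 2) {
    abort("Need at least two systems to compare.", class = "medsimplify_bad_input")
  }
  pairs <- utils::combn(systems, 2, simplify = FALSE)
  rows <- list()
  for (m in sort(unique(rt$metric))) {
    rm_ <- rt[rt$metric == m, ]
    for (pr in pairs) {
      a <- rm_[rm_$system == pr[1], c("id", "score")]
      b <- rm_[rm_$system == pr[2], c("id", "score")]
      j <- dplyr::inner_join(a, b, by = "id", suffix = c("_a", "_b"))
      res <- tryCatch(
        wilcoxon_signed_rank(j$score_a, j$score_b),
        medsimplify_degenerate = function(e) NULL)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metric = m, system_a = pr[1], system_b = pr[2], n = nrow(j),
        mean_a = mean(j$score_a), mean_b = mean(j$score_b),
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        stars = significance_stars(if (is.null(res)) NA_real_ else res$p_value),
        degenerate = is.null(res))
    }
  }
  dplyr::bind_rows(rows)
}
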