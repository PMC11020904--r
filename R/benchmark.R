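#' Align paired per-definition values across corpora
#'
#' Joins two (or more) per-definition value tables by id and keeps only ids
#' that are present with a defined (non-missing) value in every table —
#' the "union of post-processed datasets" alignment used when some
#' definitions are lost to processing errors. Dropped ids are attached as
#' attribute `"dropped"` (with the table responsible) and counted in a
#' message.
#'
#' @param pre A data frame with an id column and a value column — the
#'   pre-processing values.
#' @param ... One or more post-processing data frames of the same shape.
#'   Unnamed arguments are called `post` (then `post2`, ...).
#' @param by Id column name (default `"id"`).
#' @param value Value column name (default `"value"`).
#' @param quiet Suppress the drop-count message.
#' @return A tibble with the id column, `pre`, and one column per
#'   post-corpus; attribute `"dropped"` holds a tibble of excluded ids.
#' @export
align_pairs <- function(pre, ..., by = "id", value = "value", quiet = FALSE) {
  posts <- list(...)
  if (length(posts) == 0) {
    abort("Supply at least one post-processing table.",
          class = "medsimplify_bad_input")
  }
  nm <- names(posts)
  if (is.null(nm)) nm <- rep("", length(posts))
  auto <- c("post", paste0("post", seq_len(max(0, length(posts) - 1)) + 1))
  nm[!nzchar(nm)] <- auto[seq_len(sum(!nzchar(nm)))]
  tabs <- c(list(pre = pre), stats::setNames(posts, nm))
  cleaned <- purrr::imap(tabs, function(tb, name) {
    if (!is.data.frame(tb) || !all(c(by, value) %in% names(tb))) {
      abort(paste0("Table '", name, "' needs columns '", by, "' and '",
                   value, "'."), class = "medsimplify_bad_input")
    }
    tibble::tibble(!!by := as.character(tb[[by]]), !!name := tb[[value]])
  })
  merged <- purrr::reduce(cleaned, dplyr::full_join, by = by)
  keep <- stats::complete.cases(merged)
  dropped <- merged[!keep, ]
  dropped_tbl <- tibble::tibble(
    !!by := dropped[[by]],
    missing_in = purrr::map_chr(seq_len(nrow(dropped)), function(i) {
      cols <- names(dropped)[-1]
      paste(cols[is.na(unlist(dropped[i, -1]))], collapse = ", ")
    }))
  out <- merged[keep, ]
  if (nrow(out) == 0) {
    abort("No ids are present and defined in all corpora.",
          class = "medsimplify_empty_intersection")
  }
  if (!quiet) {
    inform(paste0("Aligned ", nrow(out), " pairs; dropped ",
                  nrow(dropped_tbl), " id(s)."))
  }
  attr(out, "dropped") <- dropped_tbl
  out
}

#' Per-metric paired delta report
#'
#' The benchmark table of a simplification run: for each metric, the mean
#' and IQR of the per-definition delta `post - pre`, the paired Wilcoxon
#' signed-rank test, significance stars (`*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.005), and optionally a nonparametric bootstrap confidence interval
#' for the mean delta. Definitions where either value is undefined (e.g.
#' MTLD with zero factors) are excluded per metric and counted in
#' `n_excluded`.
#'
#' @param paired A long data frame with columns `metric`, `id`, `pre`,
#'   `post`.
#' @param boot_ci Compute bootstrap CIs for the mean delta?
#' @param boot_n Bootstrap resamples (default 10000).
#' @param conf_level CI coverage (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A tibble of class `medsim_benchmark`, one row per metric:
#'   `metric`, `n_used`, `n_excluded`, `mean_delta`, `iqr_delta`,
#'   `ci_lower`/`ci_upper` (if requested), `statistic`, `p_value`, `method`,
#'   `stars`, `degenerate`.
#' @export
paired_deltas <- function(paired, boot_ci = TRUE, boot_n = 10000L,
                          conf_level = 0.95, seed = NULL) {
  needed <- c("metric", "id", "pre", "post")
  if (!is.data.frame(paired) || !all(needed %in% names(paired))) {
    abort("`paired` needs columns metric, id, pre, post.",
          class = "medsimplify_bad_input")
  }
  if (nrow(paired) == 0) {
    abort("`paired` is empty.", class = "medsimplify_bad_input")
  }
  metrics <- unique(paired$metric)
  rows <- purrr::map(metrics, function(m) {
    pm <- paired[paired$metric == m, ]
    ok <- stats::complete.cases(pm$pre, pm$post)
    d <- pm$post[ok] - pm$pre[ok]
    res <- if (length(d) == 0 || all(d == 0)) NULL else wilcoxon_signed_rank(pm$pre[ok], pm$post[ok])
    ci <- c(NA_real_, NA_real_)
    if (boot_ci && length(d) > 0) {
      ci <- boot_mean_ci(d, boot_n = boot_n, conf_level = conf_level, seed = seed)
    }
    tibble::tibble(
      metric = m,
      n_used = sum(ok), n_excluded = sum(!ok),
      mean_delta = if (length(d) == 0) NA_real_ else mean(d),
      iqr_delta = if (length(d) == 0) NA_real_ else stats::IQR(d),
      ci_lower = ci[1], ci_upper = ci[2],
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      method = if (is.null(res)) NA_character_ else res$method,
      stars = significance_stars(if (is.null(res)) NA_real_ else res$p_value),
      degenerate = is.null(res))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("medsim_benchmark", class(tibble::tibble()))
  out
}

boot_mean_ci <- function(d, boot_n = 10000L, conf_level = 0.95, seed = NULL) {
  run <- function() {
    means <- vapply(seq_len(boot_n), function(i) {
      mean(d[sample.int(length(d), replace = TRUE)])
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    unname(stats::quantile(means, c(alpha, 1 - alpha)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Evaluate a simplification run end to end
#'
#' Computes the per-definition readability table ([readability()]) for the
#' pre- and post-processing corpora, aligns them by id per metric, and
#' produces the paired-delta benchmark report. Mean dependency distance is
#' included only when per-definition CoNLL-U parses are supplied for both
#' sides; otherwise the MDD row is omitted with a warning (this package does
#' not bundle a dependency parser).
#'
#' @param pre,post Corpora (`id`, `text`).
#' @param conllu_pre,conllu_post Optional dependency token tables from
#'   [read_conllu()], with `doc_id` matching corpus ids.
#' @param metrics Readability metrics to report.
#' @param quiet Suppress alignment messages.
#' @inheritParams paired_deltas
#' @return A `medsim_benchmark` tibble (see [paired_deltas()]).
#' @export
evaluate_simplification <- function(pre, post, conllu_pre = NULL,
                                    conllu_post = NULL,
                                    metrics = c("fks", "fkg", "ari", "gfi", "mtld"),
                                    boot_ci = TRUE, boot_n = 10000L,
                                    seed = NULL, quiet = TRUE) {
  rb_pre <- readability(pre)
  rb_post <- readability(post)
  long <- purrr::map_dfr(metrics, function(m) {
    al <- align_pairs(
      tibble::tibble(id = rb_pre$id, value = rb_pre[[m]]),
      tibble::tibble(id = rb_post$id, value = rb_post[[m]]),
      quiet = quiet)
    tibble::tibble(metric = m, id = al$id, pre = al$pre, post = al$post)
  })
  if (!is.null(conllu_pre) && !is.null(conllu_post)) {
    md_pre <- mdd(conllu_pre)
    md_post <- mdd(conllu_post)
    al <- align_pairs(
      tibble::tibble(id = md_pre$doc_id, value = md_pre$mdd),
      tibble::tibble(id = md_post$doc_id, value = md_post$mdd),
      quiet = quiet)
    long <- dplyr::bind_rows(long, tibble::tibble(
      metric = "mdd", id = al$id, pre = al$pre, post = al$post))
  } else if (!is.null(conllu_pre) || !is.null(conllu_post)) {
    warn("CoNLL-U parses supplied for only one side; MDD omitted.")
  } else {
    warn("No CoNLL-U parses supplied; MDD omitted from the report.")
  }
  paired_deltas(long, boot_ci = boot_ci, boot_n = boot_n, seed = seed)
}

#' Write a benchmark report to disk
#'
#' @param report A `medsim_benchmark`.
#' @param path Output path (without or with extension).
#' @param format `"csv"` or `"json"`.
#' @export
write_benchmark <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "csv") {
    readr::write_csv(df, path)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
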