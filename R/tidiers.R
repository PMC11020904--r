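#' Tidy a Wilcoxon signed-rank result
#'
#' @param x A `medsim_wsr`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p.value`, `n`, `method`.
#' @method tidy medsim_wsr
#' @export
tidy.medsim_wsr <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n = x$n_used, method = x$method)
}

#' @rdname tidy.medsim_wsr
#' @method glance medsim_wsr
#' @export
glance.medsim_wsr <- function(x, ...) tidy.medsim_wsr(x)

#' Tidy a Cohen's kappa result
#'
#' @param x A `medsim_kappa`.
#' @param ... Unused.
#' @return A one-row tibble: `kappa`, `agreement`, `p.observed`,
#'   `p.expected`, `n`.
#' @method tidy medsim_kappa
#' @export
tidy.medsim_kappa <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, agreement = x$band,
                 p.observed = x$p_o, p.expected = x$p_e, n = x$n)
}

#' Substitution provenance records of a simplification run
#'
#' @param x A `medsim_simplified_corpus`.
#' @param ... Unused.
#' @return A tibble with one row per substitution: `id`, `from`, `to`,
#'   `repairs`, `char_start`, `char_end`.
#' @method tidy medsim_simplified_corpus
#' @export
tidy.medsim_simplified_corpus <- function(x, ...) {
  recs <- purrr::map2(x$id, x$substitutions, function(id, subs) {
    if (nrow(subs) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(id = rep(id, nrow(subs))), subs)
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(id = character(), from = character(),
                          to = character(), repairs = list(),
                          char_start = integer(), char_end = integer())
  }
  out
}

#' Run-level summary of a simplification run
#'
#' @param x A `medsim_simplified_corpus`.
#' @param ... Unused.
#' @return A one-row tibble: `n_definitions`, `n_failed`, `n_substituted`,
#'   `n_substitutions`.
#' @method glance medsim_simplified_corpus
#' @export
glance.medsim_simplified_corpus <- function(x, ...) {
  tibble::tibble(
    n_definitions = nrow(x) + nrow(failures(x)),
    n_failed = nrow(failures(x)),
    n_substituted = sum(x$n_substitutions > 0),
    n_substitutions = sum(x$n_substitutions))
}
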