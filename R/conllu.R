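#' Read a CoNLL-U dependency file
#'
#' Minimal reader for the standard 10-column CoNLL-U format, keeping exactly
#' what mean dependency distance needs: token position, surface form, UPOS
#' (column 4, used to exclude punctuation) and head position (column 7).
#' Multiword-token ranges (`1-2`) and empty nodes (`1.1`) are skipped.
#' `# newdoc id =` and `# sent_id =` comments are honoured so arcs can be
#' grouped per definition.
#'
#' @param path Path to a CoNLL-U file.
#' @return A tibble with columns `doc_id`, `sent_id`, `token_id`, `form`,
#'   `upos`, `head`, `deprel`.
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("CoNLL-U file not found: ", path), class = "medsimplify_io_error")
  }
  lines <- readr::read_lines(path)
  doc <- NA_character_
  sent <- NA_character_
  sent_n <- 0L
  out <- vector("list", length(lines))
  k <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) {       # blank line closes the sentence
      sent <- NA_character_
      next
    }
    if (startsWith(ln, "#")) {
      if (grepl("^# *newdoc id *=", ln)) {
        doc <- trimws(sub("^# *newdoc id *=", "", ln))
      } else if (grepl("^# *sent_id *=", ln)) {
        sent <- trimws(sub("^# *sent_id *=", "", ln))
        sent_n <- sent_n + 1L
      }
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L) {
      abort(paste0("Malformed CoNLL-U token line ", i,
                   ": expected 10 columns, got ", length(fields), "."),
            class = "medsimplify_io_error")
    }
    if (grepl("[-.]", fields[1])) next  # multiword range or empty node
    if (is.na(sent)) {                  # token line opening an unlabelled sentence
      sent_n <- sent_n + 1L
      sent <- paste0("s", sent_n)
    }
    k <- k + 1L
    out[[k]] <- list(
      doc_id   = if (is.na(doc)) "doc1" else doc,
      sent_id  = sent,
      token_id = as.integer(fields[1]),
      form     = fields[2],
      upos     = fields[4],
      head     = as.integer(fields[7]),
      deprel   = fields[8]
    )
  }
  if (k == 0L) {
    abort("CoNLL-U file contains no token lines.", class = "medsimplify_io_error")
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Write dependency parses in CoNLL-U format
#'
#' @param x A tibble shaped like the output of [read_conllu()].
#' @param path Output path.
#' @export
write_conllu <- function(x, path) {
  needed <- c("doc_id", "sent_id", "token_id", "form", "upos", "head", "deprel")
  if (!all(needed %in% names(x))) {
    abort("CoNLL-U table lacks required columns.", class = "medsimplify_bad_input")
  }
  lines <- character(0)
  last_doc <- NA_character_
  for (key in unique(paste(x$doc_id, x$sent_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sent <- x[x$doc_id == parts[1] & x$sent_id == parts[2], ]
    if (!identical(parts[1], last_doc)) {
      lines <- c(lines, paste0("# newdoc id = ", parts[1]))
      last_doc <- parts[1]
    }
    lines <- c(lines, paste0("# sent_id = ", parts[2]))
    lines <- c(lines, paste(sent$token_id, sent$form, "_", sent$upos, "_", "_",
                            sent$head, sent$deprel, "_", "_", sep = "\t"))
    lines <- c(lines, "")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Mean dependency distance (MDD)
#'
#' The mean linear distance `|head - dependent|` over dependency arcs,
#' pooling all arcs of all sentences within a document (robust when single
#' sentences contribute only one arc). The root arc (head position 0) and
#' arcs whose dependent is tagged `PUNCT` are excluded; relation labels are
#' ignored. Documents with no qualifying arcs yield `NA`.
#'
#' @param x A tibble of dependency tokens as returned by [read_conllu()].
#' @param by Grouping column, default `"doc_id"`; use `NULL` to pool
#'   everything into a single value.
#' @return A tibble with columns `doc_id` (unless `by` is `NULL`), `mdd` and
#'   `n_arcs`.
#' @export
mdd <- function(x, by = "doc_id") {
  needed <- c("token_id", "upos", "head")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    abort("`x` must be a dependency token table (see read_conllu()).",
          class = "medsimplify_bad_input")
  }
  arcs <- dplyr::filter(x, .data$head != 0L, .data$upos != "PUNCT")
  arcs <- dplyr::mutate(arcs, dist = abs(.data$head - .data$token_id))
  if (is.null(by)) {
    return(tibble::tibble(
      mdd = if (nrow(arcs) == 0) NA_real_ else mean(arcs$dist),
      n_arcs = nrow(arcs)))
  }
  all_ids <- tibble::tibble(!!by := unique(x[[by]]))
  res <- dplyr::summarise(dplyr::group_by(arcs, dplyr::across(dplyr::all_of(by))),
                          mdd = mean(.data$dist), n_arcs = dplyr::n(),
                          .groups = "drop")
  out <- dplyr::left_join(all_ids, res, by = by)
  out$n_arcs[is.na(out$n_arcs)] <- 0L
  out
}
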