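# Independent oracles, written with dense vectors and explicit loops so they
# share no code path with the package implementations they check.

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments of the ranked absolute differences.
oracle_wsr <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  eps <- 1e-9
  p_le <- mean(Ws <= W + eps)
  p_ge <- mean(Ws >= W - eps)
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

# Brute-force character 3-gram TF-IDF cosine scan over a term list.
oracle_grams <- function(x) {
  p <- paste0("##", tolower(x), "##")
  n <- nchar(p)
  substring(p, 1:(n - 2), 3:n)
}

oracle_match <- function(queries, terms, k = 5L, min_sim = 0.4) {
  term_grams <- lapply(terms, oracle_grams)
  vocab <- sort(unique(unlist(term_grams)))
  n_terms <- length(terms)
  df <- sapply(vocab, function(g) {
    sum(vapply(term_grams, function(tg) g %in% tg, logical(1)))
  })
  idf <- log(n_terms / df)
  tf_fallback <- all(idf == 0)
  profile <- function(grams) {
    tf <- sapply(vocab, function(g) sum(grams == g))
    w <- if (tf_fallback) tf else tf * idf
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w / nrm else w
  }
  term_prof <- lapply(term_grams, profile)
  out <- list()
  for (q in queries) {
    qp <- profile(oracle_grams(q))
    sims <- vapply(term_prof, function(tp) sum(qp * tp), numeric(1))
    sel <- which(sims >= min_sim & sims > 0)
    ord <- sel[order(-sims[sel], terms[sel])]
    ord <- head(ord, k)
    if (length(ord) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        query = q, term = terms[ord], similarity = sims[ord],
        rank = seq_along(ord), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(query = character(), term = character(),
                      similarity = numeric(), rank = integer()))
  }
  do.call(rbind, out)
}

# Canonical ordering for comparing rankings in the presence of numerically
# near-tied similarities.
canonical_ranking <- function(df) {
  df$similarity <- round(df$similarity, 9)
  df <- df[order(df$query, -df$similarity, df$term), ]
  rownames(df) <- NULL
  df[, c("query", "term", "similarity")]
}

# A small hand-worked biomedical-flavoured lexicon used across tests.
toy_lexicon <- function() {
  as_lexicon(tibble::tibble(
    term = c("lymphoma", "lymphoma", "histamine receptor", "histamine",
             "carcinoma", "erythrocyte"),
    hypernym = c("cancer", "neoplastic process", "organ", "amine",
                 "cancer", "cell"),
    source = c("wordnet", "semantic_type", "semantic_type", "wordnet",
               "wordnet", "wordnet"),
    semantic_type = c(NA, "Neoplastic Process", "Receptor", NA, NA, NA)))
}
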