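# Clustering genes by the text of their functional descriptions:
# unigram+bigram tokenization, TF-IDF weighting, cosine similarity,
# average-linkage clustering, and per-cluster keyword extraction.

# compact english stopword list; fixed so tokenization is reproducible
nlp_stopwords <- c(
  "a", "about", "above", "after", "again", "all", "also", "an", "and",
  "any", "are", "as", "at", "be", "because", "been", "before", "being",
  "below", "between", "both", "but", "by", "can", "could", "did", "do",
  "does", "doing", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "just", "may", "me", "might", "more", "most", "my", "no",
  "nor", "not", "now", "of", "off", "on", "once", "only", "or", "other",
  "our", "out", "over", "own", "same", "she", "should", "so", "some",
  "such", "than", "that", "the", "their", "theirs", "them", "then",
  "there", "these", "they", "this", "those", "through", "to", "too",
  "under", "until", "up", "very", "was", "we", "were", "what", "when",
  "where", "which", "while", "who", "whom", "why", "will", "with", "would",
  "you", "your", "yours"
)

#' Tokenize a gene description into unigram and bigram terms
#'
#' Lowercases, splits on non-alphanumeric characters, drops stopwords and
#' tokens of length <= 2, and emits the surviving unigrams plus
#' adjacent-pair bigrams joined with `_` (adjacency is evaluated after
#' stopword removal). Repeated tokens keep their multiplicity.
#'
#' @param text a character string.
#' @return Character vector of terms (possibly empty).
#' @export
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nchar(toks) > 2 & !toks %in% nlp_stopwords]
  if (length(toks) < 2) return(toks)
  c(toks, paste(toks[-length(toks)], toks[-1], sep = "_"))
}

#' TF-IDF model of a gene-description corpus
#'
#' Term frequency is the term count normalized by document length (total
#' emitted terms); `idf = ln(N / df)` without smoothing, so a term present
#' in every document weighs exactly 0 everywhere; weight = tf * idf.
#'
#' @param corpus data frame with columns `gene` and `text`.
#' @return A list of class `tfidf_model`: `weights` (documents x terms),
#'   `df` (document frequencies), `idf`, `vocabulary`, and `empty`
#'   (genes whose documents produced no terms or all-zero weights).
#' @export
tfidf <- function(corpus) {
  if (nrow(corpus) == 0) stop_input("empty corpus")
  terms <- lapply(corpus$text, tokenize)
  empty_docs <- corpus$gene[lengths(terms) == 0]
  if (length(empty_docs)) {
    stop_input(
      "document(s) with no usable terms: %s",
      paste(utils::head(empty_docs, 5), collapse = ", ")
    )
  }
  vocab <- sort(unique(unlist(terms)))
  n <- nrow(corpus)
  tf <- matrix(0, n, length(vocab), dimnames = list(corpus$gene, vocab))
  for (i in seq_len(n)) {
    cnt <- table(terms[[i]])
    tf[i, names(cnt)] <- as.numeric(cnt) / length(terms[[i]])
  }
  df <- colSums(tf > 0)
  idf <- log(n / df)
  if (n == 1) {
    warning("single-document corpus: all idf are 0, clustering is undefined")
  }
  w <- sweep(tf, 2, idf, "*")
  flagged <- rownames(w)[rowSums(w) == 0]
  structure(
    list(
      weights = w, df = df, idf = idf, vocabulary = vocab, empty = flagged
    ),
    class = "tfidf_model"
  )
}

#' Cosine similarity matrix between documents
#'
#' For nonnegative weights the values lie in `[0, 1]`; the diagonal is 1
#' for nonzero rows. Zero rows yield 0 similarity to everything (including
#' themselves).
#'
#' @param weights documents-by-terms weight matrix (or a `tfidf_model`).
#' @return Symmetric similarity matrix.
#' @export
cosine_matrix <- function(weights) {
  if (inherits(weights, "tfidf_model")) weights <- weights$weights
  nrm <- sqrt(rowSums(weights^2))
  safe <- ifelse(nrm == 0, 1, nrm)
  u <- weights / safe
  s <- tcrossprod(u)
  s[nrm == 0, ] <- 0
  s[, nrm == 0] <- 0
  pmin(pmax(s, 0), 1)
}

#' Cluster documents by cosine similarity
#'
#' Average-linkage agglomerative clustering on distance `1 - cosine`, cut
#' at `k` clusters. Assignments are invariant to document order up to label
#' permutation.
#'
#' @param similarity cosine similarity matrix (see [cosine_matrix()]).
#' @param k number of clusters (1 <= k <= N).
#' @return Named integer vector of cluster assignments.
#' @export
cluster_documents <- function(similarity, k) {
  n <- nrow(similarity)
  if (k < 1 || k > n) stop_input("k must be between 1 and %d", n)
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  stats::cutree(hc, k = k)
}

#' Suggest a cluster count by mean silhouette width
#'
#' Scans `k` in `ks` and returns the value maximizing the average
#' silhouette computed on distance `1 - cosine`.
#'
#' @param similarity cosine similarity matrix.
#' @param ks candidate cluster counts.
#' @export
suggest_k <- function(similarity, ks = 2:8) {
  d <- 1 - similarity
  score <- vapply(ks, function(k) {
    cl <- cluster_documents(similarity, k)
    mean(vapply(seq_len(nrow(d)), function(i) {
      own <- d[i, cl == cl[i] & seq_len(nrow(d)) != i]
      a <- if (length(own)) mean(own) else 0
      b <- min(vapply(
        setdiff(unique(cl), cl[i]),
        function(g) mean(d[i, cl == g]), numeric(1)
      ))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
  }, numeric(1))
  ks[which.max(score)]
}

#' Per-cluster keyword extraction
#'
#' A term's keyword score for a cluster is its mean TF-IDF weight inside the
#' cluster minus its mean weight outside; the `top_n` positive-score terms
#' characterize the cluster. Terms uniform across documents score about 0
#' and never surface.
#'
#' @param model a `tfidf_model`.
#' @param assignments cluster assignments (named as the documents).
#' @param top_n keywords per cluster.
#' @return Data frame with `cluster`, `size`, `term`, `score`, `rank`.
#' @export
cluster_keywords <- function(model, assignments, top_n = 10L) {
  w <- model$weights
  assignments <- assignments[rownames(w)]
  res <- lapply(sort(unique(assignments)), function(cl) {
    inside <- w[assignments == cl, , drop = FALSE]
    outside <- w[assignments != cl, , drop = FALSE]
    m_in <- colMeans(inside)
    m_out <- if (nrow(outside)) colMeans(outside) else 0
    score <- m_in - m_out
    keep <- which(score > 0)
    keep <- keep[order(-score[keep], names(score)[keep])]
    keep <- utils::head(keep, top_n)
    if (length(keep) == 0) return(NULL)
    data.frame(
      cluster = cl, size = nrow(inside), term = names(score)[keep],
      score = unname(score[keep]), rank = seq_along(keep),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}
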