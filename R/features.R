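.ngram_tokens <- function(tokens, ngram_range = c(1L, 2L)) {
  out <- character(0)
  if (1L %in% ngram_range) out <- c(out, tokens)
  if (2L %in% ngram_range && length(tokens) >= 2L) {
    out <- c(out, paste(tokens[-length(tokens)], tokens[-1L]))
  }
  out
}

#' Build a document-frequency-filtered count feature matrix
#'
#' Counts unigram and bigram occurrences of medical terms per referral
#' and drops columns by document frequency: a term must occur in at least
#' `min_doc_count` distinct referrals (default 30, the full-corpus noise
#' floor; small corpora need a lower value) and in no more than
#' `max_doc_fraction` of all referrals (default 0.8). Columns are ordered
#' lexicographically. This matrix is the shared feature space of the
#' KNN, supervised, semi-supervised and seeded k-means predictors.
#'
#' @param token_lists List of character token vectors, one per referral.
#' @param ids Row (referral) identifiers; defaults to names or indices.
#' @param min_doc_count Minimum document frequency, default 30.
#' @param max_doc_fraction Maximum document-frequency fraction, default
#'   0.8 (columns in *more* than this fraction of referrals are dropped).
#' @param ngram_range Integer vector of n-gram sizes among `1:2`.
#' @return Object of class `feature_matrix`: list with `matrix` (sparse
#'   dgCMatrix, rows = referrals, columns = vocabulary), `vocab`, and
#'   `params`.
#' @export
build_features <- function(token_lists, ids = NULL, min_doc_count = 30L,
                           max_doc_fraction = 0.8,
                           ngram_range = c(1L, 2L)) {
  stopifnot(is.list(token_lists), length(token_lists) > 0L,
            min_doc_count >= 1L, max_doc_fraction > 0,
            max_doc_fraction <= 1, all(ngram_range %in% 1:2))
  n <- length(token_lists)
  if (is.null(ids)) {
    ids <- if (!is.null(names(token_lists))) names(token_lists) else
      as.character(seq_len(n))
  }
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  grams <- lapply(token_lists, .ngram_tokens, ngram_range = ngram_range)
  counts <- lapply(grams, function(g) {
    if (!length(g)) return(integer(0))
    table(g)
  })
  docfreq <- table(unlist(lapply(counts, names), use.names = FALSE))
  keep <- names(docfreq)[docfreq >= min_doc_count &
                           docfreq <= max_doc_fraction * n]
  if (!length(keep)) {
    stop("all feature columns were filtered out; lower min_doc_count or ",
         "raise max_doc_fraction for this corpus size")
  }
  vocab <- sort(keep)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    ct <- counts[[i]]
    if (!length(ct)) next
    hit <- names(ct) %in% vocab
    if (!any(hit)) next
    ii <- c(ii, rep.int(i, sum(hit)))
    jj <- c(jj, match(names(ct)[hit], vocab))
    xx <- c(xx, as.numeric(ct[hit]))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, length(vocab)),
                            dimnames = list(ids, vocab))
  structure(
    list(matrix = m, vocab = vocab,
         params = list(min_doc_count = min_doc_count,
                       max_doc_fraction = max_doc_fraction,
                       ngram_range = ngram_range)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$matrix), "documents x",
      ncol(x$matrix), "n-gram features\n")
  invisible(x)
}

#' Vectorise new token sequences into an existing feature space
#'
#' @param token_lists List of character token vectors.
#' @param features A [build_features()] result (defines vocabulary and
#'   n-gram range).
#' @param ids Optional row names.
#' @return A sparse matrix with columns matching `features$vocab`.
#' @export
vectorize_tokens <- function(token_lists, features, ids = NULL) {
  stopifnot(inherits(features, "feature_matrix"), is.list(token_lists))
  vocab <- features$vocab
  n <- length(token_lists)
  if (is.null(ids)) ids <- names(token_lists)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    g <- .ngram_tokens(token_lists[[i]], features$params$ngram_range)
    if (!length(g)) next
    ct <- table(g)
    hit <- names(ct) %in% vocab
    if (!any(hit)) next
    ii <- c(ii, rep.int(i, sum(hit)))
    jj <- c(jj, match(names(ct)[hit], vocab))
    xx <- c(xx, as.numeric(ct[hit]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(vocab)),
                       dimnames = list(ids, vocab))
}

#' Write / read a feature matrix as MatrixMarket + vocabulary file
#'
#' @param features A [build_features()] result.
#' @param path Basename; writes `<path>.mtx`, `<path>.vocab.txt` and
#'   `<path>.ids.txt`.
#' @return `path` (write); a `feature_matrix` (read).
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  Matrix::writeMM(features$matrix, paste0(path, ".mtx"))
  writeLines(features$vocab, paste0(path, ".vocab.txt"))
  writeLines(rownames(features$matrix), paste0(path, ".ids.txt"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  m <- as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  vocab <- readLines(paste0(path, ".vocab.txt"))
  ids <- readLines(paste0(path, ".ids.txt"))
  dimnames(m) <- list(ids, vocab)
  structure(list(matrix = m, vocab = vocab,
                 params = list(min_doc_count = NA_integer_,
                               max_doc_fraction = NA_real_,
                               ngram_range = c(1L, 2L))),
            class = "feature_matrix")
}

#' Euclidean distance converted to similarity
#'
#' `exp(-Euc(A, B))`: strictly decreasing in distance, equal to 1 at
#' distance 0 and approaching 0 for distant vectors.
#'
#' @param a,b Numeric feature vectors of equal length.
#' @return Numeric scalar in `(0, 1]`.
#' @export
euc_similarity <- function(a, b) {
  exp(-sqrt(sum((as.numeric(a) - as.numeric(b))^2)))
}

#' Weighted k-nearest-neighbour CPC vote
#'
#' Finds the `k` labelled referrals most similar to `x` under
#' [euc_similarity()] (keeping only strictly positive similarities),
#' sums neighbour similarities per CPC and returns the argmax CPC. Ties
#' break toward the lexicographically smallest `cpc_id`. When no
#' neighbour qualifies the sentinel `NA_character_` is returned.
#'
#' @param x Numeric feature vector for the unlabelled referral.
#' @param labeled Matrix of labelled referral feature vectors (rows).
#' @param labels Character vector of CPC ids, one per row of `labeled`.
#' @param k Number of neighbours, default 10.
#' @return List with `cpc_id` (may be `NA_character_`) and `votes`
#'   (named numeric vector of per-CPC similarity sums).
#' @export
knn_predict <- function(x, labeled, labels, k = 10L) {
  if (k < 1L) stop("k must be at least 1")
  labeled <- as.matrix(labeled)
  stopifnot(nrow(labeled) >= 1L, length(labels) == nrow(labeled))
  x <- as.numeric(x)
  stopifnot(length(x) == ncol(labeled))
  d <- sqrt(rowSums(sweep(labeled, 2L, x)^2))
  sims <- exp(-d)
  ord <- order(-sims)
  ord <- ord[sims[ord] > 0]
  ord <- head(ord, k)
  if (!length(ord)) {
    return(list(cpc_id = NA_character_, votes = numeric(0)))
  }
  votes <- tapply(sims[ord], labels[ord], sum)
  votes <- setNames(as.numeric(votes), names(votes))
  votes <- votes[order(names(votes))]
  list(cpc_id = names(votes)[which.max(votes)], votes = votes)
}
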