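#' Render an epoch as a token document
#'
#' Each rounded sample value becomes a fixed-width "word" with exactly
#' three decimals (`"0.000"` ... `"1.000"`); tokens are emitted channel by
#' channel (channel 1 first), in sample order within a channel. With this
#' fixed-width alphabet, lexicographic token order equals numeric order.
#'
#' @param epoch channels x samples matrix of values on the 3-decimal
#'   [0, 1] grid.
#' @return Character vector of tokens, length `channels * samples`.
#' @export
tokenize_epoch <- function(epoch) {
  stopifnot(is.matrix(epoch))
  v <- as.vector(t(epoch))  # channel-major order
  if (any(abs(v * 1000 - round(v * 1000)) > 1e-9) ||
      any(v < 0) || any(v > 1)) {
    stop("epoch values must lie on the rounded 3-decimal [0, 1] grid")
  }
  formatC(v, format = "f", digits = 3)
}

#' Tokenize every epoch of an epoch set
#'
#' @param epochs an `epoch_set` from [extract_epochs()].
#' @return List of token documents (character vectors), one per epoch.
#' @export
tokenize_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  lapply(seq_len(dim(epochs$data)[3]),
         function(i) tokenize_epoch(epochs$data[, , i, drop = TRUE]))
}

#' Build the sorted vocabulary of a corpus
#'
#' @param corpus list of token documents.
#' @return Character vector of unique terms in lexicographic (C-locale)
#'   order; for the fixed-width numeric tokens this equals numeric order.
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0) stop("empty corpus")
  terms <- unique(unlist(corpus, use.names = FALSE))
  terms[order(terms, method = "radix")]
}

#' Count-vectorize a corpus over a vocabulary
#'
#' `counts[d, t]` is the multiplicity of term `t` in document `d`.
#' Out-of-vocabulary tokens are ignored (the vocabulary is frozen on the
#' training corpus).
#'
#' @param corpus list of token documents.
#' @param vocab vocabulary from [build_vocabulary()].
#' @return Integer matrix, documents x terms, with terms as column names.
#' @export
count_vectorize <- function(corpus, vocab) {
  counts <- t(vapply(corpus, function(doc) {
    idx <- match(doc, vocab)
    tabulate(idx[!is.na(idx)], nbins = length(vocab))
  }, integer(length(vocab))))
  colnames(counts) <- vocab
  counts
}

#' Smoothed inverse document frequency
#'
#' `IDF_t = ln((n + 1) / (DF_t + 1)) + 1`, with `n` documents and `DF_t`
#' the number of documents containing term `t`. Since `DF_t <= n`, every
#' IDF is at least 1.
#'
#' @param doc_freq integer vector of document frequencies (all >= 1 for
#'   in-vocabulary terms).
#' @param n_docs number of documents.
#' @return Numeric vector of IDF weights.
#' @export
idf_weights <- function(doc_freq, n_docs) {
  if (any(doc_freq < 1) || any(doc_freq > n_docs)) {
    stop("document frequencies must lie in [1, n_docs]")
  }
  log((n_docs + 1) / (doc_freq + 1)) + 1
}

#' TF-IDF weighting of a count matrix
#'
#' `weights[d, t] = counts[d, t] * IDF_t` (term frequency is the raw
#' count). With `l2_normalize = TRUE` (default) each document row is then
#' scaled to unit Euclidean norm; an all-zero row is left as zeros.
#'
#' @param counts documents x terms count matrix.
#' @param idf per-term IDF vector (e.g. [idf_weights()]).
#' @param l2_normalize scale each row to unit L2 norm.
#' @return Numeric weight matrix with the shape of `counts`.
#' @export
tfidf_weights <- function(counts, idf, l2_normalize = TRUE) {
  stopifnot(ncol(counts) == length(idf))
  w <- sweep(counts, 2, idf, `*`)
  if (l2_normalize) {
    nrm <- sqrt(rowSums(w^2))
    nz <- nrm > 0
    w[nz, ] <- w[nz, , drop = FALSE] / nrm[nz]
  }
  w
}

#' Corpus to TF-IDF features in one step
#'
#' Builds (or reuses) the vocabulary, count-vectorizes, computes document
#' frequencies and IDF, and weights by TF-IDF.
#'
#' @param corpus list of token documents.
#' @param vocab optional frozen vocabulary; default: built from `corpus`.
#' @param l2_normalize passed to [tfidf_weights()].
#' @return List `vocab`, `counts`, `doc_freq`, `idf`, `weights`.
#' @export
featurize <- function(corpus, vocab = NULL, l2_normalize = TRUE) {
  if (is.null(vocab)) vocab <- build_vocabulary(corpus)
  counts <- count_vectorize(corpus, vocab)
  doc_freq <- colSums(counts > 0)
  # a frozen vocabulary may contain terms absent from this corpus;
  # clamp DF to 1 so the smoothed IDF stays defined
  idf <- idf_weights(pmax(doc_freq, 1L), nrow(counts))
  list(vocab = vocab, counts = counts, doc_freq = doc_freq, idf = idf,
       weights = tfidf_weights(counts, idf, l2_normalize))
}

#' Export a feature matrix as MatrixMarket plus a vocabulary file
#'
#' @param features list from [featurize()].
#' @param basepath output path without extension; writes `<base>.mtx`
#'   (sparse coordinate format of the weights) and `<base>.vocab.txt`
#'   (one term per line).
#' @export
write_features_mtx <- function(features, basepath) {
  w <- features$weights
  nz <- which(w != 0, arr.ind = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate real general",
             sprintf("%d %d %d", nrow(w), ncol(w), nrow(nz)),
             sprintf("%d %d %.17g", nz[, 1], nz[, 2], w[nz]))
  writeLines(lines, paste0(basepath, ".mtx"))
  writeLines(features$vocab, paste0(basepath, ".vocab.txt"))
  invisible(basepath)
}
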