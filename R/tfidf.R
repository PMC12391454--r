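#' Fit a TF-IDF vectorizer on tokenized documents
#'
#' Vocabulary comes from the training documents only. The dialect (recorded
#' in the model) is raw term counts weighted by the smoothed inverse document
#' frequency `idf(t) = ln((1 + n) / (1 + df(t))) + 1`, with each document
#' vector L2-normalized — the convention used by mainstream text-ML
#' toolkits. Unseen tokens at transform time are ignored.
#'
#' @param token_lists list of character vectors (one tokenized document each).
#' @param min_df minimum number of documents a token must appear in to enter
#'   the vocabulary (noisy clinical text is full of one-off typo tokens that
#'   carry no generalizable signal; the classifier prunes them by default).
#' @return A `siteshift_tfidf` object with `vocabulary`, `idf`, and `dialect`.
#' @export
fit_tfidf <- function(token_lists, min_df = 1) {
  if (!length(token_lists) || all(lengths(token_lists) == 0L)) {
    stop_data("TF-IDF needs at least one non-empty document")
  }
  vocab <- sort(unique(unlist(token_lists, use.names = FALSE)))
  n <- length(token_lists)
  df <- integer(length(vocab))
  names(df) <- vocab
  for (doc in token_lists) {
    u <- unique(doc)
    df[u] <- df[u] + 1L
  }
  keep <- df >= min_df
  if (!any(keep)) stop_data("no token reaches min_df")
  vocab <- vocab[keep]
  df <- df[keep]
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocabulary = vocab, idf = idf, n_docs = n,
                 dialect = list(tf = "raw_count",
                                idf = "ln((1+n)/(1+df))+1",
                                norm = "l2", min_df = min_df)),
            class = "siteshift_tfidf")
}

#' @rdname fit_tfidf
#' @param model a fitted `siteshift_tfidf`.
#' @return `tfidf_transform()` returns a sparse `dgCMatrix`
#'   (documents x vocabulary) of L2-normalized tf-idf weights.
#' @export
tfidf_transform <- function(model, token_lists) {
  vocab <- model$vocabulary
  nd <- length(token_lists)
  toks <- unlist(token_lists, use.names = FALSE)
  doc <- rep.int(seq_len(nd), lengths(token_lists))
  j <- match(toks, vocab)
  keep <- !is.na(j)
  X <- Matrix::sparseMatrix(i = doc[keep], j = j[keep], x = 1,
                            dims = c(nd, length(vocab)),
                            dimnames = list(NULL, vocab))
  X <- X %*% Matrix::Diagonal(x = unname(model$idf))
  rs <- sqrt(Matrix::rowSums(X^2))
  rs[rs == 0] <- 1
  X <- methods::as(Matrix::Diagonal(x = 1 / rs) %*% X, "CsparseMatrix")
  dimnames(X) <- list(NULL, vocab)  # diagonal products drop dimnames
  X
}
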