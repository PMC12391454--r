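#' Specification of the procedure-code classifier
#'
#' A TF-IDF vectorizer feeding a three-layer feed-forward network: two ReLU
#' hidden layers (default 500 and 250 units, each followed by 25% dropout)
#' and a softmax output over the corpus' global label set, trained with Adam
#' on categorical cross-entropy. Epochs, batch size and learning rate are
#' not dictated by the architecture and are exposed here; training stops
#' early when the epoch training loss plateaus.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param dropout_rate dropout probability in `[0, 1)` after each hidden
#'   layer.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param early_stop_patience epochs without sufficient loss improvement
#'   before stopping.
#' @param early_stop_min_delta minimum absolute improvement of the mean
#'   epoch training loss (nats) that counts as progress.
#' @param tfidf_min_df minimum document frequency for a token to enter the
#'   TF-IDF vocabulary (see [fit_tfidf()]); default 2 drops one-off typo
#'   tokens.
#' @param seed base seed for weight init, dropout and batch shuffling.
#' @return A `siteshift_classifier_spec` list.
#' @export
classifier_spec <- function(hidden_sizes = c(500, 250),
                            dropout_rate = 0.25,
                            epochs = 30,
                            batch_size = 128,
                            learning_rate = 1e-3,
                            early_stop_patience = 2,
                            early_stop_min_delta = 5e-3,
                            tfidf_min_df = 2,
                            seed = 1L) {
  if (!is.numeric(hidden_sizes) || any(hidden_sizes < 1)) {
    stop_config("'hidden_sizes' must be positive")
  }
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("'dropout_rate' must be in [0, 1)")
  }
  for (f in c("epochs", "batch_size")) {
    if (!is_count(get(f))) stop_config(sprintf("'%s' must be a count", f))
  }
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 optimizer = "adam", loss = "categorical_cross_entropy",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta,
                 tfidf_min_df = as.integer(tfidf_min_df),
                 seed = as.integer(seed)),
            class = "siteshift_classifier_spec")
}

#' Train the procedure-code classifier on a corpus subset
#'
#' Fits TF-IDF on the training documents only (so transfer evaluation sees
#' genuinely unseen vocabulary) and trains the feed-forward network over the
#' corpus' global label set. Deterministic given the spec seed.
#'
#' @param corpus_subset corpus rows to train on (institution subset, CV fold,
#'   pooled split, ...); must contain at least two distinct labels.
#' @param spec a [classifier_spec()].
#' @param level preprocessing level applied to the text.
#' @param lexicons a [load_lexicons()] object.
#' @param tokens optional precomputed token lists aligned with
#'   `corpus_subset` rows.
#' @return A `siteshift_model` with the TF-IDF model, network weights, label
#'   index, spec, level and a fingerprint (hash of sorted training record
#'   ids) used for leakage checks.
#' @export
train_cpt_model <- function(corpus_subset, spec = classifier_spec(),
                            level = "minimal", lexicons = load_lexicons(),
                            tokens = NULL) {
  level <- normalize_level(level)
  labels <- corpus_labels(corpus_subset)
  if (length(unique(corpus_subset$label)) < 2) {
    stop_data("degenerate training set: fewer than 2 distinct labels")
  }
  if (is.null(tokens)) {
    tokens <- preprocess_corpus_text(corpus_subset$text, level, lexicons)
  }
  tfidf <- fit_tfidf(tokens, min_df = spec$tfidf_min_df %||% 1)
  X <- tfidf_transform(tfidf, tokens)
  y <- match(corpus_subset$label, labels)
  net <- train_mlp(X, y, k_out = length(labels),
                   hidden = spec$hidden_sizes, dropout = spec$dropout_rate,
                   epochs = spec$epochs, batch_size = spec$batch_size,
                   lr = spec$learning_rate,
                   patience = spec$early_stop_patience,
                   min_delta = spec$early_stop_min_delta,
                   seed = spec$seed)
  structure(list(tfidf = tfidf, net = net, label_index = labels,
                 spec = spec, level = level,
                 train_ids = sort(corpus_subset$record_id),
                 fingerprint = rlang::hash(sort(corpus_subset$record_id))),
            class = "siteshift_model")
}

#' @export
print.siteshift_model <- function(x, ...) {
  cat(sprintf("<siteshift_model> level=%s, vocab=%d, labels=%d, fingerprint=%s\n",
              x$level, length(x$tfidf$vocabulary), length(x$label_index),
              substr(x$fingerprint, 1, 8)))
  invisible(x)
}

#' Predict procedure codes for new texts
#' @param model a [train_cpt_model()] model.
#' @param text character vector of raw texts (preprocessed at the model's
#'   level) or a corpus.
#' @param lexicons lexicons used at training time.
#' @return character vector of predicted labels.
#' @export
predict_codes <- function(model, text, lexicons = load_lexicons()) {
  if (inherits(text, "siteshift_corpus")) text <- text$text
  tokens <- preprocess_corpus_text(text, model$level, lexicons)
  X <- tfidf_transform(model$tfidf, tokens)
  model$label_index[predict_mlp(model$net, X)]
}

# micro-averaged precision/recall/F1 from pooled per-class TP/FP/FN
micro_f1_pooled <- function(truth, pred, labels) {
  tp <- fp <- fn <- 0
  for (lb in labels) {
    tp <- tp + sum(pred == lb & truth == lb)
    fp <- fp + sum(pred == lb & truth != lb)
    fn <- fn + sum(pred != lb & truth == lb)
  }
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

eval_result <- function(train_id, test_id, level, accuracy, micro_f1, n_test,
                        self = FALSE, fold = NA_integer_) {
  # algebraic identity for single-label multiclass prediction
  if (abs(micro_f1 - accuracy) > 1e-12) {
    rlang::abort("micro-F1 must equal accuracy for single-label evaluation",
                 class = "siteshift_internal_error")
  }
  tibble::tibble(train_id = train_id, test_id = test_id, level = level,
                 fold = fold, self = self, accuracy = accuracy,
                 micro_f1 = micro_f1, n_test = as.integer(n_test))
}

#' Evaluate a trained model on a test subset
#'
#' Accuracy is the fraction of exactly predicted codes; micro-averaged F1 is
#' computed from per-class true/false positives and false negatives pooled
#' over all classes. For single-label multiclass prediction the two are
#' algebraically identical, and that identity is asserted on every result.
#'
#' @param model a [train_cpt_model()] model.
#' @param test_subset corpus rows to evaluate on (non-empty; labels within
#'   the model's label set).
#' @param lexicons lexicons used at training time.
#' @param train_id,test_id identifiers recorded in the result.
#' @param tokens optional precomputed token lists aligned with `test_subset`.
#' @param self,fold bookkeeping flags for result tables.
#' @return One-row tibble: train_id, test_id, level, fold, self, accuracy,
#'   micro_f1, n_test.
#' @export
evaluate_model <- function(model, test_subset, lexicons = load_lexicons(),
                           train_id = "train", test_id = "test",
                           tokens = NULL, self = FALSE, fold = NA_integer_) {
  if (nrow(test_subset) == 0L) stop_data("empty test set")
  if (!all(test_subset$label %in% model$label_index)) {
    stop_data("test labels outside the model's label set")
  }
  if (is.null(tokens)) {
    tokens <- preprocess_corpus_text(test_subset$text, model$level, lexicons)
  }
  X <- tfidf_transform(model$tfidf, tokens)
  pred <- model$label_index[predict_mlp(model$net, X)]
  truth <- test_subset$label
  acc <- mean(pred == truth)
  f1 <- micro_f1_pooled(truth, pred, model$label_index)
  eval_result(train_id, test_id, model$level, acc, f1, nrow(test_subset),
              self = self, fold = fold)
}
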