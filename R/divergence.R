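DIVERGENCE_METRICS <- c("overlap", "jaccard", "kld_cpt", "kld_word", "kld_composite")

#' Directed vocabulary overlap and Jaccard similarity
#'
#' `vocab_overlap(a, b)` is the share of institution B's unique words that
#' institution A's vocabulary covers, `|A ∩ B| / |B|` — an asymmetric measure
#' that mimics transferring a model trained at A onto B's text.
#' `jaccard_similarity` is the symmetric `|A ∩ B| / |A ∪ B|`.
#'
#' @param vocab_a,vocab_b [institution_vocabulary()] objects or plain
#'   character vectors of tokens.
#' @return A number in `[0, 1]`.
#' @export
vocab_overlap <- function(vocab_a, vocab_b) {
  a <- vocab_tokens(vocab_a); b <- vocab_tokens(vocab_b)
  if (length(b) == 0L) stop_metric("overlap undefined: target vocabulary is empty")
  length(intersect(a, b)) / length(b)
}

#' @rdname vocab_overlap
#' @export
jaccard_similarity <- function(vocab_a, vocab_b) {
  a <- vocab_tokens(vocab_a); b <- vocab_tokens(vocab_b)
  u <- union(a, b)
  if (length(u) == 0L) stop_metric("jaccard undefined: both vocabularies empty")
  length(intersect(a, b)) / length(u)
}

vocab_tokens <- function(v) {
  if (inherits(v, "siteshift_vocabulary")) unique(v$tokens) else unique(as.character(v))
}

#' Smoothed distribution pair on a common support
#'
#' Aligns two nonnegative weight vectors on the union of their supports,
#' adds `epsilon` everywhere (KL divergence is undefined on zero cells) and
#' renormalizes.
#'
#' @param p,q named nonnegative numeric vectors (counts or probabilities).
#' @param epsilon additive smoothing constant.
#' @return list with `support`, `p`, `q`, `epsilon`; both vectors sum to 1.
#' @export
distribution_pair <- function(p, q, epsilon = 1e-9) {
  if (is.null(names(p)) || is.null(names(q))) {
    if (length(p) != length(q)) stop_metric("unnamed p and q must share a support")
    support <- paste0("x", seq_along(p))
    names(p) <- support; names(q) <- support
  }
  support <- sort(union(names(p), names(q)))
  al <- function(x) {
    v <- stats::setNames(numeric(length(support)), support)
    v[names(x)] <- v[names(x)] + as.numeric(x)
    if (any(v < 0) || !any(v > 0)) stop_metric("weights must be nonnegative with positive mass")
    v <- v + epsilon
    v / sum(v)
  }
  list(support = support, p = al(p), q = al(q), epsilon = epsilon)
}

#' Kullback-Leibler divergence
#'
#' `D(p || q) = sum_i p_i log(p_i / q_i)` in nats (natural log). Zero exactly
#' when the smoothed distributions coincide; higher values mean greater
#' divergence between the datasets the distributions summarize.
#'
#' @param pair a [distribution_pair()], or a probability vector (then `q`
#'   must be given).
#' @param q optional second probability vector when `pair` is a vector.
#' @param epsilon smoothing applied when raw vectors are supplied.
#' @return Nonnegative divergence in nats.
#' @export
kl_divergence <- function(pair, q = NULL, epsilon = 1e-9) {
  if (!is.list(pair)) pair <- distribution_pair(pair, q, epsilon)
  p <- pair$p; qq <- pair$q
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(qq) - 1) > 1e-9) {
    stop_metric("distribution pair is not normalized")
  }
  max(0, sum(p * log(p / qq)))
}

label_distribution <- function(corpus, institution_id) {
  recs <- institution_records(corpus, institution_id)
  labels <- corpus_labels(corpus)
  counts <- table(factor(recs$label, levels = labels))
  stats::setNames(as.numeric(counts) / sum(counts), labels)
}

#' Label-distribution divergence between two institutions (KLD_CPT)
#'
#' KL divergence between the empirical procedure-code distributions of two
#' institutions on the corpus' global label set. The direction convention
#' (see [divergence_matrix()]) is that `kld_cpt(corpus, a, b)` quantifies
#' applying institution `a`'s model to institution `b`'s data, computed as
#' `D(P_b || P_a)`.
#'
#' @param corpus a corpus.
#' @param inst_a,inst_b institution ids (model source, model target).
#' @param epsilon smoothing constant.
#' @param direction `"target_given_source"` (default, `D(P_b || P_a)`) or
#'   `"source_given_target"` (`D(P_a || P_b)`).
#' @return Nonnegative divergence in nats.
#' @export
kld_cpt <- function(corpus, inst_a, inst_b, epsilon = 1e-9,
                    direction = c("target_given_source", "source_given_target")) {
  direction <- match.arg(direction)
  pa <- label_distribution(corpus, inst_a)
  pb <- label_distribution(corpus, inst_b)
  if (direction == "target_given_source") {
    kl_divergence(distribution_pair(pb, pa, epsilon))
  } else {
    kl_divergence(distribution_pair(pa, pb, epsilon))
  }
}

word_distribution <- function(tokens_list) {
  tok <- unlist(tokens_list, use.names = FALSE)
  if (!length(tok)) return(NULL)
  tab <- table(tok)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Within-label word-distribution divergence (KLD_word)
#'
#' KL divergence between two institutions' word (token-frequency)
#' distributions over records sharing one label, after preprocessing —
#' covariate shift in how the two institutions describe the same procedure.
#' Labels absent at either institution are incomparable and signalled by
#' returning `NA` (aggregations count and exclude them).
#'
#' @inheritParams kld_cpt
#' @param label the shared procedure code to condition on.
#' @param level preprocessing level.
#' @param lexicons a [load_lexicons()] object.
#' @param tokens optional precomputed token lists (named by record_id order
#'   of `corpus`) to avoid re-preprocessing.
#' @return Nonnegative divergence in nats, or `NA_real_` if incomparable.
#' @export
kld_word <- function(corpus, inst_a, inst_b, label, level = "minimal",
                     lexicons = load_lexicons(), epsilon = 1e-9,
                     direction = c("target_given_source", "source_given_target"),
                     tokens = NULL) {
  direction <- match.arg(direction)
  if (is.null(tokens)) tokens <- preprocess_corpus_text(corpus$text, level, lexicons)
  sel_a <- corpus$institution_id == inst_a & corpus$label == label
  sel_b <- corpus$institution_id == inst_b & corpus$label == label
  if (!inst_a %in% corpus$institution_id || !inst_b %in% corpus$institution_id) {
    stop_data("unknown institution")
  }
  pa <- word_distribution(tokens[sel_a])
  pb <- word_distribution(tokens[sel_b])
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  if (direction == "target_given_source") {
    kl_divergence(distribution_pair(pb, pa, epsilon))
  } else {
    kl_divergence(distribution_pair(pa, pb, epsilon))
  }
}

#' Composite divergence combining label and word shift
#'
#' Combines the per-label word divergences into one pairwise statistic.
#' With the default `"product"` strategy the label divergence multiplies the
#' label-weighted mean word divergence:
#' `KLD_CPT(a,b) * sum_c w_c KLD_word_c(a,b)` with
#' `w_c = (p_a(c) + p_b(c)) / 2` over the labels comparable at both
#' institutions. The `"weighted_sum"` strategy reports the weighted word
#' term alone. The strategy used is recorded in matrix metadata.
#'
#' @inheritParams kld_word
#' @param strategy `"product"` (default) or `"weighted_sum"`.
#' @return list with `value`, `n_incomparable` (labels skipped), `strategy`.
#' @export
kld_composite <- function(corpus, inst_a, inst_b, level = "minimal",
                          lexicons = load_lexicons(), epsilon = 1e-9,
                          strategy = c("product", "weighted_sum"),
                          direction = c("target_given_source", "source_given_target"),
                          tokens = NULL) {
  strategy <- match.arg(strategy)
  direction <- match.arg(direction)
  if (is.null(tokens)) tokens <- preprocess_corpus_text(corpus$text, level, lexicons)
  labels <- corpus_labels(corpus)
  pa <- label_distribution(corpus, inst_a)
  pb <- label_distribution(corpus, inst_b)
  kw <- vapply(labels, function(lb) {
    kld_word(corpus, inst_a, inst_b, lb, level, lexicons, epsilon,
             direction, tokens = tokens)
  }, numeric(1))
  ok <- !is.na(kw)
  if (!any(ok)) stop_metric("no comparable labels between institutions")
  w <- (pa[labels] + pb[labels]) / 2
  word_term <- sum(w[ok] * kw[ok])
  kc <- kld_cpt(corpus, inst_a, inst_b, epsilon, direction)
  value <- if (strategy == "product") kc * word_term else word_term
  list(value = value, n_incomparable = sum(!ok), strategy = strategy,
       kld_cpt = kc, word_term = word_term)
}

#' Pairwise divergence matrix over institutions
#'
#' Computes one divergence metric for every ordered institution pair. Entry
#' `[a, b]` quantifies transferring institution `a`'s model to institution
#' `b`'s data (for KL metrics, `D(P_b || P_a)` under the default direction).
#' Overlap and Jaccard have unit diagonal; KL metrics have zero diagonal;
#' Jaccard is symmetric.
#'
#' @inheritParams kld_composite
#' @param metric one of `"overlap"`, `"jaccard"`, `"kld_cpt"`, `"kld_word"`
#'   (label-weighted mean of per-label word divergences), `"kld_composite"`.
#' @return A `siteshift_divergence_matrix`: numeric institution-by-institution
#'   matrix with `metric`, `directed`, and `meta` (epsilon, log base,
#'   direction, strategy, incomparable-label counts) attributes.
#' @export
divergence_matrix <- function(corpus, metric = "kld_composite",
                              level = "minimal", lexicons = load_lexicons(),
                              epsilon = 1e-9,
                              strategy = c("product", "weighted_sum"),
                              direction = c("target_given_source", "source_given_target")) {
  metric <- match.arg(metric, DIVERGENCE_METRICS)
  strategy <- match.arg(strategy)
  direction <- match.arg(direction)
  insts <- corpus_institutions(corpus)
  n <- length(insts)
  m <- matrix(0, n, n, dimnames = list(insts, insts))
  tokens <- NULL
  vocabs <- NULL
  if (metric %in% c("overlap", "jaccard")) {
    vocabs <- lapply(insts, function(id) institution_vocabulary(corpus, id, level, lexicons))
    names(vocabs) <- insts
  } else if (metric %in% c("kld_word", "kld_composite")) {
    tokens <- preprocess_corpus_text(corpus$text, level, lexicons)
  }
  incomparable <- 0L
  for (a in insts) for (b in insts) {
    m[a, b] <- if (a == b) {
      if (metric %in% c("overlap", "jaccard")) 1 else 0
    } else if (metric == "overlap") {
      vocab_overlap(vocabs[[a]], vocabs[[b]])
    } else if (metric == "jaccard") {
      jaccard_similarity(vocabs[[a]], vocabs[[b]])
    } else if (metric == "kld_cpt") {
      kld_cpt(corpus, a, b, epsilon, direction)
    } else {
      comp <- kld_composite(corpus, a, b, level, lexicons, epsilon,
                            strategy, direction, tokens = tokens)
      incomparable <- incomparable + comp$n_incomparable
      if (metric == "kld_word") comp$word_term else comp$value
    }
  }
  structure(m, metric = metric,
            directed = metric != "jaccard",
            meta = list(level = normalize_level(level), epsilon = epsilon,
                        log_base = "e", direction = direction,
                        strategy = if (metric == "kld_composite") strategy else NULL,
                        n_incomparable_labels = incomparable),
            class = c("siteshift_divergence_matrix", "matrix", "array"))
}

#' Write/read a divergence matrix as CSV with a JSON metadata sidecar
#' @param m a [divergence_matrix()].
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_divergence_matrix <- function(m, path) {
  df <- data.frame(institution_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  readr::write_csv(df, path)
  meta <- c(attr(m, "meta"), list(metric = attr(m, "metric"),
                                  directed = attr(m, "directed")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
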