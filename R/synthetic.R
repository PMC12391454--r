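# Probabilities of the optional phrase slots; part of the generating model
# and mirrored exactly in the analytic ground-truth word distributions.
MODIFIER_P <- 0.7
TAIL_P <- 0.4
STOPWORD_INSERT_P <- 0.5
DIGIT_INSERT_P <- 0.25
INSERT_POOL_STOP <- c("of", "the", "with", "for", "and", "to")
INSERT_POOL_DIGIT <- c("27447", "29881", "47562", "66984", "2", "3", "10")

#' Configuration for the synthetic multi-institution corpus generator
#'
#' The generator emulates a multi-center procedure registry: each institution
#' draws its own label (procedure-code) mix from a Dirichlet distribution
#' (label shift), renders each record's text from per-label phrase templates
#' with institution-private synonym vocabulary (covariate shift), and then
#' injects realistic noise: single-character misspellings, acronym
#' substitution, mixed casing, punctuation, and stray stop-word/digit tokens.
#'
#' @param n_institutions number of institutions (>= 1).
#' @param n_labels number of procedure codes, 2..12 (the packaged template
#'   bank defines 12 procedure families).
#' @param records_per_institution records generated per institution.
#' @param label_concentration Dirichlet concentration for per-institution
#'   label mixes; smaller values give more skew (more label shift).
#' @param private_vocab_fraction share of the template vocabulary that each
#'   institution replaces with its own private variant tokens.
#' @param misspell_word_rate per-word probability of a single character
#'   substitution or adjacent transposition.
#' @param abbreviation_rate per-record probability that the head phrase is
#'   replaced by its acronym (when the procedure family has one).
#' @param outlier_institutions list of planted outliers; each element is
#'   `list(institution =, labels =, mass =)` (mass concentrated on the named
#'   labels, remainder uniform) or `list(institution =, weights =)` with a
#'   full probability vector.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return A `siteshift_generator_config` list.
#' @export
generator_config <- function(n_institutions = 6,
                             n_labels = 12,
                             records_per_institution = 1500,
                             label_concentration = 1.0,
                             private_vocab_fraction = 0.4,
                             misspell_word_rate = 0.10,
                             abbreviation_rate = 0.10,
                             outlier_institutions = list(),
                             seed = 1L) {
  cfg <- list(n_institutions = n_institutions, n_labels = n_labels,
              records_per_institution = records_per_institution,
              label_concentration = label_concentration,
              private_vocab_fraction = private_vocab_fraction,
              misspell_word_rate = misspell_word_rate,
              abbreviation_rate = abbreviation_rate,
              outlier_institutions = outlier_institutions,
              seed = as.integer(seed))
  for (f in c("n_institutions", "n_labels", "records_per_institution")) {
    if (!is_count(cfg[[f]])) stop_config(sprintf("'%s' must be a count >= 1", f))
  }
  if (cfg$n_labels < 2) stop_config("'n_labels' must be >= 2")
  for (f in c("private_vocab_fraction", "misspell_word_rate", "abbreviation_rate")) {
    if (!is_rate(cfg[[f]])) stop_config(sprintf("'%s' must be a rate in [0,1]", f))
  }
  if (!is.numeric(cfg$label_concentration) || cfg$label_concentration <= 0) {
    stop_config("'label_concentration' must be a positive real")
  }
  bank <- tryCatch(length(load_templates()), error = function(e) NA_integer_)
  if (!is.na(bank) && cfg$n_labels > bank) {
    stop_config(sprintf("template bank defines %d labels; n_labels = %d requested",
                        bank, cfg$n_labels))
  }
  structure(cfg, class = "siteshift_generator_config")
}

load_templates <- function(n_labels = 12) {
  path <- system.file("extdata", "templates.tsv", package = "siteshift")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  labels <- unique(df$label)
  if (n_labels > length(labels)) {
    stop_config(sprintf("template bank defines %d labels; n_labels = %d requested",
                        length(labels), n_labels))
  }
  labels <- labels[seq_len(n_labels)]
  out <- lapply(labels, function(lb) {
    rows <- df[df$label == lb, ]
    comp <- function(what) {
      r <- rows$alternatives[rows$component == what]
      if (!length(r)) return(list())
      strsplit(strsplit(r, "|", fixed = TRUE)[[1]], " ", fixed = TRUE)
    }
    acr <- rows$alternatives[rows$component == "acronym"]
    acronym <- NULL
    if (length(acr)) {
      kv <- strsplit(acr, "=", fixed = TRUE)[[1]]
      acronym <- list(token = kv[1],
                      expansion = strsplit(kv[2], " ", fixed = TRUE)[[1]])
    }
    list(label = lb, heads = comp("head"), modifiers = comp("modifier"),
         tails = comp("tail"), acronym = acronym)
  })
  stats::setNames(out, labels)
}

template_vocabulary <- function(templates) {
  sort(unique(unlist(lapply(templates, function(t) {
    unlist(c(t$heads, t$modifiers, t$tails))
  }))))
}

institution_suffixes <- function(n) {
  pool <- as.vector(outer(c("z", "x", "q", "v", "w", "j", "k"),
                          c("q", "z", "x", "j", "v", "w", "k"), paste0))
  if (n > length(pool)) stop_config("too many institutions for private suffix pool")
  pool[seq_len(n)]
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, k)
  g / sum(g)
}

resolve_outlier_weights <- function(ov, labels) {
  k <- length(labels)
  if (!is.null(ov$weights)) {
    w <- as.numeric(ov$weights)
    if (length(w) != k || any(w < 0) || sum(w) <= 0) {
      stop_config("outlier 'weights' must be a non-negative vector over all labels")
    }
    return(w / sum(w))
  }
  idx <- if (is.character(ov$labels)) match(ov$labels, labels) else as.integer(ov$labels)
  if (anyNA(idx) || any(idx < 1 | idx > k)) stop_config("unknown outlier labels")
  mass <- ov$mass %||% 0.9
  if (!is_rate(mass)) stop_config("outlier 'mass' must be in [0,1]")
  w <- rep((1 - mass) / (k - length(idx)), k)
  w[idx] <- mass / length(idx)
  w
}

corrupt_token <- function(tok) {
  n <- nchar(tok)
  ch <- strsplit(tok, "")[[1]]
  transposable <- which(ch[-n] != ch[-1])
  if (n >= 4 && length(transposable) && stats::runif(1) < 0.5) {
    i <- transposable[sample.int(length(transposable), 1)]
    ch[c(i, i + 1)] <- ch[c(i + 1, i)]
  } else {
    i <- sample.int(n, 1)
    ch[i] <- sample(setdiff(letters, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

apply_casing <- function(tokens, style) {
  switch(style,
         lower = tokens,
         title = vapply(tokens, function(t) {
           paste0(toupper(substr(t, 1, 1)), substr(t, 2, nchar(t)))
         }, character(1), USE.NAMES = FALSE),
         upper = toupper(tokens),
         mixed = vapply(tokens, function(t) {
           if (stats::runif(1) < 0.3) toupper(t) else t
         }, character(1), USE.NAMES = FALSE))
}

# Analytic per-label content-token distribution: slot marginals of the
# template model, with the institution's private-vocabulary map applied.
expected_word_dist <- function(tmpl, private_map) {
  w <- c()
  add <- function(w, phrases, p_slot) {
    if (!length(phrases)) return(w)
    per <- p_slot / length(phrases)
    for (ph in phrases) for (tok in ph) {
      w[tok] <- (if (tok %in% names(w)) w[[tok]] else 0) + per
    }
    w
  }
  w <- add(w, tmpl$modifiers, MODIFIER_P)
  w <- add(w, tmpl$heads, 1.0)
  w <- add(w, tmpl$tails, TAIL_P)
  toks <- names(w)
  mapped <- ifelse(toks %in% names(private_map),
                   unname(private_map[toks]), toks)
  agg <- tapply(as.numeric(w), mapped, sum)
  stats::setNames(as.numeric(agg) / sum(agg), names(agg))
}

# Build one record's raw text. Returns the rendered text plus misspelling
# bookkeeping (eligible word count, misspelled count, misspelling pairs).
generate_record <- function(tmpl, private_map, config) {
  seg_mod <- character(0)
  if (length(tmpl$modifiers) && stats::runif(1) < MODIFIER_P) {
    seg_mod <- tmpl$modifiers[[sample.int(length(tmpl$modifiers), 1)]]
  }
  seg_head <- tmpl$heads[[sample.int(length(tmpl$heads), 1)]]
  seg_tail <- character(0)
  if (length(tmpl$tails) && stats::runif(1) < TAIL_P) {
    seg_tail <- tmpl$tails[[sample.int(length(tmpl$tails), 1)]]
  }
  privatize <- function(toks) {
    hit <- toks %in% names(private_map)
    toks[hit] <- unname(private_map[toks[hit]])
    toks
  }
  seg_mod <- privatize(seg_mod)
  seg_head <- privatize(seg_head)
  seg_tail <- privatize(seg_tail)

  abbreviated <- FALSE
  if (!is.null(tmpl$acronym) && stats::runif(1) < config$abbreviation_rate) {
    seg_head <- tmpl$acronym$token
    abbreviated <- TRUE
  }

  tokens <- c(seg_mod, seg_head, seg_tail)
  eligible <- grepl("^[a-z]{3,}$", tokens)
  n_words <- sum(eligible)
  miss_from <- character(0); miss_to <- character(0)
  for (j in which(eligible)) {
    if (stats::runif(1) < config$misspell_word_rate) {
      bad <- corrupt_token(tokens[j])
      miss_from <- c(miss_from, bad)
      miss_to <- c(miss_to, tokens[j])
      tokens[j] <- bad
    }
  }

  n_seg <- c(length(seg_mod), length(seg_head), length(seg_tail))
  # stray tokens clinicians leave in: stop words, counts, other billing codes
  if (stats::runif(1) < STOPWORD_INSERT_P) {
    k <- sample.int(2, 1)
    ins <- sample(INSERT_POOL_STOP, k, replace = TRUE)
    for (tok in ins) {
      pos <- sample.int(length(tokens) + 1L, 1) - 1L
      tokens <- append(tokens, tok, after = pos)
    }
  }
  if (stats::runif(1) < DIGIT_INSERT_P) {
    pos <- sample.int(length(tokens) + 1L, 1) - 1L
    tokens <- append(tokens, sample(INSERT_POOL_DIGIT, 1), after = pos)
  }

  style <- sample(c("lower", "title", "upper", "mixed"), 1,
                  prob = c(0.35, 0.35, 0.15, 0.15))
  tokens <- apply_casing(tokens, style)
  if (abbreviated && stats::runif(1) < 0.7) {
    up <- tolower(tokens) == tmpl$acronym$token
    tokens[up] <- toupper(tokens[up])
  }

  text <- paste(tokens, collapse = " ")
  if (n_seg[1] > 0 && stats::runif(1) < 0.3) {
    pat <- sprintf("^((?:\\S+\\s+){%d}\\S+)", n_seg[1] - 1L)
    text <- sub(pat, "\\1,", text)  # comma after the modifier segment
  }
  if (n_seg[3] > 0 && stats::runif(1) < 0.2) {
    tail_txt <- paste(utils::tail(tokens, n_seg[3]), collapse = " ")
    head_txt <- paste(utils::head(tokens, length(tokens) - n_seg[3]), collapse = " ")
    text <- paste0(head_txt, " (", tail_txt, ")")
  }
  list(text = text, n_words = n_words,
       n_misspelled = length(miss_from),
       miss_from = miss_from, miss_to = miss_to)
}

#' Generate a synthetic multi-institution corpus
#'
#' Deterministic given the config: the same config always yields a
#' byte-identical corpus. Returns the corpus together with the ground truth
#' that generated it (per-institution label distributions, per-label content
#' word distributions, and the noise lexicons), enabling parameter-recovery
#' checks of the divergence estimators.
#'
#' @param config a [generator_config()].
#' @return list with elements `corpus` (a [as_corpus()] object carrying noise
#'   metadata in `attr(corpus, "noise")`) and `truth` (class
#'   `siteshift_ground_truth`: `label_dist` institution-by-label matrix,
#'   `word_dists[[institution]][[label]]` named probability vectors,
#'   `private_maps`, `misspelling_map`, `abbreviation_map`, `vocabulary`).
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "siteshift_generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  templates <- load_templates(config$n_labels)
  labels <- names(templates)
  insts <- sprintf("inst%02d", seq_len(config$n_institutions))
  suffixes <- institution_suffixes(config$n_institutions)
  vocab <- template_vocabulary(templates)

  res <- with_seed(config$seed, {
    label_dist <- t(vapply(seq_along(insts), function(i) {
      rdirichlet1(length(labels), config$label_concentration)
    }, numeric(length(labels))))
    dimnames(label_dist) <- list(insts, labels)
    for (ov in config$outlier_institutions) {
      i <- as.integer(ov$institution)
      if (is.na(i) || i < 1 || i > length(insts)) {
        stop_config("bad outlier institution index")
      }
      label_dist[i, ] <- resolve_outlier_weights(ov, labels)
    }

    private_maps <- stats::setNames(lapply(seq_along(insts), function(i) {
      is_priv <- stats::runif(length(vocab)) < config$private_vocab_fraction
      stats::setNames(paste0(vocab[is_priv], suffixes[i]), vocab[is_priv])
    }), insts)

    word_dists <- stats::setNames(lapply(insts, function(id) {
      lapply(templates, expected_word_dist, private_map = private_maps[[id]])
    }), insts)

    all_from <- character(0); all_to <- character(0)
    rows <- vector("list", length(insts))
    noise <- vector("list", length(insts))
    for (i in seq_along(insts)) {
      n <- config$records_per_institution
      lab_idx <- sample.int(length(labels), n, replace = TRUE,
                            prob = label_dist[i, ])
      texts <- character(n); nw <- integer(n); nm <- integer(n)
      for (r in seq_len(n)) {
        rec <- generate_record(templates[[lab_idx[r]]],
                               private_maps[[i]], config)
        texts[r] <- rec$text
        nw[r] <- rec$n_words
        nm[r] <- rec$n_misspelled
        if (rec$n_misspelled) {
          all_from <- c(all_from, rec$miss_from)
          all_to <- c(all_to, rec$miss_to)
        }
      }
      ids <- sprintf("%s#%06d", insts[i], seq_len(n))
      rows[[i]] <- tibble::tibble(record_id = ids, institution_id = insts[i],
                                  text = texts, label = labels[lab_idx])
      noise[[i]] <- tibble::tibble(record_id = ids, n_words = nw,
                                   n_misspelled = nm)
    }
    list(records = dplyr::bind_rows(rows), noise = dplyr::bind_rows(noise),
         label_dist = label_dist, word_dists = word_dists,
         private_maps = private_maps,
         miss_from = all_from, miss_to = all_to)
  })

  corpus <- as_corpus(res$records, labels = labels)
  attr(corpus, "noise") <- res$noise

  keep <- !duplicated(res$miss_from) & !(res$miss_from %in% vocab)
  abbrev <- list()
  for (t in templates) {
    if (!is.null(t$acronym)) abbrev[[t$acronym$token]] <- t$acronym$expansion
  }
  truth <- structure(list(
    label_dist = res$label_dist,
    word_dists = res$word_dists,
    private_maps = res$private_maps,
    misspelling_map = stats::setNames(res$miss_to[keep], res$miss_from[keep]),
    abbreviation_map = abbrev,
    vocabulary = vocab,
    config = config
  ), class = "siteshift_ground_truth")

  list(corpus = corpus, truth = truth)
}

#' Misspelling rates of a generated corpus
#'
#' Computed from the generation metadata that records, per record, how many
#' word tokens were eligible for corruption and how many were corrupted —
#' the synthetic analogue of running a spell checker over a registry and
#' reporting the share of misspelled words and of records containing at
#' least one misspelling.
#'
#' @param corpus a corpus produced by [generate_corpus()].
#' @return list with `word_rate` (misspelled / eligible word tokens) and
#'   `record_rate` (fraction of records with >= 1 misspelling).
#' @export
corpus_misspelling_stats <- function(corpus) {
  noise <- attr(corpus, "noise")
  if (is.null(noise)) {
    stop_data("corpus has no generation metadata; misspelling stats need a generated corpus")
  }
  total <- sum(noise$n_words)
  list(word_rate = if (total == 0) 0 else sum(noise$n_misspelled) / total,
       record_rate = mean(noise$n_misspelled > 0))
}
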