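PREPROCESS_LEVELS <- c("minimal", "spell", "maximal")

NUMBER_WORDS <- c("1" = "one", "2" = "two", "3" = "three", "4" = "four",
                  "5" = "five", "6" = "six", "7" = "seven", "8" = "eight",
                  "9" = "nine", "10" = "ten")

normalize_level <- function(level) {
  level <- tolower(level)
  if (level == "cspell") level <- "spell"
  if (!level %in% PREPROCESS_LEVELS) {
    stop_config(sprintf("unknown preprocessing level '%s'", level))
  }
  level
}

#' Lexicons for clinical text preprocessing
#'
#' Bundles the resources the three preprocessing levels rely on: a stop-word
#' list, a curated misspelling dictionary, an acronym-expansion map, and a
#' reference word list used for edit-distance spelling correction. The
#' packaged defaults are small TSV files (`stopwords.tsv`: one token per
#' line; `misspellings.tsv`: wrong TAB right; `abbreviations.tsv`: acronym
#' TAB space-joined expansion) that users can replace with institution- or
#' UMLS-derived tables.
#'
#' @param dir directory holding the three TSV files; defaults to the
#'   packaged lexicons.
#' @param extra_words additional reference words (e.g. a corpus' known-good
#'   vocabulary) appended to the word list.
#' @return A `siteshift_lexicons` object.
#' @export
load_lexicons <- function(dir = system.file("extdata", "lexicons",
                                            package = "siteshift"),
                          extra_words = character(0)) {
  read_col <- function(f) readLines(file.path(dir, f), warn = FALSE)
  read_map <- function(f) {
    lines <- read_col(f)
    lines <- lines[nzchar(trimws(lines))]
    kv <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, character(1), 2),
                    vapply(kv, `[`, character(1), 1))
  }
  stopwords <- read_col("stopwords.tsv")
  stopwords <- stopwords[nzchar(trimws(stopwords))]
  miss <- read_map("misspellings.tsv")
  abbr_flat <- read_map("abbreviations.tsv")
  abbreviations <- lapply(abbr_flat, function(x) strsplit(x, " ", fixed = TRUE)[[1]])
  bad <- vapply(abbreviations, function(x) {
    any(grepl("[[:upper:][:punct:]]", x))
  }, logical(1))
  if (any(bad)) stop_config("abbreviation expansions must be lowercase and punctuation-free")

  tmpl_words <- tryCatch(template_vocabulary(load_templates(12)), error = function(e) character(0))
  wordlist <- unique(c(tmpl_words, unname(miss), names(abbreviations),
                       unlist(abbreviations), stopwords, unname(NUMBER_WORDS),
                       extra_words))
  structure(list(stopwords = stopwords, misspellings = miss,
                 abbreviations = abbreviations, wordlist = wordlist,
                 .cache = new.env(parent = emptyenv())),
            class = "siteshift_lexicons")
}

#' Lexicons matched to a generated corpus
#'
#' Builds preprocessing lexicons whose reference word list is the generating
#' vocabulary of a synthetic corpus (shared and institution-private variants,
#' acronyms and their expansions), mimicking a domain lexicon that knows the
#' field's legitimate terms but not the corpus' typos.
#'
#' @param truth ground truth returned by [generate_corpus()].
#' @return A `siteshift_lexicons` object.
#' @export
lexicons_for_truth <- function(truth) {
  stopifnot(inherits(truth, "siteshift_ground_truth"))
  lex <- load_lexicons()
  lex$abbreviations <- utils::modifyList(lex$abbreviations, truth$abbreviation_map)
  priv <- unlist(lapply(truth$private_maps, unname), use.names = FALSE)
  lex$wordlist <- unique(c(lex$wordlist, truth$vocabulary, priv,
                           names(truth$abbreviation_map),
                           unlist(truth$abbreviation_map)))
  lex$.cache <- new.env(parent = emptyenv())
  lex
}

tokenize_raw <- function(text) {
  text <- tolower(text)
  text <- gsub("(?<=[0-9]),(?=[0-9])", "", text, perl = TRUE)  # 27,447 -> 27447
  text <- gsub("[^a-z0-9]+", " ", text)
  toks <- strsplit(trimws(text), " +")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Preprocess procedure text
#'
#' Three strictly cumulative levels:
#' * `"minimal"` — lowercase, strip punctuation (digit-grouping commas are
#'   deleted so `27,447` stays one token), collapse whitespace, drop stop
#'   words, and convert standalone integers 1–10 to words.
#' * `"spell"` — minimal, then correct each token absent from the reference
#'   word list: a curated-dictionary hit wins, otherwise the unique reference
#'   word within one edit (substitution, insertion, deletion, or adjacent
#'   transposition); ambiguous or distant tokens are left unchanged.
#' * `"maximal"` — spell, then replace acronyms with their expansion word
#'   sequence.
#'
#' @param text character vector of raw texts.
#' @param level one of `"minimal"`, `"spell"` (alias `"cspell"`), `"maximal"`.
#' @param lexicons a [load_lexicons()] object.
#' @return list of token character vectors, one per input text.
#' @export
preprocess_corpus_text <- function(text, level, lexicons) {
  level <- normalize_level(level)
  toks <- tokenize_raw(text)
  sw <- lexicons$stopwords
  toks <- lapply(toks, function(t) {
    t <- t[!t %in% sw]
    num <- t %in% names(NUMBER_WORDS)
    t[num] <- NUMBER_WORDS[t[num]]
    t
  })
  if (level == "minimal") return(toks)
  toks <- correct_tokens(toks, lexicons)
  # a corrected token can land on a stop word (e.g. a typo of "with");
  # it is removed again so every level honors the minimal contract
  toks <- lapply(toks, function(t) t[!t %in% sw])
  if (level == "spell") return(toks)
  expand_tokens(toks, lexicons)
}

#' @rdname preprocess_corpus_text
#' @export
preprocess_minimal <- function(text, lexicons) {
  preprocess_corpus_text(text, "minimal", lexicons)[[1]]
}

#' @rdname preprocess_corpus_text
#' @export
preprocess_spell <- function(text, lexicons) {
  preprocess_corpus_text(text, "spell", lexicons)[[1]]
}

#' @rdname preprocess_corpus_text
#' @export
preprocess_maximal <- function(text, lexicons) {
  preprocess_corpus_text(text, "maximal", lexicons)[[1]]
}

# All single-edit variants of a word (Damerau: substitution, deletion,
# insertion, adjacent transposition).
edits1 <- function(word) {
  ch <- strsplit(word, "")[[1]]
  n <- length(ch)
  out <- character(0)
  if (n > 1) {
    out <- c(out, vapply(seq_len(n), function(i) {
      paste(ch[-i], collapse = "")
    }, character(1)))
    out <- c(out, vapply(seq_len(n - 1), function(i) {
      v <- ch; v[c(i, i + 1)] <- v[c(i + 1, i)]; paste(v, collapse = "")
    }, character(1)))
  }
  for (i in seq_len(n)) {
    pre <- if (i > 1) paste(ch[seq_len(i - 1)], collapse = "") else ""
    post <- if (i < n) paste(ch[seq.int(i + 1, n)], collapse = "") else ""
    out <- c(out, paste0(pre, letters, post))
  }
  for (i in 0:n) {
    pre <- if (i > 0) paste(ch[seq_len(i)], collapse = "") else ""
    post <- if (i < n) paste(ch[seq.int(i + 1, n)], collapse = "") else ""
    out <- c(out, paste0(pre, letters, post))
  }
  unique(out)
}

correct_one <- function(tok, lexicons) {
  if (!grepl("^[a-z]+$", tok) || tok %in% lexicons$wordlist) return(tok)
  hit <- lexicons$misspellings[tok]
  if (!is.na(hit)) return(unname(hit))
  cand <- unique(intersect(edits1(tok), lexicons$wordlist))
  if (length(cand) == 1L) cand else tok
}

correct_tokens <- function(toks, lexicons) {
  cache <- lexicons$.cache
  lapply(toks, function(t) {
    vapply(t, function(tok) {
      key <- paste0("c_", tok)
      got <- cache[[key]]
      if (is.null(got)) {
        got <- correct_one(tok, lexicons)
        cache[[key]] <- got
      }
      got
    }, character(1), USE.NAMES = FALSE)
  })
}

expand_tokens <- function(toks, lexicons) {
  abbr <- lexicons$abbreviations
  lapply(toks, function(t) {
    if (!any(t %in% names(abbr))) return(t)
    unlist(lapply(t, function(tok) abbr[[tok]] %||% tok), use.names = FALSE)
  })
}

#' Institutional vocabulary
#'
#' The set of unique word tokens appearing in one institution's procedure
#' texts after a given preprocessing level.
#'
#' @param corpus a corpus.
#' @param institution_id institution to extract.
#' @inheritParams preprocess_corpus_text
#' @return A `siteshift_vocabulary`: list with `institution_id`, `tokens`
#'   (sorted unique tokens) and `level`.
#' @export
institution_vocabulary <- function(corpus, institution_id, level, lexicons) {
  recs <- institution_records(corpus, institution_id)
  toks <- preprocess_corpus_text(recs$text, level, lexicons)
  structure(list(institution_id = institution_id,
                 tokens = sort(unique(unlist(toks))),
                 level = normalize_level(level)),
            class = "siteshift_vocabulary")
}
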