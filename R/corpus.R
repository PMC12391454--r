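#' Multi-institution procedure-text corpora
#'
#' A corpus is a tibble of procedure records — one row per
#' `(institution_id, text, label)` triple — carrying the global label set
#' and, for generated corpora, noise metadata as attributes. Labels play the
#' role of procedure (CPT-style) billing codes; every institution draws its
#' labels from one shared label set, mirroring registry studies that restrict
#' to codes billed at all sites.
#'
#' @param records data frame with character columns `institution_id`, `text`,
#'   `label`. A `record_id` column is added if absent.
#' @param labels character vector giving the global label set; defaults to the
#'   labels observed in `records`.
#' @return A `siteshift_corpus`: a tibble with columns `record_id`,
#'   `institution_id`, `text`, `label`.
#' @export
as_corpus <- function(records, labels = NULL) {
  records <- tibble::as_tibble(records)
  need <- c("institution_id", "text", "label")
  if (!all(need %in% names(records))) {
    stop_data(paste0("corpus needs columns: ", paste(need, collapse = ", ")))
  }
  records$institution_id <- as.character(records$institution_id)
  records$text <- as.character(records$text)
  records$label <- as.character(records$label)
  if (!"record_id" %in% names(records)) {
    records$record_id <- sprintf("%s#%06d", records$institution_id,
                                 seq_len(nrow(records)))
  }
  records <- records[, c("record_id", "institution_id", "text", "label")]
  labels <- sort(unique(labels %||% records$label))
  structure(records,
            labels = labels,
            class = c("siteshift_corpus", class(records)))
}

#' @export
print.siteshift_corpus <- function(x, ...) {
  cat(sprintf("<siteshift_corpus> %d records, %d institutions, %d labels\n",
              nrow(x), length(unique(x$institution_id)),
              length(attr(x, "labels"))))
  NextMethod()
}

#' Global label set and institution ids of a corpus
#' @param corpus a corpus.
#' @return character vector of labels / sorted institution ids.
#' @export
corpus_labels <- function(corpus) attr(corpus, "labels")

#' @rdname corpus_labels
#' @export
corpus_institutions <- function(corpus) sort(unique(corpus$institution_id))

#' Subset a corpus by row index or logical mask, keeping the global label set
#' @param corpus a corpus.
#' @param idx integer or logical row index.
#' @return A corpus with the same label set attribute.
#' @export
corpus_subset <- function(corpus, idx) {
  out <- corpus[idx, , drop = FALSE]
  attr(out, "labels") <- attr(corpus, "labels")
  noise <- attr(corpus, "noise")
  if (!is.null(noise)) {
    attr(out, "noise") <- noise[noise$record_id %in% out$record_id, , drop = FALSE]
  }
  class(out) <- class(corpus)
  out
}

institution_records <- function(corpus, institution_id) {
  if (!institution_id %in% corpus$institution_id) {
    stop_data(sprintf("unknown institution '%s'", institution_id))
  }
  corpus_subset(corpus, corpus$institution_id == institution_id)
}

#' Read and write corpora as JSONL or CSV
#'
#' JSONL holds one record object per line with keys `institution_id`, `text`,
#' `label` (and `record_id` when present); CSV uses the same columns.
#'
#' @param corpus a [as_corpus()] object.
#' @param path file path; format chosen by extension (`.jsonl`/`.json` vs
#'   `.csv`).
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` returns
#'   a corpus.
#' @export
write_corpus <- function(corpus, path) {
  df <- as.data.frame(corpus)[, c("record_id", "institution_id", "text", "label")]
  if (grepl("\\.csv$", path)) {
    readr::write_csv(df, path)
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("cannot read corpus file '%s'", path))
  if (grepl("\\.csv$", path)) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
    df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  as_corpus(df)
}

#' Validate a corpus against the study's inclusion rules
#'
#' Applies the registry-style exclusions: records with empty text or a missing
#' label are dropped, then labels are restricted to those present at every
#' institution. Because dropping records can itself un-share labels (an
#' institution may lose its last record of some label), the shared-label
#' filter is iterated to a fixpoint.
#'
#' @param corpus a corpus or a path readable by [read_corpus()].
#' @return list with `corpus` (surviving records), `dropped` (named counts per
#'   rule: `empty_text`, `empty_label`, `unshared_label`) and
#'   `dropped_by_institution`.
#' @export
validate_corpus <- function(corpus) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  dropped <- c(empty_text = 0L, empty_label = 0L, unshared_label = 0L)
  bad_text <- is.na(corpus$text) | !nzchar(trimws(corpus$text))
  bad_label <- is.na(corpus$label) | !nzchar(trimws(corpus$label))
  dropped["empty_text"] <- sum(bad_text)
  dropped["empty_label"] <- sum(bad_label & !bad_text)
  by_inst <- table(corpus$institution_id[bad_text | (bad_label & !bad_text)])
  keep <- corpus_subset(corpus, !(bad_text | bad_label))

  repeat {
    insts <- unique(keep$institution_id)
    shared <- Reduce(intersect, lapply(split(keep$label, keep$institution_id), unique))
    drop <- !(keep$label %in% shared)
    if (!any(drop)) break
    dropped["unshared_label"] <- dropped["unshared_label"] + sum(drop)
    t2 <- table(keep$institution_id[drop])
    for (nm in names(t2)) by_inst[nm] <- (if (nm %in% names(by_inst)) by_inst[nm] else 0L) + t2[nm]
    keep <- corpus_subset(keep, !drop)
  }
  if (nrow(keep) == 0L) stop_data("no records survive validation")
  attr(keep, "labels") <- sort(unique(keep$label))
  list(corpus = keep, dropped = as.list(dropped),
       dropped_by_institution = as.list(by_inst))
}
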