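EXPERIMENT_DESIGNS <- c("pairwise", "pooled_8020", "loio_holdout")

#' Plan for a model-generalizability experiment
#'
#' Three designs mirror the usual multi-site evaluation questions:
#' * `"pairwise"` — one model per institution per preprocessing level,
#'   evaluated on every other institution's full data; the self cell uses
#'   k-fold cross-validation so no record is scored by a model that saw it.
#' * `"pooled_8020"` — one model on a combined 80% of every institution's
#'   data, tested on the remaining 20%, repeated as k folds.
#' * `"loio_holdout"` — leave-one-institution-out: train on all but one
#'   institution, test on the held-out one.
#'
#' @param design one of `r paste0('"', EXPERIMENT_DESIGNS, '"', collapse = ", ")`.
#' @param levels preprocessing levels to run.
#' @param cv_folds folds for self-evaluation and pooled splits (>= 2).
#' @param seed experiment seed; all fold assignments and model seeds derive
#'   from it.
#' @param self_cells for the pairwise design, whether to compute the
#'   cross-validated self cells (skipping them leaves transfer cells only).
#' @return A `siteshift_experiment_plan`.
#' @export
experiment_plan <- function(design = "pairwise", levels = "minimal",
                            cv_folds = 5, seed = 1L, self_cells = TRUE) {
  design <- match.arg(design, EXPERIMENT_DESIGNS)
  levels <- vapply(levels, normalize_level, character(1), USE.NAMES = FALSE)
  if (!is_count(cv_folds) || cv_folds < 2) stop_config("'cv_folds' must be >= 2")
  structure(list(design = design, levels = levels,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 self_cells = isTRUE(self_cells)),
            class = "siteshift_experiment_plan")
}

new_result_table <- function(rows, design, models = list()) {
  rows <- dplyr::bind_rows(rows)
  rows <- dplyr::mutate(rows, design = design, .before = 1)
  structure(rows, models = models,
            class = c("siteshift_result_table", class(rows)))
}

assert_no_leakage <- function(model, test_ids) {
  if (length(intersect(model$train_ids, test_ids))) {
    rlang::abort("train/test leakage: evaluated record present in training fingerprint",
                 class = "siteshift_internal_error")
  }
}

# Stratified fold labels: within each stratum, records are shuffled and dealt
# round-robin so fold sizes differ by at most one per stratum.
stratified_folds <- function(strata, k, seed) {
  with_seed(seed, {
    fold <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      base <- rep_len(seq_len(k), length(idx))
      rot <- sample.int(k, 1)  # rotate so remainders do not pile on fold 1
      vals <- ((base + rot - 2L) %% k) + 1L
      # sample(x) on a length-1 vector would permute 1:x instead
      fold[idx] <- vals[sample.int(length(vals))]
    }
    fold
  })
}

check_min_records <- function(corpus, k) {
  sizes <- table(corpus$institution_id)
  if (any(sizes < k)) {
    stop_config(sprintf("institutions with fewer than %d records: %s", k,
                        paste(names(sizes)[sizes < k], collapse = ", ")))
  }
}

#' Run the all-pairs single-institution transfer design
#'
#' For each preprocessing level, trains one model per institution on that
#' institution's entire data and evaluates it on every other institution's
#' full data. The self cell is the mean over `cv_folds` stratified
#' cross-validation folds (per-fold rows are kept in
#' `attr(result, "self_folds")`).
#'
#' @param corpus a validated corpus with >= 2 institutions.
#' @param plan an [experiment_plan()].
#' @param spec a [classifier_spec()]; its seed is re-derived per model from
#'   the plan seed.
#' @param lexicons preprocessing lexicons.
#' @return A `siteshift_result_table` (tidy rows: design, level, train_id,
#'   test_id, fold, self, accuracy, micro_f1, n_test).
#' @export
run_pairwise <- function(corpus, plan = experiment_plan("pairwise"),
                         spec = classifier_spec(),
                         lexicons = load_lexicons()) {
  insts <- corpus_institutions(corpus)
  if (length(insts) < 2) stop_config("pairwise design needs >= 2 institutions")
  check_min_records(corpus, plan$cv_folds)
  rows <- list(); fold_rows <- list(); models <- list()
  for (level in plan$levels) {
    tokens <- preprocess_corpus_text(corpus$text, level, lexicons)
    for (inst in insts) {
      idx <- which(corpus$institution_id == inst)
      mspec <- spec
      mspec$seed <- derive_seed(plan$seed, paste("pairwise", level, inst))
      model <- train_cpt_model(corpus_subset(corpus, idx), mspec, level,
                               lexicons, tokens = tokens[idx])
      models[[paste(level, inst, sep = "/")]] <- model$fingerprint
      for (other in setdiff(insts, inst)) {
        jdx <- which(corpus$institution_id == other)
        assert_no_leakage(model, corpus$record_id[jdx])
        rows[[length(rows) + 1L]] <-
          evaluate_model(model, corpus_subset(corpus, jdx), lexicons,
                         train_id = inst, test_id = other,
                         tokens = tokens[jdx], self = FALSE)
      }
      if (!isTRUE(plan$self_cells %||% TRUE)) next
      fold <- stratified_folds(corpus$label[idx], plan$cv_folds,
                               derive_seed(plan$seed, paste("folds", level, inst)))
      per_fold <- lapply(seq_len(plan$cv_folds), function(f) {
        tr <- idx[fold != f]; te <- idx[fold == f]
        fspec <- spec
        fspec$seed <- derive_seed(plan$seed, paste("cv", level, inst, f))
        fm <- train_cpt_model(corpus_subset(corpus, tr), fspec, level,
                              lexicons, tokens = tokens[tr])
        assert_no_leakage(fm, corpus$record_id[te])
        evaluate_model(fm, corpus_subset(corpus, te), lexicons,
                       train_id = inst, test_id = inst,
                       tokens = tokens[te], self = TRUE, fold = f)
      })
      per_fold <- dplyr::bind_rows(per_fold)
      per_fold$level <- level
      fold_rows[[length(fold_rows) + 1L]] <- per_fold
      rows[[length(rows) + 1L]] <-
        eval_result(inst, inst, level, mean(per_fold$accuracy),
                    mean(per_fold$micro_f1), sum(per_fold$n_test),
                    self = TRUE)
    }
  }
  out <- new_result_table(rows, "pairwise", models)
  attr(out, "self_folds") <- dplyr::bind_rows(fold_rows)
  out
}

#' Run the pooled 80:20 combined-data design
#'
#' Records are dealt into `cv_folds` folds stratified by institution and
#' label; each fold in turn is the combined 20% test set for a model trained
#' on the other 80%, and test metrics are reported per institution per fold.
#'
#' @inheritParams run_pairwise
#' @return A `siteshift_result_table` with `train_id = "pooled"` rows.
#' @export
run_pooled_8020 <- function(corpus, plan = experiment_plan("pooled_8020"),
                            spec = classifier_spec(),
                            lexicons = load_lexicons()) {
  insts <- corpus_institutions(corpus)
  if (length(insts) < 2) stop_config("pooled design needs >= 2 institutions")
  check_min_records(corpus, plan$cv_folds)
  rows <- list(); models <- list()
  for (level in plan$levels) {
    tokens <- preprocess_corpus_text(corpus$text, level, lexicons)
    fold <- stratified_folds(paste(corpus$institution_id, corpus$label),
                             plan$cv_folds,
                             derive_seed(plan$seed, paste("pooled-folds", level)))
    for (f in seq_len(plan$cv_folds)) {
      tr <- which(fold != f)
      mspec <- spec
      mspec$seed <- derive_seed(plan$seed, paste("pooled", level, f))
      model <- train_cpt_model(corpus_subset(corpus, tr), mspec, level,
                               lexicons, tokens = tokens[tr])
      models[[paste(level, "pooled", f, sep = "/")]] <- model$fingerprint
      for (inst in insts) {
        te <- which(fold == f & corpus$institution_id == inst)
        assert_no_leakage(model, corpus$record_id[te])
        rows[[length(rows) + 1L]] <-
          evaluate_model(model, corpus_subset(corpus, te), lexicons,
                         train_id = "pooled", test_id = inst,
                         tokens = tokens[te], self = FALSE, fold = f)
      }
    }
  }
  new_result_table(rows, "pooled_8020", models)
}

#' Run the leave-one-institution-out holdout design
#'
#' One model per institution, trained on all other institutions' full data
#' and evaluated on the held-out institution.
#'
#' @inheritParams run_pairwise
#' @return A `siteshift_result_table` with `train_id = "all_but_<inst>"` rows.
#' @export
run_loio_holdout <- function(corpus, plan = experiment_plan("loio_holdout"),
                             spec = classifier_spec(),
                             lexicons = load_lexicons()) {
  insts <- corpus_institutions(corpus)
  if (length(insts) < 3) stop_config("leave-one-institution-out needs >= 3 institutions")
  rows <- list(); models <- list()
  for (level in plan$levels) {
    tokens <- preprocess_corpus_text(corpus$text, level, lexicons)
    for (inst in insts) {
      tr <- which(corpus$institution_id != inst)
      te <- which(corpus$institution_id == inst)
      mspec <- spec
      mspec$seed <- derive_seed(plan$seed, paste("loio", level, inst))
      model <- train_cpt_model(corpus_subset(corpus, tr), mspec, level,
                               lexicons, tokens = tokens[tr])
      models[[paste(level, "loio", inst, sep = "/")]] <- model$fingerprint
      assert_no_leakage(model, corpus$record_id[te])
      rows[[length(rows) + 1L]] <-
        evaluate_model(model, corpus_subset(corpus, te), lexicons,
                       train_id = paste0("all_but_", inst), test_id = inst,
                       tokens = tokens[te], self = FALSE)
    }
  }
  new_result_table(rows, "loio_holdout", models)
}

# institution-level aggregates: self rows as-is; non-self rows averaged per
# training institution (pairwise) or per test institution (combined designs)
institution_aggregates <- function(results) {
  res <- tibble::as_tibble(results)
  agg_key <- function(df) {
    if (unique(df$design) == "pairwise") df$train_id else df$test_id
  }
  res |>
    dplyr::group_by(.data$design, .data$level, .data$self) |>
    dplyr::group_modify(function(df, key) {
      df$institution <- if (key$design == "pairwise") df$train_id else df$test_id
      df |>
        dplyr::group_by(.data$institution) |>
        dplyr::summarise(accuracy = mean(.data$accuracy),
                         micro_f1 = mean(.data$micro_f1), .groups = "drop")
    }) |>
    dplyr::ungroup()
}

#' Summaries and paired level deltas for result tables
#'
#' `result_summary()` reports mean and SD of accuracy and micro-F1 over
#' institution-level aggregates, split by design, level, and self vs
#' non-self. `summarize_deltas()` adds paired preprocessing-level deltas
#' (e.g. maximal minus minimal) computed per institution and then averaged.
#'
#' @param results a `siteshift_result_table` or a list of them (they must
#'   cover the same institutions).
#' @return Tibbles of summary rows.
#' @export
result_summary <- function(results) {
  results <- combine_results(results)
  institution_aggregates(results) |>
    dplyr::group_by(.data$design, .data$level, .data$self) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     mean_micro_f1 = mean(.data$micro_f1),
                     sd_micro_f1 = stats::sd(.data$micro_f1),
                     n_institutions = dplyr::n(), .groups = "drop")
}

#' @rdname result_summary
#' @export
summarize_deltas <- function(results) {
  results <- combine_results(results)
  agg <- institution_aggregates(results)
  levels <- unique(agg$level)
  out <- list()
  for (d in unique(agg$design)) for (sf in unique(agg$self)) {
    sub <- agg[agg$design == d & agg$self == sf, ]
    lv <- intersect(PREPROCESS_LEVELS, unique(sub$level))
    if (length(lv) < 2) next
    for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
      a <- sub[sub$level == lv[j], ]; b <- sub[sub$level == lv[i], ]
      m <- match(a$institution, b$institution)
      if (anyNA(m)) stop_data("mismatched institution sets between levels")
      d_acc <- b$accuracy[m] - a$accuracy
      d_f1 <- b$micro_f1[m] - a$micro_f1
      out[[length(out) + 1L]] <- tibble::tibble(
        design = d, self = sf, level_from = lv[j], level_to = lv[i],
        mean_delta_accuracy = mean(d_acc), sd_delta_accuracy = stats::sd(d_acc),
        mean_delta_micro_f1 = mean(d_f1), sd_delta_micro_f1 = stats::sd(d_f1),
        n_institutions = length(d_acc))
    }
  }
  dplyr::bind_rows(out)
}

combine_results <- function(results) {
  if (inherits(results, "siteshift_result_table") || is.data.frame(results)) {
    return(tibble::as_tibble(results))
  }
  tabs <- lapply(results, tibble::as_tibble)
  insts <- lapply(tabs, function(t) sort(unique(t$test_id)))
  if (length(unique(vapply(insts, paste, character(1), collapse = ","))) > 1) {
    stop_data("result tables cover different institution sets")
  }
  dplyr::bind_rows(tabs)
}
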