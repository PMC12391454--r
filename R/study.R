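#' Configuration for an end-to-end generalizability study
#'
#' Bundles every stage's settings: the synthetic generator (or a path to an
#' external JSONL/CSV corpus), the preprocessing levels, the experiment
#' designs, the classifier spec, divergence settings, and clustering
#' settings. One global seed propagates to every stage through tagged
#' derived seeds.
#'
#' @param generator a [generator_config()], or a file path to an existing
#'   corpus.
#' @param levels preprocessing levels to evaluate.
#' @param designs experiment designs to run.
#' @param classifier a [classifier_spec()].
#' @param divergence list: `epsilon`, `direction`, `strategy` (see
#'   [divergence_matrix()]); divergence matrices are computed at the first
#'   level in `levels`.
#' @param clustering list: `k` (integer or `"auto"` for elbow selection),
#'   `k_range`, `threshold_sd` for outlier flagging.
#' @param seed global study seed.
#' @param out_dir output directory for the report bundle.
#' @return A `siteshift_study_config`.
#' @export
study_config <- function(generator = generator_config(),
                         levels = "minimal",
                         designs = c("pairwise", "pooled_8020", "loio_holdout"),
                         classifier = classifier_spec(),
                         divergence = list(epsilon = 1e-9,
                                           direction = "target_given_source",
                                           strategy = "product"),
                         clustering = list(k = "auto", k_range = 2:25,
                                           threshold_sd = 1.0),
                         seed = 1L,
                         out_dir = tempfile("siteshift_study_")) {
  if (!length(levels)) stop_config("at least one preprocessing level is required")
  if (!length(designs)) stop_config("at least one experiment design is required")
  levels <- vapply(levels, normalize_level, character(1), USE.NAMES = FALSE)
  designs <- vapply(designs, function(d) match.arg(d, EXPERIMENT_DESIGNS),
                    character(1), USE.NAMES = FALSE)
  structure(list(generator = generator, levels = levels, designs = designs,
                 classifier = classifier, divergence = divergence,
                 clustering = clustering, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "siteshift_study_config")
}

stage_marker <- function(out_dir, stage) {
  file.path(out_dir, ".stages", paste0(stage, ".done"))
}

mark_stage <- function(out_dir, stage) {
  dir.create(file.path(out_dir, ".stages"), showWarnings = FALSE, recursive = TRUE)
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage_marker(out_dir, stage))
}

log_stage <- function(stage, seed, t0) {
  message(sprintf("[siteshift] stage=%s seed=%d elapsed=%.1fs",
                  stage, seed, as.numeric(proc.time()[3] - t0)))
}

#' Run a complete generalizability study
#'
#' Generates (or loads and validates) the corpus, runs every configured
#' experiment design at every preprocessing level, computes all five
#' divergence matrices, correlates composite divergence with transfer
#' performance, clusters institutions (k-medoids with elbow selection and a
#' 2-D MDS embedding), flags outliers, and writes the full report bundle to
#' `config$out_dir`: `corpus.jsonl`, `ground_truth.json`, `results.csv`,
#' `summary.json`, per-metric `divergence_<metric>.csv` (+ metadata
#' sidecars), `correlation.json`, `clusters.json`, `embedding.csv`,
#' `outliers.json`, a text `report.txt`, and `manifest.json` with MD5 hashes
#' of every artifact. Stage markers under `.stages/` make an interrupted run
#' resumable at the corpus/experiment boundary. Re-running with the same
#' config and seed reproduces identical numeric outputs.
#'
#' @param config a [study_config()].
#' @return A `siteshift_study_report` list: paths, the result table, the
#'   summaries, correlation, clustering, and outlier objects.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "siteshift_study_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  timings <- list()

  # --- corpus ---
  if (is.character(config$generator)) {
    val <- validate_corpus(config$generator)
    corpus <- val$corpus
    truth <- NULL
    lexicons <- load_lexicons()
  } else {
    gen_cfg <- config$generator
    gen_cfg$seed <- derive_seed(config$seed, "generator")
    gen <- generate_corpus(gen_cfg)
    val <- validate_corpus(gen$corpus)
    corpus <- val$corpus
    truth <- gen$truth
    lexicons <- lexicons_for_truth(truth)
  }
  write_corpus(corpus, file.path(out_dir, "corpus.jsonl"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(label_dist = as.data.frame(truth$label_dist),
           misspelling_map = as.list(truth$misspelling_map),
           abbreviation_map = truth$abbreviation_map,
           config = unclass(truth$config)),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  mark_stage(out_dir, "corpus")
  timings$corpus <- proc.time()[3] - t0
  log_stage("corpus", config$seed, t0)

  # --- experiments ---
  tables <- list()
  for (design in config$designs) {
    plan <- experiment_plan(design, config$levels, seed = derive_seed(config$seed, design))
    runner <- switch(design, pairwise = run_pairwise,
                     pooled_8020 = run_pooled_8020,
                     loio_holdout = run_loio_holdout)
    tables[[design]] <- runner(corpus, plan, config$classifier, lexicons)
    mark_stage(out_dir, paste0("experiment_", design))
  }
  results <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  readr::write_csv(dplyr::mutate(results,
                                 dplyr::across(dplyr::where(is.numeric),
                                               ~ round(.x, 10))),
                   file.path(out_dir, "results.csv"))
  timings$experiments <- proc.time()[3] - timings$corpus - t0
  log_stage("experiments", config$seed, t0)

  # --- divergence matrices ---
  level0 <- config$levels[1]
  dv <- config$divergence
  matrices <- list()
  for (metric in DIVERGENCE_METRICS) {
    m <- divergence_matrix(corpus, metric, level0, lexicons,
                           epsilon = dv$epsilon %||% 1e-9,
                           strategy = dv$strategy %||% "product",
                           direction = dv$direction %||% "target_given_source")
    matrices[[metric]] <- m
    write_divergence_matrix(m, file.path(out_dir, paste0("divergence_", metric, ".csv")))
  }
  mark_stage(out_dir, "divergence")
  log_stage("divergence", config$seed, t0)

  # --- correlation / clustering / outliers (need pairwise results) ---
  correlation <- NULL; clusters <- NULL; outliers <- NULL; intra_inter <- NULL
  if ("pairwise" %in% names(tables)) {
    pw <- tables$pairwise
    correlation <- lapply(
      stats::setNames(nm = c("overlap", "kld_cpt", "kld_word", "kld_composite")),
      function(metric) correlate_divergence(matrices[[metric]], pw, "micro_f1"))
    jsonlite::write_json(
      lapply(correlation, function(cr) {
        list(metric = cr$metric_name, pearson_r = cr$pearson_r,
             r_squared = cr$r_squared, n_pairs = cr$n_pairs,
             per_institution = as.list(cr$per_institution))
      }),
      file.path(out_dir, "correlation.json"), auto_unbox = TRUE, digits = NA)

    dsym <- symmetrize(matrices$kld_composite)
    cl_cfg <- config$clustering
    if (identical(cl_cfg$k %||% "auto", "auto")) {
      sel <- elbow_select_k(dsym, cl_cfg$k_range %||% 2:25,
                            seed = derive_seed(config$seed, "elbow"))
      k <- sel$k; curve <- sel$curve
    } else {
      k <- as.integer(cl_cfg$k); curve <- NULL
    }
    clusters <- kmedoids_fit(dsym, k, seed = derive_seed(config$seed, "pam"))
    emb <- mds_embed(dsym)
    readr::write_csv(tibble::tibble(institution_id = rownames(emb),
                                    x = emb[, "x"], y = emb[, "y"],
                                    cluster = unname(clusters$labels[rownames(emb)])),
                     file.path(out_dir, "embedding.csv"))
    intra_inter <- intra_inter_summary(clusters, pw)
    outliers <- flag_outliers(matrices$kld_composite, clusters,
                              cl_cfg$threshold_sd %||% 1.0)
    jsonlite::write_json(
      list(k = clusters$k, medoid_ids = clusters$medoid_ids,
           labels = as.list(clusters$labels),
           total_within_dissimilarity = clusters$total_within_dissimilarity,
           elbow_curve = curve, intra_inter = intra_inter),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    jsonlite::write_json(outliers, file.path(out_dir, "outliers.json"),
                         auto_unbox = TRUE, digits = NA)
    mark_stage(out_dir, "clustering")
    log_stage("clustering", config$seed, t0)
  }

  # --- summaries, report, manifest ---
  summary_tab <- result_summary(results)
  deltas <- if (length(config$levels) > 1) summarize_deltas(results) else NULL
  jsonlite::write_json(list(summary = summary_tab, level_deltas = deltas,
                            dropped = val$dropped, timings = timings),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(render_report(summary_tab, deltas, correlation, clusters, outliers),
             file.path(out_dir, "report.txt"))

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  files <- files[!startsWith(files, ".stages")]
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(list(files = manifest,
                            seed = config$seed,
                            package_version = as.character(utils::packageVersion("siteshift"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  mark_stage(out_dir, "report")
  log_stage("report", config$seed, t0)

  structure(list(out_dir = out_dir, corpus = corpus, truth = truth,
                 results = results, tables = tables, summary = summary_tab,
                 level_deltas = deltas, matrices = matrices,
                 correlation = correlation, clusters = clusters,
                 intra_inter = intra_inter, outliers = outliers,
                 manifest = manifest),
            class = "siteshift_study_report")
}

render_report <- function(summary_tab, deltas, correlation, clusters, outliers) {
  fmt_pct <- function(m, s) sprintf("%.1f%% [%.1f%%]", 100 * m, 100 * s)
  lines <- c("Model generalizability study", strrep("=", 60), "",
             "Performance by design / level (mean [SD] over institutions)")
  for (i in seq_len(nrow(summary_tab))) {
    r <- summary_tab[i, ]
    lines <- c(lines, sprintf("  %-12s %-8s %-8s acc %s  f1 %.3f [%.3f]",
                              r$design, r$level,
                              ifelse(r$self, "self", "non-self"),
                              fmt_pct(r$mean_accuracy, r$sd_accuracy),
                              r$mean_micro_f1, r$sd_micro_f1))
  }
  if (!is.null(deltas) && nrow(deltas)) {
    lines <- c(lines, "", "Preprocessing level deltas (mean [SD])")
    for (i in seq_len(nrow(deltas))) {
      r <- deltas[i, ]
      lines <- c(lines, sprintf("  %-12s %-8s %s - %s: %+.2f%% [%.2f%%]",
                                r$design, ifelse(r$self, "self", "non-self"),
                                r$level_to, r$level_from,
                                100 * r$mean_delta_accuracy,
                                100 * r$sd_delta_accuracy))
    }
  }
  if (!is.null(correlation)) {
    lines <- c(lines, "", "Divergence vs transfer micro-F1")
    for (cr in correlation) {
      lines <- c(lines, sprintf("  %-14s r = %+.4f  R^2 = %.4f  (n = %d)",
                                cr$metric_name, cr$pearson_r, cr$r_squared,
                                cr$n_pairs))
    }
  }
  if (!is.null(clusters)) {
    lines <- c(lines, "", sprintf("k-medoid clustering: k = %d, medoids: %s",
                                  clusters$k,
                                  paste(clusters$medoid_ids, collapse = ", ")))
  }
  if (!is.null(outliers)) {
    lines <- c(lines, sprintf("Outlier institutions: %s",
                              if (nrow(outliers)) paste(outliers$institution, collapse = ", ")
                              else "none"))
  }
  lines
}
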