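# Shared fixtures. Expensive objects (generated corpora, the demo-scale
# study) are computed once per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small corpus + matched lexicons used by several unit-test files
small_gen <- function(seed = 7, n_institutions = 3, n_labels = 6,
                      records = 200, ...) {
  key <- paste("gen", seed, n_institutions, n_labels, records,
               paste(unlist(list(...)), collapse = "_"), sep = "_")
  cached(key, {
    g <- generate_corpus(generator_config(
      n_institutions = n_institutions, n_labels = n_labels,
      records_per_institution = records, seed = seed, ...))
    g$lexicons <- lexicons_for_truth(g$truth)
    g
  })
}

# quick classifier settings for unit tests on tiny corpora
fast_spec <- function(seed = 1L) {
  classifier_spec(epochs = 12, batch_size = 64, seed = seed)
}

# hand-built corpus from explicit triples
toy_corpus <- function(institution_id, text, label) {
  as_corpus(tibble::tibble(institution_id = institution_id,
                           text = text, label = label))
}

# The demo-scale shifted study (6 institutions x 1500 records, one
# preprocessing level, all three designs) reused by the acceptance tests.
demo_study <- function(run = 1L) {
  cached(paste0("demo_study_", run), {
    out <- file.path(tempdir(), paste0("siteshift_demo_", run))
    run_study(demo_study_config(out))
  })
}

demo_study_config <- function(out_dir) {
  study_config(
    generator = generator_config(),          # the default shifted conditions
    levels = "minimal",
    designs = c("pairwise", "pooled_8020", "loio_holdout"),
    classifier = classifier_spec(),
    clustering = list(k = "auto", k_range = 2:5, threshold_sd = 1.0),
    seed = 101L,
    out_dir = out_dir)
}

# pairwise-only run at the spell level on the demo corpus, for the
# preprocessing-effect comparison
demo_spell_pairwise <- function() {
  cached("demo_spell_pairwise", {
    rep1 <- demo_study(1L)
    lex <- lexicons_for_truth(rep1$truth)
    run_pairwise(rep1$corpus,
                 experiment_plan("pairwise", "spell", seed = 202L,
                                 self_cells = FALSE),
                 classifier_spec(), lex)
  })
}
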