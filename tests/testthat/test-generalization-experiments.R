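# tiny-scale corpus for orchestration checks: 3 institutions, 4 labels
exp_fixture <- function() {
  cached("exp_fixture", {
    g <- generate_corpus(generator_config(
      n_institutions = 3, n_labels = 4, records_per_institution = 120,
      private_vocab_fraction = 0.6, seed = 61))
    list(corpus = g$corpus, truth = g$truth,
         lex = lexicons_for_truth(g$truth))
  })
}

test_that("pairwise design produces the expected cell grid", {
  fx <- exp_fixture()
  res <- cached("pairwise_tiny", {
    run_pairwise(fx$corpus, experiment_plan("pairwise", "minimal", seed = 1),
                 fast_spec(), fx$lex)
  })
  expect_equal(nrow(res), 9L)           # 3 self-CV cells + 6 transfer cells
  expect_equal(sum(res$self), 3L)
  expect_equal(sum(!res$self), 6L)
  expect_setequal(unique(res$train_id), c("inst01", "inst02", "inst03"))
  folds <- attr(res, "self_folds")
  expect_equal(nrow(folds), 3L * 5L)
  expect_true(all(res$micro_f1 == res$accuracy))
})

test_that("vocabulary shift makes self outperform transfer; no shift equalizes", {
  fx <- exp_fixture()
  res <- cached("pairwise_tiny", {
    run_pairwise(fx$corpus, experiment_plan("pairwise", "minimal", seed = 1),
                 fast_spec(), fx$lex)
  })
  expect_gt(mean(res$accuracy[res$self]), mean(res$accuracy[!res$self]) + 0.05)

  # null corpus: two disjoint iid samples of one institution's distribution
  # (byte-duplicating records would put each model's training rows in the
  # other institution's test set and measure memorization, not transfer);
  # sized so the self-CV 80% vs full-data learning-curve gap is negligible
  g <- small_gen(seed = 62, n_institutions = 1, n_labels = 4, records = 1500,
                 private_vocab_fraction = 0)
  half <- tibble::as_tibble(g$corpus)
  half$institution_id <- rep(c("instA", "instB"), length.out = nrow(half))
  null_corpus <- as_corpus(half)
  resn <- run_pairwise(null_corpus,
                       experiment_plan("pairwise", "minimal", seed = 2),
                       fast_spec(), g$lexicons)
  expect_lt(abs(mean(resn$accuracy[resn$self]) -
                  mean(resn$accuracy[!resn$self])), 0.02)
})

test_that("pooled 80:20 splits are stratified and close to the 20% contract", {
  fx <- exp_fixture()
  res <- cached("pooled_tiny", {
    run_pooled_8020(fx$corpus,
                    experiment_plan("pooled_8020", "minimal", seed = 3),
                    fast_spec(), fx$lex)
  })
  expect_equal(nrow(res), 5L * 3L)      # folds x institutions
  per_inst_n <- tapply(res$n_test, res$test_id, sum)
  expect_true(all(per_inst_n == 120L))  # folds partition each institution
  # each fold's test share per institution is 20% up to stratum rounding
  expect_true(all(abs(res$n_test - 24L) <= 4L))
  expect_true(all(res$train_id == "pooled"))
})

test_that("leave-one-institution-out produces one holdout cell per institution", {
  fx <- exp_fixture()
  res <- cached("loio_tiny", {
    run_loio_holdout(fx$corpus,
                     experiment_plan("loio_holdout", "minimal", seed = 4),
                     fast_spec(), fx$lex)
  })
  expect_equal(nrow(res), 3L)
  expect_setequal(res$test_id, c("inst01", "inst02", "inst03"))
  expect_equal(res$train_id, paste0("all_but_", res$test_id))
  expect_true(all(res$n_test == 120L))
})

test_that("combined-data designs beat single-institution transfer under shift", {
  fx <- exp_fixture()
  pw <- cached("pairwise_tiny", {
    run_pairwise(fx$corpus, experiment_plan("pairwise", "minimal", seed = 1),
                 fast_spec(), fx$lex)
  })
  po <- cached("pooled_tiny", {
    run_pooled_8020(fx$corpus,
                    experiment_plan("pooled_8020", "minimal", seed = 3),
                    fast_spec(), fx$lex)
  })
  lo <- cached("loio_tiny", {
    run_loio_holdout(fx$corpus,
                     experiment_plan("loio_holdout", "minimal", seed = 4),
                     fast_spec(), fx$lex)
  })
  for (inst in corpus_institutions(fx$corpus)) {
    transfer <- mean(pw$accuracy[!pw$self & pw$test_id == inst])
    expect_gt(mean(po$accuracy[po$test_id == inst]), transfer)
    expect_gt(lo$accuracy[lo$test_id == inst], transfer)
  }
})

test_that("experiment plans and small institutions are validated", {
  fx <- exp_fixture()
  expect_error(experiment_plan("bootstrap"), "arg")
  expect_error(experiment_plan("pairwise", cv_folds = 1),
               class = "siteshift_config_error")
  tiny <- corpus_subset(fx$corpus, c(1:3, which(fx$corpus$institution_id != "inst01")))
  expect_error(run_pairwise(tiny, experiment_plan("pairwise", seed = 1),
                            fast_spec(), fx$lex),
               class = "siteshift_config_error")
  one_inst <- corpus_subset(fx$corpus, fx$corpus$institution_id == "inst01")
  expect_error(run_pairwise(one_inst, experiment_plan("pairwise", seed = 1),
                            fast_spec(), fx$lex),
               class = "siteshift_config_error")
  expect_error(run_loio_holdout(
    corpus_subset(fx$corpus, fx$corpus$institution_id != "inst01"),
    experiment_plan("loio_holdout", seed = 1), fast_spec(), fx$lex),
    class = "siteshift_config_error")
})

test_that("no evaluated record appears in its model's training fingerprint", {
  fx <- exp_fixture()
  model <- train_cpt_model(
    corpus_subset(fx$corpus, fx$corpus$institution_id == "inst01"),
    fast_spec(), "minimal", fx$lex)
  expect_error(siteshift:::assert_no_leakage(model, fx$corpus$record_id[1]),
               class = "siteshift_internal_error")
  expect_silent(siteshift:::assert_no_leakage(
    model, fx$corpus$record_id[fx$corpus$institution_id == "inst02"]))
})

test_that("summaries and level deltas reproduce hand arithmetic", {
  mk <- function(train, test, level, acc, self) {
    siteshift:::eval_result(train, test, level, acc, acc, 10, self = self)
  }
  rows <- dplyr::bind_rows(
    mk("i1", "i1", "minimal", 0.90, TRUE), mk("i1", "i2", "minimal", 0.70, FALSE),
    mk("i2", "i2", "minimal", 0.80, TRUE), mk("i2", "i1", "minimal", 0.60, FALSE),
    mk("i1", "i1", "spell", 0.92, TRUE), mk("i1", "i2", "spell", 0.71, FALSE),
    mk("i2", "i2", "spell", 0.78, TRUE), mk("i2", "i1", "spell", 0.63, FALSE))
  rows$design <- "pairwise"
  summ <- result_summary(rows)
  nonself_min <- summ[!summ$self & summ$level == "minimal", ]
  expect_equal(nonself_min$mean_accuracy, mean(c(0.70, 0.60)))
  expect_equal(nonself_min$sd_accuracy, sd(c(0.70, 0.60)))
  self_min <- summ[summ$self & summ$level == "minimal", ]
  expect_equal(self_min$mean_accuracy, 0.85)

  deltas <- summarize_deltas(rows)
  d_nonself <- deltas[!deltas$self, ]
  expect_equal(d_nonself$level_from, "minimal")
  expect_equal(d_nonself$level_to, "spell")
  expect_equal(d_nonself$mean_delta_accuracy, mean(c(0.71 - 0.70, 0.63 - 0.60)))
  expect_equal(d_nonself$sd_delta_accuracy, sd(c(0.01, 0.03)))
  d_self <- deltas[deltas$self, ]
  expect_equal(d_self$mean_delta_accuracy, mean(c(0.02, -0.02)))

  # identical tables -> zero deltas
  rows2 <- rows
  rows2$level[rows2$level == "spell"] <- "maximal"
  rows2$accuracy[rows2$level == "maximal"] <- rows2$accuracy[rows2$level == "minimal"]
  rows2$micro_f1 <- rows2$accuracy
  d0 <- summarize_deltas(rows2)
  expect_true(all(abs(d0$mean_delta_accuracy) < 1e-12))
})

test_that("mismatched institution sets are rejected when combining tables", {
  fx <- exp_fixture()
  lo <- cached("loio_tiny", {
    run_loio_holdout(fx$corpus,
                     experiment_plan("loio_holdout", "minimal", seed = 4),
                     fast_spec(), fx$lex)
  })
  other <- tibble::as_tibble(lo)
  other$test_id <- paste0("x_", other$test_id)
  expect_error(result_summary(list(lo, other)), class = "siteshift_data_error")
})
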