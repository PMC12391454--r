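# distance matrix with planted groups: tight within, far between
planted_distance <- function(sizes, seed, within = 0.1, between = 1.0) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  set.seed(seed)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    base <- if (grp[i] == grp[j]) within else between
    d[i, j] <- d[j, i] <- base + runif(1, 0, 0.05)
  }
  dimnames(d) <- list(paste0("i", 1:n), paste0("i", 1:n))
  d
}

brute_force_best <- function(d, k) {
  combos <- utils::combn(nrow(d), k)
  costs <- apply(combos, 2, function(m) sum(apply(d[, m, drop = FALSE], 1, min)))
  min(costs)
}

test_that("correlation report matches closed-form Pearson computation", {
  m <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  attr(m, "metric") <- "kld_composite"
  mk <- function(train, test, acc) {
    siteshift:::eval_result(train, test, "minimal", acc, acc, 10)
  }
  # performance exactly linear in divergence -> r = -1
  res <- dplyr::bind_rows(
    mk("a", "b", 0.9 - 0.1 * 1), mk("a", "c", 0.9 - 0.1 * 2),
    mk("b", "a", 0.9 - 0.1 * 3), mk("b", "c", 0.9 - 0.1 * 4),
    mk("c", "a", 0.9 - 0.1 * 5), mk("c", "b", 0.9 - 0.1 * 6))
  rep <- correlate_divergence(m, res, "accuracy")
  expect_equal(rep$pearson_r, -1, tolerance = 1e-12)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)
  expect_equal(rep$n_pairs, 6L)
  expect_equal(rep$r_squared, rep$pearson_r^2, tolerance = 1e-14)
  expect_length(rep$per_institution, 3)

  # textbook formula on five hand-entered pairs
  x <- c(1, 2, 3, 4, 6); yv <- c(0.9, 0.8, 0.85, 0.6, 0.5)
  r_hand <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  m5 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m5["a", "b"] <- 1; m5["a", "c"] <- 2; m5["b", "a"] <- 3
  m5["b", "c"] <- 4; m5["c", "a"] <- 6
  res5 <- dplyr::bind_rows(mk("a", "b", 0.9), mk("a", "c", 0.8),
                           mk("b", "a", 0.85), mk("b", "c", 0.6),
                           mk("c", "a", 0.5))
  expect_equal(correlate_divergence(m5, res5, "accuracy")$pearson_r, r_hand,
               tolerance = 1e-9)
  expect_error(correlate_divergence(m5, res5[1:2, ], "accuracy"),
               class = "siteshift_data_error")
})

test_that("shuffled performance shows no correlation with divergence", {
  set.seed(77)
  n <- 8
  ids <- paste0("i", 1:n)
  d <- matrix(runif(n * n, 0.5, 3), n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  rows <- list()
  for (a in ids) for (b in setdiff(ids, a)) {
    acc <- runif(1, 0.5, 0.9)  # independent of d
    rows[[length(rows) + 1L]] <- siteshift:::eval_result(a, b, "minimal",
                                                         acc, acc, 10)
  }
  rep <- correlate_divergence(d, dplyr::bind_rows(rows), "accuracy")
  expect_equal(rep$n_pairs, 56L)
  expect_lt(abs(rep$pearson_r), 0.3)
})

test_that("k-medoids equals the brute-force optimum on small instances", {
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
    d <- d + t(d)
    fit <- kmedoids_fit(d, k, seed = trial)
    expect_equal(fit$total_within_dissimilarity, brute_force_best(d, k),
                 tolerance = 1e-12)
  }
})

test_that("k-medoids recovers planted structure and handles degenerate k", {
  d <- planted_distance(c(2, 2), seed = 1)
  fit <- kmedoids_fit(d, 2, seed = 1)
  expect_setequal(unname(fit$labels[c("i1", "i2")]),
                  unname(fit$labels[c("i1", "i2")])[1])
  expect_equal(length(unique(fit$labels[c("i1", "i2")])), 1L)
  expect_equal(length(unique(fit$labels[c("i3", "i4")])), 1L)
  expect_false(fit$labels[["i1"]] == fit$labels[["i3"]])

  d6 <- planted_distance(c(3, 3), seed = 2)
  fit6 <- kmedoids_fit(d6, 2, seed = 1)
  expect_equal(fit6$total_within_dissimilarity, brute_force_best(d6, 2),
               tolerance = 1e-12)
  expect_equal(length(unique(fit6$labels[1:3])), 1L)

  # k = n: every point its own medoid at zero cost
  fitn <- kmedoids_fit(d6, 6, seed = 1)
  expect_equal(fitn$total_within_dissimilarity, 0)
  expect_length(fitn$medoid_ids, 6)

  expect_error(kmedoids_fit(matrix(c(0, 1, 2, 0), 2, 2), 1),
               class = "siteshift_data_error")  # asymmetric
})

test_that("k-medoids agrees with an independent PAM implementation", {
  skip_if_not_installed("cluster")
  set.seed(99)
  for (trial in 1:5) {
    d <- planted_distance(c(3, 4, 3), seed = 200 + trial)
    ours <- kmedoids_fit(d, 3, seed = trial)
    ref <- cluster::pam(stats::as.dist(d), k = 3)
    ref_cost <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
    expect_equal(ours$total_within_dissimilarity, ref_cost, tolerance = 1e-9)
  }
})

test_that("symmetrization averages the directed entries", {
  m <- matrix(c(0, 1, 3, 0), 2, 2)  # m[1,2] = 3, m[2,1] = 1
  s <- symmetrize(m)
  expect_equal(s[1, 2], 2)
  expect_equal(s, t(s))
  expect_equal(diag(s), c(0, 0))
  sym_in <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(symmetrize(sym_in), sym_in)
})

test_that("elbow selection recovers planted group counts", {
  hits <- 0L
  for (seed in 1:5) {
    d <- planted_distance(c(4, 4, 4), seed = 300 + seed)
    sel <- elbow_select_k(d, 2:8, seed = seed)
    if (sel$k == 3L) hits <- hits + 1L
    expect_true(all(diff(sel$curve$cost) <= 1e-9))  # cost non-increasing in k
  }
  expect_gte(hits, 4L)

  for (k_true in c(2L, 4L)) {
    d <- planted_distance(rep(4, k_true), seed = 310 + k_true)
    expect_equal(elbow_select_k(d, 2:8, seed = 1)$k, k_true)
  }

  # identical points: flat curve -> smallest k with a warning
  d0 <- matrix(0, 5, 5)
  expect_warning(sel0 <- elbow_select_k(d0, 2:4, seed = 1), "flat")
  expect_equal(sel0$k, 2L)
})

test_that("classical MDS reproduces Euclidean-realizable distances", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  xy <- mds_embed(d)
  emb <- as.matrix(stats::dist(xy))
  expect_equal(unname(emb), unname(d), tolerance = 1e-6)

  d2 <- matrix(c(0, 2, 2, 0), 2, 2)
  xy2 <- mds_embed(d2)
  expect_equal(sort(abs(xy2[, 1])), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(xy2[, 2]), c(0, 0), tolerance = 1e-9)

  deq <- matrix(1, 3, 3); diag(deq) <- 0
  xyeq <- mds_embed(deq)
  de <- as.matrix(stats::dist(xyeq))
  off <- de[upper.tri(de)]
  expect_lt(max(off) - min(off), 1e-6)  # equilateral layout
})

test_that("intra- vs inter-cluster summaries match hand arithmetic", {
  assign <- structure(list(
    k = 2L, medoid_ids = c("a", "c"),
    labels = c(a = "a", b = "a", c = "c", d = "c"),
    total_within_dissimilarity = 0),
    class = "siteshift_cluster_assignment")
  mk <- function(train, test, acc) {
    siteshift:::eval_result(train, test, "minimal", acc, acc, 10)
  }
  rows <- dplyr::bind_rows(
    mk("a", "b", 0.9), mk("b", "a", 0.8),   # intra cluster 1
    mk("c", "d", 0.7), mk("d", "c", 0.6),   # intra cluster 2
    mk("a", "c", 0.5), mk("a", "d", 0.4),   # inter from cluster 1
    mk("b", "c", 0.3), mk("b", "d", 0.2),
    mk("c", "a", 0.55), mk("c", "b", 0.45), # inter from cluster 2
    mk("d", "a", 0.35), mk("d", "b", 0.25))
  tab <- intra_inter_summary(assign, rows)
  c1_intra <- tab[tab$cluster == "a" & tab$scope == "intra", ]
  expect_equal(c1_intra$mean_accuracy, mean(c(0.9, 0.8)))
  expect_equal(c1_intra$sd_accuracy, sd(c(0.9, 0.8)))
  c1_inter <- tab[tab$cluster == "a" & tab$scope == "inter", ]
  expect_equal(c1_inter$mean_accuracy, mean(c(0.5, 0.4, 0.3, 0.2)))
  expect_equal(c1_inter$n_cells, 4L)

  # all institutions in one cluster: no inter rows
  assign1 <- structure(list(k = 1L, medoid_ids = "a",
                            labels = c(a = "a", b = "a", c = "a", d = "a"),
                            total_within_dissimilarity = 1),
                       class = "siteshift_cluster_assignment")
  tab1 <- intra_inter_summary(assign1, rows)
  expect_false("inter" %in% tab1$scope)
})

test_that("outlier flagging finds deviant members and singletons", {
  # cluster of 4 where i4 sits far from the other three
  ids <- paste0("i", 1:5)
  d <- matrix(0.2, 5, 5, dimnames = list(ids, ids)); diag(d) <- 0
  d["i4", 1:3] <- d[1:3, "i4"] <- 2.0
  d["i5", 1:4] <- d[1:4, "i5"] <- 5.0   # singleton candidate
  assign <- kmedoids_fit(d, 2, seed = 1)
  out <- flag_outliers(d, assign, threshold_sd = 1.0)
  expect_true("i4" %in% out$institution)
  expect_true("i5" %in% out$institution)
  expect_equal(out$institution[1], "i5")  # sorted by deviation, Inf first

  # homogeneous data -> nothing flagged beyond singletons
  dh <- matrix(0.5, 4, 4, dimnames = list(ids[1:4], ids[1:4])); diag(dh) <- 0
  ah <- kmedoids_fit(dh, 1, seed = 1)
  expect_equal(nrow(flag_outliers(dh, ah, 1.0)), 0L)

  # infinite threshold: only singleton-cluster members remain
  out_inf <- flag_outliers(d, assign, threshold_sd = Inf)
  expect_true(all(out_inf$reason == "singleton_cluster"))
})
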