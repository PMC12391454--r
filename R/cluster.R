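#' Correlate a divergence matrix with transfer performance
#'
#' Pools all non-self (train institution, test institution) cells, pairing
#' each divergence value with the corresponding transfer metric, and reports
#' the Pearson correlation and its square, plus a per-training-institution
#' correlation (each institution's transfer row correlated separately).
#'
#' @param divergence a [divergence_matrix()] (entry `[a, b]` = model a on
#'   data b).
#' @param results a pairwise `siteshift_result_table`.
#' @param performance_field `"micro_f1"` or `"accuracy"`.
#' @return A `siteshift_correlation_report`: list with `metric_name`,
#'   `pearson_r`, `r_squared`, `per_institution` (named vector), `n_pairs`.
#' @export
correlate_divergence <- function(divergence, results,
                                 performance_field = c("micro_f1", "accuracy")) {
  performance_field <- match.arg(performance_field)
  res <- tibble::as_tibble(results)
  res <- res[!res$self & res$train_id %in% rownames(divergence) &
               res$test_id %in% colnames(divergence), ]
  if (nrow(res) < 3) stop_data("need at least 3 non-self pairs to correlate")
  x <- divergence[cbind(res$train_id, res$test_id)]
  y <- res[[performance_field]]
  r <- stats::cor(x, y)
  per_inst <- vapply(sort(unique(res$train_id)), function(id) {
    sub <- res$train_id == id
    if (sum(sub) < 3 || stats::sd(x[sub]) == 0 || stats::sd(y[sub]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[sub], y[sub])
  }, numeric(1))
  structure(list(metric_name = attr(divergence, "metric") %||% "divergence",
                 performance_field = performance_field,
                 pearson_r = r, r_squared = r^2,
                 per_institution = per_inst, n_pairs = nrow(res)),
            class = "siteshift_correlation_report")
}

#' @export
print.siteshift_correlation_report <- function(x, ...) {
  cat(sprintf("<correlation> %s vs %s: r = %.4f, R^2 = %.4f (n = %d pairs)\n",
              x$metric_name, x$performance_field, x$pearson_r, x$r_squared,
              x$n_pairs))
  invisible(x)
}

#' Symmetrize a directed divergence matrix
#'
#' k-medoids needs a dissimilarity; directed divergences are symmetrized by
#' the element-wise mean of the matrix and its transpose (diagonal
#' preserved).
#'
#' @param m square numeric matrix.
#' @return symmetric matrix of the same dimension.
#' @export
symmetrize <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) stop_data("matrix must be square")
  (m + t(m)) / 2
}

pam_cost <- function(d, medoid_idx) {
  sum(apply(d[, medoid_idx, drop = FALSE], 1, min))
}

pam_assign <- function(d, medoid_idx) {
  nearest <- apply(d[, medoid_idx, drop = FALSE], 1, which.min)
  medoid_idx[nearest]
}

#' k-medoids (PAM) on a precomputed dissimilarity matrix
#'
#' Partitioning Around Medoids. Small instances (at most 50,000 candidate
#' medoid sets) are solved exactly by enumeration, so the reported optimum
#' is global there; larger instances use the classic greedy BUILD phase
#' followed by a SWAP phase that exchanges medoids with non-medoids while
#' any swap lowers the total within-cluster dissimilarity. Deterministic
#' given the seed (used only to break exact ties in BUILD).
#'
#' @param distance square symmetric nonnegative matrix with zero diagonal
#'   (symmetrize directed divergences first; see [symmetrize()]).
#' @param k number of clusters, `2 <= k <= n` (`k = n` puts every point in
#'   its own cluster at cost zero).
#' @param seed tie-break seed.
#' @return A `siteshift_cluster_assignment`: list with `k`, `medoid_ids`,
#'   `labels` (named medoid id per point), `total_within_dissimilarity`.
#' @export
kmedoids_fit <- function(distance, k, seed = 1L) {
  d <- unclass(as.matrix(distance))
  n <- nrow(d)
  if (ncol(d) != n) stop_data("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) {
    stop_data("distance matrix must be symmetric; apply symmetrize() first")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop_data("distance matrix must be nonnegative with zero diagonal")
  }
  if (!is_count(k) || k < 1 || k > n) stop_config("k must be in 1..n")
  ids <- rownames(d) %||% as.character(seq_len(n))

  if (choose(n, k) <= 50000) {
    combos <- utils::combn(n, k)
    costs <- apply(combos, 2, function(m) pam_cost(d, m))
    medoids <- combos[, which.min(costs)]  # ties: first in combn order
    labels <- pam_assign(d, sort(medoids))
    return(structure(list(k = as.integer(k),
                          medoid_ids = ids[sort(medoids)],
                          labels = stats::setNames(ids[labels], ids),
                          total_within_dissimilarity = pam_cost(d, medoids)),
                     class = "siteshift_cluster_assignment"))
  }

  with_seed(seed, {
    # BUILD: first medoid minimizes total distance; then greedy additions
    costs <- colSums(d)
    medoids <- which(costs == min(costs))
    medoids <- medoids[sample.int(length(medoids), 1)]
    while (length(medoids) < k) {
      best_gain <- -Inf; best_cand <- integer(0)
      dmin <- apply(d[, medoids, drop = FALSE], 1, min)
      for (cand in setdiff(seq_len(n), medoids)) {
        gain <- sum(pmax(dmin - d[, cand], 0))
        if (gain > best_gain + 1e-15) {
          best_gain <- gain; best_cand <- cand
        } else if (abs(gain - best_gain) <= 1e-15) {
          best_cand <- c(best_cand, cand)
        }
      }
      medoids <- c(medoids, best_cand[sample.int(length(best_cand), 1)])
    }
    # SWAP until no improving exchange
    repeat {
      improved <- FALSE
      cur_cost <- pam_cost(d, medoids)
      for (mi in seq_along(medoids)) {
        for (cand in setdiff(seq_len(n), medoids)) {
          trial <- medoids; trial[mi] <- cand
          tc <- pam_cost(d, trial)
          if (tc < cur_cost - 1e-12) {
            medoids <- trial; cur_cost <- tc; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    labels <- pam_assign(d, sort(medoids))
    structure(list(k = as.integer(k),
                   medoid_ids = ids[sort(medoids)],
                   labels = stats::setNames(ids[labels], ids),
                   total_within_dissimilarity = pam_cost(d, medoids)),
              class = "siteshift_cluster_assignment")
  })
}

#' Choose k by the elbow of the within-cluster cost curve
#'
#' Fits k-medoids for each k in `k_range`, records the within-cluster sum of
#' squared dissimilarities, and returns the k whose point on the
#' (normalized) cost curve lies farthest below the chord joining the curve's
#' endpoints. Ties break toward the smallest k; a degenerate flat curve
#' returns the smallest k with a warning.
#'
#' @inheritParams kmedoids_fit
#' @param k_range candidate k values (capped at n - 1).
#' @return list with `k`, `curve` (tibble k, cost, chord_distance).
#' @export
elbow_select_k <- function(distance, k_range = 2:25, seed = 1L) {
  d <- unclass(as.matrix(distance))
  n <- nrow(d)
  k_range <- k_range[k_range >= 1 & k_range <= n - 1]
  if (!length(k_range)) stop_config("no admissible k in range")
  # anchor the chord at k = 1 so a bend at min(k_range) is visible
  k_curve <- union(1L, k_range)
  cost <- vapply(k_curve, function(k) {
    fit <- kmedoids_fit(d, k, seed = derive_seed(seed, paste0("elbow", k)))
    m <- match(fit$labels, rownames(d) %||% as.character(seq_len(n)))
    sum(d[cbind(seq_len(n), m)]^2)
  }, numeric(1))
  if (max(cost) - min(cost) < 1e-15) {
    rlang::warn("flat cost curve: all clusterings equivalent; returning smallest k")
    return(list(k = min(k_range),
                curve = tibble::tibble(k = k_curve, cost = cost,
                                       chord_distance = 0)))
  }
  x <- (k_curve - min(k_curve)) / max(1, diff(range(k_curve)))
  y <- (cost - min(cost)) / (max(cost) - min(cost))
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  chord <- ((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / denom
  chord[!k_curve %in% k_range] <- -Inf   # the anchor itself is not selectable
  # positive chord distance = below the chord (the bend of a convex curve)
  if (all(chord <= 1e-12)) {
    rlang::warn("cost curve has no bend below the chord; falling back to max second difference")
    if (length(cost) >= 3) {
      d2 <- diff(diff(cost))
      cand <- k_curve[seq_along(d2) + 1L]
      d2[!cand %in% k_range] <- -Inf
      k_sel <- cand[which.max(d2)]
    } else {
      k_sel <- min(k_range)
    }
  } else {
    k_sel <- k_curve[which.max(chord)]
  }
  list(k = k_sel,
       curve = tibble::tibble(k = k_curve, cost = cost,
                              chord_distance = chord))
}

#' Classical (Torgerson) multidimensional scaling to 2-D
#'
#' Double-centers the squared dissimilarities and embeds on the top two
#' eigenvectors scaled by the square root of their eigenvalues. Orientation
#' is fixed by a sign convention: each axis is flipped so its largest-
#' magnitude coordinate is positive. Warns when negative eigenvalues
#' dominate (non-Euclidean input).
#'
#' @param distance symmetric dissimilarity matrix.
#' @param seed unused; accepted for interface uniformity.
#' @return matrix n x 2 of coordinates with the input's rownames.
#' @export
mds_embed <- function(distance, seed = 1L) {
  d <- unclass(as.matrix(distance))
  fit <- stats::cmdscale(stats::as.dist(d), k = min(2, nrow(d) - 1), eig = TRUE)
  ev <- fit$eig
  if (sum(pmax(-ev, 0)) > sum(pmax(ev, 0))) {
    rlang::warn("negative eigenvalues dominate: dissimilarities are strongly non-Euclidean")
  }
  xy <- fit$points
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  for (j in 1:2) {
    i_max <- which.max(abs(xy[, j]))
    if (xy[i_max, j] < 0) xy[, j] <- -xy[, j]
  }
  colnames(xy) <- c("x", "y")
  rownames(xy) <- rownames(d)
  xy
}

#' Intra- vs inter-cluster transfer performance
#'
#' For each cluster, averages the non-self pairwise cells whose training and
#' test institutions both fall in the cluster (intracluster) and those whose
#' training institution is in the cluster but whose test institution is not
#' (intercluster). Singleton clusters have no intracluster cells and report
#' the intercluster side only.
#'
#' @param assignment a [kmedoids_fit()] result.
#' @param results a pairwise `siteshift_result_table`.
#' @return tibble: cluster, scope (intra/inter), mean/SD accuracy and
#'   micro-F1, n_cells.
#' @export
intra_inter_summary <- function(assignment, results) {
  res <- tibble::as_tibble(results)
  res <- res[!res$self, ]
  labels <- assignment$labels
  if (!all(res$train_id %in% names(labels))) {
    stop_data("assignment and results cover different institutions")
  }
  out <- list()
  for (cl in unique(labels)) {
    members <- names(labels)[labels == cl]
    intra <- res[res$train_id %in% members & res$test_id %in% members, ]
    inter <- res[res$train_id %in% members & !(res$test_id %in% members), ]
    for (scope in c("intra", "inter")) {
      sub <- if (scope == "intra") intra else inter
      if (!nrow(sub)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        cluster = cl, scope = scope,
        mean_accuracy = mean(sub$accuracy), sd_accuracy = stats::sd(sub$accuracy),
        mean_micro_f1 = mean(sub$micro_f1), sd_micro_f1 = stats::sd(sub$micro_f1),
        n_cells = nrow(sub))
    }
  }
  dplyr::bind_rows(out)
}

#' Flag outlier institutions from a clustered divergence matrix
#'
#' An institution is an outlier when its mean within-cluster divergence
#' exceeds its cluster's mean by `threshold_sd` standard deviations (both
#' over cluster members), or when it sits alone in a singleton cluster.
#' Results are sorted by decreasing deviation.
#'
#' @param divergence a (possibly directed) divergence matrix; symmetrized
#'   internally.
#' @param assignment a [kmedoids_fit()] result.
#' @param threshold_sd deviation threshold in cluster SD units.
#' @return tibble: institution, cluster, mean_within_divergence, deviation
#'   (SD units; `Inf` for singletons), reason.
#' @export
flag_outliers <- function(divergence, assignment, threshold_sd = 1.0) {
  d <- symmetrize(divergence)
  labels <- assignment$labels
  out <- list()
  for (cl in unique(labels)) {
    members <- names(labels)[labels == cl]
    if (length(members) == 1L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        institution = members, cluster = cl,
        mean_within_divergence = NA_real_, deviation = Inf,
        reason = "singleton_cluster")
      next
    }
    mw <- vapply(members, function(i) {
      mean(d[i, setdiff(members, i)])
    }, numeric(1))
    mu <- mean(mw); s <- stats::sd(mw)
    dev <- if (s > 0) (mw - mu) / s else rep(0, length(mw))
    hit <- which(dev > threshold_sd)
    for (h in hit) {
      out[[length(out) + 1L]] <- tibble::tibble(
        institution = members[h], cluster = cl,
        mean_within_divergence = mw[h], deviation = dev[h],
        reason = "high_within_cluster_divergence")
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res <- res[order(-res$deviation), ]
  res
}
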