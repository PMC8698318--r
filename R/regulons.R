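# Regulon inference: expression z-scoring, consensus-k agglomerative
# clustering, hypergeometric regulon enrichment with BH correction,
# regulator merging, correlation gating, regulon activity, switch
# classification and TF-TF network construction.

#' Z-score genes across conditions
#'
#' Per-gene standardization `(x - mean) / sd` (sample SD) across conditions.
#' Zero-variance genes are flagged as degenerate and dropped from the
#' returned matrix (attribute `degenerate`).
#'
#' @param expression gene x condition numeric matrix (>= 2 conditions).
#' @return z-score matrix with attribute `degenerate` naming excluded genes.
#' @export
zscore_genes <- function(expression) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 2) stop("need >= 2 conditions to z-score")
  s <- apply(expression, 1, stats::sd)
  degenerate <- rownames(expression)[s < 1e-12]
  keep <- s >= 1e-12
  z <- (expression[keep, , drop = FALSE] -
          rowMeans(expression[keep, , drop = FALSE])) / s[keep]
  attr(z, "degenerate") <- degenerate
  z
}

#' Internal cluster-validity indices for a partition
#'
#' Textbook definitions with Euclidean distance: mean silhouette width
#' (singleton clusters contribute 0), Calinski-Harabasz
#' (between/within variance ratio scaled by degrees of freedom, higher
#' better) and Davies-Bouldin (mean worst-pair centroid-scatter ratio,
#' lower better).
#'
#' @param z numeric matrix of observations (rows) x features.
#' @param labels integer cluster labels, k >= 2, every cluster non-empty.
#' @return named numeric vector (silhouette, calinski_harabasz,
#'   davies_bouldin).
#' @export
cluster_quality_scores <- function(z, labels) {
  z <- as.matrix(z)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  n <- nrow(z)
  if (k < 2) stop("need k >= 2 clusters")
  sil <- mean(cluster::silhouette(labels, stats::dist(z))[, "sil_width"])
  centroids <- rowsum(z, labels) / as.vector(table(labels))
  grand <- colMeans(z)
  sizes <- as.vector(table(labels))
  bss <- sum(sizes * rowSums(sweep(centroids, 2, grand)^2))
  wss <- sum(rowSums((z - centroids[labels, , drop = FALSE])^2))
  ch <- if (wss < 1e-300) Inf else (bss / (k - 1)) / (wss / (n - k))
  # Davies-Bouldin: s_i = mean distance to own centroid
  si <- vapply(seq_len(k), function(i)
    mean(sqrt(rowSums((z[labels == i, , drop = FALSE] -
                         matrix(centroids[i, ], sum(labels == i),
                                ncol(z), byrow = TRUE))^2))), 0)
  dcent <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_len(k), function(i) {
    r <- (si[i] + si[-i]) / dcent[i, -i]
    max(r[is.finite(r)], 0)
  }, 0))
  c(silhouette = sil, calinski_harabasz = ch, davies_bouldin = db)
}

#' Select a cluster partition by consensus over validity indices
#'
#' Agglomerative (Ward linkage, Euclidean) clustering is cut at every k in
#' `[k_min, k_max]`; the k with the best mean rank across silhouette
#' (higher better), Calinski-Harabasz (higher better) and Davies-Bouldin
#' (lower better) is selected, ties broken toward the smallest k.
#'
#' @param z observation x feature matrix (e.g., gene z-scores).
#' @param k_min smallest k (default 3).
#' @param k_max largest k (default `min(114, n - 1)`).
#' @return list of class `cluster_partition`: `k`, `labels` (named by row),
#'   `quality` (selected k's indices), `scores` (data.frame over all k).
#' @export
select_partition <- function(z, k_min = 3, k_max = min(114, nrow(z) - 1)) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < k_min + 1) stop("fewer observations than k_min + 1")
  k_max <- min(k_max, n - 1)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  ks <- k_min:k_max
  scores <- t(vapply(ks, function(k)
    cluster_quality_scores(z, stats::cutree(hc, k)),
    c(silhouette = 0, calinski_harabasz = 0, davies_bouldin = 0)))
  scores <- as.data.frame(scores)
  scores$k <- ks
  mean_rank <- (rank(-scores$silhouette, ties.method = "average") +
                rank(-scores$calinski_harabasz, ties.method = "average") +
                rank(scores$davies_bouldin, ties.method = "average")) / 3
  best <- ks[which.min(mean_rank)]  # which.min takes the first = smallest k
  labels <- stats::cutree(hc, best)
  names(labels) <- rownames(z)
  structure(list(k = best, labels = labels,
                 quality = unlist(scores[scores$k == best,
                                         c("silhouette", "calinski_harabasz",
                                           "davies_bouldin")]),
                 scores = scores[, c("k", "silhouette", "calinski_harabasz",
                                     "davies_bouldin")]),
            class = "cluster_partition")
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for X ~ hypergeometric(N, K, n): drawing n items from a
#' population of N containing K successes.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draw size.
#' @param k observed successes in the draw.
#' @return the enrichment p-value.
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < 0 || any(c(N, K, n) < 0))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues p-values in [0, 1].
#' @param alpha FDR level for the significance flags (default 0.1).
#' @return list with `adjusted` (monotone step-up adjusted p-values) and
#'   `significant` (adjusted <= alpha).
#' @export
bh_adjust <- function(pvalues, alpha = 0.1) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, significant = adj <= alpha)
}

#' Name a regulon as regulator.size
#'
#' @param regulator regulator (TF) name.
#' @param n_targets number of target genes (>= 1).
#' @return e.g. `"E2F8.123"`.
#' @export
name_regulon <- function(regulator, n_targets) {
  if (!nzchar(regulator)) stop("empty regulator name")
  if (n_targets < 1) stop("n_targets must be >= 1")
  paste0(regulator, ".", as.integer(n_targets))
}

#' Classify a regulon activity profile as a switch or transient pattern
#'
#' With activity ordered by time point: "up" if the late minus early
#' activity exceeds `delta`; "down" if below `-delta`; otherwise
#' "transient" if an interior extremum exceeds (or falls below) both
#' endpoints by `delta`. When no rule fires the direction of the (small)
#' endpoint difference is used, an exact tie giving "transient".
#'
#' @param activity numeric activity per time point (>= 3 time points).
#' @param delta switch threshold in z-units (default 0.5).
#' @return one of "up", "down", "transient".
#' @export
classify_switch <- function(activity, delta = 0.5) {
  if (length(activity) < 3) stop("need >= 3 time points")
  early <- activity[1]; late <- activity[length(activity)]
  interior <- activity[-c(1, length(activity))]
  if (late - early > delta) return("up")
  if (late - early < -delta) return("down")
  if (max(interior) > max(early, late) + delta) return("transient")
  if (min(interior) < min(early, late) - delta) return("transient")
  if (late > early) "up" else if (late < early) "down" else "transient"
}

#' Infer regulons from clustered response genes and a regulatory prior
#'
#' For every cluster x regulator pair (within the up- and downregulated
#' response sets separately), the overlap between the cluster and the
#' regulator's prior target set is tested for enrichment with an upper-tail
#' hypergeometric test, population = the direction's response gene set.
#' P-values are BH-corrected within each direction. Significant
#' (cluster intersect prior-target) sets sharing a regulator are merged;
#' a candidate is retained iff the Pearson correlation between the
#' regulator's z-profile and its merged targets' mean z-profile exceeds
#' `r_threshold` (positive-correlation gate; anti-correlated candidates are
#' dropped). Regulon activity is the per-condition mean target z-score;
#' direction is the [classify_switch()] class of the donor-averaged
#' per-time-point activity.
#'
#' @param z gene x condition z-score matrix covering response genes and
#'   regulators (see [zscore_genes()]).
#' @param partition_up,partition_down [select_partition()] results on the
#'   up-/downregulated response genes (either may be NULL).
#' @param prior data.frame with columns regulator, target.
#' @param r_threshold correlation gate (default 0.8).
#' @param alpha BH FDR level (default 0.1).
#' @param timepoints integer time-point index per column of `z`, used to
#'   average activity across donors for switch classification.
#' @param delta switch threshold passed to [classify_switch()].
#' @return list of `regulon` objects: regulator, targets, name, correlation,
#'   activity (per condition), activity_timepoint, direction,
#'   deg_direction ("up"/"down" response set), n_targets.
#' @export
infer_regulons <- function(z, partition_up, partition_down, prior,
                           r_threshold = 0.8, alpha = 0.1,
                           timepoints = NULL, delta = 0.5) {
  if (!all(c("regulator", "target") %in% names(prior)))
    stop("prior must have columns regulator and target")
  prior_sets <- split(as.character(prior$target),
                      as.character(prior$regulator))
  parts <- list(up = partition_up, down = partition_down)
  regulons <- list()
  for (dir_ in names(parts)) {
    part <- parts[[dir_]]
    if (is.null(part)) next
    population <- names(part$labels)
    N <- length(population)
    tests <- list()
    for (reg in names(prior_sets)) {
      targ_pop <- intersect(prior_sets[[reg]], population)
      K <- length(targ_pop)
      if (K == 0) next
      for (cl in sort(unique(part$labels))) {
        members <- population[part$labels == cl]
        ov <- intersect(members, targ_pop)
        tests[[length(tests) + 1L]] <- list(
          regulator = reg, cluster = cl, N = N, K = K,
          n = length(members), k = length(ov), overlap = ov,
          pvalue = hypergeom_pvalue(N, K, length(members), length(ov)))
      }
    }
    if (!length(tests)) next
    pv <- vapply(tests, `[[`, 0, "pvalue")
    adj <- bh_adjust(pv, alpha)
    sig <- which(adj$significant & vapply(tests, `[[`, 0L, "k") > 0)
    if (!length(sig)) next
    by_reg <- split(sig, vapply(tests[sig], `[[`, "", "regulator"))
    for (reg in names(by_reg)) {
      targets <- sort(unique(unlist(lapply(tests[by_reg[[reg]]], `[[`,
                                           "overlap"))))
      if (!reg %in% rownames(z)) {
        warning(sprintf("regulator %s absent from expression matrix; candidate dropped", reg))
        next
      }
      mean_profile <- colMeans(z[targets, , drop = FALSE])
      r <- stats::cor(z[reg, ], mean_profile)
      if (!is.finite(r) || r <= r_threshold) next
      activity <- mean_profile
      act_tp <- if (!is.null(timepoints))
        as.numeric(tapply(activity, timepoints, mean)) else activity
      regulons[[length(regulons) + 1L]] <- structure(list(
        regulator = reg, targets = targets,
        name = name_regulon(reg, length(targets)),
        correlation = r, activity = activity,
        activity_timepoint = act_tp,
        direction = classify_switch(act_tp, delta),
        deg_direction = dir_, n_targets = length(targets)),
        class = "regulon")
    }
  }
  regulons
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("regulon %s (%s, r = %.3f, %s response set)\n",
              x$name, x$direction, x$correlation, x$deg_direction))
  invisible(x)
}

#' Build the directed TF-TF influence network
#'
#' A node per involved transcription factor; a directed edge regulator ->
#' TF for every retained regulon whose target set contains another TF. Node
#' attributes: `n_targets` (regulon size, 0 for pure targets) and
#' `direction` (switch class, NA for pure targets).
#'
#' @param regulons list of retained regulons from [infer_regulons()].
#' @param tf_list transcription-factor identifiers.
#' @return a directed [igraph::graph] (possibly empty).
#' @export
build_tf_network <- function(regulons, tf_list) {
  edges <- list()
  for (r in regulons) {
    heads <- intersect(r$targets, tf_list)
    if (length(heads))
      edges[[length(edges) + 1L]] <- data.frame(from = r$regulator,
                                                to = heads)
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0))
  nodes <- unique(c(vapply(regulons, `[[`, "", "regulator"),
                    edge_df$from, edge_df$to))
  if (!length(nodes))
    return(igraph::make_empty_graph(directed = TRUE))
  n_targets <- stats::setNames(rep(0L, length(nodes)), nodes)
  direction <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (r in regulons) {
    n_targets[r$regulator] <- r$n_targets
    direction[r$regulator] <- r$direction
  }
  g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$n_targets <- as.integer(n_targets[igraph::V(g)$name])
  igraph::V(g)$direction <- direction[igraph::V(g)$name]
  g
}
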