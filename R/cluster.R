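#' Form candidate electrode clusters from a Wald topography
#'
#' Groups spatially contiguous electrodes whose uncorrected p-value falls
#' below the cluster-forming threshold and whose effects share a sign
#' into connected components of the adjacency graph; components smaller
#' than `min_size` are dropped. The cluster mass is the sum of member
#' Wald statistics. Non-converged electrodes cannot seed or join
#' clusters.
#'
#' @param stats data frame from [channelwise_fit()] (columns `electrode`,
#'   `wald`, `p`, `sign`, `converged`).
#' @param graph adjacency graph from [build_adjacency()].
#' @param p_thresh cluster-forming threshold on the uncorrected p.
#' @param min_size minimum number of contiguous electrodes.
#' @return data frame, one row per candidate cluster: `cluster`, `sign`,
#'   `size`, `mass`, `members` (comma-separated labels); zero rows when
#'   nothing survives.
#' @export
form_clusters <- function(stats, graph, p_thresh = 0.005, min_size = 3L) {
  vn <- igraph::V(graph)$name
  stopifnot(setequal(vn, stats$electrode))
  empty <- data.frame(cluster = integer(), sign = numeric(),
                      size = integer(), mass = numeric(),
                      members = character(), stringsAsFactors = FALSE)
  ok <- stats$converged & !is.na(stats$p) & stats$p < p_thresh &
    stats$sign != 0
  if (!any(ok)) return(empty)
  rows <- list()
  for (sgn in c(1, -1)) {
    keep <- stats$electrode[ok & stats$sign == sgn]
    if (length(keep) == 0L) next
    sub <- igraph::induced_subgraph(graph, keep)
    comp <- igraph::components(sub)
    for (ci in seq_len(comp$no)) {
      members <- igraph::V(sub)$name[comp$membership == ci]
      if (length(members) < min_size) next
      mass <- sum(stats$wald[match(members, stats$electrode)])
      rows[[length(rows) + 1L]] <- data.frame(
        sign = sgn, size = length(members), mass = mass,
        members = paste(sort(members), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$mass), , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Permute a vector within strata
#'
#' Fisher-Yates shuffle applied independently inside each stratum, so
#' each stratum's multiset of values is preserved. This is the exchange
#' scheme of the cluster permutation test: the predicted variable is
#' shuffled within participant-by-experiment cells, preserving all
#' between-participant structure under the null.
#'
#' @param y numeric vector.
#' @param strata factor-like stratum labels, same length as `y`.
#' @return permuted copy of `y`.
#' @export
permute_within_strata <- function(y, strata) {
  s <- as.integer(factor(strata))
  out <- y
  for (k in unique(s)) {
    idx <- which(s == k)
    if (length(idx) > 1L) out[idx] <- y[idx[sample.int(length(idx))]]
  }
  out
}

#' Max cluster-mass permutation null distribution
#'
#' Repeats the whole channel-wise analysis on outcome values shuffled
#' within participant-by-experiment strata: for each permutation the same
#' models are refit on every electrode, clusters are formed with the same
#' threshold/size rules as for the observed data, and the maximum
#' absolute cluster mass is recorded (0 when no cluster forms). The
#' resulting vector is the reference distribution for
#' [significant_clusters()].
#'
#' @param records awakening data frame.
#' @param features `band_power_table`.
#' @param outcome,nuisance,modifier,group as in [channelwise_fit()].
#' @param graph adjacency graph.
#' @param n_perm number of permutations (the study convention is 5,000;
#'   values below 100 trigger an unstable-tail warning).
#' @param p_thresh,min_size cluster-formation parameters.
#' @param seed integer seed; the null is deterministic given it.
#' @param use_identity if `TRUE`, every "permutation" is the identity
#'   (sanity mode: each null value then equals the observed max mass).
#' @return object of class `permutation_null`: list with `max_mass`
#'   (length `n_perm`), `n_perm`, `seed`, and the cluster-formation
#'   parameters.
#' @export
permutation_null <- function(records, features, outcome,
                             nuisance = c("experiment", "night", "time"),
                             modifier = NULL, group = "participant_id",
                             graph, n_perm = 5000L, p_thresh = 0.005,
                             min_size = 3L, seed = 1L,
                             use_identity = FALSE) {
  if (n_perm < 100L) warning("fewer than 100 permutations: tail unstable")
  prep <- prep_channelwise(features, records, outcome, nuisance,
                           modifier, group)
  tab <- table(prep$strata)
  if (any(tab < 2L)) {
    warning(sprintf("%d strata have a single observation and cannot contribute",
                    sum(tab < 2L)))
  }
  max_mass <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yb <- if (use_identity) prep$y else
        permute_within_strata(prep$y, prep$strata)
      st <- channelwise_stats(prep, yb)
      cl <- form_clusters(st, graph, p_thresh, min_size)
      max_mass[b] <- if (nrow(cl)) max(abs(cl$mass)) else 0
    }
  })
  structure(list(max_mass = max_mass, n_perm = n_perm, seed = seed,
                 p_thresh = p_thresh, min_size = min_size),
            class = "permutation_null")
}

#' Permutation-corrected significance of candidate clusters
#'
#' Compares each observed cluster mass to the max-|mass| null
#' distribution. The corrected p-value uses the add-one convention,
#' `(1 + #\{null >= mass\}) / (1 + n_perm)`, so it is never exactly zero;
#' a cluster is significant when the corrected p falls below `alpha`,
#' equivalently when its mass exceeds the empirical `1 - alpha` null
#' quantile.
#'
#' @param candidates cluster table from [form_clusters()].
#' @param null a [permutation_null()].
#' @param alpha corrected significance level.
#' @return the candidate table with `corrected_p` and `significant`
#'   columns appended.
#' @export
significant_clusters <- function(candidates, null, alpha = 0.05) {
  stopifnot(inherits(null, "permutation_null"), length(null$max_mass) > 0)
  if (!nrow(candidates)) {
    candidates$corrected_p <- numeric()
    candidates$significant <- logical()
    return(candidates)
  }
  cp <- vapply(candidates$mass, function(m) {
    (1 + sum(null$max_mass >= m)) / (1 + null$n_perm)
  }, numeric(1))
  candidates$corrected_p <- cp
  candidates$significant <- cp < alpha
  candidates
}

#' End-to-end cluster-mass permutation test
#'
#' Convenience wrapper running the observed channel-wise fits, cluster
#' formation, the permutation null, and corrected significance in one
#' call.
#'
#' @inheritParams permutation_null
#' @param alpha corrected significance level.
#' @return list with `stats` (observed topography), `clusters`
#'   (with corrected p), and `null`.
#' @export
cluster_permutation_test <- function(records, features, outcome,
                                     nuisance = c("experiment", "night", "time"),
                                     modifier = NULL,
                                     group = "participant_id",
                                     graph, n_perm = 5000L,
                                     p_thresh = 0.005, min_size = 3L,
                                     alpha = 0.05, seed = 1L) {
  stats <- channelwise_fit(features, records, outcome, nuisance,
                           modifier, group)
  cand <- form_clusters(stats, graph, p_thresh, min_size)
  null <- permutation_null(records, features, outcome, nuisance, modifier,
                           group, graph, n_perm, p_thresh, min_size, seed)
  list(stats = stats,
       clusters = significant_clusters(cand, null, alpha),
       null = null)
}
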