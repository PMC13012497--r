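# Shared fixture builders and independent oracles.

# regular planar grid sensor array (z = 0), unit spacing
grid_sensors <- function(nx = 4L, ny = 4L, step = 1) {
  g <- expand.grid(x = (seq_len(nx) - 1) * step,
                   y = (seq_len(ny) - 1) * step)
  sensor_array(data.frame(x = g$x, y = g$y, z = 0))
}

# small cohort used across mixed-model tests
small_cohort <- function(seed = 1L, n_participants = 12L, n_electrodes = 8L,
                         ...) {
  generate_cohort(sim_config(n_participants = n_participants,
                             n_electrodes = n_electrodes,
                             seed = seed, ...))
}

# Brute-force cluster oracle: exhaustive flood fill over the adjacency
# matrix, independent of igraph. Returns a list of member-label sets with
# masses, for supra-threshold sign-homogeneous electrodes.
bf_clusters <- function(stats, adj, p_thresh, min_size) {
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- which(stats$converged & !is.na(stats$p) & stats$p < p_thresh &
                   stats$sign == sgn)
    seen <- logical(length(idx))
    for (k in seq_along(idx)) {
      if (seen[k]) next
      comp <- idx[k]
      repeat {
        grow <- idx[!idx %in% comp &
                      sapply(idx, function(j)
                        any(adj[j, comp]))]
        if (!length(grow)) break
        comp <- c(comp, grow)
      }
      seen[idx %in% comp] <- TRUE
      if (length(comp) >= min_size) {
        out[[length(out) + 1L]] <- list(
          members = sort(stats$electrode[comp]),
          mass = sum(stats$wald[comp]), sign = sgn)
      }
    }
  }
  out
}

# Step-up Benjamini-Hochberg oracle written directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}
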