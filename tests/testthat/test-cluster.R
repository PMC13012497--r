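make_stats <- function(labels, wald, sign, converged = TRUE) {
  data.frame(electrode = labels, estimate = sign * sqrt(wald),
             se = 1, wald = wald,
             p = pchisq(wald, 1, lower.tail = FALSE),
             sign = sign, converged = converged,
             stringsAsFactors = FALSE)
}

test_that("adjacency construction matches brute-force geometry", {
  # three collinear equidistant points -> chain
  chain <- sensor_array(data.frame(x = 0:2, y = 0, z = 0))
  g <- build_adjacency(chain, method = "distance", threshold = 1)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "E001", "E002"))
  expect_false(igraph::are_adjacent(g, "E001", "E003"))

  # regular 4x4 grid at threshold = grid step -> rook adjacency, 24 edges
  gr <- grid_sensors(4L, 4L)
  gg <- build_adjacency(gr, method = "distance", threshold = 1)
  expect_equal(igraph::ecount(gg), 24)
  A <- igraph::as_adjacency_matrix(gg, sparse = FALSE)
  expect_identical(A, t(A))
  # brute-force pairwise distance check
  pos <- as.matrix(gr[c("x", "y", "z")])
  D <- as.matrix(dist(pos)); diag(D) <- Inf
  expect_identical(unname(A == 1), unname(D <= 1))

  dup <- sensor_array(data.frame(x = c(0, 0, 1), y = 0, z = 0))
  expect_error(build_adjacency(dup), "duplicate")

  kg <- build_adjacency(gr, method = "knn", k = 3L)
  Ak <- igraph::as_adjacency_matrix(kg, sparse = FALSE)
  expect_identical(Ak, t(Ak))
})

test_that("cluster formation matches exhaustive enumeration on toy graphs", {
  # fixed 10-node example: two disjoint supra-threshold patches (4 and 3)
  sa <- sensor_array(data.frame(x = c(0:4, 0:4), y = rep(c(0, 1), each = 5),
                                z = 0))
  g <- build_adjacency(sa, method = "distance", threshold = 1)
  wald <- rep(0.5, 10)
  sup <- c(1, 2, 6, 7, 4, 5, 10)       # patch {1,2,6,7} and patch {4,5,10}
  wald[sup] <- c(12, 14, 11, 16, 13, 12, 15)
  st <- make_stats(sa$label, wald, sign = 1)
  cl <- form_clusters(st, g, p_thresh = 0.005, min_size = 3L)
  expect_identical(nrow(cl), 2L)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) == 1
  bf <- bf_clusters(st, A, 0.005, 3L)
  expect_setequal(cl$members,
                  vapply(bf, function(b) paste(b$members, collapse = ","),
                         character(1)))
  expect_equal(sort(cl$mass), sort(vapply(bf, `[[`, numeric(1), "mass")))

  # randomized equivalence on graphs of <= 12 electrodes
  for (s in 1:12) {
    set.seed(400 + s)
    n <- sample(6:12, 1)
    sa2 <- sensor_array(data.frame(x = runif(n, 0, 3), y = runif(n, 0, 3),
                                   z = 0))
    g2 <- suppressWarnings(build_adjacency(sa2, threshold = 1.2))
    st2 <- make_stats(sa2$label, rchisq(n, 1) * 8,
                      sign = sample(c(-1, 1), n, TRUE),
                      converged = runif(n) > 0.1)
    A2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE) == 1
    for (ms in c(1L, 3L)) {
      cl2 <- form_clusters(st2, g2, p_thresh = 0.05, min_size = ms)
      bf2 <- bf_clusters(st2, A2, 0.05, ms)
      expect_setequal(cl2$members,
                      vapply(bf2, function(b) paste(b$members, collapse = ","),
                             character(1)))
    }
  }
})

test_that("cluster rules enforce threshold, sign homogeneity and min size", {
  sa <- grid_sensors(3L, 3L)
  g <- build_adjacency(sa, threshold = 1)
  null_st <- make_stats(sa$label, rep(1, 9), sign = 1)
  expect_identical(nrow(form_clusters(null_st, g)), 0L)

  # two adjacent supra-threshold electrodes only: below min size 3
  w <- rep(0.1, 9); w[c(1, 2)] <- 20
  expect_identical(nrow(form_clusters(make_stats(sa$label, w, 1), g)), 0L)
  # same patch passes with min_size 2
  expect_identical(nrow(form_clusters(make_stats(sa$label, w, 1), g,
                                      min_size = 2L)), 1L)

  # opposite signs break contiguity
  w3 <- rep(0.1, 9); w3[c(1, 2, 3)] <- 20
  sg <- rep(1, 9); sg[2] <- -1
  expect_identical(nrow(form_clusters(make_stats(sa$label, w3, sg), g)), 0L)

  # non-converged electrodes cannot join
  cv <- rep(TRUE, 9); cv[2] <- FALSE
  expect_identical(nrow(form_clusters(make_stats(sa$label, w3, 1, cv), g)),
                   0L)

  # lowering the forming threshold never enlarges any cluster
  set.seed(99)
  wr <- rchisq(9, 1) * 6
  st_loose <- form_clusters(make_stats(sa$label, wr, 1), g,
                            p_thresh = 0.2, min_size = 1L)
  st_tight <- form_clusters(make_stats(sa$label, wr, 1), g,
                            p_thresh = 0.02, min_size = 1L)
  loose_members <- unlist(strsplit(st_loose$members, ","))
  for (m in st_tight$members) {
    expect_true(all(unlist(strsplit(m, ",")) %in% loose_members))
  }
})

test_that("permutations preserve stratum multisets and the identity mode", {
  coh <- small_cohort(seed = 13L, n_participants = 8L)
  strata <- interaction(coh$records$participant_id, coh$records$experiment)
  y <- coh$records$sleep_depth
  set.seed(1)
  for (i in 1:20) {
    yp <- permute_within_strata(y, strata)
    for (s in levels(strata)) {
      idx <- strata == s
      expect_identical(sort(yp[idx]), sort(y[idx]))
    }
  }

  sa <- coh$sensors
  g <- build_adjacency(sa)
  st <- channelwise_fit(coh$features$ratio, coh$records, "sleep_depth")
  cand <- form_clusters(st, g, p_thresh = 0.05, min_size = 2L)
  obs_max <- if (nrow(cand)) max(abs(cand$mass)) else 0
  idn <- suppressWarnings(permutation_null(
    coh$records, coh$features$ratio, "sleep_depth", graph = g,
    n_perm = 5L, p_thresh = 0.05, min_size = 2L, seed = 2L,
    use_identity = TRUE))
  expect_true(all(idn$max_mass == obs_max))
})

test_that("corrected p-values follow the add-one permutation convention", {
  null <- structure(list(max_mass = c(5, 10, 15, 20), n_perm = 4L,
                         seed = 1L, p_thresh = 0.005, min_size = 3L),
                    class = "permutation_null")
  cand <- data.frame(cluster = 1:2, sign = 1, size = 3,
                     mass = c(1, 100), members = c("a,b,c", "d,e,f"))
  res <- significant_clusters(cand, null, alpha = 0.05)
  expect_equal(res$corrected_p, c(5 / 5, 1 / 5))
  # mass above every null draw with 5000 permutations -> 1/5001
  null5k <- structure(list(max_mass = rep(1, 5000), n_perm = 5000L),
                      class = "permutation_null")
  r2 <- significant_clusters(data.frame(cluster = 1L, sign = 1, size = 3,
                                        mass = 50, members = "x,y,z"),
                             null5k)
  expect_equal(r2$corrected_p, 1 / 5001)
  expect_true(r2$significant)
})

test_that("corrected inference is invariant to sensor relabeling", {
  coh <- small_cohort(seed = 17L, n_participants = 8L, n_electrodes = 8L)
  sa <- coh$sensors
  g <- suppressWarnings(build_adjacency(sa))   # sparse toy cap may disconnect
  res <- suppressWarnings(cluster_permutation_test(
    coh$records, coh$features$ratio, "sleep_depth", graph = g,
    n_perm = 60L, p_thresh = 0.05, min_size = 2L, seed = 3L))
  # relabel electrodes (reversed names), keeping geometry and data aligned
  sa2 <- sa; sa2$label <- rev(sprintf("Q%02d", seq_len(nrow(sa))))
  feat2 <- coh$features$ratio
  colnames(feat2) <- sa2$label
  g2 <- suppressWarnings(build_adjacency(sa2))
  res2 <- suppressWarnings(cluster_permutation_test(
    coh$records, feat2, "sleep_depth", graph = g2,
    n_perm = 60L, p_thresh = 0.05, min_size = 2L, seed = 3L))
  expect_equal(res2$null$max_mass, res$null$max_mass, tolerance = 1e-9)
  expect_equal(res2$clusters$corrected_p, res$clusters$corrected_p,
               tolerance = 1e-9)
})
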