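pheno_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(duration_seconds = exp(rnorm(n, 3.5, 1)),
             vividness = rnorm(n, 3, 1),
             perceptual = rnorm(n, 3, 1),
             bizarreness = rnorm(n, 3, 1),
             emotional_intensity = rnorm(n, 3, 1),
             dream_awareness = rnorm(n, 3, 1))
}

test_that("report classification follows the questionnaire logic", {
  r <- classify_report(c("NCE", "NCE", "CEWR", "CEWR", "CE", "CEWR"),
                       c(TRUE, FALSE, TRUE, FALSE, NA, NA))
  expect_identical(r$report5, c("CESP", "UNC", "rCEWR", "sCEWR", "CE", NA))
  expect_identical(r$report3[6], "CEWR")   # subtype missing, class retained

  expect_error(classify_report("CE", TRUE), "contradictory")
  expect_error(classify_report("XX"), "invalid")

  # five-level marginals collapse exactly onto three-level marginals
  set.seed(5)
  r3 <- sample(c("CE", "CEWR", "NCE"), 500, TRUE)
  fu <- ifelse(r3 == "CE", NA, runif(500) > 0.5)
  cl <- classify_report(r3, fu)
  map <- c(CE = "CE", rCEWR = "CEWR", sCEWR = "CEWR",
           CESP = "NCE", UNC = "NCE")
  expect_identical(unname(map[cl$report5]), cl$report3)
})

test_that("BH q-values match the step-up oracle", {
  # hand-computed case: (0.01, 0.02, 0.03, 0.04) with m = 4
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("pairwise contrasts recover report-type differences with FDR", {
  coh <- generate_cohort(sim_config(n_participants = 24L, n_electrodes = 3L,
                                    seed = 41L))
  ct <- pairwise_contrasts(coh$records, "sleep_depth")
  expect_identical(nrow(ct), 6L)
  expect_true(all(ct$q >= ct$p - 1e-12))
  expect_equal(ct$q, bh_oracle(ct$p), tolerance = 1e-12)
  # CESP is the generating low point: CE vs CESP contrast is negative
  row <- ct[ct$level_a == "CE" & ct$level_b == "CESP", ]
  expect_lt(row$beta, 0)

  # two levels only: q equals p
  ct2 <- pairwise_contrasts(coh$records, "sleep_depth",
                            levels = c("CE", "NCE"))
  expect_identical(nrow(ct2), 1L)
  expect_equal(ct2$q, ct2$p)
})

test_that("proportion tests behave at their symmetry points", {
  # identical proportions for every participant -> Friedman statistic 0
  rec <- expand.grid(participant_id = sprintf("P%02d", 1:8),
                     i = 1:3, KEEP.OUT.ATTRS = FALSE)
  rec$report3 <- c("CE", "CEWR", "NCE")[rec$i]
  rec$report5 <- c("CE", "sCEWR", "UNC")[rec$i]
  pt <- proportion_tests(rec)
  expect_equal(pt$friedman_stat, 0, tolerance = 1e-9)

  expect_error(proportion_tests(rec[rec$participant_id %in%
                                      sprintf("P%02d", 1:3), ]),
               "at least 5")

  # default generator: UNC makes up about half of NCE -> sign-rank n.s.
  coh <- generate_cohort(sim_config(n_participants = 30L, n_electrodes = 3L,
                                    seed = 42L))
  pts <- proportion_tests(coh$records)
  expect_gt(pts$signrank_unc_cesp_p, 0.05)
  expect_equal(pts$mean_unc_share, 0.5, tolerance = 0.12)
  # while simple white dreams dominate their subtype clearly
  expect_lt(pts$signrank_scewr_rcewr_p, 0.01)
  expect_equal(pts$mean_scewr_share, 0.70, tolerance = 0.12)
})

test_that("phenomenology PCA has the expected eigenstructure", {
  # six independent unit-variance features: isotropic spectrum
  iso <- phenomenology_pca(pheno_frame(6000, seed = 2))
  expect_true(all(abs(iso$var_explained - 1 / 6) < 0.03))

  # a perfectly correlated pair concentrates 2/6 of the variance on PC1
  d <- pheno_frame(6000, seed = 3)
  d$perceptual <- d$vividness * 2 + 1   # affine copy, z-scores identical
  pc <- phenomenology_pca(d)
  expect_equal(pc$var_explained[1], 2 / 6, tolerance = 0.02)
  l1 <- pc$loadings[, 1]
  expect_equal(abs(l1[["vividness"]]), abs(l1[["perceptual"]]),
               tolerance = 1e-6)

  # orthonormal loadings, sign convention, z-scoring invariance
  L <- pc$loadings
  expect_lt(max(abs(t(L) %*% L - diag(6))), 1e-9)
  for (j in 1:6) expect_gte(L[which.max(abs(L[, j])), j], 0)

  d2 <- pheno_frame(300, seed = 4)
  p1 <- phenomenology_pca(d2)
  d3 <- d2
  d3$duration_seconds <- d2$duration_seconds^2   # log-scale affine
  d3$bizarreness <- 5 * d2$bizarreness - 2
  p2 <- phenomenology_pca(d3)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)

  dz <- pheno_frame(50, seed = 5); dz$vividness <- 3
  expect_error(phenomenology_pca(dz), "vividness")
  expect_error(phenomenology_pca(pheno_frame(4)), "at least 6")
})

test_that("component associations vanish when scores are shuffled", {
  coh <- generate_cohort(sim_config(n_participants = 24L, n_electrodes = 3L,
                                    likert = FALSE, seed = 44L))
  fit <- pc_association(coh$records, "sleep_depth", "pc1")
  b <- fit$coefficients
  expect_gt(b$estimate[b$term == "pc1"], 0.1)

  rec <- coh$records
  ok <- !is.na(rec$pc1)
  set.seed(8)
  rec$pc1[ok] <- sample(rec$pc1[ok])
  fsh <- pc_association(rec, "sleep_depth", "pc1")
  bs <- fsh$coefficients
  expect_lt(abs(bs$estimate[bs$term == "pc1"]), 0.1)
  expect_gt(bs$p[bs$term == "pc1"], 0.01)
})
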