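test_that("Wald statistics follow the squared standardized coefficient", {
  expect_equal(wald_statistic(2, 1)$wald, 4)
  w0 <- wald_statistic(0, 1)
  expect_equal(w0$wald, 0); expect_equal(w0$p, 1)
  # z = 1.96 corresponds to two-sided p ~ 0.05 via the chi-square(1) tail
  expect_equal(wald_statistic(1.96, 1)$p, 0.05, tolerance = 1e-3)
  expect_error(wald_statistic(1, 0), "> 0")
})

test_that("fit_lmm recovers a noise-free generating slope exactly", {
  cfg <- sim_config(
    n_participants = 10L, n_electrodes = 3L, participant_sd = 0,
    residual_sd = 0, likert = FALSE,
    report_effects_depth = c(CE = 0, rCEWR = 0, sCEWR = 0, CESP = 0, UNC = 0),
    fixed_effects = c(depth_activation = 0, depth_pc1 = 0, depth_pc2 = 0,
                      depth_sleepiness = 0, depth_time = 0.127),
    seed = 5L)
  coh <- generate_cohort(cfg)
  fit <- fit_lmm(coh$records, "sleep_depth")
  b <- fit$coefficients
  expect_equal(b$estimate[b$term == "time"], 0.127, tolerance = 1e-6)
  expect_true(all(abs(b$wald - (b$estimate / b$se)^2) < 1e-6 * b$wald))
})

test_that("with zero between-group variance the LMM collapses to OLS", {
  coh <- generate_cohort(sim_config(
    n_participants = 10L, n_electrodes = 3L, participant_sd = 0,
    residual_sd = 0.8, likert = FALSE, seed = 6L))
  fit <- fit_lmm(coh$records, "sleep_depth", predictors = "pc1")
  d <- coh$records[!is.na(coh$records$pc1), ]
  ols <- lm(sleep_depth ~ pc1 + factor(experiment) + factor(night) + time,
            data = d)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "pc1"],
               unname(coef(ols)[["pc1"]]), tolerance = 1e-6)
})

test_that("degenerate outcomes are rejected", {
  coh <- small_cohort(seed = 7L)
  rec <- coh$records
  rec$sleep_depth <- 3
  expect_error(fit_lmm(rec, "sleep_depth"), "constant")
})

test_that("adding a constant to the outcome shifts only the intercept", {
  coh <- small_cohort(seed = 8L)
  f1 <- fit_lmm(coh$records, "sleep_depth")
  rec <- coh$records
  rec$sleep_depth <- rec$sleep_depth + 10
  f2 <- fit_lmm(rec, "sleep_depth")
  c1 <- f1$coefficients; c2 <- f2$coefficients
  ni <- c1$term != "(Intercept)"
  expect_equal(c1$estimate[ni], c2$estimate[ni], tolerance = 1e-6)
  expect_equal(c2$estimate[!ni] - c1$estimate[!ni], 10, tolerance = 1e-6)
})

test_that("the compiled profiled-REML fitter agrees with lme4", {
  for (s in 1:3) {
    set.seed(100 + s)
    n <- 240; G <- 10
    g <- sample(rep(seq_len(G), length.out = n))
    x <- rnorm(n); tm <- runif(n, -1, 7)
    tau <- c(0.6, 0, 1.5)[s]  # includes a boundary (tau = 0) case
    y <- 1 + 0.3 * x - 0.05 * tm + rnorm(G, sd = tau)[g] + rnorm(n)
    X <- cbind(`(Intercept)` = 1, x = x, time = tm)
    d <- data.frame(y = y, x = x, time = tm, g = factor(g))
    for (reml in c(TRUE, FALSE)) {
      f <- fast_lmm(X, y, g, reml = reml)
      m <- suppressMessages(lme4::lmer(
        y ~ x + time + (1 | g), data = d, REML = reml,
        control = lme4::lmerControl(check.conv.singular = "ignore")))
      expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-5)
      expect_equal(unname(f$se),
                   unname(sqrt(diag(as.matrix(vcov(m))))), tolerance = 1e-4)
      expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-5)
    }
  }
})

test_that("channel-wise fits rank truly affected electrodes first", {
  sa <- grid_sensors(4L, 4L)
  topo <- rep(0, 16); topo[c(1, 2, 5, 6, 9, 10)] <- 2
  coh <- generate_cohort(sim_config(
    n_participants = 20L, sensors = sa, effect_topography = topo,
    fixed_effects = c(depth_activation = -0.5), seed = 21L))
  st <- channelwise_fit(coh$features$ratio, coh$records, "sleep_depth")
  top6 <- st$electrode[order(-st$wald)][1:6]
  expect_setequal(top6, sa$label[topo != 0])

  # duplicated feature columns give identical results
  feat <- coh$features$ratio
  feat2 <- feat; feat2[, 2] <- feat2[, 1]
  st2 <- channelwise_fit(feat2, coh$records, "sleep_depth")
  expect_equal(st2$wald[1], st2$wald[2], tolerance = 1e-9)

  # shuffling row order with ids intact changes nothing
  perm <- sample(nrow(feat))
  st3 <- channelwise_fit(feat[perm, ], coh$records, "sleep_depth")
  expect_equal(st3$estimate, st$estimate, tolerance = 1e-9)

  # misaligned ids are reported
  bad <- feat; rownames(bad)[1] <- "ghost"
  expect_error(channelwise_fit(bad, coh$records, "sleep_depth"), "ghost")
})

test_that("model comparison follows the likelihood-ratio conventions", {
  coh <- small_cohort(seed = 9L, n_participants = 16L)
  full <- fit_lmm(coh$records, "sleep_depth", predictors = "pc1")
  same <- compare_models(full, full)
  expect_equal(same$lrt_stat, 0)
  expect_equal(same$p, 1)

  # a strong simulated effect produces a decisive LRT
  cfgs <- sim_config(n_participants = 16L, n_electrodes = 3L,
                     fixed_effects = c(depth_pc1 = 0.8), likert = FALSE,
                     seed = 10L)
  cohs <- generate_cohort(cfgs)
  ce <- cohs$records[!is.na(cohs$records$pc1), ]
  fullS <- fit_lmm(ce, "sleep_depth", predictors = "pc1")
  redS <- fit_lmm(ce, "sleep_depth")
  cmp <- compare_models(fullS, redS)
  expect_identical(cmp$df, 1L)
  expect_lt(cmp$p, 1e-4)
  expect_gt(cmp$delta_aic, 0)

  # chi-square(1) reference: a statistic of 3.84 sits at p ~ 0.05
  fake <- function(ll, df, n) {
    structure(list(logLik_ml = ll, df_ml = df, n = n,
                   AIC = -2 * ll + 2 * df, BIC = -2 * ll + log(n) * df),
              class = "fit_result")
  }
  cmp2 <- compare_models(fake(-100, 5L, 50L), fake(-101.92, 4L, 50L))
  expect_equal(cmp2$p, 0.05, tolerance = 0.002)
  expect_error(compare_models(fake(-1, 4L, 50L), fake(-1, 5L, 50L)),
               "more parameters")
  expect_error(compare_models(fake(-1, 5L, 50L), fake(-1, 4L, 49L)),
               "different numbers")
})

test_that("tied ranks average over ties", {
  expect_equal(tied_rank(c(10, 20, 20, 40)), c(1, 2.5, 2.5, 4))
  expect_equal(tied_rank(rep(7, 5)), rep(3, 5))
  expect_equal(tied_rank(1:6), as.numeric(1:6))
  expect_true(all(diff(tied_rank(sort(rnorm(20)))) >= 0))
})
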