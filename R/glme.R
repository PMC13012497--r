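#' Fit a linear mixed-effects model with a participant random intercept
#'
#' The workhorse model of the analysis: a Gaussian-identity mixed model
#' `outcome ~ predictors + nuisance + (1 | group)`. Experiment and night
#' enter as treatment-coded factors (references: experiment 1, night 1),
#' time of night as a continuous covariate in decimal hours relative to
#' midnight. Coefficients are reported from the REML fit with Wald
#' statistics `W = (beta/SE)^2`, chi-square(1) p-values and Wald-normal
#' 95% CIs; log-likelihood, AIC and BIC come from an ML refit so nested
#' models are comparable via [compare_models()].
#'
#' Nuisance terms that are constant in the data (e.g. a single-experiment
#' cohort) are dropped with a message rather than failing.
#'
#' @param data data frame of awakening records.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor terms of interest
#'   (column names or formula terms such as `"exp_flag:log_ratio"`).
#' @param nuisance nuisance fixed-effect column names.
#' @param group grouping column for the random intercept.
#' @param reml fit coefficients by REML (default) or ML.
#' @return object of class `fit_result`: list with `coefficients` (term,
#'   estimate, se, wald, p, ci_lo, ci_hi), `logLik`, `logLik_ml`, `df_ml`,
#'   `AIC`, `BIC`, `n`, `n_groups`, `converged`, `formula`, and the
#'   underlying `lme4` fit in `$model`.
#' @export
fit_lmm <- function(data, outcome, predictors = character(),
                    nuisance = c("experiment", "night", "time"),
                    group = "participant_id", reml = TRUE) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  d <- prepare_model_data(data, group)
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  used <- unique(unlist(lapply(c(predictors, nuisance),
                               function(tm) all.vars(as.formula(paste("~", tm))))))
  for (v in used) d <- d[!is.na(d[[v]]), , drop = FALSE]
  if (length(unique(d[[group]])) < 2L) {
    stop("need at least 2 grouping levels")
  }
  y <- d[[outcome]]
  if (var(y) == 0) stop(sprintf("outcome '%s' is constant", outcome))
  nuisance <- keep_varying_terms(d, nuisance)
  rhs <- c(predictors, nuisance)
  fml <- as.formula(paste(outcome, "~",
                          if (length(rhs)) paste(rhs, collapse = " + ") else "1",
                          "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = d, REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  fit_ml <- if (reml) lme4::refitML(fit) else fit
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  be <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  W <- (be / se)^2
  pv <- pchisq(W, df = 1L, lower.tail = FALSE)
  z <- qnorm(0.975)
  coefs <- data.frame(term = names(be), estimate = unname(be),
                      se = unname(se), wald = unname(W), p = unname(pv),
                      ci_lo = unname(be - z * se),
                      ci_hi = unname(be + z * se),
                      stringsAsFactors = FALSE)
  ll_ml <- logLik(fit_ml)
  out <- list(coefficients = coefs,
              logLik = as.numeric(logLik(fit)),
              logLik_ml = as.numeric(ll_ml),
              df_ml = attr(ll_ml, "df"),
              AIC = stats::AIC(fit_ml),
              BIC = stats::BIC(fit_ml),
              n = nrow(d), n_groups = length(unique(d[[group]])),
              converged = conv,
              formula = deparse(fml),
              model = fit)
  class(out) <- "fit_result"
  out
}

#' @method print fit_result
#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$formula, "\n")
  cat(sprintf("  n = %d, groups = %d, logLik(REML-or-ML) = %.2f, AIC = %.1f, BIC = %.1f%s\n",
              x$n, x$n_groups, x$logLik, x$AIC, x$BIC,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

prepare_model_data <- function(data, group = "participant_id") {
  d <- data
  if ("experiment" %in% names(d)) d$experiment <- factor(d$experiment)
  if ("night" %in% names(d)) d$night <- factor(d$night)
  if (group %in% names(d)) d[[group]] <- factor(d[[group]])
  d
}

keep_varying_terms <- function(d, terms) {
  keep <- vapply(terms, function(tm) {
    vs <- all.vars(as.formula(paste("~", tm)))
    all(vapply(vs, function(v) length(unique(d[[v]])) > 1L, logical(1)))
  }, logical(1))
  if (any(!keep)) {
    message("dropping constant nuisance term(s): ",
            paste(terms[!keep], collapse = ", "))
  }
  terms[keep]
}

#' Wald statistic and chi-square p-value for a coefficient
#'
#' `W = (beta / SE)^2`, compared to a chi-square distribution with one
#' degree of freedom.
#'
#' @param beta coefficient estimate(s).
#' @param se standard error(s), strictly positive.
#' @return data frame with columns `wald` and `p`.
#' @export
wald_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("standard errors must be > 0")
  W <- (beta / se)^2
  data.frame(wald = W, p = pchisq(W, df = 1L, lower.tail = FALSE))
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Compares ML log-likelihoods of a full and a reduced (nested) model on
#' the same observations. `delta_aic`/`delta_bic` are signed so positive
#' values favour the full model (reduced minus full). For identical
#' models the LRT statistic is 0 and p = 1.
#'
#' @param full,reduced `fit_result`s with `reduced` nested in `full`.
#' @return list with `lrt_stat`, `df`, `p`, `delta_aic`, `delta_bic`.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  if (full$n != reduced$n) stop("models fit to different numbers of observations")
  df <- full$df_ml - reduced$df_ml
  if (df < 0) stop("reduced model has more parameters than full model")
  stat <- max(0, 2 * (full$logLik_ml - reduced$logLik_ml))
  p <- if (df == 0L) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  list(lrt_stat = stat, df = df, p = p,
       delta_aic = reduced$AIC - full$AIC,
       delta_bic = reduced$BIC - full$BIC)
}

#' Tied-rank transform
#'
#' Average ranks for ties; a monotone transform used to blunt the
#' influence of outliers in stage-distance covariates.
#'
#' @param values numeric vector (length >= 1); `NA`s are kept as `NA`.
#' @return numeric vector of ranks.
#' @export
tied_rank <- function(values) {
  stopifnot(length(values) >= 1L)
  rank(values, ties.method = "average", na.last = "keep")
}

#' Fast profiled-REML fit of a single-random-intercept model
#'
#' Direct interface to the compiled fitter used by the channel-wise and
#' permutation machinery. Fits `y = X beta + (1 | group) + e` by
#' profiled (RE)ML over the variance ratio.
#'
#' @param X numeric design matrix (including intercept column).
#' @param y numeric outcome.
#' @param group factor (or coercible) grouping vector.
#' @param reml REML (default) or ML.
#' @return list with `beta`, `se`, `sigma2`, `tau2`, `loglik`,
#'   `converged`.
#' @export
fast_lmm <- function(X, y, group, reml = TRUE) {
  g <- as.integer(factor(group))
  stopifnot(nrow(X) == length(y), length(g) == length(y))
  res <- .fastlmm_fit(as.matrix(X), as.numeric(y), g - 1L,
                      max(g), isTRUE(reml))
  if (isTRUE(res$converged)) {
    res$beta <- drop(res$beta); res$se <- drop(res$se)
    names(res$beta) <- names(res$se) <- colnames(X)
  }
  res
}

# Prepare aligned design pieces for channel-wise fitting. Returns the
# nuisance design (with intercept), the feature matrix aligned to records,
# the outcome, integer group codes, and the optional interaction modifier.
prep_channelwise <- function(features, records, outcome,
                             nuisance = c("experiment", "night", "time"),
                             modifier = NULL, group = "participant_id") {
  stopifnot(inherits(features, "band_power_table") || is.matrix(features))
  ids <- records$record_id
  miss <- setdiff(ids, rownames(features))
  extra <- setdiff(rownames(features), ids)
  if (length(miss) || length(extra)) {
    stop("feature rows and records do not align; missing: [",
         paste(head(miss, 5L), collapse = ", "), "], unmatched: [",
         paste(head(extra, 5L), collapse = ", "), "]")
  }
  feat <- features[match(ids, rownames(features)), , drop = FALSE]
  d <- prepare_model_data(records, group)
  nuisance <- keep_varying_terms(d, nuisance)
  modv <- NULL
  if (!is.null(modifier)) {
    modv <- if (is.character(modifier) && length(modifier) == 1L) {
      as.numeric(d[[modifier]])
    } else as.numeric(modifier)
    stopifnot(length(modv) == nrow(d))
  }
  rhs <- if (length(nuisance)) paste(nuisance, collapse = " + ") else "1"
  Xbase <- model.matrix(as.formula(paste("~", rhs)), data = d)
  if (!is.null(modv)) Xbase <- cbind(Xbase, modifier = modv)
  g <- as.integer(factor(d[[group]]))
  if (max(g) < 2L) stop("need at least 2 grouping levels")
  y <- as.numeric(d[[outcome]])
  if (anyNA(y) || anyNA(Xbase) || anyNA(feat)) {
    stop("channel-wise fitting requires complete data")
  }
  list(Xbase = Xbase, feat = unclass(feat), y = y, g = g, G = max(g),
       modifier = modv, labels = colnames(feat),
       strata = interaction(d[[group]], d$experiment, drop = TRUE))
}

channelwise_stats <- function(prep, y = prep$y) {
  res <- .fastlmm_channelwise(prep$Xbase, prep$feat, y, prep$g - 1L,
                              prep$G, prep$modifier)
  data.frame(electrode = prep$labels,
             estimate = res$estimate, se = res$se, wald = res$wald,
             p = pchisq(res$wald, df = 1L, lower.tail = FALSE),
             sign = sign(res$estimate),
             converged = res$converged == 1L,
             stringsAsFactors = FALSE)
}

#' Channel-wise mixed-model statistics across an electrode array
#'
#' Fits one mixed model per electrode relating the outcome to that
#' electrode's band-power feature, with the configured nuisance fixed
#' effects and a participant random intercept, and returns the Wald
#' topography. With `modifier` supplied (a 0/1 conscious-experience flag
#' or any numeric column), the model instead tests the feature-by-modifier
#' interaction, whose statistic is reported.
#'
#' Uses the compiled profiled-REML fitter; results agree with
#' [fit_lmm()]/`lme4` to numerical precision, at about three orders of
#' magnitude less cost, which is what makes the 5,000-permutation
#' cluster correction feasible.
#'
#' @param features `band_power_table` (records x electrodes, log scale).
#' @param records awakening data frame (must contain `record_id`).
#' @param outcome outcome column name.
#' @param nuisance nuisance fixed-effect columns.
#' @param modifier optional interaction modifier (column name or numeric
#'   vector); when given, the reported statistic is for
#'   `feature x modifier`.
#' @param group random-intercept grouping column.
#' @return data frame with one row per electrode: `electrode`,
#'   `estimate`, `se`, `wald`, `p`, `sign`, `converged`. Non-converged
#'   electrodes carry `NA` statistics and are excluded from clustering.
#' @export
channelwise_fit <- function(features, records, outcome,
                            nuisance = c("experiment", "night", "time"),
                            modifier = NULL, group = "participant_id") {
  prep <- prep_channelwise(features, records, outcome, nuisance,
                           modifier, group)
  channelwise_stats(prep)
}
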