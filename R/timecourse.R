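#' Time-of-night polynomial trend with BIC order selection
#'
#' Fits mixed models with raw time powers up to each candidate order
#' (linear, quadratic, cubic) plus the supplied covariates and a
#' participant random intercept, compares ML-fit BICs, and reports the
#' winning order's REML coefficients. For the two subjective ratings the
#' other rating is typically supplied as a covariate to absorb shared
#' variance.
#'
#' @param records awakening data frame.
#' @param outcome outcome column name.
#' @param covariates additional fixed-effect columns beyond the standard
#'   experiment/night nuisance (e.g. the co-rating).
#' @param orders candidate polynomial orders.
#' @param group random-intercept grouping column.
#' @return object of class `trend_fit`: `outcome`, `order` (BIC winner),
#'   `coefficients` (REML, winning order), `bic` (named per order),
#'   `time_range`, `fit` (the winning REML `fit_result`).
#' @export
fit_trend <- function(records, outcome, covariates = character(),
                      orders = 1:3, group = "participant_id") {
  d <- records[!is.na(records[[outcome]]), , drop = FALSE]
  for (v in covariates) d <- d[!is.na(d[[v]]), , drop = FALSE]
  n <- nrow(d)
  orders <- sort(unique(as.integer(orders)))
  usable <- orders[orders + 8L < n]
  if (length(usable) < length(orders)) {
    warning("dropping order(s) with too few observations: ",
            paste(setdiff(orders, usable), collapse = ", "))
  }
  if (!length(usable)) stop("no usable polynomial order")
  time_terms <- function(k) {
    c("time", if (k >= 2) sprintf("I(time^%d)", 2:k))
  }
  X <- outer(d$time, usable, `^`)
  if (kappa(cbind(1, X)) > 1e6) {
    warning("raw time-power design is ill-conditioned; coefficients remain interpretable but SEs may be inflated")
  }
  bics <- setNames(numeric(length(usable)), paste0("order", usable))
  fits_ml <- vector("list", length(usable))
  for (i in seq_along(usable)) {
    f <- fit_lmm(d, outcome,
                 predictors = c(time_terms(usable[i]), covariates),
                 nuisance = c("experiment", "night"),
                 group = group, reml = FALSE)
    bics[i] <- f$BIC
    fits_ml[[i]] <- f
  }
  best <- usable[which.min(bics)]
  fit <- fit_lmm(d, outcome,
                 predictors = c(time_terms(best), covariates),
                 nuisance = c("experiment", "night"),
                 group = group, reml = TRUE)
  structure(list(outcome = outcome, order = best,
                 coefficients = fit$coefficients, bic = bics,
                 time_range = range(d$time), fit = fit),
            class = "trend_fit")
}

#' @method print trend_fit
#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: BIC-selected order %d (BICs: %s)\n",
              x$outcome, x$order,
              paste(sprintf("%s=%.1f", names(x$bic), x$bic), collapse = ", ")))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Extremum time of a quadratic trend
#'
#' For a quadratic fixed-effect polynomial `a + b t + c t^2` the
#' stationary point is `-b / (2c)`: a peak when the curvature `c` is
#' negative (the usual sleepiness case), a trough otherwise (flagged).
#' Times outside the observed range are also flagged.
#'
#' @param trend a [fit_trend()] result with `order == 2`.
#' @return list with `time` (hours relative to midnight), `type`
#'   (`"peak"` or `"trough"`), and `in_range`.
#' @export
estimate_peak <- function(trend) {
  stopifnot(inherits(trend, "trend_fit"))
  if (trend$order != 2L) {
    stop(sprintf("peak estimation needs a quadratic fit (order is %d)",
                 trend$order))
  }
  co <- trend$coefficients
  b <- co$estimate[co$term == "time"]
  c2 <- co$estimate[co$term == "I(time^2)"]
  if (c2 == 0) stop("quadratic coefficient is zero")
  tm <- -b / (2 * c2)
  list(time = tm,
       type = if (c2 < 0) "peak" else "trough",
       in_range = tm >= trend$time_range[1] && tm <= trend$time_range[2])
}

#' Post-cutoff divergence of two ratings over time
#'
#' Reshapes depth and sleepiness into long format (two rows per
#' awakening), restricts to awakenings at or after the cutoff (default
#' 4 AM, the fitted sleepiness peak region), and fits
#' `value ~ experiment + night + measure * time` with a random intercept
#' per participant-by-measure cell, so each rating keeps its own
#' participant offset while the measure-by-time interaction estimates
#' how much more slowly the second measure rises with time than the
#' first.
#'
#' @param records awakening data frame with `sleep_depth` and
#'   `sleepiness`.
#' @param cutoff inclusive time cutoff in hours relative to midnight.
#' @param measures outcome columns; the first is the reference level of
#'   the measure factor.
#' @return a `fit_result`; the interaction term is
#'   `measure<second>:time`.
#' @export
measure_by_time_interaction <- function(records, cutoff = 4.0,
                                        measures = c("sleep_depth",
                                                     "sleepiness")) {
  stopifnot(all(measures %in% names(records)))
  d <- records[records$time >= cutoff, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no data at or after cutoff %.1f h", cutoff))
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(record_id = d$record_id, participant_id = d$participant_id,
               experiment = d$experiment, night = d$night, time = d$time,
               measure = m, value = d[[m]], stringsAsFactors = FALSE)
  }))
  long$measure <- factor(long$measure, levels = measures)
  long$participant_measure <- interaction(long$participant_id, long$measure)
  fit_lmm(long, "value", predictors = "measure * time",
          nuisance = c("experiment", "night"),
          group = "participant_measure")
}

#' Nuisance-adjusted outcome values for display
#'
#' Residualises an outcome against the nuisance fixed effects and the
#' participant random intercepts, then recentres to the raw grand mean:
#' a display/diagnostic transform (the inferential models always adjust
#' internally instead). The default nuisance set (experiment, night,
#' participant) deliberately excludes time so time courses remain
#' visible in the adjusted values.
#'
#' @param records awakening data frame.
#' @param outcome outcome column.
#' @param nuisance nuisance fixed-effect columns.
#' @param covariates extra fixed-effect columns also removed (e.g. the
#'   co-rating).
#' @return numeric vector of adjusted values aligned with `records`
#'   (`NA` where the outcome is missing).
#' @export
adjusted_values <- function(records, outcome,
                            nuisance = c("experiment", "night"),
                            covariates = character()) {
  keep <- !is.na(records[[outcome]])
  for (v in covariates) keep <- keep & !is.na(records[[v]])
  d <- prepare_model_data(records[keep, , drop = FALSE])
  terms <- keep_varying_terms(d, c(nuisance, covariates))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- as.formula(paste(outcome, "~", rhs, "+ (1 | participant_id)"))
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  contrib <- predict(fit) - lme4::fixef(fit)[["(Intercept)"]]
  adj <- d[[outcome]] - contrib
  adj <- adj - mean(adj) + mean(d[[outcome]])
  out <- rep(NA_real_, nrow(records))
  out[keep] <- adj
  out
}
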