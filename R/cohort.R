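#' Simulation configuration for a synthetic serial-awakening cohort
#'
#' Captures the generative design the downstream analyses assume: a
#' two-experiment cohort of participants (nested in experiment), four
#' nights each, repeated N2 awakenings with report classification,
#' Likert ratings, phenomenology, and electrode-level band-power features
#' driven by a latent cortical-activation variable.
#'
#' Defaults mirror the study design the package emulates: 44 participants
#' x 4 nights with 4-8 retained awakenings per night (about 1,050
#' records), report-type probabilities matching the published report mix
#' (CE 42.2%, CEWR 35.5% of which 70.4% simple, NCE 22.3% of which 50.2%
#' unconscious), awakening times uniform between 1 h before and 7.5 h
#' after midnight, a linear increase of sleep depth with time (0.127
#' points/h), a quadratic sleepiness time course peaking at 3.3 h, and
#' phenomenology-component slopes of 0.277 (immersion) and -0.195
#' (reflective thought) on sleep depth.
#'
#' @param n_participants number of participants.
#' @param n_nights nights per participant.
#' @param awakenings_per_night integer range `c(lo, hi)` of retained
#'   awakenings per night (drawn uniformly).
#' @param report_probabilities named 5-vector of probabilities over
#'   `CE, rCEWR, sCEWR, CESP, UNC`; must sum to 1 (tolerance 1e-9).
#' @param participant_sd SD of the participant random intercept
#'   (rating-scale units), applied independently to depth and sleepiness.
#' @param residual_sd residual SD of the latent ratings.
#' @param fixed_effects named numeric vector of generative coefficients;
#'   see Details. Partial overrides are merged into the defaults.
#' @param report_effects_depth,report_effects_sleepiness named 5-vectors of
#'   report-type offsets on each rating.
#' @param effect_topography per-electrode coefficient vector linking the
#'   latent activation to the gamma/delta ratio feature (defaults to a
#'   uniform 1, i.e., a global activation signal); see
#'   [inject_cluster_effect()] for localized ground truth.
#' @param feature_noise_sd SD of electrode-level log band-power noise.
#' @param n_electrodes electrode count for the default cap layout (used
#'   when `sensors` is `NULL`).
#' @param sensors optional [sensor_array()] overriding the default cap.
#' @param time_window hours relative to midnight, `c(lo, hi)`.
#' @param likert round and clip ratings to the 1-5 Likert scale
#'   (`TRUE`, the realistic default) or keep the continuous latent scale.
#' @param include_segments also synthesise raw EEG segments per record
#'   (slow; intended for small cohorts).
#' @param segment_duration,segment_fs raw segment length (s) and sampling
#'   rate (Hz) when `include_segments = TRUE`.
#' @param seed master seed; all stages derive child streams from it via
#'   [child_seed()].
#'
#' @details `fixed_effects` entries (all optional, defaults shown by
#' `sim_config()$fixed_effects`): `depth_intercept`, `depth_time`,
#' `depth_experiment` (experiment 2 offset), `depth_night` (per-night
#' linear step), `depth_activation` (slope on the latent activation),
#' `depth_pc1`, `depth_pc2` (slopes on the realized phenomenology
#' component scores of CE records), `depth_sleepiness`;
#' `sleepiness_intercept`, `sleepiness_time`, `sleepiness_time2`,
#' `sleepiness_experiment`, `sleepiness_night`, `sleepiness_activation`.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 44L,
                       n_nights = 4L,
                       awakenings_per_night = c(4L, 8L),
                       report_probabilities = c(
                         CE    = 0.421875,
                         rCEWR = 0.35546875 * (1 - 0.7039),
                         sCEWR = 0.35546875 * 0.7039,
                         CESP  = 0.22265625 * (1 - 0.5015),
                         UNC   = 0.22265625 * 0.5015),
                       participant_sd = 0.5,
                       residual_sd = 0.9,
                       fixed_effects = NULL,
                       report_effects_depth = c(
                         CE = 0.552, rCEWR = 0.7353, sCEWR = 0.4763,
                         CESP = 0, UNC = 0.593),
                       report_effects_sleepiness = c(
                         CE = 0, rCEWR = 0, sCEWR = 0,
                         CESP = 0, UNC = 0.31),
                       effect_topography = NULL,
                       feature_noise_sd = 0.3,
                       n_electrodes = 256L,
                       sensors = NULL,
                       time_window = c(-1, 7.5),
                       likert = TRUE,
                       include_segments = FALSE,
                       segment_duration = 150,
                       segment_fs = 128,
                       seed = 1L) {
  fe_default <- c(
    depth_intercept = 2.6, depth_time = 0.127, depth_experiment = 0.10,
    depth_night = 0.03, depth_activation = -0.20,
    depth_pc1 = 0.277, depth_pc2 = -0.195, depth_sleepiness = 0,
    sleepiness_intercept = 2.2, sleepiness_time = 0.528,
    sleepiness_time2 = -0.08, sleepiness_experiment = 0,
    sleepiness_night = 0, sleepiness_activation = -0.15)
  if (!is.null(fixed_effects)) {
    if (is.null(names(fixed_effects)) ||
        !all(names(fixed_effects) %in% names(fe_default))) {
      stop("unknown fixed_effects names: ",
           paste(setdiff(names(fixed_effects), names(fe_default)),
                 collapse = ", "))
    }
    fe_default[names(fixed_effects)] <- fixed_effects
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_nights = as.integer(n_nights),
    awakenings_per_night = as.integer(awakenings_per_night),
    report_probabilities = report_probabilities,
    participant_sd = participant_sd,
    residual_sd = residual_sd,
    fixed_effects = fe_default,
    report_effects_depth = report_effects_depth,
    report_effects_sleepiness = report_effects_sleepiness,
    effect_topography = effect_topography,
    feature_noise_sd = feature_noise_sd,
    n_electrodes = as.integer(n_electrodes),
    sensors = sensors,
    time_window = time_window,
    likert = isTRUE(likert),
    include_segments = isTRUE(include_segments),
    segment_duration = segment_duration,
    segment_fs = segment_fs,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$report_probabilities
  if (length(p) != 5L ||
      !setequal(names(p), c("CE", "rCEWR", "sCEWR", "CESP", "UNC"))) {
    stop("report_probabilities must be named over CE, rCEWR, sCEWR, CESP, UNC")
  }
  if (any(p < 0) || any(p > 1)) stop("report probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("report probabilities must sum to 1 (got %.12f)", sum(p)))
  }
  if (cfg$participant_sd < 0 || cfg$residual_sd < 0 ||
      cfg$feature_noise_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (cfg$n_participants < 0 || cfg$n_nights < 0) stop("counts must be >= 0")
  if (length(cfg$awakenings_per_night) != 2L ||
      any(cfg$awakenings_per_night < 0) ||
      cfg$awakenings_per_night[1] > cfg$awakenings_per_night[2]) {
    stop("awakenings_per_night must be a nondecreasing nonnegative range")
  }
  if (diff(cfg$time_window) <= 0) stop("time_window must be increasing")
  invisible(cfg)
}

# internal phenomenology factor loadings: component 1 = perceptual
# immersion (duration, vividness, perceptual content, bizarreness, emotion),
# component 2 = reflective thought (awareness + thought-like vs vivid).
.PHENO_FEATURES <- c("duration_seconds", "vividness", "perceptual",
                     "bizarreness", "emotional_intensity", "dream_awareness")
.PHENO_L1 <- c(0.8, 0.7, 0.7, 0.6, 0.6, 0.1)
.PHENO_L2 <- c(0.0, -0.4, -0.5, 0.0, 0.0, 0.8)
.PHENO_NOISE <- 0.5

#' Generate a synthetic serial-awakening cohort
#'
#' Draws a full dataset with the statistical structure the analysis
#' pipeline assumes: participants nested in experiment with Gaussian
#' random intercepts, report types multinomial over the five-level
#' taxonomy, awakening times uniform in the configured window, electrode
#' band-power features driven by a latent activation with configurable
#' topography, phenomenology ratings for CE records driven by two latent
#' components, and Likert ratings assembled from the configured linear
#' predictor plus Gaussian noise (rounded/clipped to 1-5 on request).
#'
#' The generator is deterministic given `config$seed`; each internal stage
#' draws from its own child stream so e.g. enlarging the electrode count
#' does not change the drawn report types.
#'
#' @param config a [sim_config()].
#' @return an object of class `cohort_dataset`: list with elements
#'   `sensors`, `records` (one row per awakening), `features` (named list
#'   of `band_power_table` matrices: `delta`, `gamma`, `ratio`),
#'   `segments` (optional named list of [eeg_segment()]s), and `truth`
#'   (the generating config plus derived per-electrode regression slopes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  sensors <- if (!is.null(cfg$sensors)) cfg$sensors
             else spherical_cap_array(cfg$n_electrodes)
  E <- nrow(sensors)
  topo <- if (is.null(cfg$effect_topography)) rep(1, E) else cfg$effect_topography
  if (length(topo) != E) stop("effect_topography length must match sensors")

  # -- design: participants, nights, awakening times ------------------------
  des <- with_seed(child_seed(cfg$seed, "design"), {
    if (cfg$n_participants == 0L) {
      data.frame(record_id = character(), participant_id = character(),
                 experiment = integer(), night = integer(), time = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      pid <- sprintf("P%03d", seq_len(cfg$n_participants))
      expt <- ifelse(seq_len(cfg$n_participants) <=
                       ceiling(cfg$n_participants / 2), 1L, 2L)
      rows <- list()
      for (i in seq_len(cfg$n_participants)) {
        for (nt in seq_len(cfg$n_nights)) {
          k <- if (cfg$awakenings_per_night[1] == cfg$awakenings_per_night[2])
            cfg$awakenings_per_night[1]
          else sample(cfg$awakenings_per_night[1]:cfg$awakenings_per_night[2], 1L)
          if (k == 0L) next
          tm <- sort(runif(k, cfg$time_window[1], cfg$time_window[2]))
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = pid[i], experiment = expt[i], night = nt,
            time = tm, stringsAsFactors = FALSE)
        }
      }
      d <- if (length(rows)) do.call(rbind, rows) else
        data.frame(participant_id = character(), experiment = integer(),
                   night = integer(), time = numeric())
      d$record_id <- sprintf("A%05d", seq_len(nrow(d)))
      d[c("record_id", "participant_id", "experiment", "night", "time")]
    }
  })
  n <- nrow(des)

  # -- report types ---------------------------------------------------------
  lv5 <- c("CE", "rCEWR", "sCEWR", "CESP", "UNC")
  rep5 <- with_seed(child_seed(cfg$seed, "reports"), {
    if (n == 0L) character() else
      sample(lv5, n, replace = TRUE, prob = cfg$report_probabilities[lv5])
  })
  rep3 <- report5_to_report3(rep5)

  # -- latent activation and band-power features ----------------------------
  feat <- with_seed(child_seed(cfg$seed, "features"), {
    a <- rnorm(n)
    nd <- matrix(rnorm(n * E, sd = cfg$feature_noise_sd), n, E)
    ng <- matrix(rnorm(n * E, sd = cfg$feature_noise_sd), n, E)
    delta <- 2.0 + nd - 0.5 * outer(a, topo)
    gamma <- -1.0 + ng + 0.5 * outer(a, topo)
    list(a = a, delta = delta, gamma = gamma)
  })
  a <- feat$a
  ratio <- feat$gamma - feat$delta
  dimn <- list(des$record_id, sensors$label)
  features <- list(
    delta = band_power_table(`dimnames<-`(feat$delta, dimn), "delta"),
    gamma = band_power_table(`dimnames<-`(feat$gamma, dimn), "gamma"),
    ratio = band_power_table(`dimnames<-`(ratio, dimn), "ratio"))

  # -- phenomenology for CE records ----------------------------------------
  is_ce <- rep5 == "CE"
  pheno <- matrix(NA_real_, n, length(.PHENO_FEATURES),
                  dimnames = list(des$record_id, .PHENO_FEATURES))
  f1 <- rep(NA_real_, n); f2 <- rep(NA_real_, n)
  if (any(is_ce)) {
    ph <- with_seed(child_seed(cfg$seed, "phenomenology"), {
      m <- sum(is_ce)
      l1 <- rnorm(m); l2 <- rnorm(m)
      eps <- matrix(rnorm(m * 6, sd = .PHENO_NOISE), m, 6)
      z <- outer(l1, .PHENO_L1) + outer(l2, .PHENO_L2) + eps
      # duration in seconds (log-normal), remaining features Likert-like
      vals <- cbind(exp(3.5 + z[, 1]),
                    3 + z[, 2:6])
      if (cfg$likert) {
        vals[, 2:6] <- pmin(.LIKERT_MAX, pmax(.LIKERT_MIN, round(vals[, 2:6])))
      }
      list(vals = vals, l1 = l1, l2 = l2)
    })
    pheno[is_ce, ] <- ph$vals
    f1[is_ce] <- ph$l1; f2[is_ce] <- ph$l2
  }

  # realized component scores: the outcome model uses the scores the
  # analysis itself would compute, so generating slopes are recoverable
  # exactly rather than attenuated by factor-score estimation error.
  pc1 <- rep(NA_real_, n); pc2 <- rep(NA_real_, n)
  cc <- is_ce & complete.cases(pheno)
  if (sum(cc) >= 6L) {
    pca <- phenomenology_pca(as.data.frame(pheno[cc, , drop = FALSE]))
    # orient recovered components along the generating latents
    s1 <- sign(stats::cor(pca$scores[, 1], f1[cc])); if (is.na(s1) || s1 == 0) s1 <- 1
    s2 <- sign(stats::cor(pca$scores[, 2], f2[cc])); if (is.na(s2) || s2 == 0) s2 <- 1
    pc1[cc] <- s1 * pca$scores[, 1]
    pc2[cc] <- s2 * pca$scores[, 2]
  }

  # -- ratings --------------------------------------------------------------
  fe <- cfg$fixed_effects
  ratings <- with_seed(child_seed(cfg$seed, "ratings"), {
    if (n == 0L) {
      list(depth = numeric(), sleepiness = numeric())
    } else {
      pid_f <- factor(des$participant_id)
      u_d <- rnorm(nlevels(pid_f), sd = cfg$participant_sd)[as.integer(pid_f)]
      u_s <- rnorm(nlevels(pid_f), sd = cfg$participant_sd)[as.integer(pid_f)]
      e2 <- as.numeric(des$experiment == 2L)
      rep_d <- cfg$report_effects_depth[rep5]
      rep_s <- cfg$report_effects_sleepiness[rep5]
      pc1c <- ifelse(is.na(pc1), 0, pc1)
      pc2c <- ifelse(is.na(pc2), 0, pc2)
      sleepiness <- fe["sleepiness_intercept"] +
        fe["sleepiness_time"] * des$time +
        fe["sleepiness_time2"] * des$time^2 +
        fe["sleepiness_experiment"] * e2 +
        fe["sleepiness_night"] * (des$night - 1) +
        fe["sleepiness_activation"] * a + rep_s + u_s +
        rnorm(n, sd = cfg$residual_sd)
      depth <- fe["depth_intercept"] +
        fe["depth_time"] * des$time +
        fe["depth_experiment"] * e2 +
        fe["depth_night"] * (des$night - 1) +
        fe["depth_activation"] * a +
        fe["depth_pc1"] * pc1c + fe["depth_pc2"] * pc2c +
        fe["depth_sleepiness"] * sleepiness + rep_d + u_d +
        rnorm(n, sd = cfg$residual_sd)
      if (cfg$likert) {
        depth <- pmin(.LIKERT_MAX, pmax(.LIKERT_MIN, round(depth)))
        sleepiness <- pmin(.LIKERT_MAX, pmax(.LIKERT_MIN, round(sleepiness)))
      }
      list(depth = unname(depth), sleepiness = unname(sleepiness))
    }
  })

  records <- des
  records$report3 <- rep3
  records$report5 <- rep5
  records$sleep_depth <- ratings$depth
  records$sleepiness <- ratings$sleepiness
  records$pc1 <- pc1
  records$pc2 <- pc2
  records <- cbind(records, as.data.frame(pheno))
  rownames(records) <- NULL

  # -- optional raw EEG segments -------------------------------------------
  segments <- NULL
  if (cfg$include_segments && n > 0L) {
    segments <- vector("list", n)
    names(segments) <- des$record_id
    base_seed <- child_seed(cfg$seed, "segments")
    for (i in seq_len(n)) {
      # activation shifts power from delta to gamma on the log scale
      damp <- sqrt(2 * exp(2.0 - 0.5 * a[i]))
      gamp <- sqrt(2 * exp(-1.0 + 0.5 * a[i]))
      segments[[i]] <- generate_eeg_segment(
        band_profile = c(delta = damp, gamma = gamp),
        duration = cfg$segment_duration, fs = cfg$segment_fs,
        n_channels = E, channel_labels = sensors$label,
        noise_sd = 0.5, pink_sd = 1,
        seed = (base_seed + i) %% 2147483647)
    }
  }

  # derived per-electrode regression slope of depth on the ratio feature
  # (errors-in-variables form: topography slope attenuated by feature noise)
  chan_slope <- fe["depth_activation"] * topo /
    (topo^2 + 2 * cfg$feature_noise_sd^2)

  out <- list(
    sensors = sensors,
    records = records,
    features = features,
    segments = segments,
    truth = list(config = cfg, effect_topography = setNames(topo, sensors$label),
                 channel_slope_ratio = setNames(chan_slope, sensors$label),
                 latent_activation = setNames(a, des$record_id)))
  class(out) <- "cohort_dataset"
  out
}

#' @method print cohort_dataset
#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d awakenings, %d participants, %d electrodes\n",
              nrow(x$records),
              length(unique(x$records$participant_id)),
              nrow(x$sensors)))
  if (nrow(x$records)) {
    print(table(x$records$report3))
  }
  invisible(x)
}

report5_to_report3 <- function(report5) {
  map <- c(CE = "CE", rCEWR = "CEWR", sCEWR = "CEWR",
           CESP = "NCE", UNC = "NCE")
  unname(map[report5])
}

#' Band-power table constructor
#'
#' An awakenings x electrodes matrix of log band powers (natural log of
#' Hz-integrated power) for one band or the gamma/delta log-ratio.
#'
#' @param values numeric matrix with record-id rownames and channel-label
#'   colnames.
#' @param band band name (e.g. `"delta"`, `"gamma"`, `"ratio"`).
#' @param definition optional [band_definition()].
#' @return a `band_power_table` (matrix with attributes).
#' @export
band_power_table <- function(values, band, definition = NULL) {
  stopifnot(is.matrix(values))
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("band_power_table needs record-id rownames and channel colnames")
  }
  structure(values, band = band, definition = definition,
            class = c("band_power_table", class(values)))
}
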