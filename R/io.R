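#' Read and validate an awakening table
#'
#' Reads one row per awakening from CSV. Mandatory columns: `record_id`,
#' `participant_id`, `experiment` (1/2), `night` (1-4), `time` (decimal
#' hours relative to midnight, may be negative), `report3`
#' (CE/CEWR/NCE). Optional: `report5` (subtype, may be blank for the
#' occasional report whose follow-up was unavailable), `sleep_depth` and
#' `sleepiness` (Likert 1-5), the six phenomenology columns, and
#' `stage_distance` (minutes). Invariant violations are reported with
#' row numbers.
#'
#' @param path CSV path.
#' @return validated data frame of awakening records.
#' @export
read_awakening_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_awakening_table(d)
}

validate_awakening_table <- function(d) {
  mandatory <- c("record_id", "participant_id", "experiment", "night",
                 "time", "report3")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) stop("missing mandatory columns: ",
                         paste(miss, collapse = ", "))
  problems <- character()
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("%s (rows %s)", what,
                                       paste(head(rows, 10L), collapse = ", ")))
    }
  }
  dup <- which(duplicated(d$record_id))
  note(dup, "duplicate record_id")
  note(which(!d$report3 %in% c("CE", "CEWR", "NCE")), "unknown report3 code")
  if ("report5" %in% names(d)) {
    d$report5[d$report5 %in% c("", "NA")] <- NA_character_
    lv5 <- c("CE", "rCEWR", "sCEWR", "CESP", "UNC")
    note(which(!is.na(d$report5) & !d$report5 %in% lv5),
         "unknown report5 code")
    ok5 <- is.na(d$report5) | report5_to_report3(d$report5) == d$report3
    note(which(!ok5), "report5 inconsistent with report3")
  }
  for (col in c("sleep_depth", "sleepiness")) {
    if (col %in% names(d)) {
      v <- d[[col]]
      bad <- which(!is.na(v) & (v < .LIKERT_MIN | v > .LIKERT_MAX))
      note(bad, sprintf("%s outside the 1-5 Likert range", col))
    }
  }
  if ("duration_seconds" %in% names(d)) {
    note(which(!is.na(d$duration_seconds) & d$duration_seconds <= 0),
         "nonpositive duration_seconds")
  }
  note(which(!d$experiment %in% c(1L, 2L)), "experiment must be 1 or 2")
  if (length(problems)) {
    stop("invalid awakening table:\n  ", paste(problems, collapse = "\n  "))
  }
  d
}

#' Write an awakening table (locale-independent CSV)
#'
#' @param records awakening data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_awakening_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write electrode coordinates as `label,x,y,z` CSV
#' @param sensors a [sensor_array()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_array <- function(sensors, path) {
  write.csv(as.data.frame(sensors), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read electrode coordinates from CSV
#' @param path CSV with columns `label,x,y,z`.
#' @return a [sensor_array()].
#' @export
read_sensor_array <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  sensor_array(d[c("x", "y", "z")], labels = d$label)
}

#' Write a band-power table as CSV plus JSON metadata
#'
#' Rows are record ids, columns channel labels. A sibling `.json` file
#' records the band edges, Welch parameters, and log base.
#'
#' @param table a `band_power_table`.
#' @param path CSV output path.
#' @param meta extra metadata fields to merge into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_band_power_table <- function(table, path, meta = list()) {
  df <- data.frame(record_id = rownames(table), unclass(table),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  defn <- attr(table, "definition")
  info <- c(list(band = attr(table, "band"),
                 f_lo = if (!is.null(defn)) defn$f_lo else NA,
                 f_hi = if (!is.null(defn)) defn$f_hi else NA,
                 log_base = "e"),
            meta)
  jsonlite::write_json(info, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a band-power table written by [write_band_power_table()]
#' @param path CSV path.
#' @param band band name (falls back to the JSON sidecar when present).
#' @return a `band_power_table`.
#' @export
read_band_power_table <- function(path, band = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[-1L])
  rownames(m) <- d$record_id
  if (is.null(band)) {
    side <- sub("\\.csv$", ".json", path)
    band <- if (file.exists(side)) jsonlite::read_json(side)$band else "unknown"
  }
  band_power_table(m, band)
}

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] (simulation mode) or `NULL` with `paths`
#'   pointing at input files.
#' @param paths named list of input paths (`awakenings`, `sensors`,
#'   optional band-power CSVs) for file mode.
#' @param stages analysis stages to run, subset of
#'   `c("channelwise", "contrasts", "pca", "timecourse")`.
#' @param n_perm,p_thresh,min_size,alpha cluster-permutation settings.
#' @param adjacency adjacency construction method.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, paths = NULL,
                       stages = c("channelwise", "contrasts", "pca",
                                  "timecourse"),
                       n_perm = 5000L, p_thresh = 0.005, min_size = 3L,
                       alpha = 0.05, adjacency = "distance",
                       seed = 1L, out_dir = "results") {
  if (is.null(sim) && is.null(paths)) stop("need either sim or paths")
  if (!is.null(paths)) {
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  structure(list(sim = sim, paths = paths,
                 stages = match.arg(stages, several.ok = TRUE),
                 n_perm = as.integer(n_perm), p_thresh = p_thresh,
                 min_size = as.integer(min_size), alpha = alpha,
                 adjacency = adjacency, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates or ingests a cohort, then executes the configured stages:
#' channel-wise mixed models with cluster-mass permutation correction on
#' the gamma/delta ratio vs sleep depth (`"channelwise"`), FDR-corrected
#' pairwise report-type contrasts (`"contrasts"`), the phenomenology PCA
#' and component associations (`"pca"`), and time-of-night trend models
#' with the post-4AM divergence test (`"timecourse"`). All tabular
#' outputs are written as locale-independent CSV under `out_dir`
#' together with a provenance manifest (parameters, seeds, input
#' digests); re-running the same configuration reproduces every
#' stochastic output bit for bit.
#'
#' @param config a [run_config()].
#' @return invisible list of in-memory results per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    message(sprintf("[dreamdepth] %s %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  results <- list()

  if (!is.null(config$sim)) {
    log_stage("simulate: generating synthetic cohort (seed %d)",
              config$sim$seed)
    cohort <- generate_cohort(config$sim)
    sensors <- cohort$sensors
    records <- cohort$records
    features <- cohort$features
  } else {
    log_stage("ingest: reading %s", config$paths$awakenings)
    records <- read_awakening_table(config$paths$awakenings)
    sensors <- read_sensor_array(config$paths$sensors)
    features <- list()
    for (b in c("delta", "gamma", "ratio")) {
      if (!is.null(config$paths[[b]])) {
        features[[b]] <- read_band_power_table(config$paths[[b]], b)
      }
    }
    cohort <- NULL
  }
  write_awakening_table(records, file.path(config$out_dir, "awakenings.csv"))
  write_sensor_array(sensors, file.path(config$out_dir, "sensors.csv"))
  for (b in names(features)) {
    write_band_power_table(features[[b]],
                           file.path(config$out_dir,
                                     sprintf("bandpower_%s.csv", b)))
  }

  if ("channelwise" %in% config$stages && length(features)) {
    log_stage("channelwise: ratio vs sleep depth, %d permutations",
              config$n_perm)
    graph <- build_adjacency(sensors, method = config$adjacency)
    res <- cluster_permutation_test(
      records, features$ratio, "sleep_depth", graph = graph,
      n_perm = config$n_perm, p_thresh = config$p_thresh,
      min_size = config$min_size, alpha = config$alpha,
      seed = child_seed(config$seed, "permutation"))
    write.csv(res$stats, file.path(config$out_dir, "topography_ratio_depth.csv"),
              row.names = FALSE)
    write.csv(res$clusters, file.path(config$out_dir, "clusters_ratio_depth.csv"),
              row.names = FALSE)
    write.csv(data.frame(max_mass = res$null$max_mass),
              file.path(config$out_dir, "null_distribution.csv"),
              row.names = FALSE)
    results$channelwise <- res
  }

  if ("contrasts" %in% config$stages) {
    log_stage("contrasts: pairwise report-type models with FDR")
    ct <- pairwise_contrasts(records, "sleep_depth")
    write.csv(ct, file.path(config$out_dir, "contrasts_depth.csv"),
              row.names = FALSE)
    pt <- proportion_tests(records)
    results$contrasts <- list(contrasts = ct, proportions = pt)
  }

  if ("pca" %in% config$stages) {
    log_stage("pca: phenomenology components and associations")
    ce <- records[records$report3 == "CE", , drop = FALSE]
    rownames(ce) <- ce$record_id
    pca <- phenomenology_pca(ce)
    rec2 <- records
    rec2$pc1 <- pca$scores[match(rec2$record_id, pca$row_ids), "pc1"]
    rec2$pc2 <- pca$scores[match(rec2$record_id, pca$row_ids), "pc2"]
    fits <- list(pc1_depth = pc_association(rec2, "sleep_depth", "pc1"),
                 pc2_depth = pc_association(rec2, "sleep_depth", "pc2"))
    write.csv(data.frame(feature = rownames(pca$loadings),
                         round(pca$loadings[, 1:2], 6)),
              file.path(config$out_dir, "pca_loadings.csv"),
              row.names = FALSE)
    results$pca <- list(pca = pca, fits = fits)
  }

  if ("timecourse" %in% config$stages) {
    log_stage("timecourse: BIC trend selection and post-4AM divergence")
    tr_d <- fit_trend(records, "sleep_depth", covariates = "sleepiness")
    tr_s <- fit_trend(records, "sleepiness", covariates = "sleep_depth")
    div <- tryCatch(measure_by_time_interaction(records),
                    error = function(e) NULL)
    tab <- rbind(
      data.frame(outcome = "sleep_depth", order = tr_d$order,
                 tr_d$coefficients),
      data.frame(outcome = "sleepiness", order = tr_s$order,
                 tr_s$coefficients))
    write.csv(tab, file.path(config$out_dir, "timecourse_trends.csv"),
              row.names = FALSE)
    adj <- data.frame(
      record_id = records$record_id, time = records$time,
      sleep_depth_adj = adjusted_values(records, "sleep_depth",
                                        covariates = "sleepiness"),
      sleepiness_adj = adjusted_values(records, "sleepiness",
                                       covariates = "sleep_depth"))
    write.csv(adj, file.path(config$out_dir, "adjusted_values.csv"),
              row.names = FALSE)
    results$timecourse <- list(depth = tr_d, sleepiness = tr_s,
                               divergence = div)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dreamdepth")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stages = config$stages,
    permutation = list(n_perm = config$n_perm, p_thresh = config$p_thresh,
                       min_size = config$min_size, alpha = config$alpha,
                       adjacency = config$adjacency),
    sim = if (!is.null(config$sim)) unclass(config$sim)[
      c("n_participants", "n_nights", "awakenings_per_night",
        "participant_sd", "residual_sd", "time_window", "likert", "seed")]
      else NULL,
    input_digests = if (!is.null(config$paths))
      as.list(tools::md5sum(unlist(config$paths))) else NULL,
    output_digests = as.list(tools::md5sum(
      list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(results)
}
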