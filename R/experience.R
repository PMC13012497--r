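#' Classify awakening reports into the five-level taxonomy
#'
#' First-level answers distinguish contentful conscious experience (CE),
#' conscious experience without recall of content (CEWR, "white dream"),
#' and no conscious experience (NCE). The level-specific follow-up
#' refines CEWR into rich (rCEWR: the impression of a forgotten rich,
#' detailed experience) vs simple (sCEWR), and NCE into a contentless
#' sense of presence (CESP) vs complete unconsciousness (UNC). A missing
#' follow-up leaves the subtype missing while the three-level class is
#' retained (as happens for a small fraction of real reports).
#'
#' @param report3 character vector over `CE`, `CEWR`, `NCE`.
#' @param followup logical vector: for CEWR, `TRUE` = rich impression;
#'   for NCE, `TRUE` = sense of presence; must be `NA` for CE (a CE
#'   report with a follow-up flag is contradictory and rejected).
#' @return data frame with columns `report3` and `report5` (`NA` subtype
#'   where the follow-up is missing).
#' @export
classify_report <- function(report3, followup = NA) {
  followup <- rep_len(followup, length(report3))
  bad <- !report3 %in% c("CE", "CEWR", "NCE")
  if (any(bad)) {
    stop("invalid first-level report(s): ",
         paste(unique(report3[bad]), collapse = ", "))
  }
  contra <- report3 == "CE" & !is.na(followup)
  if (any(contra)) {
    stop(sprintf("%d CE report(s) carry a follow-up flag: contradictory",
                 sum(contra)))
  }
  report5 <- ifelse(report3 == "CE", "CE",
             ifelse(report3 == "CEWR",
                    ifelse(is.na(followup), NA_character_,
                           ifelse(followup, "rCEWR", "sCEWR")),
                    ifelse(is.na(followup), NA_character_,
                           ifelse(followup, "CESP", "UNC"))))
  data.frame(report3 = report3, report5 = report5, stringsAsFactors = FALSE)
}

#' Pairwise report-type contrasts with FDR correction
#'
#' Fits one mixed model per unordered pair of report levels (outcome ~
#' report + nuisance + participant intercept) rather than a single
#' multi-level model, avoiding any assumption of an ordinal hierarchy of
#' consciousness levels. Benjamini-Hochberg q-values are computed across
#' the pair family. The reported `beta` is the effect of `level_b`
#' relative to `level_a` (treatment coding, `level_a` = reference).
#'
#' @param records awakening data frame.
#' @param outcome outcome column (`"sleep_depth"` or `"sleepiness"`).
#' @param levels report levels to contrast; matched against `report5`
#'   where the level is a subtype and `report3` otherwise (so
#'   `c("CE", "CEWR", "CESP", "UNC")` works directly).
#' @param nuisance nuisance fixed effects.
#' @param adjust p-adjustment method (default Benjamini-Hochberg).
#' @return data frame with one row per pair: `level_a`, `level_b`,
#'   `beta`, `se`, `ci_lo`, `ci_hi`, `p`, `q`.
#' @export
pairwise_contrasts <- function(records, outcome,
                               levels = c("CE", "CEWR", "CESP", "UNC"),
                               nuisance = c("experiment", "night", "time"),
                               adjust = "BH") {
  lab <- report_level_labels(records, levels)
  pairs <- utils::combn(levels, 2L)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    la <- pairs[1L, j]; lb <- pairs[2L, j]
    sel <- !is.na(lab) & lab %in% c(la, lb)
    d <- records[sel, , drop = FALSE]
    d$.report <- factor(lab[sel], levels = c(la, lb))
    if (length(unique(d$.report)) < 2L ||
        min(table(d$.report)) == 0L) {
      warning(sprintf("pair %s vs %s skipped: empty level", la, lb))
      next
    }
    fit <- fit_lmm(d, outcome, predictors = ".report", nuisance = nuisance)
    co <- fit$coefficients
    row <- co[grepl("^\\.report", co$term), , drop = FALSE][1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      level_a = la, level_b = lb, beta = row$estimate, se = row$se,
      ci_lo = row$ci_lo, ci_hi = row$ci_hi, p = row$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

report_level_labels <- function(records, levels) {
  three <- c("CE", "CEWR", "NCE")
  lab <- rep(NA_character_, nrow(records))
  for (lv in levels) {
    src <- if (lv %in% three) records$report3 else records$report5
    lab[!is.na(src) & src == lv] <- lv
  }
  lab
}

#' Report-type proportion tests across participants
#'
#' Computes per-participant report-type proportions, a Friedman test of
#' whether the three-level report types occur with different relative
#' frequencies, and Wilcoxon signed-rank tests for the two binary
#' subtype splits (UNC vs CESP share of NCE reports; sCEWR vs rCEWR
#' share of CEWR reports).
#'
#' @param records awakening data frame with `participant_id`, `report3`,
#'   `report5`.
#' @return list with `proportions` (participant x type, three-level),
#'   `friedman_p`, `signrank_unc_cesp_p`, `signrank_scewr_rcewr_p`, and
#'   the mean subtype shares.
#' @export
proportion_tests <- function(records) {
  keep <- !is.na(records$report3)
  d <- records[keep, , drop = FALSE]
  np <- length(unique(d$participant_id))
  if (np < 5L) stop("need at least 5 participants")
  counts <- table(d$participant_id, d$report3)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning("participants with zero reports excluded")
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  prop <- sweep(unclass(counts), 1L, tot, `/`)
  fr <- suppressWarnings(friedman.test(prop))
  fr_stat <- unname(fr$statistic)
  fr_p <- fr$p.value
  if (!is.finite(fr_stat)) {
    # fully tied ranks (identical proportions everywhere): no evidence
    fr_stat <- 0; fr_p <- 1
  }

  share <- function(sub, within) {
    idx <- d$report3 == within & !is.na(d$report5)
    vapply(rownames(prop), function(p) {
      n <- sum(idx & d$participant_id == p)
      if (n == 0L) NA_real_ else
        sum(idx & d$participant_id == p & d$report5 == sub) / n
    }, numeric(1))
  }
  unc <- share("UNC", "NCE")
  cesp <- share("CESP", "NCE")
  scewr <- share("sCEWR", "CEWR")
  rcewr <- share("rCEWR", "CEWR")
  sr <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || all(x[ok] == y[ok])) return(1)
    suppressWarnings(wilcox.test(x[ok], y[ok], paired = TRUE)$p.value)
  }
  list(proportions = prop,
       friedman_stat = fr_stat,
       friedman_p = fr_p,
       signrank_unc_cesp_p = sr(unc, cesp),
       signrank_scewr_rcewr_p = sr(scewr, rcewr),
       mean_unc_share = mean(unc, na.rm = TRUE),
       mean_scewr_share = mean(scewr, na.rm = TRUE))
}

#' Principal components of dream phenomenology
#'
#' Z-scores the six experiential dimensions (subjective duration
#' log-transformed first, with a 1-s clamp), eigendecomposes their
#' correlation structure, and retains the first two components:
#' "perceptual immersion" (typically loading on duration, vividness,
#' perceptual content, bizarreness, emotional intensity) and "reflective
#' thought" (thought-like content and dream awareness against
#' vividness). Each component is oriented so its largest-|loading|
#' feature loads positively, making signs reproducible.
#'
#' @param ratings data frame with columns `duration_seconds`,
#'   `vividness`, `perceptual`, `bizarreness`, `emotional_intensity`,
#'   `dream_awareness`; rows with missing values are dropped (>= 6
#'   complete rows required).
#' @return object of class `pca_result`: `loadings` (6 x 6 orthonormal),
#'   `var_explained` (fractions), `scores` (complete rows x 2, PC1/PC2),
#'   `center`/`scale` of the z-scoring, `row_ids`.
#' @export
phenomenology_pca <- function(ratings) {
  need <- .PHENO_FEATURES
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stop("missing phenomenology columns: ",
                         paste(miss, collapse = ", "))
  x <- ratings[need]
  cc <- complete.cases(x)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 6L) stop("need at least 6 complete rating vectors")
  x$duration_seconds <- log(pmax(x$duration_seconds, 1))
  xm <- as.matrix(x)
  ctr <- colMeans(xm)
  scl <- apply(xm, 2L, sd)
  if (any(scl == 0)) {
    stop("zero-variance feature(s): ",
         paste(need[scl == 0], collapse = ", "))
  }
  z <- scale(xm, center = ctr, scale = scl)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  L <- pc$rotation
  for (j in seq_len(ncol(L))) {
    imax <- which.max(abs(L[, j]))
    if (L[imax, j] < 0) {
      L[, j] <- -L[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  colnames(scores) <- c("pc1", "pc2")
  structure(list(loadings = L, var_explained = ve, scores = scores,
                 center = ctr, scale = scl,
                 row_ids = rownames(ratings)[cc]),
            class = "pca_result")
}

#' @method print pca_result
#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained[1:2]), collapse = ", "),
      "(PC1 perceptual immersion, PC2 reflective thought)\n")
  print(round(x$loadings[, 1:2], 3))
  invisible(x)
}

#' Association between a phenomenology component and a rating
#'
#' Fits `outcome ~ pc + experiment + night + time + (1 | participant)`
#' for one principal-component score column.
#'
#' @param records awakening data frame containing the score column.
#' @param outcome outcome column name.
#' @param pc score column name (`"pc1"` or `"pc2"`).
#' @param nuisance nuisance fixed effects.
#' @return a `fit_result`; the coefficient of interest is the `pc` term.
#' @export
pc_association <- function(records, outcome, pc = "pc1",
                           nuisance = c("experiment", "night", "time")) {
  d <- records[!is.na(records[[pc]]), , drop = FALSE]
  fit_lmm(d, outcome, predictors = pc, nuisance = nuisance)
}
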