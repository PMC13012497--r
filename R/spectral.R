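#' Robust polynomial detrending of an EEG segment
#'
#' Removes a low-order polynomial trend from each channel by iteratively
#' reweighted least squares with Tukey bisquare weights, so brief
#' high-amplitude transients do not drag the fitted baseline. Used with a
#' second-order polynomial to remove slow DC drifts before spectral
#' analysis.
#'
#' @param segment an [eeg_segment()].
#' @param order polynomial degree (`>= 0`).
#' @param iterations reweighting iterations.
#' @param threshold outlier threshold in robust-SD units.
#' @return detrended [eeg_segment()] of the same shape.
#' @export
robust_detrend <- function(segment, order = 2L, iterations = 3L,
                           threshold = 3) {
  stopifnot(inherits(segment, "eeg_segment"), order >= 0)
  ns <- ncol(segment$data)
  if (ns < order + 2L) stop("need at least order + 2 samples")
  tt <- seq(-1, 1, length.out = ns)  # scaled basis for conditioning
  B <- outer(tt, 0:order, `^`)
  out <- segment
  for (ch in seq_len(nrow(segment$data))) {
    y <- segment$data[ch, ]
    w <- rep(1, ns)
    fit <- rep(mean(y), ns)
    for (it in seq_len(iterations)) {
      wb <- B * sqrt(w)
      beta <- tryCatch(qr.coef(qr(wb), y * sqrt(w)),
                       error = function(e) rep(NA_real_, order + 1L))
      if (anyNA(beta)) break
      fit <- drop(B %*% beta)
      r <- y - fit
      s <- mad(r)
      if (s <= .Machine$double.eps * max(1, max(abs(y)))) {
        # (near-)exact polynomial: residual is numerically zero
        break
      }
      u <- r / (threshold * s)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (all(w == 0)) w <- rep(1, ns)
    }
    out$data[ch, ] <- y - fit
  }
  out
}

#' Extract the pre-alarm analysis window
#'
#' Returns exactly `window * fs` samples ending at the alarm onset, the
#' epoch whose spectral content is related to the subsequent subjective
#' report.
#'
#' @param segment an [eeg_segment()].
#' @param window window length in seconds (default 120).
#' @return an [eeg_segment()] whose alarm index is its final sample.
#' @export
extract_prealarm_window <- function(segment, window = 120) {
  stopifnot(inherits(segment, "eeg_segment"))
  nw <- round(window * segment$fs)
  if (nw <= 0) stop("window must cover at least one sample")
  avail <- segment$alarm_index
  if (avail < nw) {
    stop(sprintf("only %.1f s available before alarm, %.1f s requested",
                 avail / segment$fs, window))
  }
  idx <- (segment$alarm_index - nw + 1L):segment$alarm_index
  eeg_segment(segment$data[, idx, drop = FALSE], segment$fs,
              segment$channel_labels, alarm_index = nw)
}

#' Welch power spectral density estimate
#'
#' One-sided PSD (density scaling, power per Hz) per channel, averaging
#' modified periodograms of Hamming-tapered windows. At the defaults
#' (4-s windows, 90% overlap) the frequency resolution is 0.25 Hz and the
#' integral of the PSD over frequency approximates the signal variance.
#'
#' @param segment an [eeg_segment()].
#' @param window_len taper length in seconds.
#' @param overlap fractional overlap between consecutive windows, in
#'   `[0, 1)`.
#' @return list with `freq` (Hz) and `psd` (channels x frequencies
#'   matrix, units microvolt^2/Hz), class `welch_psd`.
#' @export
welch_psd <- function(segment, window_len = 4, overlap = 0.9) {
  stopifnot(inherits(segment, "eeg_segment"),
            overlap >= 0, overlap < 1)
  fs <- segment$fs
  nw <- round(window_len * fs)
  ns <- ncol(segment$data)
  if (nw > ns) stop("window longer than segment")
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, ns - nw + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nw) - 1L) / (nw - 1L))  # Hamming
  u <- sum(w^2)
  nfreq <- nw %/% 2L + 1L
  acc <- matrix(0, nrow(segment$data), nfreq)
  for (s0 in starts) {
    seg <- segment$data[, s0:(s0 + nw - 1L), drop = FALSE]
    tap <- sweep(seg, 2L, w, `*`)
    sp <- stats::mvfft(t(tap))[seq_len(nfreq), , drop = FALSE]
    acc <- acc + t(Mod(sp)^2)
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nw is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nw %% 2L == 0L) dbl[nfreq] <- 1
  psd <- sweep(psd, 2L, dbl, `*`)
  freq <- (seq_len(nfreq) - 1L) * fs / nw
  rownames(psd) <- segment$channel_labels
  structure(list(freq = freq, psd = psd, fs = fs,
                 window_len = window_len, overlap = overlap),
            class = "welch_psd")
}

#' Band power by trapezoidal integration of the PSD
#'
#' Integrates the PSD between the band edges (trapezoidal rule). Edge
#' frequencies falling between grid points are included by linear
#' interpolation onto the exact band edges, so the integral does not
#' depend on the phase of the frequency grid.
#'
#' @param psd a [welch_psd()].
#' @param band a [band_definition()].
#' @return named numeric vector: integrated power per channel
#'   (microvolt^2).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "welch_psd"), inherits(band, "band_definition"))
  f <- psd$freq
  if (band$f_lo < min(f) - 1e-9 || band$f_hi > max(f) + 1e-9) {
    stop(sprintf("band %s [%g, %g] Hz outside PSD range [%g, %g] Hz",
                 band$name, band$f_lo, band$f_hi, min(f), max(f)))
  }
  apply(psd$psd, 1L, function(p) {
    inner <- f > band$f_lo & f < band$f_hi
    fg <- c(band$f_lo, f[inner], band$f_hi)
    pg <- c(approx(f, p, xout = band$f_lo)$y, p[inner],
            approx(f, p, xout = band$f_hi)$y)
    pracma::trapz(fg, pg)
  })
}

#' Extract log band-power feature tables from raw segments
#'
#' Full spectral path for a cohort with raw segments: per record, robust
#' second-order detrend, extraction of the 120-s pre-alarm window, Welch
#' PSD (4-s Hamming windows, 90% overlap), trapezoidal band integration
#' for delta and gamma, natural-log transform, and the log gamma/delta
#' ratio (identically log gamma minus log delta).
#'
#' Nonpositive integrated powers (possible only for degenerate synthetic
#' input) are floored at a machine-epsilon-scaled constant with a
#' warning.
#'
#' @param dataset a `cohort_dataset` with non-`NULL` `segments`, or a
#'   named list of [eeg_segment()]s.
#' @param bands named list with `delta` and `gamma` [band_definition()]s.
#' @param window pre-alarm window in seconds.
#' @param detrend_order polynomial order for [robust_detrend()].
#' @return named list of `band_power_table`s: `delta`, `gamma`, `ratio`
#'   (all natural-log scale).
#' @export
extract_features <- function(dataset, bands = default_bands(),
                             window = 120, detrend_order = 2L) {
  segments <- if (inherits(dataset, "cohort_dataset")) dataset$segments
              else dataset
  if (is.null(segments) || !length(segments)) {
    stop("no EEG segments available")
  }
  ids <- names(segments)
  first <- segments[[1L]]
  labels <- first$channel_labels
  res <- lapply(segments, function(seg) {
    seg <- robust_detrend(seg, order = detrend_order)
    seg <- extract_prealarm_window(seg, window = window)
    psd <- welch_psd(seg)
    list(delta = band_power(psd, bands$delta),
         gamma = band_power(psd, bands$gamma))
  })
  dmat <- do.call(rbind, lapply(res, `[[`, "delta"))
  gmat <- do.call(rbind, lapply(res, `[[`, "gamma"))
  floor_val <- .Machine$double.eps * 1e3
  n_floored <- sum(dmat <= 0) + sum(gmat <= 0)
  if (n_floored > 0L) {
    warning(sprintf("%d nonpositive band powers floored at %.3g",
                    n_floored, floor_val))
    dmat[dmat <= 0] <- floor_val
    gmat[gmat <= 0] <- floor_val
  }
  ld <- log(dmat); lg <- log(gmat)
  dimnames(ld) <- dimnames(lg) <- list(ids, labels)
  list(delta = band_power_table(ld, "delta", bands$delta),
       gamma = band_power_table(lg, "gamma", bands$gamma),
       ratio = band_power_table(lg - ld, "ratio"))
}
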