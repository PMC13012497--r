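#' EEG segment container
#'
#' A channels x samples amplitude matrix (microvolts) with sampling rate,
#' channel labels, and the sample index of alarm onset.
#'
#' @param data numeric matrix, channels in rows.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per row of `data`.
#' @param alarm_index sample index (1-based) of alarm onset; defaults to
#'   the last sample.
#' @return object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, channel_labels = NULL, alarm_index = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) {
      channel_labels <- sprintf("E%03d", seq_len(nrow(data)))
    }
  }
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per data row required")
  }
  if (is.null(alarm_index)) alarm_index <- ncol(data)
  if (alarm_index > ncol(data)) stop("alarm_index beyond segment end")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 alarm_index = as.integer(alarm_index)),
            class = "eeg_segment")
}

#' @method print eeg_segment
#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz (%.1f s), alarm at %.1f s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$alarm_index / x$fs))
  invisible(x)
}

#' Frequency band definition
#'
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`.
#' @return a `band_definition` list.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(f_lo >= 0, f_lo < f_hi)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Default spectral bands: slow-wave delta and high-frequency gamma
#'
#' Delta (0.5-4 Hz) indexes slow-wave activity and homeostatic sleep
#' pressure; gamma (25-50 Hz) indexes wake-like cortical activation.
#'
#' @return named list of [band_definition()]s.
#' @export
default_bands <- function() {
  list(delta = band_definition("delta", 0.5, 4),
       gamma = band_definition("gamma", 25, 50))
}

# carrier frequencies used when synthesising band-limited activity
.BAND_CARRIER <- c(delta = 2, gamma = 35)

#' Synthesise a multichannel EEG segment with controlled band content
#'
#' Builds a test signal as 1/f ("pink") background plus white noise plus
#' sinusoidal carriers at fixed in-band frequencies (delta: 2 Hz, gamma:
#' 35 Hz) with the requested amplitudes. A sinusoid of amplitude `a`
#' contributes band power `a^2/2`, giving closed-form expectations for
#' the spectral pipeline. Channels share amplitudes but get independent
#' phases and noise.
#'
#' @param band_profile named numeric vector of sinusoid amplitudes
#'   (microvolts), names among `names(.BAND_CARRIER)` or custom
#'   frequencies supplied via `carriers`.
#' @param duration segment length in seconds; `duration * fs` must be
#'   integral.
#' @param fs sampling rate, Hz; must exceed 100 Hz so the 25-50 Hz gamma
#'   band is resolvable.
#' @param n_channels number of channels.
#' @param channel_labels optional labels.
#' @param noise_sd white-noise SD per sample (0 for none).
#' @param pink_sd SD of the 1/f background (0 for none).
#' @param carriers named numeric vector mapping band name to carrier
#'   frequency (Hz); defaults to the built-in map.
#' @param seed integer seed; the output is deterministic given it.
#' @return an [eeg_segment()] with alarm at the final sample.
#' @export
generate_eeg_segment <- function(band_profile = c(delta = 0, gamma = 0),
                                 duration = 150, fs = 500,
                                 n_channels = 1L, channel_labels = NULL,
                                 noise_sd = 0, pink_sd = 0,
                                 carriers = .BAND_CARRIER, seed = 1L) {
  if (fs <= 100) stop("fs must exceed 100 Hz to resolve the 25-50 Hz band")
  ns <- duration * fs
  if (abs(ns - round(ns)) > 1e-8) stop("duration * fs must be integral")
  ns <- as.integer(round(ns))
  if (!all(names(band_profile) %in% names(carriers))) {
    stop("unknown band in band_profile: ",
         paste(setdiff(names(band_profile), names(carriers)), collapse = ", "))
  }
  t <- (seq_len(ns) - 1L) / fs
  with_seed(seed, {
    dat <- matrix(0, n_channels, ns)
    for (ch in seq_len(n_channels)) {
      sig <- numeric(ns)
      for (bn in names(band_profile)) {
        amp <- band_profile[[bn]]
        if (amp == 0) next
        phase <- runif(1, 0, 2 * pi)
        sig <- sig + amp * sin(2 * pi * carriers[[bn]] * t + phase)
      }
      if (noise_sd > 0) sig <- sig + rnorm(ns, sd = noise_sd)
      if (pink_sd > 0) sig <- sig + pink_noise(ns, fs, pink_sd)
      dat[ch, ] <- sig
    }
    eeg_segment(dat, fs, channel_labels, alarm_index = ns)
  })
}

# 1/f-amplitude noise via spectral shaping of white noise
pink_noise <- function(n, fs, sd) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))  # avoid dividing DC by zero
  shape <- 1 / sqrt(pmin(f, n - f + 1))
  shape[1] <- 0
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}
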