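DB_FLOOR <- -300

db10 <- function(p) ifelse(p > 0, 10 * log10(p), DB_FLOOR)

#' One-sided periodogram of a single epoch
#'
#' Power spectrum (uV^2 per bin) of one epoch at the 1 Hz resolution implied
#' by 1-second epochs, with window power-gain compensation (division by the
#' mean squared window) so that the spectrum sums to the windowed-signal
#' variance (Parseval).  With a rectangular window a unit-amplitude sinusoid
#' at an exact bin carries power 1/2 in its bin.
#'
#' @param x Numeric vector of `rate` samples (one 1-second epoch).
#' @param rate Sampling rate in Hz.
#' @param window `"hamming"` (default) or `"rectangular"`.
#' @return Named numeric vector of power at frequencies `0:(rate/2)` Hz.
#' @export
epoch_periodogram <- function(x, rate, window = c("hamming", "rectangular")) {
  window <- match.arg(window)
  n <- length(x)
  if (n != round(rate))
    stop("epoch must contain exactly `rate` samples (1 s)")
  w <- if (window == "hamming")
    0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  else rep(1, n)
  X <- stats::fft(x * w)
  nf <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nf)])^2 / (n^2 * mean(w^2))
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  p <- p * scale
  names(p) <- as.character((seq_len(nf) - 1L) * rate / n)
  p
}

# epochs x bands matrix of linear per-epoch band powers (retained epochs)
retained_band_power_matrix <- function(ep, electrode, bands,
                                       window = "hamming") {
  ic <- channel_index(ep, electrode)
  keep <- which(ep$retained)
  if (length(keep) < 1) stop("no retained epochs")
  out <- matrix(NA_real_, length(keep), length(bands),
                dimnames = list(NULL, names(bands)))
  sel <- NULL
  for (i in seq_along(keep)) {
    p <- epoch_periodogram(ep$data[keep[i], ic, ], ep$rate, window)
    if (is.null(sel)) {
      f <- as.numeric(names(p))
      sel <- lapply(bands, function(b) which(f >= b[1] & f <= b[2]))
    }
    for (j in seq_along(bands)) out[i, j] <- mean(p[sel[[j]]])
  }
  out
}

retained_band_powers <- function(ep, electrode, band, window = "hamming") {
  bands <- list(band = band)
  retained_band_power_matrix(ep, electrode, bands, window)[, 1]
}

#' Band power and power variability in decibels
#'
#' Per-epoch band power is the mean periodogram power over the inclusive
#' band bins.  The mean power is averaged in the linear domain over retained
#' epochs and then converted to dB (re 1 uV^2); the power variability is the
#' standard deviation over retained epochs of the linear per-epoch band
#' powers, also in dB.  Degenerate zero power or spread is floored at the
#' -300 dB sentinel.
#'
#' @param ep A `qeeg_epochs` (at least 2 retained epochs).
#' @param electrode Channel label (e.g. `"FZ"`, `"OZ"`).
#' @param band `c(lo, hi)` in Hz, edges inclusive.
#' @param window Periodogram window, see [epoch_periodogram()].
#' @return Named numeric vector `c(mean_power_db, power_sd_db, n_epochs)`.
#' @export
band_power_db <- function(ep, electrode, band, window = "hamming") {
  stopifnot(inherits(ep, "qeeg_epochs"))
  if (sum(ep$retained) < 2) stop("need at least 2 retained epochs")
  p <- retained_band_powers(ep, electrode, band, window)
  c(mean_power_db = db10(mean(p)),
    power_sd_db = db10(stats::sd(p)),
    n_epochs = length(p))
}

#' Mean dB spectrum table for inspection and plotting
#'
#' @param ep A `qeeg_epochs`.
#' @param electrode Channel label.
#' @param freqs Frequencies to tabulate (default 1-40 Hz).
#' @param window Periodogram window.
#' @return Data frame with columns `freq_hz` and `power_db` (epoch-mean
#'   linear power converted to dB).
#' @export
spectrum_table <- function(ep, electrode, freqs = 1:40, window = "hamming") {
  stopifnot(inherits(ep, "qeeg_epochs"))
  ic <- channel_index(ep, electrode)
  keep <- which(ep$retained)
  if (length(keep) < 1) stop("no retained epochs")
  acc <- NULL
  for (e in keep) {
    p <- epoch_periodogram(ep$data[e, ic, ], ep$rate, window)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc <- acc / length(keep)
  f <- as.numeric(names(acc))
  sel <- match(freqs, f)
  data.frame(freq_hz = freqs, power_db = db10(acc[sel]))
}

#' Band power table for a set of preprocessed sessions
#'
#' Long-format table with one row per session x electrode x band carrying
#' mean band power and band-power variability in dB and the retained epoch
#' count.
#'
#' @param epochs_list List of `qeeg_epochs` (one per session) with session
#'   metadata in `$meta`.
#' @param electrodes Electrodes of interest (default FZ and OZ).
#' @param bands Band definition list, see [default_bands()].
#' @param window Periodogram window.
#' @return Data frame of class `qeeg_band_power`.
#' @export
band_power_table <- function(epochs_list, electrodes = c("FZ", "OZ"),
                             bands = default_bands(), window = "hamming") {
  validate_bands(bands)
  out <- list()
  for (ep in epochs_list)
    for (el in electrodes) {
      if (sum(ep$retained) < 2) stop("need at least 2 retained epochs")
      pm <- retained_band_power_matrix(ep, el, bands, window)
      for (b in names(bands))
        out[[length(out) + 1L]] <- data.frame(
          participant = ep$meta$subject %||% NA,
          environment = ep$meta$environment %||% NA_character_,
          condition = ep$meta$task %||% NA_character_,
          electrode = el, band = b,
          mean_power_db = db10(mean(pm[, b])),
          power_sd_db = db10(stats::sd(pm[, b])),
          n_epochs = nrow(pm),
          stringsAsFactors = FALSE)
    }
  res <- do.call(rbind, out)
  class(res) <- c("qeeg_band_power", "data.frame")
  res
}
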