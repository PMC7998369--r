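# Shared fixture builders: everything is generated in code at test time.

# A quiet design: no artifacts, no background, no subject/session variance.
quiet_design <- function(..., seed = 42) {
  args <- utils::modifyList(
    list(n_subjects = 4, duration_rest = 8, duration_pasat = 8,
         subject_sdlog = 0, session_sdlog = 0, noise_rms = 0,
         blink_rate_per_min = 0, emg_rate_per_min = 0, bad_channel_prob = 0,
         seed = seed),
    list(...))
  do.call(simulation_design, args)
}

# Build a qeeg_recording directly from a channels x samples matrix.
make_recording <- function(signal, rate = 256, montage = qeeg_montage(),
                           meta = list()) {
  rec <- list(signal = signal, rate = rate, montage = montage, meta = meta)
  class(rec) <- "qeeg_recording"
  rec
}

# A recording with named channels filled from a generator function
# f(label, n) -> numeric vector; default small white noise.
synth_recording <- function(dur_s = 4, rate = 256,
                            f = function(lab, n) rnorm(n, 0, 1)) {
  mon <- qeeg_montage()
  labs <- mon$label[mon$type != "reference"]
  n <- dur_s * rate
  sig <- t(vapply(labs, function(l) f(l, n), numeric(n)))
  rownames(sig) <- labs
  make_recording(sig, rate, mon)
}

channel_idx <- function(ep, lab) match(lab, ep$labels)

# One-sided band power of a full-length signal by direct FFT (test oracle,
# independent of the epoch periodogram path).
fft_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  2 * sum(p[f >= lo & f <= hi & f > 0 & f < rate / 2]) +
    sum(p[f >= lo & f <= hi & (f == 0 | f == rate / 2)])
}

# Independent F computation for fully-within 2^k designs: per-subject
# signed contrast of cell means, F = t^2 (test oracle for rm_anova).
contrast_F <- function(data, dv, subject, factors, which_effect) {
  subj <- unique(data[[subject]])
  signs <- lapply(factors, function(f) {
    lv <- sort(unique(as.character(data[[f]])))
    stats::setNames(c(-1, 1), lv)
  })
  names(signs) <- factors
  d <- vapply(subj, function(s) {
    rows <- data[data[[subject]] == s, , drop = FALSE]
    sgn <- rep(1, nrow(rows))
    for (f in which_effect)
      sgn <- sgn * signs[[f]][as.character(rows[[f]])]
    mean(rows[[dv]] * sgn * 2)  # contrast of half-means
  }, numeric(1))
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  tstat^2
}
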