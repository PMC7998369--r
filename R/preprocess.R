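#' Decompose a recording into baseline-corrected overlapping epochs
#'
#' Epochs of `length_s` seconds start at multiples of
#' `step = length_s * (1 - overlap)`, giving
#' `floor((T - length_s) / step) + 1` epochs for a `T`-second recording.
#' Each epoch is baseline-corrected by subtracting its per-channel mean.
#'
#' @param rec A `qeeg_recording`.
#' @param length_s Epoch length in seconds (default 1).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return A list of class `qeeg_epochs`: `data` (epochs x channels x
#'   samples array), `labels`, `rate`, `epoch_length_s`, `overlap`,
#'   `retained` (logical), `reason` (per-epoch rejection reason or NA),
#'   `reference_state`, `interpolated`, `montage`, `meta`.
#' @export
epoch_signal <- function(rec, length_s = 1, overlap = 0.5) {
  stopifnot(inherits(rec, "qeeg_recording"), overlap >= 0, overlap < 1)
  nspe <- round(rec$rate * length_s)
  total <- ncol(rec$signal)
  if (total < nspe) stop("recording shorter than one epoch")
  step <- length_s * (1 - overlap) * rec$rate
  n_ep <- floor((total - nspe) / step) + 1L
  starts <- round((seq_len(n_ep) - 1L) * step)
  nch <- nrow(rec$signal)
  data <- array(0, dim = c(n_ep, nch, nspe))
  for (e in seq_len(n_ep)) {
    seg <- rec$signal[, (starts[e] + 1L):(starts[e] + nspe), drop = FALSE]
    data[e, , ] <- seg - rowMeans(seg)
  }
  ep <- list(data = data, labels = rownames(rec$signal), rate = rec$rate,
             epoch_length_s = length_s, overlap = overlap,
             starts_s = starts / rec$rate,
             retained = rep(TRUE, n_ep),
             reason = rep(NA_character_, n_ep),
             reference_state = "vertex",
             interpolated = character(0),
             montage = rec$montage, meta = rec$meta)
  class(ep) <- "qeeg_epochs"
  ep
}

#' @export
print.qeeg_epochs <- function(x, ...) {
  cat(sprintf("<qeeg_epochs> %d epochs (%d retained) x %d channels x %d samples, %s reference\n",
              dim(x$data)[1], sum(x$retained), dim(x$data)[2], dim(x$data)[3],
              x$reference_state))
  invisible(x)
}

channel_index <- function(ep, label) {
  i <- match(label, ep$labels)
  if (anyNA(i)) stop("channel(s) not present: ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

#' Re-reference epochs to digitally linked mastoids
#'
#' Subtracts the mastoid average `0.5 * (M1 + M2)` from every EEG channel.
#' The implicit vertex (CZ) reference channel is first reconstructed as an
#' all-zero channel so that it survives re-referencing as
#' `-0.5 * (M1 + M2)`.  The EOG channel is left untouched.  Applying the
#' transform to already re-referenced epochs is an error.
#'
#' @param ep A `qeeg_epochs` in the `"vertex"` reference state.
#' @return Re-referenced `qeeg_epochs` (reference state
#'   `"linked_mastoids"`), with a CZ channel appended.
#' @export
rereference_linked_mastoids <- function(ep) {
  stopifnot(inherits(ep, "qeeg_epochs"))
  if (ep$reference_state != "vertex")
    stop("epochs are already re-referenced (state: ", ep$reference_state, ")")
  im <- channel_index(ep, c("M1", "M2"))
  d <- dim(ep$data)
  has_cz <- "CZ" %in% ep$labels
  if (!has_cz) {
    data <- array(0, dim = c(d[1], d[2] + 1L, d[3]))
    data[, seq_len(d[2]), ] <- ep$data
    ep$data <- data
    ep$labels <- c(ep$labels, "CZ")
    d <- dim(ep$data)
  }
  eog <- which(ep$labels == "LVEOG")
  mast_avg <- (ep$data[, im[1], , drop = FALSE] +
               ep$data[, im[2], , drop = FALSE]) / 2
  for (ch in seq_len(d[2]))
    if (!ch %in% eog)
      ep$data[, ch, ] <- ep$data[, ch, ] - mast_avg[, 1, ]
  ep$reference_state <- "linked_mastoids"
  ep
}

#' Reject epochs on the EOG channel amplitude
#'
#' Drops retained epochs whose LVEOG peak absolute amplitude (after baseline
#' correction) exceeds the threshold, recording reason `"eog_threshold"`.
#'
#' @param ep A `qeeg_epochs` with an LVEOG channel.
#' @param threshold_uV Rejection threshold in microvolts (default 50).
#' @return Updated `qeeg_epochs`.
#' @export
reject_eog <- function(ep, threshold_uV = 50) {
  stopifnot(inherits(ep, "qeeg_epochs"), threshold_uV > 0)
  ie <- channel_index(ep, "LVEOG")
  peak <- apply(abs(ep$data[, ie, , drop = FALSE]), 1, max)
  hit <- ep$retained & peak > threshold_uV
  ep$retained[hit] <- FALSE
  ep$reason[hit] <- "eog_threshold"
  ep
}

epoch_hf_rms <- function(x, rate, cutoff_hz = 20) {
  n <- length(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  p <- Mod(stats::fft(x))^2 / n^2
  sqrt(sum(p[f > cutoff_hz]))
}

#' Reject epochs by peak amplitude and high-frequency RMS
#'
#' A deterministic surrogate for manual EMG/motion screening: drops retained
#' epochs whose peak absolute amplitude exceeds `peak_uV` or whose > 20 Hz
#' high-passed RMS exceeds `hf_rms_uV` on any of the screened channels
#' (reason `"amplitude"`).  An explicit `manual_drop` epoch index list is
#' honoured with reason `"manual_list"`.
#'
#' @param ep A `qeeg_epochs`.
#' @param channels Channels screened (default the analysis electrodes FZ and
#'   OZ).
#' @param peak_uV Peak amplitude threshold (default 100).
#' @param hf_rms_uV High-frequency RMS threshold (default 15).
#' @param manual_drop Optional integer vector of epoch indices to drop.
#' @return Updated `qeeg_epochs`.
#' @export
reject_amplitude <- function(ep, channels = c("FZ", "OZ"), peak_uV = 100,
                             hf_rms_uV = 15, manual_drop = integer(0)) {
  stopifnot(inherits(ep, "qeeg_epochs"), length(channels) >= 1)
  ic <- channel_index(ep, channels)
  n_ep <- dim(ep$data)[1]
  for (e in seq_len(n_ep)) {
    if (!ep$retained[e]) next
    seg <- ep$data[e, ic, , drop = FALSE]
    bad <- max(abs(seg)) > peak_uV
    if (!bad && is.finite(hf_rms_uV))
      for (j in seq_along(ic)) {
        if (epoch_hf_rms(ep$data[e, ic[j], ], ep$rate) > hf_rms_uV) {
          bad <- TRUE
          break
        }
      }
    if (bad) {
      ep$retained[e] <- FALSE
      ep$reason[e] <- "amplitude"
    }
  }
  manual_drop <- intersect(as.integer(manual_drop), seq_len(n_ep))
  hit <- manual_drop[ep$retained[manual_drop]]
  ep$retained[hit] <- FALSE
  ep$reason[hit] <- "manual_list"
  ep
}

# Perrin-style g function: sum over the Legendre series
# g(x) = 1/(4*pi) * sum_n (2n+1) / (n (n+1))^m * P_n(x)
spline_gfun <- function(x, m = 4, n_terms = 50) {
  dm <- dim(x)
  x <- as.vector(x)
  res <- numeric(length(x))
  pnm1 <- rep(1, length(x))   # P_0
  pn <- x                     # P_1
  for (n in seq_len(n_terms)) {
    res <- res + (2 * n + 1) / (n * (n + 1))^m * pn
    pnext <- ((2 * n + 1) * x * pn - n * pnm1) / (n + 1)
    pnm1 <- pn
    pn <- pnext
  }
  res <- res / (4 * pi)
  if (!is.null(dm)) dim(res) <- dm
  res
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each bad channel's signal, sample by sample, with the
#' spherical-spline estimate from the remaining good scalp-field channels
#' (EEG and mastoid sites; the EOG channel never enters the field).  The
#' spline follows the classical g-function formulation on the unit sphere
#' with stiffness order `m`, a truncated Legendre series, and ridge
#' smoothing `lambda` on the diagonal.
#'
#' @param ep A `qeeg_epochs`.
#' @param bad Character vector of bad channel labels.
#' @param montage Montage providing unit-sphere positions (defaults to the
#'   montage stored with the epochs).
#' @param m Stiffness order (default 4).
#' @param n_terms Legendre series truncation (default 50).
#' @param lambda Smoothing constant (default 1e-5; 0 gives exact
#'   interpolation at the good sites).
#' @return Updated `qeeg_epochs` with `interpolated` extended; good channels
#'   are untouched.
#' @export
interpolate_bad_channels <- function(ep, bad, montage = NULL, m = 4,
                                     n_terms = 50, lambda = 1e-5) {
  stopifnot(inherits(ep, "qeeg_epochs"))
  if (!length(bad)) return(ep)
  if (is.null(montage)) montage <- ep$montage
  ib <- channel_index(ep, bad)
  field <- setdiff(ep$labels[ep$labels %in%
                               montage$label[montage$type != "eog"]], bad)
  if (length(field) < 4)
    stop("need at least 4 good field channels for interpolation")
  pos_good <- montage_positions(montage, field)
  pos_bad <- montage_positions(montage, bad)
  p <- nrow(pos_good)
  G <- spline_gfun(tcrossprod(pos_good), m, n_terms)
  C <- rbind(cbind(G + lambda * diag(p), rep(1, p)), c(rep(1, p), 0))
  Tb <- cbind(spline_gfun(tcrossprod(pos_bad, pos_good), m, n_terms),
              rep(1, length(bad)))
  # weights mapping good-channel data to bad-channel estimates
  W <- t(solve(t(C), t(Tb)))[, seq_len(p), drop = FALSE]
  ig <- channel_index(ep, field)
  n_ep <- dim(ep$data)[1]
  for (e in seq_len(n_ep)) {
    est <- W %*% ep$data[e, ig, ]
    for (j in seq_along(ib)) ep$data[e, ib[j], ] <- est[j, ]
  }
  ep$interpolated <- union(ep$interpolated, bad)
  ep
}

#' Per-recording rejection report
#'
#' @param ep A `qeeg_epochs` after rejection.
#' @return One-row data frame: totals, retained count, per-reason counts,
#'   interpolated-channel count.
#' @export
rejection_report <- function(ep) {
  stopifnot(inherits(ep, "qeeg_epochs"))
  n <- length(ep$retained)
  reasons <- c("eog_threshold", "amplitude", "manual_list")
  cnt <- vapply(reasons, function(r)
    sum(!ep$retained & !is.na(ep$reason) & ep$reason == r), integer(1))
  data.frame(subject = ep$meta$subject %||% NA,
             environment = ep$meta$environment %||% NA_character_,
             task = ep$meta$task %||% NA_character_,
             total_epochs = n, retained = sum(ep$retained),
             eog_threshold = cnt[["eog_threshold"]],
             amplitude = cnt[["amplitude"]],
             manual_list = cnt[["manual_list"]],
             interpolated_channels = length(ep$interpolated),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
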