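#' Simulation design for a synthetic mobile-EEG experiment
#'
#' Describes a within-subjects group design of `n_subjects` participants,
#' each recorded in two environments (laboratory, outdoor) during eyes-closed
#' rest, eyes-open rest and PASAT performance.  Signals are sums of
#' narrowband (filtered-white-noise) oscillations in the theta, alpha and low
#' beta bands on top of a 1/f background, with scheduled blink transients,
#' broadband EMG bursts and occasional flat-lined bad channels.
#'
#' Defaults emulate the study conditions the analysis targets: 256 Hz
#' sampling, 300 s of retained resting data and 180 s of PASAT data, band
#' amplitudes and electrode topography gradients back-solved from typical
#' resting spectra (eyes-closed alpha enhancement about 3.5 dB, frontal theta
#' and posterior alpha/beta dominance), blink and EMG rates set so that about
#' 467 of 600 resting epochs survive the default rejection thresholds, and a
#' 1/f scale giving an eyes-closed alpha band SNR of roughly 5:1.
#'
#' @param n_subjects Number of participants (default 21).
#' @param rate Sampling rate in Hz (default 256).
#' @param duration_rest,duration_pasat Retained recording length in seconds
#'   per resting-state / PASAT session.
#' @param bands Named list of band edges in Hz, see [default_bands()].
#' @param base_amp_uv Per-band RMS amplitude (microvolts) of the band
#'   oscillation in the eyes-open laboratory reference condition.
#' @param ec_mult Eyes-closed amplitude multiplier per band (> 0).
#' @param pasat_mult PASAT amplitude multiplier per band relative to
#'   eyes-open rest (alpha < 1 encodes task alpha suppression).
#' @param outdoor_mult Outdoor-environment amplitude multiplier per band.
#' @param topo_gradient Per-band linear anterior-posterior amplitude
#'   gradient: channel gain is `1 + g * x` with `x` the nasion-axis
#'   coordinate, so positive values weight frontal sites.
#' @param subject_sdlog SD of the subject-level log-normal amplitude
#'   multiplier (shared across that subject's sessions).
#' @param session_sdlog SD of the per-session log-normal amplitude jitter
#'   (subject-by-condition noise).
#' @param oneoverf_exponent,noise_rms Spectral exponent and total RMS
#'   amplitude (microvolts, 1-45 Hz) of the 1/f background; `noise_rms = 0`
#'   disables it.
#' @param blink_rate_per_min,emg_rate_per_min Artifact event rates.
#' @param blink_amp_uv Peak blink amplitude on the LVEOG channel.
#' @param bad_channel_prob Probability that a recording contains one
#'   flat-lined bad channel.
#' @param pasat_accuracy Per-trial probability of a correct PASAT response.
#' @param tones Optional data frame with columns `freq` and `amp_uv` adding
#'   pure sinusoids (used mainly for spectral calibration checks).
#' @param seed Integer seed; identical designs and seeds give identical data.
#' @return A list of class `qeeg_design`.
#' @examples
#' des <- simulation_design(n_subjects = 3, duration_rest = 4,
#'                          duration_pasat = 4, seed = 1)
#' rec <- generate_recording(des, subject = 1, environment = "laboratory",
#'                           task = "rest_ec")
#' dim(rec$signal)
#' @export
simulation_design <- function(n_subjects = 21,
                              rate = 256,
                              duration_rest = 300,
                              duration_pasat = 180,
                              bands = default_bands(),
                              base_amp_uv = c(theta = 6, alpha = 5.5, beta = 3),
                              ec_mult = c(theta = 1.15, alpha = 1.5, beta = 1.1),
                              pasat_mult = c(theta = 1, alpha = 0.75, beta = 1),
                              outdoor_mult = c(theta = 1, alpha = 1, beta = 1.08),
                              topo_gradient = c(theta = 0.14, alpha = -0.14,
                                                beta = -0.08),
                              subject_sdlog = 0.30,
                              session_sdlog = 0.10,
                              oneoverf_exponent = 1,
                              noise_rms = 10,
                              blink_rate_per_min = 10,
                              emg_rate_per_min = 2,
                              blink_amp_uv = 150,
                              bad_channel_prob = 0.15,
                              pasat_accuracy = 0.75,
                              tones = NULL,
                              seed = 1L) {
  validate_bands(bands)
  bn <- names(bands)
  for (v in c("base_amp_uv", "ec_mult", "pasat_mult", "outdoor_mult",
              "topo_gradient")) {
    val <- get(v)
    if (is.null(names(val)) || !all(bn %in% names(val)))
      stop(v, " must be named with an entry per band")
  }
  if (any(c(ec_mult, pasat_mult, outdoor_mult) <= 0))
    stop("condition multipliers must be > 0")
  if (any(c(blink_rate_per_min, emg_rate_per_min, bad_channel_prob) < 0))
    stop("artifact rates must be >= 0")
  if (rate <= 2 * max(vapply(bands, max, 1)))
    stop("sampling rate too low for the configured bands")
  des <- list(n_subjects = as.integer(n_subjects), rate = rate,
              duration_rest = duration_rest, duration_pasat = duration_pasat,
              bands = bands, base_amp_uv = base_amp_uv[bn],
              ec_mult = ec_mult[bn], pasat_mult = pasat_mult[bn],
              outdoor_mult = outdoor_mult[bn],
              topo_gradient = topo_gradient[bn],
              subject_sdlog = subject_sdlog, session_sdlog = session_sdlog,
              oneoverf_exponent = oneoverf_exponent, noise_rms = noise_rms,
              blink_rate_per_min = blink_rate_per_min,
              emg_rate_per_min = emg_rate_per_min,
              blink_amp_uv = blink_amp_uv,
              bad_channel_prob = bad_channel_prob,
              pasat_accuracy = pasat_accuracy,
              tones = tones, seed = as.integer(seed))
  class(des) <- "qeeg_design"
  des
}

#' Read a simulation design from a YAML configuration file
#'
#' The file mirrors the [simulation_design()] arguments; `bands` and the
#' named per-band vectors are given as mappings.
#'
#' @param path Path to a YAML file.
#' @return A `qeeg_design` list.
#' @export
read_design_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$bands))
    cfg$bands <- lapply(cfg$bands, as.numeric)
  for (v in c("base_amp_uv", "ec_mult", "pasat_mult", "outdoor_mult",
              "topo_gradient"))
    if (!is.null(cfg[[v]])) cfg[[v]] <- unlist(cfg[[v]])
  do.call(simulation_design, cfg)
}

qeeg_conditions <- function() {
  expand.grid(environment = c("laboratory", "outdoor"),
              task = c("rest_ec", "rest_eo", "pasat"),
              stringsAsFactors = FALSE)
}

# Deterministic per-session sub-seed below 2^31, derived from the design seed.
session_seed <- function(design, subject, environment, task) {
  env_i <- match(environment, c("laboratory", "outdoor"))
  task_i <- match(task, c("rest_ec", "rest_eo", "pasat"))
  if (is.na(env_i)) stop("unknown environment: ", environment)
  if (is.na(task_i)) stop("unknown task: ", task)
  base <- (as.double(design$seed) %% 1e6) * 2099
  as.integer((base + subject * 1009 + env_i * 101 + task_i * 11) %% 2147483647)
}

# Frequency-domain synthesis helpers.  Components are drawn as complex
# Gaussian spectra on the positive-frequency bins of a band and scaled so
# that the time-domain RMS is exactly `target_rms` (Parseval; there is no
# DC component, so the signal is zero-mean).
spectrum_bins <- function(n, rate, lo, hi) {
  f <- seq_len(floor(n / 2)) * rate / n
  keep <- which(f >= lo & f <= hi)
  if (!length(keep)) stop("band contains no FFT bins at this length")
  keep
}

add_spectrum_component <- function(spec, keep, target_rms, n,
                                   shape = NULL) {
  z <- complex(real = stats::rnorm(length(keep)),
               imaginary = stats::rnorm(length(keep)))
  if (!is.null(shape)) z <- z * shape
  tot <- sum(Mod(z)^2)
  if (tot == 0) return(spec)
  z <- z * (n * target_rms / sqrt(2 * tot))
  spec[keep + 1L] <- spec[keep + 1L] + z
  spec[n + 1L - keep] <- spec[n + 1L - keep] + Conj(z)
  spec
}

# Band-limited Gaussian noise with exact RMS (used for EMG bursts).
narrowband_noise <- function(n, rate, lo, hi, target_rms = 1) {
  keep <- spectrum_bins(n, rate, lo, hi)
  spec <- add_spectrum_component(complex(real = rep(0, n)), keep,
                                 target_rms, n)
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# 0.2 s biphasic blink pulse, unit peak.
blink_pulse <- function(rate) {
  n <- round(0.2 * rate)
  t <- seq_len(n) / n
  sin(2 * pi * t) * sin(pi * t)^2 / max(abs(sin(2 * pi * t) * sin(pi * t)^2))
}

subject_multipliers <- function(design) {
  # one log-normal amplitude multiplier per subject and band, drawn from the
  # design seed so every session of a subject shares it
  set.seed(as.integer(design$seed %% 2147483647))
  nb <- length(design$bands)
  m <- matrix(exp(stats::rnorm(design$n_subjects * nb, 0,
                               design$subject_sdlog)),
              design$n_subjects, nb,
              dimnames = list(NULL, names(design$bands)))
  m
}

condition_multiplier <- function(design, environment, task) {
  m <- rep(1, length(design$bands))
  names(m) <- names(design$bands)
  if (task == "rest_ec") m <- m * design$ec_mult
  if (task == "pasat")   m <- m * design$pasat_mult
  if (environment == "outdoor") m <- m * design$outdoor_mult
  m
}

band_channel_gain <- function(design, mon) {
  # gain per channel and band: anterior-posterior gradient on the scalp
  # field; the EOG channel carries only attenuated cortical activity
  g <- outer(mon$x, design$topo_gradient, function(x, gr) 1 + gr * x)
  dimnames(g) <- list(mon$label, names(design$bands))
  g[mon$type == "eog", ] <- 0.3
  pmax(g, 0.05)
}

#' Generate one synthetic mobile-EEG recording
#'
#' Returns a continuous multichannel recording (microvolts) for one subject,
#' environment and task: per-band narrowband oscillations scaled by subject,
#' condition and topography multipliers, 1/f background, blink transients
#' (largest on LVEOG, decaying front to back on the scalp) and broadband
#' (> 20 Hz) EMG bursts.  Deterministic given the design seed.
#'
#' @param design A [simulation_design()].
#' @param subject Subject index in `1:n_subjects`.
#' @param environment `"laboratory"` or `"outdoor"`.
#' @param task `"rest_ec"`, `"rest_eo"` or `"pasat"`.
#' @param montage Montage to record from, see [qeeg_montage()]; the
#'   reference position (CZ) is implicit and not recorded.
#' @return A list of class `qeeg_recording` with elements `signal`
#'   (channels x samples matrix, rownames = labels), `rate`, `montage` and
#'   `meta` (ids, condition, bad channels, blink/EMG event times).
#' @export
generate_recording <- function(design, subject, environment, task,
                               montage = qeeg_montage()) {
  stopifnot(inherits(design, "qeeg_design"))
  if (!environment %in% c("laboratory", "outdoor"))
    stop("unknown environment: ", environment)
  if (!task %in% c("rest_ec", "rest_eo", "pasat"))
    stop("unknown task: ", task)
  if (subject < 1 || subject > design$n_subjects)
    stop("subject index out of range")
  dur <- if (task == "pasat") design$duration_pasat else design$duration_rest
  n <- round(dur * design$rate)
  rate <- design$rate
  mon <- montage[montage$type != "reference", , drop = FALSE]
  nch <- nrow(mon)

  subj_mult <- subject_multipliers(design)[subject, ]
  cond_mult <- condition_multiplier(design, environment, task)
  gain <- band_channel_gain(design, mon)

  set.seed(session_seed(design, subject, environment, task))
  sig <- matrix(0, nch, n, dimnames = list(mon$label, NULL))

  sess_mult <- exp(stats::rnorm(length(design$bands), 0, design$session_sdlog))
  names(sess_mult) <- names(design$bands)
  band_keep <- lapply(design$bands, function(b)
    spectrum_bins(n, rate, b[1], b[2]))
  noise_keep <- spectrum_bins(n, rate, 1, min(45, rate / 2 - 1))
  noise_shape <- (noise_keep * rate / n)^(-design$oneoverf_exponent / 2)
  noise_gain <- ifelse(mon$type == "eog", 0.5, 1) * design$noise_rms
  for (ch in seq_len(nch)) {
    spec <- complex(real = rep(0, n))
    for (b in names(design$bands)) {
      amp <- design$base_amp_uv[[b]] * subj_mult[[b]] * cond_mult[[b]] *
        sess_mult[[b]] * gain[ch, b]
      if (amp <= 0) next
      spec <- add_spectrum_component(spec, band_keep[[b]], amp, n)
    }
    if (noise_gain[ch] > 0)
      spec <- add_spectrum_component(spec, noise_keep, noise_gain[ch], n,
                                     shape = noise_shape)
    sig[ch, ] <- Re(stats::fft(spec, inverse = TRUE)) / n
  }
  if (!is.null(design$tones))
    for (k in seq_len(nrow(design$tones))) {
      tone <- design$tones$amp_uv[k] *
        sin(2 * pi * design$tones$freq[k] * seq_len(n) / rate)
      sig <- sweep(sig, 2, tone, "+")
    }

  # blink transients: Poisson-scheduled, peak blink_amp_uv on LVEOG, frontal
  # gradient on the scalp (must trip the EOG rejection threshold)
  blink_t <- numeric(0)
  n_blinks <- stats::rpois(1, design$blink_rate_per_min * dur / 60)
  if (n_blinks > 0) {
    blink_t <- sort(stats::runif(n_blinks, 0, dur - 0.25))
    pulse <- blink_pulse(rate)
    bg <- ifelse(mon$type == "eog", 1, pmax(mon$x, 0)^2 * 0.45)
    bg[mon$type == "mastoid"] <- 0.05
    for (t0 in blink_t) {
      i0 <- floor(t0 * rate) + 1L
      idx <- i0:(i0 + length(pulse) - 1L)
      sig[, idx] <- sig[, idx] +
        design$blink_amp_uv * outer(bg, pulse)
    }
  }

  # EMG bursts: 0.5 s of 21-45 Hz noise, random per-channel gain
  emg_t <- numeric(0)
  n_emg <- stats::rpois(1, design$emg_rate_per_min * dur / 60)
  if (n_emg > 0) {
    emg_t <- sort(stats::runif(n_emg, 0, dur - 0.55))
    m <- round(0.5 * rate)
    taper <- sin(pi * seq_len(m) / (m + 1))^2
    for (t0 in emg_t) {
      i0 <- floor(t0 * rate) + 1L
      idx <- i0:(i0 + m - 1L)
      cg <- stats::runif(nch, 0.6, 1.6)
      cg[mon$type == "eog"] <- 0.2
      burst <- narrowband_noise(m, rate, 21, min(45, rate / 2 - 1)) * taper
      sig[, idx] <- sig[, idx] + 40 * outer(cg, burst)
    }
  }

  # occasional bad channel: flat line with low-amplitude drift
  bad <- character(0)
  if (stats::runif(1) < design$bad_channel_prob) {
    cand <- mon$label[mon$type == "eeg"]
    bad <- sample(cand, 1)
    drift <- 2 * sin(2 * pi * 0.3 * seq_len(n) / rate)
    sig[bad, ] <- drift + stats::rnorm(n, 0, 0.2)
  }

  if (any(!is.finite(sig))) stop("non-finite samples generated")
  rec <- list(signal = sig, rate = rate, montage = montage,
              meta = list(subject = subject, environment = environment,
                          task = task, duration = dur,
                          bad_channels = bad, blink_times = blink_t,
                          emg_times = emg_t))
  class(rec) <- "qeeg_recording"
  rec
}

#' @export
print.qeeg_recording <- function(x, ...) {
  cat(sprintf("<qeeg_recording> subject %s, %s, %s: %d channels x %d samples @ %g Hz\n",
              x$meta$subject, x$meta$environment, x$meta$task,
              nrow(x$signal), ncol(x$signal), x$rate))
  if (length(x$meta$bad_channels))
    cat("  bad channels:", paste(x$meta$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Counterbalanced session order list
#'
#' Emulates the predetermined order list balancing environment order,
#' eyes-closed/open order, task order and PASAT version across subjects.
#'
#' @param n_subjects Number of subjects.
#' @return Data frame with one row per subject.
#' @export
session_orders <- function(n_subjects) {
  s <- seq_len(n_subjects) - 1L
  data.frame(subject = s + 1L,
             env_first = ifelse(s %% 2 == 0, "laboratory", "outdoor"),
             rest_first = ifelse((s %/% 2) %% 2 == 0, "rest_ec", "rest_eo"),
             task_first = ifelse((s %/% 4) %% 2 == 0, "rest", "pasat"),
             pasat_version = (s %% 2) + 1L,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic group dataset
#'
#' One recording per subject x environment x task, plus the noiseless
#' ground-truth band-power table (dB), the counterbalanced order list, the
#' outdoor weather covariates and simulated PASAT responses.  For the default
#' session durations the recordings are large; use short durations when a
#' materialized list is needed, or [run_pipeline()] which streams sessions.
#'
#' @param design A [simulation_design()].
#' @param tasks Subset of tasks to generate (default all three).
#' @param montage Montage, see [qeeg_montage()].
#' @return List with elements `recordings` (list of `qeeg_recording`),
#'   `truth` (data frame), `orders`, `weather` and `pasat`.
#' @export
generate_group <- function(design, tasks = c("rest_ec", "rest_eo", "pasat"),
                           montage = qeeg_montage()) {
  stopifnot(inherits(design, "qeeg_design"), design$n_subjects >= 2)
  cond <- qeeg_conditions()
  cond <- cond[cond$task %in% tasks, , drop = FALSE]
  recs <- vector("list", design$n_subjects * nrow(cond))
  k <- 0L
  for (s in seq_len(design$n_subjects))
    for (i in seq_len(nrow(cond))) {
      k <- k + 1L
      recs[[k]] <- generate_recording(design, s, cond$environment[i],
                                      cond$task[i], montage)
    }
  list(recordings = recs,
       truth = ground_truth_power(design, tasks = tasks, montage = montage),
       orders = session_orders(design$n_subjects),
       weather = generate_weather(design, design$n_subjects),
       pasat = generate_pasat_behavior(design))
}

#' Noiseless ground-truth band power table
#'
#' Expected per-cell band power in dB (power/1 uV^2) at the analysis
#' electrodes, from the design amplitudes and multipliers alone: the
#' band-average power of a narrowband component of RMS amplitude `a` spread
#' over `k` 1-Hz bins is `a^2 / k`.
#'
#' @param design A [simulation_design()].
#' @param electrodes Electrodes to tabulate.
#' @param tasks Tasks to tabulate.
#' @param montage Montage.
#' @return Long data frame (participant, environment, condition, electrode,
#'   band, truth_db).
#' @export
ground_truth_power <- function(design, electrodes = c("FZ", "OZ"),
                               tasks = c("rest_ec", "rest_eo", "pasat"),
                               montage = qeeg_montage()) {
  mon <- montage[montage$type != "reference", , drop = FALSE]
  gain <- band_channel_gain(design, mon)
  subj_mult <- subject_multipliers(design)
  cond <- qeeg_conditions()
  cond <- cond[cond$task %in% tasks, , drop = FALSE]
  out <- list()
  for (s in seq_len(design$n_subjects))
    for (i in seq_len(nrow(cond))) {
      cm <- condition_multiplier(design, cond$environment[i], cond$task[i])
      for (el in electrodes)
        for (b in names(design$bands)) {
          nb <- design$bands[[b]][2] - design$bands[[b]][1] + 1
          amp <- design$base_amp_uv[[b]] * subj_mult[s, b] * cm[[b]] *
            gain[el, b]
          out[[length(out) + 1L]] <- data.frame(
            participant = s, environment = cond$environment[i],
            condition = cond$task[i], electrode = el, band = b,
            truth_db = 10 * log10(amp^2 / nb), stringsAsFactors = FALSE)
        }
    }
  do.call(rbind, out)
}

#' Generate outdoor weather covariates
#'
#' One row per outdoor session, drawn around the mean outdoor conditions of
#' the study (temperature 19 C, relative humidity 57 %, pressure 742 mm Hg,
#' wind 4 m/s, cloud cover 43 %, time of day 14.0 h) with spreads consistent
#' with their reported 95% CIs at n = 21; humidity and cloudiness are clipped
#' to [0, 100] and wind to >= 0.
#'
#' @param design A [simulation_design()] (supplies the seed).
#' @param n_sessions Number of outdoor sessions (>= 1).
#' @param zero_variance If `TRUE` every row equals the means exactly.
#' @return Data frame of class `qeeg_weather`.
#' @export
generate_weather <- function(design, n_sessions, zero_variance = FALSE) {
  stopifnot(n_sessions >= 1)
  means <- c(temperature = 19, humidity = 57, pressure = 742,
             wind = 4, cloudiness = 43, time_of_day = 14)
  # sd = CI half-width * sqrt(21) / 1.96
  hw <- c(temperature = 2.5, humidity = 10.5, pressure = 11.5,
          wind = 1, cloudiness = 20.5, time_of_day = 1)
  sds <- hw * sqrt(21) / 1.96
  if (zero_variance) {
    w <- as.data.frame(t(matrix(means, length(means), n_sessions,
                                dimnames = list(names(means), NULL))))
  } else {
    set.seed(as.integer((design$seed + 7919) %% 2147483647))
    w <- as.data.frame(vapply(names(means), function(v)
      stats::rnorm(n_sessions, means[[v]], sds[[v]]),
      numeric(n_sessions)))
  }
  w$humidity <- pmin(pmax(w$humidity, 0), 100)
  w$cloudiness <- pmin(pmax(w$cloudiness, 0), 100)
  w$wind <- pmax(w$wind, 0)
  w$time_of_day <- pmin(pmax(w$time_of_day, 7), 20)
  w <- cbind(session = seq_len(n_sessions), w)
  class(w) <- c("qeeg_weather", "data.frame")
  w
}

#' PASAT answer key
#'
#' Sixty pairwise sums of a seeded random digit stream (digits 1-9), as
#' presented every 3 s.
#'
#' @param seed Integer seed.
#' @param n_trials Number of scored trials (default 60).
#' @return Integer vector of correct answers.
#' @export
generate_pasat_key <- function(seed = 1L, n_trials = 60) {
  set.seed(as.integer(seed %% 2147483647))
  digits <- sample(1:9, n_trials + 1, replace = TRUE)
  digits[-1] + digits[-(n_trials + 1)]
}

#' Simulate a PASAT responder
#'
#' Each trial is answered correctly with probability `accuracy`; errors are
#' off-by-one-or-two slips and a small fraction of blanks (NA).
#'
#' @param key Answer key from [generate_pasat_key()].
#' @param accuracy Per-trial probability of a correct response.
#' @param seed Integer seed.
#' @return Integer vector (with NAs) the same length as `key`.
#' @export
simulate_pasat_responses <- function(key, accuracy, seed = 1L) {
  set.seed(as.integer(seed %% 2147483647))
  n <- length(key)
  ok <- stats::runif(n) < accuracy
  resp <- key
  wrong <- which(!ok)
  blank <- wrong[stats::runif(length(wrong)) < 0.3]
  slip <- setdiff(wrong, blank)
  resp[slip] <- key[slip] + sample(c(-2, -1, 1, 2), length(slip),
                                   replace = TRUE)
  resp[blank] <- NA_integer_
  resp
}

generate_pasat_behavior <- function(design) {
  out <- list()
  for (s in seq_len(design$n_subjects))
    for (env in c("laboratory", "outdoor")) {
      sd <- session_seed(design, s, env, "pasat") + 1L
      key <- generate_pasat_key(sd, 60)
      resp <- simulate_pasat_responses(key, design$pasat_accuracy, sd + 1L)
      out[[length(out) + 1L]] <- data.frame(
        subject = s, environment = env,
        score = pasat_score(resp, key), stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}
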