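# Independent epoch-count oracle: enumerate window starts directly.
count_epochs <- function(T, L, overlap) {
  step <- L * (1 - overlap)
  k <- 0
  t0 <- 0
  while (t0 + L <= T + 1e-9) {
    k <- k + 1
    t0 <- k * step
  }
  k
}

test_that("epoch counts follow the overlapping-window convention", {
  mk <- function(T) synth_recording(dur_s = T)
  expect_equal(dim(epoch_signal(mk(1))$data)[1], 1)
  expect_equal(dim(epoch_signal(mk(2))$data)[1], 3)
  expect_equal(dim(epoch_signal(mk(300))$data)[1], 599)
  expect_equal(dim(epoch_signal(mk(180))$data)[1], 359)
  for (T in c(3, 5, 10))
    for (L in c(1, 2))
      for (ov in c(0, 0.25, 0.5, 0.75)) {
        got <- dim(epoch_signal(mk(T), length_s = L, overlap = ov)$data)[1]
        expect_equal(got, count_epochs(T, L, ov),
                     info = sprintf("T=%g L=%g ov=%g", T, L, ov))
      }
  expect_error(epoch_signal(mk(2), length_s = 3), "shorter")
})

test_that("epochs are baseline-corrected per channel", {
  rec <- synth_recording(4, f = function(lab, n) rnorm(n, 7, 1))
  ep <- epoch_signal(rec)
  expect_lt(max(abs(apply(ep$data, c(1, 2), mean))), 1e-12)
})

test_that("linked-mastoids re-referencing is the expected affine map", {
  # silent mastoids: data unchanged, CZ appended as zeros
  rec <- synth_recording(2, f = function(lab, n)
    if (lab %in% c("M1", "M2")) rep(0, n) else sin(seq_len(n) / 9))
  ep0 <- epoch_signal(rec)
  ep <- rereference_linked_mastoids(ep0)
  expect_equal(ep$reference_state, "linked_mastoids")
  expect_true("CZ" %in% ep$labels)
  expect_equal(ep$data[, channel_idx(ep, "CZ"), ], ep$data[, 1, ] * 0)
  expect_equal(ep$data[, seq_along(ep0$labels), ], ep0$data)

  # common-mode mastoid signal shifts every scalp channel by -s(t)
  s_t <- function(n) cos(seq_len(n) / 5)
  rec2 <- synth_recording(2, f = function(lab, n)
    if (lab %in% c("M1", "M2")) s_t(n) else rep(0, n))
  ep2 <- rereference_linked_mastoids(epoch_signal(rec2))
  fz <- ep2$data[, channel_idx(ep2, "FZ"), ]
  base <- epoch_signal(rec2)$data[, channel_idx(epoch_signal(rec2), "M1"), ]
  expect_equal(fz, -base, tolerance = 1e-12)
  # the EOG channel is left untouched
  expect_equal(ep2$data[, channel_idx(ep2, "LVEOG"), ], fz * 0)

  # random data: the mean of the re-referenced mastoid traces is zero
  rec3 <- synth_recording(2)
  ep3 <- rereference_linked_mastoids(epoch_signal(rec3))
  m <- (ep3$data[, channel_idx(ep3, "M1"), ] +
          ep3$data[, channel_idx(ep3, "M2"), ]) / 2
  expect_lt(max(abs(m)), 1e-12)

  # guard: a second application errors; with the guard bypassed it differs
  # from one application by exactly another mastoid-average subtraction
  expect_error(rereference_linked_mastoids(ep3), "already")
  ep3b <- ep3
  ep3b$reference_state <- "vertex"
  ep4 <- rereference_linked_mastoids(ep3b)
  again <- (ep3$data[, channel_idx(ep3, "M1"), ] +
              ep3$data[, channel_idx(ep3, "M2"), ]) / 2
  expect_equal(ep4$data[, channel_idx(ep4, "FZ"), ],
               ep3$data[, channel_idx(ep3, "FZ"), ] - again,
               tolerance = 1e-12)
})

test_that("EOG rejection drops exactly the epochs whose EOG trace crosses threshold", {
  rec <- synth_recording(4, f = function(lab, n) rep(0, n))
  ep <- reject_eog(epoch_signal(rec))
  expect_true(all(ep$retained))

  # a single 60 uV spike in the third epoch window only
  rec2 <- synth_recording(4, f = function(lab, n) {
    x <- rep(0, n)
    if (lab == "LVEOG") x[290] <- 60   # 1.13 s: inside epochs 2 and 3 only
    x
  })
  ep2 <- reject_eog(epoch_signal(rec2), threshold_uV = 50)
  expect_equal(which(!ep2$retained), c(2L, 3L))
  expect_true(all(ep2$reason[!ep2$retained] == "eog_threshold"))
})

test_that("blink-train rejection matches a reconstruction oracle", {
  des <- quiet_design(
    base_amp_uv = c(theta = 0, alpha = 0, beta = 0),
    blink_rate_per_min = 10, duration_rest = 300, seed = 77)
  rec <- generate_recording(des, 1, "outdoor", "rest_eo")
  ep <- reject_eog(epoch_signal(rec), threshold_uV = 50)

  # oracle: rebuild the EOG trace from the scheduled blink times and test
  # each epoch window independently
  rate <- rec$rate
  n <- ncol(rec$signal)
  m <- round(0.2 * rate)
  tt <- seq_len(m) / m
  pulse <- sin(2 * pi * tt) * sin(pi * tt)^2
  pulse <- pulse / max(abs(pulse))
  eog <- rep(0, n)
  for (t0 in rec$meta$blink_times) {
    i0 <- floor(t0 * rate) + 1
    eog[i0:(i0 + m - 1)] <- eog[i0:(i0 + m - 1)] + 150 * pulse
  }
  starts <- round((seq_along(ep$retained) - 1) * 0.5 * rate)
  keep_oracle <- vapply(starts, function(s0) {
    seg <- eog[(s0 + 1):(s0 + rate)]
    max(abs(seg - mean(seg))) <= 50
  }, logical(1))
  expect_identical(ep$retained, keep_oracle)
  expect_gt(sum(!keep_oracle), 0)
})

test_that("amplitude rejection applies peak, HF-RMS and manual rules", {
  rec <- synth_recording(6, f = function(lab, n) rnorm(n, 0, 2))
  ep <- epoch_signal(rec)
  expect_true(all(reject_amplitude(ep, peak_uV = Inf,
                                   hf_rms_uV = Inf)$retained))

  # inject a 30 Hz burst into epoch 5 on FZ with RMS above threshold
  rec2 <- synth_recording(6, f = function(lab, n) {
    x <- rnorm(n, 0, 2)
    if (lab == "FZ") {
      idx <- (2 * 256 + 1):(2 * 256 + 128)   # 2.0-2.5 s
      x[idx] <- x[idx] + 40 * sin(2 * pi * 30 * seq_along(idx) / 256)
    }
    x
  })
  ep2 <- reject_amplitude(epoch_signal(rec2), peak_uV = 100, hf_rms_uV = 15)
  expect_equal(which(!ep2$retained), c(4L, 5L))
  expect_true(all(ep2$reason[!ep2$retained] == "amplitude"))

  ep3 <- reject_amplitude(ep, peak_uV = Inf, hf_rms_uV = Inf,
                          manual_drop = c(2, 9))
  expect_equal(which(!ep3$retained), c(2L, 9L))
  expect_true(all(ep3$reason[c(2, 9)] == "manual_list"))
  expect_error(reject_amplitude(ep, channels = "NOPE"), "not present")
})

test_that("amplitude screening agrees with a brute-force per-epoch re-check", {
  des <- simulation_design(n_subjects = 2, duration_rest = 60,
                           blink_rate_per_min = 0, seed = 15)
  rec <- generate_recording(des, 1, "laboratory", "rest_eo")
  ep <- epoch_signal(rec)
  got <- reject_amplitude(ep, peak_uV = 60, hf_rms_uV = 10)

  hp_rms <- function(x, rate) {
    n <- length(x)
    X <- fft(x)
    f <- (seq_len(n) - 1) * rate / n
    f <- pmin(f, rate - f)
    X[f <= 20] <- 0
    sqrt(mean(Re(fft(X, inverse = TRUE) / n)^2))
  }
  ic <- channel_idx(ep, "FZ")
  io <- channel_idx(ep, "OZ")
  keep_oracle <- vapply(seq_len(dim(ep$data)[1]), function(e) {
    xs <- list(ep$data[e, ic, ], ep$data[e, io, ])
    all(vapply(xs, function(x)
      max(abs(x)) <= 60 && hp_rms(x, ep$rate) <= 10, logical(1)))
  }, logical(1))
  expect_identical(got$retained, keep_oracle)
})

test_that("rejection is equivariant under epoch permutation", {
  des <- simulation_design(n_subjects = 2, duration_rest = 30, seed = 8)
  rec <- generate_recording(des, 1, "outdoor", "rest_ec")
  ep <- epoch_signal(rec)
  run <- function(e) reject_amplitude(reject_eog(e), peak_uV = 60,
                                      hf_rms_uV = 10)
  mask1 <- run(ep)$retained
  set.seed(1)
  perm <- sample(length(mask1))
  ep2 <- ep
  ep2$data <- ep$data[perm, , , drop = FALSE]
  expect_identical(run(ep2)$retained, mask1[perm])
})

test_that("spherical-spline interpolation reproduces constants and smooth fields", {
  mon <- qeeg_montage()
  # constant field: the interpolated channel is exactly the constant
  rec <- synth_recording(1, f = function(lab, n)
    if (lab == "LVEOG") rep(0, n) else rep(3.25, n))
  ep <- epoch_signal(rec)
  ep$data <- ep$data + 3.25 * 0  # keep baseline-corrected copy implicit
  # bypass baseline correction: inject the constant after epoching
  for (ch in seq_along(ep$labels))
    if (ep$labels[ch] != "LVEOG") ep$data[, ch, ] <- 3.25
  out <- interpolate_bad_channels(ep, "P3")
  expect_equal(out$data[, channel_idx(out, "P3"), ],
               ep$data[, channel_idx(ep, "P3"), ] * 0 + 3.25,
               tolerance = 1e-9)
  expect_equal(out$interpolated, "P3")
  # good channels are bit-identical
  for (lab in setdiff(ep$labels, "P3"))
    expect_identical(out$data[, channel_idx(out, lab), ],
                     ep$data[, channel_idx(ep, lab), ])

  # with lambda = 0 the spline interpolates its own knots exactly
  labs <- mon$label[mon$type %in% c("eeg", "mastoid")]
  pos <- as.matrix(mon[match(labs, mon$label), c("x", "y", "z")])
  z <- sin(3 * pos[, 1]) + pos[, 2]^2
  G <- qeegpower:::spline_gfun(tcrossprod(pos), m = 4, n_terms = 50)
  C <- rbind(cbind(G, 1), c(rep(1, nrow(pos)), 0))
  a <- solve(C, c(z, 0))
  fitted <- as.vector(cbind(G, 1) %*% a)
  expect_equal(fitted, unname(z), tolerance = 1e-6)
})

test_that("interpolation matches a direct Legendre-series oracle", {
  skip_if_not_installed("pracma")
  mon <- qeeg_montage()
  set.seed(4)
  rec <- synth_recording(2)
  ep <- epoch_signal(rec)
  bad <- c("C4", "P3")
  out <- interpolate_bad_channels(ep, bad, lambda = 1e-5)

  # oracle: independent g-function via pracma Legendre polynomials and a
  # fresh solve of the augmented system for every sample
  g_oracle <- function(x) {
    s <- 0
    for (n in 1:50)
      s <- s + (2 * n + 1) / (n * (n + 1))^4 * pracma::legendre(n, x)[1, ]
    s / (4 * pi)
  }
  field <- setdiff(mon$label[mon$type %in% c("eeg", "mastoid")], bad)
  pos_g <- as.matrix(mon[match(field, mon$label), c("x", "y", "z")])
  pos_b <- as.matrix(mon[match(bad, mon$label), c("x", "y", "z")])
  p <- nrow(pos_g)
  G <- matrix(g_oracle(pmin(as.vector(tcrossprod(pos_g)), 1)), p, p)
  C <- rbind(cbind(G + 1e-5 * diag(p), 1), c(rep(1, p), 0))
  gb <- matrix(g_oracle(pmin(as.vector(tcrossprod(pos_b, pos_g)), 1)),
               nrow(pos_b), p)
  ig <- match(field, ep$labels)
  for (e in c(1, 2)) {
    for (smp in c(10, 100)) {
      zz <- ep$data[e, ig, smp]
      a <- solve(C, c(zz, 0))
      est <- as.vector(cbind(gb, 1) %*% a)
      expect_equal(out$data[e, match(bad, out$labels), smp], est,
                   tolerance = 1e-6)
    }
  }
})

test_that("too few good channels is an error", {
  rec <- synth_recording(1)
  ep <- epoch_signal(rec)
  bad <- setdiff(ep$labels, c("FZ", "OZ", "M1", "LVEOG"))
  expect_error(interpolate_bad_channels(ep, bad), "at least 4")
})

test_that("rejection report counts reconcile", {
  des <- simulation_design(n_subjects = 2, duration_rest = 60, seed = 12)
  rec <- generate_recording(des, 2, "outdoor", "rest_ec")
  ep <- preprocess_recording(rec, manual_drop = 1:3)
  rep <- rejection_report(ep)
  expect_equal(rep$total_epochs,
               rep$retained + rep$eog_threshold + rep$amplitude +
                 rep$manual_list)
  expect_equal(rep$total_epochs, 119)
  # every dropped epoch has exactly one reason
  expect_true(all(is.na(ep$reason[ep$retained])))
  expect_true(all(!is.na(ep$reason[!ep$retained])))
})
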