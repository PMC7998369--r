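test_that("the BIC Bayes factor reproduces its closed-form anchors", {
  expect_equal(unname(bf01_from_f(0, 1, 20, 21)["B01"]), sqrt(21))
  b <- bf01_from_f(10.38, 1, 20, 21)
  expect_equal(unname(b["B10"]), 17.60, tolerance = 0.01)
  b2 <- bf01_from_f(24.32, 1, 20, 21)
  expect_equal(unname(b2["B10"]), 927.41, tolerance = 0.01)
  expect_error(bf01_from_f(-1, 1, 20, 21), "F must")
  expect_error(bf01_from_f(1, 1, 0, 21), "degrees of freedom")
  expect_error(bf01_from_f(1, 25, 20, 21), "exceed")
})

test_that("B01 is a continuous, strictly decreasing function of F", {
  Fs <- seq(0, 60, by = 0.25)
  b <- vapply(Fs, function(f) bf01_from_f(f, 1, 20, 21)[["B01"]], numeric(1))
  expect_true(all(diff(b) < 0))
  expect_true(all(abs(vapply(Fs, function(f)
    prod(bf01_from_f(f, 1, 20, 21)), numeric(1)) - 1) < 1e-12))
})

test_that("posterior probabilities round-trip with both Bayes factors", {
  expect_equal(unname(posterior_probs(1)), c(0.5, 0.5))
  expect_equal(posterior_probs(4.47)[["pH0"]], 0.82, tolerance = 0.005)
  expect_equal(posterior_probs(2.47)[["pH0"]], 0.71, tolerance = 0.005)
  for (b01 in c(0.03, 0.5, 1, 2.2, 40)) {
    pp <- posterior_probs(b01)
    b10 <- 1 / b01
    expect_equal(pp[["pH1"]], b10 / (1 + b10), tolerance = 1e-12)
    expect_equal(sum(pp), 1)
  }
  expect_error(posterior_probs(0), "B01")
})

test_that("Jeffreys labels use half-open bins with the documented boundaries", {
  expect_equal(jeffreys_label(2), "weak")
  expect_equal(jeffreys_label(3.16), "substantial")
  expect_equal(jeffreys_label(10), "strong")
  expect_equal(jeffreys_label(31.62), "very strong")
  expect_equal(jeffreys_label(100), "decisive")
  expect_equal(jeffreys_label(c(1, 9.99, 99.99)),
               c("weak", "substantial", "very strong"))
  expect_error(jeffreys_label(0.5), ">= 1")
  expect_equal(bf_evidence_mark(c(2, 5, 17, 50, 300)),
               c("†", "††", "†††", "†††", "†††"))
})

test_that("rm_anova returns zero F on condition-invariant data", {
  d <- expand.grid(subject = 1:6, environment = c("lab", "out"),
                   condition = c("ec", "eo"), electrode = c("FZ", "OZ"))
  d$value <- 3 + d$subject
  res <- rm_anova(d, factors = c("environment", "condition", "electrode"))
  expect_equal(nrow(res), 7)
  expect_true(all(res$F == 0))
  expect_true(all(res$eta2p == 0))
  expect_true(all(res$B01 == sqrt(6)))
})

test_that("rm_anova agrees with an independent per-subject contrast oracle", {
  set.seed(17)
  for (k in 1:3) {
    facs <- c("A", "B", "C")[seq_len(k)]
    d <- expand.grid(c(list(subject = 1:7),
                       stats::setNames(rep(list(c("l1", "l2")), k), facs)))
    d$value <- rnorm(nrow(d)) + (d$A == "l2") * 0.8 + d$subject / 5
    res <- rm_anova(d, factors = facs)
    for (i in seq_len(nrow(res))) {
      eff <- strsplit(res$effect[i], " × ")[[1]]
      expect_equal(res$F[i], contrast_F(d, "value", "subject", facs, eff),
                   tolerance = 1e-8, info = res$effect[i])
    }
    expect_true(all(res$df1 == 1 & res$df2 == 6))
  }
})

test_that("rm_anova is invariant to adding a constant", {
  set.seed(23)
  d <- expand.grid(subject = 1:5, A = c("a", "b"), B = c("x", "y"))
  d$value <- rnorm(nrow(d))
  r1 <- rm_anova(d, factors = c("A", "B"))
  d$value <- d$value + 100
  r2 <- rm_anova(d, factors = c("A", "B"))
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
})

test_that("the within-subject sums of squares decompose completely", {
  set.seed(31)
  d <- expand.grid(subject = factor(1:6), A = c("a", "b"), B = c("x", "y"))
  d$value <- rnorm(nrow(d))
  # brute-force SS decomposition of the 2x2 within design
  grand <- mean(d$value)
  ss_tot <- sum((d$value - grand)^2)
  subj_means <- tapply(d$value, d$subject, mean)
  ss_subj <- 4 * sum((subj_means - grand)^2)
  cell <- function(by) tapply(d$value, d[by], mean)
  ss_A <- 12 * sum((cell("A") - grand)^2)
  ss_B <- 12 * sum((cell("B") - grand)^2)
  ab <- cell(c("A", "B"))
  ss_AB <- 6 * sum((sweep(sweep(ab, 1, cell("A")), 2, cell("B")) + grand)^2)
  # error strata via subject x factor means
  sa <- cell(c("subject", "A"))
  ss_sA <- 2 * sum((sweep(sweep(sa, 1, subj_means), 2, cell("A")) + grand)^2)
  sb <- cell(c("subject", "B"))
  ss_sB <- 2 * sum((sweep(sweep(sb, 1, subj_means), 2, cell("B")) + grand)^2)
  ss_err3 <- ss_tot - ss_subj - ss_A - ss_B - ss_AB - ss_sA - ss_sB
  res <- rm_anova(d, factors = c("A", "B"))
  fA <- (ss_A / 1) / (ss_sA / 5)
  fB <- (ss_B / 1) / (ss_sB / 5)
  fAB <- (ss_AB / 1) / (ss_err3 / 5)
  expect_equal(res$F[res$effect == "A"], fA, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "B"], fB, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "A × B"], fAB, tolerance = 1e-8)
})

test_that("rm_anova rejects malformed designs", {
  d <- expand.grid(subject = 1:4, A = c("a", "b"))
  d$value <- rnorm(8)
  expect_error(rm_anova(d[-1, ], factors = "A"), "balanced")
  d3 <- expand.grid(subject = 1:4, A = c("a", "b", "c"))
  d3$value <- rnorm(12)
  expect_error(rm_anova(d3, factors = "A"), "2 levels")
  d2 <- expand.grid(subject = 1:2, A = c("a", "b"))
  d2$value <- rnorm(4)
  expect_error(rm_anova(d2, factors = "A"), "3 subjects")
})

test_that("corrected correlations reproduce a hand computation", {
  set.seed(41)
  n <- 21
  covs <- as.data.frame(matrix(rnorm(n * 6), n, 6,
                               dimnames = list(NULL, paste0("v", 1:6))))
  y <- rnorm(n)
  res <- corrected_correlations(covs, y)
  for (i in 1:6) {
    ct <- cor.test(covs[[i]], y)
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p[i], min(1, 6 * ct$p.value), tolerance = 1e-8)
    expect_equal(res$F[i], unname(ct$statistic)^2, tolerance = 1e-8)
  }
  expect_true(all(res$df2 == n - 2))
  # r = 0 gives F = 0 and B01 = sqrt(n)
  x0 <- c(-2, -1, 0, 1, 2)
  y0 <- c(1, -1, 0, -1, 1)  # exactly uncorrelated with x0
  r0 <- corrected_correlations(data.frame(a = x0), y0)
  expect_equal(r0$F, 0)
  expect_equal(r0$B01, sqrt(5))
  # perfect collinearity: corrected p -> 0, B10 large
  rc <- corrected_correlations(data.frame(a = y), y)
  expect_lt(rc$p, 1e-10)
  expect_gt(rc$B10, 1e6)
  expect_error(corrected_correlations(data.frame(a = rep(1, n)), y),
               "zero-variance")
})

test_that("PASAT scoring counts exact matches only", {
  key <- generate_pasat_key(seed = 2)
  expect_equal(pasat_score(key, key), 60)
  expect_equal(pasat_score(rep(NA_integer_, 60), key), 0)
  resp <- key
  resp[c(3, 10, 50)] <- resp[c(3, 10, 50)] + 1
  resp[20] <- NA
  expect_equal(pasat_score(resp, key), 56)
  expect_error(pasat_score(key[-1], key), "lengths differ")
  expect_error(pasat_score(rep(1, 59), rep(1, 59)), "60 trials")
})
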