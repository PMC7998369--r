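hedges_J <- function(n) 1 - 3 / (4 * (n - 1) - 1)

make_estimate <- function(g, se, n, source) {
  if (se <= 0) stop("standard error must be > 0")
  est <- list(g = g, se = se, ci_lo = g - 1.96 * se, ci_hi = g + 1.96 * se,
              n = n, source = source)
  class(est) <- "qeeg_effectsize"
  est
}

#' @export
print.qeeg_effectsize <- function(x, ...) {
  cat(sprintf("Hedges' g = %.3f, 95%% CI (%.3f, %.3f), se = %.3f, n = %d [%s]\n",
              x$g, x$ci_lo, x$ci_hi, x$se, x$n, x$source))
  invisible(x)
}

#' Repeated-measures Hedges' g from paired observations
#'
#' The average-SD variant: the mean paired difference standardized by the
#' average of the two condition standard deviations, times the small-sample
#' bias correction `J = 1 - 3 / (4(n-1) - 1)`.  The standard error uses the
#' paired-design normal approximation
#' `var(d) = (1/n + d^2/(2n)) * 2(1 - rho)` with the observed
#' cross-condition correlation (or `rho_assumed` when raw pairs are not
#' available), scaled by `J^2`; the 95% CI is `g +/- 1.96 se`.
#'
#' @param a,b Paired per-subject values (condition A and B).
#' @param rho_assumed Fallback correlation when `a` and `b` have zero
#'   variance or are not jointly available (default 0.7).
#' @return A `qeeg_effectsize` object (positive g means A > B).
#' @export
hedges_g_rm <- function(a, b, rho_assumed = 0.7) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  s_av <- (stats::sd(a) + stats::sd(b)) / 2
  if (s_av == 0) stop("zero pooled standard deviation")
  J <- hedges_J(n)
  d <- mean(a - b) / s_av
  g <- J * d
  rho <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b)
         else rho_assumed
  var_d <- (1 / n + d^2 / (2 * n)) * 2 * (1 - rho)
  var_d <- max(var_d, 1e-12)
  make_estimate(g, J * sqrt(var_d), n, "observed")
}

#' Literature study record
#'
#' Holds the statistics a published study reported in exactly one of three
#' forms: condition means and SDs (with optional cross-condition
#' correlation), a paired t statistic, or a single-df F statistic.
#'
#' @param study Study identifier.
#' @param n Number of subjects (>= 2).
#' @param band Frequency band label.
#' @param contrast Contrast label (free text).
#' @param means,sds Length-2 numeric vectors (condition A, condition B).
#' @param rho Optional cross-condition correlation accompanying means/sds.
#' @param t Paired t statistic.
#' @param F Single-df F statistic (converted via `t = sqrt(F)`).
#' @param direction Sign (+1/-1) applied when only F is reported.
#' @return A list of class `qeeg_study`.
#' @export
study_record <- function(study, n, band = NA_character_,
                         contrast = NA_character_, means = NULL, sds = NULL,
                         rho = NULL, t = NULL, F = NULL, direction = 1) {
  forms <- c(means = !is.null(means), t = !is.null(t), F = !is.null(F))
  if (sum(forms) != 1)
    stop("exactly one of means/sds, t, or F must be supplied")
  if (forms[["means"]] && (is.null(sds) || length(means) != 2 ||
                           length(sds) != 2))
    stop("means and sds must both be length-2 vectors")
  if (n < 2) stop("n must be >= 2")
  rec <- list(study = study, n = n, band = band, contrast = contrast,
              means = means, sds = sds, rho = rho, t = t, F = F,
              direction = sign(direction))
  class(rec) <- "qeeg_study"
  rec
}

#' Hedges' g from reported study statistics
#'
#' Means/SDs are standardized by the average condition SD; a paired t gives
#' `g = J * t / sqrt(n)`; a single-df F is converted through `t = sqrt(F)`
#' with the record's direction sign.  Standard errors use the paired-design
#' approximation with `rho_assumed` (or the record's own correlation).
#'
#' @param record A [study_record()].
#' @param rho_assumed Cross-condition correlation assumed when the record
#'   does not report one (default 0.7).
#' @return A `qeeg_effectsize` with source `"literature"`.
#' @export
g_from_reported <- function(record, rho_assumed = 0.7) {
  stopifnot(inherits(record, "qeeg_study"))
  n <- record$n
  J <- hedges_J(n)
  rho <- record$rho %||% rho_assumed
  if (!is.null(record$means)) {
    s_av <- mean(record$sds)
    if (s_av <= 0) stop("non-positive condition SDs")
    d <- (record$means[1] - record$means[2]) / s_av
  } else {
    t <- record$t %||% (sqrt(record$F) * record$direction)
    d <- t / sqrt(n)
  }
  g <- J * d
  var_d <- (1 / n + d^2 / (2 * n)) * 2 * (1 - rho)
  est <- make_estimate(g, J * sqrt(max(var_d, 1e-12)), n, "literature")
  est
}

#' Fixed-effect meta-analytic mean effect size
#'
#' Inverse-variance weighted mean of the input estimates with
#' `se = 1 / sqrt(sum(weights))` and a 95% normal CI.
#'
#' @param estimates List of `qeeg_effectsize` objects.
#' @return A pooled `qeeg_effectsize` with source `"meta"`.
#' @export
meta_mean <- function(estimates) {
  if (!length(estimates)) stop("no estimates to pool")
  g <- vapply(estimates, function(e) e$g, numeric(1))
  se <- vapply(estimates, function(e) e$se, numeric(1))
  if (any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  make_estimate(sum(w * g) / sum(w), 1 / sqrt(sum(w)),
                sum(vapply(estimates, function(e) e$n, numeric(1))), "meta")
}

#' Compare an observed effect size against a meta-analytic estimate
#'
#' Reports the three qualitative comparisons used to relate observed and
#' laboratory meta-analytic effects: 95% CI overlap, sign agreement, and
#' which magnitude is larger.
#'
#' @param observed,meta `qeeg_effectsize` objects (or any list with `g`,
#'   `ci_lo`, `ci_hi`).
#' @return A one-row data frame: `ci_overlap`, `same_sign`, `meta_larger`.
#' @export
compare_observed_vs_meta <- function(observed, meta) {
  overlap <- observed$ci_lo <= meta$ci_hi && meta$ci_lo <= observed$ci_hi
  data.frame(ci_overlap = overlap,
             same_sign = sign(observed$g) == sign(meta$g),
             meta_larger = abs(meta$g) > abs(observed$g))
}
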