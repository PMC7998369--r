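#' BIC-approximation Bayes factor from an F statistic
#'
#' Converts a repeated-measures F value, its degrees of freedom and the
#' number of subjects into the Bayes factor in favour of the null hypothesis
#' using the Bayesian Information Criterion approximation
#' `B01 = sqrt(n^df1 * (1 + F*df1/df2)^(-n))`, and its reciprocal `B10`.
#' At `F = 0` this gives `B01 = n^(df1/2)` exactly (e.g. `sqrt(21) = 4.58`
#' for a single-df effect at n = 21).
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param n Number of subjects entering the BIC penalty.
#' @return Named numeric vector `c(B01, B10)`.
#' @examples
#' bf01_from_f(10.38, 1, 20, 21)  # B10 approximately 17.6
#' @export
bf01_from_f <- function(F, df1, df2, n) {
  if (any(F < 0)) stop("F must be >= 0")
  if (df1 < 1 || df2 <= 0) stop("invalid degrees of freedom")
  if (n <= df1) stop("n must exceed df1")
  # log-domain evaluation keeps very large B10 values accurate
  logb01 <- 0.5 * (df1 * log(n) - n * log1p(F * df1 / df2))
  c(B01 = exp(logb01), B10 = exp(-logb01))
}

#' Posterior hypothesis probabilities from a Bayes factor
#'
#' `P(H0|Data) = B01 / (1 + B01)` and `P(H1|Data) = 1 - P(H0|Data)`.
#'
#' @param B01 Bayes factor in favour of the null (> 0).
#' @return Named numeric vector `c(pH0, pH1)`.
#' @examples
#' posterior_probs(4.47)  # pH0 = 0.82
#' @export
posterior_probs <- function(B01) {
  if (any(B01 <= 0)) stop("B01 must be > 0")
  p0 <- B01 / (1 + B01)
  c(pH0 = p0, pH1 = 1 - p0)
}

#' Jeffreys evidence label for a Bayes factor
#'
#' Half-open bins: weak `[1, 3.16)`, substantial `[3.16, 10)`, strong
#' `[10, 31.62)`, very strong `[31.62, 100)`, decisive `[100, Inf)`.
#' Apply to the larger of B01 and B10.
#'
#' @param B Bayes factor magnitude (>= 1).
#' @return Character label.
#' @export
jeffreys_label <- function(B) {
  if (any(B < 1)) stop("label the larger of B01 and B10 (B >= 1)")
  cut(B, breaks = c(1, 3.16, 10, 31.62, 100, Inf), right = FALSE,
      labels = c("weak", "substantial", "strong", "very strong", "decisive"),
      include.lowest = TRUE) |> as.character()
}

#' Table annotation mark for a Bayes factor
#'
#' The compact dagger annotation used in results tables: one dagger for weak
#' evidence, two for substantial, three for strong or better.
#'
#' @param B Bayes factor magnitude (>= 1).
#' @return Character vector of marks.
#' @export
bf_evidence_mark <- function(B) {
  lab <- jeffreys_label(B)
  ifelse(lab == "weak", "†",
         ifelse(lab == "substantial", "††", "†††"))
}

bayes_fields <- function(F, df1, df2, n) {
  bf <- bf01_from_f(F, df1, df2, n)
  pp <- posterior_probs(bf[["B01"]])
  bmax <- max(bf)
  data.frame(B01 = bf[["B01"]], B10 = bf[["B10"]],
             pH0 = pp[["pH0"]], pH1 = pp[["pH1"]],
             evidence = sprintf("%s (%s)", jeffreys_label(bmax),
                                if (bf[["B01"]] >= bf[["B10"]]) "H0" else "H1"),
             stringsAsFactors = FALSE)
}

#' Fully-within repeated-measures ANOVA with Bayes factors
#'
#' Fits a complete, balanced within-subjects ANOVA with one to three
#' two-level factors, each effect tested against its own subject-by-effect
#' error stratum, and augments each effect with partial eta squared
#' (`F*df1 / (F*df1 + df2)`), the BIC-approximation Bayes factors, posterior
#' probabilities and the Jeffreys evidence label.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject id column.
#' @param factors Character vector of 1-3 within-subject factor columns,
#'   each with exactly two levels.
#' @return An object of class `qeeg_anova`: a data frame with one row per
#'   effect (effect, F, df1, df2, n, p, eta2p, B01, B10, pH0, pH1,
#'   evidence).
#' @examples
#' d <- expand.grid(subject = factor(1:6), A = c("a1", "a2"))
#' d$value <- rnorm(nrow(d)) + (d$A == "a2")
#' rm_anova(d, dv = "value", factors = "A")
#' @export
rm_anova <- function(data, dv = "value", subject = "subject", factors) {
  stopifnot(is.data.frame(data), length(factors) >= 1, length(factors) <= 3,
            all(c(dv, subject, factors) %in% names(data)))
  dd <- data
  dd[[subject]] <- factor(dd[[subject]])
  for (f in factors) {
    dd[[f]] <- factor(dd[[f]])
    if (nlevels(dd[[f]]) != 2)
      stop("factor ", f, " must have exactly 2 levels")
  }
  if (!all(is.finite(dd[[dv]]))) stop("response contains non-finite values")
  n <- nlevels(dd[[subject]])
  if (n < 3) stop("need at least 3 subjects")
  counts <- table(dd[, c(subject, factors)])
  if (any(counts != 1))
    stop("design must be complete and balanced (one value per cell)")
  fstr <- paste(factors, collapse = " * ")
  form <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                    dv, fstr, subject, fstr))
  fit <- stats::aov(form, data = dd)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    rn <- trimws(rownames(tab))
    for (i in which(rn != "Residuals")) {
      ss_eff <- tab[i, "Sum Sq"]
      j <- which(rn == "Residuals")
      ss_err <- tab[j, "Sum Sq"]
      df1 <- tab[i, "Df"]; df2 <- tab[j, "Df"]
      tot <- ss_eff + ss_err
      Fv <- if (tot <= 0 || ss_eff / max(tot, .Machine$double.eps) < 1e-12) 0
            else tab[i, "F value"]
      if (is.nan(Fv)) Fv <- 0          # 0/0: no effect, no error variance
      Fv <- min(Fv, 1e12)              # zero error variance with an effect
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " × ", rn[i]), F = Fv, df1 = df1, df2 = df2,
        n = n, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
        eta2p = Fv * df1 / (Fv * df1 + df2),
        bayes_fields(Fv, df1, df2, n), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "dv") <- dv
  attr(res, "n") <- n
  class(res) <- c("qeeg_anova", "data.frame")
  res
}

#' @export
print.qeeg_anova <- function(x, digits = 2, ...) {
  n <- attr(x, "n", exact = TRUE) %||% unique(x$n)
  if (!length(n)) n <- "?"
  cat(sprintf("Within-subjects ANOVA with BIC Bayes factors (n = %s)\n",
              paste(n, collapse = "/")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.qeeg_anova <- function(object, ...) {
  n <- attr(object, "n", exact = TRUE) %||% unique(object$n)
  cat(sprintf("n = %s subjects; %d effects\n", paste(n, collapse = "/"),
              nrow(object)))
  sig <- object$effect[object$p < 0.05]
  cat("significant (p < 0.05):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  nullish <- object$effect[object$B01 > 3.16]
  cat("substantial-or-better null evidence (B01 > 3.16):",
      if (length(nullish)) paste(nullish, collapse = ", ") else "none", "\n")
  invisible(object)
}

#' Bonferroni-corrected Pearson correlations with Bayes factors
#'
#' Correlates each covariate column with the outcome, converts r to its
#' F-equivalent `r^2 (n-2) / (1-r^2)` on (1, n-2) degrees of freedom,
#' multiplies the p value by the number of tests (capped at 1) and fills the
#' Bayes fields from the BIC conversion.
#'
#' @param covariates Data frame or matrix (sessions x covariates).
#' @param y Outcome vector, one value per session.
#' @param n_bayes Sample size for the BIC penalty (defaults to the number of
#'   complete sessions).
#' @param n_tests Number of tests corrected across (default the number of
#'   covariate columns).
#' @return Data frame with one row per covariate (covariate, r, F, df1, df2,
#'   p, B01, B10, pH0, pH1, evidence).
#' @export
corrected_correlations <- function(covariates, y, n_bayes = NULL,
                                   n_tests = ncol(covariates)) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(y))
  rows <- list()
  for (v in names(covariates)) {
    x <- covariates[[v]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) stop("need at least 3 complete pairs for ", v)
    if (stats::sd(x[ok]) == 0) stop("zero-variance covariate: ", v)
    n <- sum(ok)
    r <- stats::cor(x[ok], y[ok])
    df2 <- n - 2
    Fv <- if (abs(r) >= 1) Inf else r^2 * df2 / (1 - r^2)
    p <- min(1, n_tests * stats::pf(Fv, 1, df2, lower.tail = FALSE))
    nb <- if (is.null(n_bayes)) n else n_bayes
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = v, r = r, F = Fv, df1 = 1, df2 = df2, n = nb, p = p,
      bayes_fields(min(Fv, 1e12), 1, df2, nb), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Score a PASAT response sheet
#'
#' Counts exact matches against the answer key; blanks (NA) are incorrect.
#'
#' @param responses Integer vector of 60 responses (NAs allowed).
#' @param key Integer answer key of length 60.
#' @return Integer score in `0:60`.
#' @export
pasat_score <- function(responses, key) {
  if (length(key) != 60) stop("PASAT key must have 60 trials")
  if (length(responses) != length(key))
    stop("responses and key lengths differ")
  sum(!is.na(responses) & responses == key)
}
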