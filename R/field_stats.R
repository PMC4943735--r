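# Supporting field statistics: 2x2 contingency chi-square (uncorrected),
# exact binomial test, maximum-likelihood logistic regression with
# per-term likelihood-ratio tests, and one-way ANOVA with Tukey HSD
# pairwise comparisons.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Tests association between two binary nominal variables (e.g. body-color
#' class vs a behavioral outcome). The statistic is the uncorrected
#' Pearson chi-square, equal to the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with a P-value from the
#' chi-square distribution on 1 degree of freedom. No Yates continuity
#' correction is applied. For very small cells, Fisher's exact test is
#' available via `fisher = TRUE`.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups,
#'   columns = outcomes: row 1 is (a, b), row 2 is (c, d). A 2x2 matrix
#'   may be given as `a`.
#' @param fisher If `TRUE`, also report Fisher's exact P-value.
#' @return A list: `statistic`, `df` (1), `p_value`, `table`, and
#'   `fisher_p` when requested.
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL, fisher = FALSE) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (!all(dim(tab) == 2L) || anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop_validation("cells must be four non-negative integers")
  if (sum(tab) < 1L) stop_validation("table total must be >= 1")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_validation("degenerate table: a row or column margin is zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- list(statistic = unname(ht$statistic), df = 1L,
              p_value = unname(ht$p.value), table = tab)
  if (fisher) out$fisher_p <- stats::fisher.test(tab)$p.value
  out
}

#' Exact binomial test
#'
#' Exact tail probability of observing `k` or more successes (one-sided
#' "greater") — or a deviation at least as extreme in either direction
#' (two-sided) — in `n` independent trials with success probability
#' `null_p`.
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Number of trials.
#' @param null_p Null success probability, in (0, 1) (default 0.5).
#' @param alternative `"greater"` (P(X >= k)) or `"two_sided"`.
#' @return The exact P-value.
#' @export
binomial_exact_test <- function(k, n, null_p = 0.5,
                                alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!is_scalar_number(k) || !is_scalar_number(n) ||
      k != round(k) || n != round(n) || k < 0 || n < 1 || k > n)
    stop_validation("need integers 0 <= k <= n with n >= 1")
  if (!is_scalar_number(null_p) || null_p <= 0 || null_p >= 1)
    stop_validation("null_p must lie strictly inside (0, 1)")
  alt <- if (alternative == "greater") "greater" else "two.sided"
  stats::binom.test(k, n, p = null_p, alternative = alt)$p.value
}

#' Maximum-likelihood logistic regression with likelihood-ratio tests
#'
#' Fits a binary-outcome logistic model (e.g. brown vs green body color
#' on month and snout-vent length) by maximum likelihood and tests each
#' term by a likelihood-ratio test: `LR chi^2 = 2 (LL_full -
#' LL_reduced)` on 1 degree of freedom, where the reduced model drops
#' that term.
#'
#' @param data A data.frame containing the outcome and predictor columns.
#' @param outcome Name of the binary outcome column (factor, character,
#'   logical, or 0/1 numeric; the second sorted level is modeled as the
#'   "success").
#' @param predictors Character vector of continuous predictor column
#'   names.
#' @param epsilon Convergence tolerance on the relative change in
#'   deviance (default 1e-8).
#' @return An object of class `logistic_fit`: `intercept`,
#'   `coefficients` (named), `log_lik`, `n`, `lr_tests` (data.frame with
#'   `term`, `lr_chisq`, `df`, `p_value`), and the underlying `glm` fit.
#' @export
logistic_fit_lr <- function(data, outcome, predictors, epsilon = 1e-8) {
  if (!is.data.frame(data)) stop_validation("data must be a data.frame")
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss)) stop_validation("missing column(s): ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_validation("outcome must be binary")
  if (length(unique(y)) < 2L)
    stop_validation("outcome must have both levels present")
  X <- as.matrix(data[predictors])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop_validation("rank-deficient design: predictors are collinear")
  if (nrow(data) <= length(predictors) + 1L)
    stop_validation("need n > number of parameters + 1")
  df <- data.frame(.y = y, X)
  fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = epsilon, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  # perfect separation: residual deviance collapses to 0 (the likelihood
  # has no finite maximizer), or the IRLS path diverges with a warning
  scaled <- abs(cf[-1]) * apply(X, 2, stats::sd)
  if (stats::deviance(fit) < 1e-6 || (sep_warn && max(scaled) > 10)) {
    worst <- names(which.max(scaled))
    stop("logistic fit did not converge: data are (quasi-)separated along '",
         worst, "'", call. = FALSE)
  }
  ll_full <- as.numeric(stats::logLik(fit))
  lr <- do.call(rbind, lapply(predictors, function(tm) {
    red <- setdiff(predictors, tm)
    fml_r <- stats::as.formula(
      paste(".y ~", if (length(red)) paste(red, collapse = " + ") else "1"))
    fit_r <- suppressWarnings(
      stats::glm(fml_r, family = stats::binomial(), data = df,
                 control = stats::glm.control(epsilon = epsilon, maxit = 100L)))
    chisq <- max(0, 2 * (ll_full - as.numeric(stats::logLik(fit_r))))
    data.frame(term = tm, lr_chisq = chisq, df = 1L,
               p_value = stats::pchisq(chisq, 1L, lower.tail = FALSE))
  }))
  structure(
    list(intercept = unname(cf[1]), coefficients = cf[-1],
         log_lik = ll_full, n = nrow(df), lr_tests = lr, fit = fit),
    class = "logistic_fit")
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fixed-effects one-way analysis of variance of a continuous measurement
#' (e.g. snout-vent length) across groups (e.g. courtship pattern
#' classes), followed by Tukey's honest-significant-difference test on
#' all group pairs using the studentized-range distribution. Unequal
#' group sizes use the Tukey-Kramer generalization (the default of
#' [stats::TukeyHSD()]).
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values`; >= 2 groups with
#'   >= 2 values each.
#' @param alpha Level used only for the `significant` flags (default
#'   0.05).
#' @return A list: `F`, `df1`, `df2`, `p_value`, and `tukey` (data.frame
#'   with `pair`, `diff`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  if (length(values) != length(groups))
    stop_validation("values and groups must have equal length")
  g <- factor(groups)
  tab <- table(g)
  if (length(tab) < 2L) stop_validation("need at least 2 groups")
  if (any(tab < 2L))
    stop_validation("every group needs >= 2 values; counts: ",
                    paste(names(tab), tab, sep = "=", collapse = ", "))
  if (all(tapply(values, g, stats::var) == 0))
    stop_validation("no within-group variance in any group")
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
                      p_adj = hsd[, "p adj"],
                      significant = hsd[, "p adj"] <= alpha,
                      row.names = NULL)
  list(F = s[1, "F value"], df1 = s[1, "Df"], df2 = s[2, "Df"],
       p_value = s[1, "Pr(>F)"], tukey = tukey)
}
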