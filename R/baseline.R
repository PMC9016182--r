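#' Yates-corrected chi-square test for a 2x2 table
#'
#' Pearson chi-square with continuity correction,
#' `N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2)` (correction floored at zero), with
#' the p-value from the chi-square distribution on 1 df. Backed by
#' [stats::chisq.test()] with `correct = TRUE`. The statistic is invariant to
#' transposing the table and to swapping rows or columns.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `statistic` and `p`.
#' @examples
#' chisq_2x2_yates(matrix(c(38, 136, 48, 55), 2)) # smoking x case status
#' @export
chisq_2x2_yates <- function(table) {
  check_that(is.matrix(table) && all(dim(table) == 2), "table must be 2x2")
  check_that(all(table >= 0) && all(table == round(table)), "counts must be non-negative integers")
  check_that(sum(table) > 0, "table total must be positive")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal total: the chi-square statistic is undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Two-group summary with a pooled-variance t test
#'
#' Per-group mean and SD of a continuous variable plus a two-sample
#' pooled-variance t statistic and two-sided p-value (the conventional
#' location test for baseline-characteristics tables).
#'
#' @param values numeric vector.
#' @param groups binary 0/1 vector of group labels (1 = case).
#' @return list with `summary` (2 x 3 matrix: n, mean, sd per group),
#'   `statistic` and `p`.
#' @export
group_summary <- function(values, groups) {
  check_that(is.numeric(values) && !anyNA(values), "values must be numeric without NAs")
  check_that(is_binary01(groups) && length(groups) == length(values),
             "groups must be a 0/1 vector aligned with values")
  g0 <- values[groups == 0]; g1 <- values[groups == 1]
  check_that(length(g0) >= 2 && length(g1) >= 2, "each group needs at least 2 observations")
  smry <- rbind(control = c(n = length(g0), mean = mean(g0), sd = stats::sd(g0)),
                case = c(n = length(g1), mean = mean(g1), sd = stats::sd(g1)))
  if (stats::sd(values) == 0) {
    return(list(summary = smry, statistic = 0, p = 1))
  }
  tt <- stats::t.test(g0, g1, var.equal = TRUE)
  list(summary = smry, statistic = unname(tt$statistic), p = unname(tt$p.value))
}

#' Adjusted exposure-outcome logistic regression
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' exposure and confounders (IRLS via [stats::glm()], deviance tolerance
#' 1e-8, at most 100 iterations), with Wald standard errors, odds ratios and
#' 95% Wald confidence intervals on the OR scale. Non-convergence or
#' quasi-separation is flagged with a warning rather than an error; rank
#' deficiency is an error naming the collinear columns.
#'
#' @param data a [cohort_data()].
#' @param formula_terms ordered names of regressors among `"X"` and the
#'   columns of `data$C`; default uses the exposure and all confounders.
#' @return an object of class `logistic_fit`: coefficients, standard errors,
#'   odds ratios with 95% CI, p-values, `n_used`, `converged`,
#'   `se_reliable`.
#' @export
fit_logistic <- function(data, formula_terms = NULL) {
  check_that(inherits(data, "cohort_data"), "data must be a cohort_data")
  if (is.null(formula_terms)) formula_terms <- c("X", colnames(data$C))
  df <- data.frame(Y = data$Y, X = data$X, data$C, check.names = FALSE)
  missing_terms <- setdiff(formula_terms, names(df))
  check_that(!length(missing_terms),
             paste("unknown formula terms:", paste(missing_terms, collapse = ", ")))
  mm <- cbind(`(Intercept)` = 1, as.matrix(df[, formula_terms, drop = FALSE]))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(sprintf("`%s`", formula_terms), response = "Y")
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  co <- summary(fit)$coefficients
  est <- co[, 1]; se <- co[, 2]
  separated <- any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  se_reliable <- fit$converged && !separated
  if (!se_reliable) {
    warning("logistic fit did not converge cleanly (possible separation); standard errors unreliable")
  }
  structure(
    list(coefficients = est, standard_errors = se,
         odds_ratios = exp(est),
         ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
         p_values = co[, 4], n_used = stats::nobs(fit),
         converged = fit$converged, se_reliable = se_reliable, glm = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  tab <- data.frame(
    estimate = x$coefficients, se = x$standard_errors,
    OR = x$odds_ratios, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_values
  )
  cat("Logistic regression (n =", x$n_used, ")",
      if (!x$se_reliable) "[WARNING: unreliable SEs]" else "", "\n")
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' Baseline characteristics table (Table-1 schema)
#'
#' Group summaries for each confounder (continuous variables by
#' [group_summary()], binary variables by [chisq_2x2_yates()]) plus the
#' exposure, by case status.
#'
#' @param data a [cohort_data()].
#' @return data.frame with columns variable, control, case, statistic, p.
#' @export
baseline_table1 <- function(data) {
  check_that(inherits(data, "cohort_data"), "data must be a cohort_data")
  fmt_ms <- function(m, s) sprintf("%.3f (+/-%.3f)", m, s)
  fmt_np <- function(k, n) sprintf("%d (%.3f)", k, k / n)
  rows <- list()
  vars <- cbind(smoking = data$X, data$C)
  for (v in colnames(vars)) {
    x <- vars[, v]
    if (all(x %in% c(0, 1))) {
      tab <- table(factor(x, levels = c(1, 0)), factor(data$Y, levels = c(0, 1)))
      ct <- chisq_2x2_yates(matrix(as.numeric(tab), 2))
      n0 <- sum(data$Y == 0); n1 <- sum(data$Y == 1)
      rows[[v]] <- data.frame(variable = v,
                              control = fmt_np(sum(x == 1 & data$Y == 0), n0),
                              case = fmt_np(sum(x == 1 & data$Y == 1), n1),
                              statistic = ct$statistic, p = ct$p)
    } else {
      gs <- group_summary(x, data$Y)
      rows[[v]] <- data.frame(variable = v,
                              control = fmt_ms(gs$summary["control", "mean"], gs$summary["control", "sd"]),
                              case = fmt_ms(gs$summary["case", "mean"], gs$summary["case", "sd"]),
                              statistic = gs$statistic, p = gs$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted association table (Table-2 schema)
#'
#' One row per regressor of the adjusted exposure-outcome logistic model:
#' estimate, SE, OR with 95% CI, p.
#'
#' @param fit a [fit_logistic()] result.
#' @return data.frame.
#' @export
baseline_table2 <- function(fit) {
  check_that(inherits(fit, "logistic_fit"), "fit must be a logistic_fit")
  data.frame(
    variable = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$standard_errors),
    or = unname(fit$odds_ratios),
    ci_low = unname(fit$ci_low),
    ci_high = unname(fit$ci_high),
    p = unname(fit$p_values)
  )
}
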