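# De-sparsified LASSO inference for the logistic outcome model.
#
# Notation: rho is the per-observation logistic negative log-likelihood,
# Pn g = (1/n) sum_i g(y_i, x_i). The LASSO estimator is
#   beta_hat = argmin Pn rho_beta + lambda * ||beta_penalized||_1,
# Sigma_hat = Pn rho''_betahat = X' W X / n with W = diag(p(1-p)),
# Theta_hat is the nodewise-LASSO relaxed inverse of Sigma_hat, and the
# de-sparsified estimator is b_hat = beta_hat - Theta_hat * Pn rho'_betahat,
# whose entries are asymptotically normal with variance
# diag(Theta_hat Sigma_hat Theta_hat') / n.

# mean logistic negative log-likelihood at linear predictor eta
mean_nll <- function(eta, y) mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)

# design with explicit intercept column
add_intercept <- function(design) {
  check_that(is.matrix(design) && is.numeric(design), "design must be a numeric matrix")
  check_that(ncol(design) == 0 || !is.null(colnames(design)),
             "design must have column names")
  cbind(`(Intercept)` = 1, design)
}

#' L1-penalized logistic regression with a penalization mask
#'
#' Solves `argmin Pn rho_beta + lambda * ||beta_penalized||_1` for the
#' logistic loss `rho`, where only the columns flagged by `penalized_mask`
#' are penalized; the intercept (added internally) and unmasked columns
#' (exposure, confounders) are left unpenalized. Solved by coordinate
#' descent ([glmnet::glmnet()] with per-column penalty factors and the
#' penalty rescaled to keep the stated objective); `lambda = 0` reduces to
#' the unpenalized MLE. The Karush-Kuhn-Tucker conditions are verified at
#' the solution: `|score_j| <= lambda + 1e-6` for zero penalized
#' coefficients (a violation warns with diagnostics).
#'
#' @param Y binary 0/1 response.
#' @param design numeric model matrix without intercept, named columns;
#'   penalized columns should be standardized.
#' @param lambda penalty weight (>= 0) on the mean-loss scale.
#' @param penalized_mask logical vector over `design` columns; `TRUE` =
#'   penalized. Default penalizes everything.
#' @return object of class `penalized_fit`: `beta_hat` (named, with
#'   intercept), `lambda`, `penalized_mask`, `objective_value`, `fitted`,
#'   `score` (Pn rho' at the solution), `kkt_ok`.
#' @export
lasso_logistic <- function(Y, design, lambda, penalized_mask = rep(TRUE, ncol(design))) {
  check_that(is_binary01(Y), "Y must be binary 0/1")
  check_that(is.numeric(lambda) && length(lambda) == 1 && lambda >= 0, "lambda must be >= 0")
  check_that(length(penalized_mask) == ncol(design), "penalized_mask must match design columns")
  X <- add_intercept(design)
  n <- nrow(X)
  check_that(length(Y) == n, "Y and design must have the same number of rows")

  lam_max <- if (any(penalized_mask)) lambda_max_penalized(Y, design, penalized_mask) else 0
  if (lambda == 0 || !any(penalized_mask) || lambda >= lam_max) {
    # exact solution: at lambda >= lambda_max all penalized coefficients are
    # zero and the rest solve the unpenalized subproblem; at lambda = 0 the
    # whole problem is the MLE
    free <- if (lambda == 0) rep(TRUE, ncol(design)) else !penalized_mask
    X0 <- add_intercept(design[, free, drop = FALSE])
    fit <- suppressWarnings(stats::glm.fit(X0, Y, family = stats::binomial(),
                                           control = list(epsilon = 1e-12, maxit = 200)))
    if (!fit$converged) stop("unpenalized logistic fit did not converge", call. = FALSE)
    beta <- stats::setNames(numeric(ncol(X)), colnames(X))
    beta[c(TRUE, free)] <- fit$coefficients
  } else {
    pf <- as.numeric(penalized_mask)
    xg <- design
    if (ncol(xg) == 1) { # glmnet needs >= 2 columns; pad with an inert zero
      xg <- cbind(xg, `..pad..` = 0)
      pf <- c(pf, 1)
    }
    # glmnet rescales penalty factors to sum to nvars; compensate so the
    # objective keeps a common lambda on the penalized set
    lam_gn <- lambda * sum(pf) / ncol(xg)
    lam_path <- lambda_path(max(lam_max, lambda * 1.01), lambda, n_lambda = 30)
    gfit <- glmnet::glmnet(xg, Y, family = "binomial",
                           lambda = lam_path * sum(pf) / ncol(xg),
                           penalty.factor = pf, standardize = FALSE,
                           thresh = 1e-12, maxit = 1e7)
    co <- as.numeric(stats::coef(gfit, s = lam_gn, exact = FALSE))
    beta <- stats::setNames(co[seq_len(ncol(design) + 1)],
                            c("(Intercept)", colnames(design)))
  }

  eta <- drop(X %*% beta)
  prob <- stats::plogis(eta)
  score <- drop(crossprod(X, prob - Y)) / n
  mask_full <- c(FALSE, penalized_mask) # intercept never penalized
  obj <- mean_nll(eta, Y) + lambda * sum(abs(beta[mask_full]))

  zero_pen <- mask_full & abs(beta) < 1e-12
  kkt_ok <- all(abs(score[zero_pen]) <= lambda + 1e-6)
  if (!kkt_ok) {
    warning(sprintf("KKT violation at the LASSO solution: max |score| on the zero set = %.3g > lambda + 1e-6 = %.3g",
                    max(abs(score[zero_pen])), lambda + 1e-6))
  }
  structure(
    list(beta_hat = beta, lambda = lambda, penalized_mask = penalized_mask,
         objective_value = obj, fitted = prob, score = score, kkt_ok = kkt_ok,
         Y = Y, design = design),
    class = "penalized_fit"
  )
}

#' @export
print.penalized_fit <- function(x, ...) {
  nz <- sum(abs(x$beta_hat[c(FALSE, x$penalized_mask)]) > 1e-12)
  cat("L1-penalized logistic fit: lambda =", signif(x$lambda, 4), "|",
      nz, "of", sum(x$penalized_mask), "penalized coefficients nonzero |",
      "objective =", signif(x$objective_value, 6), "\n")
  invisible(x)
}

# smallest lambda with all penalized coefficients zero: the max absolute
# score on the penalized set at the fit using only unpenalized columns
lambda_max_penalized <- function(Y, design, penalized_mask) {
  X0 <- add_intercept(design[, !penalized_mask, drop = FALSE])
  fit0 <- suppressWarnings(stats::glm.fit(X0, Y, family = stats::binomial()))
  p0 <- fit0$fitted.values
  n <- length(Y)
  max(abs(drop(crossprod(design[, penalized_mask, drop = FALSE], Y - p0)) / n))
}

lambda_path <- function(lam_max, lam_min = NULL, n_lambda = 50, decades = 4) {
  if (is.null(lam_min)) lam_min <- lam_max * 10^(-decades)
  exp(seq(log(lam_max), log(lam_min), length.out = n_lambda))
}

#' Cross-validated penalty selection
#'
#' Selects `lambda` by `n_folds`-fold cross-validated binomial deviance over
#' a 50-point log-spaced path from `lambda_max` (the smallest penalty with
#' all penalized coefficients zero) downward, with seeded fold assignment
#' ([glmnet::cv.glmnet()] under the hood). The path spans four decades when
#' the sample comfortably exceeds the number of penalized columns and two
#' decades otherwise (the usual convention for p close to or above n, where
#' the near-unpenalized end of a longer path is a separation regime that
#' adds cost but never wins cross-validation).
#'
#' @inheritParams lasso_logistic
#' @param n_folds number of CV folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @param n_lambda,decades path resolution and extent (`decades = NULL` for
#'   the adaptive default).
#' @return the selected `lambda` (mean-loss scale); attributes `path` and
#'   `cvm` carry the path and mean CV deviance for diagnostics.
#' @export
select_lambda <- function(Y, design, penalized_mask = rep(TRUE, ncol(design)),
                          n_folds = 10, seed = 1, n_lambda = 50, decades = NULL) {
  check_that(is_count(n_folds) && n_folds >= 2, "n_folds must be >= 2")
  n <- nrow(design)
  pf <- as.numeric(penalized_mask)
  if (is.null(decades)) decades <- if (n > 5 * ncol(design)) 4 else 2
  lam_max <- lambda_max_penalized(Y, design, penalized_mask)
  path <- lambda_path(lam_max, n_lambda = n_lambda, decades = decades)
  foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  cv <- glmnet::cv.glmnet(design, Y, family = "binomial",
                          lambda = path * sum(pf) / ncol(design),
                          penalty.factor = pf, standardize = FALSE,
                          foldid = foldid, type.measure = "deviance",
                          maxit = 1e6)
  sel <- cv$lambda[which.min(cv$cvm)] * ncol(design) / sum(pf)
  structure(sel, path = path, cvm = cv$cvm)
}

#' Weighted Gram matrix of the logistic fit
#'
#' `Sigma_hat = Pn rho''_betahat = X' W X / n`, the average observed
#' information at the penalized solution, with `W = diag(p(1-p))` and `X`
#' the design including the intercept.
#'
#' @param fit a [lasso_logistic()] result.
#' @return list with `sigma` (symmetric PSD matrix) and `design_w`
#'   (`sqrt(W) X`, the weighted design rows used for nodewise regressions).
#' @export
sigma_hat <- function(fit) {
  check_that(inherits(fit, "penalized_fit"), "fit must be a penalized_fit")
  X <- add_intercept(fit$design)
  w <- fit$fitted * (1 - fit$fitted)
  Xw <- X * sqrt(w)
  sig <- crossprod(Xw) / nrow(X)
  list(sigma = sig, design_w = Xw)
}

# covariance-space coordinate descent for one nodewise lasso:
# argmin_gamma (Sjj - 2 gamma' s + gamma' S gamma)/2 + lambda ||gamma||_1
nodewise_cd <- function(S, j, lambda, max_iter = 1000, tol = 1e-10) {
  p <- ncol(S)
  idx <- setdiff(seq_len(p), j)
  Sm <- S[idx, idx, drop = FALSE]
  s <- S[idx, j]
  m <- length(idx)
  gamma <- numeric(m)
  dS <- diag(Sm)
  q <- numeric(m) # running Sm %*% gamma, updated only when a coordinate moves
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_len(m)) {
      if (dS[k] < .Machine$double.eps) next
      r <- s[k] - q[k] + dS[k] * gamma[k]
      new <- sign(r) * max(abs(r) - lambda, 0) / dS[k]
      step <- new - gamma[k]
      if (step != 0) {
        q <- q + Sm[, k] * step
        delta <- max(delta, abs(step))
        gamma[k] <- new
      }
    }
    if (delta < tol) break
  }
  gamma
}

#' Nodewise LASSO relaxed inverse of the weighted Gram matrix
#'
#' Builds `Theta_hat` row by row: column `j` of the weighted design is
#' regressed on the others with an L1 penalty (solved in covariance space
#' from `Sigma_hat` directly), the nodewise residual variance is
#' `tau2_j = Sigma_jj - Sigma_(j,-j) gamma_j`, and row `j` of `Theta_hat` is
#' `(e_j - gamma-padded) / tau2_j`. With zero node penalties and a
#' well-conditioned `Sigma_hat` this reproduces the matrix inverse; in
#' general `Theta_hat Sigma_hat` is close to the identity with off-diagonal
#' entries bounded by `lambda_j / tau2_j`.
#'
#' Per-node penalties are taken from `lambdas_node` when supplied; otherwise
#' they are tied across nodes through a common cross-validated rate: the
#' Gaussian nodewise regression is cross-validated ([glmnet::cv.glmnet()],
#' `n_folds` folds, seeded) on `cv_nodes` nodes spread over the design, the
#' per-node selected penalties are reduced to the median of
#' `lambda_k / sqrt(Sigma_kk)`, and every node then gets
#' `lambda_j = rate * sqrt(Sigma_jj)` (the nodewise noise scale). Tying the
#' rate keeps the selection rule while avoiding one cross-validation per
#' column.
#'
#' @param sigma symmetric PSD matrix `Sigma_hat` (see [sigma_hat()]).
#' @param lambdas_node optional numeric vector (length `ncol(sigma)` or 1)
#'   of node penalties.
#' @param design_w weighted design rows (`sqrt(W) X`); required when
#'   `lambdas_node` is `NULL`.
#' @param n_folds,n_lambda CV control for the node-penalty rate.
#' @param cv_nodes number of nodes on which the rate is cross-validated.
#' @param seed integer seed for CV fold assignment.
#' @return list of class `nodewise_theta`: `theta` (matrix), `tau2`,
#'   `lambdas_node`.
#' @export
nodewise_theta <- function(sigma, lambdas_node = NULL, design_w = NULL,
                           n_folds = 5, n_lambda = 25, cv_nodes = 5, seed = 1) {
  check_that(is.matrix(sigma) && nrow(sigma) == ncol(sigma), "sigma must be square")
  check_that(max(abs(sigma - t(sigma))) < 1e-8, "sigma must be symmetric")
  p <- ncol(sigma)
  if (is.null(lambdas_node)) {
    check_that(!is.null(design_w), "design_w is required to select node penalties by CV")
    n <- nrow(design_w)
    foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
    nodes <- unique(round(seq(1, p, length.out = min(cv_nodes, p))))
    rates <- vapply(nodes, function(j) {
      y <- design_w[, j]
      x <- design_w[, -j, drop = FALSE]
      lmax <- max(abs(crossprod(x, y))) / n # no intercept in nodewise fits
      path <- lambda_path(lmax, n_lambda = n_lambda, decades = 3)
      cv <- glmnet::cv.glmnet(x, y, family = "gaussian", lambda = path,
                              standardize = FALSE, intercept = FALSE,
                              foldid = foldid)
      cv$lambda[which.min(cv$cvm)] / sqrt(sigma[j, j])
    }, numeric(1))
    lambdas_node <- stats::median(rates) * sqrt(diag(sigma))
  } else {
    lambdas_node <- rep_len(lambdas_node, p)
  }
  theta <- matrix(0, p, p, dimnames = dimnames(sigma))
  tau2 <- numeric(p)
  for (j in seq_len(p)) {
    gamma <- nodewise_cd(sigma, j, lambdas_node[j])
    tau2[j] <- sigma[j, j] - sum(sigma[j, -j] * gamma)
    if (tau2[j] <= 1e-12) {
      stop(sprintf("nodewise residual variance tau2[%d] <= 1e-12; Sigma_hat is degenerate", j),
           call. = FALSE)
    }
    row <- numeric(p)
    row[j] <- 1
    row[-j] <- -gamma
    theta[j, ] <- row / tau2[j]
  }
  structure(list(theta = theta, tau2 = tau2, lambdas_node = lambdas_node),
            class = "nodewise_theta")
}

#' De-sparsified LASSO estimates with FDR selection
#'
#' Bias-corrects the penalized coefficients,
#' `b_hat = beta_hat - Theta_hat * Pn rho'_betahat`, attaches asymptotic
#' standard errors `sqrt(diag(Theta_hat Sigma_hat Theta_hat') / n)`,
#' two-sided normal p-values, and Benjamini-Hochberg adjusted p-values over
#' the penalized (mediator) coefficients; `selected` is the set with
#' `p_fdr < q`.
#'
#' @param fit a [lasso_logistic()] result.
#' @param theta a [nodewise_theta()] result built from the same fit's
#'   `Sigma_hat`.
#' @param q FDR level (default 0.05, strict inequality at the threshold).
#' @return object of class `desparsified_result` with `b_hat`, `se`,
#'   `p_raw`, `p_fdr` (NA for unpenalized coefficients), `selected`
#'   (character), `sigma_hat_summary`, `theta_diag`, `q`.
#' @export
desparsify <- function(fit, theta, q = 0.05) {
  check_that(inherits(fit, "penalized_fit"), "fit must be a penalized_fit")
  check_that(inherits(theta, "nodewise_theta"), "theta must be a nodewise_theta")
  check_that(is_prob(q) && q > 0 && q < 1, "q must lie in (0, 1)")
  sh <- sigma_hat(fit)
  Th <- theta$theta
  check_that(ncol(Th) == length(fit$beta_hat), "theta and fit dimensions differ")
  n <- length(fit$Y)
  b_hat <- fit$beta_hat - drop(Th %*% fit$score)
  avar <- Th %*% sh$sigma %*% t(Th)
  se <- sqrt(pmax(diag(avar), 0) / n)
  p_raw <- ifelse(se > 0, pnorm2(b_hat, se), 1)
  p_raw[abs(b_hat) < 1e-300 & se == 0] <- 1
  mask_full <- c(FALSE, fit$penalized_mask)
  p_fdr <- rep(NA_real_, length(p_raw))
  adj <- bh_fdr(p_raw[mask_full], q = q)
  p_fdr[mask_full] <- adj$p_adjusted
  names(b_hat) <- names(se) <- names(p_raw) <- names(p_fdr) <- names(fit$beta_hat)
  selected <- names(b_hat)[mask_full][adj$selected]
  structure(
    list(b_hat = b_hat, se = se, p_raw = p_raw, p_fdr = p_fdr,
         selected = selected, q = q,
         sigma_hat_summary = c(min_diag = min(diag(sh$sigma)),
                               max_diag = max(diag(sh$sigma))),
         theta_diag = diag(Th), penalized_mask = mask_full),
    class = "desparsified_result"
  )
}

#' @export
print.desparsified_result <- function(x, ...) {
  cat("De-sparsified LASSO inference:", sum(x$penalized_mask), "penalized coefficients,",
      length(x$selected), "selected at FDR <", x$q, "\n")
  if (length(x$selected)) cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.desparsified_result <- function(object, ...) object$b_hat

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjusted p-values (monotone-enforced, via
#' [stats::p.adjust()]); selected = adjusted strictly below `q`.
#'
#' @param p_raw vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `p_adjusted` and `selected` (integer indices).
#' @export
bh_fdr <- function(p_raw, q = 0.05) {
  check_that(is_prob(p_raw), "p_raw must be probabilities")
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  list(p_adjusted = p_adj, selected = which(p_adj < q))
}

#' De-sparsified LASSO stage on a screened mediator set
#'
#' Assembles the design `[X, retained mediators, C]` (mediators penalized;
#' intercept, exposure and confounders unpenalized), selects `lambda` by
#' cross-validation unless given, fits the penalized model, builds the
#' nodewise relaxed inverse, and returns de-sparsified inference plus a
#' candidate table.
#'
#' @param data a [cohort_data()].
#' @param m a standardized-M [meth_matrix()].
#' @param screening a [screen_mediators()] result (or NULL to use all probes).
#' @param lambda optional penalty; `NULL` selects by CV.
#' @param q FDR level.
#' @param seed seed for CV folds.
#' @param n_folds CV folds for lambda selection.
#' @param nodewise_folds,nodewise_lambda CV folds for node penalties, or
#'   fixed node penalties.
#' @return object of class `dlasso_fit`: the `desparsified_result`, the
#'   `penalized_fit`, `lambda`, and `table` (probe_id, estimate, se, ci_low,
#'   ci_high, p_raw, p_fdr, selected).
#' @export
dlasso <- function(data, m, screening = NULL, lambda = NULL, q = 0.05, seed = 1,
                   n_folds = 10, nodewise_folds = 5, nodewise_lambda = NULL) {
  check_that(inherits(data, "cohort_data"), "data must be a cohort_data")
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  ids <- if (is.null(screening)) rownames(m$values) else screening$retained_ids
  Mr <- t(m$values[ids, , drop = FALSE])
  design <- cbind(X = data$X, Mr, data$C)
  penalized <- c(FALSE, rep(TRUE, ncol(Mr)), rep(FALSE, ncol(data$C)))
  if (is.null(lambda)) {
    lambda <- select_lambda(data$Y, design, penalized, n_folds = n_folds, seed = seed)
  }
  fit <- lasso_logistic(data$Y, design, lambda = as.numeric(lambda),
                        penalized_mask = penalized)
  sh <- sigma_hat(fit)
  th <- nodewise_theta(sh$sigma, lambdas_node = nodewise_lambda,
                       design_w = sh$design_w, n_folds = nodewise_folds,
                       seed = seed + 1L)
  res <- desparsify(fit, th, q = q)
  med <- res$penalized_mask
  tab <- data.frame(
    probe_id = names(res$b_hat)[med],
    estimate = unname(res$b_hat[med]),
    se = unname(res$se[med]),
    ci_low = unname(res$b_hat[med] - 1.96 * res$se[med]),
    ci_high = unname(res$b_hat[med] + 1.96 * res$se[med]),
    p_raw = unname(res$p_raw[med]),
    p_fdr = unname(res$p_fdr[med]),
    selected = as.integer(names(res$b_hat)[med] %in% res$selected)
  )
  structure(list(result = res, fit = fit, lambda = as.numeric(lambda),
                 table = tab, selected = res$selected),
            class = "dlasso_fit")
}

#' @export
print.dlasso_fit <- function(x, ...) {
  cat("De-sparsified LASSO stage: lambda =", signif(x$lambda, 4), "\n")
  print(x$result)
  invisible(x)
}
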