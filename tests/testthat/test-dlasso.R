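# shared small logistic design for solver tests
dl_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(51)
      n <- 400; p <- 6
      X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
      y <- rbinom(n, 1, plogis(-0.3 + X %*% c(0.8, -0.5, 0.3, 0, 0, 0)))
      cache <<- list(X = X, y = y, n = n, p = p)
    }
    cache
  }
})

test_that("penalized solution matches an independent proximal-gradient oracle", {
  fx <- dl_fixture()
  lam <- 0.05
  pen <- rep(TRUE, fx$p)
  fit <- lasso_logistic(fx$y, fx$X, lambda = lam, penalized_mask = pen)

  # oracle: ISTA on the same objective, intercept unpenalized
  Xi <- cbind(1, fx$X)
  maskf <- c(FALSE, pen)
  b <- rep(0, fx$p + 1)
  L <- max(eigen(crossprod(Xi) / fx$n)$values) / 4
  for (it in 1:20000) {
    pr <- plogis(drop(Xi %*% b))
    g <- drop(crossprod(Xi, pr - fx$y)) / fx$n
    b <- b - g / L
    b[maskf] <- sign(b[maskf]) * pmax(abs(b[maskf]) - lam / L, 0)
  }
  obj_oracle <- mean(log(1 + exp(Xi %*% b)) - fx$y * (Xi %*% b)) + lam * sum(abs(b[maskf]))
  expect_equal(unname(fit$beta_hat), unname(b), tolerance = 1e-6)
  expect_equal(fit$objective_value, obj_oracle, tolerance = 1e-8)
  expect_true(fit$kkt_ok)

  # KKT: active penalized coordinates sit at the penalty boundary
  act <- c(FALSE, pen) & abs(fit$beta_hat) > 1e-8
  expect_lt(max(abs(abs(fit$score[act]) - lam)), 1e-4)
  # unpenalized coordinates have (near) zero score
  expect_lt(max(abs(fit$score[!c(FALSE, pen)])), 1e-6)
})

test_that("lambda = 0 reduces to the MLE and lambda >= lambda_max kills the penalized set", {
  fx <- dl_fixture()
  pen <- rep(TRUE, fx$p)
  f0 <- lasso_logistic(fx$y, fx$X, lambda = 0, penalized_mask = pen)
  g <- glm(fx$y ~ fx$X, family = binomial)
  expect_equal(unname(f0$beta_hat), unname(coef(g)), tolerance = 1e-5)

  lmax <- hdmethmediate:::lambda_max_penalized(fx$y, fx$X, pen)
  fmax <- lasso_logistic(fx$y, fx$X, lambda = lmax * 1.0001, penalized_mask = pen)
  expect_true(all(abs(fmax$beta_hat[c(FALSE, pen)]) < 1e-10))
})

test_that("duplicated columns give an equal-objective (non-unique) solution", {
  fx <- dl_fixture()
  lam <- 0.05
  Xd <- cbind(fx$X, V1b = fx$X[, 1])
  fd <- lasso_logistic(fx$y, Xd, lambda = lam, penalized_mask = rep(TRUE, fx$p + 1))
  f1 <- lasso_logistic(fx$y, fx$X, lambda = lam, penalized_mask = rep(TRUE, fx$p))
  expect_equal(fd$objective_value, f1$objective_value, tolerance = 1e-6)
})

test_that("cross-validated lambda selection is seeded and behaves at the extremes", {
  fx <- dl_fixture()
  pen <- rep(TRUE, fx$p)
  l1 <- select_lambda(fx$y, fx$X, pen, seed = 3)
  l2 <- select_lambda(fx$y, fx$X, pen, seed = 3)
  expect_identical(as.numeric(l1), as.numeric(l2))

  # pure-noise design: selected lambda leaves the model sparse
  sparse_hits <- vapply(1:20, function(s) {
    set.seed(900 + s)
    Xn <- matrix(rnorm(150 * 25), 150, 25, dimnames = list(NULL, paste0("N", 1:25)))
    yn <- rbinom(150, 1, 0.5)
    lam <- select_lambda(yn, Xn, n_folds = 5, seed = s)
    fit <- lasso_logistic(yn, Xn, as.numeric(lam))
    sum(abs(fit$beta_hat[-1]) > 1e-8) <= 3
  }, logical(1))
  expect_gte(mean(sparse_hits), 0.8)

  # strong single predictor survives selection
  strong_hits <- vapply(1:20, function(s) {
    set.seed(950 + s)
    Xs <- matrix(rnorm(200 * 10), 200, 10, dimnames = list(NULL, paste0("S", 1:10)))
    ys <- rbinom(200, 1, plogis(1.5 * Xs[, 1]))
    lam <- select_lambda(ys, Xs, n_folds = 5, seed = s)
    fit <- lasso_logistic(ys, Xs, as.numeric(lam))
    abs(fit$beta_hat["S1"]) > 1e-8
  }, logical(1))
  expect_gte(mean(strong_hits), 0.95)
})

test_that("nodewise construction reproduces the inverse in the classical limits", {
  # diagonal input: exact reciprocal diagonal
  d <- diag(c(2, 1, 0.5, 4))
  dimnames(d) <- list(paste0("a", 1:4), paste0("a", 1:4))
  th <- nodewise_theta(d, lambdas_node = 0.1)
  expect_equal(th$theta, diag(1 / diag(d)), ignore_attr = TRUE)

  # dense well-conditioned input with vanishing penalties: matrix inverse
  fx <- dl_fixture()
  fit <- lasso_logistic(fx$y, fx$X[, 1:4], lambda = 0.02,
                        penalized_mask = rep(TRUE, 4))
  S <- sigma_hat(fit)$sigma
  th2 <- nodewise_theta(S, lambdas_node = 1e-10)
  expect_equal(th2$theta, solve(S), tolerance = 1e-3)

  # KKT bound on the relaxed-inverse residual
  lamn <- 0.05
  th3 <- nodewise_theta(S, lambdas_node = lamn)
  R <- th3$theta %*% S - diag(ncol(S))
  for (j in seq_len(ncol(S))) {
    expect_lte(max(abs(R[j, -j])), lamn / th3$tau2[j] + 1e-8)
  }
  expect_error(nodewise_theta(matrix(0, 2, 2), lambdas_node = 0.1), "degenerate")
})

test_that("de-sparsified inference matches unpenalized Wald inference in low dimension", {
  fx <- dl_fixture()
  pen <- rep(TRUE, fx$p)
  fit <- lasso_logistic(fx$y, fx$X, lambda = 0.001, penalized_mask = pen)
  th <- nodewise_theta(sigma_hat(fit)$sigma, lambdas_node = 1e-8)
  ds <- desparsify(fit, th)
  g <- summary(glm(fx$y ~ fx$X, family = binomial))$coefficients
  expect_equal(unname(ds$b_hat), unname(g[, 1]), tolerance = 0.02)
  expect_equal(unname(ds$se), unname(g[, 2]), tolerance = 0.02)
  # p_fdr covers exactly the penalized set and dominates p_raw
  expect_true(all(is.na(ds$p_fdr[!ds$penalized_mask])))
  expect_true(all(ds$p_fdr[ds$penalized_mask] >= ds$p_raw[ds$penalized_mask] - 1e-12))
})

test_that("de-sparsified estimator equals the one-step Newton correction when theta is the inverse", {
  fx <- dl_fixture()
  pen <- rep(TRUE, fx$p)
  fit <- lasso_logistic(fx$y, fx$X, lambda = 0.08, penalized_mask = pen)
  sh <- sigma_hat(fit)
  th <- nodewise_theta(sh$sigma, lambdas_node = 0)
  ds <- desparsify(fit, th)
  newton <- fit$beta_hat - drop(solve(sh$sigma) %*% fit$score)
  expect_equal(unname(ds$b_hat), unname(newton), tolerance = 1e-6)
})

test_that("zero fit with zero score de-sparsifies to zero with p-values of one", {
  # crafted balanced data where the null fit has exactly zero score
  y <- c(0, 1, 0, 1)
  X <- cbind(v = c(1, 1, -1, -1))
  fit <- lasso_logistic(y, X, lambda = 1, penalized_mask = TRUE)
  expect_equal(unname(fit$beta_hat), c(0, 0))
  expect_equal(unname(fit$score), c(0, 0))
  th <- nodewise_theta(sigma_hat(fit)$sigma, lambdas_node = 0.01)
  ds <- desparsify(fit, th)
  expect_equal(unname(ds$b_hat), c(0, 0))
  expect_equal(unname(ds$p_raw), c(1, 1))
})

test_that("Benjamini-Hochberg adjustment follows the step-up computation", {
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)                       # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$p_adjusted, rep(0.04, 4))
  expect_length(bh_fdr(rep(1, 10))$selected, 0)
  res <- bh_fdr(c(0.001, 0.2, 0.04, 0.5), q = 0.05)
  expect_equal(res$p_adjusted, p.adjust(c(0.001, 0.2, 0.04, 0.5), "BH"))
  expect_identical(res$selected, which(res$p_adjusted < 0.05))
})

test_that("true mediators are recovered and signed correctly by the dlasso stage", {
  reps <- 6
  all4 <- logical(reps); signs_ok <- logical(reps)
  for (s in seq_len(reps)) {
    sd1 <- make_screening_data(n = 277, p = 150, n_true = 4, theta2 = 1, seed = 700 + s)
    scr <- screen_mediators(sd1$cohort, sd1$meth)
    dl <- dlasso(sd1$cohort, sd1$meth, scr, seed = s)
    sel <- dl$selected
    all4[s] <- all(sd1$true_ids %in% sel)
    est <- dl$table$estimate[match(intersect(sd1$true_ids, sel), dl$table$probe_id)]
    signs_ok[s] <- length(est) == 0 || all(sign(est) == 1)
  }
  expect_gte(mean(all4), 0.7)
  expect_gte(mean(signs_ok), 0.95)
})
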