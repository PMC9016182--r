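#' SIS retention count
#'
#' Number of mediators kept by sure independence screening,
#' `d = ceiling(2n / ln(n))` (natural log). At the motivating study's sample
#' size n = 277 this gives d = 99.
#'
#' @param n sample count (>= 3).
#' @return integer retention count.
#' @examples
#' retention_count(277) # 99
#' @export
retention_count <- function(n) {
  check_that(is_count(n) && n >= 3, "n must be an integer >= 3")
  as.integer(ceiling(2 * n / log(n)))
}

#' Marginal screening magnitudes
#'
#' For each probe `j`, fits the single-mediator logistic outcome model
#' `Y ~ intercept + X + M_j + C` and records the mediator coefficient as
#' `omega_j`. Screening is therefore confounder-adjusted rather than a raw
#' correlation; a marginal-correlation variant (`method = "correlation"`,
#' correlation of `M_j` with `Y`) is available for comparison. Probes whose
#' fit fails or does not converge get `omega_j = 0` with a warning.
#'
#' @param data a [cohort_data()].
#' @param m a [meth_matrix()] of standardized M-values whose samples match
#'   `data` in order (checked against sample counts and, when phenotype
#'   rownames are present, ids).
#' @param method `"coefficient"` (default, adjusted outcome-model
#'   coefficient) or `"correlation"`.
#' @return named numeric vector `omega` over probes.
#' @export
marginal_omega <- function(data, m, method = c("coefficient", "correlation")) {
  method <- match.arg(method)
  check_that(inherits(data, "cohort_data"), "data must be a cohort_data")
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(m$scale == "standardized-M", "screening expects standardized M-values")
  check_that(ncol(m$values) == data$n,
             "methylation samples and phenotype rows are misaligned")
  rn <- rownames(data$C)
  if (!is.null(rn) && !identical(rn, m$sample_ids)) {
    stop("sample ids of the methylation matrix do not match the phenotype table",
         call. = FALSE)
  }
  M <- m$values
  if (method == "correlation") {
    om <- apply(M, 1, function(mj) {
      if (stats::sd(mj) == 0) 0 else stats::cor(mj, data$Y)
    })
    return(stats::setNames(om, rownames(M)))
  }
  base <- cbind(`(Intercept)` = 1, X = data$X, data$C)
  k <- ncol(base)
  base_fit <- stats::glm.fit(base, data$Y, family = stats::binomial())
  start <- c(base_fit$coefficients, 0)
  om <- numeric(nrow(M))
  for (j in seq_len(nrow(M))) {
    mj <- M[j, ]
    if (stats::sd(mj) == 0) { om[j] <- 0; next }
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(base, mj), data$Y,
                                      family = stats::binomial(), start = start)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
      warning(sprintf("probe %s: single-mediator fit failed; omega set to 0",
                      rownames(M)[j]))
      om[j] <- 0
    } else {
      om[j] <- fit$coefficients[k + 1]
    }
  }
  stats::setNames(om, rownames(M))
}

#' Sure-independence screening of mediators
#'
#' Retains the indices of the `min(d, p)` largest `|omega|` values. Ties are
#' broken by ascending probe index; the result is ordered by descending
#' `|omega|`, then ascending index.
#'
#' @param omega numeric vector of screening magnitudes.
#' @param d retention count (>= 1).
#' @return integer vector of retained indices.
#' @export
sis_screen <- function(omega, d) {
  check_that(is.numeric(omega) && length(omega) >= 1, "omega must be a numeric vector")
  check_that(is_count(d) && d >= 1, "d must be a positive count")
  p <- length(omega)
  keep <- min(d, p)
  ord <- order(-abs(omega), seq_len(p))
  ord[seq_len(keep)]
}

#' Screen a methylation matrix by SIS
#'
#' Convenience wrapper: computes `omega` with [marginal_omega()],
#' `d = ceiling(2n / ln n)` (unless overridden) with [retention_count()], and
#' the retained set with [sis_screen()].
#'
#' @param data a [cohort_data()].
#' @param m a standardized-M [meth_matrix()].
#' @param d optional retention count override.
#' @param method passed to [marginal_omega()].
#' @return object of class `screening_result`: `omega`, `d`, `retained`
#'   (indices), `retained_ids`, `n`, `gamma` (= d/n, reporting only).
#' @export
screen_mediators <- function(data, m, d = NULL, method = "coefficient") {
  if (is.null(d)) d <- retention_count(data$n)
  omega <- marginal_omega(data, m, method = method)
  retained <- sis_screen(omega, d)
  structure(
    list(omega = omega, d = as.integer(d), retained = retained,
         retained_ids = names(omega)[retained], n = data$n, gamma = d / data$n),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("SIS screening: retained", length(x$retained), "of", length(x$omega),
      "probes (d =", x$d, ", n =", x$n, ")\n")
  cat("|omega| range of retained set: [",
      signif(min(abs(x$omega[x$retained])), 3), ",",
      signif(max(abs(x$omega[x$retained])), 3), "]\n")
  invisible(x)
}

#' Screening table (probe-level TSV schema)
#'
#' @param x a `screening_result`.
#' @return data.frame with probe_id, omega, abs_rank, retained.
#' @export
screening_table <- function(x) {
  check_that(inherits(x, "screening_result"), "x must be a screening_result")
  p <- length(x$omega)
  rank_abs <- integer(p)
  rank_abs[order(-abs(x$omega), seq_len(p))] <- seq_len(p)
  data.frame(
    probe_id = names(x$omega),
    omega = unname(x$omega),
    abs_rank = rank_abs,
    retained = as.integer(seq_len(p) %in% x$retained)
  )
}
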