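#' High-dimensional methylation mediation analysis
#'
#' The central model fit: given a cohort (binary outcome, binary exposure,
#' confounders) and a standardized M-value methylation matrix, runs the
#' three-stage mediator discovery and estimation procedure:
#'
#' 1. **Screening** — sure independence screening of the confounder-adjusted
#'    single-mediator outcome coefficients, keeping the top
#'    `d = ceiling(2n / ln n)` probes ([screen_mediators()]).
#' 2. **Selection** — de-sparsified LASSO inference on the logistic outcome
#'    model over the screened set, with Benjamini-Hochberg selection at FDR
#'    `q` ([dlasso()]).
#' 3. **Mediation** — per selected CpG, counterfactual ACME/ADE estimation
#'    with bootstrap intervals ([estimate_mediation()]) and a rho
#'    sensitivity analysis ([sensitivity_analysis()]).
#'
#' @param data a [cohort_data()].
#' @param m a standardized-M [meth_matrix()] aligned with `data`.
#' @param d SIS retention count; `NULL` uses `ceiling(2n / ln n)`.
#' @param q FDR level for candidate selection.
#' @param lambda LASSO penalty; `NULL` selects by cross-validation.
#' @param n_boot bootstrap resamples per mediation estimate.
#' @param n_draws Monte-Carlo draws for the mediator integral.
#' @param rho_grid sensitivity-parameter grid.
#' @param sens_boot bootstrap resamples for sensitivity bands.
#' @param seed integer seed governing all randomness (CV folds, bootstrap,
#'   mediator draws).
#' @param stages character subset of `c("mediation", "sensitivity")` to run
#'   after selection.
#' @return an object of class `hdmm` with elements `screening`, `dlasso`,
#'   `mediation` (list of [estimate_mediation()] results), `sensitivity`
#'   (list of [sensitivity_analysis()] results), `table` (candidate-level
#'   summary in the mediation-table schema) and `funnel` (named counts).
#' @seealso [simulate_cohort()] to generate test cohorts; [run_pipeline()]
#'   for the file-based end-to-end workflow.
#' @examples
#' \donttest{
#' sc <- simulate_cohort(sim_config(n_probes = 150, seed = 7))
#' pp <- preprocess_meth(sc$methylation)
#' M <- subset_probes(pp$meth, setdiff(rownames(pp$meth$values),
#'                                     rownames(sc$reference$profiles)))
#' fit <- hdmm(analysis_cohort(sc), M, n_boot = 200, n_draws = 200, seed = 7)
#' print(fit)
#' }
#' @export
hdmm <- function(data, m, d = NULL, q = 0.05, lambda = NULL,
                 n_boot = 1000, n_draws = 1000,
                 rho_grid = seq(-0.9, 0.9, by = 0.1), sens_boot = 200,
                 seed = 1, stages = c("mediation", "sensitivity")) {
  check_that(inherits(data, "cohort_data"), "data must be a cohort_data")
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(m$scale == "standardized-M",
             "hdmm expects standardized M-values; run preprocess_meth() first")
  stages <- match.arg(stages, several.ok = TRUE)

  scr <- screen_mediators(data, m, d = d)
  dl <- dlasso(data, m, scr, lambda = lambda, q = q, seed = seed)
  candidates <- dl$selected

  med <- list(); sens <- list()
  if ("mediation" %in% stages && length(candidates)) {
    for (i in seq_along(candidates)) {
      id <- candidates[i]
      mj <- m$values[id, ]
      med[[id]] <- estimate_mediation(data, mj, n_boot = n_boot,
                                      seed = seed + 100L + i, n_draws = n_draws)
      if ("sensitivity" %in% stages) {
        sens[[id]] <- sensitivity_analysis(data, mj, rho_grid = rho_grid,
                                           seed = seed + 200L + i,
                                           n_boot = sens_boot)
      }
    }
  }

  tab <- mediation_table(candidates, med, sens, m$annotation)
  n_sig <- if (length(med)) sum(vapply(med, function(e) e$p_acme < 0.05, logical(1))) else 0L
  funnel <- c(probes = length(scr$omega), screened = length(scr$retained),
              candidates = length(candidates), mediation_significant = n_sig)

  structure(list(screening = scr, dlasso = dl, mediation = med,
                 sensitivity = sens, table = tab, funnel = funnel,
                 q = q, seed = seed, call = match.call()),
            class = "hdmm")
}

# assemble the candidate-level mediation table (probe annotation optional)
mediation_table <- function(candidates, med, sens, annotation = NULL) {
  if (!length(candidates)) {
    return(data.frame(probe_id = character(), chrom = character(), pos = integer(),
                      nearest_gene = character(), gene_group = character(),
                      acme = numeric(), acme_ci_low = numeric(), acme_ci_high = numeric(),
                      acme_p = numeric(), ade = numeric(), ade_ci_low = numeric(),
                      ade_ci_high = numeric(), ade_p = numeric(),
                      log_or_acme = numeric(), rho_zero = numeric()))
  }
  ann <- function(id, field) {
    if (is.null(annotation)) return(NA)
    i <- match(id, annotation$probe_id)
    if (is.na(i)) NA else annotation[[field]][i]
  }
  rows <- lapply(candidates, function(id) {
    e <- med[[id]]; s <- sens[[id]]
    data.frame(
      probe_id = id,
      chrom = as.character(ann(id, "chrom")), pos = ann(id, "pos"),
      nearest_gene = as.character(ann(id, "nearest_gene")),
      gene_group = as.character(ann(id, "gene_group")),
      acme = if (is.null(e)) NA_real_ else e$acme,
      acme_ci_low = if (is.null(e)) NA_real_ else e$ci_acme[1],
      acme_ci_high = if (is.null(e)) NA_real_ else e$ci_acme[2],
      acme_p = if (is.null(e)) NA_real_ else e$p_acme,
      ade = if (is.null(e)) NA_real_ else e$ade,
      ade_ci_low = if (is.null(e)) NA_real_ else e$ci_ade[1],
      ade_ci_high = if (is.null(e)) NA_real_ else e$ci_ade[2],
      ade_p = if (is.null(e)) NA_real_ else e$p_ade,
      log_or_acme = if (is.null(e)) NA_real_ else e$log_or_acme,
      rho_zero = if (is.null(s)) NA_real_ else s$rho_zero
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.hdmm <- function(x, ...) {
  cat("High-dimensional methylation mediation fit\n")
  cat(sprintf("  %d probes -> SIS retained %d -> FDR(%g)-selected %d -> mediation-significant %d\n",
              x$funnel["probes"], x$funnel["screened"],
              x$q, x$funnel["candidates"], x$funnel["mediation_significant"]))
  if (length(x$dlasso$selected)) {
    cat("  Candidates:", paste(x$dlasso$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hdmm <- function(object, ...) {
  structure(list(funnel = object$funnel,
                 dlasso_table = object$dlasso$table,
                 mediation_table = object$table,
                 q = object$q),
            class = "summary.hdmm")
}

#' @export
print.summary.hdmm <- function(x, ...) {
  cat("Funnel:\n"); print(x$funnel)
  cat("\nDe-sparsified LASSO candidates (FDR <", x$q, "):\n")
  print(x$dlasso_table[x$dlasso_table$selected == 1, , drop = FALSE], row.names = FALSE)
  if (nrow(x$mediation_table)) {
    cat("\nMediation estimates:\n")
    print(x$mediation_table[, c("probe_id", "acme", "acme_ci_low", "acme_ci_high",
                                "acme_p", "ade", "ade_p", "rho_zero")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.hdmm <- function(object, ...) {
  res <- object$dlasso$result
  res$b_hat[res$penalized_mask]
}

#' Plot method for hdmm fits
#'
#' `type = "screening"` shows the ranked screening magnitudes with the
#' retention cutoff; `type = "sensitivity"` draws the ACME sensitivity
#' curves of all candidates.
#'
#' @param x an `hdmm` object.
#' @param type which panel to draw.
#' @param ... passed on to the underlying plot calls.
#' @export
plot.hdmm <- function(x, type = c("sensitivity", "screening"), ...) {
  type <- match.arg(type)
  if (type == "screening") {
    om <- sort(abs(x$screening$omega), decreasing = TRUE)
    graphics::plot(om, type = "h", xlab = "rank", ylab = "|omega|",
                   main = "SIS screening magnitudes", ...)
    graphics::abline(v = x$screening$d + 0.5, lty = 2)
  } else {
    if (!length(x$sensitivity)) {
      warning("no sensitivity curves in this fit")
      return(invisible(x))
    }
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(x$sensitivity)))
    on.exit(graphics::par(old))
    for (id in names(x$sensitivity)) plot(x$sensitivity[[id]], main = id, ...)
  }
  invisible(x)
}
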