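#' Detection-p-value probe filter
#'
#' Removes every probe whose detection p-value is `>= p_threshold` in any
#' sample (a conservative any-sample rule; the usual array default threshold
#' is 0.01). Probe order is preserved and the removed count is reported via
#' `message()` and the `"removed"` attribute.
#'
#' @param m a [meth_matrix()] carrying detection p-values.
#' @param p_threshold detection p-value threshold (probe fails at `>=`).
#' @return the filtered `meth_matrix`; `attr(, "removed")` holds the removed
#'   probe ids.
#' @export
filter_probes <- function(m, p_threshold = 0.01) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(!is.null(m$detection_p), "m carries no detection p-values")
  check_that(is_prob(p_threshold) && length(p_threshold) == 1, "p_threshold must be in [0, 1]")
  bad <- apply(m$detection_p >= p_threshold, 1, any)
  if (all(bad)) stop("all probes removed by the detection p-value filter", call. = FALSE)
  message(sprintf("filter_probes: removed %d of %d probes (detection p >= %g in any sample)",
                  sum(bad), length(bad), p_threshold))
  out <- subset_probes(m, which(!bad))
  attr(out, "removed") <- rownames(m$values)[bad]
  out
}

#' Mean-detection-p-value sample filter
#'
#' Removes samples whose mean detection p-value across probes is strictly
#' greater than `mean_p_threshold` (default 0.05; a sample at exactly the
#' threshold is retained).
#'
#' @param m a [meth_matrix()] carrying detection p-values.
#' @param mean_p_threshold threshold on the per-sample mean detection p.
#' @return the filtered `meth_matrix`; `attr(, "removed")` holds the removed
#'   sample ids.
#' @export
filter_samples <- function(m, mean_p_threshold = 0.05) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(!is.null(m$detection_p), "m carries no detection p-values")
  check_that(is_prob(mean_p_threshold) && length(mean_p_threshold) == 1,
             "mean_p_threshold must be in [0, 1]")
  bad <- colMeans(m$detection_p) > mean_p_threshold
  if (all(bad)) stop("all samples removed by the mean detection p-value filter", call. = FALSE)
  message(sprintf("filter_samples: removed %d of %d samples (mean detection p > %g)",
                  sum(bad), length(bad), mean_p_threshold))
  out <- subset_samples(m, which(!bad))
  attr(out, "removed") <- m$sample_ids[bad]
  out
}

#' Annotation-based probe filter
#'
#' Removes probes whose assayed sequence overlaps a common SNP
#' (`snp_overlap == 1`) and probes on the sex chromosomes (chrX / chrY).
#' Counts are tallied separately; a probe flagged for both reasons is counted
#' once, under the SNP rule.
#'
#' @param m a [meth_matrix()] with annotation.
#' @return the filtered `meth_matrix`; `attr(, "removed")` is a list with
#'   `snp` and `sex_chrom` probe ids.
#' @export
filter_annotation <- function(m) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(!is.null(m$annotation), "m carries no probe annotation")
  check_that("chrom" %in% names(m$annotation), "annotation is missing the chrom field")
  check_that("snp_overlap" %in% names(m$annotation), "annotation is missing the snp_overlap field")
  snp <- m$annotation$snp_overlap == 1
  sex <- m$annotation$chrom %in% c("chrX", "chrY", "X", "Y") & !snp
  message(sprintf("filter_annotation: removed %d SNP-overlap probes and %d chrX/chrY probes",
                  sum(snp), sum(sex)))
  keep <- which(!(snp | sex))
  if (!length(keep)) stop("all probes removed by the annotation filter", call. = FALSE)
  out <- subset_probes(m, keep)
  attr(out, "removed") <- list(snp = m$annotation$probe_id[snp],
                               sex_chrom = m$annotation$probe_id[sex])
  out
}

#' Quantile normalization across samples
#'
#' Maps every sample's empirical distribution onto the across-sample mean
#' quantile function, so sorted value vectors agree across samples while
#' within-sample ranks are preserved. Backed by [limma::normalizeQuantiles()].
#'
#' @param m a [meth_matrix()] on the beta scale with no missing values.
#' @return the normalized `meth_matrix` (beta scale).
#' @export
quantile_normalize <- function(m) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(m$scale == "beta", "quantile normalization expects beta-scale values")
  check_that(!anyNA(m$values), "missing values are not supported (imputation is out of scope)")
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  out <- m
  out$values <- v
  out
}

#' Beta-value to M-value conversion
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into `[eps, 1 - eps]`,
#' so boundary values stay finite. The inverse transform is [m_to_beta()].
#'
#' @param m a [meth_matrix()] on the beta scale.
#' @param eps clipping constant in (0, 0.5).
#' @return the `meth_matrix` on the M scale.
#' @export
beta_to_m <- function(m, eps = 1e-6) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(m$scale == "beta", "beta_to_m expects beta-scale values")
  check_that(is.numeric(eps) && length(eps) == 1 && eps > 0 && eps < 0.5,
             "eps must lie in (0, 0.5)")
  b <- pmin(pmax(m$values, eps), 1 - eps)
  out <- m
  out$values <- log2(b / (1 - b))
  out$scale <- "M"
  out
}

#' M-value to beta-value conversion
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m a [meth_matrix()] on the M scale.
#' @return the `meth_matrix` on the beta scale.
#' @export
m_to_beta <- function(m) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(m$scale == "M", "m_to_beta expects M-scale values")
  out <- m
  out$values <- 1 / (1 + 2^(-m$values))
  out$scale <- "beta"
  out
}

#' Per-probe standardization of M-values
#'
#' Centers and scales each probe row to sample mean 0 and SD 1 (denominator
#' n - 1), so downstream penalized coefficients share a common scale.
#' Constant rows cannot be scaled and are dropped with a warning.
#'
#' @param m a [meth_matrix()] on the M scale.
#' @return the `meth_matrix` on the standardized-M scale.
#' @export
standardize_probes <- function(m) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(m$scale %in% c("M", "standardized-M"),
             "standardize_probes expects (standardized-)M-scale values")
  sds <- apply(m$values, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sprintf("dropping %d constant probe row(s) that cannot be standardized", sum(const)))
  }
  if (all(const)) stop("all probes are constant; nothing to standardize", call. = FALSE)
  keep <- which(!const)
  out <- subset_probes(m, keep)
  v <- out$values
  v <- (v - rowMeans(v)) / apply(v, 1, stats::sd)
  out$values <- v
  out$scale <- "standardized-M"
  out
}

#' Reference-based cell-type deconvolution
#'
#' Estimates per-sample leukocyte proportions by non-negative least squares
#' of the sample's marker-probe beta values on the reference profiles
#' (constrained projection; negative solutions are truncated at zero by the
#' NNLS active-set solver, [pracma::lsqnonneg()]). Proportions are reported
#' unnormalized (they may sum below 1) together with a sum-to-one normalized
#' variant.
#'
#' @param m a [meth_matrix()] on the beta scale containing the reference's
#'   marker probes (at least half of them must be present).
#' @param ref a [celltype_reference()].
#' @return list with `proportions` and `proportions_normalized`
#'   (samples x cell-types matrices) and `residual_norm` (per-sample residual
#'   L2 norm).
#' @export
estimate_cell_proportions <- function(m, ref) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(inherits(ref, "celltype_reference"), "ref must be a celltype_reference")
  check_that(m$scale == "beta", "deconvolution expects beta-scale values")
  markers <- intersect(rownames(ref$profiles), rownames(m$values))
  if (length(markers) < 0.5 * nrow(ref$profiles)) {
    stop(sprintf("only %d of %d marker probes available (< 50%%)",
                 length(markers), nrow(ref$profiles)), call. = FALSE)
  }
  R <- ref$profiles[markers, , drop = FALSE]
  B <- m$values[markers, , drop = FALSE]
  k <- ncol(R)
  props <- matrix(NA_real_, ncol(B), k,
                  dimnames = list(colnames(B), colnames(R)))
  resid <- numeric(ncol(B))
  for (i in seq_len(ncol(B))) {
    fit <- pracma::lsqnonneg(R, B[, i])
    props[i, ] <- fit$x
    resid[i] <- sqrt(fit$resid.norm)
  }
  norm <- props / pmax(rowSums(props), .Machine$double.eps)
  list(proportions = props, proportions_normalized = norm, residual_norm = resid)
}

#' Standard preprocessing chain
#'
#' Applies, in order: sample filter, probe detection filter, annotation
#' filter, quantile normalization, beta-to-M conversion and per-probe
#' standardization, collecting a stage-by-stage processing log of counts.
#'
#' @param m a [meth_matrix()] on the beta scale with detection p-values and
#'   annotation.
#' @param p_threshold probe detection p-value threshold.
#' @param sample_threshold sample mean detection p-value threshold.
#' @param eps clipping constant for the M-value transform.
#' @return list with `meth` (standardized-M [meth_matrix()]) and `log`
#'   (data.frame of stage, probes, samples).
#' @export
preprocess_meth <- function(m, p_threshold = 0.01, sample_threshold = 0.05, eps = 1e-6) {
  steps <- list()
  note <- function(stage, mm) {
    steps[[length(steps) + 1L]] <<- data.frame(stage = stage, probes = nrow(mm$values),
                                               samples = ncol(mm$values))
  }
  note("input", m)
  m <- filter_samples(m, sample_threshold);  note("filter_samples", m)
  m <- filter_probes(m, p_threshold);        note("filter_probes", m)
  m <- filter_annotation(m);                 note("filter_annotation", m)
  m <- quantile_normalize(m);                note("quantile_normalize", m)
  m <- beta_to_m(m, eps);                    note("beta_to_m", m)
  m <- standardize_probes(m);                note("standardize", m)
  list(meth = m, log = do.call(rbind, steps))
}
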