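#' Cohort phenotype container
#'
#' Aligned phenotype vectors and confounder matrix for `n` subjects: binary
#' outcome `Y` (1 = case), binary exposure `X` (1 = currently exposed, e.g.
#' current smoker), and a named confounder matrix `C` (typically age, sex and
#' estimated leukocyte proportions CD8T, CD4T, NK, Bcell, Mono, Gran).
#'
#' Subjects with missing exposure must be excluded before construction; the
#' constructor rejects missing values.
#'
#' @param Y binary outcome vector (0/1).
#' @param X binary exposure vector (0/1).
#' @param C numeric confounder matrix (or data.frame) with named columns;
#'   cell-type proportion columns must lie in \[0, 1\].
#' @return an object of class `cohort_data` with elements `Y`, `X`, `C`, `n`.
#' @examples
#' cohort_data(Y = c(0, 1, 1, 0), X = c(0, 0, 1, 1),
#'             C = cbind(age = c(30, 40, 50, 60), sex = c(0, 1, 0, 1)))
#' @export
cohort_data <- function(Y, X, C) {
  Y <- as.numeric(Y)
  X <- as.numeric(X)
  if (is.data.frame(C)) C <- as.matrix(C)
  check_that(is_binary01(Y), "Y must be a binary 0/1 vector with no missing values")
  check_that(is_binary01(X), "X must be a binary 0/1 vector with no missing values")
  check_that(is.matrix(C) && is.numeric(C), "C must be a numeric matrix")
  check_that(!anyNA(C), "C must not contain missing values")
  check_that(length(Y) == length(X) && length(Y) == nrow(C),
             "Y, X and C must describe the same subjects (equal lengths)")
  check_that(!is.null(colnames(C)) && all(nzchar(colnames(C))),
             "C must have named columns")
  prop_cols <- intersect(colnames(C), c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran"))
  if (length(prop_cols)) {
    check_that(all(C[, prop_cols] >= 0 & C[, prop_cols] <= 1),
               "cell-type proportion columns must lie in [0, 1]")
  }
  structure(list(Y = Y, X = X, C = C, n = length(Y)), class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("Cohort:", x$n, "subjects |", sum(x$Y), "cases /", sum(1 - x$Y), "controls |",
      sum(x$X), "exposed\n")
  cat("Confounders:", paste(colnames(x$C), collapse = ", "), "\n")
  invisible(x)
}

#' Methylation matrix container
#'
#' Probes x samples methylation values together with the matching detection
#' p-value matrix and per-probe annotation. The value scale is tagged as one
#' of `"beta"` (values strictly in (0,1)), `"M"` (log2 beta/(1-beta)) or
#' `"standardized-M"` (per-probe mean 0, SD 1).
#'
#' @param values numeric probes x samples matrix with probe rownames and
#'   sample-id colnames.
#' @param detection_p matching probability matrix (same dim and dimnames), or
#'   `NULL` if detection p-values are unavailable (QC filters then error).
#' @param annotation data.frame with one row per probe and columns
#'   `probe_id`, `chrom`, `pos` (1-based), `nearest_gene`, `gene_group`,
#'   `snp_overlap` (0/1); or `NULL`.
#' @param scale value scale tag, one of `"beta"`, `"M"`, `"standardized-M"`.
#' @return an object of class `meth_matrix`.
#' @export
meth_matrix <- function(values, detection_p = NULL, annotation = NULL,
                        scale = c("beta", "M", "standardized-M")) {
  scale <- match.arg(scale)
  check_that(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  check_that(!is.null(rownames(values)), "values must have probe rownames")
  check_that(!is.null(colnames(values)), "values must have sample-id colnames")
  if (scale == "beta") {
    check_that(all(is.finite(values)) && all(values > 0 & values < 1),
               "beta-scale values must lie strictly in (0, 1)")
  }
  if (!is.null(detection_p)) {
    check_that(is.matrix(detection_p) && all(dim(detection_p) == dim(values)),
               "detection_p must share dimensions with values")
    check_that(all(detection_p >= 0 & detection_p <= 1),
               "detection p-values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  if (!is.null(annotation)) {
    check_that(is.data.frame(annotation) && nrow(annotation) == nrow(values),
               "annotation must have one row per probe")
    check_that("probe_id" %in% names(annotation), "annotation needs a probe_id column")
    check_that(identical(as.character(annotation$probe_id), rownames(values)),
               "annotation probe_id must match probe rownames in order")
  }
  structure(
    list(values = values, detection_p = detection_p,
         annotation = annotation, sample_ids = colnames(values), scale = scale),
    class = "meth_matrix"
  )
}

#' @export
dim.meth_matrix <- function(x) dim(x$values)

#' @export
print.meth_matrix <- function(x, ...) {
  cat("Methylation matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples |", x$scale, "scale\n")
  cat("detection p:", if (is.null(x$detection_p)) "absent" else "present",
      "| annotation:", if (is.null(x$annotation)) "absent" else "present", "\n")
  invisible(x)
}

# replace values (and optionally scale) keeping the other slots aligned
update_meth <- function(m, values, scale = m$scale, keep = rownames(values)) {
  meth_matrix(
    values = values,
    detection_p = if (!is.null(m$detection_p)) m$detection_p[keep, , drop = FALSE],
    annotation = if (!is.null(m$annotation)) {
      a <- m$annotation[match(keep, m$annotation$probe_id), , drop = FALSE]
      rownames(a) <- NULL
      a
    },
    scale = scale
  )
}

#' Subset a methylation matrix
#'
#' Keeps the given probes (`subset_probes`) or samples (`subset_samples`),
#' keeping values, detection p-values and annotation aligned.
#'
#' @param m a [meth_matrix()].
#' @param keep probe/sample names or indices.
#' @return the subset `meth_matrix`.
#' @export
subset_probes <- function(m, keep) {
  v <- m$values[keep, , drop = FALSE]
  out <- m
  out$values <- v
  if (!is.null(m$detection_p)) out$detection_p <- m$detection_p[keep, , drop = FALSE]
  if (!is.null(m$annotation)) {
    a <- m$annotation[match(rownames(v), m$annotation$probe_id), , drop = FALSE]
    rownames(a) <- NULL
    out$annotation <- a
  }
  out
}

#' @rdname subset_probes
#' @export
subset_samples <- function(m, keep) {
  out <- m
  out$values <- m$values[, keep, drop = FALSE]
  if (!is.null(m$detection_p)) out$detection_p <- m$detection_p[, keep, drop = FALSE]
  out$sample_ids <- colnames(out$values)
  out
}

#' Cell-type reference profiles
#'
#' Mean beta-value profiles of purified leukocyte populations over a set of
#' marker probes, used for reference-based deconvolution.
#'
#' @param profiles marker-probes x cell-types numeric matrix on the beta
#'   scale, with probe rownames and cell-type colnames.
#' @return an object of class `celltype_reference`.
#' @export
celltype_reference <- function(profiles) {
  check_that(is.matrix(profiles) && is.numeric(profiles), "profiles must be a numeric matrix")
  check_that(ncol(profiles) >= 2, "a reference needs at least 2 cell types")
  check_that(all(profiles > 0 & profiles < 1), "profile values must lie in (0, 1)")
  check_that(!is.null(rownames(profiles)) && !is.null(colnames(profiles)),
             "profiles must carry probe rownames and cell-type colnames")
  structure(list(profiles = profiles, cell_type_names = colnames(profiles)),
            class = "celltype_reference")
}

#' @export
print.celltype_reference <- function(x, ...) {
  cat("Cell-type reference:", nrow(x$profiles), "marker probes x",
      ncol(x$profiles), "cell types (", paste(x$cell_type_names, collapse = ", "), ")\n")
  invisible(x)
}
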