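# Plain TSV input/output. Matrix layout follows the series-matrix
# convention: probes as rows, a leading probe_id column, sample ids as the
# header row.

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
}

matrix_to_df <- function(mat) {
  data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
             stringsAsFactors = FALSE)
}

df_to_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a methylation matrix to TSV files
#'
#' @param m a [meth_matrix()].
#' @param beta_file,detp_file,annot_file output paths (`detp_file` and
#'   `annot_file` may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
write_meth_tsv <- function(m, beta_file, detp_file = NULL, annot_file = NULL) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  write_tsv(matrix_to_df(m$values), beta_file)
  if (!is.null(detp_file)) {
    check_that(!is.null(m$detection_p), "m has no detection p-values to write")
    write_tsv(matrix_to_df(m$detection_p), detp_file)
  }
  if (!is.null(annot_file)) {
    check_that(!is.null(m$annotation), "m has no annotation to write")
    write_tsv(m$annotation, annot_file)
  }
  invisible(c(beta_file, detp_file, annot_file))
}

#' Read a methylation matrix from TSV files
#'
#' @param beta_file values TSV (probe_id column + one column per sample).
#' @param detp_file,annot_file optional detection-p and annotation TSVs.
#' @param scale value scale tag of the values file.
#' @return a [meth_matrix()].
#' @export
read_meth_tsv <- function(beta_file, detp_file = NULL, annot_file = NULL,
                          scale = "beta") {
  values <- df_to_matrix(read_tsv(beta_file))
  detp <- if (!is.null(detp_file)) df_to_matrix(read_tsv(detp_file))
  annot <- if (!is.null(annot_file)) read_tsv(annot_file)
  meth_matrix(values, detection_p = detp, annotation = annot, scale = scale)
}

#' Write a phenotype table
#'
#' Columns: sample_id, case, smoking, age, sex (cell-type proportions are
#' estimated from the methylation data, not stored in the phenotype table).
#'
#' @param cohort a [cohort_data()] whose confounders include age and sex.
#' @param sample_ids sample identifiers, aligned with the cohort.
#' @param file output path.
#' @export
write_pheno_tsv <- function(cohort, sample_ids, file) {
  check_that(inherits(cohort, "cohort_data"), "cohort must be a cohort_data")
  check_that(length(sample_ids) == cohort$n, "sample_ids must align with the cohort")
  write_tsv(data.frame(sample_id = sample_ids, case = cohort$Y, smoking = cohort$X,
                       age = cohort$C[, "age"], sex = cohort$C[, "sex"]),
            file)
}

#' Read a phenotype table
#'
#' @param file TSV with columns sample_id, case, smoking, age, sex.
#' @return data.frame.
#' @export
read_pheno_tsv <- function(file) {
  ph <- read_tsv(file)
  need <- c("sample_id", "case", "smoking", "age", "sex")
  missing_cols <- setdiff(need, names(ph))
  check_that(!length(missing_cols),
             paste("phenotype table is missing columns:", paste(missing_cols, collapse = ", ")))
  ph
}

#' Write / read a cell-type reference panel
#'
#' @param ref a [celltype_reference()].
#' @param file TSV path (probe_id column + one column per cell type).
#' @export
write_reference_tsv <- function(ref, file) {
  check_that(inherits(ref, "celltype_reference"), "ref must be a celltype_reference")
  write_tsv(matrix_to_df(ref$profiles), file)
}

#' @rdname write_reference_tsv
#' @export
read_reference_tsv <- function(file) {
  celltype_reference(df_to_matrix(read_tsv(file)))
}

#' Export a synthetic cohort as pipeline input files
#'
#' Writes the beta matrix, detection-p matrix, annotation, phenotype table
#' and reference panel of a [simulate_cohort()] result into a directory, in
#' the formats [run_pipeline()] consumes.
#'
#' @param sc a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named list of file paths suitable for splicing into a pipeline
#'   config.
#' @export
export_cohort <- function(sc, dir) {
  check_that(inherits(sc, "synthetic_cohort"), "sc must be a synthetic_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    beta_file = file.path(dir, "beta.tsv"),
    detp_file = file.path(dir, "detection_p.tsv"),
    annot_file = file.path(dir, "annotation.tsv"),
    pheno_file = file.path(dir, "phenotype.tsv"),
    ref_file = file.path(dir, "reference.tsv")
  )
  write_meth_tsv(sc$methylation, paths$beta_file, paths$detp_file, paths$annot_file)
  write_pheno_tsv(sc$cohort, sc$methylation$sample_ids, paths$pheno_file)
  write_reference_tsv(sc$reference, paths$ref_file)
  paths
}
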