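# Shared fixture builders. Everything is generated in code at test time.

# tiny beta-scale methylation matrix with detection p-values and annotation
make_test_meth <- function(n_probes = 20, n_samples = 8, seed = 1) {
  set.seed(seed)
  v <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(n_samples))))
  dp <- matrix(runif(n_probes * n_samples, 0, 0.005), n_probes,
               dimnames = dimnames(v))
  ann <- data.frame(
    probe_id = rownames(v),
    chrom = rep("chr1", n_probes),
    pos = seq_len(n_probes) * 1000L,
    nearest_gene = "GENE1",
    gene_group = "Body",
    snp_overlap = 0L,
    stringsAsFactors = FALSE
  )
  meth_matrix(v, detection_p = dp, annotation = ann, scale = "beta")
}

# direct cohort with age/sex confounders (no cell proportions)
make_test_cohort <- function(n = 200, beta1 = 0, theta1 = 0, theta2 = 0,
                             theta0 = -0.5, seed = 1) {
  set.seed(seed)
  X <- rbinom(n, 1, 0.4)
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  m <- 0.2 + beta1 * X + 0.1 * C[, 1] + rnorm(n)
  y <- rbinom(n, 1, plogis(theta0 + theta1 * X + theta2 * m + 0.2 * C[, 1]))
  list(cohort = cohort_data(y, X, C), m = m)
}

# standardized meth_matrix + cohort for screening/dlasso tests: p probes of
# which the first n_true carry outcome effects theta2 (given X and C)
make_screening_data <- function(n = 300, p = 100, n_true = 0, theta2 = 1,
                                theta1 = 0.3, seed = 1) {
  set.seed(seed)
  X <- rbinom(n, 1, 0.4)
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  M <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("cg%05d", seq_len(p)),
                              sprintf("S%04d", seq_len(n))))
  M <- (M - rowMeans(M)) / apply(M, 1, sd)
  eta <- -0.4 + theta1 * X + 0.2 * C[, 1]
  if (n_true > 0) eta <- eta + theta2 * colSums(M[seq_len(n_true), , drop = FALSE])
  y <- rbinom(n, 1, plogis(eta))
  Cn <- C
  rownames(Cn) <- colnames(M)
  list(cohort = cohort_data(y, X, Cn),
       meth = meth_matrix(M, scale = "standardized-M"),
       true_ids = if (n_true > 0) rownames(M)[seq_len(n_true)] else character())
}

# small synthetic cohort reused across pipeline-level tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(n_probes = 150, n_marker_probes = 24,
                                           seed = 7))
    }
    cache
  }
})

# analysis-ready standardized matrix (marker probes removed)
analysis_matrix <- function(sc) {
  pp <- suppressMessages(suppressWarnings(preprocess_meth(sc$methylation)))
  subset_probes(pp$meth, setdiff(rownames(pp$meth$values),
                                 rownames(sc$reference$profiles)))
}
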