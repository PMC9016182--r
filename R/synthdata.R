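#' Configuration for the synthetic-cohort generator
#'
#' Defines the generative model of a case-control methylation study: a binary
#' exposure (smoking), a binary outcome (disease status), high-dimensional
#' CpG mediators on the M-value scale, and shared confounders (age, sex and
#' leukocyte proportions) entering both the mediator and the outcome model.
#'
#' Defaults mirror the motivating study: 103 cases / 174 controls, current
#' smoking prevalence 0.466 in cases and 0.218 in controls, four true
#' mediator CpGs whose exposure->mediator effects (`alpha_xm`) and
#' mediator->outcome log-odds effects (`beta_my`) equal the study's reported
#' estimates for its four significant CpGs, and a direct exposure log-odds
#' effect of 0.19.
#'
#' @param n_cases,n_controls target case and control counts; the generator is
#'   prospective, so realized counts are binomial around this split.
#' @param n_probes number of CpG probes (desk-scale default 2000).
#' @param n_true_mediators number of truly mediating CpGs.
#' @param alpha_xm exposure->mediator effects on the M-value scale, length
#'   `n_true_mediators`.
#' @param beta_my mediator->outcome log-odds effects, length `n_true_mediators`.
#' @param theta_direct direct exposure->outcome log-odds effect.
#' @param theta0 outcome-model intercept; `NULL` (default) calibrates it by
#'   root-finding so the expected case fraction equals
#'   `n_cases / (n_cases + n_controls)`.
#' @param smoking_prevalence_case,smoking_prevalence_control exposure
#'   prevalence by outcome group; combined into the marginal exposure
#'   prevalence used for prospective generation.
#' @param confounder_strength scale of the confounder loadings on mediators
#'   and of the confounder coefficients in the outcome model (0 switches all
#'   confounding off).
#' @param noise_sd residual SD of mediator M-values (> 0).
#' @param block_rho optional equicorrelation of mediator noise within blocks
#'   of `block_size` probes (0 = independent; no claim of realism attached).
#' @param block_size block size used when `block_rho > 0`.
#' @param n_celltypes,n_marker_probes size of the embedded cell-type
#'   reference panel (marker probes are appended to the methylation matrix so
#'   proportions can be re-estimated by deconvolution).
#' @param seed mandatory integer seed; the generator is a pure function of
#'   the configuration.
#' @return a validated object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_cases = 103, n_controls = 174,
                       n_probes = 2000, n_true_mediators = 4,
                       alpha_xm = c(-0.106, -0.109, -0.131, -0.166),
                       beta_my = c(-3.279, -2.169, -4.486, -2.441),
                       theta_direct = 0.19,
                       theta0 = NULL,
                       smoking_prevalence_case = 0.466,
                       smoking_prevalence_control = 0.218,
                       confounder_strength = 1,
                       noise_sd = 1,
                       block_rho = 0, block_size = 10,
                       n_celltypes = 6, n_marker_probes = 60,
                       seed) {
  check_that(!missing(seed), "seed is required")
  check_that(is_count(n_cases) && n_cases >= 1, "n_cases must be a positive count")
  check_that(is_count(n_controls) && n_controls >= 1, "n_controls must be a positive count")
  check_that(is_count(n_probes) && n_probes >= 1, "n_probes must be a positive count")
  check_that(is_count(n_true_mediators), "n_true_mediators must be a count")
  check_that(n_true_mediators <= n_probes, "n_true_mediators must not exceed n_probes")
  check_that(length(alpha_xm) == n_true_mediators && all(is.finite(alpha_xm)),
             "alpha_xm must be finite with length n_true_mediators")
  check_that(length(beta_my) == n_true_mediators && all(is.finite(beta_my)),
             "beta_my must be finite with length n_true_mediators")
  check_that(is.finite(theta_direct), "theta_direct must be finite")
  check_that(is.null(theta0) || is.finite(theta0), "theta0 must be finite or NULL")
  check_that(is_prob(smoking_prevalence_case) && is_prob(smoking_prevalence_control),
             "prevalences must be probabilities in [0, 1]")
  check_that(is.finite(confounder_strength), "confounder_strength must be finite")
  check_that(is.finite(noise_sd) && noise_sd > 0, "noise_sd must be > 0")
  check_that(is.finite(block_rho) && block_rho >= 0 && block_rho < 1,
             "block_rho must lie in [0, 1)")
  check_that(is_count(n_celltypes) && n_celltypes >= 2, "n_celltypes must be >= 2")
  check_that(is_count(n_marker_probes) && n_marker_probes >= n_celltypes,
             "need at least one marker probe per cell type")
  structure(
    list(n_cases = n_cases, n_controls = n_controls, n_probes = n_probes,
         n_true_mediators = n_true_mediators, alpha_xm = alpha_xm,
         beta_my = beta_my, theta_direct = theta_direct, theta0 = theta0,
         smoking_prevalence_case = smoking_prevalence_case,
         smoking_prevalence_control = smoking_prevalence_control,
         confounder_strength = confounder_strength, noise_sd = noise_sd,
         block_rho = block_rho, block_size = block_size,
         n_celltypes = n_celltypes, n_marker_probes = n_marker_probes,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Table-1-informed population moments used by the generator
.sim_pop <- list(
  age_mean = 37, age_sd = 14,
  # control-group mean cell proportions, normalized to the simplex
  cell_means = c(CD8T = 0.104, CD4T = 0.147, NK = 0.040,
                 Bcell = 0.081, Mono = 0.065, Gran = 0.599) / 1.036,
  dirichlet_conc = 40,
  # confounder -> outcome log-odds coefficients (scaled age, sex, proportions);
  # positive granulocyte and negative lymphocyte terms emulate the observed
  # case-control differences in cell composition
  zeta = c(age = 0.3, sex = 0, CD8T = -2, CD4T = -2, NK = -1,
           Bcell = -2, Mono = 0, Gran = 2)
)

inv_m_value <- function(m) 1 / (1 + 2^(-m))

#' Simulate a synthetic case-control methylation cohort
#'
#' Generates a cohort following the assumed causal structure: confounders
#' `C` affect mediators and outcome; exposure `X` affects the true mediator
#' CpGs (M-value scale) and, directly, the outcome; the binary outcome is
#' drawn from a logistic model in `X`, the true mediators and `C`. Mediator
#' values are stored on the beta scale together with simulated detection
#' p-values, probe annotation, and marker probes mixing a generated
#' cell-type reference by each subject's true proportions.
#'
#' The generator is prospective: `X` is Bernoulli with the marginal exposure
#' prevalence implied by the configured group prevalences, and the outcome
#' intercept is calibrated so the expected case fraction matches the
#' configured case:control split. The truth record carries the mediator
#' indices and the closed-form log odds-ratio effects
#' `log(OR_ACME) = alpha_xm * beta_my` and `log(OR_ADE) = theta_direct`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_cohort`: list with `cohort`
#'   ([cohort_data()]; confounders are the *true* proportions plus age, sex),
#'   `methylation` ([meth_matrix()], beta scale, mediator/null probes first
#'   and marker probes last), `reference` ([celltype_reference()]), `truth`
#'   (list of `indices`, `probe_ids`, `alpha_xm`, `beta_my`, `log_or_acme`,
#'   `log_or_ade`, `theta0`) and `config`.
#' @examples
#' sc <- simulate_cohort(sim_config(n_probes = 50, n_marker_probes = 12, seed = 1))
#' sc$truth$log_or_acme
#' @export
simulate_cohort <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config object")
  cf <- config
  n <- cf$n_cases + cf$n_controls
  f_case <- cf$n_cases / n
  p_x <- (cf$n_cases * cf$smoking_prevalence_case +
            cf$n_controls * cf$smoking_prevalence_control) / n

  with_seed(cf$seed, {
    ## subjects
    X <- stats::rbinom(n, 1, p_x)
    age <- stats::rnorm(n, .sim_pop$age_mean, .sim_pop$age_sd)
    sex <- stats::rbinom(n, 1, 0.5)
    g <- matrix(stats::rgamma(n * cf$n_celltypes,
                              shape = rep(cell_alpha(cf$n_celltypes),
                                          each = n)),
                nrow = n)
    props <- g / rowSums(g)
    colnames(props) <- celltype_names(cf$n_celltypes)
    C <- cbind(age = age, sex = sex, props)

    ## standardized confounders for loadings (unitless confounder_strength)
    Cs <- cbind(age = (age - .sim_pop$age_mean) / .sim_pop$age_sd, sex = sex,
                sweep(props, 2, colMeans(props)))

    ## mediators and null probes (M scale)
    p <- cf$n_probes
    true_idx <- sort(sample.int(p, cf$n_true_mediators))
    intercepts <- stats::runif(p, -3, 3)
    L <- matrix(stats::rnorm(p * ncol(Cs), 0, 0.3), nrow = p) * cf$confounder_strength
    eps <- matrix(stats::rnorm(p * n, 0, cf$noise_sd), nrow = p)
    if (cf$block_rho > 0) {
      blocks <- ceiling(seq_len(p) / cf$block_size)
      fac <- matrix(stats::rnorm(max(blocks) * n, 0, cf$noise_sd), ncol = n)
      eps <- sqrt(1 - cf$block_rho) * eps + sqrt(cf$block_rho) * fac[blocks, , drop = FALSE]
    }
    M <- intercepts + L %*% t(Cs) + eps
    M[true_idx, ] <- M[true_idx, ] + cf$alpha_xm %o% X

    ## outcome
    zeta <- .sim_pop$zeta[colnames(Cs)] * cf$confounder_strength
    eta <- cf$theta_direct * X + drop(crossprod(M[true_idx, , drop = FALSE], cf$beta_my)) +
      drop(Cs %*% zeta)
    theta0 <- cf$theta0
    if (is.null(theta0)) {
      theta0 <- stats::uniroot(function(t0) mean(stats::plogis(t0 + eta)) - f_case,
                               lower = -40, upper = 40, tol = 1e-10)$root
    }
    Y <- stats::rbinom(n, 1, stats::plogis(theta0 + eta))

    ## reference panel and marker probes (beta scale, mixed by true proportions)
    ref <- simulate_reference(n_celltypes = cf$n_celltypes,
                              n_marker_probes = cf$n_marker_probes,
                              seed = cf$seed + 1L)
    markers <- ref$profiles %*% t(props) +
      matrix(stats::rnorm(cf$n_marker_probes * n, 0, 0.02), nrow = cf$n_marker_probes)
    markers <- pmin(pmax(markers, 1e-4), 1 - 1e-4)

    ## assemble beta-scale matrix: analysis probes first, marker probes last
    probe_ids <- sprintf("cg%08d", seq_len(p))
    sample_ids <- sprintf("S%04d", seq_len(n))
    beta <- inv_m_value(M)
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
    values <- rbind(beta, markers)
    rownames(values) <- c(probe_ids, rownames(ref$profiles))
    colnames(values) <- sample_ids

    detp <- matrix(stats::runif(length(values), 0, 0.005), nrow = nrow(values),
                   dimnames = dimnames(values))

    annot <- data.frame(
      probe_id = rownames(values),
      chrom = paste0("chr", sample(1:22, nrow(values), replace = TRUE)),
      pos = sample.int(2e8, nrow(values)),
      nearest_gene = sprintf("GENE%05d", sample.int(20000, nrow(values), replace = TRUE)),
      gene_group = sample(c("TSS1500", "TSS200", "Body", "1stExon", "5'UTR", "3'UTR"),
                          nrow(values), replace = TRUE),
      snp_overlap = 0L,
      stringsAsFactors = FALSE
    )

    meth <- meth_matrix(values, detection_p = detp, annotation = annot, scale = "beta")
    cohort <- cohort_data(Y = Y, X = X, C = C)

    truth <- list(
      indices = true_idx,
      probe_ids = probe_ids[true_idx],
      alpha_xm = cf$alpha_xm,
      beta_my = cf$beta_my,
      log_or_acme = cf$alpha_xm * cf$beta_my,
      log_or_ade = cf$theta_direct,
      theta0 = theta0
    )

    structure(list(cohort = cohort, methylation = meth, reference = ref,
                   truth = truth, config = cf),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$cohort$n, "subjects (", sum(x$cohort$Y), "cases ),",
      x$config$n_probes, "analysis probes +", x$config$n_marker_probes,
      "marker probes\n")
  cat("True mediators:", paste(x$truth$probe_ids, collapse = ", "), "\n")
  cat("Truth log(OR_ACME):", paste(signif(x$truth$log_or_acme, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Analysis-ready cohort from a synthetic cohort
#'
#' Rebuilds the confounder matrix the way the analysis pipeline would see
#' it: age and sex from the phenotype plus cell-type proportions
#' re-estimated from the methylation data by reference-based deconvolution
#' ([estimate_cell_proportions()], unnormalized NNLS estimates). The
#' generator's true proportions lie exactly on the simplex and would make a
#' design with an intercept and all six proportions singular; estimated
#' proportions -- like those used in real studies -- do not.
#'
#' @param sc a `synthetic_cohort`.
#' @return a [cohort_data()].
#' @export
analysis_cohort <- function(sc) {
  check_that(inherits(sc, "synthetic_cohort"), "sc must be a synthetic_cohort")
  props <- estimate_cell_proportions(sc$methylation, sc$reference)$proportions
  C <- cbind(age = sc$cohort$C[, "age"], sex = sc$cohort$C[, "sex"], props)
  rownames(C) <- sc$methylation$sample_ids
  cohort_data(Y = sc$cohort$Y, X = sc$cohort$X, C = C)
}

celltype_names <- function(k) {
  base <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")
  if (k <= 6) base[seq_len(k)] else c(base, sprintf("CT%d", seq_len(k - 6)))
}

cell_alpha <- function(k) {
  if (k == 6) {
    .sim_pop$cell_means * .sim_pop$dirichlet_conc
  } else {
    rep(.sim_pop$dirichlet_conc / k, k)
  }
}

#' Simulate a cell-type reference panel
#'
#' Builds per-cell-type mean beta profiles over marker probes. Markers are
#' assigned round-robin to cell types; each marker is hyper-methylated (beta
#' around 0.9) in exactly its own type and hypo-methylated (around 0.1) in
#' all others, giving well-separated signatures for deconvolution.
#'
#' @param n_celltypes number of cell types (>= 2); up to six are labeled with
#'   the standard leukocyte names CD8T, CD4T, NK, Bcell, Mono, Gran.
#' @param n_marker_probes total number of marker probes.
#' @param seed integer seed.
#' @return a [celltype_reference()] object.
#' @export
simulate_reference <- function(n_celltypes = 6, n_marker_probes = 60, seed) {
  check_that(is_count(n_celltypes) && n_celltypes >= 2, "n_celltypes must be >= 2")
  check_that(is_count(n_marker_probes) && n_marker_probes >= n_celltypes,
             "need at least one marker probe per cell type")
  with_seed(seed, {
    owner <- rep_len(seq_len(n_celltypes), n_marker_probes)
    prof <- matrix(stats::runif(n_marker_probes * n_celltypes, 0.05, 0.15),
                   nrow = n_marker_probes)
    prof[cbind(seq_len(n_marker_probes), owner)] <-
      stats::runif(n_marker_probes, 0.85, 0.95)
    rownames(prof) <- sprintf("cgM%06d", seq_len(n_marker_probes))
    colnames(prof) <- celltype_names(n_celltypes)
    celltype_reference(prof)
  })
}

#' Plant detection-p-value artifacts for QC testing
#'
#' Returns a copy of the methylation matrix whose detection p-values are
#' uniformly small except for planted bad probes (one entry with p >= 0.01 in
#' an otherwise good sample) and planted bad samples (all entries raised so
#' the sample mean p exceeds 0.05). Planted identities are attached as the
#' `"planted"` attribute, so QC filters can be checked against ground truth.
#'
#' @param m a [meth_matrix()].
#' @param frac_bad_probes,frac_bad_samples fractions in \[0, 1).
#' @param seed integer seed.
#' @return the modified `meth_matrix`; `attr(, "planted")` is a list with
#'   `bad_probes` and `bad_samples` (character ids).
#' @export
plant_detection_artifacts <- function(m, frac_bad_probes = 0, frac_bad_samples = 0, seed) {
  check_that(inherits(m, "meth_matrix"), "m must be a meth_matrix")
  check_that(is_prob(frac_bad_probes) && frac_bad_probes < 1, "frac_bad_probes must be in [0, 1)")
  check_that(is_prob(frac_bad_samples) && frac_bad_samples < 1, "frac_bad_samples must be in [0, 1)")
  p <- nrow(m$values); n <- ncol(m$values)
  with_seed(seed, {
    detp <- matrix(stats::runif(p * n, 0, 0.005), nrow = p, dimnames = dimnames(m$values))
    bad_s <- sort(sample.int(n, round(frac_bad_samples * n)))
    if (length(bad_s)) {
      detp[, bad_s] <- stats::runif(p * length(bad_s), 0.055, 0.25)
    }
    good_s <- setdiff(seq_len(n), bad_s)
    bad_p <- sort(sample.int(p, round(frac_bad_probes * p)))
    for (j in bad_p) { # one failing entry per bad probe, in a retained sample
      detp[j, sample(good_s, 1)] <- stats::runif(1, 0.01, 0.5)
    }
    out <- m
    out$detection_p <- detp
    attr(out, "planted") <- list(bad_probes = rownames(m$values)[bad_p],
                                 bad_samples = colnames(m$values)[bad_s])
    out
  })
}
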