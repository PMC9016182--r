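#' Pipeline configuration
#'
#' Builds (and fills defaults into) the configuration consumed by
#' [run_pipeline()]. Configurations can also be written as YAML and loaded
#' with [read_pipeline_config()]; every default is recorded in the run log
#' for provenance.
#'
#' @param beta_file,detp_file,annot_file,pheno_file,ref_file input TSV paths.
#' @param out_dir output directory.
#' @param p_threshold,sample_threshold,eps preprocessing parameters.
#' @param d SIS retention override (`NULL` = `ceiling(2n/ln n)`).
#' @param q FDR level.
#' @param n_boot,n_draws,sens_boot mediation bootstrap / Monte-Carlo sizes.
#' @param rho_min,rho_max,rho_step sensitivity grid.
#' @param seed integer seed (mandatory).
#' @param stages named logical list toggling `baseline`, `screening`,
#'   `dlasso`, `mediation`, `sensitivity`.
#' @param write_plots write per-candidate sensitivity plots (PNG) in
#'   addition to the tables.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(beta_file, detp_file, annot_file, pheno_file, ref_file,
                            out_dir, p_threshold = 0.01, sample_threshold = 0.05,
                            eps = 1e-6, d = NULL, q = 0.05,
                            n_boot = 1000, n_draws = 1000, sens_boot = 200,
                            rho_min = -0.9, rho_max = 0.9, rho_step = 0.1,
                            seed = NULL,
                            stages = list(baseline = TRUE, screening = TRUE,
                                          dlasso = TRUE, mediation = TRUE,
                                          sensitivity = TRUE),
                            write_plots = FALSE) {
  cfg <- list(beta_file = beta_file, detp_file = detp_file, annot_file = annot_file,
              pheno_file = pheno_file, ref_file = ref_file, out_dir = out_dir,
              p_threshold = p_threshold, sample_threshold = sample_threshold,
              eps = eps, d = d, q = q, n_boot = n_boot, n_draws = n_draws,
              sens_boot = sens_boot, rho_min = rho_min, rho_max = rho_max,
              rho_step = rho_step, seed = seed, stages = stages,
              write_plots = write_plots)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param file YAML file whose keys match the [pipeline_config()] arguments;
#'   relative input paths are resolved against the YAML file's directory.
#' @param seed optional seed override (e.g. from a CLI flag).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file, seed = NULL) {
  raw <- yaml::read_yaml(file)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
    raw <- raw[intersect(names(raw), known)]
  }
  if (!is.null(raw$stages)) raw$stages <- utils::modifyList(
    list(baseline = TRUE, screening = TRUE, dlasso = TRUE,
         mediation = TRUE, sensitivity = TRUE), raw$stages)
  base <- dirname(normalizePath(file))
  for (k in c("beta_file", "detp_file", "annot_file", "pheno_file", "ref_file")) {
    if (!is.null(raw[[k]]) && !grepl("^(/|[A-Za-z]:)", raw[[k]])) {
      raw[[k]] <- file.path(base, raw[[k]])
    }
  }
  if (!is.null(seed)) raw$seed <- seed
  do.call(pipeline_config, raw)
}

#' Validate a pipeline configuration
#'
#' Checks completeness and ranges; violations are returned (one string per
#' problem, naming the field and constraint), never raised.
#'
#' @param config a `pipeline_config` (or plain list with the same fields).
#' @return character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  need(!is.null(config$seed) && is.finite(config$seed), "seed: required")
  for (k in c("beta_file", "detp_file", "annot_file", "pheno_file", "ref_file")) {
    if (is.null(config[[k]])) {
      v <- c(v, paste0(k, ": required"))
    } else if (!file.exists(config[[k]])) {
      v <- c(v, paste0(k, ": file does not exist (", config[[k]], ")"))
    }
  }
  need(!is.null(config$out_dir), "out_dir: required")
  need(is.numeric(config$q) && config$q > 0 && config$q < 1, "q: must be in (0,1)")
  need(is.numeric(config$p_threshold) && config$p_threshold >= 0 && config$p_threshold <= 1,
       "p_threshold: must be in [0,1]")
  need(is.numeric(config$sample_threshold) && config$sample_threshold >= 0 &&
         config$sample_threshold <= 1, "sample_threshold: must be in [0,1]")
  need(is.numeric(config$eps) && config$eps > 0 && config$eps < 0.5,
       "eps: must be in (0,0.5)")
  need(is.null(config$d) || (is.numeric(config$d) && config$d >= 1),
       "d: must be NULL or >= 1")
  need(is.numeric(config$n_boot) && config$n_boot >= 100, "n_boot: must be >= 100")
  need(is.numeric(config$rho_min) && is.numeric(config$rho_max) &&
         config$rho_min > -1 && config$rho_max < 1 && config$rho_min < config$rho_max,
       "rho grid: must satisfy -1 < rho_min < rho_max < 1")
  v
}

#' Run the end-to-end mediation pipeline
#'
#' Reads the input TSVs, applies the preprocessing chain, estimates
#' cell-type proportions by deconvolution, builds the analysis cohort
#' (confounders: age, sex, estimated proportions), and runs baseline
#' statistics, SIS screening, de-sparsified LASSO selection, and per-CpG
#' mediation plus sensitivity analysis per the stage toggles, writing every
#' output table, a run log and a run report into `config$out_dir`. The run
#' is a pure function of (input files, config): identical inputs give
#' byte-identical outputs.
#'
#' @param config a validated [pipeline_config()].
#' @return an object of class `run_report`: stage funnel counts, output file
#'   manifest, seeds, and the (deterministic) config fingerprint.
#' @export
run_pipeline <- function(config) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid pipeline config:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  logf <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  manifest <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    manifest <<- c(manifest, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop(sprintf("pipeline failed at stage '%s': %s (partial manifest: %s)",
                   name, conditionMessage(e),
                   paste(basename(manifest), collapse = ", ")), call. = FALSE)
    })
  }
  cfg_print <- utils::capture.output(utils::str(unclass(config)))
  logf("pipeline config:")
  log_lines <- c(log_lines, cfg_print)

  ## ---- load ----
  meth <- stage("load", read_meth_tsv(config$beta_file, config$detp_file, config$annot_file))
  pheno <- stage("load", read_pheno_tsv(config$pheno_file))
  ref <- stage("load", read_reference_tsv(config$ref_file))
  logf("loaded %d probes x %d samples; %d phenotype rows; %d-type reference",
       nrow(meth$values), ncol(meth$values), nrow(pheno), ncol(ref$profiles))

  ## ---- preprocess ----
  counts <- list(probes_in = nrow(meth$values), samples_in = ncol(meth$values))
  pp <- stage("preprocess", {
    m <- suppressMessages(filter_samples(meth, config$sample_threshold))
    logf("filter_samples: %d -> %d samples", counts$samples_in, ncol(m$values))
    m2 <- suppressMessages(filter_probes(m, config$p_threshold))
    logf("filter_probes: %d -> %d probes", nrow(m$values), nrow(m2$values))
    m3 <- suppressMessages(filter_annotation(m2))
    logf("filter_annotation: %d -> %d probes", nrow(m2$values), nrow(m3$values))
    quantile_normalize(m3)
  })
  counts$samples_used <- ncol(pp$values)
  props <- stage("deconvolution", estimate_cell_proportions(pp, ref))
  logf("deconvolution: estimated %d cell-type proportions for %d samples",
       ncol(props$proportions), nrow(props$proportions))

  analysis_probes <- setdiff(rownames(pp$values), rownames(ref$profiles))
  mstd <- stage("preprocess", {
    m <- subset_probes(pp, analysis_probes)
    suppressWarnings(standardize_probes(beta_to_m(m, config$eps)))
  })
  counts$probes_used <- nrow(mstd$values)
  logf("analysis matrix: %d standardized probes (marker probes excluded)", counts$probes_used)

  ## ---- cohort ----
  cohort <- stage("cohort", {
    ph <- pheno[match(mstd$sample_ids, pheno$sample_id), ]
    check_that(!anyNA(ph$sample_id), "phenotype table is missing surviving samples")
    C <- cbind(age = ph$age, sex = ph$sex,
               props$proportions[mstd$sample_ids, , drop = FALSE])
    rownames(C) <- mstd$sample_ids
    cohort_data(Y = ph$case, X = ph$smoking, C = C)
  })

  ## ---- baseline ----
  if (isTRUE(config$stages$baseline)) {
    stage("baseline", {
      emit(baseline_table1(cohort), "table1_baseline.tsv")
      bl <- fit_logistic(cohort)
      emit(baseline_table2(bl), "table2_association.tsv")
      logf("baseline: adjusted smoking OR = %.3f", bl$odds_ratios["X"])
    })
  }

  ## ---- screening / dlasso / mediation via the central fit ----
  funnel <- c(probes = counts$probes_used, screened = NA_integer_,
              candidates = NA_integer_, mediation_significant = NA_integer_)
  if (isTRUE(config$stages$screening)) {
    fit_stages <- character()
    if (isTRUE(config$stages$mediation)) fit_stages <- "mediation"
    if (isTRUE(config$stages$sensitivity)) fit_stages <- c(fit_stages, "sensitivity")
    run_dlasso <- isTRUE(config$stages$dlasso)
    scr <- stage("screening", screen_mediators(cohort, mstd, d = config$d))
    emit(screening_table(scr), "screening.tsv")
    funnel["screened"] <- length(scr$retained)
    logf("screening: retained %d of %d probes (d = %d)",
         length(scr$retained), counts$probes_used, scr$d)
    if (run_dlasso) {
      dl <- stage("dlasso", dlasso(cohort, mstd, scr, q = config$q, seed = config$seed))
      emit(dl$table, "table3_desparsified.tsv")
      funnel["candidates"] <- length(dl$selected)
      logf("dlasso: %d candidate CpGs at FDR < %g", length(dl$selected), config$q)
      if (length(fit_stages) && length(dl$selected)) {
        rho_grid <- seq(config$rho_min, config$rho_max, by = config$rho_step)
        med <- list(); sens <- list()
        stage("mediation", {
          for (i in seq_along(dl$selected)) {
            id <- dl$selected[i]
            mj <- mstd$values[id, ]
            med[[id]] <- estimate_mediation(cohort, mj, n_boot = config$n_boot,
                                            seed = config$seed + 100L + i,
                                            n_draws = config$n_draws)
            if ("sensitivity" %in% fit_stages) {
              sens[[id]] <- sensitivity_analysis(cohort, mj, rho_grid = rho_grid,
                                                 seed = config$seed + 200L + i,
                                                 n_boot = config$sens_boot)
            }
          }
        })
        # exposure -> CpG effects among candidates (smoking-effect table schema)
        t4 <- do.call(rbind, lapply(dl$selected, function(id) {
          mf <- fit_mediator_model(cohort, mstd$values[id, ])
          n <- cohort$n; k <- length(mf$beta)
          Xm <- cbind(1, cohort$X, cohort$C)
          xtxinv <- chol2inv(chol(crossprod(Xm)))
          se <- mf$residual_sd * sqrt(xtxinv[2, 2])
          tval <- mf$beta["X"] / se
          data.frame(probe_id = id, estimate = unname(mf$beta["X"]), se = se,
                     t_value = unname(tval),
                     p = 2 * stats::pt(-abs(tval), df = n - k))
        }))
        emit(t4, "table4_smoking_effects.tsv")
        tab5 <- mediation_table(dl$selected, med, sens, mstd$annotation)
        emit(tab5, "table5_mediation.tsv")
        funnel["mediation_significant"] <- sum(tab5$acme_p < 0.05, na.rm = TRUE)
        logf("mediation: %d of %d candidates significant (ACME p < 0.05)",
             funnel["mediation_significant"], length(dl$selected))
        if (isTRUE(config$write_plots) && length(sens)) {
          for (id in names(sens)) {
            path <- file.path(out_dir, sprintf("sensitivity_%s.png", id))
            grDevices::png(path, width = 800, height = 600)
            plot(sens[[id]], main = id)
            grDevices::dev.off()
            manifest <- c(manifest, path)
          }
        }
      } else if (length(fit_stages)) {
        logf("mediation: no candidates selected; nothing to estimate")
        funnel["mediation_significant"] <- 0L
      }
    }
  }

  fingerprint <- paste(utils::capture.output(dput(unclass(config))), collapse = "")
  report <- structure(
    list(counts = counts, funnel = funnel, manifest = manifest,
         seed = config$seed, config_fingerprint = fingerprint),
    class = "run_report"
  )
  logf("funnel: probes=%s screened=%s candidates=%s mediation_significant=%s",
       funnel["probes"], funnel["screened"], funnel["candidates"],
       funnel["mediation_significant"])
  writeLines(log_lines, file.path(out_dir, "run.log"))
  rep_df <- data.frame(key = c(names(counts), names(funnel), "seed"),
                       value = as.character(c(unlist(counts), funnel, config$seed)))
  emit(rep_df, "run_report.tsv")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed", x$seed, ")\n")
  cat("  probes:", x$counts$probes_in, "in ->", x$counts$probes_used, "used |",
      "samples:", x$counts$samples_in, "in ->", x$counts$samples_used, "used\n")
  cat("  funnel:", paste(names(x$funnel), x$funnel, sep = "=", collapse = " "), "\n")
  cat("  outputs:", paste(basename(x$manifest), collapse = ", "), "\n")
  invisible(x)
}
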