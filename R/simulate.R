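# Synthetic matched-cohort generator. Three cohorts (tumor tissue, matched
# organoid, independent organoid) share one gene universe with planted rank-1
# modules: each module m has a latent per-sample factor, module genes load on
# it with gene-specific loadings, background genes are pure noise. The matched
# organoid shares each tissue sample's factors up to a tunable correlation
# rho_m; IC50 in the independent organoid cohort and survival in the tissue
# cohort are both driven by the drug module's factor.

#' Simulation configuration for matched synthetic cohorts
#'
#' The defaults are the canonical small design used throughout the test suite
#' and documentation: three modules of 60/50/40 genes plus 150 background
#' genes, cohorts of 60 tissue, 60 matched-organoid and 40 independent-organoid
#' samples, tissue-organoid factor correlations (0.9, 0.8, 0.2), module 1
#' driving both IC50 and survival.
#'
#' @param n_genes_background Number of unassigned ("grey") noise genes.
#' @param module_sizes Integer vector of module sizes.
#' @param n_tissue,n_organoid_matched,n_organoid_independent Cohort sizes;
#'   the matched organoid cohort is paired sample-by-sample with tissue and
#'   must have the same size.
#' @param concordance_rho Per-module correlation in `[0, 1]` between the
#'   tissue and matched-organoid latent factors.
#' @param drug_module Index of the module whose factor drives IC50 and
#'   survival.
#' @param drug_effect Slope of IC50 on the drug-module factor.
#' @param drug_noise_sd Residual sd of IC50.
#' @param loading_range Range `(low, high]` in (0, 1] for the per-gene
#'   loadings on the module factor.
#' @param noise_sd Residual sd of every gene (module genes on top of the
#'   factor term; background genes are pure noise at this sd).
#' @param survival_log_hr Log hazard ratio per unit of the drug-module factor.
#' @param baseline_hazard Baseline exponential event rate (per month).
#' @param censor_max Upper bound of the uniform censoring time (months).
#' @param seed Integer seed fixing all randomness.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes_background = 150L,
                       module_sizes = c(60L, 50L, 40L),
                       n_tissue = 60L,
                       n_organoid_matched = 60L,
                       n_organoid_independent = 40L,
                       concordance_rho = c(0.9, 0.8, 0.2),
                       drug_module = 1L,
                       drug_effect = 1.5,
                       drug_noise_sd = 0.5,
                       loading_range = c(0.4, 0.95),
                       noise_sd = 0.5,
                       survival_log_hr = 0.8,
                       baseline_hazard = 0.05,
                       censor_max = 60,
                       seed = 20240101L) {
  cfg <- list(n_genes_background = as.integer(n_genes_background),
              module_sizes = as.integer(module_sizes),
              n_tissue = as.integer(n_tissue),
              n_organoid_matched = as.integer(n_organoid_matched),
              n_organoid_independent = as.integer(n_organoid_independent),
              concordance_rho = concordance_rho,
              drug_module = as.integer(drug_module),
              drug_effect = drug_effect,
              drug_noise_sd = drug_noise_sd,
              loading_range = loading_range,
              noise_sd = noise_sd,
              survival_log_hr = survival_log_hr,
              baseline_hazard = baseline_hazard,
              censor_max = censor_max,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes_background >= 0,
            length(cfg$module_sizes) >= 1, all(cfg$module_sizes >= 2),
            cfg$n_tissue >= 2, cfg$n_organoid_independent >= 2,
            cfg$n_organoid_matched == cfg$n_tissue,
            length(cfg$concordance_rho) == length(cfg$module_sizes),
            all(cfg$concordance_rho >= 0), all(cfg$concordance_rho <= 1),
            cfg$drug_module >= 1, cfg$drug_module <= length(cfg$module_sizes),
            cfg$drug_noise_sd > 0,
            length(cfg$loading_range) == 2,
            cfg$loading_range[1] > 0, cfg$loading_range[2] <= 1,
            cfg$loading_range[1] <= cfg$loading_range[2],
            cfg$noise_sd >= 0,
            cfg$baseline_hazard > 0, cfg$censor_max > 0)
  structure(cfg, class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("Synthetic matched-cohort design\n")
  cat(sprintf("  genes: %d in %d module(s) (%s) + %d background\n",
              sum(x$module_sizes), length(x$module_sizes),
              paste(x$module_sizes, collapse = "/"), x$n_genes_background))
  cat(sprintf("  samples: tissue %d, matched organoid %d, independent organoid %d\n",
              x$n_tissue, x$n_organoid_matched, x$n_organoid_independent))
  cat(sprintf("  tissue-organoid factor rho: %s; drug module: %d\n",
              paste(x$concordance_rho, collapse = ", "), x$drug_module))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Generate matched synthetic cohorts with planted ground truth
#'
#' Draws, for each module and tissue sample, a standard-normal latent factor;
#' the matched organoid factor is `rho_m * f + sqrt(1 - rho_m^2) * eps`, the
#' independent organoid factors are fresh normals. A gene in module m is
#' `loading_g * f_m + noise_sd * z`; background genes are pure noise. IC50 in
#' the independent organoid cohort is `drug_effect * f_drug + noise`; tissue
#' OS and RFS event times are exponential with rate
#' `baseline_hazard * exp(survival_log_hr * f_drug)`, censored uniformly on
#' `(0, censor_max)`. Age and sex covariates are generated independently of
#' outcome. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `tissue`, `organoid_matched`,
#'   `organoid_independent` (genes x samples matrices), `phenotype` (tibble),
#'   `drug` (tibble) and `truth` (planted module labels, loadings, drug gene
#'   set, latent factors, per-sample linear predictor and IC50 mean).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- length(config$module_sizes)
  n_mod_genes <- sum(config$module_sizes)
  G <- n_mod_genes + config$n_genes_background
  genes <- sprintf("G%04d", seq_len(G))
  module_of <- c(rep(sprintf("M%d", seq_len(M)), config$module_sizes),
                 rep("grey", config$n_genes_background))

  loading <- numeric(G)
  loading[seq_len(n_mod_genes)] <- runif(n_mod_genes, config$loading_range[1],
                                         config$loading_range[2])

  n_t <- config$n_tissue
  n_i <- config$n_organoid_independent
  f_tissue <- matrix(rnorm(M * n_t), nrow = M)
  eps <- matrix(rnorm(M * n_t), nrow = M)
  rho <- config$concordance_rho
  f_matched <- rho * f_tissue + sqrt(1 - rho^2) * eps
  f_indep <- matrix(rnorm(M * n_i), nrow = M)

  # loading matrix: G x M, lambda_g in the gene's module column
  L <- matrix(0, nrow = G, ncol = M)
  for (m in seq_len(M)) {
    idx <- which(module_of == sprintf("M%d", m))
    L[idx, m] <- loading[idx]
  }

  make_expr <- function(f, ids) {
    n <- ncol(f)
    e <- L %*% f + config$noise_sd * matrix(rnorm(G * n), nrow = G)
    dimnames(e) <- list(genes, ids)
    e
  }
  tissue_ids <- sprintf("P%03d", seq_len(n_t))
  indep_ids <- sprintf("O%03d", seq_len(n_i))
  tissue <- make_expr(f_tissue, tissue_ids)
  organoid_matched <- make_expr(f_matched, tissue_ids)
  organoid_independent <- make_expr(f_indep, indep_ids)

  dm <- config$drug_module
  ic50_mean <- config$drug_effect * f_indep[dm, ]
  ic50 <- ic50_mean + rnorm(n_i, 0, config$drug_noise_sd)
  drug <- tibble(sample_id = indep_ids, ic50 = ic50)

  lp <- config$survival_log_hr * f_tissue[dm, ]
  rate <- config$baseline_hazard * exp(lp)
  t_os <- rexp(n_t, rate)
  c_os <- runif(n_t, 0, config$censor_max)
  t_rfs <- rexp(n_t, rate)
  c_rfs <- runif(n_t, 0, config$censor_max)
  phenotype <- tibble(
    sample_id = tissue_ids,
    os_time = pmin(t_os, c_os),
    os_event = as.integer(t_os <= c_os),
    rfs_time = pmin(t_rfs, c_rfs),
    rfs_event = as.integer(t_rfs <= c_rfs),
    age = round(rnorm(n_t, 65, 10), 1),
    sex = rbinom(n_t, 1, 0.5)
  )

  truth <- list(
    modules = tibble(gene = genes, module = module_of, loading = loading),
    drug_module = sprintf("M%d", dm),
    drug_genes = genes[module_of == sprintf("M%d", dm)],
    factors = list(tissue = f_tissue, organoid_matched = f_matched,
                   organoid_independent = f_indep),
    linear_predictor = setNames(lp, tissue_ids),
    ic50_mean = setNames(ic50_mean, indep_ids),
    config = config
  )

  list(tissue = tissue,
       organoid_matched = organoid_matched,
       organoid_independent = organoid_independent,
       phenotype = phenotype,
       drug = drug,
       truth = truth)
}

#' Canonical small synthetic fixture
#'
#' [generate_cohorts()] under the default [sim_config()] (seed 20240101);
#' 300 genes, cohorts of 60/60/40 samples.
#'
#' @return See [generate_cohorts()].
#' @export
default_fixture <- function() {
  generate_cohorts(sim_config())
}

#' Generate an independent validation cohort
#'
#' Re-runs the generator with a fresh seed and (optionally) a different
#' tissue-cohort size, keeping the same gene universe and module design, and
#' returns only the tissue expression and phenotype. Loadings and factors are
#' redrawn, so the cohort is independent of the training data while carrying
#' the same planted drug-module survival signal.
#'
#' @param config A [sim_config()] describing the design.
#' @param n Tissue-cohort size.
#' @param seed Seed for the validation draw.
#' @return List with `expr` (genes x samples), `phenotype` (tibble), `truth`.
#' @export
generate_validation_cohort <- function(config, n = 200L, seed = config$seed + 1L) {
  cfg <- unclass(config)
  cfg$n_tissue <- as.integer(n)
  cfg$n_organoid_matched <- as.integer(n)
  cfg$seed <- as.integer(seed)
  g <- generate_cohorts(do.call(sim_config, cfg))
  list(expr = g$tissue, phenotype = g$phenotype, truth = g$truth)
}
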