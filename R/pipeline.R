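# End-to-end pipeline: variance filter -> consensus network -> dual module
# filter -> hub genes -> drug-response model -> tissue evaluation.

#' Run the matched tumor-organoid biomarker pipeline end to end
#'
#' Applies the common top-variance gene filter across the three cohorts,
#' builds the consensus network, screens modules by survival association and
#' tumor-organoid eigengene concordance, extracts hub genes, trains the
#' drug-response candidates on the drug-profiled organoid cohort and
#' evaluates them on the tissue cohort.
#'
#' @param cohorts List with `tissue`, `organoid_matched`,
#'   `organoid_independent` (genes x samples matrices on one gene universe),
#'   `phenotype` and `drug` tibbles -- the shape returned by
#'   [generate_cohorts()].
#' @param top_fraction Common variance-filter fraction (default 0.5);
#'   `NULL` skips filtering.
#' @param beta,cut_height,min_size,consensus Network parameters.
#' @param alpha Module-filter significance level.
#' @param kme_threshold Hub-gene consensus-kME cutoff.
#' @param candidates Drug-model kinds to train.
#' @param folds,cv_reps,n_trees,n_perm,log_ic50 Passed to
#'   [train_drug_model()].
#' @param seed Seed for the model-training stages.
#' @return Object of class `ocr_pipeline` with the network, module screen,
#'   hub genes and training results.
#' @export
run_pipeline <- function(cohorts,
                         top_fraction = 0.5,
                         beta = 12, cut_height = 0.999, min_size = 30,
                         consensus = "mean",
                         alpha = 0.05, kme_threshold = 0.5,
                         candidates = c("ridge", "rf", "ensemble"),
                         folds = 3, cv_reps = 100, n_trees = 500,
                         n_perm = 10, log_ic50 = FALSE, seed = 1) {
  need <- c("tissue", "organoid_matched", "organoid_independent",
            "phenotype", "drug")
  miss <- setdiff(need, names(cohorts))
  if (length(miss)) abort(sprintf("cohorts lacks: %s", paste(miss, collapse = ", ")))
  exprs <- cohorts[c("tissue", "organoid_matched", "organoid_independent")]

  genes <- if (is.null(top_fraction) || top_fraction >= 1) {
    Reduce(intersect, lapply(exprs, rownames))
  } else {
    variance_filter_common(exprs, top_fraction)
  }
  exprs <- lapply(exprs, function(e) e[genes, , drop = FALSE])

  net <- consensus_network(exprs, beta = beta, cut_height = cut_height,
                           min_size = min_size, consensus = consensus)
  if (is.null(net$eigengenes)) abort("no module detected; cannot proceed")

  outcomes <- intersect(c("OS", "RFS"),
                        c("OS", if (all(c("rfs_time", "rfs_event") %in%
                                        colnames(cohorts$phenotype))) "RFS"))
  surv <- cox_me_association(net$eigengenes$tissue, cohorts$phenotype,
                             outcomes = outcomes)
  conc <- eigengene_concordance(net$eigengenes$tissue,
                                net$eigengenes$organoid_matched)
  modules <- select_significant_modules(surv, conc, alpha = alpha)
  if (length(modules) == 0) {
    abort("no module passes the dual survival + concordance filter")
  }
  hubs <- select_hub_genes(net, modules = modules, threshold = kme_threshold)
  if (nrow(hubs) == 0) abort("no hub gene at the consensus kME threshold")

  training <- train_drug_model(cohorts$organoid_independent, cohorts$drug,
                               hubs$gene,
                               tissue_expr = exprs$tissue,
                               phenotype = cohorts$phenotype,
                               candidates = candidates, folds = folds,
                               cv_reps = cv_reps, n_trees = n_trees,
                               n_perm = n_perm, log_ic50 = log_ic50,
                               seed = seed)
  structure(list(genes = genes,
                 network = net,
                 survival = surv,
                 concordance = conc,
                 selected_modules = modules,
                 hub_genes = hubs,
                 training = training,
                 params = list(top_fraction = top_fraction, beta = beta,
                               cut_height = cut_height, min_size = min_size,
                               alpha = alpha, kme_threshold = kme_threshold,
                               seed = seed)),
            class = "ocr_pipeline")
}

#' @exportS3Method base::print
print.ocr_pipeline <- function(x, ...) {
  cat("Matched tumor-organoid biomarker pipeline\n")
  cat(sprintf("  %d filtered genes, %d module(s) + grey\n",
              length(x$genes), length(x$network$sizes)))
  cat(sprintf("  selected module(s): %s\n",
              paste(x$selected_modules, collapse = ", ")))
  cat(sprintf("  %d hub gene(s); final model: %s (%d gene(s))\n",
              nrow(x$hub_genes), x$training$selected_kind,
              length(x$training$final$genes)))
  invisible(x)
}
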