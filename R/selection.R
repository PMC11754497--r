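# Dual module filter: survival association of tissue eigengenes (Cox) and
# tumor-organoid eigengene concordance (Spearman), followed by hub-gene
# extraction by consensus module membership.

#' Cox proportional-hazards association of module eigengenes with survival
#'
#' One univariate Cox fit per module and outcome (partial likelihood, Efron
#' tie handling), relating the tissue eigengene to overall survival (OS)
#' and/or recurrence-free survival (RFS). Fits are unadjusted; covariate
#' adjustment belongs to the per-gene baseline ([per_gene_cox()]).
#'
#' @param eigengenes Eigengene list from [module_eigengene()] or a modules x
#'   samples matrix (tissue cohort).
#' @param phenotype Phenotype tibble with `sample_id`, `os_time`, `os_event`
#'   and, for RFS, `rfs_time`, `rfs_event`.
#' @param outcomes Character subset of `c("OS", "RFS")`.
#' @return Tibble with module, outcome, log_hr, hazard_ratio, se and
#'   p_value (Wald); non-converged fits carry NA p-values.
#' @export
cox_me_association <- function(eigengenes, phenotype, outcomes = c("OS", "RFS")) {
  me <- if (is.list(eigengenes)) eigengenes$me else eigengenes
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  missing_samples <- setdiff(colnames(me), phenotype$sample_id)
  if (length(missing_samples)) {
    abort(sprintf("eigengene sample(s) absent from phenotype: %s",
                  paste(head(missing_samples, 5), collapse = ", ")))
  }
  ph <- phenotype[match(colnames(me), phenotype$sample_id), ]
  rows <- list()
  for (oc in outcomes) {
    tm <- if (oc == "OS") ph$os_time else ph$rfs_time
    ev <- if (oc == "OS") ph$os_event else ph$rfs_event
    if (is.null(tm) || is.null(ev)) abort(sprintf("phenotype lacks %s columns", oc))
    if (sum(ev, na.rm = TRUE) < 1) abort(sprintf("no %s events", oc))
    for (m in rownames(me)) {
      x <- me[m, ]
      fit <- tryCatch(coxph(Surv(tm, ev) ~ x, ties = "efron"),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || !is.finite(sqrt(fit$var[1, 1]))) {
        rows[[length(rows) + 1L]] <- tibble(module = m, outcome = oc,
                                            log_hr = NA_real_,
                                            hazard_ratio = NA_real_,
                                            se = NA_real_, p_value = NA_real_)
        next
      }
      b <- unname(coef(fit)[1])
      se <- sqrt(fit$var[1, 1])
      rows[[length(rows) + 1L]] <- tibble(
        module = m, outcome = oc, log_hr = b, hazard_ratio = exp(b), se = se,
        p_value = pchisq((b / se)^2, df = 1, lower.tail = FALSE))
    }
  }
  purrr::list_rbind(rows)
}

#' Tumor-organoid eigengene concordance
#'
#' Per-module Spearman correlation between the tissue and matched-organoid
#' eigengenes, over the paired samples shared by both cohorts. Two-sided
#' p-values use the t approximation for n > 9 and the exact permutation null
#' for n <= 9.
#'
#' @param me_tissue,me_organoid Eigengene lists or modules x samples matrices
#'   sharing module labels; samples are paired by shared identifiers.
#' @return Tibble with module, rho, p_value, n.
#' @export
eigengene_concordance <- function(me_tissue, me_organoid) {
  mt <- if (is.list(me_tissue)) me_tissue$me else me_tissue
  mo <- if (is.list(me_organoid)) me_organoid$me else me_organoid
  shared <- intersect(colnames(mt), colnames(mo))
  if (length(shared) < 4) abort("fewer than 4 paired samples")
  mods <- intersect(rownames(mt), rownames(mo))
  if (length(mods) == 0) abort("no shared module labels")
  purrr::map(mods, function(m) {
    x <- mt[m, shared]; y <- mo[m, shared]
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = length(shared) <= 9))
    tibble(module = m, rho = unname(ct$estimate), p_value = ct$p.value,
           n = length(shared))
  }) |> purrr::list_rbind()
}

#' Select modules passing the dual survival + concordance filter
#'
#' A module is retained when its best Cox p-value across outcomes (OS or
#' RFS) is below `alpha` AND its tumor-organoid eigengene concordance
#' p-value is below `alpha`. `"grey"` is always excluded. P-values are used
#' raw (no multiple-testing correction) by default; set `fdr = TRUE` to
#' apply Benjamini-Hochberg within each criterion first.
#'
#' @param surv_results Tibble from [cox_me_association()].
#' @param conc_results Tibble from [eigengene_concordance()].
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply BH adjustment before thresholding (default `FALSE`).
#' @return Character vector of selected module labels.
#' @export
select_significant_modules <- function(surv_results, conc_results,
                                       alpha = 0.05, fdr = FALSE) {
  surv <- dplyr::filter(surv_results, .data$module != "grey")
  conc <- dplyr::filter(conc_results, .data$module != "grey")
  if (fdr) {
    surv <- dplyr::mutate(dplyr::group_by(surv, .data$outcome),
                          p_value = p.adjust(.data$p_value, "BH")) |> ungroup()
    conc <- dplyr::mutate(conc, p_value = p.adjust(.data$p_value, "BH"))
  }
  best_surv <- surv |>
    group_by(.data$module) |>
    summarise(p = suppressWarnings(min(.data$p_value, na.rm = TRUE)),
              .groups = "drop")
  hit_surv <- best_surv$module[is.finite(best_surv$p) & best_surv$p < alpha]
  hit_conc <- conc$module[!is.na(conc$p_value) & conc$p_value < alpha]
  intersect(conc$module, intersect(hit_surv, hit_conc))
}

#' Extract hub genes by consensus module membership
#'
#' Hub genes are the members of the selected modules whose absolute consensus
#' kME reaches `threshold` (inclusive: a gene at exactly the threshold is a
#' hub). Genes with missing kME are excluded.
#'
#' @param kme_table Consensus kME matrix (genes x modules) from
#'   [consensus_kme()], or a `consensus_network` object.
#' @param assignment Module assignment (tibble, named vector, or
#'   `module_detection`); taken from the network object if one is given.
#' @param modules Character vector of selected module labels.
#' @param threshold Absolute kME cutoff (default 0.5).
#' @return Tibble with gene, module, consensus_kme; empty (with a warning)
#'   when no gene qualifies.
#' @export
select_hub_genes <- function(kme_table, assignment = NULL, modules,
                             threshold = 0.5) {
  if (inherits(kme_table, "consensus_network")) {
    assignment <- kme_table$modules
    kme_table <- kme_table$consensus_kme
  }
  stopifnot(!is.null(assignment))
  mv <- as_module_vector(assignment)
  unknown <- setdiff(modules, colnames(kme_table))
  if (length(unknown)) {
    abort(sprintf("module(s) absent from the kME table: %s",
                  paste(unknown, collapse = ", ")))
  }
  rows <- purrr::map(modules, function(m) {
    genes <- intersect(names(mv)[mv == m], rownames(kme_table))
    k <- kme_table[genes, m]
    keep <- !is.na(k) & abs(k) >= threshold
    tibble(gene = genes[keep], module = m, consensus_kme = unname(k[keep]))
  }) |> purrr::list_rbind()
  if (nrow(rows) == 0) warn("no gene reaches the consensus kME threshold")
  rows
}
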