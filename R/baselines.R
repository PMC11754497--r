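# Comparison gene-selection procedures (per-gene association tests and
# alternative single/dual-cohort network models) and hypergeometric
# over-representation analysis.

#' Per-gene Cox regression on overall survival
#'
#' One proportional-hazards fit per gene of OS on the gene's expression plus
#' the requested covariates (age and sex by default, when present in the
#' phenotype). Wald p-values; non-converged fits carry NA.
#'
#' @param expr Genes x samples matrix.
#' @param phenotype Phenotype tibble with OS columns (and covariates).
#' @param covariates Covariate column names to adjust for; silently reduced
#'   to those present.
#' @return Tibble with gene, test = `"cox_os"`, effect (log HR), p_value.
#' @export
per_gene_cox <- function(expr, phenotype, covariates = c("age", "sex")) {
  covariates <- intersect(covariates, colnames(phenotype))
  samples <- intersect(colnames(expr), phenotype$sample_id)
  if (length(samples) < 3) abort("too few samples shared with the phenotype")
  ph <- phenotype[match(samples, phenotype$sample_id), ]
  if (sum(ph$os_event) < 1) abort("no OS events")
  Z <- if (length(covariates)) as.matrix(ph[, covariates]) else NULL
  srv <- Surv(ph$os_time, ph$os_event)
  purrr::map(rownames(expr), function(g) {
    x <- expr[g, samples]
    fit <- tryCatch({
      if (is.null(Z)) coxph(srv ~ x, ties = "efron")
      else coxph(srv ~ x + Z, ties = "efron")
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(sqrt(fit$var[1, 1]))) {
      return(tibble(gene = g, test = "cox_os", effect = NA_real_,
                    p_value = NA_real_))
    }
    b <- unname(coef(fit)[1]); se <- sqrt(fit$var[1, 1])
    tibble(gene = g, test = "cox_os", effect = b,
           p_value = pchisq((b / se)^2, df = 1, lower.tail = FALSE))
  }) |> purrr::list_rbind()
}

spearman_row_test <- function(x, y, gene, test) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(gene = gene, test = test, effect = NA_real_,
                  p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(gene = gene, test = test, effect = unname(ct$estimate),
         p_value = ct$p.value)
}

#' Per-gene Spearman correlation with drug response
#'
#' @param expr Genes x samples matrix (organoid cohort).
#' @param drug Tibble with `sample_id`, `ic50`.
#' @return Tibble with gene, test = `"spearman_drug"`, effect (rho), p_value.
#' @export
gene_drug_spearman <- function(expr, drug) {
  samples <- intersect(colnames(expr), drug$sample_id)
  if (length(samples) < 4) abort("too few drug-profiled samples")
  y <- drug$ic50[match(samples, drug$sample_id)]
  purrr::map(rownames(expr), function(g) {
    spearman_row_test(expr[g, samples], y, g, "spearman_drug")
  }) |> purrr::list_rbind()
}

#' Per-gene paired tumor-organoid Spearman correlation
#'
#' Correlates each gene's expression across the paired samples shared by the
#' tissue and matched-organoid cohorts.
#'
#' @param tissue,organoid Genes x samples matrices sharing gene and sample
#'   ids.
#' @return Tibble with gene, test = `"spearman_paired"`, effect (rho),
#'   p_value.
#' @export
paired_gene_spearman <- function(tissue, organoid) {
  samples <- intersect(colnames(tissue), colnames(organoid))
  if (length(samples) < 4) abort("too few paired samples")
  genes <- intersect(rownames(tissue), rownames(organoid))
  purrr::map(genes, function(g) {
    spearman_row_test(tissue[g, samples], organoid[g, samples], g,
                      "spearman_paired")
  }) |> purrr::list_rbind()
}

#' Filter genes by the association-test criteria
#'
#' Criterion 1 keeps genes whose three association tests (gene-OS Cox,
#' gene-drug Spearman, paired tumor-organoid Spearman) are all significant
#' at `alpha`. Criterion 2 additionally requires the gene-OS log hazard
#' ratio and the gene-drug rho to agree in sign, so the criterion-2 list is
#' always a subset of criterion 1.
#'
#' @param cox_tab,drug_tab,paired_tab Tibbles from [per_gene_cox()],
#'   [gene_drug_spearman()], [paired_gene_spearman()].
#' @param criterion 1 or 2.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of genes (in `cox_tab` order).
#' @export
filter_by_criteria <- function(cox_tab, drug_tab, paired_tab, criterion = 1,
                               alpha = 0.05) {
  stopifnot(criterion %in% c(1, 2))
  tab <- cox_tab |>
    dplyr::select(gene = "gene", p_cox = "p_value", log_hr = "effect") |>
    inner_join(dplyr::select(drug_tab, gene = "gene", p_drug = "p_value",
                             rho_drug = "effect"), by = "gene") |>
    inner_join(dplyr::select(paired_tab, gene = "gene", p_paired = "p_value"),
               by = "gene")
  pass <- with(tab, !is.na(p_cox) & !is.na(p_drug) & !is.na(p_paired) &
                 p_cox < alpha & p_drug < alpha & p_paired < alpha)
  if (criterion == 2) {
    pass <- pass & with(tab, sign(log_hr) == sign(rho_drug))
  }
  tab$gene[pass]
}

#' Alternative network-based gene-selection models
#'
#' Re-runs the network + module-selection machinery under three reduced
#' designs: variant 1 uses only the tissue cohort, variant 2 the matched
#' tissue/organoid pair (consensus of two), variant 3 only the drug-profiled
#' organoid cohort. Module relevance is Cox-on-OS of the (tissue) eigengenes
#' for variants 1-2 and the Spearman correlation between IC50 and the
#' eigengene for variant 3. Hub genes use the same absolute consensus-kME
#' filter as the main pipeline.
#'
#' @param variant 1, 2 or 3.
#' @param tissue,organoid_matched,organoid_independent Genes x samples
#'   matrices (only the ones the variant needs are required).
#' @param phenotype Phenotype tibble (variants 1-2).
#' @param drug Drug-response tibble (variant 3).
#' @param beta,cut_height,min_size Network parameters.
#' @param alpha Module-relevance significance level.
#' @param kme_threshold Hub-gene cutoff.
#' @return List with `genes` (hub tibble), `selected_modules`, `relevance`
#'   (per-module test results) and `network`.
#' @export
alternative_wgcna_models <- function(variant, tissue = NULL,
                                     organoid_matched = NULL,
                                     organoid_independent = NULL,
                                     phenotype = NULL, drug = NULL,
                                     beta = 12, cut_height = 0.999,
                                     min_size = 30, alpha = 0.05,
                                     kme_threshold = 0.5) {
  stopifnot(variant %in% 1:3)
  exprs <- switch(as.character(variant),
                  "1" = list(tissue = tissue),
                  "2" = list(tissue = tissue, organoid_matched = organoid_matched),
                  "3" = list(organoid_independent = organoid_independent))
  if (any(vapply(exprs, is.null, logical(1)))) {
    abort(sprintf("variant %d requires cohort(s): %s", variant,
                  paste(names(exprs), collapse = ", ")))
  }
  net <- consensus_network(exprs, beta = beta, cut_height = cut_height,
                           min_size = min_size)
  if (is.null(net$eigengenes)) abort("no module detected")
  if (variant %in% 1:2) {
    stopifnot(!is.null(phenotype))
    relevance <- cox_me_association(net$eigengenes$tissue, phenotype,
                                    outcomes = "OS")
    sel <- relevance |>
      filter(.data$module != "grey", !is.na(.data$p_value),
             .data$p_value < alpha) |>
      pull("module") |> unique()
  } else {
    stopifnot(!is.null(drug))
    me <- net$eigengenes$organoid_independent$me
    samples <- intersect(colnames(me), drug$sample_id)
    y <- drug$ic50[match(samples, drug$sample_id)]
    relevance <- purrr::map(rownames(me), function(m) {
      ct <- suppressWarnings(cor.test(me[m, samples], y, method = "spearman",
                                      exact = FALSE))
      tibble(module = m, rho = unname(ct$estimate), p_value = ct$p.value)
    }) |> purrr::list_rbind()
    sel <- relevance$module[!is.na(relevance$p_value) & relevance$p_value < alpha]
    sel <- setdiff(sel, "grey")
  }
  hubs <- if (length(sel)) {
    select_hub_genes(net$consensus_kme, net$modules, sel,
                     threshold = kme_threshold)
  } else {
    tibble(gene = character(), module = character(),
           consensus_kme = numeric())
  }
  list(genes = hubs, selected_modules = sel, relevance = relevance,
       network = net)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set, after intersecting sets with the universe and applying
#' the size filter; Benjamini-Hochberg FDR across the retained sets. A set
#' with zero overlap gets p = 1.
#'
#' @param query_genes Character vector, a subset of `universe`.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector: the gene universe (typically the
#'   network's filtered gene list).
#' @param min_size,max_size Retained set-size bounds within the universe
#'   (defaults 10 and 500).
#' @return Tibble with set, set_size, overlap, p_value, fdr, ordered by
#'   p-value.
#' @export
ora <- function(query_genes, gene_sets, universe, min_size = 10,
                max_size = 500) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    abort(sprintf("query gene(s) outside the universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  sets <- lapply(gene_sets, intersect, y = universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (length(sets) == 0) {
    return(tibble(set = character(), set_size = integer(),
                  overlap = integer(), p_value = numeric(), fdr = numeric()))
  }
  N <- length(universe); q <- length(query)
  res <- purrr::imap(sets, function(s, nm) {
    m <- length(s)
    k <- length(intersect(query, s))
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    tibble(set = nm, set_size = m, overlap = k, p_value = p)
  }) |> purrr::list_rbind()
  res$fdr <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value)
}
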