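# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' Tidy a consensus network into a gene-level tibble
#'
#' @param x A `consensus_network`.
#' @param ... Unused.
#' @return Tibble with gene, module, per-cohort kME columns (`kme_<cohort>`)
#'   and `consensus_kme` (each gene's membership in its own module; NA for
#'   grey genes).
#' @export
tidy.consensus_network <- function(x, ...) {
  out <- x$modules
  if (is.null(x$consensus_kme)) return(out)
  own <- function(mat) {
    vapply(seq_len(nrow(out)), function(i) {
      m <- out$module[i]
      if (m == "grey") NA_real_ else mat[out$gene[i], m]
    }, numeric(1))
  }
  for (nm in names(x$kme)) out[[paste0("kme_", nm)]] <- own(x$kme[[nm]])
  out$consensus_kme <- own(x$consensus_kme)
  out
}

#' One-row summary of a consensus network
#'
#' @param x A `consensus_network`.
#' @param ... Unused.
#' @export
glance.consensus_network <- function(x, ...) {
  tibble(n_genes = length(x$genes),
         n_cohorts = length(x$cohorts),
         n_modules = length(x$sizes),
         n_grey = sum(x$modules$module == "grey"),
         beta = x$params$beta,
         cut_height = x$params$cut_height,
         min_size = x$params$min_size)
}

#' Tidy a drug-response model
#'
#' Linear kinds return gene/coefficient pairs; the `"rf"` kind returns
#' gene/importance pairs.
#'
#' @param x A `drug_response_model`.
#' @param ... Unused.
#' @export
tidy.drug_response_model <- function(x, ...) {
  if (x$kind == "rf") {
    tibble(gene = names(x$importance), importance = unname(x$importance))
  } else {
    tibble(gene = names(x$coefficients),
           coefficient = unname(x$coefficients))
  }
}

#' One-row summary of a drug-response model
#'
#' @param x A `drug_response_model`.
#' @param ... Unused.
#' @export
glance.drug_response_model <- function(x, ...) {
  tibble(kind = x$kind,
         n_genes = length(x$genes),
         lambda = if (x$kind == "rf") NA_real_ else x$lambda,
         intercept = if (x$kind == "rf") NA_real_ else x$intercept)
}

#' One-row summary of a cohort validation
#'
#' @param x A `cohort_validation`.
#' @param ... Unused.
#' @export
glance.cohort_validation <- function(x, ...) {
  gs <- x$comparison$group_sizes
  tibble(model_kind = x$model_kind,
         cutpoint = x$cutpoint,
         n_sensitive = as.integer(gs[["sensitive"]]),
         n_resistant = as.integer(gs[["resistant"]]),
         chisq = x$comparison$chisq,
         p_value = x$comparison$p_value)
}

#' One-row summary of a full pipeline run
#'
#' @param x An `ocr_pipeline`.
#' @param ... Unused.
#' @export
glance.ocr_pipeline <- function(x, ...) {
  rep <- x$training$report
  fin <- rep[rep$kind == x$training$selected_kind, ]
  tibble(n_genes = length(x$genes),
         n_modules = length(x$network$sizes),
         n_selected_modules = length(x$selected_modules),
         n_hub_genes = nrow(x$hub_genes),
         final_kind = x$training$selected_kind,
         n_model_genes = length(x$training$final$genes),
         cv_mse = fin$cv_mse,
         tissue_auc = fin$auc,
         tissue_logrank_p = fin$logrank_p)
}

#' Kaplan-Meier plot of a survival comparison
#'
#' Step curves per group with censoring implicit in the steps.
#'
#' @param object A `survival_comparison` or `cohort_validation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  cv <- object$curves |>
    group_by(.data$group) |>
    dplyr::reframe(time = c(0, .data$time), surv = c(1, .data$surv))
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  color = NULL,
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.survival_comparison
#' @export
autoplot.cohort_validation <- function(object, ...) {
  autoplot(object$comparison) +
    ggplot2::labs(title = sprintf("Drug-resistance score split (%s model), cutpoint %.3g",
                                  object$model_kind, object$cutpoint))
}

#' Module-size bar chart of a consensus network
#'
#' @param object A `consensus_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_network <- function(object, ...) {
  sizes <- c(object$sizes, grey = sum(object$modules$module == "grey"))
  df <- tibble(module = factor(names(sizes), levels = names(sizes)),
               size = as.integer(sizes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$size,
                                   fill = .data$module)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = NULL, y = "Genes") +
    ggplot2::theme_minimal()
}

#' Soft-threshold scan plot
#'
#' Scale-free fit and slope as a function of the soft-thresholding power.
#'
#' @param scan Tibble from [pick_soft_threshold()] (`$scan`).
#' @param r2_target Horizontal reference line (default 0.75).
#' @return A ggplot.
#' @export
plot_soft_threshold <- function(scan, r2_target = 0.75) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$beta, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = r2_target, linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Soft-thresholding power",
                  y = expression(paste("Scale-free fit ", R^2))) +
    ggplot2::theme_minimal()
}
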