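# Patient-level drug-resistance scoring: linear score over the model genes,
# maximally selected rank-statistic cutpoint, dichotomization, Kaplan-Meier
# curves and the log-rank test.

#' Patient-specific drug-resistance score
#'
#' For linear model kinds the score of a patient is
#' `sum_i beta_i * Exp_i` over the model genes -- no intercept, so the score
#' is a pure linear combination of expression. For the `"rf"` kind the score
#' is the forest-predicted value.
#'
#' @param model A `drug_response_model`.
#' @param expr Genes x samples matrix; all model genes must be present.
#' @return Tibble with `sample_id` and `score`.
#' @export
drug_resistance_score <- function(model, expr) {
  stopifnot(inherits(model, "drug_response_model"), is.matrix(expr))
  miss <- setdiff(model$genes, rownames(expr))
  if (length(miss)) {
    abort(sprintf("model gene(s) missing from expression: %s",
                  paste(miss, collapse = ", ")))
  }
  sub <- expr[model$genes, , drop = FALSE]
  if (!all(is.finite(sub))) abort("non-finite expression values for model genes")
  score <- if (model$kind == "rf") {
    predict(model, t(sub))
  } else {
    drop(crossprod(sub, model$coefficients))
  }
  tibble(sample_id = colnames(expr), score = unname(score))
}

# standardized log-rank statistic for a binary split (TRUE = high group):
# z = (O - E) / sqrt(V) accumulated over distinct event times, with the
# hypergeometric variance under ties.
logrank_z <- function(in_high, time, event) {
  dtimes <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in dtimes) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & in_high)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(list(z = 0, chisq = 0))
  list(z = (O - E) / sqrt(V), chisq = (O - E)^2 / V)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Evaluates every candidate cutpoint (midpoints between consecutive distinct
#' score values whose split leaves at least a `minprop` fraction of samples
#' on each side) and returns the one maximizing the absolute standardized
#' log-rank statistic of the induced two-group comparison. Ties go to the
#' smallest cutpoint. The p-value of the selected split, when reported
#' downstream, is the raw log-rank p: the maximal selection inflates it, and
#' no selection adjustment is applied.
#'
#' @param scores Numeric scores (>= 10 samples).
#' @param time,event Survival outcome (>= 2 events).
#' @param minprop Minimum group fraction on each side (default 0.1).
#' @return List with `cutpoint`, `statistic` (the maximal |z|) and
#'   `candidates`, a tibble of all evaluated cutpoints and statistics.
#' @export
maxstat_cutpoint <- function(scores, time, event, minprop = 0.1) {
  n <- length(scores)
  stopifnot(n >= 10, length(time) == n, length(event) == n,
            minprop > 0, minprop < 0.5)
  if (sum(event) < 2) abort("need at least 2 events")
  u <- sort(unique(scores))
  if (length(u) < 2) abort("all scores identical: no candidate cutpoint")
  cand <- (u[-1] + u[-length(u)]) / 2
  keep <- vapply(cand, function(cp) {
    nh <- sum(scores >= cp)
    nh / n >= minprop && (n - nh) / n >= minprop
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) abort("no candidate cutpoint satisfies the minprop constraint")
  stat <- vapply(cand, function(cp) abs(logrank_z(scores >= cp, time, event)$z),
                 numeric(1))
  best <- which(stat >= max(stat) - 1e-12)[1]   # ties -> smallest cutpoint
  list(cutpoint = cand[best], statistic = stat[best],
       candidates = tibble(cutpoint = cand, statistic = stat))
}

#' Dichotomize scores at a cutpoint
#'
#' Resistant if and only if `score >= cutpoint` (the boundary is resistant).
#'
#' @param scores Numeric scores.
#' @param cutpoint Finite cutpoint.
#' @return Factor with levels `sensitive`, `resistant`.
#' @export
dichotomize <- function(scores, cutpoint) {
  stopifnot(is.finite(cutpoint))
  factor(ifelse(scores >= cutpoint, "resistant", "sensitive"),
         levels = c("sensitive", "resistant"))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with at-risk counts; subjects censored at an event
#' time remain at risk for the event at that time (the standard convention).
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @return Tibble with time, n_risk, n_event, n_censor, surv.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) abort("empty input")
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  fit <- survfit(Surv(time, event) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-sample log-rank test with per-group Kaplan-Meier curves
#'
#' Standard log-rank chi-square (observed versus hypergeometric-expected
#' events at each distinct event time), 1 degree of freedom, two-sided.
#'
#' @param groups Factor/vector with exactly 2 non-empty groups.
#' @param time,event Survival outcome (>= 1 event overall).
#' @return Object of class `survival_comparison`: chisq, df, p_value,
#'   `curves` (tibble of per-group KM curves) and `group_sizes`.
#' @export
logrank_test <- function(groups, time, event) {
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) != 2) abort("exactly 2 non-empty groups required")
  if (sum(event) < 1) abort("no events")
  sd <- survdiff(Surv(time, event) ~ g)
  chisq <- sd$chisq
  curves <- purrr::map(levels(g), function(lv) {
    km <- km_estimate(time[g == lv], event[g == lv])
    km$group <- lv
    km
  }) |> purrr::list_rbind() |>
    dplyr::select("group", dplyr::everything())
  structure(list(chisq = chisq, df = 1L,
                 p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
                 curves = curves,
                 group_sizes = table(g)),
            class = "survival_comparison")
}

#' @exportS3Method base::print
print.survival_comparison <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f (df = %d), p = %.3g\n",
              x$chisq, x$df, x$p_value))
  cat("  group sizes:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Validate a drug-response model on a patient cohort
#'
#' Scores every sample, estimates the maxstat cutpoint on this cohort (the
#' cutpoint is re-estimated per cohort, not carried over), splits into
#' resistant/sensitive groups and compares overall survival by Kaplan-Meier
#' and log-rank. Deterministic given inputs.
#'
#' @param model A `drug_response_model`.
#' @param expr Genes x samples cohort expression.
#' @param phenotype Phenotype tibble with OS columns.
#' @param minprop Maxstat group-fraction bound (default 0.1).
#' @return Object of class `cohort_validation`: `scores` (tibble with
#'   sample_id, score, group, cutpoint), `cutpoint`, `statistic` and
#'   `comparison` (a `survival_comparison`).
#' @export
validate_cohort <- function(model, expr, phenotype, minprop = 0.1) {
  sc <- drug_resistance_score(model, expr)
  ph <- phenotype[match(sc$sample_id, phenotype$sample_id), ]
  if (anyNA(ph$sample_id)) {
    abort("some scored samples are missing from the phenotype table")
  }
  ms <- maxstat_cutpoint(sc$score, ph$os_time, ph$os_event, minprop = minprop)
  grp <- dichotomize(sc$score, ms$cutpoint)
  cmp <- logrank_test(grp, ph$os_time, ph$os_event)
  structure(list(scores = mutate(sc, group = grp, cutpoint = ms$cutpoint),
                 cutpoint = ms$cutpoint,
                 statistic = ms$statistic,
                 comparison = cmp,
                 model_kind = model$kind),
            class = "cohort_validation")
}

#' @exportS3Method base::print
print.cohort_validation <- function(x, ...) {
  cat(sprintf("Cohort validation (%s model): cutpoint = %.4g\n",
              x$model_kind, x$cutpoint))
  print(x$comparison)
  invisible(x)
}
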