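# Organoid drug-response models: ridge regression (exact penalized
# least-squares on standardized predictors), random forest with out-of-bag
# permutation importance, and the ensemble (importance-filtered genes
# refitted by ridge). Candidate models are compared by repeated k-fold CV,
# AUC on a tissue cohort, and log-rank separation after maxstat
# dichotomization.

standardize_columns <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  if (any(s == 0)) {
    abort(sprintf("constant predictor(s): %s",
                  paste(head(colnames(X)[s == 0], 5), collapse = ", ")))
  }
  list(x = sweep(sweep(X, 2L, mu), 2L, s, `/`), mu = mu, s = s)
}

# ridge path via SVD: beta(lambda) = V diag(d / (d^2 + lambda)) U' y
ridge_path <- function(Xs, yc, lambdas) {
  sv <- svd(Xs)
  uty <- crossprod(sv$u, yc)
  shrink <- outer(sv$d, lambdas, function(d, l) d / (d^2 + l))
  beta <- sv$v %*% (shrink * drop(uty))
  rownames(beta) <- colnames(Xs)
  beta
}

default_lambda_grid <- function(Xs, yc, n_lambda = 100) {
  lmax <- max(abs(crossprod(Xs, yc)))
  if (lmax <= 0) lmax <- 1
  10^seq(log10(lmax), log10(lmax * 1e-4), length.out = n_lambda)
}

#' Fit a ridge (or elastic-net) drug-response model
#'
#' Ridge regression of the response on standardized gene expression,
#' minimizing `||y - X beta||^2 + lambda ||beta||^2`, so that at fixed
#' `lambda` the standardized-scale coefficients equal the closed form
#' `(X'X + lambda I)^-1 X'y`. `lambda` is chosen by minimum mean k-fold CV
#' MSE over the grid; the final fit uses all samples, and coefficients are
#' returned on the original expression scale (intercept kept separately; the
#' exported resistance score omits it).
#'
#' With a non-trivial `alpha_grid`, the elastic net over the (alpha, lambda)
#' grid is delegated to \pkg{glmnet} and the pair with the lowest CV MSE is
#' used.
#'
#' @param X Samples x genes numeric matrix with column names.
#' @param y Numeric response (e.g. IC50), length `nrow(X)`.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @param lambda_grid Optional penalty grid (default: 100 log-spaced values
#'   from the data-driven maximum down to 1e-4 of it).
#' @param folds Number of CV folds (default 3).
#' @param seed Seed for fold assignment.
#' @param alpha_grid Optional elastic-net mixing grid; `NULL` (default) means
#'   pure ridge.
#' @return A `drug_response_model` of kind `"ridge"`.
#' @export
fit_ridge <- function(X, y, lambda = NULL, lambda_grid = NULL, folds = 3,
                      seed = 1, alpha_grid = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y), folds >= 2,
            nrow(X) >= folds)
  if (sd(y) == 0) abort("constant response: ridge fit undefined")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))

  if (!is.null(alpha_grid) && any(alpha_grid > 0)) {
    return(fit_enet_glmnet(X, y, alpha_grid, folds, seed))
  }

  std <- standardize_columns(X)
  yc <- y - mean(y)
  if (is.null(lambda)) {
    if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(std$x, yc)
    lambda_grid <- sort(lambda_grid, decreasing = TRUE)
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(folds), nrow(X)))
    mse <- matrix(NA_real_, nrow = folds, ncol = length(lambda_grid))
    for (k in seq_len(folds)) {
      tr <- foldid != k
      std_tr <- standardize_columns(X[tr, , drop = FALSE])
      ytr <- y[tr]
      beta <- ridge_path(std_tr$x, ytr - mean(ytr), lambda_grid)
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, std_tr$mu), 2L, std_tr$s, `/`)
      pred <- Xte %*% beta + mean(ytr)
      mse[k, ] <- colMeans((y[!tr] - pred)^2)
    }
    cv <- colMeans(mse)
    lambda <- lambda_grid[which.min(cv)]
    cv_tab <- tibble(lambda = lambda_grid, cv_mse = cv)
  } else {
    cv_tab <- NULL
  }
  beta_std <- drop(ridge_path(std$x, yc, lambda))
  beta <- beta_std / std$s
  intercept <- mean(y) - sum(beta * std$mu)
  structure(list(kind = "ridge",
                 genes = colnames(X),
                 coefficients = setNames(beta, colnames(X)),
                 intercept = intercept,
                 lambda = lambda,
                 alpha = 0,
                 cv = cv_tab,
                 folds = folds,
                 seed = seed),
            class = "drug_response_model")
}

fit_enet_glmnet <- function(X, y, alpha_grid, folds, seed) {
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(X)))
  fits <- purrr::map(alpha_grid, function(a) {
    # glmnet needs alpha > 0 for its own lambda path; supply one at alpha = 0
    if (a == 0) {
      cvf <- glmnet::cv.glmnet(X, y, alpha = 0, foldid = foldid)
    } else {
      cvf <- glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid)
    }
    list(alpha = a, cv = cvf, mse = min(cvf$cvm))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "mse"))]]
  co <- coef(best$cv, s = "lambda.min")
  beta <- setNames(as.numeric(co)[-1], rownames(co)[-1])
  structure(list(kind = "ridge",
                 genes = colnames(X),
                 coefficients = beta,
                 intercept = as.numeric(co)[1],
                 lambda = best$cv$lambda.min,
                 alpha = best$alpha,
                 cv = tibble(lambda = best$cv$lambda, cv_mse = best$cv$cvm),
                 folds = folds,
                 seed = seed),
            class = "drug_response_model")
}

ranger_predict_all <- function(fit, X) {
  predict(fit, data = as.data.frame(X), predict.all = TRUE,
          num.threads = 1)$predictions
}

#' Fit a random-forest drug-response model with permutation importance
#'
#' Regression forest (\pkg{ranger}, single-threaded and seeded, so results
#' are reproducible) plus out-of-bag permutation importance: for each gene,
#' its column is permuted `n_perm` times and the importance is the mean
#' increase in out-of-bag MSE over the permutations.
#'
#' @param X Samples x genes matrix (>= 10 samples).
#' @param y Numeric response.
#' @param n_trees Number of trees (default 500).
#' @param mtry Variables tried per split; default `ceiling(p / 3)`.
#' @param n_perm Permutations per gene for the importance (default 10);
#'   0 skips the importance computation.
#' @param seed Seed controlling both the forest and the permutations.
#' @return A `drug_response_model` of kind `"rf"` carrying the fitted forest,
#'   the named importance vector and the baseline out-of-bag MSE.
#' @export
fit_rf <- function(X, y, n_trees = 500, mtry = NULL, n_perm = 10, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) >= 10, nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  p <- ncol(X)
  if (is.null(mtry)) mtry <- min(p, ceiling(p / 3))
  fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = n_trees,
                        mtry = mtry, keep.inbag = TRUE, seed = seed,
                        num.threads = 1)
  n <- nrow(X)
  inbag <- matrix(unlist(fit$inbag.counts), nrow = n)
  oob <- inbag == 0
  oob_n <- rowSums(oob)
  use <- oob_n > 0
  oob_mean <- function(P) rowSums(P * oob) / oob_n
  base_pred <- oob_mean(ranger_predict_all(fit, X))
  oob_mse <- mean((y[use] - base_pred[use])^2)

  importance <- setNames(rep(NA_real_, p), colnames(X))
  if (n_perm > 0) {
    set.seed(seed + 1L)
    for (j in seq_len(p)) {
      inc <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        Xp <- X
        Xp[, j] <- X[sample(n), j]
        pred <- oob_mean(ranger_predict_all(fit, Xp))
        inc[b] <- mean((y[use] - pred[use])^2) - oob_mse
      }
      importance[j] <- mean(inc)
    }
  }
  structure(list(kind = "rf",
                 genes = colnames(X),
                 forest = fit,
                 importance = importance,
                 oob_mse = oob_mse,
                 n_trees = n_trees, mtry = mtry, n_perm = n_perm,
                 seed = seed),
            class = "drug_response_model")
}

#' Fit the ensemble drug-response model (RF importance filter + ridge)
#'
#' Genes with positive out-of-bag permutation importance in a random forest
#' are refitted by ridge regression; the resulting linear coefficients define
#' the exported model.
#'
#' @inheritParams fit_rf
#' @param folds,lambda_grid Passed to [fit_ridge()].
#' @return A `drug_response_model` of kind `"ensemble"` whose
#'   `selected_genes`/`coefficients` come from the ridge refit; the RF
#'   importance vector is kept for auditing.
#' @export
fit_ensemble <- function(X, y, n_trees = 500, mtry = NULL, n_perm = 10,
                         folds = 3, lambda_grid = NULL, seed = 1) {
  rf <- fit_rf(X, y, n_trees = n_trees, mtry = mtry, n_perm = n_perm, seed = seed)
  sel <- names(rf$importance)[!is.na(rf$importance) & rf$importance > 0]
  if (length(sel) == 0) {
    abort("no gene has positive permutation importance; fall back to the random-forest model")
  }
  ridge <- fit_ridge(X[, sel, drop = FALSE], y, lambda_grid = lambda_grid,
                     folds = folds, seed = seed)
  structure(list(kind = "ensemble",
                 genes = sel,
                 coefficients = ridge$coefficients,
                 intercept = ridge$intercept,
                 lambda = ridge$lambda,
                 alpha = 0,
                 importance = rf$importance,
                 cv = ridge$cv,
                 folds = folds,
                 n_trees = n_trees, n_perm = n_perm,
                 seed = seed),
            class = "drug_response_model")
}

#' Predict the response for new samples
#'
#' Linear kinds use intercept + coefficients (the prediction, unlike the
#' exported resistance score, includes the intercept); the `"rf"` kind uses
#' the fitted forest.
#'
#' @param object A `drug_response_model`.
#' @param newdata Samples x genes matrix containing the model's genes.
#' @param ... Unused.
#' @export
predict.drug_response_model <- function(object, newdata, ...) {
  miss <- setdiff(object$genes, colnames(newdata))
  if (length(miss)) {
    abort(sprintf("missing gene(s) in newdata: %s", paste(miss, collapse = ", ")))
  }
  Xm <- newdata[, object$genes, drop = FALSE]
  if (object$kind == "rf") {
    predict(object$forest, data = as.data.frame(Xm), num.threads = 1)$predictions
  } else {
    drop(Xm %*% object$coefficients) + object$intercept
  }
}

fit_candidate <- function(kind, X, y, folds = 3, n_trees = 500, n_perm = 10,
                          seed = 1, lambda_grid = NULL) {
  switch(kind,
         ridge = fit_ridge(X, y, lambda_grid = lambda_grid, folds = folds,
                           seed = seed),
         rf = {
           f <- fit_rf(X, y, n_trees = n_trees, n_perm = n_perm, seed = seed)
           sel <- names(f$importance)[!is.na(f$importance) & f$importance > 0]
           # refit on the positive-importance genes when any survive
           if (length(sel) >= 1 && length(sel) < ncol(X)) {
             f2 <- fit_rf(X[, sel, drop = FALSE], y, n_trees = n_trees,
                          n_perm = 0, seed = seed)
             f2$importance <- f$importance
             f2
           } else f
         },
         ensemble = fit_ensemble(X, y, n_trees = n_trees, n_perm = n_perm,
                                 folds = folds, lambda_grid = lambda_grid,
                                 seed = seed),
         abort(sprintf("unknown model kind '%s'", kind)))
}

#' Repeated k-fold cross-validation of a candidate model
#'
#' For each repetition the fold assignment is redrawn (seed = `seed + rep`),
#' the candidate's full fitting path (including any gene selection) is re-run
#' on each training fold, and held-out MSEs are collected. Reported are the
#' mean and sd over all fold-level MSEs.
#'
#' @param kind `"ridge"`, `"rf"` or `"ensemble"`.
#' @param X Samples x genes matrix.
#' @param y Response.
#' @param folds Folds per repetition (default 3).
#' @param reps Repetitions (default 100).
#' @param seed Base seed.
#' @param n_trees,n_perm Forest parameters for the rf/ensemble kinds.
#' @return One-row tibble: kind, cv_mse, cv_mse_sd, folds, reps.
#' @export
repeated_cv <- function(kind, X, y, folds = 3, reps = 100, seed = 1,
                        n_trees = 500, n_perm = 10) {
  stopifnot(folds >= 2, reps >= 1)
  mses <- numeric(0)
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    foldid <- sample(rep_len(seq_len(folds), nrow(X)))
    for (k in seq_len(folds)) {
      tr <- foldid != k
      fit <- tryCatch(
        fit_candidate(kind, X[tr, , drop = FALSE], y[tr], folds = folds,
                      n_trees = n_trees, n_perm = n_perm, seed = seed + r),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict(fit, X[!tr, , drop = FALSE])
      mses <- c(mses, mean((y[!tr] - pred)^2))
    }
  }
  tibble(kind = kind, cv_mse = mean(mses), cv_mse_sd = sd(mses),
         folds = folds, reps = reps)
}

#' Area under the ROC curve from scores and binary labels
#'
#' Rank (Mann-Whitney) formulation with ties counting one half; oriented as
#' the probability that an event sample (label 1) scores higher than a
#' non-event sample.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select the final model from a candidate report
#'
#' Candidates are filtered to those with a significant log-rank separation
#' (p < `alpha`); among the survivors, a candidate that simultaneously has
#' the lowest CV MSE and the highest AUC is chosen. When no candidate
#' dominates both criteria, candidates are ranked by CV MSE with AUC as
#' tie-breaker (with a warning). If nothing passes the log-rank filter, the
#' best CV MSE candidate is returned with a warning.
#'
#' @param cv_report Tibble with columns kind, cv_mse, auc, logrank_p.
#' @param alpha Log-rank significance filter (default 0.05).
#' @return The selected kind (character scalar).
#' @export
select_final_model <- function(cv_report, alpha = 0.05) {
  if (is.null(cv_report) || nrow(cv_report) == 0) abort("empty candidate report")
  ok <- cv_report[!is.na(cv_report$logrank_p) & cv_report$logrank_p < alpha, ]
  if (nrow(ok) == 0) {
    warn("no candidate passes the log-rank filter; choosing the lowest CV MSE")
    return(cv_report$kind[which.min(cv_report$cv_mse)])
  }
  best_mse <- ok$kind[which.min(ok$cv_mse)]
  best_auc <- ok$kind[which.max(ok$auc)]
  if (best_mse == best_auc) return(best_mse)
  warn(sprintf("no candidate dominates both criteria (MSE favors %s, AUC favors %s); ranking by CV MSE",
               best_mse, best_auc))
  best_mse
}

#' Train and compare organoid drug-response models
#'
#' Builds the training matrix from the organoid expression of the hub genes
#' and the IC50 table, fits the requested candidates, cross-validates each,
#' and -- when a tissue cohort with survival is supplied -- evaluates each
#' candidate's patient scores by AUC against the OS event indicator and by
#' log-rank test after maxstat dichotomization. The final model is chosen by
#' [select_final_model()].
#'
#' @param organoid_expr Genes x samples matrix with IC50-profiled samples.
#' @param drug Tibble with `sample_id`, `ic50`.
#' @param hub_genes Character vector of genes to train on.
#' @param tissue_expr,phenotype Optional tissue cohort for AUC / log-rank
#'   evaluation.
#' @param candidates Model kinds to fit.
#' @param folds,cv_reps CV design; `cv_reps = 0` skips repeated CV (only
#'   meaningful with a single candidate).
#' @param n_trees,n_perm Forest parameters.
#' @param log_ic50 Log2-transform IC50 before fitting (default `FALSE`).
#' @param seed Seed for all fitting stages.
#' @return Object of class `drug_model_training`: `final` (the selected
#'   `drug_response_model`), `candidates` (named list), `report` (tibble) and
#'   `selected_kind`.
#' @export
train_drug_model <- function(organoid_expr, drug, hub_genes,
                             tissue_expr = NULL, phenotype = NULL,
                             candidates = c("ridge", "rf", "ensemble"),
                             folds = 3, cv_reps = 100, n_trees = 500,
                             n_perm = 10, log_ic50 = FALSE, seed = 1) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  genes <- intersect(hub_genes, rownames(organoid_expr))
  if (length(genes) == 0) abort("none of the hub genes is present in the organoid expression")
  samples <- intersect(drug$sample_id, colnames(organoid_expr))
  if (length(samples) < folds) abort("too few drug-profiled organoid samples")
  X <- t(organoid_expr[genes, samples, drop = FALSE])
  y <- drug$ic50[match(samples, drug$sample_id)]
  if (log_ic50) y <- log2_transform(y, offset = 0)

  fits <- setNames(purrr::map(candidates, function(kd) {
    fit_candidate(kd, X, y, folds = folds, n_trees = n_trees, n_perm = n_perm,
                  seed = seed)
  }), candidates)

  report <- purrr::map(candidates, function(kd) {
    row <- if (cv_reps > 0) {
      repeated_cv(kd, X, y, folds = folds, reps = cv_reps, seed = seed,
                  n_trees = n_trees, n_perm = n_perm)
    } else {
      tibble(kind = kd, cv_mse = NA_real_, cv_mse_sd = NA_real_,
             folds = folds, reps = 0L)
    }
    row$auc <- NA_real_
    row$logrank_p <- NA_real_
    if (!is.null(tissue_expr) && !is.null(phenotype)) {
      sc <- drug_resistance_score(fits[[kd]], tissue_expr)
      ph <- phenotype[match(sc$sample_id, phenotype$sample_id), ]
      row$auc <- auc_from_scores(sc$score, ph$os_event)
      val <- tryCatch(validate_cohort(fits[[kd]], tissue_expr, phenotype),
                      error = function(e) NULL)
      if (!is.null(val)) row$logrank_p <- val$comparison$p_value
    }
    row
  }) |> purrr::list_rbind()

  selected <- if (length(candidates) == 1) {
    candidates
  } else if (all(is.na(report$logrank_p)) && all(is.na(report$cv_mse))) {
    abort("cannot rank candidates without CV or a tissue cohort")
  } else if (all(is.na(report$logrank_p))) {
    report$kind[which.min(report$cv_mse)]
  } else {
    select_final_model(report)
  }
  structure(list(final = fits[[selected]],
                 candidates = fits,
                 report = report,
                 selected_kind = selected,
                 seed = seed),
            class = "drug_model_training")
}

#' Build a linear drug-response model from published coefficients
#'
#' Wraps a fixed gene/coefficient table (for instance a published ridge
#' signature) as a `drug_response_model`, so it can be scored and validated
#' like a freshly trained model. The intercept is zero: the exported
#' resistance score is the pure linear combination.
#'
#' @param genes Character vector of gene ids.
#' @param coefficients Numeric vector of the same length.
#' @param kind Stored kind label (default `"ridge"`).
#' @return A `drug_response_model`.
#' @export
linear_drug_model <- function(genes, coefficients, kind = "ridge") {
  stopifnot(length(genes) == length(coefficients), !anyDuplicated(genes),
            all(is.finite(coefficients)))
  structure(list(kind = kind,
                 genes = as.character(genes),
                 coefficients = setNames(as.numeric(coefficients), genes),
                 intercept = 0,
                 lambda = NA_real_,
                 alpha = 0,
                 cv = NULL,
                 seed = NA_integer_),
            class = "drug_response_model")
}

#' Seven-gene 5-FU drug-resistance signature
#'
#' Reference ridge coefficients of the seven-gene 5-fluorouracil
#' drug-response signature for colorectal cancer (six tan-module genes and
#' one salmon-module gene). Use with [linear_drug_model()] and
#' [drug_resistance_score()] to score external cohorts.
#'
#' @return Tibble with gene, coefficient, module.
#' @export
signature_5fu <- function() {
  tibble(
    gene = c("CELP", "CPN1", "NEURL2", "PIPOX", "SLC19A3", "VAV3", "HOXB13"),
    coefficient = c(-0.0798, -0.0282, -0.0162, -0.0392, -0.0568, 0.0012, -0.0325),
    module = c(rep("tan", 6), "salmon")
  )
}

#' @exportS3Method base::print
print.drug_response_model <- function(x, ...) {
  cat(sprintf("Drug-response model (%s): %d gene(s)\n", x$kind, length(x$genes)))
  if (x$kind != "rf") {
    cat(sprintf("  lambda = %s, intercept = %.4g\n",
                format(x$lambda, digits = 4), x$intercept))
  } else {
    cat(sprintf("  %d trees, OOB MSE = %.4g\n", x$n_trees, x$oob_mse))
  }
  invisible(x)
}

#' @exportS3Method base::print
print.drug_model_training <- function(x, ...) {
  cat(sprintf("Drug-model training: selected '%s' among {%s}\n",
              x$selected_kind, paste(names(x$candidates), collapse = ", ")))
  print(x$report)
  invisible(x)
}
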