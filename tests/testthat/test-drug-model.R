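test_that("ridge at fixed lambda equals the closed form on standardized X", {
  set.seed(51)
  n <- 40; p <- 8
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- rnorm(n)
  lambda <- 3.7
  fit <- fit_ridge(X, y, lambda = lambda)
  Xs <- scale(X)
  yc <- y - mean(y)
  beta_std <- solve(crossprod(Xs) + lambda * diag(p), crossprod(Xs, yc))
  expect_equal(unname(fit$coefficients),
               unname(drop(beta_std) / apply(X, 2, sd)), tolerance = 1e-8)
})

test_that("ridge limits: lambda -> 0 is OLS (n > p) and lambda -> Inf shrinks to 0", {
  set.seed(52)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- X %*% c(1, -2, 0.5, 0) + rnorm(60, 0, 0.3)
  f0 <- fit_ridge(X, y, lambda = 0)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(f0$coefficients), unname(ols), tolerance = 1e-8)
  finf <- fit_ridge(X, y, lambda = 1e12)
  expect_lt(max(abs(finf$coefficients)), 1e-6)
  expect_error(fit_ridge(X, rep(2, 60)), "constant response")
})

test_that("ridge coefficient norm shrinks monotonically in lambda", {
  set.seed(53)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- rnorm(50)
  norms <- vapply(c(0.1, 1, 10, 100, 1000), function(l) {
    sqrt(sum(fit_ridge(X, y, lambda = l)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("cross-validated ridge picks the minimum-CV lambda deterministically", {
  set.seed(54)
  X <- matrix(rnorm(45 * 10), 45, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- X[, 1] - X[, 2] + rnorm(45, 0, 0.5)
  f1 <- fit_ridge(X, y, seed = 3)
  f2 <- fit_ridge(X, y, seed = 3)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_equal(f1$lambda, f1$cv$lambda[which.min(f1$cv$cv_mse)])
  # intercept reproduces the training mean at the predictor means
  expect_equal(unname(predict(f1, matrix(colMeans(X), 1,
                                         dimnames = list(NULL, colnames(X))))),
               mean(y) , tolerance = 1e-10)
})

test_that("glmnet agrees with the closed-form ridge at a matched penalty", {
  set.seed(55)
  n <- 50
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- X[, 1] + rnorm(n, 0, 0.4)
  lambda <- 8
  ours <- fit_ridge(X, y, lambda = lambda)
  # glmnet with standardize = FALSE on our standardized X minimizes
  # (1/2n)RSS + (lambda_g/2)||b||^2, so lambda_g = lambda / n matches our
  # ||y - Xs b||^2 + lambda ||b||^2 objective; a warm-started path improves
  # its coordinate-descent accuracy, which stays approximate at one lambda
  Xs <- scale(X)
  g <- glmnet::glmnet(Xs, y, alpha = 0,
                      lambda = lambda / n * c(16, 8, 4, 2, 1),
                      standardize = FALSE, thresh = 1e-14)
  beta_g <- drop(coef(g, s = lambda / n))[-1] / apply(X, 2, sd)
  expect_equal(unname(ours$coefficients), unname(beta_g), tolerance = 0.05)
  # and the exact solution of glmnet's own objective equals our coefficients
  b_obj <- solve(crossprod(Xs) / n + (lambda / n) * diag(5),
                 crossprod(Xs, y - mean(y)) / n)
  expect_equal(unname(ours$coefficients),
               unname(drop(b_obj) / apply(X, 2, sd)), tolerance = 1e-10)
})

test_that("random-forest fits and importances are reproducible and signal-driven", {
  set.seed(56)
  n <- 40
  f <- rnorm(n)
  X <- cbind(sig = f, matrix(rnorm(n * 5), n, 5,
                             dimnames = list(NULL, paste0("n", 1:5))))
  y <- f  # feature identical to the response
  r1 <- fit_rf(X, y, n_trees = 200, n_perm = 5, seed = 9)
  r2 <- fit_rf(X, y, n_trees = 200, n_perm = 5, seed = 9)
  expect_identical(r1$importance, r2$importance)
  expect_identical(names(which.max(r1$importance)), "sig")
  expect_gt(r1$importance[["sig"]], 0)
})

test_that("null permutation importances are centered at zero", {
  set.seed(57)
  pos <- 0; tot <- 0; mns <- numeric(0)
  for (r in 1:100) {
    X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))
    y <- rnorm(30)
    f <- fit_rf(X, y, n_trees = 100, n_perm = 5, seed = r)
    pos <- pos + sum(f$importance > 0)
    tot <- tot + 4
    mns <- c(mns, mean(f$importance))
  }
  expect_equal(pos / tot, 0.5, tolerance = 0.12)
  expect_lt(abs(mean(mns)), 0.05)
})

test_that("the ensemble recovers informative genes and reduces cleanly", {
  set.seed(58)
  hit <- 0
  for (s in 1:3) {
    n <- 40
    f <- rnorm(n)
    X <- cbind(matrix(rep(f, 5), n) * rep(runif(5, 0.7, 1), each = n) +
                 0.4 * matrix(rnorm(5 * n), n),
               matrix(rnorm(30 * n), n))
    colnames(X) <- c(paste0("info", 1:5), paste0("noise", 1:30))
    y <- 1.5 * f + rnorm(n, 0, 0.5)
    en <- fit_ensemble(X, y, n_trees = 300, n_perm = 5, seed = s)
    hit <- hit + (sum(paste0("info", 1:5) %in% en$genes) >= 4)
    expect_true(all(en$genes %in% colnames(X)))
  }
  expect_gte(hit, 2)

  # single informative gene: sign of the effect is recovered
  n <- 40
  x1 <- rnorm(n)
  X1 <- cbind(good = x1, matrix(rnorm(3 * n), n,
                                dimnames = list(NULL, paste0("z", 1:3))))
  y1 <- -2 * x1 + rnorm(n, 0, 0.3)
  en1 <- fit_ensemble(X1, y1, n_trees = 300, n_perm = 5, seed = 4)
  expect_true("good" %in% en1$genes)
  expect_lt(en1$coefficients[["good"]], 0)
})

test_that("an importance filter that removes everything is a documented error", {
  local_mocked_bindings(
    fit_rf = function(X, y, ...) {
      structure(list(kind = "rf", genes = colnames(X),
                     importance = setNames(rep(-1, ncol(X)), colnames(X))),
                class = "drug_response_model")
    },
    .package = "ocrnet")
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_ensemble(X, rnorm(20)), "positive permutation importance")
})

test_that("repeated CV is seeded, consistent and calibrated on pure noise", {
  set.seed(59)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rnorm(60)
  r1 <- repeated_cv("ridge", X, y, reps = 1, seed = 11)
  r2 <- repeated_cv("ridge", X, y, reps = 1, seed = 11)
  expect_identical(r1, r2)
  # noise response: the CV MSE of a shrunk model approximates var(y)
  Xn <- matrix(rnorm(150 * 5), 150, 5, dimnames = list(NULL, paste0("g", 1:5)))
  yn <- rnorm(150)
  r <- repeated_cv("ridge", Xn, yn, reps = 10, seed = 12)
  expect_equal(r$cv_mse / var(yn), 1, tolerance = 0.2)
})

test_that("more CV repetitions shrink the spread of the mean CV error", {
  set.seed(60)
  X <- matrix(rnorm(36 * 4), 36, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- X[, 1] + rnorm(36, 0, 0.7)
  m_few <- vapply(1:20, function(b) {
    repeated_cv("ridge", X, y, reps = 2, seed = 100 * b)$cv_mse
  }, numeric(1))
  m_many <- vapply(1:20, function(b) {
    repeated_cv("ridge", X, y, reps = 8, seed = 100 * b + 7)$cv_mse
  }, numeric(1))
  # 4x the repetitions -> roughly half the standard error of the mean
  expect_lt(sd(m_many), sd(m_few))
})

test_that("AUC follows the rank formulation with half-credit ties", {
  expect_equal(auc_from_scores(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc_from_scores(rep(5, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(61)
  s <- rnorm(4000); l <- rbinom(4000, 1, 0.5)
  expect_equal(auc_from_scores(s, l), 0.5, tolerance = 0.03)
  # invariant to strictly increasing transforms
  s2 <- rnorm(50); l2 <- rbinom(50, 1, 0.4)
  expect_equal(auc_from_scores(exp(s2), l2), auc_from_scores(s2, l2))
  expect_error(auc_from_scores(1:5, rep(1, 5)), "both classes")
})

test_that("final-model selection follows filter-then-lexicographic ranking", {
  rep_dom <- tibble::tibble(kind = c("ridge", "rf", "ensemble"),
                            cv_mse = c(0.5, 0.6, 0.4),
                            auc = c(0.7, 0.72, 0.8),
                            logrank_p = c(0.01, 0.2, 0.001))
  expect_identical(select_final_model(rep_dom), "ensemble")  # dominates both

  rep_conflict <- tibble::tibble(kind = c("A", "B"),
                                 cv_mse = c(0.3, 0.5), auc = c(0.6, 0.9),
                                 logrank_p = c(0.01, 0.01))
  expect_warning(sel <- select_final_model(rep_conflict), "dominates")
  expect_identical(sel, "A")  # MSE priority

  rep_nofit <- tibble::tibble(kind = c("A", "B"), cv_mse = c(0.3, 0.5),
                              auc = c(0.6, 0.9), logrank_p = c(0.2, 0.7))
  expect_warning(sel2 <- select_final_model(rep_nofit), "log-rank")
  expect_identical(sel2, "A")
  expect_error(select_final_model(tibble::tibble()), "empty")
})

test_that("training on the fixture exports a reproducible hub-gene model", {
  fx <- default_fixture()
  hubs <- fx$truth$drug_genes[1:20]
  tr1 <- train_drug_model(fx$organoid_independent, fx$drug, hubs,
                          candidates = "ensemble", cv_reps = 0,
                          n_trees = 200, n_perm = 5, seed = 2)
  tr2 <- train_drug_model(fx$organoid_independent, fx$drug, hubs,
                          candidates = "ensemble", cv_reps = 0,
                          n_trees = 200, n_perm = 5, seed = 2)
  expect_identical(tr1$final$coefficients, tr2$final$coefficients)
  expect_true(all(tr1$final$genes %in% hubs))
  expect_s3_class(tidy(tr1$final), "tbl_df")
})
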