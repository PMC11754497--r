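test_that("signed adjacency matches the closed form at the correlation extremes", {
  x <- c(1, 2, 3, 5)
  expr <- rbind(a = x, b = 2 * x + 1, c = -x)
  colnames(expr) <- paste0("s", 1:4)
  adj <- signed_adjacency(expr, beta = 7)
  expect_equal(adj["a", "b"], 1)      # r = 1 -> 1 for any beta
  expect_equal(adj["a", "c"], 0)      # r = -1 -> 0 for any beta
  # r = 0 exactly, beta = 12 -> (1/2)^12
  expr0 <- rbind(u = c(1, -1, 1, -1), v = c(1, 1, -1, -1), w = c(1, 2, 4, 9))
  colnames(expr0) <- paste0("s", 1:4)
  adj0 <- signed_adjacency(expr0, beta = 12)
  expect_equal(adj0["u", "v"], 2^-12, tolerance = 1e-15)
  expect_true(all(diag(adj) == 1))
  expect_error(signed_adjacency(rbind(k = c(1, 1, 1), a = 1:3), beta = 2), "k")
})

test_that("topological overlap matches the brute-force triple loop", {
  a <- random_adjacency(20, seed = 7)
  expect_lt(max(abs(topological_overlap(a) - brute_force_tom(a))), 1e-10)

  # zero off-diagonal adjacency -> zero off-diagonal TOM
  z <- diag(5)
  tz <- topological_overlap(z)
  expect_equal(tz[upper.tri(tz)], rep(0, 10))

  # complete graph -> all TOM exactly 1
  cg <- matrix(1, 6, 6)
  expect_equal(unique(as.vector(topological_overlap(cg))), 1)
})

test_that("adjacency and TOM are symmetric and bounded in [0, 1]", {
  expr <- random_expr(25, 15, seed = 4)
  adj <- signed_adjacency(expr, 12)
  tom <- topological_overlap(adj)
  for (m in list(adj, tom)) {
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
  }
})

test_that("scale-free fit is exact for a perfect log-log line and warns on 2 bins", {
  # Chung-Lu style adjacency whose connectivities follow k_i ~ i^-1 pattern
  set.seed(1)
  k_target <- rep(c(1, 2, 4, 8, 16, 32, 52, 64), times = c(64, 32, 16, 8, 4, 2, 1, 1))
  n <- length(k_target)
  a <- outer(k_target, k_target) / sum(k_target)
  diag(a) <- 1
  f <- scale_free_fit(a, n_bins = 10)
  expect_gt(f$r_squared, 0.9)
  expect_lt(f$slope, 0)
  expect_warning(scale_free_fit(a, n_bins = 2), "2 non-empty")
  expect_error(scale_free_fit(matrix(1, 30, 30), n_bins = 10), "degenerate")
})

test_that("fixture networks approximate scale-free topology at beta 12", {
  fx <- default_fixture()
  fits <- lapply(fx[c("tissue", "organoid_matched", "organoid_independent")],
                 function(e) scale_free_fit(signed_adjacency(e, 12)))
  expect_true(all(vapply(fits, function(f) f$slope < 0, logical(1))))
  expect_true(all(vapply(fits, function(f) f$r_squared > 0.7, logical(1))))
  expect_gte(fits$organoid_independent$r_squared, 0.75)
})

test_that("soft-threshold selection applies the smallest-qualifying rule", {
  expr <- default_fixture()$organoid_independent
  got <- pick_soft_threshold(expr, beta_grid = c(6, 12, 18), r2_target = 0.5)
  # selection rule recomputed independently from the returned scan
  ok <- got$scan$r_squared >= 0.5 & got$scan$slope < 0
  expect_equal(got$beta, got$scan$beta[which(ok)[1]])
  # unreachable target -> argmax fallback with a warning
  expect_warning(
    fb <- pick_soft_threshold(expr, beta_grid = c(6, 12), r2_target = 0.999),
    "best fit")
  expect_equal(fb$beta, fb$scan$beta[which.max(fb$scan$r_squared)])
  # deterministic re-scan
  again <- pick_soft_threshold(expr, beta_grid = c(6, 12, 18), r2_target = 0.5)
  expect_identical(got$scan, again$scan)
})

make_sym <- function(v, ids = letters[1:3]) {
  n <- length(ids)
  m <- diag(n)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

test_that("quantile calibration equalizes distributions and fixes ties by averaging", {
  # hand oracle on a 3-gene pair: order-statistic means are
  # (0.25, 0.30, 0.45); the tied pair in A shares the mean of the first two
  ca <- calibrate_toms(list(make_sym(c(0.1, 0.1, 0.3)),
                            make_sym(c(0.4, 0.5, 0.6))))
  expect_equal(sort(ca[[1]][upper.tri(ca[[1]])]), c(0.275, 0.275, 0.45))
  expect_equal(sort(ca[[2]][upper.tri(ca[[2]])]), c(0.25, 0.30, 0.45))

  # identical inputs are a fixed point
  t1 <- topological_overlap(random_adjacency(12, seed = 3))
  cal <- calibrate_toms(list(t1, t1))
  expect_lt(max(abs(cal[[1]] - t1)), 1e-12)

  # post-calibration sorted upper triangles are identical across sets
  t2 <- topological_overlap(random_adjacency(12, seed = 9))
  dimnames(t2) <- dimnames(t1)
  cal2 <- calibrate_toms(list(t1, t2))
  expect_lt(max(abs(sort(cal2[[1]][upper.tri(t1)]) -
                    sort(cal2[[2]][upper.tri(t2)]))), 1e-12)

  # calibration preserves within-matrix ranks
  expect_identical(rank(t2[upper.tri(t2)]), rank(cal2[[2]][upper.tri(t2)]))

  t3 <- topological_overlap(random_adjacency(10, seed = 2))
  expect_error(calibrate_toms(list(t1, t3)), "identical gene set")
})

test_that("consensus TOM combines entries as stated", {
  t1 <- make_sym(c(0.2, 0.3, 0.4))
  t2 <- make_sym(c(0.4, 0.1, 0.6))
  expect_equal(consensus_tom(list(t1)), t1)
  cm <- consensus_tom(list(t1, t2))
  expect_equal(cm["a", "b"], 0.3)
  expect_equal(consensus_tom(list(t1, t1, t1)), t1)
  cmin <- consensus_tom(list(t1, t2), method = "min")
  expect_equal(cmin["a", "c"], 0.1)
  # bounded by per-entry min and max
  expect_true(all(cm >= pmin(t1, t2) - 1e-15 & cm <= pmax(t1, t2) + 1e-15))
  expect_error(consensus_tom(list()), "empty")
})

test_that("consensus network construction is permutation-equivariant", {
  fx <- generate_cohorts(sim_config(module_sizes = c(12L, 10L),
                                    concordance_rho = c(0.9, 0.8),
                                    n_genes_background = 20,
                                    n_tissue = 25, n_organoid_matched = 25,
                                    n_organoid_independent = 20, seed = 21))
  exprs <- fx[c("tissue", "organoid_matched")]
  toms <- lapply(exprs, function(e) topological_overlap(signed_adjacency(e, 6)))
  ct <- consensus_tom(calibrate_toms(toms))
  perm <- sample(nrow(ct))
  toms_p <- lapply(exprs, function(e) {
    topological_overlap(signed_adjacency(e[perm, ], 6))
  })
  ct_p <- consensus_tom(calibrate_toms(toms_p))
  expect_lt(max(abs(ct_p - ct[perm, perm])), 1e-12)

  # module detection invariant to gene order up to relabeling
  d1 <- detect_modules(ct, min_size = 8)
  d2 <- detect_modules(ct_p, min_size = 8)
  l1 <- setNames(d1$assignment$module, d1$assignment$gene)
  l2 <- setNames(d2$assignment$module, d2$assignment$gene)
  expect_equal(mclust::adjustedRandIndex(l1[names(l2)], l2), 1)
})

test_that("module detection honors the size rule and degenerate inputs", {
  # all genes mutually TOM = 1 -> one module holding everything
  n <- 40
  ct <- matrix(1, n, n, dimnames = list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n)))
  det <- detect_modules(ct, min_size = 30)
  expect_identical(unique(det$assignment$module), "turquoise")

  # 10 correlated genes among noise with min_size 30 end up grey
  set.seed(14)
  f <- rnorm(40)
  expr <- rbind(matrix(rep(f, each = 10), 10) + 0.1 * matrix(rnorm(400), 10),
                matrix(rnorm(50 * 40), 50))
  dimnames(expr) <- list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:40))
  tom <- topological_overlap(signed_adjacency(expr, 6))
  det2 <- detect_modules(tom, min_size = 30)
  expect_identical(unique(det2$assignment$module), "grey")
})

test_that("modules on the default fixture recover the planted structure", {
  fx <- default_fixture()
  net <- consensus_network(fx[c("tissue", "organoid_matched",
                                "organoid_independent")])
  expect_equal(length(net$sizes), 3L)
  tr <- fx$truth$modules
  lab <- net$modules$module[match(tr$gene, net$modules$gene)]
  expect_gte(mclust::adjustedRandIndex(lab, tr$module), 0.8)
  # static cut is available and collapses structure at this scale
  det_static <- detect_modules(net$consensus_tom, method = "static")
  expect_lte(length(det_static$sizes), 1L)
})

test_that("eigengenes equal the rank-one structure and the SVD oracle", {
  # all genes a common profile (zero noise): |cor(ME, profile)| = 1,
  # explained variance = 1, and the sign rule makes the correlation positive
  f <- rnorm(30)
  expr <- outer(c(1, 2, 0.5, -1), f)
  dimnames(expr) <- list(paste0("g", 1:4), paste0("s", 1:30))
  me <- module_eigengene(expr, setNames(rep("m1", 4), rownames(expr)))
  expect_equal(unname(me$var_explained), 1, tolerance = 1e-12)
  expect_equal(abs(cor(me$me["m1", ], f)), 1, tolerance = 1e-12)
  expect_gt(mean(cor(me$me["m1", ], t(expr))), 0)

  # random block: matches an independent eigen-decomposition oracle
  x <- random_expr(12, 18, seed = 6)
  me2 <- module_eigengene(x, setNames(rep("m1", 12), rownames(x)))
  z <- t(scale(t(x)))
  ev <- eigen(crossprod(z))$vectors[, 1]
  expect_gte(abs(cor(me2$me["m1", ], ev)), 1 - 1e-10)
  expect_equal(sqrt(sum(me2$me["m1", ]^2)), 1, tolerance = 1e-12)

  # zero-variance gene dropped with a warning
  x2 <- rbind(x, flat = rep(1, 18))
  expect_warning(module_eigengene(x2, setNames(rep("m1", 13), rownames(x2))),
                 "zero-variance")
})

test_that("kME is the gene-eigengene correlation and consensus is the mean", {
  f <- rnorm(25)
  expr <- rbind(g1 = f + 0.01 * rnorm(25), g2 = f + 0.3 * rnorm(25),
                g3 = rnorm(25))
  colnames(expr) <- paste0("s", 1:25)
  me <- module_eigengene(expr[1:2, ], setNames(c("m1", "m1"), c("g1", "g2")))
  k <- kme(expr, me)
  expect_equal(k["g1", "m1"], cor(expr["g1", ], me$me["m1", ]))
  expect_gt(k["g1", "m1"], 0.99)

  k1 <- matrix(0.6, 1, 1, dimnames = list("g", "m"))
  k2 <- matrix(0.7, 1, 1, dimnames = list("g", "m"))
  k3 <- matrix(0.8, 1, 1, dimnames = list("g", "m"))
  expect_equal(consensus_kme(list(k1, k2, k3))["g", "m"], 0.7)

  # constant gene -> NA with a warning
  exprc <- rbind(expr, flat = rep(2, 25))
  expect_warning(kc <- kme(exprc, me), "constant")
  expect_true(is.na(kc["flat", "m1"]))
})

test_that("consensus kME ranks genes like the planted loadings", {
  fx <- default_fixture()
  net <- consensus_network(fx[c("tissue", "organoid_matched",
                                "organoid_independent")])
  tr <- fx$truth$modules
  for (pm in c("M1", "M2", "M3")) {
    genes <- tr$gene[tr$module == pm]
    dm <- matched_label(genes, net$modules)
    lab <- setNames(net$modules$module, net$modules$gene)
    shared <- genes[lab[genes] == dm]
    rho <- cor(tr$loading[match(shared, tr$gene)],
               net$consensus_kme[shared, dm], method = "spearman")
    expect_gte(rho, 0.8)
  }
})
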