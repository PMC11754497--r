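# Signed weighted co-expression networks, topological overlap, quantile
# calibration across cohorts, consensus modules, eigengenes and kME.

#' Canonical module color sequence
#'
#' Color labels assigned to detected modules in decreasing size order;
#' `"grey"` is reserved for unassigned genes.
#'
#' @param n Number of labels wanted.
#' @return Character vector of length `n`.
#' @export
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen",
            "darkturquoise", "darkgrey", "orange", "darkorange", "white",
            "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
            "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen",
            "skyblue3", "plum1", "orangered4", "mediumpurple3")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("module%d", seq_len(n - length(base))))
}

#' Signed weighted adjacency matrix
#'
#' Computes the signed similarity `s_ij = (1 + cor(x_i, x_j)) / 2` (Pearson)
#' and raises it to the soft-thresholding power: `a_ij = s_ij ^ beta`. The
#' signed transform maps correlation -1 to adjacency 0 and +1 to 1, so
#' negatively correlated genes are never connected.
#'
#' @param expr Numeric matrix, genes x samples (>= 3 samples).
#' @param beta Soft-thresholding power (>= 1).
#' @return Symmetric matrix in `[0, 1]` with unit diagonal; the power used is
#'   stored in the `"beta"` attribute.
#' @export
signed_adjacency <- function(expr, beta = 12) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3, beta >= 1)
  v <- row_variances(expr)
  if (any(v == 0)) {
    abort(sprintf("constant gene(s) have undefined correlation: %s",
                  paste(head(rownames(expr)[v == 0], 5), collapse = ", ")))
  }
  r <- cor(t(expr))
  a <- ((1 + r) / 2)^beta
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  a <- (a + t(a)) / 2
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' For i != j, `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` (u distinct from i, j) and `k_i` is the
#' connectivity `sum_u a_iu` (u != i). Diagonal is 1. TOM rewards pairs that
#' share neighbors, making the similarity robust to single spurious
#' correlations.
#'
#' @param adjacency Symmetric adjacency matrix in `[0, 1]`, unit diagonal.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a           # with zero diagonal, u = i and u = j terms vanish
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  attributes(tom) <- list(dim = dim(adjacency),
                          dimnames = dimnames(adjacency))
  tom
}

#' Scale-free topology fit of a weighted network
#'
#' Bins the connectivities `k_i = sum_u a_iu` into `n_bins` equal-width bins
#' and regresses `log10(frequency)` on `log10(mean k)` over the non-empty
#' bins. A network approximating scale-free topology shows a strong linear
#' fit with negative slope.
#'
#' @param adjacency Adjacency matrix.
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return List with `r_squared` and `slope` of the log-log regression.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  stopifnot(nrow(adjacency) >= 2 * n_bins)
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  if (max(k) - min(k) < .Machine$double.eps^0.5) {
    abort("all connectivities are equal; scale-free fit is degenerate")
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(keep) < 2) abort("fewer than 2 usable connectivity bins")
  if (sum(keep) == 2) warn("only 2 non-empty bins: log-log fit is exact by construction")
  fit <- lm(log10(freq[keep]) ~ log10(kmean[keep]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(coef(fit)[2]))
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' Evaluates [scale_free_fit()] over a grid of powers and picks the smallest
#' power reaching `r2_target` with negative slope; if none qualifies, returns
#' the power with the best fit, with a warning. The pipeline default keeps a
#' fixed power of 12 for signed networks; this scan is the diagnostic.
#'
#' @param expr Genes x samples matrix.
#' @param beta_grid Candidate powers (default 1..20).
#' @param r2_target Fit threshold (default 0.75).
#' @param n_bins Bins for [scale_free_fit()].
#' @return List with `beta` (chosen power) and `scan`, a tibble of
#'   (beta, r_squared, slope).
#' @export
pick_soft_threshold <- function(expr, beta_grid = 1:20, r2_target = 0.75,
                                n_bins = 10) {
  stopifnot(length(beta_grid) >= 1)
  r <- cor(t(expr))
  s <- (1 + r) / 2
  scan <- purrr::map(beta_grid, function(b) {
    a <- s^b
    diag(a) <- 1
    fit <- scale_free_fit(a, n_bins = n_bins)
    tibble(beta = b, r_squared = fit$r_squared, slope = fit$slope)
  }) |> purrr::list_rbind()
  ok <- scan$r_squared >= r2_target & scan$slope < 0
  if (any(ok)) {
    beta <- scan$beta[which(ok)[1]]
  } else {
    beta <- scan$beta[which.max(scan$r_squared)]
    warn(sprintf("no power reaches R^2 >= %.2f; returning the best fit (beta = %d)",
                 r2_target, beta))
  }
  list(beta = beta, scan = scan)
}

upper_tri_values <- function(m) m[upper.tri(m)]

rebuild_symmetric <- function(values, template) {
  out <- template
  out[upper.tri(out)] <- values
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 1
  out
}

#' Calibrate TOMs across cohorts by full quantile normalization
#'
#' The upper-triangle entries of each TOM are quantile-normalized across
#' cohorts (each cohort's sorted values replaced by the across-cohort mean of
#' order statistics; ties receive the average of their would-be values), so
#' that all cohorts share the same TOM value distribution before the
#' consensus is taken. Symmetry and the unit diagonal are restored.
#'
#' @param toms List of >= 2 TOM matrices on identical gene sets.
#' @return List of calibrated TOMs, same names and dimnames.
#' @export
calibrate_toms <- function(toms) {
  stopifnot(is.list(toms), length(toms) >= 2)
  ids <- rownames(toms[[1]])
  same <- vapply(toms, function(t) identical(rownames(t), ids), logical(1))
  if (!all(same)) abort("TOMs must share an identical gene set and order")
  mat <- vapply(toms, upper_tri_values, numeric(sum(upper.tri(toms[[1]]))))
  normed <- limma::normalizeQuantiles(mat, ties = TRUE)
  out <- purrr::map2(seq_along(toms), toms,
                     function(j, t) rebuild_symmetric(normed[, j], t))
  names(out) <- names(toms)
  out
}

#' Consensus topological overlap
#'
#' Combines calibrated per-cohort TOMs entry-wise; the default operator is
#' the component-wise mean, with the component-wise minimum available.
#'
#' @param toms Non-empty list of TOMs on identical gene sets.
#' @param method `"mean"` (default) or `"min"`.
#' @return A single TOM matrix.
#' @export
consensus_tom <- function(toms, method = c("mean", "min")) {
  method <- match.arg(method)
  stopifnot(is.list(toms))
  if (length(toms) == 0) abort("empty TOM list")
  if (length(toms) == 1) return(toms[[1]])
  ids <- rownames(toms[[1]])
  if (!all(vapply(toms, function(t) identical(rownames(t), ids), logical(1)))) {
    abort("TOMs must share an identical gene set and order")
  }
  out <- switch(method,
                mean = Reduce(`+`, toms) / length(toms),
                min = Reduce(pmin, toms))
  diag(out) <- 1
  out
}

#' Detect modules on the consensus TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' `1 - consensus TOM`, followed by a tree cut; clusters smaller than
#' `min_size` are relabeled `"grey"`. Surviving modules are named by the
#' canonical color sequence in decreasing size order (ties broken by the
#' smallest member gene index, so labeling is deterministic).
#'
#' The default `"adaptive"` cut treats `cut_height` as an eligibility
#' ceiling and places the actual cut in the middle of the widest gap of the
#' merge-height sequence below that ceiling. Module-forming merges happen
#' well below the heights at which loosely connected noise genes attach, so
#' the widest gap separates the two regimes; a literal cut at 0.999 would
#' instead absorb low-connectivity genes, whose topological overlap with a
#' module is inflated by the `min(k) + 1` denominator, into every module.
#' When the merge heights show no gap (e.g. one homogeneous module), the cut
#' falls back to `cut_height` itself. `method = "static"` cuts at
#' `cut_height` exactly.
#'
#' @param ctom Consensus TOM matrix.
#' @param cut_height Dendrogram cut ceiling (default 0.999).
#' @param min_size Minimum module size (default 30).
#' @param method `"adaptive"` (default) or `"static"`, see Details.
#' @return List of class `module_detection` with `assignment` (tibble of
#'   gene, module), `dendrogram` (hclust), `sizes` (named vector), the cut
#'   actually used (`cut_used`) and the parameters.
#' @export
detect_modules <- function(ctom, cut_height = 0.999, min_size = 30,
                           method = c("adaptive", "static")) {
  method <- match.arg(method)
  stopifnot(is.matrix(ctom), nrow(ctom) == ncol(ctom))
  genes <- rownames(ctom)
  d <- as.dist(1 - ctom)
  dend <- hclust(d, method = "average")
  cut_used <- cut_height
  if (method == "adaptive") {
    hh <- sort(dend$height[dend$height < cut_height])
    if (length(hh) >= 2) {
      gaps <- diff(hh)
      i <- which.max(gaps)
      if (gaps[i] > 0) cut_used <- (hh[i] + hh[i + 1]) / 2
    }
  }
  raw <- cutree(dend, h = cut_used)
  tab <- table(raw)
  big <- names(tab)[tab >= min_size]
  # order surviving clusters by decreasing size; ties by first member index
  first_idx <- vapply(big, function(cl) min(which(raw == cl)), integer(1))
  ord <- big[order(-tab[big], first_idx)]
  labels <- setNames(module_colors(length(ord)), ord)
  module <- rep("grey", length(raw))
  hit <- raw %in% ord
  module[hit] <- labels[as.character(raw[hit])]
  assignment <- tibble(gene = genes, module = module)
  sizes <- sort(table(assignment$module[assignment$module != "grey"]),
                decreasing = TRUE)
  structure(list(assignment = assignment,
                 dendrogram = dend,
                 sizes = c(sizes),
                 cut_height = cut_height,
                 cut_used = cut_used,
                 min_size = min_size,
                 method = method),
            class = "module_detection")
}

as_module_vector <- function(modules) {
  if (is.data.frame(modules)) {
    setNames(modules$module, modules$gene)
  } else if (inherits(modules, "module_detection")) {
    setNames(modules$assignment$module, modules$assignment$gene)
  } else {
    stopifnot(!is.null(names(modules)))
    modules
  }
}

#' Module eigengenes
#'
#' Per module, gene profiles are standardized (mean 0, sd 1 across samples)
#' and the eigengene is the first right singular vector of the standardized
#' gene x sample block (unit Euclidean norm). The sign is fixed so that the
#' average correlation between the eigengene and the module's gene profiles
#' is positive, making results reproducible across platforms. `"grey"` is
#' skipped.
#'
#' @param expr Genes x samples matrix.
#' @param modules Module assignment: tibble (gene, module), named vector, or
#'   a [detect_modules()] result.
#' @return List with `me` (modules x samples matrix of eigengenes) and
#'   `var_explained` (named vector: fraction of standardized module variance
#'   captured by the eigengene).
#' @export
module_eigengene <- function(expr, modules) {
  mv <- as_module_vector(modules)
  mods <- setdiff(unique(mv), "grey")
  if (length(mods) == 0) abort("no non-grey module to summarize")
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- intersect(names(mv)[mv == m], rownames(expr))
    block <- expr[genes, , drop = FALSE]
    v <- row_variances(block)
    if (any(v == 0)) {
      warn(sprintf("module %s: dropping %d zero-variance gene(s)", m, sum(v == 0)))
      block <- block[v > 0, , drop = FALSE]
    }
    if (nrow(block) < 2) abort(sprintf("module %s has fewer than 2 usable genes", m))
    z <- t(scale(t(block)))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(cor(e, t(z))) < 0) e <- -e
    me[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(me = me, var_explained = ve)
}

#' Module membership (kME) within one cohort
#'
#' `kME(g, m)` is the Pearson correlation of gene g's profile with the module
#' m eigengene. Constant genes get `NA` (with a warning) and are excluded
#' from hub selection downstream.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Eigengene list from [module_eigengene()] or a modules x
#'   samples matrix.
#' @return Genes x modules matrix of correlations in `[-1, 1]`.
#' @export
kme <- function(expr, eigengenes) {
  me <- if (is.list(eigengenes)) eigengenes$me else eigengenes
  stopifnot(identical(colnames(expr), colnames(me)))
  v <- row_variances(expr)
  out <- matrix(NA_real_, nrow = nrow(expr), ncol = nrow(me),
                dimnames = list(rownames(expr), rownames(me)))
  ok <- v > 0
  if (any(!ok)) warn(sprintf("%d constant gene(s): kME recorded as NA", sum(!ok)))
  out[ok, ] <- cor(t(expr[ok, , drop = FALSE]), t(me))
  out
}

#' Consensus kME across cohorts
#'
#' Unweighted mean of per-cohort kME matrices (entries missing in a cohort
#' propagate as NA).
#'
#' @param kme_list List of genes x modules kME matrices with identical
#'   dimnames.
#' @return Matrix of the same shape.
#' @export
consensus_kme <- function(kme_list) {
  stopifnot(is.list(kme_list), length(kme_list) >= 1)
  dn <- dimnames(kme_list[[1]])
  if (!all(vapply(kme_list, function(k) identical(dimnames(k), dn), logical(1)))) {
    abort("kME tables must share genes and modules")
  }
  Reduce(`+`, kme_list) / length(kme_list)
}

#' Build a consensus co-expression network across cohorts
#'
#' End-to-end wrapper: per-cohort signed adjacency and TOM, full-quantile
#' calibration, component-wise consensus, static-cut module detection, and
#' per-cohort eigengenes, kME and consensus kME.
#'
#' @param exprs Named list of genes x samples matrices on an identical gene
#'   set (one entry per cohort). A single cohort is allowed, in which case
#'   calibration is a no-op and the consensus is the cohort's own TOM.
#' @param beta Soft-thresholding power (default 12).
#' @param cut_height,min_size See [detect_modules()].
#' @param consensus `"mean"` or `"min"` (see [consensus_tom()]).
#' @param cut_method `"adaptive"` or `"static"` (see [detect_modules()]).
#' @param keep_toms Keep the per-cohort calibrated TOMs in the result
#'   (default `FALSE`; the consensus TOM is always kept).
#' @return An object of class `consensus_network` with the module assignment,
#'   dendrogram, per-cohort eigengenes/kME and consensus kME.
#' @export
consensus_network <- function(exprs, beta = 12, cut_height = 0.999,
                              min_size = 30, consensus = c("mean", "min"),
                              cut_method = c("adaptive", "static"),
                              keep_toms = FALSE) {
  cut_method <- match.arg(cut_method)
  consensus <- match.arg(consensus)
  stopifnot(is.list(exprs), length(exprs) >= 1)
  if (is.null(names(exprs))) names(exprs) <- paste0("cohort", seq_along(exprs))
  ids <- rownames(exprs[[1]])
  if (!all(vapply(exprs, function(e) identical(rownames(e), ids), logical(1)))) {
    abort("all cohorts must share an identical gene set and order")
  }
  toms <- purrr::map(exprs, function(e) topological_overlap(signed_adjacency(e, beta)))
  cal <- if (length(toms) >= 2) calibrate_toms(toms) else toms
  ctom <- consensus_tom(cal, method = consensus)
  det <- detect_modules(ctom, cut_height = cut_height, min_size = min_size,
                        method = cut_method)
  has_modules <- any(det$assignment$module != "grey")
  if (has_modules) {
    mes <- purrr::map(exprs, module_eigengene, modules = det)
    kmes <- purrr::map2(exprs, mes, kme)
    ckme <- consensus_kme(kmes)
  } else {
    warn("no module survives the size filter; eigengenes not computed")
    mes <- kmes <- NULL
    ckme <- NULL
  }
  structure(list(cohorts = names(exprs),
                 genes = ids,
                 modules = det$assignment,
                 sizes = det$sizes,
                 dendrogram = det$dendrogram,
                 consensus_tom = ctom,
                 toms = if (keep_toms) cal else NULL,
                 eigengenes = mes,
                 kme = kmes,
                 consensus_kme = ckme,
                 params = list(beta = beta, cut_height = cut_height,
                               min_size = min_size, consensus = consensus)),
            class = "consensus_network")
}

#' @exportS3Method base::print
print.consensus_network <- function(x, ...) {
  cat(sprintf("Consensus co-expression network: %d genes, %d cohort(s) (%s)\n",
              length(x$genes), length(x$cohorts), paste(x$cohorts, collapse = ", ")))
  cat(sprintf("  beta = %g, cut height = %g, min size = %d, consensus = %s\n",
              x$params$beta, x$params$cut_height, x$params$min_size,
              x$params$consensus))
  n_grey <- sum(x$modules$module == "grey")
  cat(sprintf("  %d module(s) + grey (%d genes unassigned)\n",
              length(x$sizes), n_grey))
  if (length(x$sizes)) {
    cat("  sizes: ",
        paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  }
  invisible(x)
}
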