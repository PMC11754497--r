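# Independent oracles and small generators shared across the test files.

# triple-loop topological overlap, independent of the matrix-product route
brute_force_tom <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  m
}

# Benjamini-Hochberg step-up written from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exponential survival with uniform censoring; beta = log HR per unit of x
simulate_survival <- function(n, beta = 0, x = rnorm(n), base_rate = 0.05,
                              censor_max = 60) {
  t_ev <- rexp(n, base_rate * exp(beta * x))
  cens <- runif(n, 0, censor_max)
  list(x = x, time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
}

# Cox log partial likelihood (no ties assumed) for the grid-search oracle
cox_logpl <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small expression fixture: k genes x n samples with dimnames
random_expr <- function(k, n, seed = 1, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(k * n), k, n,
         dimnames = list(sprintf("%s%03d", prefix, 1:k), sprintf("s%03d", 1:n)))
}

# map a planted module label to the detected label with the largest overlap
matched_label <- function(planted_genes, assignment) {
  lab <- setNames(assignment$module, assignment$gene)
  tt <- table(lab[planted_genes])
  names(which.max(tt))
}

# top drug-module genes by planted loading
top_drug_genes <- function(truth, k = 5) {
  tr <- truth$modules
  tr$gene[order(-(tr$loading * (tr$module == truth$drug_module)))][seq_len(k)]
}
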