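# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive loops / direct combinatorial
# arithmetic rather than sharing code with R/.

# TOM by explicit triple loop over the shared-neighbour sum
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) L <- L + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      den <- min(ki, kj) + 1 - a[i, j]
      out[i, j] <- if (den == 0) 0 else (L + a[i, j]) / den
    }
  }
  out
}

# geNorm stability M: full pairwise log-ratio SD matrix, then row means
oracle_genorm_M <- function(x) {
  lx <- log2(x)
  n <- nrow(x)
  V <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) next
      r <- lx[j, ] - lx[k, ]
      V[j, k] <- sqrt(sum((r - mean(r))^2) / (ncol(x) - 1))
    }
  }
  stats::setNames(rowMeans(V, na.rm = TRUE), rownames(x))
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  min(1, sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))))
}

# exact two-sided McNemar by full enumeration of all 2^(b+c) discordance
# sequences (each discordant pair flips either way with probability 1/2)
oracle_mcnemar <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  seqs <- as.matrix(expand.grid(rep(list(0:1), n)))
  x <- rowSums(seqs)           # count of one discordance type per sequence
  min(1, 2 * mean(x <= min(b, c)))
}

# expression matrix with planted correlation blocks:
# genes in a block share a factor with cor = rho, background genes are noise
planted_block_expr <- function(block_sizes, n_bg, n_samples, rho,
                               seed = 1) {
  set.seed(seed)
  n_genes <- sum(block_sizes) + n_bg
  expr <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  idx <- 1
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n_samples)
    rows <- idx:(idx + block_sizes[b] - 1)
    expr[rows, ] <- sqrt(rho) * matrix(f, block_sizes[b], n_samples,
                                       byrow = TRUE) +
      sqrt(1 - rho) * expr[rows, ]
    idx <- idx + block_sizes[b]
  }
  rownames(expr) <- sprintf("g%03d", seq_len(n_genes))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  expr
}

# simulate -> normalize -> module-1 eigengene (ground-truth membership) ->
# paired t-test; returns p-value and estimated shift
m1_eigengene_test <- function(seed, delta, ...) {
  sim <- simulate_panel(simulation_config(seed = seed, delta = delta, ...))
  norm <- suppressWarnings(nanostring_normalize(sim$counts))
  expr <- expr_matrix(norm)
  m1 <- sim$truth$module_of_gene[sim$truth$module_of_gene == "M1"]
  me <- module_eigengenes(expr, m1)$values["M1", ]
  pat <- unique(sim$samples$patient)
  bl <- paste0(pat, "_BL")
  pg <- paste0(pat, "_PG")
  keep <- bl %in% names(me) & pg %in% names(me)
  tt <- paired_t(unname(me[bl[keep]]), unname(me[pg[keep]]))
  c(p = tt$p_value, shift = tt$estimate)
}

# recovery ARI of the full normalize -> network path against planted truth
recovery_ari <- function(seed, ...) {
  sim <- simulate_panel(simulation_config(seed = seed, ...))
  norm <- suppressWarnings(nanostring_normalize(sim$counts))
  net <- suppressWarnings(coexpression_network(expr_matrix(norm)))
  truth <- sim$truth$module_of_gene
  mclust::adjustedRandIndex(net$modules[names(truth)], truth)
}
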