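#' Gene-gene Pearson correlation matrix
#'
#' Correlations are computed across samples for every pair of genes. Genes
#' with zero variance (possible after flooring at the detection limit) get
#' all their correlations set to 0, with a warning.
#'
#' @param expr gene x sample numeric matrix (log2 scale), >= 3 samples.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3) stop("need >= 3 samples")
  v <- apply(expr, 1, stats::var)
  const <- v == 0 | !is.finite(v)
  cc <- matrix(0, nrow(expr), nrow(expr),
               dimnames = list(rownames(expr), rownames(expr)))
  ok <- which(!const)
  if (length(ok) > 0)
    cc[ok, ok] <- stats::cor(t(expr[ok, , drop = FALSE]))
  if (any(const)) {
    warning(sum(const), " zero-variance gene(s): correlations set to 0 (",
            paste(utils::head(rownames(expr)[const], 3), collapse = ", "), " ...)")
  }
  diag(cc) <- 1
  cc
}

#' Signed soft-threshold adjacency
#'
#' Maps correlation to edge weight as `((1 + cor) / 2)^beta`, so perfectly
#' anti-correlated genes are unconnected (weight 0) and perfectly correlated
#' genes fully connected (weight 1). The diagonal is forced to 1.
#'
#' @param cor_mat correlation matrix.
#' @param beta positive integer soft-threshold power.
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(cor_mat, beta = 8) {
  if (beta < 1) stop("`beta` must be >= 1")
  a <- ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' For a symmetric adjacency `a` with unit diagonal,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu * a_uj` over `u != i, j` and `k_i = sum_u a_iu` over
#' `u != i`; the diagonal is 1. A zero denominator yields `TOM_ij = 0`.
#'
#' @param adjacency symmetric adjacency matrix, entries in \[0, 1\].
#' @return TOM similarity matrix, entries in \[0, 1\], unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  diag(a) <- 1
  aa <- a %*% a
  # remove u = i and u = j terms: (A^2)_ij includes a_ii*a_ij + a_ij*a_jj = 2 a_ij
  L <- aa - 2 * a
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  tom <- (L + a) / denom
  tom[denom == 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules by static dendrogram cut
#'
#' Genes are clustered hierarchically (average linkage) on the dissimilarity
#' `1 - TOM`; the dendrogram is cut at a fixed height and the resulting
#' groups with at least `min_module_size` genes become modules, labelled
#' `M1, M2, ...` by decreasing size (ties broken by first gene index).
#' Genes in smaller groups get the label `"unassigned"`.
#'
#' @param tom TOM similarity matrix from [tom_similarity()].
#' @param min_module_size smallest group size kept as a module.
#' @param cut_height static cut height on the `1 - TOM` dissimilarity scale,
#'   in (0, 1].
#' @return List with `modules` (named gene -> label vector), `dendrogram`
#'   (the `hclust` object) and `sizes` (named module sizes, decreasing).
#' @export
detect_modules <- function(tom, min_module_size = 10, cut_height = 0.5) {
  if (cut_height <= 0 || cut_height > 1) stop("`cut_height` must be in (0, 1]")
  genes <- rownames(tom)
  modules <- stats::setNames(rep("unassigned", nrow(tom)), genes)
  if (nrow(tom) < 2) {
    return(list(modules = modules, dendrogram = NULL,
                sizes = integer(0)))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  groups <- stats::cutree(hc, h = cut_height)
  sizes <- table(groups)
  big <- names(sizes)[sizes >= min_module_size]
  if (length(big) > 0) {
    first_idx <- vapply(big, function(g) min(which(groups == g)), numeric(1))
    big <- big[order(-as.integer(sizes[big]), first_idx)]
    for (i in seq_along(big))
      modules[groups == big[i]] <- paste0("M", i)
  }
  kept_sizes <- table(modules[modules != "unassigned"])
  kept_sizes <- kept_sizes[order(as.integer(sub("M", "", names(kept_sizes))))]
  list(modules = modules, dendrogram = hc,
       sizes = stats::setNames(as.integer(kept_sizes), names(kept_sizes)))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression: each member gene is z-scored across samples and
#' the first left singular vector of the samples x genes submatrix is taken.
#' Eigengenes have unit Euclidean norm across samples and are sign-aligned
#' so that their correlation with the module's mean standardized expression
#' is non-negative. The fraction of variance explained by the first
#' component is reported per module.
#'
#' @param expr gene x sample log2 expression matrix.
#' @param modules named gene -> module-label vector (label `"unassigned"` is
#'   skipped), e.g. from [detect_modules()].
#' @return List with `values` (module x sample eigengene matrix) and
#'   `variance_explained` (named numeric in \[0, 1\]).
#' @export
module_eigengenes <- function(expr, modules) {
  labels <- setdiff(unique(modules), "unassigned")
  labels <- labels[order(match(labels, modules))]
  if (length(labels) == 0) stop("no modules to summarize")
  me <- matrix(NA_real_, length(labels), ncol(expr),
               dimnames = list(labels, colnames(expr)))
  ve <- stats::setNames(numeric(length(labels)), labels)
  for (lab in labels) {
    genes <- names(modules)[modules == lab]
    if (!all(genes %in% rownames(expr)))
      stop("module genes missing from expression matrix")
    z <- t(scale(t(expr[genes, , drop = FALSE])))
    z[!is.finite(z)] <- 0          # zero-variance member contributes nothing
    sv <- svd(t(z), nu = 1, nv = 0)
    u1 <- sv$u[, 1]
    d2 <- sv$d^2
    ve[lab] <- if (sum(d2) > 0) d2[1] / sum(d2) else 0
    mean_profile <- colMeans(z)
    if (stats::sd(mean_profile) > 0 && stats::sd(u1) > 0 &&
        stats::cor(u1, mean_profile) < 0)
      u1 <- -u1
    me[lab, ] <- u1
  }
  list(values = me, variance_explained = ve)
}

#' Scale-free topology fit from a connectivity vector
#'
#' Bins the connectivities into `n_bins` equal-width bins, regresses
#' `log10(frequency)` on `log10(mean connectivity)` over non-empty bins and
#' returns the R-squared of that fit; `signed_r_squared` carries the sign of
#' the slope (scale-free networks have negative slope). Degenerate input
#' (constant connectivity, or fewer than 3 usable bins) returns 0 with a
#' warning.
#'
#' @param k numeric vector of node connectivities.
#' @param n_bins number of bins.
#' @return List with `r_squared`, `signed_r_squared` and `slope`.
#' @export
scale_free_index <- function(k, n_bins = 10) {
  if (diff(range(k)) == 0) {
    warning("constant connectivity: scale-free fit degenerate, returning 0")
    return(list(r_squared = 0, signed_r_squared = 0, slope = NA_real_))
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  km <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & km > 0
  if (sum(ok) < 3) {
    warning("fewer than 3 usable connectivity bins, returning 0")
    return(list(r_squared = 0, signed_r_squared = 0, slope = NA_real_))
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(km[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(r_squared = r2, signed_r_squared = r2 * sign(slope), slope = slope)
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Computes node connectivities `k_i = sum_{u != i} a_iu` and delegates to
#' [scale_free_index()].
#'
#' @param adjacency adjacency matrix.
#' @param n_bins number of connectivity bins.
#' @return See [scale_free_index()].
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- rowSums(adjacency) - diag(adjacency)
  scale_free_index(k, n_bins = n_bins)
}

#' Fit a signed weighted co-expression network
#'
#' The core model of the package: from a log2 expression matrix it computes
#' the gene-gene Pearson correlation matrix, the signed soft-threshold
#' adjacency `((1 + cor)/2)^beta`, the topological overlap matrix, an
#' average-linkage dendrogram on `1 - TOM` cut statically at `cut_height`,
#' module eigengenes (first principal components) and the scale-free
#' topology fit. Zero-variance genes are excluded from network construction
#' (with a warning) and reported as unassigned.
#'
#' @param expr gene x sample log2 expression matrix (e.g. from
#'   [expr_matrix()]).
#' @param beta signed soft-threshold power.
#' @param min_module_size smallest gene group kept as a module.
#' @param cut_height static dendrogram cut height on the `1 - TOM` scale.
#' @param n_bins connectivity bins for the scale-free fit.
#' @return An object of class `coexpr_net` with components `modules` (named
#'   gene -> label vector over all input genes), `module_sizes`,
#'   `eigengenes`, `variance_explained`, `dendrogram`, `correlations`,
#'   `adjacency`, `tom`, `scale_free`, `excluded_genes` and `params`.
#'   Methods: `print`, `summary`, `plot` (dendrogram with module bar).
#' @examples
#' sim <- simulate_panel(simulation_config(seed = 1))
#' norm <- nanostring_normalize(sim$counts)
#' net <- coexpression_network(expr_matrix(norm))
#' net
#' @export
coexpression_network <- function(expr, beta = 8, min_module_size = 10,
                                 cut_height = 0.5, n_bins = 10) {
  v <- apply(expr, 1, stats::var)
  excluded <- rownames(expr)[v == 0 | !is.finite(v)]
  use <- setdiff(rownames(expr), excluded)
  if (length(excluded) > 0)
    warning(length(excluded),
            " zero-variance gene(s) excluded from network construction")
  if (length(use) < 3) stop("need >= 3 genes with nonzero variance")
  cc <- correlation_matrix(expr[use, , drop = FALSE])
  adj <- signed_adjacency(cc, beta = beta)
  tom <- tom_similarity(adj)
  det <- detect_modules(tom, min_module_size = min_module_size,
                        cut_height = cut_height)
  modules <- stats::setNames(rep("unassigned", nrow(expr)), rownames(expr))
  modules[names(det$modules)] <- det$modules
  me <- if (length(det$sizes) > 0)
    module_eigengenes(expr[use, , drop = FALSE], det$modules)
  else list(values = NULL, variance_explained = NULL)
  sf <- scale_free_fit(adj, n_bins = n_bins)
  structure(list(modules = modules,
                 module_sizes = det$sizes,
                 eigengenes = me$values,
                 variance_explained = me$variance_explained,
                 dendrogram = det$dendrogram,
                 correlations = cc,
                 adjacency = adj,
                 tom = tom,
                 scale_free = sf,
                 excluded_genes = excluded,
                 params = list(beta = beta, min_module_size = min_module_size,
                               cut_height = cut_height)),
            class = "coexpr_net")
}

#' @export
print.coexpr_net <- function(x, ...) {
  cat("Signed co-expression network (beta =", x$params$beta, ")\n")
  cat("  ", length(x$modules), "genes;",
      length(x$module_sizes), "modules:",
      if (length(x$module_sizes) > 0)
        paste(sprintf("%s(%d)", names(x$module_sizes), x$module_sizes),
              collapse = " ") else "none",
      ";", sum(x$modules == "unassigned"), "unassigned\n")
  cat("  scale-free fit R^2 =", sprintf("%.3f", x$scale_free$r_squared),
      "(signed", sprintf("%.3f", x$scale_free$signed_r_squared), ")\n")
  invisible(x)
}

#' @export
summary.coexpr_net <- function(object, ...) {
  out <- list(n_genes = length(object$modules),
              module_sizes = object$module_sizes,
              variance_explained = object$variance_explained,
              scale_free = object$scale_free,
              excluded_genes = object$excluded_genes,
              params = object$params)
  class(out) <- "summary.coexpr_net"
  out
}

#' @export
print.summary.coexpr_net <- function(x, ...) {
  cat("Co-expression network:", x$n_genes, "genes, parameters beta =",
      x$params$beta, ", min module size =", x$params$min_module_size,
      ", cut height =", x$params$cut_height, "\n")
  if (length(x$module_sizes) > 0) {
    cat("Modules:\n")
    for (m in names(x$module_sizes))
      cat(sprintf("  %s: %d genes, eigengene variance explained %.2f\n",
                  m, x$module_sizes[m], x$variance_explained[m]))
  } else cat("No modules detected\n")
  if (length(x$excluded_genes) > 0)
    cat("Excluded (zero variance):", length(x$excluded_genes), "genes\n")
  cat(sprintf("Scale-free fit: R^2 = %.3f, slope = %.2f\n",
              x$scale_free$r_squared, x$scale_free$slope))
  invisible(x)
}

#' @param x a `coexpr_net` object.
#' @param ... passed to [plot.hclust()].
#' @rdname coexpression_network
#' @export
plot.coexpr_net <- function(x, ...) {
  if (is.null(x$dendrogram)) {
    warning("no dendrogram to plot")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(1, 4, 3, 1))
  on.exit(graphics::par(op))
  plot(x$dendrogram, labels = FALSE, hang = -1,
       main = "Gene dendrogram (1 - TOM)", xlab = "", sub = "", ...)
  graphics::abline(h = x$params$cut_height, lty = 2, col = "grey40")
  ord <- x$dendrogram$labels[x$dendrogram$order]
  lab <- x$modules[ord]
  cols <- c(unassigned = "grey80",
            stats::setNames(grDevices::hcl.colors(max(1, length(x$module_sizes)),
                                                  "Dark 3"),
                            names(x$module_sizes)))
  graphics::points(seq_along(ord), rep(-0.02, length(ord)),
                   col = cols[lab], pch = 15, cex = 0.5, xpd = NA)
  invisible(x)
}

#' Write a dendrogram as a Newick tree
#'
#' Exports an `hclust` dendrogram (gene or sample tree) to Newick format
#' with branch lengths derived from merge heights.
#'
#' @param hc an `hclust` object (e.g. `net$dendrogram`).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
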