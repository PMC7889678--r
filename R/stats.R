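#' Paired t-test on baseline/progression values
#'
#' Tests the per-patient differences `progression - baseline` against zero
#' with a two-sided Student t-test on n - 1 degrees of freedom. When both
#' vectors are named, they are aligned by patient name first.
#'
#' @param baseline,progression numeric vectors of matched per-patient values
#'   (same length, >= 2; if named, names must agree as sets).
#' @return List of class `panel_test` with `statistic` (t), `df`, `p_value`,
#'   `estimate` (mean difference), `n` and `method`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 3, 5))  # t = 4, df = 2
#' @export
paired_t <- function(baseline, progression) {
  if (!is.null(names(baseline)) && !is.null(names(progression))) {
    if (!setequal(names(baseline), names(progression)))
      stop("baseline and progression patients differ")
    progression <- progression[names(baseline)]
  }
  if (length(baseline) != length(progression))
    stop("baseline and progression must have equal length")
  n <- length(baseline)
  if (n < 2) stop("need >= 2 pairs")
  d <- progression - baseline
  if (stats::sd(d) == 0)
    stop("degenerate paired differences (zero variance)")
  ht <- stats::t.test(progression, baseline, paired = TRUE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, estimate = mean(d), n = n,
                 method = "paired t-test"),
            class = "panel_test")
}

#' @export
print.panel_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic))
    cat("  statistic =", format(x$statistic, digits = 5),
        if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", format(x$df)),
        "\n")
  cat("  p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Sorts the p-values ascending and sets
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotonicity by a
#' running maximum, caps at 1 and returns the values in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg FDR-adjusted p-values (q-values)
#'
#' Standard step-up procedure: `q_(i) = min_{j >= i} p_(j) * m / j`, capped
#' at 1, returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson chi-square test on a contingency table
#'
#' Classic chi-square of independence without continuity correction (the
#' panel convention for 2x2 tables); Yates' correction is available behind
#' the `yates` flag.
#'
#' @param counts r x c matrix of non-negative integer counts.
#' @param yates apply the continuity correction (2x2 only).
#' @return `panel_test` list with `statistic` (chi-square), `df`, `p_value`.
#' @examples
#' pearson_chi2(matrix(c(4, 1, 7, 17), 2))  # p = 0.0331
#' @export
pearson_chi2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 method = paste0("Pearson chi-square",
                                 if (yates) " (Yates-corrected)" else
                                   " (no continuity correction)")),
            class = "panel_test")
}

#' Exact McNemar test from discordant pair counts
#'
#' Exact binomial version of McNemar's test for paired binary outcomes: with
#' `b` and `c` the two discordant counts, the two-sided p-value is
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`;
#' `b + c = 0` gives p = 1. The chi-square approximation (without continuity
#' correction) is available with `exact = FALSE`.
#'
#' @param b,c non-negative discordant pair counts (e.g. positive -> negative
#'   and negative -> positive status flips).
#' @param exact use the exact binomial test (default) rather than the
#'   chi-square approximation.
#' @return `panel_test` list with `p_value`, discordant counts and method.
#' @examples
#' mcnemar_test(b = 10, c = 3)  # p = 0.0923
#' @export
mcnemar_test <- function(b, c, exact = TRUE) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("discordant counts must be non-negative integers")
  n <- b + c
  if (exact) {
    p <- if (n == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    structure(list(statistic = NULL, df = NULL, p_value = p,
                   b = b, c = c, method = "exact McNemar test (binomial)"),
              class = "panel_test")
  } else {
    if (n == 0)
      return(structure(list(statistic = 0, df = 1, p_value = 1, b = b, c = c,
                            method = "McNemar chi-square test"),
                       class = "panel_test"))
    stat <- (b - c)^2 / n
    structure(list(statistic = stat, df = 1,
                   p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                   b = b, c = c, method = "McNemar chi-square test"),
              class = "panel_test")
  }
}

#' Unsupervised hierarchical clustering of samples
#'
#' Genes are z-scored across samples ("centred and scaled per row"),
#' samples are clustered on Euclidean distance with average linkage, and the
#' dendrogram is cut into `k` groups. Zero-variance genes are dropped with a
#' warning. Cluster labels are assigned deterministically in order of first
#' appearance.
#'
#' @param expr gene x sample log2 expression matrix.
#' @param k number of sample groups.
#' @param scale_genes z-score each gene before clustering.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return An object of class `sample_clustering`: list with `labels` (named
#'   integer vector), `dendrogram` (`hclust`) and `leaf_order` (sample IDs
#'   in dendrogram order).
#' @export
cluster_samples <- function(expr, k = 2, scale_genes = TRUE,
                            linkage = "average") {
  if (k > ncol(expr)) stop("k exceeds the number of samples")
  z <- expr
  if (scale_genes) {
    v <- apply(expr, 1, stats::var)
    drop <- v == 0 | !is.finite(v)
    if (any(drop)) {
      warning(sum(drop), " zero-variance gene(s) dropped before clustering")
      z <- z[!drop, , drop = FALSE]
    }
    z <- t(scale(t(z)))
  }
  hc <- stats::hclust(stats::dist(t(z)), method = linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, dendrogram = hc,
                 leaf_order = hc$labels[hc$order]),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Sample clustering:", length(x$labels), "samples in",
      length(unique(x$labels)), "groups (sizes",
      paste(table(x$labels), collapse = "/"), ")\n")
  invisible(x)
}

#' Identify paired samples clustering as immediate neighbours
#'
#' A baseline/progression pair is called a "neighbour" pair when its two
#' samples form a two-leaf clade of the sample dendrogram, i.e. they merge
#' with each other before either merges with any other sample.
#'
#' @param hc sample dendrogram (`hclust`), e.g. from [cluster_samples()].
#' @param baseline,progression character vectors of matched sample IDs.
#' @return Logical vector, one entry per pair.
#' @export
neighbour_pairs <- function(hc, baseline, progression) {
  stopifnot(inherits(hc, "hclust"), length(baseline) == length(progression))
  missing <- setdiff(c(baseline, progression), hc$labels)
  if (length(missing) > 0)
    stop("samples not in dendrogram: ", paste(missing, collapse = ", "))
  mm <- hc$merge
  cherry <- mm[mm[, 1] < 0 & mm[, 2] < 0, , drop = FALSE]
  cherry_keys <- apply(cherry, 1, function(r) {
    paste(sort(hc$labels[abs(r)]), collapse = "\r")
  })
  keys <- mapply(function(b, p) paste(sort(c(b, p)), collapse = "\r"),
                 baseline, progression)
  unname(keys %in% cherry_keys)
}

#' Contingency analyses of paired samples across a two-group clustering
#'
#' Cross-tabulates each pair's (baseline cluster, progression cluster) into
#' a 2x2 table whose discordant counts feed the exact McNemar test of
#' marginal homogeneity (do progression samples move cluster?). If a
#' dendrogram and a per-pair treatment arm are supplied, neighbour-pair
#' calls (see [neighbour_pairs()]) are cross-tabulated against arm and
#' tested with the Pearson chi-square.
#'
#' @param clustering a [cluster_samples()] result with `k = 2` (or a named
#'   label vector with two levels).
#' @param baseline,progression matched sample ID vectors (one entry per
#'   patient pair).
#' @param arm optional per-pair treatment arm (factor/character).
#' @return List with `cluster_table` (2x2 baseline x progression),
#'   `mcnemar` (`panel_test`), `neighbours` (logical per pair or `NULL`),
#'   `arm_table` and `arm_chi2` (or `NULL` when `arm` is not supplied).
#' @export
paired_cluster_contingency <- function(clustering, baseline, progression,
                                       arm = NULL) {
  labels <- if (inherits(clustering, "sample_clustering"))
    clustering$labels else clustering
  hc <- if (inherits(clustering, "sample_clustering"))
    clustering$dendrogram else NULL
  if (length(unique(labels)) != 2)
    stop("paired contingency requires a two-group clustering")
  missing <- setdiff(c(baseline, progression), names(labels))
  if (length(missing) > 0)
    stop("samples without cluster labels: ", paste(missing, collapse = ", "))
  lv <- sort(unique(labels))
  bl <- factor(labels[baseline], levels = lv)
  pg <- factor(labels[progression], levels = lv)
  tab <- table(baseline = bl, progression = pg)
  mc <- mcnemar_test(b = tab[1, 2], c = tab[2, 1])

  neighbours <- arm_table <- arm_chi2 <- NULL
  if (!is.null(arm) && !is.null(hc)) {
    neighbours <- neighbour_pairs(hc, baseline, progression)
    arm_table <- table(arm = arm,
                       neighbour = factor(neighbours, levels = c(TRUE, FALSE)))
    if (all(rowSums(arm_table) > 0) && all(colSums(arm_table) > 0))
      arm_chi2 <- pearson_chi2(unclass(arm_table))
  }
  list(cluster_table = tab, mcnemar = mc, neighbours = neighbours,
       arm_table = arm_table, arm_chi2 = arm_chi2)
}
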