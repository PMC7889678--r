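#' Per-sample background threshold from negative controls
#'
#' Background noise of a hybridization panel is estimated per sample from the
#' negative-control (orphan) probes as mean + 2 standard deviations (sample
#' SD, n - 1 denominator).
#'
#' @param neg numeric vector of one sample's negative-control counts, or a
#'   matrix (negative probes x samples).
#' @return A single threshold for a vector input, or a named per-sample
#'   vector for a matrix input.
#' @examples
#' background_threshold(c(2, 4, 6))  # mean 4, sd 2 -> 8
#' @export
background_threshold <- function(neg) {
  if (is.matrix(neg)) {
    if (nrow(neg) < 2)
      stop("need >= 2 negative-control probes (SD undefined)")
    return(apply(neg, 2, function(x) mean(x) + 2 * stats::sd(x)))
  }
  if (length(neg) < 2)
    stop("need >= 2 negative-control probes (SD undefined)")
  mean(neg) + 2 * stats::sd(neg)
}

#' Background-correct panel counts
#'
#' Subtracts the per-sample background threshold from the endogenous and
#' normalization-candidate probes; corrected values below 1 are floored at 1
#' (so subsequent log2 values are >= 0). Control probes are excluded from the
#' output.
#'
#' @param counts a [raw_counts] object.
#' @param thresholds named per-sample thresholds from [background_threshold()].
#' @return Numeric matrix (endogenous + norm_candidate probes x samples) of
#'   corrected counts, all >= 1.
#' @export
apply_background <- function(counts, thresholds) {
  stopifnot(inherits(counts, "raw_counts"))
  s <- colnames(counts$values)
  if (!all(s %in% names(thresholds)))
    stop("thresholds missing for some samples")
  keep <- probes_of_class(counts, c("endogenous", "norm_candidate"))
  corrected <- sweep(counts$values[keep, , drop = FALSE], 2, thresholds[s])
  corrected[corrected < 1] <- 1
  corrected
}

#' Detection calls for endogenous probes
#'
#' A probe is called detected in a sample when its raw count strictly exceeds
#' that sample's background threshold.
#'
#' @inheritParams apply_background
#' @return Logical matrix (endogenous probes x samples); `TRUE` = detected.
#' @export
detection_calls <- function(counts, thresholds) {
  stopifnot(inherits(counts, "raw_counts"))
  s <- colnames(counts$values)
  if (!all(s %in% names(thresholds)))
    stop("thresholds missing for some samples")
  endo <- probes_of_class(counts, "endogenous")
  sweep(counts$values[endo, , drop = FALSE], 2, thresholds[s], `>`)
}

#' geNorm stability ranking of candidate reference genes
#'
#' Implements the geNorm gene-stability measure: for candidates j, k the
#' pairwise variation `V_jk` is the SD over samples of `log2(x_j / x_k)`, and
#' the stability `M_j` is the mean of `V_jk` over all other candidates. The
#' least stable candidate (highest M) is removed iteratively until two
#' remain; ties in M are broken by probe-ID lexicographic order. The
#' pairwise variation
#' `V_{n,n+1}` for n = 2..K-1 is the SD over samples of
#' `log2(NF_n / NF_{n+1})`, where `NF_n(s)` is the geometric mean of the n
#' most stable candidates in sample s.
#'
#' @param x candidate x sample matrix of strictly positive linear-scale
#'   expression (background-corrected counts).
#' @return An object of class `genorm`: list with `stability_M` (full-set M
#'   per candidate), `ranking` (most stable first), `elimination_order`
#'   (least stable first), and `V` (named vector, `V["2:3"]` = V_{2,3}, ...).
#' @references Vandesompele et al. (2002) Genome Biology 3:research0034,
#'   the geNorm method.
#' @export
genorm_rank <- function(x) {
  if (!is.matrix(x) || nrow(x) < 3) stop("need >= 3 candidates")
  if (ncol(x) < 2) stop("need >= 2 samples")
  if (any(x <= 0)) stop("candidate expression must be strictly positive")
  if (is.null(rownames(x))) rownames(x) <- sprintf("C%02d", seq_len(nrow(x)))
  lx <- log2(x)
  M_of <- function(ids) {
    vapply(ids, function(j) {
      mean(vapply(setdiff(ids, j),
                  function(k) stats::sd(lx[j, ] - lx[k, ]), numeric(1)))
    }, numeric(1))
  }
  all_ids <- rownames(x)
  stability_M <- M_of(all_ids)

  remaining <- all_ids
  elim <- character(0)
  last_M <- NULL
  while (length(remaining) > 2) {
    M <- M_of(remaining)
    worst <- remaining[order(M, remaining, decreasing = c(TRUE, FALSE),
                             method = "radix")][1]
    elim <- c(elim, worst)
    last_M <- M
    remaining <- setdiff(remaining, worst)
  }
  # order the two survivors by their M in the last 3-candidate round
  # (they share identical pairwise M with each other once alone); ties by ID
  if (!is.null(last_M)) {
    mm <- last_M[remaining]
    remaining <- remaining[order(mm, remaining, method = "radix")]
  } else {
    remaining <- sort(remaining)
  }
  ranking <- c(remaining, rev(elim))

  K <- length(all_ids)
  V <- numeric(0)
  if (K >= 3) {
    nf <- function(n) apply(lx[ranking[seq_len(n)], , drop = FALSE], 2, mean)
    for (n in 2:(K - 1)) {
      V[sprintf("%d:%d", n, n + 1)] <- stats::sd(nf(n) - nf(n + 1))
    }
  }
  structure(list(stability_M = stability_M, ranking = ranking,
                 elimination_order = elim, V = V),
            class = "genorm")
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm ranking (most stable first):",
      paste(x$ranking, collapse = " > "), "\n")
  cat("stability M:",
      paste(sprintf("%s=%.3f", names(x$stability_M), x$stability_M),
            collapse = ", "), "\n")
  if (length(x$V) > 0)
    cat("pairwise variation V:",
        paste(sprintf("V%s=%.3f", names(x$V), x$V), collapse = ", "), "\n")
  invisible(x)
}

#' Select reference genes from a geNorm ranking
#'
#' Starts from the two most stable candidates and adds the next candidate in
#' stability order while `V_{n,n+1} >= v_cutoff`, stopping at the first n
#' with `V < v_cutoff` (adding the (n+1)-th gene is then unnecessary).
#'
#' @param result a [genorm_rank()] result.
#' @param v_cutoff pairwise-variation cutoff (geNorm convention 0.15).
#' @param n_ref_genes optional override: take exactly the top-n most stable
#'   candidates, ignoring V.
#' @return Character vector of selected reference genes (>= 2).
#' @export
genorm_select <- function(result, v_cutoff = 0.15, n_ref_genes = NULL) {
  stopifnot(inherits(result, "genorm"))
  K <- length(result$ranking)
  if (!is.null(n_ref_genes)) {
    if (n_ref_genes < 2 || n_ref_genes > K)
      stop("`n_ref_genes` must be between 2 and the number of candidates")
    return(result$ranking[seq_len(n_ref_genes)])
  }
  n <- 2L
  while (n < K && result$V[sprintf("%d:%d", n, n + 1)] >= v_cutoff)
    n <- n + 1L
  result$ranking[seq_len(n)]
}

#' Geometric-mean normalization of background-corrected counts
#'
#' The normalization factor `NF_s` of sample s is the geometric mean of the
#' selected reference genes' corrected counts in that sample. Each sample is
#' scaled by `mean_NF / NF_s` (where `mean_NF` is the geometric mean of the
#' `NF_s` across samples, so the overall scale is preserved), floored at 1,
#' and log2-transformed.
#'
#' @param corrected matrix from [apply_background()] (includes the reference
#'   genes).
#' @param ref_genes character vector of selected reference genes.
#' @return List with `values` (log2 matrix, all >= 0), `normalization_factors`
#'   (per-sample `NF_s`) and `scale_factors` (per-sample multipliers).
#' @export
normalize_counts <- function(corrected, ref_genes) {
  if (!all(ref_genes %in% rownames(corrected)))
    stop("reference genes missing from corrected matrix")
  nf <- apply(corrected[ref_genes, , drop = FALSE], 2, geometric_mean)
  scale_factors <- geometric_mean(nf) / nf
  scaled <- sweep(corrected, 2, scale_factors, `*`)
  scaled[scaled < 1] <- 1
  list(values = log2(scaled),
       normalization_factors = nf,
       scale_factors = scale_factors)
}

#' Sample quality filter on detection fraction
#'
#' Samples in which more than `max_undetected_fraction` of the endogenous
#' probes are undetected are removed (strict ">" removal: a sample at exactly
#' the boundary is kept).
#'
#' @param detection logical detection matrix from [detection_calls()].
#' @param max_undetected_fraction maximal tolerated undetected fraction.
#' @return Character vector of kept sample IDs.
#' @export
qc_filter_samples <- function(detection, max_undetected_fraction = 0.5) {
  undetected <- colMeans(!detection)
  colnames(detection)[undetected <= max_undetected_fraction]
}

#' Normalize a raw panel count matrix
#'
#' Full normalization pipeline for nCounter-style panel data:
#' \enumerate{
#'   \item per-sample background threshold = negative-control mean + 2 SD;
#'   \item threshold subtracted from endogenous and candidate probes, values
#'     below 1 floored at 1;
#'   \item geNorm stability ranking of the candidate reference genes on the
#'     background-corrected linear-scale values, selection by the V < 0.15
#'     stopping rule (or a fixed `n_ref_genes`);
#'   \item per-sample scaling by the geometric mean of the selected
#'     reference genes; floor at 1; log2 transform;
#'   \item detection calls (raw count > threshold) and removal of samples
#'     with more than `max_undetected` undetected endogenous probes.
#' }
#' Positive controls are summarized (per-sample sums) but take no part in
#' normalization.
#'
#' @param raw a [raw_counts] object.
#' @param v_cutoff geNorm pairwise-variation cutoff.
#' @param max_undetected maximal tolerated undetected fraction per sample.
#' @param n_ref_genes optional fixed number of reference genes.
#' @return An object of class `nanostring_norm`: list with `values` (log2
#'   gene x sample matrix over endogenous + candidate probes, all samples),
#'   `detection` (logical matrix), `thresholds`, `genorm`, `reference_genes`,
#'   `normalization_factors`, `kept_samples`, `positive_control_sums` and
#'   `probe_class`.
#' @seealso [expr_matrix()] to extract the analysis-ready endogenous block.
#' @examples
#' sim <- simulate_panel(simulation_config(seed = 3))
#' norm <- nanostring_normalize(sim$counts)
#' norm
#' @export
nanostring_normalize <- function(raw, v_cutoff = 0.15, max_undetected = 0.5,
                                 n_ref_genes = NULL) {
  stopifnot(inherits(raw, "raw_counts"))
  neg <- raw$values[probes_of_class(raw, "negative"), , drop = FALSE]
  thresholds <- background_threshold(neg)
  corrected <- apply_background(raw, thresholds)
  detection <- detection_calls(raw, thresholds)

  candidates <- probes_of_class(raw, "norm_candidate")
  if (length(candidates) < 3)
    stop("need >= 3 normalization candidates for geNorm")
  gn <- genorm_rank(corrected[candidates, , drop = FALSE])
  ref_genes <- genorm_select(gn, v_cutoff = v_cutoff, n_ref_genes = n_ref_genes)
  nrm <- normalize_counts(corrected, ref_genes)

  kept <- qc_filter_samples(detection, max_undetected)
  pos <- raw$values[probes_of_class(raw, "positive"), , drop = FALSE]
  pos_sums <- if (nrow(pos) > 0) colSums(pos) else NULL

  structure(list(values = nrm$values,
                 detection = detection,
                 thresholds = thresholds,
                 genorm = gn,
                 reference_genes = ref_genes,
                 normalization_factors = nrm$normalization_factors,
                 scale_factors = nrm$scale_factors,
                 kept_samples = kept,
                 positive_control_sums = pos_sums,
                 probe_class = raw$probe_class[rownames(nrm$values)],
                 params = list(v_cutoff = v_cutoff,
                               max_undetected = max_undetected,
                               n_ref_genes = n_ref_genes)),
            class = "nanostring_norm")
}

#' @export
print.nanostring_norm <- function(x, ...) {
  n_endo <- sum(x$probe_class == "endogenous")
  cat("Normalized panel:", n_endo, "endogenous genes,",
      ncol(x$values), "samples (", length(x$kept_samples), "pass QC )\n")
  cat("  reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  cat("  median detection rate:",
      sprintf("%.1f%%", 100 * stats::median(colMeans(x$detection))), "\n")
  invisible(x)
}

#' @export
summary.nanostring_norm <- function(object, ...) {
  out <- list(n_samples = ncol(object$values),
              n_kept = length(object$kept_samples),
              removed_samples = setdiff(colnames(object$values),
                                        object$kept_samples),
              reference_genes = object$reference_genes,
              stability_M = object$genorm$stability_M,
              detection_rate = colMeans(object$detection))
  class(out) <- "summary.nanostring_norm"
  out
}

#' @export
print.summary.nanostring_norm <- function(x, ...) {
  cat("Samples:", x$n_kept, "kept of", x$n_samples, "\n")
  if (length(x$removed_samples) > 0)
    cat("  removed:", paste(x$removed_samples, collapse = ", "), "\n")
  cat("Reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  cat("Detection rate per sample: ",
      sprintf("min %.2f / median %.2f / max %.2f", min(x$detection_rate),
              stats::median(x$detection_rate), max(x$detection_rate)), "\n")
  invisible(x)
}

#' Extract an expression matrix from a normalized panel
#'
#' @param norm a [nanostring_normalize()] result.
#' @param probes `"endogenous"` (default) or `"all"` (endogenous +
#'   normalization candidates).
#' @param samples `"kept"` (QC-passing, default) or `"all"`.
#' @return Numeric log2 gene x sample matrix.
#' @export
expr_matrix <- function(norm, probes = c("endogenous", "all"),
                        samples = c("kept", "all")) {
  stopifnot(inherits(norm, "nanostring_norm"))
  probes <- match.arg(probes)
  samples <- match.arg(samples)
  rows <- if (probes == "endogenous")
    names(norm$probe_class)[norm$probe_class == "endogenous"]
  else rownames(norm$values)
  cols <- if (samples == "kept") norm$kept_samples else colnames(norm$values)
  norm$values[rows, cols, drop = FALSE]
}
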