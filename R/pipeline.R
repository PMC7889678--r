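#' Run the full paired-panel analysis pipeline
#'
#' Drives all stages in order: normalization ([nanostring_normalize()]),
#' signed co-expression network and module detection
#' ([coexpression_network()]), module eigengenes, over-representation
#' analysis ([module_ora()], when an annotation is supplied), module
#' eigengene paired t-tests with Holm-Sidak correction, per-gene paired
#' t-tests with Benjamini-Hochberg FDR inside the most significant module,
#' two-group sample clustering with McNemar and neighbour-pair chi-square
#' contingency analyses, and (when `ifng_gene` is present on the panel) the
#' detection contingency analyses for a low-abundance cytokine gene.
#'
#' The run report is a plain list (JSON-serializable) whose counts equal the
#' emitted artifacts' dimensions; identical inputs and parameters give a
#' byte-identical report (see [report_hash()]).
#'
#' @param counts a [raw_counts] object (or a path readable by
#'   [read_counts()]).
#' @param samples sample metadata data.frame (or a path readable by
#'   [read_sample_meta()]) with columns `sample`, `patient`, `timepoint`,
#'   `arm`.
#' @param gene_sets optional [gene_set_collection] (or GMT path) for ORA.
#' @param v_cutoff,max_undetected,n_ref_genes normalization parameters, see
#'   [nanostring_normalize()].
#' @param beta,min_module_size,cut_height network parameters, see
#'   [coexpression_network()].
#' @param ora_p_cutoff raw p-value cutoff for ORA significance.
#' @param fdr_q per-gene FDR significance level.
#' @param ifng_gene optional ID of a low-abundance gene whose detection
#'   status is analysed at baseline vs progression (e.g. `"IFNG_SYN"` on
#'   simulated panels).
#' @param out_dir optional directory; when given, every stage artifact
#'   (normalized matrix, detection calls, module assignment, eigengenes,
#'   enrichment and test tables, Newick dendrograms, JSON report) is written
#'   there.
#' @return A list of class `run_report`.
#' @examples
#' sim <- simulate_panel(simulation_config(seed = 1))
#' rep <- run_pipeline(sim$counts, sim$samples,
#'                     gene_sets = simulate_gene_sets(sim, seed = 1),
#'                     ifng_gene = "IFNG_SYN")
#' rep
#' @export
run_pipeline <- function(counts, samples, gene_sets = NULL,
                         v_cutoff = 0.15, max_undetected = 0.5,
                         n_ref_genes = NULL,
                         beta = 8, min_module_size = 10, cut_height = 0.5,
                         ora_p_cutoff = 0.01, fdr_q = 0.05,
                         ifng_gene = NULL, out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(samples)) samples <- read_sample_meta(samples)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  stopifnot(inherits(counts, "raw_counts"), is.data.frame(samples))
  if (!all(colnames(counts$values) %in% samples$sample))
    stop("normalize: samples missing from metadata")

  params <- list(v_cutoff = v_cutoff, max_undetected = max_undetected,
                 n_ref_genes = n_ref_genes, beta = beta,
                 min_module_size = min_module_size, cut_height = cut_height,
                 ora_p_cutoff = ora_p_cutoff, fdr_q = fdr_q,
                 ifng_gene = ifng_gene)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  norm <- stage("normalize",
                nanostring_normalize(counts, v_cutoff = v_cutoff,
                                     max_undetected = max_undetected,
                                     n_ref_genes = n_ref_genes))
  expr <- expr_matrix(norm)
  meta <- samples[match(colnames(expr), samples$sample), ]

  net <- stage("network",
               coexpression_network(expr, beta = beta,
                                    min_module_size = min_module_size,
                                    cut_height = cut_height))

  # matched pairs among QC-passing samples
  bl <- meta$sample[meta$timepoint == "baseline"]
  pg <- meta$sample[meta$timepoint == "progression"]
  bl_pat <- meta$patient[match(bl, meta$sample)]
  pg_pat <- meta$patient[match(pg, meta$sample)]
  paired_pat <- intersect(bl_pat, pg_pat)
  pair_bl <- bl[match(paired_pat, bl_pat)]
  pair_pg <- pg[match(paired_pat, pg_pat)]
  pair_arm <- meta$arm[match(pair_bl, meta$sample)]

  me_tests <- NULL
  top_module <- NULL
  if (length(net$module_sizes) > 0 && length(paired_pat) >= 2) {
    me <- net$eigengenes
    rows <- lapply(rownames(me), function(m) {
      tt <- paired_t(stats::setNames(me[m, pair_bl], paired_pat),
                     stats::setNames(me[m, pair_pg], paired_pat))
      data.frame(module = m, statistic = tt$statistic, df = tt$df,
                 estimate = tt$estimate, p_value = tt$p_value,
                 stringsAsFactors = FALSE)
    })
    me_tests <- do.call(rbind, rows)
    me_tests$p_adjusted <- holm_sidak(me_tests$p_value)
    me_tests$significant <- me_tests$p_adjusted < 0.05
    top_module <- me_tests$module[which.min(me_tests$p_value)]
  }

  gene_tests <- NULL
  if (!is.null(top_module) && length(paired_pat) >= 2) {
    genes <- names(net$modules)[net$modules == top_module]
    rows <- lapply(genes, function(g) {
      res <- tryCatch(paired_t(stats::setNames(expr[g, pair_bl], paired_pat),
                               stats::setNames(expr[g, pair_pg], paired_pat)),
                      error = function(e) NULL)
      if (is.null(res))
        data.frame(gene = g, statistic = NA_real_, estimate = NA_real_,
                   p_value = NA_real_, stringsAsFactors = FALSE)
      else
        data.frame(gene = g, statistic = res$statistic,
                   estimate = res$estimate, p_value = res$p_value,
                   stringsAsFactors = FALSE)
    })
    gene_tests <- do.call(rbind, rows)
    gene_tests$q_value <- NA_real_
    ok <- !is.na(gene_tests$p_value)
    gene_tests$q_value[ok] <- bh_fdr(gene_tests$p_value[ok])
    gene_tests$significant <- !is.na(gene_tests$q_value) &
      gene_tests$q_value < fdr_q
    gene_tests <- gene_tests[order(gene_tests$p_value), ]
    rownames(gene_tests) <- NULL
  }

  ora <- NULL
  if (!is.null(gene_sets) && length(net$module_sizes) > 0) {
    ora <- stage("enrich",
                 module_ora(net$modules, gene_sets,
                            background = rownames(expr),
                            p_cutoff = ora_p_cutoff))
  }

  clustering <- NULL
  cluster_stats <- NULL
  if (ncol(expr) >= 4) {
    clustering <- stage("cluster", cluster_samples(expr, k = 2))
    if (length(paired_pat) >= 2) {
      cluster_stats <- stage("assoc",
        paired_cluster_contingency(clustering, pair_bl, pair_pg,
                                   arm = pair_arm))
    }
  }

  ifng <- NULL
  if (!is.null(ifng_gene) && ifng_gene %in% rownames(norm$detection)) {
    det <- norm$detection[ifng_gene, norm$kept_samples]
    tp <- meta$timepoint[match(names(det), meta$sample)]
    all_tab <- table(timepoint = factor(tp, c("baseline", "progression")),
                     detected = factor(det, c(TRUE, FALSE)))
    chi2 <- if (all(rowSums(all_tab) > 0) && all(colSums(all_tab) > 0))
      pearson_chi2(unclass(all_tab)) else NULL
    mc <- NULL
    if (length(paired_pat) >= 1) {
      b <- sum(det[pair_bl] & !det[pair_pg])   # detected -> undetected
      cc <- sum(!det[pair_bl] & det[pair_pg])  # undetected -> detected
      mc <- mcnemar_test(b = b, c = cc)
    }
    ifng <- list(gene = ifng_gene,
                 detected_baseline = sum(det[tp == "baseline"]),
                 n_baseline = sum(tp == "baseline"),
                 detected_progression = sum(det[tp == "progression"]),
                 n_progression = sum(tp == "progression"),
                 chi2_p = if (!is.null(chi2)) chi2$p_value else NA_real_,
                 mcnemar_p = if (!is.null(mc)) mc$p_value else NA_real_,
                 discordant = if (!is.null(mc)) c(b = mc$b, c = mc$c) else NULL)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("coexmod")),
    params = params,
    n_probes = nrow(counts$values),
    n_endogenous = sum(counts$probe_class == "endogenous"),
    n_samples_in = ncol(counts$values),
    n_samples_kept = length(norm$kept_samples),
    removed_samples = setdiff(colnames(counts$values), norm$kept_samples),
    reference_genes = norm$reference_genes,
    genorm_M = as.list(norm$genorm$stability_M),
    n_pairs = length(paired_pat),
    n_modules = length(net$module_sizes),
    module_sizes = as.list(net$module_sizes),
    scale_free_r_squared = net$scale_free$r_squared,
    me_tests = me_tests,
    top_module = top_module,
    gene_tests = gene_tests,
    ora_significant = if (!is.null(ora)) ora[ora$significant, ] else NULL,
    clustering = if (!is.null(cluster_stats)) list(
      cluster_table = unclass(cluster_stats$cluster_table),
      mcnemar_p = cluster_stats$mcnemar$p_value,
      n_neighbour_pairs = if (!is.null(cluster_stats$neighbours))
        sum(cluster_stats$neighbours) else NA_integer_,
      arm_chi2_p = if (!is.null(cluster_stats$arm_chi2))
        cluster_stats$arm_chi2$p_value else NA_real_) else NULL,
    ifng = ifng)
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    write_matrix_tsv(norm$values, fp("normalized.tsv"), "probe_id")
    write_matrix_tsv(norm$detection * 1, fp("detection.tsv"), "probe_id")
    jsonlite::write_json(
      list(stability_M = as.list(norm$genorm$stability_M),
           ranking = norm$genorm$ranking,
           elimination_order = norm$genorm$elimination_order,
           V = as.list(norm$genorm$V),
           selected = norm$reference_genes),
      fp("genorm.json"), digits = NA, auto_unbox = TRUE)
    utils::write.table(
      data.frame(gene = names(net$modules), module = unname(net$modules)),
      fp("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(net$eigengenes))
      write_matrix_tsv(net$eigengenes, fp("eigengenes.tsv"), "module")
    if (!is.null(net$dendrogram))
      write_dendrogram(net$dendrogram, fp("gene_dendrogram.nwk"))
    if (!is.null(clustering))
      write_dendrogram(clustering$dendrogram, fp("sample_dendrogram.nwk"))
    if (!is.null(ora))
      utils::write.table(ora, fp("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(me_tests))
      utils::write.table(me_tests, fp("me_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(gene_tests))
      utils::write.table(gene_tests, fp("gene_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(report), fp("report.json"),
                         digits = NA, auto_unbox = TRUE, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Paired-panel pipeline report\n")
  cat(sprintf("  samples: %d in, %d kept (QC); %d matched pairs\n",
              x$n_samples_in, x$n_samples_kept, x$n_pairs))
  cat("  reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  cat(sprintf("  modules: %d (%s)\n", x$n_modules,
              paste(sprintf("%s=%d", names(x$module_sizes),
                            unlist(x$module_sizes)), collapse = ", ")))
  if (!is.null(x$me_tests)) {
    cat("  module eigengene paired tests (Holm-Sidak):\n")
    for (i in seq_len(nrow(x$me_tests)))
      cat(sprintf("    %s: t = %.2f, p = %.4g, adj p = %.4g%s\n",
                  x$me_tests$module[i], x$me_tests$statistic[i],
                  x$me_tests$p_value[i], x$me_tests$p_adjusted[i],
                  if (x$me_tests$significant[i]) " *" else ""))
  }
  if (!is.null(x$gene_tests)) {
    sig <- x$gene_tests$gene[x$gene_tests$significant]
    cat(sprintf("  per-gene FDR (q < %.2g) in %s: %d significant%s\n",
                x$params$fdr_q, x$top_module, length(sig),
                if (length(sig) > 0)
                  paste0(" (", paste(utils::head(sig, 6), collapse = ", "), ")")
                else ""))
  }
  if (!is.null(x$clustering))
    cat(sprintf("  sample clustering: McNemar p = %.4g; neighbour pairs = %s, arm chi2 p = %.4g\n",
                x$clustering$mcnemar_p,
                format(x$clustering$n_neighbour_pairs),
                x$clustering$arm_chi2_p))
  if (!is.null(x$ifng))
    cat(sprintf("  %s detection: %d/%d baseline vs %d/%d progression; chi2 p = %.4g, McNemar p = %.4g\n",
                x$ifng$gene, x$ifng$detected_baseline, x$ifng$n_baseline,
                x$ifng$detected_progression, x$ifng$n_progression,
                x$ifng$chi2_p, x$ifng$mcnemar_p))
  invisible(x)
}

#' MD5 hash of a run report
#'
#' Serializes the report to canonical JSON and hashes it; identical input
#' data and parameters yield identical hashes, making pipeline determinism
#' checkable.
#'
#' @param report a [run_pipeline()] result.
#' @return MD5 hex string.
#' @export
report_hash <- function(report) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(report), tmp, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
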