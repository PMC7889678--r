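#' Exact hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' drawing `n` module genes from a background of `N` genes of which `K` are
#' annotated to the term, the p-value is the exact tail sum over overlaps
#' `j = k .. min(n, K)`, accumulated in log space for numerical stability.
#'
#' @param k observed overlap (module genes annotated to the term).
#' @param n module size.
#' @param K term size within the background.
#' @param N background size.
#' @return p-value in (0, 1].
#' @examples
#' hypergeometric_test(k = 10, n = 47, K = 20, N = 201)
#' @export
hypergeometric_test <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || any(c(k, n, K, N) != round(c(k, n, K, N))))
    stop("arguments must be non-negative integers")
  if (k > min(n, K)) stop("k exceeds min(n, K)")
  if (n > N || K > N) stop("n and K must not exceed N")
  if (k == 0) return(1)
  j <- k:min(n, K)
  lp <- stats::dhyper(j, K, N - K, n, log = TRUE)
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Over-representation analysis of modules against a panel background
#'
#' Each term is first intersected with the background gene list; one exact
#' hypergeometric test is performed per (module, term). Terms with an empty
#' intersection with the background are skipped with a warning. Rows are
#' sorted by module, then p-value ascending, ties broken by term ID.
#'
#' @param modules named gene -> module-label vector (or a `coexpr_net`);
#'   label `"unassigned"` is not tested. Module genes must be contained in
#'   `background`.
#' @param sets a [gene_set_collection].
#' @param background character vector of background genes (the full panel);
#'   defaults to all genes in `modules`.
#' @param p_cutoff significance cutoff on the raw p-value.
#' @param fdr if `TRUE`, additionally report Benjamini-Hochberg adjusted
#'   p-values per module (off by default: the raw `p < p_cutoff` rule is the
#'   convention for panel-background ORA).
#' @return data.frame with columns `module`, `term`, `description`, `k`
#'   (overlap), `n` (module size), `K` (term size in background), `N`
#'   (background size), `p_value`, `significant` (and `q_value` when
#'   `fdr = TRUE`).
#' @export
module_ora <- function(modules, sets, background = NULL, p_cutoff = 0.01,
                       fdr = FALSE) {
  if (inherits(modules, "coexpr_net")) modules <- modules$modules
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(background)) background <- names(modules)
  background <- unique(background)
  labels <- setdiff(unique(modules), "unassigned")
  labels <- labels[order(match(labels, modules))]
  mod_genes <- lapply(stats::setNames(labels, labels),
                      function(l) names(modules)[modules == l])
  bad <- unlist(mod_genes)[!unlist(mod_genes) %in% background]
  if (length(bad) > 0)
    stop("module genes outside the background: ",
         paste(utils::head(bad, 5), collapse = ", "))

  N <- length(background)
  rows <- list()
  for (term in names(sets$sets)) {
    term_genes <- intersect(sets$sets[[term]], background)
    if (length(term_genes) == 0) {
      warning("term '", term, "' has no genes in the background; skipped")
      next
    }
    for (lab in labels) {
      genes <- mod_genes[[lab]]
      k <- length(intersect(genes, term_genes))
      p <- hypergeometric_test(k, length(genes), length(term_genes), N)
      rows[[length(rows) + 1L]] <-
        data.frame(module = lab, term = term,
                   description = unname(sets$descriptions[term]),
                   k = k, n = length(genes), K = length(term_genes), N = N,
                   p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(module = character(0), term = character(0),
                      description = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_value = numeric(0), significant = logical(0))
    if (fdr) out$q_value <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$module, labels), out$p_value, out$term), ]
  rownames(out) <- NULL
  out$significant <- out$p_value < p_cutoff
  if (fdr) {
    out$q_value <- stats::ave(out$p_value, out$module,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is tab-delimited: term ID, description, then one gene per field.
#' Duplicate genes within a set are dropped with a message.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields")
  terms <- vapply(fields, `[[`, character(1), 1)
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2), terms)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), terms)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets a [gene_set_collection].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(term) {
    paste(c(term, sets$descriptions[term], sets$sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
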