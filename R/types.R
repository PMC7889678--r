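#' Construct a raw panel count matrix
#'
#' Container for probe-level counts from a targeted hybridization panel.
#' Rows are probes, columns are samples. Every probe carries a class:
#' `"endogenous"` (panel genes), `"negative"` (orphan probes measuring
#' background), `"positive"` (spiked ladder controls) or `"norm_candidate"`
#' (candidate reference genes for normalization).
#'
#' @param values numeric matrix of non-negative counts with unique rownames
#'   (probe IDs) and colnames (sample IDs).
#' @param probe_class named character vector mapping every probe ID to one of
#'   `"endogenous"`, `"negative"`, `"positive"`, `"norm_candidate"`.
#' @return An object of class `raw_counts`: a list with elements `values`
#'   (the matrix) and `probe_class` (aligned to `rownames(values)`).
#' @examples
#' m <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(c("G1", "G2", "NEG1", "NEG2"), c("s1", "s2", "s3")))
#' cls <- c(G1 = "endogenous", G2 = "endogenous",
#'          NEG1 = "negative", NEG2 = "negative")
#' raw_counts(m, cls)
#' @export
raw_counts <- function(values, probe_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at probe '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  valid <- c("endogenous", "negative", "positive", "norm_candidate")
  missing <- setdiff(rownames(values), names(probe_class))
  if (length(missing) > 0)
    stop("probes without a class: ", paste(utils::head(missing, 5), collapse = ", "))
  storage.mode(values) <- "double"
  probe_class <- probe_class[rownames(values)]
  bad <- which(!probe_class %in% valid)
  if (length(bad) > 0)
    stop(sprintf("unknown probe class '%s' for probe '%s'",
                 probe_class[bad[1]], names(probe_class)[bad[1]]))
  structure(list(values = values, probe_class = probe_class),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  tab <- table(x$probe_class)
  cat("Raw panel counts:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.raw_counts <- function(x) dim(x$values)

#' Probe IDs of a given class
#'
#' @param x a [raw_counts] object.
#' @param class one or more probe classes; default all.
#' @return character vector of probe IDs, in matrix row order.
#' @export
probes_of_class <- function(x, class = c("endogenous", "negative", "positive",
                                         "norm_candidate")) {
  stopifnot(inherits(x, "raw_counts"))
  class <- match.arg(class, several.ok = TRUE)
  rownames(x$values)[x$probe_class %in% class]
}

#' Construct a gene-set collection
#'
#' Named list of gene sets, e.g. read from a GMT file, used as annotation
#' input for over-representation analysis. Duplicate genes within a set are
#' dropped (with a message stating how many).
#'
#' @param sets named list of character vectors (term -> genes). Empty sets are
#'   not allowed.
#' @param descriptions optional named character vector of term descriptions;
#'   missing terms get an empty description.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == "")))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate term IDs")
  n_dup <- 0L
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    d <- sum(duplicated(g))
    if (d > 0) n_dup <<- n_dup + d
    unique(g)
  })
  if (n_dup > 0)
    message("dropped ", n_dup, " duplicate gene(s) within sets")
  if (any(lengths(sets) == 0)) stop("empty gene set")
  desc <- stats::setNames(rep("", length(sets)), names(sets))
  if (!is.null(descriptions)) {
    keep <- intersect(names(descriptions), names(sets))
    desc[keep] <- descriptions[keep]
  }
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "terms")
  if (length(x$sets) > 0)
    cat(", set sizes ", min(lengths(x$sets)), "-", max(lengths(x$sets)), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

# Run `expr` under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

geometric_mean <- function(x) exp(mean(log(x)))
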