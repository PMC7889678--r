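# Readers/writers for the plain-text interchange formats: counts and
# metadata as TSV/CSV (delimiter auto-detected), gene sets as GMT,
# ground truth and run reports as JSON.

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Write raw panel counts as TSV
#'
#' Layout: first column `probe_id`, second column `probe_class`, then one
#' column per sample.
#'
#' @param raw a [raw_counts] object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_counts <- function(raw, path) {
  stopifnot(inherits(raw, "raw_counts"))
  df <- data.frame(probe_id = rownames(raw$values),
                   probe_class = unname(raw$probe_class),
                   raw$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read raw panel counts from TSV/CSV
#'
#' Expects the layout written by [write_counts()]; the delimiter (tab or
#' comma) is auto-detected from the header line. Duplicate probe IDs,
#' negative counts and unknown probe classes are rejected with errors naming
#' the offending row/cell.
#'
#' @param path input file path.
#' @return A [raw_counts] object.
#' @export
read_counts <- function(path) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "probe_class")
  if (!all(need %in% colnames(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  if (ncol(df) < 3) stop("no sample columns found")
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ID at row ",
         which(duplicated(df$probe_id))[1], ": ",
         df$probe_id[which(duplicated(df$probe_id))[1]])
  m <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count values")
  rownames(m) <- df$probe_id
  raw_counts(m, stats::setNames(df$probe_class, df$probe_id))
}

#' Write sample metadata as TSV
#'
#' @param samples data.frame with columns `sample`, `patient`, `timepoint`,
#'   `arm`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_sample_meta <- function(samples, path) {
  need <- c("sample", "patient", "timepoint", "arm")
  if (!all(need %in% colnames(samples)))
    stop("missing metadata column(s): ",
         paste(setdiff(need, colnames(samples)), collapse = ", "))
  utils::write.table(samples[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV/CSV
#'
#' @param path input file path.
#' @return data.frame with columns `sample`, `patient`, `timepoint`
#'   (validated against `baseline`/`progression`) and `arm`.
#' @export
read_sample_meta <- function(path) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "patient", "timepoint", "arm")
  if (!all(need %in% colnames(df)))
    stop("missing metadata column(s): ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  bad <- setdiff(unique(df$timepoint), c("baseline", "progression"))
  if (length(bad) > 0)
    stop("unknown timepoint value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in metadata")
  df[, need]
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of a [simulate_panel()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  # named vectors must go out as JSON objects, not bare arrays
  out$module_of_gene <- as.list(truth$module_of_gene)
  if (!is.null(truth$loadings)) out$loadings <- as.list(truth$loadings)
  if (!is.null(truth$baselines)) out$baselines <- as.list(truth$baselines)
  out$factor_values <- list(modules = rownames(truth$factor_values),
                            samples = colnames(truth$factor_values),
                            values = unname(truth$factor_values))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read simulation ground truth from JSON
#'
#' @param path input file path.
#' @return Ground-truth list matching [simulate_panel()]'s `truth` element.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fv <- x$factor_values
  m <- fv$values
  if (is.list(m)) m <- do.call(rbind, m)
  dimnames(m) <- list(fv$modules, fv$samples)
  x$factor_values <- m
  x$module_of_gene <- unlist(x$module_of_gene)
  if (!is.null(x$loadings)) x$loadings <- unlist(x$loadings)
  if (!is.null(x$baselines)) x$baselines <- unlist(x$baselines)
  x
}

#' Write a numeric matrix as TSV with an ID column
#'
#' @param m matrix with rownames.
#' @param path output file path.
#' @param id_name header for the rowname column.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#'
#' @param path input file path.
#' @return Numeric matrix with rownames taken from the first column.
#' @export
read_matrix_tsv <- function(path) {
  sep <- detect_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
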