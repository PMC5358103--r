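#' Write a genes x samples matrix as TSV
#'
#' First column `gene_id`, header row of sample ids. Floating-point values
#' are written at 6 significant digits; integer matrices are written as-is.
#'
#' @param values matrix with dimnames.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(values, path) {
  out <- values
  if (is.double(out)) out <- signif(out, 6)
  df <- data.frame(gene_id = rownames(values), out,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples TSV matrix
#'
#' @param path TSV file with a `gene_id` first column and sample header.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a count matrix from TSV files
#'
#' @param counts_path counts TSV (`gene_id` first column, sample header).
#' @param lengths_path two-column TSV (`gene_id`, `length`).
#' @param totals optional named per-sample totals; default column sums.
#' @return A [count_matrix].
#' @export
read_counts <- function(counts_path, lengths_path, totals = NULL) {
  values <- read_matrix_tsv(counts_path)
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  count_matrix(values,
               gene_lengths = stats::setNames(len[[2]], len[[1]]),
               totals = totals)
}

#' Read a sample table
#'
#' @param path TSV with columns `sample_id` and `stage`.
#' @return A `stage_design` reconstructed from the table (stage order is
#'   first-appearance order).
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stages <- unique(df$stage)
  design <- generate_design(stages, as.integer(table(factor(df$stage, stages))))
  # keep the file's own sample ids rather than the derived ones
  design$samples <- data.frame(sample_id = df$sample_id,
                               stage = factor(df$stage, levels = stages),
                               stringsAsFactors = FALSE)
  design
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>genes...`.
#' @return Named list of character vectors, class `gene_sets`.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  structure(sets, class = c("gene_sets", "list"))
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field per set (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "regionid") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set needs a name")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
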