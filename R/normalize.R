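#' Construct a count matrix with transcript lengths and mapped-read totals
#'
#' The container behind FPKM normalization: non-negative integer counts,
#' one transcript length per gene (bp), and per-sample mapped-read totals.
#' When `totals` is not supplied it falls back to the column sums; a totals
#' vector supplied with the data takes precedence, since mapped-read counts
#' from the aligner need not equal the column sums of a filtered matrix.
#'
#' @param values genes x samples numeric matrix of non-negative counts, with
#'   row (gene) and column (sample) names.
#' @param gene_lengths positive numeric vector, one bp length per gene; if
#'   named, matched to rownames.
#' @param totals optional positive per-sample mapped-read totals.
#' @return Object of class `count_matrix`: list with `values`,
#'   `gene_lengths`, `totals`.
#' @export
count_matrix <- function(values, gene_lengths, totals = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("counts must have gene rownames and sample colnames")
  if (any(values < 0) || any(!is.finite(values)))
    stop("counts must be finite and non-negative")
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(values), names(gene_lengths))
    if (length(missing))
      stop("gene_lengths missing for ", length(missing), " genes")
    gene_lengths <- gene_lengths[rownames(values)]
  } else if (length(gene_lengths) == nrow(values)) {
    names(gene_lengths) <- rownames(values)
  } else stop("gene_lengths must have one entry per gene")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (is.null(totals)) totals <- colSums(values)
  if (length(totals) != ncol(values)) stop("one total per sample required")
  if (any(totals <= 0)) stop("per-sample totals must be positive")
  names(totals) <- colnames(values)
  structure(list(values = values, gene_lengths = gene_lengths,
                 totals = totals), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$values), "genes x", ncol(x$values), "samples;",
      "median library size", format(stats::median(x$totals), big.mark = ","), "\n")
  invisible(x)
}

#' Construct an expression matrix
#'
#' Light container for a genes x samples matrix of non-negative expression
#' values, tagged with the normalization it carries (`"fpkm"` or
#' `"mean_normalized"`) and, optionally, a per-sample stage label.
#'
#' @param values non-negative numeric matrix with dimnames.
#' @param kind `"fpkm"` or `"mean_normalized"`.
#' @param stages optional per-sample stage labels (recycled names checked).
#' @return Object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, kind = c("fpkm", "mean_normalized"),
                              stages = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(values < 0) || any(!is.finite(values)))
    stop("expression values must be finite and non-negative")
  if (!is.null(stages)) {
    if (length(stages) != ncol(values))
      stop("one stage label per sample required")
    stages <- as.character(stages)
    names(stages) <- colnames(values)
  }
  structure(list(values = values, kind = kind, stages = stages),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix (", x$kind, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  if (!is.null(x$stages))
    cat("Stages:", paste(unique(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `FPKM = count * 1e9 / (length_bp * total_mapped_reads)`, using the
#' transcript lengths and per-sample totals carried by the count matrix.
#'
#' @param counts a [count_matrix].
#' @param stages optional per-sample stage labels carried forward.
#' @return An `expr_matrix` with `kind = "fpkm"`.
#' @examples
#' cm <- count_matrix(matrix(10, 1, 1, dimnames = list("g1", "s1")),
#'                    gene_lengths = 1000, totals = 1e6)
#' compute_fpkm(cm)$values  # 10
#' @export
compute_fpkm <- function(counts, stages = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  fpkm <- counts$values * 1e9 /
    outer(counts$gene_lengths, counts$totals)
  expression_matrix(fpkm, kind = "fpkm", stages = stages)
}

#' Discard transcripts never reaching an FPKM threshold
#'
#' Removes rows whose maximum FPKM across all samples is strictly below
#' `threshold` (default 1). A row whose maximum is exactly the threshold is
#' retained. Row order of survivors is preserved, and the removed gene ids
#' are attached as the `removed_genes` element of the result.
#'
#' @param expr an `expr_matrix` of kind `"fpkm"`.
#' @param threshold minimum acceptable row maximum.
#' @return Filtered `expr_matrix` (kind `"fpkm"`) with `removed_genes`.
#' @export
filter_low_expression <- function(expr, threshold = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$kind != "fpkm")
    stop("the low-expression filter is defined on FPKM values")
  row_max <- apply(expr$values, 1L, max)
  keep <- row_max >= threshold
  if (!any(keep))
    stop("all ", nrow(expr$values), " rows fall below max-FPKM threshold ",
         threshold, "; nothing left to analyse")
  out <- expression_matrix(expr$values[keep, , drop = FALSE], kind = "fpkm",
                           stages = expr$stages)
  out$removed_genes <- rownames(expr$values)[!keep]
  out
}

#' Scale each gene by its mean across samples
#'
#' Divides each row by its mean so that every surviving gene has mean 1;
#' this removes absolute-expression bias and focuses the factorization on
#' variation across stages.
#'
#' @param expr an `expr_matrix` (any kind) with strictly positive row means.
#' @return An `expr_matrix` with `kind = "mean_normalized"`.
#' @export
mean_normalize <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  mu <- rowMeans(expr$values)
  if (any(mu <= 0)) {
    bad <- rownames(expr$values)[which(mu <= 0)]
    stop("zero-mean gene(s) cannot be mean-normalized: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  expression_matrix(expr$values / mu, kind = "mean_normalized",
                    stages = expr$stages)
}

#' Restrict an expression matrix to a gene class
#'
#' Keeps only rows in `gene_class` (for example DNA-binding proteins from
#' PFAM annotations), preserving row order. The intersection size is
#' reported via a message and stored as the `n_class_found` element.
#'
#' @param expr an `expr_matrix`.
#' @param gene_class non-empty character vector of gene ids.
#' @return The restricted `expr_matrix`.
#' @export
subset_gene_class <- function(expr, gene_class) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(gene_class) == 0L) stop("gene_class must be non-empty")
  keep <- rownames(expr$values) %in% gene_class
  if (!any(keep))
    stop("gene_class shares no genes with the expression matrix")
  out <- expression_matrix(expr$values[keep, , drop = FALSE],
                           kind = expr$kind, stages = expr$stages)
  out$n_class_found <- sum(keep)
  message(sum(keep), " of ", length(unique(gene_class)),
          " class genes found in the matrix")
  out
}
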