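#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` where `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `x` marked genes when `n` genes are drawn without replacement from
#' a universe of `N` genes of which `K` are marked. This is the
#' over-representation p-value for an overlap of `x` genes between a program
#' of size `n` and a gene set of size `K`. Delegates to [stats::phyper()],
#' which is numerically stable far into the tail.
#'
#' @param x observed overlap (vectorized).
#' @param n number drawn (program size).
#' @param K number marked in the universe (gene-set size).
#' @param N universe size.
#' @return `P(X >= x)`, exactly 1 when `x <= 0`.
#' @examples
#' hypergeom_upper_tail(3, 3, 4, 10)  # 4 / choose(10, 3)
#' @export
hypergeom_upper_tail <- function(x, n, K, N) {
  if (any(n < 0) || any(K < 0) || any(N < 0))
    stop("n, K, N must be non-negative")
  if (any(n > N) || any(K > N))
    stop("n and K cannot exceed the universe size N")
  if (any(x < 0) || any(x > n) || any(x > K))
    stop("x must satisfy 0 <= x <= min(n, K)")
  stats::phyper(x - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of programs against gene sets
#'
#' For every (program, gene set) pair: restricts the set to the universe,
#' counts its overlap with the program's member genes, and computes the
#' upper-tail hypergeometric p-value. Results are ordered by p-value within
#' each program. Raw p-values are the headline output; a
#' Benjamini-Hochberg column over all pairs is added when `bh = TRUE`.
#' Sets smaller than `min_set_size` after universe restriction are flagged
#' (`small_set`) rather than dropped.
#'
#' @param programs an `expression_programs` object (or named list of gene-id
#'   vectors).
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background gene ids; must contain
#'   every program member.
#' @param stages optional data frame from [assign_program_stages()]; adds a
#'   `stage` column.
#' @param bh add a BH-adjusted p-value column.
#' @param min_set_size sets with fewer in-universe genes are flagged.
#' @return Data frame of class `enrichment_result` with columns `program`,
#'   (`stage`,) `set_name`, `x`, `n`, `K`, `N`, `p_value`,
#'   (`p_adjusted`,) `small_set`, `overlap_genes` (comma-separated).
#' @export
enrich <- function(programs, sets, universe, stages = NULL, bh = FALSE,
                   min_set_size = 10L) {
  members <- if (inherits(programs, "expression_programs"))
    programs$members else programs
  if (length(members) == 0L || length(sets) == 0L)
    stop("programs and sets must be non-empty")
  universe <- unique(as.character(universe))
  stray <- setdiff(unlist(members, use.names = FALSE), universe)
  if (length(stray))
    stop("program member(s) outside the universe (universe construction ",
         "bug): ", paste(utils::head(stray, 5), collapse = ", "))
  N <- length(universe)
  rows <- list()
  for (p in names(members)) {
    prog <- unique(members[[p]])
    for (s in names(sets)) {
      set_u <- intersect(unique(sets[[s]]), universe)
      ov <- intersect(prog, set_u)
      rows[[length(rows) + 1L]] <- data.frame(
        program = p, set_name = s,
        x = length(ov), n = length(prog), K = length(set_u), N = N,
        p_value = hypergeom_upper_tail(length(ov), length(prog),
                                       length(set_u), N),
        small_set = length(set_u) < min_set_size,
        overlap_genes = paste(ov, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (bh) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(match(res$program, names(members)), res$p_value), ]
  rownames(res) <- NULL
  if (!is.null(stages))
    res$stage <- stages$stage[match(res$program, stages$program)]
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Hypergeometric enrichment:", length(unique(x$program)), "programs x",
      length(unique(x$set_name)), "gene sets, universe N =", x$N[1], "\n")
  show <- as.data.frame(x)
  show$overlap_genes <- NULL
  show$p_value <- signif(show$p_value, 3)
  if (!is.null(show$p_adjusted)) show$p_adjusted <- signif(show$p_adjusted, 3)
  print(utils::head(show, 25))
  if (nrow(show) > 25) cat("... and", nrow(show) - 25, "more pairs\n")
  invisible(x)
}

#' Expression table of program / gene-set overlap genes
#'
#' Collects the overlapping genes of selected (program, gene set) pairs and
#' returns their expression across samples, rows blocked by program and
#' ordered by loading (descending) within each block — the data behind an
#' overlap heatmap. By default the selected pairs are, per program, the
#' best-p set with `p_value < p_cutoff` (small-flagged sets excluded).
#'
#' @param enr an `enrichment_result`.
#' @param expr the `expr_matrix` (mean-normalized) the programs came from.
#' @param fit the `nnmf` fit providing the loadings used for ordering.
#' @param pairs optional data frame with columns `program`, `set_name`
#'   overriding the default selection.
#' @param p_cutoff p-value cutoff for the default selection.
#' @return List of class `overlap_table`: `values` (genes x samples matrix,
#'   possibly 0-row) and `row_info` (gene, program, set_name, loading).
#' @export
overlap_table <- function(enr, expr, fit, pairs = NULL, p_cutoff = 0.05) {
  stopifnot(inherits(enr, "enrichment_result"), inherits(expr, "expr_matrix"),
            inherits(fit, "nnmf"))
  if (is.null(pairs)) {
    keep <- enr[!enr$small_set & enr$p_value < p_cutoff, ]
    keep <- keep[!duplicated(keep$program), ]  # enr is sorted by p in program
    pairs <- keep[, c("program", "set_name")]
  }
  info_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    row <- enr[enr$program == pairs$program[i] &
                 enr$set_name == pairs$set_name[i], ]
    if (nrow(row) == 0L) next
    genes <- strsplit(row$overlap_genes, ",", fixed = TRUE)[[1]]
    genes <- genes[genes != ""]
    if (length(genes) == 0L) next
    load <- fit$W[genes, row$program]
    ord <- order(load, decreasing = TRUE)
    info_rows[[length(info_rows) + 1L]] <- data.frame(
      gene = genes[ord], program = row$program, set_name = row$set_name,
      loading = unname(load[ord]), stringsAsFactors = FALSE)
  }
  if (length(info_rows) == 0L) {
    warning("no overlapping genes in the selected pairs; empty table")
    return(structure(list(values = expr$values[0, , drop = FALSE],
                          row_info = data.frame()), class = "overlap_table"))
  }
  info <- do.call(rbind, info_rows)
  structure(list(values = expr$values[info$gene, , drop = FALSE],
                 row_info = info),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("Overlap table:", nrow(x$values), "genes x", ncol(x$values),
      "samples from", length(unique(x$row_info$program)), "program(s)\n")
  invisible(x)
}
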