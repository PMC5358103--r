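#' Assemble a stage-program heatmap specification
#'
#' Selects the `top_n` genes per program by loading, blocks rows by program
#' in stage order, and min-max scales each row to \[0, 1\] for display; the
#' raw mean-normalized values are kept alongside. Columns are grouped by
#' stage in design order.
#'
#' @param expr mean-normalized `expr_matrix`.
#' @param programs an `expression_programs` object.
#' @param fit the `nnmf` fit (loadings for ranking).
#' @param assignments data frame from [assign_program_stages()].
#' @param design the `stage_design` (column grouping).
#' @param top_n genes shown per program; programs with fewer members
#'   contribute all of them (with a warning).
#' @return List of class `heatmap_spec`: `values` (row-scaled, in \[0,1\]),
#'   `raw`, `row_info` (gene, program, stage, loading), `col_info`
#'   (sample, stage).
#' @export
build_program_heatmap <- function(expr, programs, fit, assignments, design,
                                  top_n = 10L) {
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(programs, "expression_programs"),
            inherits(fit, "nnmf"))
  # programs in their assigned stage's order
  prog_order <- assignments$program[order(match(assignments$stage,
                                                design$stages))]
  rows <- list()
  for (p in prog_order) {
    genes <- programs$members[[p]]
    if (length(genes) == 0L) next
    if (top_n > length(genes))
      warning("program ", p, " has only ", length(genes),
              " members; taking all")
    load <- fit$W[genes, p]
    genes <- genes[order(load, decreasing = TRUE)][seq_len(min(top_n,
                                                               length(genes)))]
    rows[[p]] <- data.frame(
      gene = genes, program = p,
      stage = assignments$stage[assignments$program == p],
      loading = unname(fit$W[genes, p]), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no program has any member genes")
  row_info <- do.call(rbind, rows)
  rownames(row_info) <- NULL
  col_order <- order(match(expr$stages, design$stages))
  raw <- expr$values[row_info$gene, col_order, drop = FALSE]
  rng <- apply(raw, 1L, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1  # constant rows map to 0
  scaled <- (raw - rng[1, ]) / span
  col_info <- data.frame(sample = colnames(raw),
                         stage = unname(expr$stages[col_order]),
                         stringsAsFactors = FALSE)
  structure(list(values = scaled, raw = raw, row_info = row_info,
                 col_info = col_info),
            class = "heatmap_spec")
}

#' @export
print.heatmap_spec <- function(x, ...) {
  cat("Heatmap spec:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$row_info$program)), "program blocks\n")
  invisible(x)
}

#' Render a heatmap and its TSV sidecar
#'
#' Writes a PNG image (via pheatmap, rows and columns kept in spec order)
#' and a TSV sidecar of the plotted values; the sidecar, not the pixels, is
#' the testable artifact and round-trips the spec values at 6 significant
#' digits.
#'
#' @param spec a `heatmap_spec` or `overlap_table`.
#' @param path output path without extension; writes `<path>.png` and
#'   `<path>.tsv`.
#' @param raw write (and plot) the raw rather than the row-scaled values
#'   (heatmap specs only).
#' @return Invisibly, named vector with the `png` and `tsv` paths.
#' @export
render_heatmap <- function(spec, path, raw = FALSE) {
  if (inherits(spec, "heatmap_spec")) {
    values <- if (raw) spec$raw else spec$values
  } else if (inherits(spec, "overlap_table")) {
    values <- spec$values
  } else stop("spec must be a heatmap_spec or overlap_table")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("cannot render an empty heatmap")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tsv <- paste0(path, ".tsv")
  png <- paste0(path, ".png")
  write_matrix_tsv(values, tsv)
  plot_values <- values
  rownames(plot_values) <- make.unique(rownames(values))
  grDevices::png(png, width = 200 + 40 * ncol(values),
                 height = 200 + 12 * nrow(values), res = 96)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(plot_values, cluster_rows = FALSE, cluster_cols = FALSE,
                     fontsize_row = 6)
  invisible(c(png = png, tsv = tsv))
}
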