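#' Default pipeline configuration
#'
#' Parameter home for the whole analysis: FPKM filter threshold 1, rank k
#' defaulting to the number of stages, 10 factorization replicates, 2-SD
#' membership, Frobenius objective with tol 1e-6 and at most 2000
#' iterations. Any entry can be overridden via `...`.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fpkm_threshold = 1,
    k = NULL,                 # NULL = number of stages in the design
    n_replicates = 10L,
    sd_multiplier = 2,
    sd_type = "population",
    objective = "frobenius",
    tol = 1e-6,
    max_iter = 2000L,
    base_seed = 1L,
    bh_correction = FALSE,
    min_set_size = 10L,
    specificity_ratio = 2,
    top_n = 10L,
    universe = "filtered"     # "filtered" or "filtered_and_sets"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the regional-identity pipeline end to end
#'
#' Composes the whole analysis: FPKM normalization, max-FPKM filter, mean
#' normalization, replicated NMF, 2-SD program extraction, stage
#' assignment, hypergeometric enrichment against the supplied gene sets,
#' and the program/overlap heatmap specs. When `out_dir` is given, all
#' intermediates (FPKM, filtered, normalized matrices, W, H, replicate log,
#' programs as GMT/JSON, enrichment TSV, heatmap sidecars) are written
#' there; reruns with the same seeds are bit-identical.
#'
#' @param counts a [count_matrix] (or a `synthetic_bundle`, whose design is
#'   then used).
#' @param design a `stage_design`; ignored when `counts` is a bundle.
#' @param sets named list of gene sets (e.g. [read_gmt()] output).
#' @param config list from [pipeline_config()].
#' @param out_dir optional output directory.
#' @return List of class `regionid_result` with elements `fpkm`,
#'   `filtered`, `normalized`, `fit`, `programs`, `assignments`,
#'   `enrichment`, `heatmap`, `overlap`, `universe`, `config`.
#' @export
run_pipeline <- function(counts, design = NULL, sets, config = pipeline_config(),
                         out_dir = NULL) {
  if (inherits(counts, "synthetic_bundle")) {
    design <- counts$design
    counts <- counts$counts
  }
  stopifnot(inherits(counts, "count_matrix"), inherits(design, "stage_design"))
  k <- if (is.null(config$k)) length(design$stages) else config$k
  if (k > ncol(counts$values))
    stop("factorization rank k = ", k, " exceeds the ", ncol(counts$values),
         " samples")
  stage_labels <- design$samples$stage[match(colnames(counts$values),
                                             design$samples$sample_id)]
  if (anyNA(stage_labels)) stop("samples in counts missing from the design")

  fpkm <- compute_fpkm(counts, stages = stage_labels)
  filtered <- filter_low_expression(fpkm, threshold = config$fpkm_threshold)
  normalized <- mean_normalize(filtered)

  fit <- nnmf_replicates(normalized, k = k,
                         n_replicates = config$n_replicates,
                         base_seed = config$base_seed,
                         objective = config$objective,
                         tol = config$tol, max_iter = config$max_iter)
  programs <- extract_programs(fit, sd_multiplier = config$sd_multiplier,
                               sd_type = config$sd_type)
  assignments <- assign_program_stages(fit, design,
                                       specificity_ratio = config$specificity_ratio)

  universe <- rownames(normalized$values)
  if (identical(config$universe, "filtered_and_sets"))
    universe <- intersect(union(universe, unlist(sets, use.names = FALSE)),
                          rownames(fpkm$values))
  enr <- enrich(programs, sets, universe = universe, stages = assignments,
                bh = config$bh_correction, min_set_size = config$min_set_size)

  heat <- build_program_heatmap(normalized, programs, fit, assignments,
                                design, top_n = config$top_n)
  ov <- suppressWarnings(overlap_table(enr, normalized, fit))

  res <- structure(list(fpkm = fpkm, filtered = filtered,
                        normalized = normalized, fit = fit,
                        programs = programs, assignments = assignments,
                        enrichment = enr, heatmap = heat, overlap = ov,
                        universe = universe, config = config, design = design),
                   class = "regionid_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.regionid_result <- function(x, ...) {
  cat("Regional-identity pipeline result\n")
  cat("  ", nrow(x$fpkm$values), " transcripts; ",
      length(x$filtered$removed_genes), " removed by max-FPKM < ",
      x$config$fpkm_threshold, "; ", nrow(x$normalized$values),
      " analysed\n", sep = "")
  print(x$fit)
  print(x$programs)
  best <- x$enrichment[!duplicated(x$enrichment$program), ]
  cat("  best gene set per program:\n")
  print(data.frame(program = best$program, stage = best$stage,
                   set = best$set_name, overlap = best$x,
                   p = signif(best$p_value, 3)), row.names = FALSE)
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_matrix_tsv(res$fpkm$values, p("fpkm.tsv"))
  write_matrix_tsv(res$filtered$values, p("fpkm_filtered.tsv"))
  write_matrix_tsv(res$normalized$values, p("mean_normalized.tsv"))
  write_matrix_tsv(res$fit$W, p("W.tsv"))
  write_matrix_tsv(res$fit$H, p("H.tsv"))
  utils::write.table(
    data.frame(seed = names(res$fit$replicate_objectives),
               objective = signif(unname(res$fit$replicate_objectives), 6)),
    p("replicates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  prog_sets <- res$programs$members
  names(prog_sets) <- paste0(names(prog_sets), "_",
                             res$assignments$stage[match(names(prog_sets),
                                                         res$assignments$program)])
  nonempty <- lengths(prog_sets) > 0
  if (any(nonempty)) write_gmt(prog_sets[nonempty], p("programs.gmt"))
  jsonlite::write_json(
    list(thresholds = as.list(res$programs$thresholds),
         sd_multiplier = res$programs$sd_multiplier,
         objective = res$fit$objective,
         replicate_objectives = as.list(res$fit$replicate_objectives),
         assignments = res$assignments,
         universe_size = length(res$universe)),
    p("programs.json"), auto_unbox = TRUE, digits = NA)
  enr <- as.data.frame(res$enrichment)
  utils::write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  render_heatmap(res$heatmap, p("program_heatmap"))
  if (nrow(res$overlap$values) > 0)
    render_heatmap(res$overlap, p("overlap_heatmap"))
  invisible(out_dir)
}

#' Write a synthetic study to disk
#'
#' Generates a stage design, planted counts, matched/decoy literature gene
#' sets and (optionally) a qPCR Ct table under the synthetic-data defaults,
#' and writes them to `dir`.
#'
#' @param dir output directory.
#' @param stages stage labels.
#' @param replicates replicates per stage.
#' @param seed integer seed.
#' @param qpcr also write a Ct table with a proximal-high gradient.
#' @param match_fraction fraction of each planted program included in its
#'   matched literature set.
#' @param decoy_size size of every generated gene set; defaults to the
#'   planted program size.
#' @param ... passed to [generate_counts()].
#' @return The `synthetic_bundle`, invisibly, with `sets` attached.
#' @export
simulate_bundle <- function(dir = NULL,
                            stages = c("ES", "DE", "OD5", "OD7", "OD10"),
                            replicates = 3L, seed = 1L, qpcr = FALSE,
                            match_fraction = 0.5, decoy_size = NULL, ...) {
  design <- generate_design(stages, replicates)
  bundle <- generate_counts(design, seed = seed, ...)
  if (is.null(decoy_size))
    decoy_size <- length(bundle$truth$program_genes[[1]])
  bundle$sets <- generate_literature_sets(bundle,
                                          match_fraction = match_fraction,
                                          decoy_size = decoy_size,
                                          seed = seed + 1L)
  if (qpcr) {
    bundle$qpcr <- generate_qpcr(
      regions = c("proximal", "middle", "distal"),
      genes = c("PDX1", "GUCA2A"),
      gradient = list(PDX1 = c(proximal = 3, middle = 1.5, distal = 0),
                      GUCA2A = c(proximal = 0, middle = 1.5, distal = 3)),
      seed = seed + 2L)
  }
  if (!is.null(dir)) {
    paths <- write_bundle(bundle, dir, sets = bundle$sets)
    if (qpcr) {
      qp <- file.path(dir, "qpcr.tsv")
      utils::write.table(bundle$qpcr, qp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[["qpcr"]] <- qp
    }
  }
  invisible(bundle)
}
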