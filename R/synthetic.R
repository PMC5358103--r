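#' Build a stage design
#'
#' Lays out an ordered set of differentiation stages (for example ES, DE,
#' OD5, OD7, OD10) with a number of biological replicates per stage, and
#' derives unique sample identifiers of the form `<stage>_r<i>`.
#'
#' @param stages character vector of stage labels, in differentiation order.
#' @param replicates positive integer; either a single value recycled across
#'   stages or one value per stage.
#' @return An object of class `stage_design`: a list with `stages`,
#'   `replicates` (named by stage) and `samples`, a data frame with columns
#'   `sample_id` and `stage` (factor with levels in stage order).
#' @examples
#' generate_design(c("ES", "DE", "OD5", "OD7", "OD10"), 3)
#' @export
generate_design <- function(stages, replicates) {
  stages <- as.character(stages)
  if (length(stages) < 1L) stop("at least one stage label is required")
  if (anyDuplicated(stages)) stop("duplicate stage labels: ",
                                  paste(unique(stages[duplicated(stages)]), collapse = ", "))
  if (length(replicates) == 1L) replicates <- rep(replicates, length(stages))
  if (length(replicates) != length(stages))
    stop("replicates must be length 1 or one per stage")
  replicates <- as.integer(replicates)
  if (any(is.na(replicates)) || any(replicates < 1L))
    stop("replicates must be positive integers")
  names(replicates) <- stages
  samples <- data.frame(
    sample_id = unlist(lapply(stages, function(s)
      paste0(s, "_r", seq_len(replicates[[s]]))), use.names = FALSE),
    stage = factor(rep(stages, replicates), levels = stages),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(samples$sample_id))
  structure(list(stages = stages, replicates = replicates, samples = samples),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat("Stage design:", length(x$stages), "stages,",
      nrow(x$samples), "samples\n")
  print(x$replicates)
  invisible(x)
}

#' Simulate a staged count matrix with planted expression programs
#'
#' Draws a genes x samples matrix of negative-binomial (or, optionally,
#' log-normal) counts. For each stage a disjoint block of `program_size`
#' genes is planted: those genes have their mean multiplied by `fold_change`
#' in that stage's samples only. Per-sample library-size factors are drawn
#' log-normal(0, `libsize_sd`) so that the total-read correction in FPKM is
#' exercised, and transcript lengths are drawn uniformly from `length_range`
#' so that the per-kilobase correction is exercised.
#'
#' @param design a `stage_design`.
#' @param n_genes total number of genes; must be at least
#'   `length(design$stages) * program_size`.
#' @param program_size number of genes planted per stage.
#' @param fold_change multiplicative up-regulation (> 1) of planted genes in
#'   their own stage.
#' @param baseline_mean expected background count per gene per sample.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); ignored by the log-normal model, where it is
#'   used as the log-scale sd.
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param length_range 2-vector of transcript length bounds in bp.
#' @param libsize_sd log-scale sd of the per-sample size factors.
#' @param count_model `"nb"` (default) or `"lognormal"`.
#' @return An object of class `synthetic_bundle`: list with `counts`
#'   (a [count_matrix]), `design`, and `truth` (planted program gene sets,
#'   generative parameters, and the gene universe).
#' @export
generate_counts <- function(design, n_genes = 2000L, program_size = 200L,
                            fold_change = 8, baseline_mean = 50,
                            dispersion = 0.1, seed = 1L,
                            length_range = c(500L, 5000L),
                            libsize_sd = 0.2,
                            count_model = c("nb", "lognormal")) {
  stopifnot(inherits(design, "stage_design"))
  count_model <- match.arg(count_model)
  n_stages <- length(design$stages)
  if (n_genes < n_stages * program_size)
    stop("n_genes must be at least stages * program_size")
  if (fold_change <= 1) stop("fold_change must be > 1")
  if (baseline_mean <= 0 || dispersion <= 0 || program_size < 1)
    stop("baseline_mean, dispersion and program_size must be positive")

  set.seed(as.integer(seed))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  sample_ids <- design$samples$sample_id
  n_samples <- length(sample_ids)

  # disjoint planted blocks, one per stage, at the top of the gene list
  program_genes <- lapply(seq_len(n_stages) - 1L, function(i)
    gene_ids[i * program_size + seq_len(program_size)])
  names(program_genes) <- design$stages

  size_factors <- exp(stats::rnorm(n_samples, 0, libsize_sd))
  mu <- matrix(baseline_mean, n_genes, n_samples,
               dimnames = list(gene_ids, sample_ids))
  for (s in design$stages) {
    cols <- design$samples$stage == s
    mu[program_genes[[s]], cols] <- baseline_mean * fold_change
  }
  mu <- sweep(mu, 2L, size_factors, `*`)

  counts <- if (count_model == "nb") {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_genes, n_samples, dimnames = dimnames(mu))
  } else {
    matrix(round(stats::rlnorm(length(mu), meanlog = log(mu), sdlog = dispersion)),
           n_genes, n_samples, dimnames = dimnames(mu))
  }
  lengths <- round(stats::runif(n_genes, length_range[1], length_range[2]))
  names(lengths) <- gene_ids

  cm <- count_matrix(counts, gene_lengths = lengths)
  truth <- list(program_genes = program_genes, fold_change = fold_change,
                baseline_mean = baseline_mean, dispersion = dispersion,
                size_factors = stats::setNames(size_factors, sample_ids),
                universe = gene_ids, seed = as.integer(seed))
  structure(list(counts = cm, design = design, truth = truth),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic bundle:", nrow(x$counts$values), "genes x",
      ncol(x$counts$values), "samples;",
      length(x$truth$program_genes), "planted programs of",
      length(x$truth$program_genes[[1]]), "genes, fold change",
      x$truth$fold_change, "\n")
  invisible(x)
}

#' Simulate literature-style regional gene sets
#'
#' For each planted stage program, builds a "matched" gene set containing a
#' fraction `match_fraction` of that program's genes topped up with random
#' filler genes to `decoy_size` members, emulating partially overlapping
#' published regional gene lists. One extra fully random set, disjoint from
#' every planted program, plays the role of the colon negative control.
#'
#' @param truth either a `synthetic_bundle` or its `truth` component.
#' @param match_fraction fraction in \[0, 1\] of each planted program included
#'   in its matched set.
#' @param decoy_size target size of every generated set.
#' @param seed integer seed.
#' @return Named list of character vectors (class `gene_sets`); matched sets
#'   are named `<stage>_matched`, the negative control `colon_decoy`.
#' @export
generate_literature_sets <- function(truth, match_fraction = 0.5,
                                     decoy_size = 200L, seed = 1L) {
  if (inherits(truth, "synthetic_bundle")) truth <- truth$truth
  if (match_fraction < 0 || match_fraction > 1)
    stop("match_fraction must be in [0, 1]")
  universe <- truth$universe
  if (decoy_size > length(universe))
    stop("decoy_size exceeds the gene universe")
  set.seed(as.integer(seed))
  planted_all <- unlist(truth$program_genes, use.names = FALSE)

  sets <- lapply(names(truth$program_genes), function(stage) {
    planted <- truth$program_genes[[stage]]
    n_match <- round(match_fraction * length(planted))
    core <- if (n_match > 0) sample(planted, n_match) else character()
    n_fill <- max(0L, decoy_size - length(core))
    pool <- setdiff(universe, planted)
    c(core, sample(pool, min(n_fill, length(pool))))
  })
  names(sets) <- paste0(names(truth$program_genes), "_matched")
  neutral <- setdiff(universe, planted_all)
  if (decoy_size > length(neutral))
    stop("decoy_size exceeds the non-planted gene pool")
  sets$colon_decoy <- sample(neutral, decoy_size)
  structure(sets, class = c("gene_sets", "list"))
}

#' Simulate a qRT-PCR Ct table with a planted regional gradient
#'
#' Each biological sample in each region yields `n_technical` technical
#' replicate Ct measurements per gene. The gene Ct is the fixed housekeeping
#' Ct minus the region's planted delta-Ct plus Gaussian noise, so a positive
#' delta-Ct means higher expression (lower cycle threshold).
#'
#' @param regions character vector of group labels (e.g. proximal/middle/distal).
#' @param genes character vector of assayed genes.
#' @param gradient named list, one entry per gene, each a numeric vector of
#'   per-region delta-Ct values named by region (missing regions default 0).
#' @param noise_sd Gaussian sd on the gene Ct, in cycles.
#' @param n_per_region biological samples per region.
#' @param n_technical technical replicates per sample and gene.
#' @param housekeeping_ct fixed housekeeping cycle threshold.
#' @param seed integer seed.
#' @return Data frame with columns `sample_id`, `group`, `gene`, `replicate`,
#'   `gene_ct`, `housekeeping_ct`.
#' @export
generate_qpcr <- function(regions, genes, gradient = list(),
                          noise_sd = 0.25, n_per_region = 5L,
                          n_technical = 3L, housekeeping_ct = 20,
                          seed = 1L) {
  if (length(regions) < 1L || length(genes) < 1L)
    stop("regions and genes must be non-empty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(n_technical),
                      gene = genes,
                      bio = seq_len(n_per_region),
                      group = regions,
                      stringsAsFactors = FALSE)
  dct <- mapply(function(g, r) {
    v <- gradient[[g]]
    if (is.null(v)) return(0)
    val <- unname(v[r])
    if (length(val) != 1L || is.na(val)) 0 else val
  }, grid$gene, grid$group)
  gene_ct <- housekeeping_ct - dct + stats::rnorm(nrow(grid), 0, noise_sd)
  data.frame(sample_id = paste0(grid$group, "_s", grid$bio),
             group = grid$group,
             gene = grid$gene,
             replicate = grid$replicate,
             gene_ct = gene_ct,
             housekeeping_ct = housekeeping_ct,
             stringsAsFactors = FALSE)
}

#' Write a synthetic bundle to disk
#'
#' Writes the counts (TSV, gene id first column), transcript lengths
#' (two-column TSV), sample table (TSV), literature gene sets (GMT) and the
#' planted truth (JSON) under `dir`.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory, created if needed.
#' @param sets optional `gene_sets` to write as GMT.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir, sets = NULL) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(bundle$counts$values, paths[["counts"]])
  utils::write.table(
    data.frame(gene_id = names(bundle$counts$gene_lengths),
               length = unname(bundle$counts$gene_lengths)),
    paths[["lengths"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$design$samples, paths[["samples"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(program_genes = bundle$truth$program_genes,
         fold_change = bundle$truth$fold_change,
         baseline_mean = bundle$truth$baseline_mean,
         dispersion = bundle$truth$dispersion,
         seed = bundle$truth$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(sets)) {
    paths[["gene_sets"]] <- file.path(dir, "gene_sets.gmt")
    write_gmt(sets, paths[["gene_sets"]])
  }
  invisible(paths)
}
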