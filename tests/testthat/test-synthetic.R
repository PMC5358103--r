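test_that("stage designs count samples correctly and reject bad input", {
  d <- generate_design(c("ES", "DE", "OD5", "OD7", "OD10"), 3L)
  expect_equal(nrow(d$samples), 15L)
  expect_false(anyDuplicated(d$samples$sample_id) > 0)

  # the study layout: 42 samples across five stages
  d42 <- generate_design(c("ES", "DE", "OD5", "OD7", "OD10"),
                         c(8L, 8L, 9L, 9L, 8L))
  expect_equal(nrow(d42$samples), 42L)

  # a single-stage design is a valid (if degenerate) layout
  d1 <- generate_design("ES", 4L)
  expect_equal(nrow(d1$samples), 4L)

  expect_error(generate_design(c("ES", "ES"), 2L), "duplicate")
  expect_error(generate_design(character(), 1L))
  expect_error(generate_design("ES", 0L), "positive")
})

test_that("planted counts follow the stated generative model", {
  b <- generate_counts(generate_design(c("ES", "DE", "OD5", "OD7", "OD10"), 3L),
                       n_genes = 2000L, program_size = 200L, fold_change = 8,
                       baseline_mean = 50, dispersion = 0.1, seed = 7L)
  cm <- b$counts
  expect_s3_class(cm, "count_matrix")
  expect_equal(dim(cm$values), c(2000L, 15L))
  expect_true(all(cm$values >= 0))
  expect_equal(unname(cm$totals), unname(colSums(cm$values)))
  expect_true(all(cm$gene_lengths >= 500 & cm$gene_lengths <= 5000))

  # planted sets are pairwise disjoint and drawn from the matrix genes
  planted <- b$truth$program_genes
  expect_false(anyDuplicated(unlist(planted)) > 0)
  expect_true(all(unlist(planted) %in% rownames(cm$values)))

  # empirical planted/background mean ratio ~ fold_change, after undoing the
  # per-sample size factors the generator reports
  adj <- sweep(cm$values, 2L, b$truth$size_factors, `/`)
  stage_of <- b$design$samples$stage
  for (s in c("ES", "OD10")) {
    own <- adj[planted[[s]], stage_of == s]
    bg <- adj[setdiff(rownames(adj), unlist(planted)), stage_of == s]
    ratio <- mean(own) / mean(bg)
    # 3-standard-error band on the planted-gene mean
    se <- stats::sd(own) / sqrt(length(own)) / mean(bg)
    expect_gt(ratio, 8 - 3 * se - 3 * 0.05)
    expect_lt(ratio, 8 + 3 * se + 3 * 0.05)
  }

  expect_error(generate_counts(b$design, n_genes = 100L, program_size = 200L),
               "at least")
  expect_error(generate_counts(b$design, fold_change = 1), "fold_change")
  expect_error(generate_counts(b$design, baseline_mean = -1), "positive")
})

test_that("synthetic generation is bit-identical under a fixed seed", {
  b1 <- small_bundle(seed = 11)
  b2 <- small_bundle(seed = 11)
  b3 <- small_bundle(seed = 12)
  expect_identical(b1$counts$values, b2$counts$values)
  expect_identical(b1$counts$gene_lengths, b2$counts$gene_lengths)
  expect_false(identical(b1$counts$values, b3$counts$values))

  q1 <- generate_qpcr("proximal", "PDX1", seed = 3L)
  q2 <- generate_qpcr("proximal", "PDX1", seed = 3L)
  expect_identical(q1, q2)
})

test_that("matched literature sets hit the planted programs at the requested fraction", {
  b <- small_bundle(seed = 2)
  # identity case: full match, no fillers
  sets1 <- generate_literature_sets(b, match_fraction = 1, decoy_size = 60L,
                                    seed = 5L)
  expect_setequal(sets1$ES_matched, b$truth$program_genes$ES)

  # half match topped up with fillers: overlap = 30 planted genes exactly,
  # because fillers are drawn outside the program
  sets <- generate_literature_sets(b, match_fraction = 0.5, decoy_size = 60L,
                                   seed = 5L)
  for (st in names(b$truth$program_genes)) {
    ov <- intersect(sets[[paste0(st, "_matched")]], b$truth$program_genes[[st]])
    expect_length(ov, 30L)
    expect_length(sets[[paste0(st, "_matched")]], 60L)
  }
  # the decoy avoids every planted program
  expect_length(intersect(sets$colon_decoy,
                          unlist(b$truth$program_genes)), 0L)

  # zero match: pure noise set
  sets0 <- generate_literature_sets(b, match_fraction = 0, decoy_size = 60L,
                                    seed = 5L)
  expect_length(intersect(sets0$ES_matched, b$truth$program_genes$ES), 0L)

  expect_error(generate_literature_sets(b, decoy_size = 10000L), "universe")
  expect_error(generate_literature_sets(b, match_fraction = 2), "match_fraction")
})

test_that("qPCR tables encode the planted delta-Ct gradient", {
  # noiseless table: AU downstream is exact
  q <- generate_qpcr(c("proximal", "distal"), "PDX1",
                     gradient = list(PDX1 = c(proximal = 3, distal = 0)),
                     noise_sd = 0, n_per_region = 2L, seed = 1L)
  au <- arbitrary_units(q$gene_ct, q$housekeeping_ct)
  expect_equal(unique(au[q$group == "distal"]), 10000)
  # a 3-cycle delta-Ct advantage is an 8-fold AU ratio
  expect_equal(unique(au[q$group == "proximal"]) /
                 unique(au[q$group == "distal"]), 8)

  expect_error(generate_qpcr(character(), "PDX1"), "non-empty")
  expect_error(generate_qpcr("proximal", "PDX1", noise_sd = -1), "noise_sd")
})

test_that("bundles round-trip through their on-disk formats", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(dir, replicates = 2L, n_genes = 300L,
                       program_size = 30L, seed = 4L, qpcr = TRUE)
  expect_true(all(file.exists(file.path(
    dir, c("counts.tsv", "gene_lengths.tsv", "samples.tsv", "truth.json",
           "gene_sets.gmt", "qpcr.tsv")))))
  cm <- read_counts(file.path(dir, "counts.tsv"),
                    file.path(dir, "gene_lengths.tsv"))
  expect_equal(cm$values, b$counts$values)
  expect_equal(cm$gene_lengths, b$counts$gene_lengths)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(unclass(sets)[order(names(sets))],
                   lapply(b$sets, as.character)[order(names(b$sets))])
  des <- read_sample_table(file.path(dir, "samples.tsv"))
  expect_equal(des$samples$sample_id, b$design$samples$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_false(anyDuplicated(unlist(truth$program_genes)) > 0)
})
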