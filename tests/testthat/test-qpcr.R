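test_that("arbitrary units follow the 2^(dCt) x 10000 formula", {
  expect_identical(arbitrary_units(25, 25), 10000)
  expect_equal(arbitrary_units(26, 25), 5000)
  expect_equal(arbitrary_units(20, 15), 312.5)
  # one fewer cycle exactly doubles, so AU is strictly decreasing in gene Ct
  ct <- seq(15, 30, by = 0.5)
  au <- arbitrary_units(ct, 20)
  expect_equal(arbitrary_units(ct - 1, 20), 2 * au)
  expect_true(all(diff(au) < 0))
  expect_error(arbitrary_units(NA, 20), "finite")
  expect_error(arbitrary_units(20, Inf), "finite")
})

test_that("technical replicates collapse to per-sample AU means", {
  rec <- data.frame(
    sample_id = c("s1", "s1", "s2", "s2", "s2"),
    group = "proximal", gene = "PDX1",
    replicate = c(1, 2, 1, 2, 3),
    gene_ct = c(20, 20, 20 - log2(3), 20, NA),
    housekeeping_ct = 20)
  out <- collapse_technical_replicates(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$au[out$sample_id == "s1"], 10000)
  # AUs (30000, 10000) average to 20000; the missing Ct is dropped and counted
  expect_equal(out$au[out$sample_id == "s2"], 20000)
  expect_equal(out$n_replicates[out$sample_id == "s2"], 2L)
  expect_equal(out$n_missing[out$sample_id == "s2"], 1L)
  expect_error(collapse_technical_replicates(data.frame(x = 1)), "columns")
})

test_that("one-way ANOVA matches explicit sum-of-squares arithmetic", {
  groups <- list(a = c(6, 8, 4, 5, 3, 4),
                 b = c(8, 12, 9, 11, 6, 8),
                 c = c(13, 9, 11, 8, 7, 12))
  res <- one_way_anova(groups)
  expect_equal(res$f, anova_f_ss(groups), tolerance = 1e-12)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 15)
  expect_equal(res$p_value, pf(res$f, 2, 15, lower.tail = FALSE))

  # identical group means with spread: F = 0, p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(one_way_anova(same)$f, 0)
  expect_equal(one_way_anova(same)$p_value, 1)

  # two groups: F is the square of the pooled t statistic
  a <- c(2, 4, 5, 7); b <- c(6, 8, 9, 12)
  expect_equal(one_way_anova(list(a, b))$f,
               unpaired_t_test(a, b)$t^2, tolerance = 1e-12)

  # invariances: location shift and positive scaling
  shifted <- lapply(groups, `+`, 100)
  scaled <- lapply(groups, `*`, 3.5)
  expect_equal(one_way_anova(shifted)$f, res$f, tolerance = 1e-9)
  expect_equal(one_way_anova(scaled)$f, res$f, tolerance = 1e-9)

  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(one_way_anova(list(a = c(2, 2), b = c(2, 2))), "identical")
})

test_that("the unpaired t-test pools variances and matches hand arithmetic", {
  # pooled sd 1, se = sqrt(2/3), t = -3 / sqrt(2/3)
  res <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(res$t, 4), tolerance = 1e-12)

  # a == b elementwise: t = 0, p = 1
  eq <- unpaired_t_test(c(1, 5, 9), c(1, 5, 9))
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  # |t| grows monotonically as b shifts away
  ts <- vapply(c(0.5, 1, 2, 4), function(c)
    abs(unpaired_t_test(c(1, 2, 3), c(1, 2, 3) + c)$t), 0)
  expect_true(all(diff(ts) > 0))

  # Welch flag gives the unequal-variance df
  w <- unpaired_t_test(c(1, 2, 3), c(10, 20, 30, 40), welch = TRUE)
  expect_lt(w$df, 5)
  expect_error(unpaired_t_test(c(2, 2), c(2, 2)), "variance")
})

test_that("summaries report n / mean / sem / median with the right stars", {
  expect_identical(significance_stars(c(0.04, 0.0005, 0.2, 0.009, 5e-5)),
                   c("*", "***", "", "**", "****"))

  q <- generate_qpcr(c("proximal", "middle", "distal"), c("PDX1", "GUCA2A"),
                     gradient = list(PDX1 = c(proximal = 3, middle = 1.5,
                                              distal = 0)),
                     noise_sd = 0.25, seed = 10L)
  col <- collapse_technical_replicates(q)
  s <- summarize_groups(col)
  expect_equal(nrow(s$groups), 6L)
  pdx <- s$groups[s$groups$gene == "PDX1", ]
  expect_equal(pdx$n, rep(5L, 3))
  expect_true(all(is.finite(pdx$sem_au)))
  # planted proximal-high gradient shows up in the means
  expect_gt(pdx$mean_au[pdx$group == "proximal"],
            pdx$mean_au[pdx$group == "distal"])
  expect_equal(s$tests$stars[s$tests$gene == "PDX1"], "****")

  # sem is sd/sqrt(n)
  one <- col[col$gene == "PDX1" & col$group == "distal", ]
  expect_equal(pdx$sem_au[pdx$group == "distal"],
               sd(one$au) / sqrt(nrow(one)))
})

test_that("a planted gradient is detected with high power at noise_sd 0.25", {
  hits <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    q <- generate_qpcr(c("proximal", "middle", "distal"), "PDX1",
                       gradient = list(PDX1 = c(proximal = 3, middle = 1.5,
                                                distal = 0)),
                       noise_sd = 0.25, seed = 5000L + i)
    col <- collapse_technical_replicates(q)
    groups <- split(col$au, col$group)
    ok <- mean(groups$proximal) > mean(groups$distal) &&
      one_way_anova(groups)$p_value < 0.05
    hits <- hits + ok
  }
  expect_gte(hits / n_sim, 0.95)
})
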