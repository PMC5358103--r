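#' qRT-PCR relative expression in arbitrary units
#'
#' `AU = 2^(housekeeping_ct - gene_ct) * 10000`: a gene amplifying at the
#' same cycle as the housekeeping gene scores exactly 10,000; each extra
#' cycle the gene needs halves the value.
#'
#' @param gene_ct gene cycle threshold(s).
#' @param housekeeping_ct housekeeping cycle threshold(s).
#' @return Arbitrary units (vectorized).
#' @examples
#' arbitrary_units(25, 25)   # 10000
#' arbitrary_units(20, 15)   # 312.5
#' @export
arbitrary_units <- function(gene_ct, housekeeping_ct) {
  if (any(!is.finite(gene_ct)) || any(!is.finite(housekeeping_ct)))
    stop("Ct values must be finite")
  2^(housekeeping_ct - gene_ct) * 10000
}

#' Average technical replicates to per-sample AU
#'
#' Converts each Ct record to arbitrary units and averages the technical
#' replicates of each (sample, gene) on the AU (linear) scale. Records with
#' missing Ct are dropped from the mean and counted.
#'
#' @param records data frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `gene_ct`, `housekeeping_ct`.
#' @return Data frame with one row per (sample, gene): `sample_id`, `group`,
#'   `gene`, `au`, `n_replicates`, `n_missing`.
#' @export
collapse_technical_replicates <- function(records) {
  needed <- c("sample_id", "group", "gene", "gene_ct", "housekeeping_ct")
  if (!all(needed %in% names(records)))
    stop("records must have columns ", paste(needed, collapse = ", "))
  ok <- is.finite(records$gene_ct) & is.finite(records$housekeeping_ct)
  au <- rep(NA_real_, nrow(records))
  au[ok] <- arbitrary_units(records$gene_ct[ok], records$housekeeping_ct[ok])
  key <- interaction(records$sample_id, records$gene, drop = TRUE)
  split_au <- split(au, key)
  first <- !duplicated(key)
  out <- data.frame(sample_id = records$sample_id[first],
                    group = records$group[first],
                    gene = records$gene[first],
                    stringsAsFactors = FALSE)
  idx <- match(interaction(out$sample_id, out$gene, drop = TRUE),
               names(split_au))
  out$au <- vapply(split_au[idx], function(v) mean(v, na.rm = TRUE), 0)
  out$n_replicates <- vapply(split_au[idx], function(v) sum(!is.na(v)), 0L)
  out$n_missing <- vapply(split_au[idx], function(v) sum(is.na(v)), 0L)
  out
}

#' One-way analysis of variance on arbitrary units
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom, via [stats::oneway.test()] with
#' equal variances assumed.
#'
#' @param groups named list of numeric vectors, one per group, each with at
#'   least 2 observations.
#' @return List with `f`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0)
    stop("all observations identical; F is undefined")
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(f = unname(ft$statistic), p_value = unname(ft$p.value),
       df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]))
}

#' Unpaired two-sample t-test on arbitrary units
#'
#' Pooled-variance (classical unpaired) t-test on `n_a + n_b - 2` degrees of
#' freedom, two-sided; Welch's unequal-variance form behind `welch = TRUE`.
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @param welch use the Welch correction instead of pooling.
#' @return List with `t`, `p_value`, `df`.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero pooled variance; t is undefined")
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p_value = unname(tt$p.value),
       df = unname(tt$parameter))
}

#' Significance stars at the conventional thresholds
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, `"***"` for p < 0.001,
#' `"****"` for p < 0.0001, empty otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) "****"
    else if (pp < 1e-3) "***"
    else if (pp < 1e-2) "**"
    else if (pp < 0.05) "*"
    else ""
  }, character(1))
}

#' Group summaries and per-gene test annotation
#'
#' Per (gene, group): n, mean AU, s.e.m. and median. Per gene, groups are
#' compared with one-way ANOVA (default) or, for two groups, optionally the
#' unpaired t-test, and the p-value is annotated with significance stars.
#'
#' @param collapsed output of [collapse_technical_replicates()] (columns
#'   `group`, `gene`, `au`).
#' @param test `"anova"` or `"t.test"` (the latter requires exactly 2 groups).
#' @return List of class `qpcr_summary`: `groups` (data frame gene, group,
#'   n, mean_au, sem_au, median_au) and `tests` (data frame gene, statistic,
#'   p_value, stars).
#' @export
summarize_groups <- function(collapsed, test = c("anova", "t.test")) {
  test <- match.arg(test)
  stopifnot(all(c("group", "gene", "au") %in% names(collapsed)))
  per <- split(collapsed, collapsed$gene)
  group_rows <- lapply(names(per), function(g) {
    d <- per[[g]]
    agg <- split(d$au, d$group)
    data.frame(gene = g, group = names(agg),
               n = lengths(agg),
               mean_au = vapply(agg, mean, 0),
               sem_au = vapply(agg, function(v)
                 if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
                 else NA_real_, 0),
               median_au = vapply(agg, stats::median, 0),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  test_rows <- lapply(names(per), function(g) {
    d <- per[[g]]
    agg <- split(d$au, d$group)
    res <- if (test == "anova") {
      r <- one_way_anova(agg); list(stat = r$f, p = r$p_value)
    } else {
      if (length(agg) != 2L) stop("t.test requires exactly 2 groups")
      r <- unpaired_t_test(agg[[1]], agg[[2]]); list(stat = r$t, p = r$p_value)
    }
    data.frame(gene = g, statistic = res$stat, p_value = res$p,
               stars = significance_stars(res$p),
               stringsAsFactors = FALSE)
  })
  structure(list(groups = do.call(rbind, group_rows),
                 tests = do.call(rbind, test_rows),
                 test = test),
            class = "qpcr_summary")
}

#' @export
print.qpcr_summary <- function(x, ...) {
  cat("qRT-PCR summary (", x$test, "):\n", sep = "")
  g <- x$groups
  g$mean_au <- signif(g$mean_au, 4); g$sem_au <- signif(g$sem_au, 3)
  g$median_au <- signif(g$median_au, 4)
  print(g, row.names = FALSE)
  t <- x$tests
  t$statistic <- signif(t$statistic, 4); t$p_value <- signif(t$p_value, 3)
  print(t, row.names = FALSE)
  invisible(x)
}
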