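# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::phyper/oneway.test) so that each check
# is a genuine cross-validation.

# Upper-tail hypergeometric by direct combinatorial enumeration:
# P(X >= x) = sum_i C(K, i) C(N-K, n-i) / C(N, n).
hyper_tail_enum <- function(x, n, K, N) {
  hi <- min(n, K)
  if (x > hi) return(0)
  i <- x:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# One-way ANOVA F by explicit sum-of-squares arithmetic.
anova_f_ss <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, 0))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# A small planted-truth bundle shared by several tests.
small_bundle <- function(seed = 1, ...) {
  design <- generate_design(c("ES", "DE", "OD5", "OD7", "OD10"), 3L)
  b <- generate_counts(design, n_genes = 600L, program_size = 60L,
                       fold_change = 8, seed = seed, ...)
  b$sets <- generate_literature_sets(b, match_fraction = 0.5,
                                     decoy_size = 60L, seed = seed + 1000L)
  b
}
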