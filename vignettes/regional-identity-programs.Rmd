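---
title: "Discovering stage-enriched expression programs and scoring regional identity"
author: "regionid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering stage-enriched expression programs and scoring regional identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionid)
```

## The problem

Human intestinal organoids derived from embryonic stem cells pass through a
series of differentiation stages — pluripotent cells (ES), definitive
endoderm (DE), and organoids grown from spheroids collected after 5, 7 or 10
days of WNT/FGF exposure (OD5, OD7, OD10). The biological question is whether
the later organoid stages acquire a distinct regional identity along the
proximal–distal axis of the small intestine: do OD5 organoids express a
duodenum-like transcriptome and OD10 organoids an ileum-like one?

`regionid` answers that question in two steps. First it extracts, from a
staged bulk RNA-seq count matrix, *gene expression programs*: cohorts of
genes whose expression rises together at one stage. Second, it asks whether
each program overlaps published regional gene sets (duodenal, ileal,
colonic) more than chance would allow.

## The model and procedure

### Normalization

Transcript counts $c_{gs}$ with transcript length $L_g$ (bp) and per-sample
mapped-read total $T_s$ are converted to

$$\mathrm{FPKM}_{gs} = \frac{c_{gs} \times 10^9}{L_g \, T_s}.$$

Transcripts whose *maximum* FPKM across all samples is strictly below 1 are
discarded; a row whose maximum is exactly 1 is retained (we read "less than
one" literally). Each surviving gene is then divided by its mean across
samples, so every row of the analysed matrix $V$ has mean 1. This removes
absolute-abundance bias: the factorization sees only how a gene's
expression is *distributed* across stages, not how high it is.

When mapped-read totals accompany the counts they are used directly for the
per-million correction; column sums are the fallback. The totals from an
aligner need not equal the column sums of a (possibly filtered) matrix,
which is why a supplied value wins. The pipeline is agnostic to whether
rows are transcripts or genes; no collapsing is performed.

An optional step restricts $V$ to a gene class (e.g. DNA-binding proteins
from PFAM annotations) for a more interpretable factorization; by default
mean normalization happens on the full filtered matrix and the subset is
taken afterwards, so a gene's scaling does not depend on which class view
is being factorized.

### Replicated non-negative matrix factorization

The mean-normalized matrix $V \ (genes \times samples)$ is factorized as
$V \approx WH$ with $W \ge 0$ (gene loadings, genes × k) and $H \ge 0$
(program activity per sample, k × samples), minimizing the squared
Frobenius error $\lVert V - WH\rVert_F^2$ with the Lee–Seung multiplicative
updates. The updates can only decrease the objective, which the fit records
per iteration (`fit$trace`) and the tests assert. Generalized
Kullback–Leibler divergence is available behind `objective = "kl"`; both
interpretations of the underlying method exist in the literature, and
Frobenius is our default because "highest scoring factorization" then has
the unambiguous reading *lowest reconstruction error*.

Because multiplicative updates find local optima, the factorization is run
as 10 random restarts (`nnmf_replicates()`, seeds `base_seed + 0..9`) and
the restart with the smallest objective wins; ties break to the lowest
seed, and all replicate objectives are retained for audit.

Numerical choices: both factors initialize uniform-random on (0, 1); a
guard of $10^{-10}$ is added to update denominators; convergence is a
relative objective change below $10^{-6}$, capped at 2000 iterations.
All-zero rows cannot reach the factorization — the FPKM filter removes
them upstream.

The rank $k$ is a genuinely open choice: nothing in the analysed design
fixes it, so the default is the number of distinct stages (5 here), which
is the number of "one program per stage" patterns the study design can
express. It is overridable, and no automatic rank selection (consensus
clustering, cophenetic correlation) is attempted.

### The 2-SD membership rule

A gene belongs to program $j$ when its loading exceeds
$\mathrm{mean}(W_{\cdot j}) + 2\,\mathrm{SD}(W_{\cdot j})$, strictly. The SD
is the population SD (divide by $n$) by default — the source of the rule
does not say which, so the choice is exposed (`sd_type = "sample"`). The
strict inequality means a degenerate column with all-equal loadings yields
an *empty* program (SD 0, nothing exceeds the mean) rather than a full
one. The SD is taken over genes within a program column, which is the
natural reading of "the mean loading in the program".

Each program is assigned the stage with the highest mean $H$ coefficient
over that stage's samples, and flagged non-specific when the top stage's
mean is less than twice the runner-up's (ratio configurable).

### Hypergeometric enrichment

For a program with $n$ member genes and a literature set with $K$ genes
inside the universe of $N$ analysed genes, an overlap of $x$ genes is
scored by the upper tail $P(X \ge x)$, $X \sim \mathrm{Hypergeom}(N, K,
n)$ — the over-representation convention, $\ge$ not $>$. Raw p-values are
the headline output (matching how such overlaps are conventionally
reported); Benjamini–Hochberg adjustment is an optional column. Sets with
fewer than 10 in-universe genes are flagged rather than dropped, mirroring
the caution that very small regional sets do not support confident
comparison. Gene identifiers match as exact strings; no ortholog mapping
is attempted.

The universe is a design decision the source analysis leaves unstated. The
default is the set of genes surviving the FPKM filter (the genes that
*could* have entered a program); `universe = "filtered_and_sets"` restricts
to filtered genes that the literature annotation space also covers.

### qRT-PCR arbitrary units

Marker validation uses the arbitrary-units transform
$\mathrm{AU} = 2^{\,\mathrm{Ct}_{hk} - \mathrm{Ct}_{gene}} \times 10{,}000$:
a gene amplifying at the housekeeping cycle scores exactly 10,000 and each
additional cycle halves the value. Technical replicates are averaged on
the AU (linear) scale, since that is the plotted scale; at small replicate
spread the difference from Ct-scale averaging is second-order. Groups are
compared with classical one-way ANOVA (pooled-variance unpaired *t*-test
for two-group designs, Welch behind a flag) and annotated with the
conventional star thresholds (0.05, 0.01, 0.001, 0.0001), per gene and
uncorrected across genes, matching the presentation style of the source
figures.

## What the synthetic generator emulates — and what it does not

`simulate_bundle()` builds a study with the same *shape* as the real one:
five stages with replicates (default 5 × 3 = 15 samples; the real study ran
42 samples whose per-stage split is unpublished, so the split is a
configurable plumbing choice), a genome-scale gene list, and one disjoint
block of genes per stage whose negative-binomial mean is multiplied by a
fold change in that stage only. Defaults: 2000 genes, 200-gene programs,
fold change 8, baseline mean 50, NB dispersion 0.1 — a strong, clean
stage signal of the kind the factorization is meant to recover.
Transcript lengths are uniform on 500–5000 bp and per-sample size factors
log-normal(0, 0.2), so both FPKM corrections do real work.
"Literature" sets are planted with a controlled match fraction plus random
filler, and one fully random set disjoint from every program plays the
colon negative control. The qPCR generator plants a per-region
$\Delta\mathrm{Ct}$ gradient around a fixed housekeeping Ct of 20, with
Gaussian noise only on the gene channel so AU variance is attributable to
it.

What it does **not** emulate: correlated gene–gene noise, batch effects,
isoform structure, graded (rather than single-stage) programs, ortholog
ambiguity between species, or the partially overlapping biology of adjacent
regions. Passing the planted-recovery tests therefore shows the machinery
is correct and well-calibrated, not that real organoid data will yield
equally crisp programs.

## Validation summary

The test suite checks, among others: FPKM/filter/mean-normalization
contracts against hand-computed cases; NMF objective monotonicity on random
matrices and exact recovery of low-rank matrices; the 2-SD rule against a
hand-computed loading column; the hypergeometric tail against exhaustive
combinatorial enumeration for every parameterization with $N \le 20$;
ANOVA and *t* statistics against explicit sum-of-squares and hand
arithmetic; end-to-end recovery of all five planted programs (precision and
recall ≥ 0.8, bijective program↔stage assignment) across ten simulation
seeds on the 2000-gene bundle; enrichment discrimination (half-matched sets
at $p < 10^{-10}$, the colon-like decoy never below 0.01); and uniform
calibration of null enrichment p-values. Problem sizes in the tests (600 or
2000 genes, 15 samples) were chosen so the whole suite represents the
default study conditions while running in well under a minute per file.

## Worked example

```{r example, eval = FALSE}
library(regionid)
bundle <- simulate_bundle(seed = 1)          # 2000 genes x 15 samples
result <- run_pipeline(bundle, sets = bundle$sets)
result                                        # programs + best-set table
summary(result$fit)                           # replicate objectives
head(result$enrichment)
```

## Known limitations

- Multiplicative-update NMF converges to local optima; 10 restarts is a
  pragmatic, not exhaustive, safeguard.
- The rank default ties programs to stages one-to-one; biology with shared
  or split programs needs a manually chosen `k`.
- Enrichment assumes the universe is honest; mixing annotation spaces
  between programs and gene sets silently deflates or inflates $N$, which
  is why program members outside the universe raise an error.
- No multiple-testing correction in the headline p-values (by design,
  matching the reporting convention); switch on `bh_correction` when
  screening many sets.
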