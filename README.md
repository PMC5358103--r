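# regionid

Regional identity scoring of staged transcriptomes by replicated
non-negative matrix factorization.

## What this is for

Human intestinal organoids differentiated from embryonic stem cells pass
through staged conditions — pluripotent cells (ES), definitive endoderm
(DE), and organoids from spheroids collected after 5, 7 or 10 days of
WNT/FGF exposure (OD5, OD7, OD10). A central question is whether the later
stages acquire proximal (duodenum-like) versus distal (ileum-like)
intestinal identity. `regionid` answers it from a bulk RNA-seq count
matrix in two steps:

1. **Program discovery.** Counts are normalized to FPKM
   (`count × 10⁹ / (length_bp × mapped_reads)`), transcripts whose maximum
   FPKM never reaches 1 are discarded, each gene is scaled by its mean
   across samples, and the resulting matrix `V` (genes × samples) is
   factorized as `V ≈ WH`, `W, H ≥ 0`, by Lee–Seung multiplicative updates
   minimizing `‖V − WH‖²_F`. Ten random restarts are run and the lowest
   reconstruction error wins. A gene is a member of program *j* when its
   loading exceeds `mean(W[,j]) + 2·SD(W[,j])`, and each program is
   assigned the stage where its `H` coefficients are highest.
2. **Regional scoring.** Each program's overlap of `x` genes with a
   literature regional gene set (`K` genes) inside the analysed universe
   (`N` genes) is scored with the upper-tail hypergeometric probability
   `P(X ≥ x)`, `X ~ Hypergeom(N, K, n)` — duodenal and ileal sets as
   positives, a colonic set as the negative control.

A qRT-PCR module implements the companion marker analysis: arbitrary units
`AU = 2^(housekeeping Ct − gene Ct) × 10,000`, technical-replicate
collapsing, one-way ANOVA / unpaired *t*-test group comparisons and star
annotations. A synthetic-data module plants known stage programs in
negative-binomial counts so every pipeline stage can be verified against
ground truth without any download.

## Worked example

```r
library(regionid)
bundle <- simulate_bundle(seed = 1)          # 2000 genes x 15 samples, 5 stages
result <- run_pipeline(bundle, sets = bundle$sets)
result
```

```
Regional-identity pipeline result
  2000 transcripts; 0 removed by max-FPKM < 1; 2000 analysed
Non-negative matrix factorization (frobenius)
  V: 2000 genes x 15 samples, rank k = 5
  objective 3605.65 after 187 iterations (converged, seed 2)
  best of 10 replicates
Expression programs (loading > mean + 2 population SD):
  P1: 199 genes
  P2: 199 genes
  P3: 198 genes
  P4: 200 genes
  P5: 198 genes
  best gene set per program:
 program stage          set overlap        p
      P1   OD7  OD7_matched     100 1.62e-56
      P2    DE   DE_matched      99 2.74e-55
      P3  OD10 OD10_matched      98 2.41e-54
      P4   OD5  OD5_matched     100 3.07e-56
      P5    ES   ES_matched      98 2.41e-54
```

Reading this: all five planted 200-gene programs were recovered nearly
exactly (198–200 members each), every program was assigned its own stage,
and each one overlaps its half-matched "literature" set in ~100 genes — an
overlap a random draw from the 2000-gene universe would essentially never
produce (p ≈ 10⁻⁵⁶) — while the colon-like decoy set stays non-significant.
The qPCR formula behaves as advertised:

```r
arbitrary_units(c(25, 26, 20), c(25, 25, 15))
#> [1] 10000.0  5000.0   312.5
```

`run_pipeline(..., out_dir = "out/")` additionally writes every
intermediate (FPKM, filtered and mean-normalized matrices, `W`, `H`,
replicate objective log, programs as GMT/JSON, enrichment TSV, heatmap
PNG + TSV sidecars), bit-identically across reruns with the same seeds.
A thin command-line wrapper with `simulate` and `run` subcommands lives at
`inst/scripts/regionid.R`.

## Documentation

The methods vignette (`vignettes/regional-identity-programs.Rmd`) explains
the model, its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
known limitations.
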