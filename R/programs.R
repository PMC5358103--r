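#' Extract gene expression programs by the 2-SD loading rule
#'
#' A gene belongs to program j when its loading `W[g, j]` is strictly more
#' than `sd_multiplier` standard deviations above the mean loading of that
#' program's column. The default multiplier is 2, and the SD is the
#' population SD (divide by n); the sample SD (divide by n - 1) is available
#' via `sd_type`. A degenerate column with all-equal loadings has SD 0, so
#' the strict inequality makes its program empty.
#'
#' @param fit an `nnmf` fit.
#' @param sd_multiplier number of SDs above the column mean (default 2).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Object of class `expression_programs`: list with `members`
#'   (named list of gene-id vectors, one per program), `thresholds`,
#'   `sd_multiplier`, `sd_type`, and the loading matrix `W`.
#' @export
extract_programs <- function(fit, sd_multiplier = 2,
                             sd_type = c("population", "sample")) {
  stopifnot(inherits(fit, "nnmf"))
  sd_type <- match.arg(sd_type)
  W <- fit$W
  n <- nrow(W)
  mu <- colMeans(W)
  ss <- colSums(sweep(W, 2L, mu)^2)
  sdv <- sqrt(ss / if (sd_type == "population") n else n - 1L)
  thresholds <- mu + sd_multiplier * sdv
  members <- lapply(seq_len(ncol(W)), function(j)
    rownames(W)[W[, j] > thresholds[j]])
  names(members) <- colnames(W)
  names(thresholds) <- colnames(W)
  structure(list(members = members, thresholds = thresholds,
                 sd_multiplier = sd_multiplier, sd_type = sd_type, W = W),
            class = "expression_programs")
}

#' @export
print.expression_programs <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("Expression programs (loading > mean + ", x$sd_multiplier, " ",
      x$sd_type, " SD):\n", sep = "")
  for (j in seq_along(sizes)) {
    cat("  ", names(sizes)[j], ": ", sizes[j], " genes",
        if (!is.null(attr(x, "stages"))) paste0(" [", attr(x, "stages")[j], "]"),
        if (sizes[j] == 0L) "  (empty)", "\n", sep = "")
  }
  invisible(x)
}

#' Assign each program to the stage where it is most active
#'
#' A program's activity in a stage is the mean of its `H` coefficients over
#' that stage's samples. Each program gets the stage with the highest mean;
#' it is flagged non-specific when the top stage's mean is less than
#' `specificity_ratio` times the runner-up's.
#'
#' @param fit an `nnmf` fit whose `H` columns align with `design`.
#' @param design a `stage_design` covering exactly the fitted samples.
#' @param specificity_ratio top-to-second mean ratio below which a program
#'   is flagged non-specific (default 2).
#' @return Data frame with one row per program: `program`, `stage`,
#'   `top_mean`, `second_mean`, `specific`.
#' @export
assign_program_stages <- function(fit, design, specificity_ratio = 2) {
  stopifnot(inherits(fit, "nnmf"), inherits(design, "stage_design"))
  samp <- design$samples
  if (!setequal(colnames(fit$H), samp$sample_id) ||
      ncol(fit$H) != nrow(samp))
    stop("design samples do not match the factorized samples")
  stage_of <- stats::setNames(as.character(samp$stage), samp$sample_id)
  stages <- design$stages
  stage_means <- sapply(stages, function(s)
    rowMeans(fit$H[, names(stage_of)[stage_of == s], drop = FALSE]))
  if (is.null(dim(stage_means)))
    stage_means <- matrix(stage_means, nrow = 1,
                          dimnames = list(rownames(fit$H), stages))
  top <- apply(stage_means, 1L, which.max)
  sorted <- apply(stage_means, 1L, sort, decreasing = TRUE)
  top_mean <- sorted[1L, ]
  second_mean <- if (length(stages) > 1L) sorted[2L, ] else rep(0, nrow(fit$H))
  data.frame(program = rownames(fit$H),
             stage = stages[top],
             top_mean = top_mean,
             second_mean = second_mean,
             specific = top_mean >= specificity_ratio * second_mean,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
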