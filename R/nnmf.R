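#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative genes x samples matrix `V` as `V ~ W %*% H`
#' with `W` (genes x k, the gene loadings) and `H` (k x samples, the
#' per-sample program coefficients) both non-negative, using the Lee-Seung
#' multiplicative update rules. The default objective is the squared
#' Frobenius reconstruction error `||V - WH||_F^2`; generalized
#' Kullback-Leibler divergence is available via `objective = "kl"`. Both
#' factors are initialized uniform-random on (0, 1) from `seed`, and the
#' objective trace is non-increasing by construction of the updates.
#'
#' Iteration stops when the relative objective change drops below `tol`
#' or after `max_iter` iterations.
#'
#' @param V an `expr_matrix` (typically mean-normalized) or a non-negative
#'   numeric matrix.
#' @param k factorization rank, `1 <= k <= min(dim(V))`. Each of the k
#'   factors is interpreted downstream as a candidate gene expression
#'   program.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-change convergence threshold.
#' @param seed integer seed for the random initialization.
#' @param objective `"frobenius"` (default) or `"kl"`.
#' @param eps small constant guarding denominators of the updates.
#' @return Object of class `nnmf`: list with `W`, `H`, `k`, `objective`
#'   (final value), `objective_type`, `trace` (objective per iteration),
#'   `n_iter`, `converged`, `seed`, and the input matrix `V` (as a plain
#'   matrix) with any stage labels in `stages`.
#' @seealso [nnmf_replicates()] for restart selection, [extract_programs()]
#'   for the 2-SD membership rule.
#' @export
nnmf <- function(V, k, max_iter = 2000L, tol = 1e-6, seed = 1L,
                 objective = c("frobenius", "kl"), eps = 1e-10) {
  objective <- match.arg(objective)
  stages <- NULL
  if (inherits(V, "expr_matrix")) {
    stages <- V$stages
    V <- V$values
  }
  V <- as.matrix(V)
  if (any(V < 0) || any(!is.finite(V)))
    stop("V must be finite and non-negative")
  n <- nrow(V); m <- ncol(V)
  if (k < 1L || k > min(n, m))
    stop("rank k must satisfy 1 <= k <= min(genes, samples) = ", min(n, m))

  set.seed(as.integer(seed))
  W <- matrix(stats::runif(n * k), n, k)
  H <- matrix(stats::runif(k * m), k, m)

  loss <- function(W, H) {
    R <- W %*% H
    if (objective == "frobenius") sum((V - R)^2)
    else sum(ifelse(V > 0, V * log(V / pmax(R, eps)), 0) - V + R)
  }

  trace <- numeric(max_iter)
  prev <- loss(W, H)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (objective == "frobenius") {
      H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
      W <- W * tcrossprod(V, H) / (W %*% tcrossprod(H) + eps)
    } else {
      R <- pmax(W %*% H, eps)
      H <- H * crossprod(W, V / R) / (colSums(W) + eps)
      R <- pmax(W %*% H, eps)
      W <- W * tcrossprod(V / R, H) /
        matrix(rowSums(H), n, k, byrow = TRUE)
    }
    cur <- loss(W, H)
    trace[it] <- cur
    if (prev > 0 && abs(prev - cur) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- cur
  }

  dimnames(W) <- list(rownames(V), paste0("P", seq_len(k)))
  dimnames(H) <- list(paste0("P", seq_len(k)), colnames(V))
  structure(list(W = W, H = H, k = k, objective = trace[it],
                 objective_type = objective, trace = trace[seq_len(it)],
                 n_iter = it, converged = converged, seed = as.integer(seed),
                 V = V, stages = stages),
            class = "nnmf")
}

#' Replicated NMF with best-factorization selection
#'
#' Runs [nnmf()] `n_replicates` times with seeds `base_seed, base_seed + 1,
#' ...` and returns the replicate with the lowest final objective ("highest
#' scoring" factorization); ties go to the lowest seed. All replicate
#' objectives are kept in the result's `replicate_objectives`.
#'
#' @inheritParams nnmf
#' @param n_replicates number of random restarts (default 10).
#' @param base_seed seed of the first replicate.
#' @param ... further arguments passed to [nnmf()].
#' @return The winning `nnmf` fit, with `replicate_objectives` (named by
#'   seed) attached.
#' @export
nnmf_replicates <- function(V, k, n_replicates = 10L, base_seed = 1L, ...) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  seeds <- as.integer(base_seed) + seq_len(n_replicates) - 1L
  fits <- lapply(seeds, function(s) nnmf(V, k, seed = s, ...))
  objs <- vapply(fits, `[[`, numeric(1), "objective")
  best <- fits[[which.min(objs)]]  # which.min takes the first (lowest seed) tie
  best$replicate_objectives <- stats::setNames(objs, seeds)
  best
}

#' @export
print.nnmf <- function(x, ...) {
  cat("Non-negative matrix factorization (", x$objective_type, ")\n", sep = "")
  cat("  V: ", nrow(x$V), " genes x ", ncol(x$V), " samples, rank k = ",
      x$k, "\n", sep = "")
  cat("  objective ", format(x$objective, digits = 6), " after ", x$n_iter,
      " iterations (", if (x$converged) "converged" else "max_iter reached",
      ", seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$replicate_objectives))
    cat("  best of", length(x$replicate_objectives), "replicates\n")
  invisible(x)
}

#' @export
summary.nnmf <- function(object, ...) {
  rel <- object$objective / sum(object$V^2)
  out <- list(
    dims = dim(object$V), k = object$k,
    objective = object$objective, relative_error = rel,
    n_iter = object$n_iter, converged = object$converged,
    replicate_objectives = object$replicate_objectives,
    program_scale = colSums(object$W))
  class(out) <- "summary.nnmf"
  out
}

#' @export
print.summary.nnmf <- function(x, ...) {
  cat("NMF fit: ", x$dims[1], " x ", x$dims[2], ", k = ", x$k, "\n", sep = "")
  cat("  objective ", format(x$objective, digits = 6),
      " (relative to ||V||^2: ", format(x$relative_error, digits = 3),
      "), ", x$n_iter, " iterations\n", sep = "")
  if (!is.null(x$replicate_objectives)) {
    cat("  replicate objectives:\n")
    print(signif(x$replicate_objectives, 6))
  }
  invisible(x)
}

#' Extract factor matrices from an NMF fit
#'
#' @param object an `nnmf` fit.
#' @param which `"W"` for gene loadings (default), `"H"` for sample
#'   coefficients, or `"both"` for a list of the two.
#' @param ... unused.
#' @return The requested matrix or a list of both.
#' @export
coef.nnmf <- function(object, which = c("W", "H", "both"), ...) {
  which <- match.arg(which)
  switch(which, W = object$W, H = object$H,
         both = list(W = object$W, H = object$H))
}

#' @export
fitted.nnmf <- function(object, ...) object$W %*% object$H

#' @export
residuals.nnmf <- function(object, ...) object$V - fitted(object)

#' Project new samples onto fitted programs
#'
#' Holds the gene-loading matrix `W` fixed and fits non-negative
#' coefficients for new sample columns by the same multiplicative update,
#' i.e. solves `newdata ~ W %*% H_new` over `H_new >= 0`.
#'
#' @param object an `nnmf` fit (Frobenius objective).
#' @param newdata genes x new-samples matrix (or `expr_matrix`) with the
#'   same genes, in the same order, as the fitted `V`.
#' @param max_iter,tol iteration controls.
#' @param ... unused.
#' @return k x new-samples coefficient matrix.
#' @export
predict.nnmf <- function(object, newdata, max_iter = 500L, tol = 1e-8, ...) {
  if (inherits(newdata, "expr_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (nrow(newdata) != nrow(object$W))
    stop("newdata must have the fitted gene rows")
  if (object$objective_type != "frobenius")
    stop("projection is implemented for the Frobenius objective")
  eps <- 1e-10
  W <- object$W
  H <- matrix(stats::runif(object$k * ncol(newdata), 0.5, 1),
              object$k, ncol(newdata))
  WtV <- crossprod(W, newdata)
  WtW <- crossprod(W)
  prev <- Inf
  for (i in seq_len(max_iter)) {
    H <- H * WtV / (WtW %*% H + eps)
    cur <- sum((newdata - W %*% H)^2)
    if (is.finite(prev) && prev > 0 && abs(prev - cur) / prev < tol) break
    prev <- cur
  }
  dimnames(H) <- list(colnames(W), colnames(newdata))
  H
}

#' Plot an NMF objective trace
#'
#' @param x an `nnmf` fit.
#' @param log use a log objective axis (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.nnmf <- function(x, log = TRUE, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 log = if (log) "y" else "",
                 xlab = "iteration", ylab = "reconstruction objective", ...)
  invisible(x)
}
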