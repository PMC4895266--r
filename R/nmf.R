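#' Configuration for one penalized NMF fit
#'
#' @param alpha Non-negative weight of the conflicting-bin penalty
#'   (default 0.1).
#' @param c Binarization threshold in (0, 1) applied to the bias-corrected
#'   factor `A^-1 W` (default 0.4).
#' @param max_iter Maximum number of multiplicative-update iterations.
#' @param tol Relative objective-change convergence threshold, assessed over
#'   a trailing window of `window` iterations.
#' @param epsilon Positive smoothing floor used inside logs and divisions.
#' @param seed Integer seed for the random initialization.
#' @param window Trailing window (iterations) for the convergence check.
#' @return A list of class `nmf_config`.
#' @export
nmf_config <- function(alpha = 0.1, c = 0.4, max_iter = 2000, tol = 1e-6,
                       epsilon = 1e-10, seed = 1L, window = 10L) {
  stopifnot(alpha >= 0, c > 0, c < 1, max_iter >= 1, tol > 0, epsilon > 0,
            window >= 1)
  structure(list(alpha = alpha, c = c, max_iter = as.integer(max_iter),
                 tol = tol, epsilon = epsilon, seed = as.integer(seed),
                 window = as.integer(window)),
            class = "nmf_config")
}

## Coerce V argument to a plain matrix (+ carry scheme conflicts if present)
as_V <- function(V) {
  if (inherits(V, "normalized_matrix")) V$V else as.matrix(V)
}

conflicts_of <- function(V, conflicts) {
  if (!is.null(conflicts)) return(conflicts * 1)
  if (inherits(V, "normalized_matrix")) return(V$scheme$conflicts * 1)
  matrix(0, 0, 0)
}

#' Penalized NMF objective
#'
#' Generalized Kullback-Leibler divergence between `V` and `W %*% H`
#' (with `0 * log 0 := 0` and the reconstruction floored at `epsilon`),
#' plus `alpha` times the sum of `(W %*% t(W))[i, j]` over unordered
#' conflicting bin pairs.
#'
#' @param V Non-negative matrix or `normalized_matrix`.
#' @param W,H Non-negative factor matrices.
#' @param alpha Penalty weight.
#' @param conflicts Symmetric logical/0-1 conflict matrix; taken from the
#'   `normalized_matrix`'s scheme when omitted.
#' @param epsilon Smoothing floor.
#' @return Non-negative scalar.
#' @export
nmf_objective <- function(V, W, H, alpha = 0.1, conflicts = NULL,
                          epsilon = 1e-10) {
  C <- conflicts_of(V, conflicts)
  V <- as_V(V)
  if (any(V < 0) || any(W < 0) || any(H < 0))
    stop("V, W and H must be non-negative")
  .nmf_objective_cpp(V, as.matrix(W), as.matrix(H), C, alpha, epsilon)
}

#' Fit the penalized NMF at a fixed rank
#'
#' Factorizes the normalized bin-count matrix as `V ~ W %*% H` with `s`
#' columns in `W`, by seeded random initialization followed by
#' multiplicative updates that minimise the generalized KL divergence plus
#' the conflicting-bin penalty (see [nmf_objective()]). On return `W` is
#' column-max-normalised to `[0, 1]` with the inverse scale folded into the
#' rows of `H`, so that a value of 1 marks the bin of maximal read intensity
#' within each factor. The per-bin bias `A` (row maxima of `W`) and the
#' binary bin-membership matrix `G` (thresholded `A^-1 W`) are derived from
#' the fit.
#'
#' @param V `normalized_matrix` or non-negative matrix.
#' @param s Rank (number of isoform patterns sought); `s >= 1`.
#' @param config An [nmf_config].
#' @param conflicts Optional conflict matrix override.
#' @param trace_every Evaluate the objective (and the convergence check)
#'   only every `trace_every`-th iteration; `1` (default) gives the full
#'   per-iteration trace, larger values give a cheaper fit whose
#'   `objective_trace` holds one value per evaluation.
#' @return Object of class `nmf_fit`: list with `W`, `H`, `A`, `G`,
#'   `objective_trace`, `iterations`, `s`, `config`.
#' @export
nmf_fit <- function(V, s, config = nmf_config(), conflicts = NULL,
                    trace_every = 1L) {
  C <- conflicts_of(V, conflicts)
  Vm <- as_V(V)
  p <- nrow(Vm); m <- ncol(Vm)
  s <- as.integer(s)
  stopifnot(s >= 1)
  if (any(Vm < 0)) stop("V must be non-negative")
  if (s > min(p, m))
    warning("rank s = ", s, " exceeds min(dim(V)) = ", min(p, m))
  if (all(Vm == 0)) {
    W <- matrix(0, p, s); H <- matrix(0, s, m)
    return(structure(list(W = W, H = H, A = rep(0, p), G = W,
                          objective_trace = 0, iterations = 0L, s = s,
                          config = config), class = "nmf_fit"))
  }
  set.seed(config$seed)
  ## uniform init, H scaled so that E[WH] matches mean(V)
  W0 <- matrix(stats::runif(p * s), p, s)
  H0 <- matrix(stats::runif(s * m), s, m) * (4 * mean(Vm) / s)
  res <- .nmf_fit_cpp(Vm, W0, H0, C, config$alpha, config$max_iter,
                      config$tol, config$epsilon, config$window,
                      as.integer(trace_every))
  W <- res$W; H <- res$H
  cmax <- apply(W, 2L, max)
  scale <- ifelse(cmax > 0, cmax, 1)
  W <- sweep(W, 2L, scale, `/`)
  H <- sweep(H, 1L, scale, `*`)
  A <- estimate_A(W)
  structure(list(W = W, H = H, A = A, G = estimate_G(W, A, config$c),
                 objective_trace = res$objective_trace,
                 iterations = res$iterations, s = s, config = config),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: rank %d, %d iterations, final objective %.6g\n",
              x$s, x$iterations, utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Per-bin bias factors from a fitted W
#'
#' `A[i]` is the row maximum of `W`: the largest adjusted existence of bin
#' `i` across factors, interpreted as that bin's read-count bias.
#'
#' @param W Non-negative matrix with column maxima at most 1.
#' @return Numeric vector of length `nrow(W)`.
#' @export
estimate_A <- function(W) {
  if (any(W < 0)) stop("W must be non-negative")
  apply(as.matrix(W), 1L, max)
}

#' Binarize a fitted W into bin membership
#'
#' `G[i, j] = 1` iff `W[i, j] / A[i] >= c`; rows with `A[i] == 0` give
#' all-zero rows.
#'
#' @param W Non-negative matrix.
#' @param A Per-bin bias values (row maxima of `W`).
#' @param c Threshold in (0, 1).
#' @return Binary matrix of the same shape as `W`.
#' @export
estimate_G <- function(W, A, c = 0.4) {
  stopifnot(c > 0, c < 1)
  W <- as.matrix(W)
  ratio <- sweep(W, 1L, ifelse(A > 0, A, Inf), `/`)
  (ratio >= c) * 1
}

#' Select the NMF rank by the gap statistic
#'
#' For each candidate rank the data-fit (KL) term of the objective is
#' recorded for the observed matrix and for `B` reference matrices whose
#' entries are drawn uniformly between the corresponding bin-row's minimum
#' and maximum. `Gap(s)` is the mean reference log fit minus the observed
#' log fit. Under `rule = "max"` (default) the rank maximising the gap is
#' chosen; `rule = "1se"` instead returns the smallest `s` with
#' `Gap(s) >= Gap(s') - se(s')` for the next candidate `s'` (the
#' one-standard-error rule), which is more parsimonious but collapses to
#' the smallest candidate on noise-dominated matrices, below the number of
#' isoform patterns the method needs to resolve.
#'
#' @param V `normalized_matrix` or non-negative matrix.
#' @param candidate_ranks Integer vector of ranks to score.
#' @param config An [nmf_config]; its seed makes the procedure
#'   deterministic.
#' @param conflicts Optional conflict matrix override.
#' @param B Number of reference matrices.
#' @param rule Selection rule, `"max"` or `"1se"` (see Details).
#' @return The selected rank (integer). With a single sample the gap
#'   statistic is degenerate and the smallest candidate is returned with a
#'   warning.
#' @export
select_rank <- function(V, candidate_ranks, config = nmf_config(),
                        conflicts = NULL, B = 10L,
                        rule = c("max", "1se")) {
  rule <- match.arg(rule)
  C <- conflicts_of(V, conflicts)
  Vm <- as_V(V)
  ranks <- sort(unique(as.integer(candidate_ranks)))
  stopifnot(length(ranks) >= 1, all(ranks >= 1))
  if (length(ranks) == 1L) return(ranks)
  if (ncol(Vm) == 1L) {
    warning("gap statistic degenerate with a single sample; using smallest rank")
    return(min(ranks))
  }
  eps <- config$epsilon
  kl_fit <- function(M, s, seed) {
    cfg <- config; cfg$seed <- as.integer(seed %% .Machine$integer.max)
    ## rank scoring does not need deep convergence
    cfg$max_iter <- min(cfg$max_iter, 500L)
    fit <- nmf_fit(M, s, cfg, conflicts = C, trace_every = 10L)
    ## data-fit term only (penalty excluded)
    .nmf_objective_cpp(M, fit$W, fit$H, matrix(0, 0, 0), 0, eps)
  }
  rmin <- apply(Vm, 1L, min); rmax <- apply(Vm, 1L, max)
  ## every row constant across samples (e.g. exactly one pattern after
  ## depth normalization): the references ARE the data, the gap carries no
  ## signal beyond fit-restart noise, and there is no evidence for more
  ## than the smallest candidate rank
  if (all(rmax - rmin <= 1e-9 * pmax(rmax, 1))) return(min(ranks))
  set.seed(config$seed)
  refs <- lapply(seq_len(B), function(b)
    matrix(stats::runif(length(Vm), rmin, rmax), nrow(Vm), ncol(Vm)))
  logD <- vapply(seq_along(ranks), function(si)
    log(max(kl_fit(Vm, ranks[si], config$seed + 101 * si), eps)), numeric(1))
  logDref <- sapply(seq_along(ranks), function(si)
    vapply(seq_len(B), function(b)
      log(max(kl_fit(refs[[b]], ranks[si], config$seed + 101 * si + 7919 * b),
              eps)), numeric(1)))
  logDref <- matrix(logDref, nrow = B)
  gap <- colMeans(logDref) - logD
  ## flat gap curve (e.g. degenerate references when all columns are
  ## proportional): no evidence for extra components, take the smallest
  if (diff(range(gap)) < 1e-8) return(min(ranks))
  if (rule == "1se") {
    se <- apply(logDref, 2L, stats::sd) * sqrt(1 + 1 / B)
    for (si in seq_len(length(ranks) - 1L)) {
      if (gap[si] >= gap[si + 1L] - se[si + 1L]) return(ranks[si])
    }
  }
  ranks[which.max(gap)]
}
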