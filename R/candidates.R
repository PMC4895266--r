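#' Junction-support evidence
#'
#' Read counts of observed splice junctions, keyed `"a-b"` with `b > a`
#' (1-based subexon indices), plus the minimum count required for a
#' junction to be considered supported.
#'
#' @param counts Named non-negative numeric vector (`"a-b"` keys), e.g. the
#'   `junctions` element of a [build_count_matrix()] result.
#' @param min_reads Support threshold (default 1).
#' @return Object of class `junction_support`.
#' @export
junction_support <- function(counts = numeric(0), min_reads = 1) {
  counts <- unlist(counts)
  if (length(counts) && (is.null(names(counts)) || any(counts < 0)))
    stop("junction counts must be a named non-negative vector")
  structure(list(counts = counts, min_reads = min_reads),
            class = "junction_support")
}

junction_key <- function(a, b) paste0(a, "-", b)

#' Junction support implied by a bin-count matrix
#'
#' Under the junction interpretation of spanning bins, a read in bin
#' `(k, l)` with `l > k` is direct evidence of a splice junction from
#' subexon `k` to subexon `l`. When reads are only available in binned form
#' (e.g. a count-matrix TSV, or the synthetic generator's output), junction
#' support is therefore tallied from the spanning-bin rows of `U`, summed
#' over samples, and merged with any read-level junction observations
#' recorded on the object.
#'
#' @param counts A `count_matrix`.
#' @param min_reads Support threshold (default 1).
#' @return A [junction_support].
#' @export
junction_support_from_counts <- function(counts, min_reads = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  b <- counts$scheme$bins
  span <- which(b$l > b$k)
  tally <- stats::setNames(rowSums(counts$U)[span],
                           junction_key(b$k[span], b$l[span]))
  for (key in names(counts$junctions))
    tally[key] <- (if (is.na(tally[key])) 0 else tally[key]) +
      counts$junctions[[key]]
  junction_support(tally[tally > 0], min_reads = min_reads)
}

junction_count <- function(support, a, b) {
  x <- support$counts[junction_key(a, b)]
  if (is.na(x)) 0 else unname(x)
}

#' Is every splice junction of a candidate supported by reads?
#'
#' A candidate's splice junctions are its consecutive included subexon
#' pairs that either skip at least one subexon or cross an annotated intron
#' in the gene model. Each must have at least `min_reads` junction reads;
#' genomically contiguous included pairs produce no splice junction in
#' reads and need no evidence.
#'
#' @param inclusion Binary inclusion vector (or [isoform]).
#' @param gene A [gene_model].
#' @param support A [junction_support].
#' @return Logical scalar (vacuously `TRUE` for single-subexon candidates).
#' @export
junction_supported <- function(inclusion, gene, support) {
  if (inherits(inclusion, "isoform")) inclusion <- inclusion$inclusion
  if (length(inclusion) != gene$n)
    stop("inclusion length ", length(inclusion), " != n = ", gene$n)
  idx <- which(as.logical(inclusion))
  if (length(idx) <= 1L) return(TRUE)
  for (t in seq_len(length(idx) - 1L)) {
    a <- idx[t]; b <- idx[t + 1L]
    contiguous <- (b == a + 1L) && gene$contiguous[a]
    if (!contiguous && junction_count(support, a, b) < support$min_reads)
      return(FALSE)
  }
  TRUE
}

#' Expand one binary factor column into isoform candidates
#'
#' The included bins of a `G` column assert subexon statuses: a subexon is
#' *present* if it appears as an endpoint (`k` or `l`) of an included bin,
#' and *asserted skipped* if it lies strictly inside an included spanning
#' bin. Subexons asserted both ways are *ambiguous*: both statuses are
#' enumerated, giving up to `2^a` status assignments. Each assignment
#' resolves the column's conflicts by *dropping the bins inconsistent with
#' it* (a bin is inconsistent when one of its endpoints is assigned
#' skipped, or a subexon strictly inside it is assigned present); the
#' candidate's inclusion vector is then re-derived from the kept bins
#' alone, so a dropped bin's presence assertions disappear with it.
#' Distinct candidates passing [junction_supported()] are returned.
#' Subexons touched by no kept bin are absent.
#'
#' @param column Binary vector of length `p` (one `G` column).
#' @param scheme A `bin_scheme`.
#' @param support A [junction_support].
#' @param max_ambiguous Columns with more ambiguous subexons than this are
#'   skipped with a warning (empty result), bounding the exponential
#'   expansion.
#' @return List of binary inclusion vectors (possibly empty).
#' @export
column_to_candidates <- function(column, scheme, support,
                                 max_ambiguous = 10L) {
  stopifnot(length(column) == scheme$p)
  inc_bins <- which(column > 0)
  if (length(inc_bins) == 0L) return(list())
  b <- scheme$bins
  n <- scheme$gene$n
  present <- unique(c(b$k[inc_bins], b$l[inc_bins]))
  skipped <- unique(unlist(lapply(inc_bins, function(i)
    bin_skipped(b$k[i], b$l[i]))))
  ambiguous <- intersect(present, skipped)
  if (length(ambiguous) > max_ambiguous) {
    warning(length(ambiguous), " ambiguous subexons exceed cap ",
            max_ambiguous, "; column skipped")
    return(list())
  }
  interiors <- lapply(inc_bins, function(i) bin_skipped(b$k[i], b$l[i]))
  combos <- if (length(ambiguous) == 0L) list(integer(0)) else
    asplit(as.matrix(expand.grid(rep(list(0:1), length(ambiguous)))), 1L)
  out <- list(); seen <- character(0)
  for (cm in combos) {
    assigned_present <- ambiguous[as.integer(cm) == 1L]
    assigned_skipped <- ambiguous[as.integer(cm) == 0L]
    keep <- vapply(seq_along(inc_bins), function(t) {
      i <- inc_bins[t]
      !(b$k[i] %in% assigned_skipped) && !(b$l[i] %in% assigned_skipped) &&
        !any(interiors[[t]] %in% assigned_present)
    }, logical(1))
    if (!any(keep)) next
    inc <- integer(n)
    inc[unique(c(b$k[inc_bins[keep]], b$l[inc_bins[keep]]))] <- 1L
    key <- paste(inc, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (junction_supported(inc, scheme$gene, support))
      out[[length(out) + 1L]] <- inc
  }
  out
}

#' Pipeline configuration for multi-run candidate aggregation
#'
#' @param N Number of independently seeded NMF runs (default 100).
#' @param r Frequency threshold: candidates kept only if produced in at
#'   least `r` of the `N` runs (default 20).
#' @param max_ambiguous Per-column cap on ambiguous subexons (default 10).
#' @param rank Optional fixed rank; when given the gap statistic is
#'   skipped.
#' @param rank_per_run If `TRUE` (default) the rank is re-selected by the
#'   gap statistic within every run, so each aggregated run repeats the
#'   whole estimation procedure (rank choice included) and the stochastic
#'   reference draws contribute to across-run diversity; `FALSE` selects
#'   the rank once on `V` and reuses it for all runs.
#' @param candidate_ranks Ranks scored by the gap statistic.
#' @param B Reference matrices per rank in the gap statistic (default 5;
#'   kept small because the selection is repeated inside every run).
#' @param nmf An [nmf_config]; its `seed` is the base seed, run `t` uses
#'   `seed + t`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(N = 100L, r = 20L, max_ambiguous = 10L,
                            rank = NULL, rank_per_run = TRUE,
                            candidate_ranks = 1:6, B = 5L,
                            nmf = nmf_config()) {
  N <- as.integer(N); r <- as.integer(r)
  if (N < 1L) stop("N must be at least 1")
  if (r < 1L || r > N) stop("need 1 <= r <= N")
  structure(list(N = N, r = r, max_ambiguous = as.integer(max_ambiguous),
                 rank = if (is.null(rank)) NULL else as.integer(rank),
                 rank_per_run = isTRUE(rank_per_run),
                 candidate_ranks = as.integer(candidate_ranks),
                 B = as.integer(B), nmf = nmf),
            class = "pipeline_config")
}

#' Preselect isoform candidates by aggregated penalized NMF
#'
#' The full preselection pipeline for one gene: the penalized NMF is fitted
#' `N` times from independent seeded initializations, each run's binarized
#' factor columns are expanded into junction-supported isoform candidates,
#' and candidates are pooled by inclusion vector with a frequency equal to
#' the number of runs that produced them (once per run, regardless of how
#' many columns yielded them). Candidates recurring in at least `r` runs
#' are returned, sorted by frequency (descending) then inclusion string.
#'
#' @param V A `normalized_matrix` (see [normalize_counts()]).
#' @param support A [junction_support].
#' @param config A [pipeline_config].
#' @param scheme Optional `bin_scheme`; defaults to `V$scheme`.
#' @return Object of class `isoform_pool`: data.frame with columns
#'   `inclusion` (string), `frequency`, `supported` (all `TRUE`), ordered
#'   as above, with attributes `rank_used` (integer vector per run) and
#'   `N`.
#' @export
nmf_preselect <- function(V, support, config = pipeline_config(),
                          scheme = NULL) {
  if (is.null(scheme)) {
    stopifnot(inherits(V, "normalized_matrix"))
    scheme <- V$scheme
  }
  C <- scheme$conflicts * 1
  base_seed <- config$nmf$seed
  rank_fixed <- config$rank
  if (is.null(rank_fixed) && !config$rank_per_run) {
    rank_fixed <- select_rank(V, config$candidate_ranks, config$nmf,
                              conflicts = C, B = config$B)
  }
  freq <- new.env(parent = emptyenv())
  ranks_used <- integer(config$N)
  for (t in seq_len(config$N)) {
    cfg_t <- config$nmf
    cfg_t$seed <- as.integer((base_seed + t) %% .Machine$integer.max)
    s_t <- if (!is.null(rank_fixed)) rank_fixed else
      select_rank(V, config$candidate_ranks, cfg_t, conflicts = C,
                  B = config$B)
    ranks_used[t] <- s_t
    fit <- nmf_fit(V, s_t, cfg_t, conflicts = C)
    run_set <- character(0)
    for (col in seq_len(ncol(fit$G))) {
      cands <- column_to_candidates(fit$G[, col], scheme, support,
                                    config$max_ambiguous)
      run_set <- union(run_set, vapply(cands, inclusion_string, character(1)))
    }
    for (key in run_set) {
      freq[[key]] <- (if (is.null(freq[[key]])) 0L else freq[[key]]) + 1L
    }
  }
  keys <- ls(freq)
  counts <- vapply(keys, function(k) freq[[k]], integer(1))
  keep <- counts >= config$r
  if (!any(keep)) {
    warning("no candidate reached the frequency threshold r = ", config$r)
    keys <- character(0); counts <- integer(0)
  } else {
    keys <- keys[keep]; counts <- counts[keep]
  }
  o <- order(-counts, keys)
  pool <- data.frame(inclusion = keys[o], frequency = unname(counts[o]),
                     supported = rep(TRUE, sum(keep)),
                     stringsAsFactors = FALSE)
  attr(pool, "rank_used") <- ranks_used
  attr(pool, "N") <- config$N
  class(pool) <- c("isoform_pool", "data.frame")
  pool
}

#' Write a candidate pool as TSV
#'
#' @param pool An `isoform_pool`.
#' @param gene_id Gene identifier recorded in the table.
#' @param path Output path.
#' @export
write_pool_tsv <- function(pool, gene_id, path) {
  df <- data.frame(gene_id = gene_id, inclusion = pool$inclusion,
                   frequency = pool$frequency, supported = pool$supported)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
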