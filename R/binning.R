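#' Enumerate the read bins of a gene
#'
#' A *bin* `(k, l)` collects the mapped reads (single-end reads, or each end
#' of a paired-end read independently) whose alignment starts in subexon `k`
#' and ends in subexon `l`. A gene with `n` subexons has
#' `p = n + choose(n, 2)` bins. Row order is fixed: the `n` single-subexon
#' bins `(k, k)` first, in order of `k`, followed by the spanning bins
#' `(k, l)` with `k < l` in lexicographic order.
#'
#' Each bin carries an effective length used for the read-placement
#' probability `P[i]` (`P` is proportional to effective length and
#' normalised to sum to 1). Two conventions are available:
#'
#' * `spanning_length = "sum"` (default): a single-subexon bin has its
#'   subexon's length and a spanning bin `(k, l)` has
#'   `length(k) + length(l)` — the coarse junction interpretation in which
#'   a spanning read may start anywhere in `k` and end anywhere in `l`.
#' * `spanning_length = "read"`: effective length is the exact number of
#'   start positions a read of `read_length` bp can take while landing in
#'   the bin, assuming the bin's subexons are adjacent on the mature
#'   transcript: `length(k) - (read_length - 1)` for a single-subexon bin
#'   and `min(length(k), read_length - 1) + min(length(l), read_length - 1)
#'   - (read_length - 1)` for a spanning bin (both floored at 1). For reads
#'   much shorter than the subexons this makes junction bins roughly
#'   `read_length` wide instead of two subexons wide, matching the actual
#'   footprint of junction-spanning placements.
#'
#' The scheme also records the *conflict* relation between bins: bin
#' `(k, l)` with `l > k` asserts subexons `k` and `l` present and every
#' subexon strictly between them skipped; two bins conflict when one asserts
#' present a subexon the other asserts skipped. Conflicting bins should not
#' co-occur in one isoform and are penalised during factorization.
#'
#' @param gene A [gene_model].
#' @param spanning_length Bin effective-length convention, `"sum"` or
#'   `"read"` (see Details).
#' @param read_length Read length in bp; used only when
#'   `spanning_length = "read"`.
#' @return An object of class `bin_scheme`: list with `gene`, `bins`
#'   (data.frame `row`, `k`, `l`, `length`), `p`, `P` and `conflicts`
#'   (symmetric logical `p x p` matrix with `FALSE` diagonal).
#' @export
enumerate_bins <- function(gene, spanning_length = c("sum", "read"),
                           read_length = 76L) {
  stopifnot(inherits(gene, "gene_model"))
  spanning_length <- match.arg(spanning_length)
  n <- gene$n
  len <- gene$subexons$length
  k <- seq_len(n)
  l <- seq_len(n)
  if (n > 1L) {
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pair <- pair[order(pair[, 1L], pair[, 2L]), , drop = FALSE]
    k <- c(k, pair[, 1L])
    l <- c(l, pair[, 2L])
  }
  blen <- if (spanning_length == "sum") {
    ifelse(k == l, len[k], len[k] + len[l])
  } else {
    rl1 <- as.integer(read_length) - 1L
    stopifnot(rl1 >= 0L)
    pmax(ifelse(k == l, len[k] - rl1,
                pmin(len[k], rl1) + pmin(len[l], rl1) - rl1), 1)
  }
  p <- length(k)
  stopifnot(p == n + choose(n, 2))
  bins <- data.frame(row = seq_len(p), k = k, l = l, length = blen)
  scheme <- structure(list(
    gene = gene, bins = bins, p = p, P = blen / sum(blen),
    conflicts = NULL
  ), class = "bin_scheme")
  scheme$conflicts <- conflict_matrix(scheme)
  scheme
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("bin_scheme for %s: n=%d subexons, p=%d bins, %d conflicting pairs\n",
              x$gene$gene_id, x$gene$n, x$p, sum(x$conflicts) / 2))
  invisible(x)
}

## Subexons a bin asserts present / skipped.
bin_present <- function(k, l) unique(c(k, l))
bin_skipped <- function(k, l) if (l > k + 1L) seq(k + 1L, l - 1L) else integer(0)

#' Do two bins conflict?
#'
#' TRUE iff one bin asserts present a subexon the other asserts skipped.
#' Symmetric; never TRUE for identical bins.
#'
#' @param scheme A `bin_scheme`.
#' @param i,j Bin row indices in `1..p`.
#' @return Logical scalar.
#' @export
conflicting <- function(scheme, i, j) {
  scheme$conflicts[i, j]
}

## Full symmetric conflict matrix. A bin (k,l) with l>k asserts intermediates
## skipped; bins (k,k) assert only presence.
conflict_matrix <- function(scheme) {
  b <- scheme$bins
  p <- scheme$p
  C <- matrix(FALSE, p, p)
  skip <- lapply(seq_len(p), function(i) bin_skipped(b$k[i], b$l[i]))
  pres <- lapply(seq_len(p), function(i) bin_present(b$k[i], b$l[i]))
  for (i in seq_len(p)) {
    if (length(skip[[i]]) == 0L) next
    for (j in seq_len(p)) {
      if (i == j) next
      if (any(pres[[j]] %in% skip[[i]])) {
        C[i, j] <- TRUE
        C[j, i] <- TRUE
      }
    }
  }
  C
}

#' Assign one read to its bin
#'
#' @param start_subexon,end_subexon 1-based subexon indices of the read's
#'   alignment start and end.
#' @param scheme A `bin_scheme`.
#' @return The bin row index, or `NA` if the indices fall outside the gene.
#' @export
assign_read <- function(start_subexon, end_subexon, scheme) {
  n <- scheme$gene$n
  k <- as.integer(start_subexon); l <- as.integer(end_subexon)
  if (is.na(k) || is.na(l) || k < 1L || l < k || l > n) return(NA_integer_)
  scheme$bins$row[scheme$bins$k == k & scheme$bins$l == l]
}

#' Build the raw bin-by-sample count matrix U
#'
#' Counts, per sample, the reads assigned to each bin. Reads are supplied as
#' a data.frame of read records with columns `sample_id`, `start_subexon`,
#' `end_subexon` and (optionally) `junctions`, a `;`-separated list of
#' observed splice junctions `"a-b"`. Junction observations are tallied into
#' the returned object's `junctions` element; they support candidate
#' filtering and do not affect bin identity.
#'
#' @param reads Data.frame of read records.
#' @param scheme A `bin_scheme`.
#' @param samples Character vector of sample ids (columns of U). Reads from
#'   other samples are an error; samples without reads give zero columns.
#' @return An object of class `count_matrix`: list with `scheme`, `samples`,
#'   `U` (`p x m`), `R` (per-sample totals, the column sums of U) and
#'   `junctions` (named numeric vector of junction read counts).
#' @export
build_count_matrix <- function(reads, scheme, samples) {
  samples <- as.character(samples)
  if (length(samples) < 1L) stop("empty sample list")
  p <- scheme$p
  U <- matrix(0, p, length(samples),
              dimnames = list(NULL, samples))
  jtally <- numeric(0)
  if (nrow(reads) > 0L) {
    if (!all(reads$sample_id %in% samples))
      stop("read sample ids not in sample list: ",
           paste(setdiff(unique(reads$sample_id), samples), collapse = ", "))
    rows <- vapply(seq_len(nrow(reads)), function(i)
      assign_read(reads$start_subexon[i], reads$end_subexon[i], scheme),
      integer(1))
    keep <- !is.na(rows)
    if (any(keep)) {
      tb <- table(factor(rows[keep], levels = seq_len(p)),
                  factor(reads$sample_id[keep], levels = samples))
      U <- U + unclass(tb)
      dimnames(U) <- list(NULL, samples)
    }
    if (!is.null(reads$junctions)) {
      js <- unlist(strsplit(reads$junctions[keep & !is.na(reads$junctions) &
                                              nzchar(reads$junctions)], ";",
                            fixed = TRUE))
      if (length(js)) jtally <- c(table(js))
    }
  }
  structure(list(scheme = scheme, samples = samples, U = U,
                 R = colSums(U), junctions = jtally),
            class = "count_matrix")
}

#' Construct a count matrix from a precomputed U
#'
#' @param U Non-negative `p x m` matrix, rows in the scheme's bin order.
#' @param scheme A `bin_scheme`.
#' @param samples Optional sample ids; default from `colnames(U)` or
#'   `s1..sm`.
#' @param junctions Optional named junction counts (`"a-b"` keys).
#' @return A `count_matrix`.
#' @export
count_matrix <- function(U, scheme, samples = NULL, junctions = numeric(0)) {
  U <- as.matrix(U)
  if (nrow(U) != scheme$p) stop("U has ", nrow(U), " rows; scheme has p = ", scheme$p)
  if (any(U < 0)) stop("U must be non-negative")
  if (is.null(samples)) samples <- colnames(U)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(U)))
  colnames(U) <- samples
  structure(list(scheme = scheme, samples = samples, U = U,
                 R = colSums(U), junctions = junctions),
            class = "count_matrix")
}

#' Normalize a count matrix for depth and bin length
#'
#' Two-step normalization of the raw counts `U` into `V`:
#' sample depths are equalised, `U'[i,j] = U[i,j] * mean(R) / R[j]` (columns
#' with zero depth are left as zeros), then bin-length effects are removed,
#' `V[i,j] = U'[i,j] / (p * P[i])`, where `P[i]` is the length-proportional
#' bin probability. After the first step every non-empty column of `U'` sums
#' to `mean(R)`; the second step leaves a bin of average length unchanged.
#'
#' @param counts A `count_matrix`.
#' @return An object of class `normalized_matrix`: list with `scheme` and
#'   `V` (`p x m` non-negative matrix).
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  R <- counts$R
  if (all(R == 0)) stop("empty gene: all samples have zero reads")
  Rbar <- mean(R)
  scale_j <- ifelse(R > 0, Rbar / R, 0)
  Uprime <- sweep(counts$U, 2L, scale_j, `*`)
  V <- sweep(Uprime, 1L, counts$scheme$p * counts$scheme$P, `/`)
  structure(list(scheme = counts$scheme, V = V, samples = counts$samples),
            class = "normalized_matrix")
}

#' Read/write count matrices as TSV
#'
#' The text format has one row per bin with columns `k`, `l`, then one
#' column per sample.
#'
#' @param counts A `count_matrix`.
#' @param path File path.
#' @return `write_count_matrix_tsv`: `path` invisibly;
#'   `read_count_matrix_tsv`: a `count_matrix`.
#' @export
write_count_matrix_tsv <- function(counts, path) {
  df <- data.frame(k = counts$scheme$bins$k, l = counts$scheme$bins$l,
                   counts$U, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix_tsv
#' @param scheme A `bin_scheme` the matrix must match.
#' @export
read_count_matrix_tsv <- function(path, scheme) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!all(c("k", "l") %in% names(df))) stop("count TSV lacks k/l bin header")
  key <- paste(df$k, df$l)
  want <- paste(scheme$bins$k, scheme$bins$l)
  if (nrow(df) != scheme$p || !all(key == want))
    stop("count TSV bin rows do not match the scheme's bin enumeration")
  U <- as.matrix(df[, setdiff(names(df), c("k", "l")), drop = FALSE])
  count_matrix(U, scheme)
}

#' Read/write read records as TSV
#'
#' Columns `sample_id`, `start_subexon`, `end_subexon`, `junctions`.
#'
#' @param reads Read-record data.frame.
#' @param path File path.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sample_id = "character",
                                         junctions = "character"))
  df$junctions[is.na(df$junctions)] <- ""
  df
}
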