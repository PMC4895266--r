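## Shared fixtures for the test suite.

## A 3-subexon gene with introns between every pair (lengths 100, 200, 300).
toy_gene3 <- function() {
  gene_model("g3", "chrT", "+",
             starts = c(0, 300, 700),
             ends = c(100, 500, 1000))
}

## A 2-subexon gene with bin lengths 100 and 300 (plus one spanning bin),
## used by the normalization worked example on its two mono-subexon bins.
toy_gene2 <- function() {
  gene_model("g2", "chrT", "+", starts = c(0, 300), ends = c(100, 600))
}

## An 8-subexon intron-separated gene with fixed lengths.
toy_gene8 <- function(lens = c(200, 150, 300, 250, 100, 400, 350, 500)) {
  gap <- 200
  starts <- cumsum(c(0, lens[-length(lens)] + gap))
  gene_model("g8", "chrT", "+", starts, starts + lens)
}

## Junction support that supports everything (for candidate-expansion
## tests that are not about the support filter).
support_all <- function(gene) {
  n <- gene$n
  keys <- outer(seq_len(n), seq_len(n), function(a, b)
    ifelse(b > a, paste0(a, "-", b), NA))
  keys <- keys[!is.na(keys)]
  junction_support(stats::setNames(rep(100, length(keys)), keys))
}

## Noiseless count matrix simulated from given isoforms on `gene` at high
## depth, using the exact placement weights.
noiseless_counts <- function(gene, isoforms, depth_per_iso = 1e5,
                             read_length = 76, scheme = NULL,
                             m_samples = 6, seed = 42) {
  if (is.null(scheme)) scheme <- enumerate_bins(gene)
  set.seed(seed)
  U <- matrix(0, scheme$p, m_samples)
  for (j in seq_len(m_samples)) {
    pr <- stats::runif(length(isoforms))
    pr <- pr / sum(pr)
    for (t in seq_along(isoforms)) {
      w <- isoform_bin_weights(scheme, isoforms[[t]], read_length)
      U[, j] <- U[, j] + depth_per_iso * pr[t] * w / sum(w)
    }
  }
  count_matrix(U, scheme)
}
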