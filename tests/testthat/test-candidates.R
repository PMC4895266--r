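test_that("junction_support validates input and counts lookups work", {
  s <- junction_support(c("1-3" = 5, "2-4" = 0), min_reads = 1)
  expect_s3_class(s, "junction_support")
  expect_error(junction_support(c(5, 2)), "named")
  expect_error(junction_support(c("1-3" = -1)), "non-negative")
})

test_that("junction_supported checks only non-contiguous included pairs", {
  g <- toy_gene3()  # all pairs intron-separated
  s <- junction_support(c("1-3" = 5))
  expect_true(junction_supported(c(1, 0, 1), g, s))
  expect_false(junction_supported(c(1, 1, 1), g, s))  # 1-2 and 2-3 unsupported
  expect_true(junction_supported(c(0, 0, 1), g, s))   # single subexon: vacuous
  expect_false(junction_supported(c(1, 0, 1), g, junction_support()))

  # genomically contiguous pair needs no evidence
  gc <- gene_model("g", "c", "+", c(0, 100, 400), c(100, 200, 500))
  expect_true(junction_supported(c(1, 1, 0), gc, junction_support()))
  expect_false(junction_supported(c(0, 1, 1), gc, junction_support()))

  # min_reads threshold honored
  s2 <- junction_support(c("1-3" = 2), min_reads = 3)
  expect_false(junction_supported(c(1, 0, 1), g, s2))
  expect_error(junction_supported(c(1, 0), g, s), "length")
})

test_that("junction support can be recovered from spanning-bin counts", {
  g <- toy_gene3()
  sc <- enumerate_bins(g)
  U <- matrix(0, sc$p, 2)
  U[assign_read(1, 3, sc), 1] <- 4          # spanning bin (1,3)
  U[assign_read(2, 2, sc), ] <- 10          # mono bin: no junction
  cm <- count_matrix(U, sc)
  s <- junction_support_from_counts(cm)
  expect_equal(unname(s$counts["1-3"]), 4)
  expect_false("2-2" %in% names(s$counts))
  expect_false("1-2" %in% names(s$counts))

  # read-level junction tallies are merged in
  cm2 <- count_matrix(U, sc, junctions = c("1-3" = 1, "2-3" = 2))
  s2 <- junction_support_from_counts(cm2)
  expect_equal(unname(s2$counts["1-3"]), 5)
  expect_equal(unname(s2$counts["2-3"]), 2)
})

test_that("column expansion reproduces the ambiguous-subexon example", {
  ## n=3, included bins {(1,1),(1,3),(2,2),(3,3)}: subexon 2 is present
  ## (endpoint of (2,2)) and asserted skipped (interior of (1,3)) ->
  ## ambiguous -> raw candidates {101, 111}
  g <- toy_gene3()
  sc <- enumerate_bins(g)
  col <- numeric(sc$p)
  col[c(assign_read(1, 1, sc), assign_read(1, 3, sc),
        assign_read(2, 2, sc), assign_read(3, 3, sc))] <- 1
  out <- column_to_candidates(col, sc, support_all(g))
  keys <- sort(vapply(out, inclusion_string, character(1)))
  expect_equal(keys, c("101", "111"))

  ## mono bins only -> single unambiguous candidate
  col2 <- numeric(sc$p)
  col2[c(assign_read(1, 1, sc), assign_read(2, 2, sc),
         assign_read(3, 3, sc))] <- 1
  out2 <- column_to_candidates(col2, sc, support_all(g))
  expect_equal(vapply(out2, inclusion_string, character(1)), "111")

  ## lone spanning bin with unsupported junction -> empty
  col3 <- numeric(sc$p)
  col3[assign_read(1, 3, sc)] <- 1
  expect_length(column_to_candidates(col3, sc, junction_support()), 0)
  out3 <- column_to_candidates(col3, sc, support_all(g))
  expect_equal(vapply(out3, inclusion_string, character(1)), "101")

  ## empty column -> empty list
  expect_length(column_to_candidates(numeric(sc$p), sc, support_all(g)), 0)
})

test_that("ambiguity cap skips the column with a warning", {
  ## 8-subexon gene, include all mono bins and the bin (1,8): subexons 2..7
  ## are all ambiguous (6 of them)
  g <- toy_gene8()
  sc <- enumerate_bins(g)
  col <- numeric(sc$p)
  col[1:8] <- 1
  col[assign_read(1, 8, sc)] <- 1
  expect_warning(out <- column_to_candidates(col, sc, support_all(g),
                                             max_ambiguous = 3),
                 "ambiguous")
  expect_length(out, 0)
  out2 <- column_to_candidates(col, sc, support_all(g), max_ambiguous = 6)
  expect_length(out2, 2^6)
})

test_that("pipeline_config validates N and r", {
  expect_error(pipeline_config(N = 0), "at least 1")
  expect_error(pipeline_config(N = 10, r = 11), "1 <= r <= N")
  cfg <- pipeline_config(N = 5, r = 2, rank = 3)
  expect_equal(cfg$rank, 3L)
})

test_that("nmf_preselect recovers a single isoform on noiseless data", {
  g <- toy_gene8()
  sc <- enumerate_bins(g)
  cm <- noiseless_counts(g, list(rep(1L, 8)), scheme = sc)
  pool <- nmf_preselect(normalize_counts(cm),
                        junction_support_from_counts(cm),
                        pipeline_config(N = 5, r = 2,
                                        candidate_ranks = 1:3,
                                        nmf = nmf_config(seed = 1)))
  expect_equal(pool$inclusion, "11111111")
  expect_equal(pool$frequency, 5)
  expect_true(all(pool$supported))
  expect_equal(attr(pool, "N"), 5L)
})

test_that("frequency filter is monotone in r and bounded by N", {
  g <- toy_gene8()
  cfg <- sim_config(seed = 5, rpkm_per_sample = rep(5, 10),
                    round_counts = FALSE)
  gene <- make_gene(cfg)
  sc <- enumerate_bins(gene, spanning_length = "read",
                       read_length = cfg$read_length)
  cm <- simulate_bin_counts(gene, cfg, sc)
  V <- normalize_counts(cm)
  sup <- junction_support_from_counts(cm)
  base <- pipeline_config(N = 12, r = 1, candidate_ranks = 1:4,
                          nmf = nmf_config(seed = 3))
  p1 <- nmf_preselect(V, sup, base)
  expect_true(all(p1$frequency <= 12))
  expect_true(all(diff(p1$frequency) <= 0))          # sorted descending
  base$r <- 6L
  p6 <- suppressWarnings(nmf_preselect(V, sup, base))
  expect_true(all(p6$inclusion %in% p1$inclusion))   # raising r never adds
  expect_setequal(p6$inclusion, p1$inclusion[p1$frequency >= 6])
  # every emitted candidate passes the junction filter
  gene_chk <- gene
  expect_true(all(vapply(p1$inclusion, function(k)
    junction_supported(parse_inclusion(k), gene_chk, sup), logical(1))))
})

test_that("fixed-rank and per-run policies are both available", {
  g <- toy_gene8()
  sc <- enumerate_bins(g)
  cm <- noiseless_counts(g, list(rep(1L, 8)), scheme = sc)
  V <- normalize_counts(cm)
  sup <- junction_support_from_counts(cm)
  pf <- nmf_preselect(V, sup, pipeline_config(N = 3, r = 1, rank = 2,
                                              nmf = nmf_config(seed = 1)))
  expect_equal(unique(attr(pf, "rank_used")), 2L)
  po <- nmf_preselect(V, sup, pipeline_config(N = 3, r = 1,
                                              rank_per_run = FALSE,
                                              candidate_ranks = 1:3,
                                              nmf = nmf_config(seed = 1)))
  expect_length(unique(attr(po, "rank_used")), 1)
})

test_that("empty pool warns", {
  g <- toy_gene3()
  sc <- enumerate_bins(g)
  U <- matrix(0, sc$p, 3)
  U[assign_read(1, 3, sc), ] <- 20   # junction-only signal, no support
  cm <- count_matrix(U, sc)
  V <- normalize_counts(cm)
  expect_warning(
    pool <- nmf_preselect(V, junction_support(), # no junction evidence
                          pipeline_config(N = 2, r = 2, rank = 1,
                                          nmf = nmf_config(seed = 1))),
    "frequency threshold")
  expect_equal(nrow(pool), 0)
})

test_that("pool TSV export round-trips", {
  pool <- structure(
    data.frame(inclusion = c("111", "101"), frequency = c(9L, 4L),
               supported = c(TRUE, TRUE)),
    class = c("isoform_pool", "data.frame"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pool_tsv(pool, "gX", path)
  df <- read.delim(path, colClasses = c(inclusion = "character"))
  expect_equal(df$inclusion, c("111", "101"))
  expect_equal(df$gene_id, c("gX", "gX"))
})
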