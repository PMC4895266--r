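test_that("enumerate_bins produces the canonical bin order and count", {
  g <- toy_gene3()
  sc <- enumerate_bins(g)
  expect_equal(sc$p, 6)  # n + C(n,2) = 3 + 3
  expect_equal(sc$bins$k, c(1, 2, 3, 1, 1, 2))
  expect_equal(sc$bins$l, c(1, 2, 3, 2, 3, 3))
  expect_equal(sum(sc$P), 1)
  # mono bins carry subexon length, spanning bins the sum of both
  expect_equal(sc$bins$length, c(100, 200, 300, 300, 400, 500))

  g8 <- toy_gene8()
  expect_equal(enumerate_bins(g8)$p, 36)  # 8 + 28
  g1 <- gene_model("g1", "c", "+", 0, 100)
  sc1 <- enumerate_bins(g1)
  expect_equal(sc1$p, 1)
  expect_equal(sc1$P, 1)
})

test_that("read-informed effective lengths follow the placement footprint", {
  g <- toy_gene3()
  sc <- enumerate_bins(g, spanning_length = "read", read_length = 76)
  # mono: len - 75 ; spanning: min(len_k,75) + min(len_l,75) - 75 = 75
  expect_equal(sc$bins$length, c(100 - 75, 200 - 75, 300 - 75, 75, 75, 75))
  expect_equal(sum(sc$P), 1)
  # tiny subexon shorter than the read: floored at 1
  gt <- gene_model("gt", "c", "+", c(0, 300), c(50, 600))
  sct <- enumerate_bins(gt, spanning_length = "read", read_length = 76)
  expect_equal(sct$bins$length[1], 1)       # max(50 - 75, 1)
  expect_equal(sct$bins$length[3], 50)      # min(50,75) + 75 - 75
})

test_that("conflict relation matches the asserted-status rule", {
  g <- toy_gene3()
  sc <- enumerate_bins(g)
  row13 <- which(sc$bins$k == 1 & sc$bins$l == 3)
  row22 <- which(sc$bins$k == 2 & sc$bins$l == 2)
  row12 <- which(sc$bins$k == 1 & sc$bins$l == 2)
  row23 <- which(sc$bins$k == 2 & sc$bins$l == 3)
  expect_true(conflicting(sc, row13, row22))
  expect_true(conflicting(sc, row22, row13))     # symmetric
  expect_false(conflicting(sc, row12, row23))
  expect_false(conflicting(sc, row22, row22))    # identity
})

test_that("conflict matrix agrees with brute-force set logic up to n = 8", {
  for (n in c(2, 5, 8)) {
    lens <- rep(100, n)
    starts <- cumsum(c(0, lens[-n] + 50))
    g <- gene_model("g", "c", "+", starts, starts + lens)
    sc <- enumerate_bins(g)
    pres <- lapply(seq_len(sc$p), function(i) unique(c(sc$bins$k[i], sc$bins$l[i])))
    skip <- lapply(seq_len(sc$p), function(i) {
      k <- sc$bins$k[i]; l <- sc$bins$l[i]
      if (l > k + 1) seq(k + 1, l - 1) else integer(0)
    })
    for (i in seq_len(sc$p)) for (j in seq_len(sc$p)) {
      want <- i != j && (any(pres[[j]] %in% skip[[i]]) ||
                           any(pres[[i]] %in% skip[[j]]))
      expect_identical(unname(sc$conflicts[i, j]), want)
    }
    expect_false(any(diag(sc$conflicts)))
    expect_identical(sc$conflicts, t(sc$conflicts))
  }
})

test_that("assign_read maps subexon pairs to bin rows", {
  sc <- enumerate_bins(toy_gene3())
  expect_equal(sc$bins[assign_read(2, 2, sc), c("k", "l")],
               data.frame(k = 2, l = 2, row.names = 2L))
  expect_equal(unname(unlist(sc$bins[assign_read(1, 3, sc), c("k", "l")])),
               c(1, 3))
  expect_true(is.na(assign_read(0, 0, sc)))
  expect_true(is.na(assign_read(3, 4, sc)))
  expect_true(is.na(assign_read(2, 1, sc)))
})

test_that("build_count_matrix counts reads per bin and sample", {
  sc <- enumerate_bins(toy_gene3())
  reads <- data.frame(sample_id = c("A", "A", "A"),
                      start_subexon = 1, end_subexon = 1,
                      junctions = "")
  cm <- build_count_matrix(reads, sc, c("A", "B"))
  expect_equal(unname(cm$U[1, "A"]), 3)
  expect_equal(sum(cm$U), 3)
  expect_equal(unname(cm$R), c(3, 0))

  cm0 <- build_count_matrix(reads[0, ], sc, "A")
  expect_true(all(cm0$U == 0))
  expect_error(build_count_matrix(reads, sc, character(0)), "empty sample")
  expect_error(build_count_matrix(reads, sc, "B"), "not in sample list")

  # identical read sets in two samples give identical columns
  r2 <- rbind(transform(reads, sample_id = "A"),
              transform(reads, sample_id = "B"))
  cm2 <- build_count_matrix(r2, sc, c("A", "B"))
  expect_equal(cm2$U[, "A"], cm2$U[, "B"])

  # junction chains are tallied
  r3 <- data.frame(sample_id = "A", start_subexon = 1, end_subexon = 3,
                   junctions = "1-3")
  cm3 <- build_count_matrix(r3, sc, "A")
  expect_equal(unname(cm3$junctions["1-3"]), 1)
})

test_that("normalization reproduces the worked two-bin example", {
  ## p = 2 bins of lengths 100 and 300 (P = 0.25, 0.75),
  ## U = [[10,30],[30,90]]: R = (40,120), Rbar = 80
  ## -> U' = [[20,20],[60,60]] -> V = U' / (p*P) = [[40,40],[40,40]]
  g <- toy_gene2()
  sc <- enumerate_bins(g)
  sc_sub <- sc
  sc_sub$bins <- sc$bins[1:2, ]
  sc_sub$p <- 2L
  sc_sub$P <- c(0.25, 0.75)
  sc_sub$conflicts <- sc$conflicts[1:2, 1:2]
  U <- matrix(c(10, 30, 30, 90), 2, 2)
  cm <- count_matrix(U, sc_sub)
  V <- normalize_counts(cm)$V
  expect_equal(unname(V), matrix(40, 2, 2))
})

test_that("normalization invariances hold", {
  g <- toy_gene8()
  sc <- enumerate_bins(g)
  set.seed(7)
  U <- matrix(rpois(sc$p * 5, 20), sc$p, 5)
  V1 <- normalize_counts(count_matrix(U, sc))$V

  # equal depths and equal bin lengths -> V == U
  lens <- rep(100, 4)
  starts <- cumsum(c(0, lens[-4] + 50))
  geq <- gene_model("geq", "c", "+", starts, starts + lens)
  sceq <- enumerate_bins(geq)
  sceq$P <- rep(1 / sceq$p, sceq$p)   # force equal bin lengths
  Ueq <- matrix(5, sceq$p, 3)
  expect_equal(normalize_counts(count_matrix(Ueq, sceq))$V, Ueq,
               ignore_attr = TRUE)

  # doubling one column leaves its normalized column unchanged
  U2 <- U
  U2[, 3] <- U2[, 3] * 2
  V2 <- normalize_counts(count_matrix(U2, sc))$V
  # Rbar changes, a global scalar on all columns; compare column ratios
  expect_equal(V2[, 3] / sum(V2[, 3]), V1[, 3] / sum(V1[, 3]))

  # nonzero columns of U' sum to Rbar (conservation)
  cm <- count_matrix(U, sc)
  Uprime <- sweep(cm$U, 2, mean(cm$R) / cm$R, `*`)
  expect_equal(unname(colSums(Uprime)), rep(mean(cm$R), 5))

  # zero-depth columns stay zero
  U3 <- U
  U3[, 2] <- 0
  V3 <- normalize_counts(count_matrix(U3, sc))$V
  expect_true(all(V3[, 2] == 0))

  expect_error(normalize_counts(count_matrix(U * 0, sc)), "empty gene")
})

test_that("count matrix and read TSVs round-trip", {
  g <- toy_gene3()
  sc <- enumerate_bins(g)
  set.seed(1)
  U <- matrix(rpois(sc$p * 3, 4), sc$p, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  cm <- count_matrix(U, sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix_tsv(cm, path)
  cm2 <- read_count_matrix_tsv(path, sc)
  expect_equal(cm2$U, cm$U)
  expect_equal(cm2$samples, cm$samples)

  reads <- data.frame(sample_id = "s1", start_subexon = 1L,
                      end_subexon = 3L, junctions = "1-3")
  rpath <- withr::local_tempfile(fileext = ".tsv")
  write_reads_tsv(reads, rpath)
  expect_equal(read_reads_tsv(rpath), reads)
})
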