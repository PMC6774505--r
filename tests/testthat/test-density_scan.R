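contig_lengths <- function(len, id = "c1") stats::setNames(len, id)

test_that("the window grid is anchored at 0 and truncates at the contig end", {
  feats <- random_gene_table(5, 12000)
  w <- scan_windows(feats, character(0), contig_lengths(12000L))
  expect_equal(w$start, seq(0L, 11000L, by = 1000L))
  expect_equal(w$end, pmin(w$start + 10000L, 12000L))
  expect_true(all(w$n_phage_genes == 0L))   # empty phage set
  # contig shorter than the window: one truncated window
  w2 <- scan_windows(feats, character(0), contig_lengths(4000L))
  expect_equal(nrow(w2[w2$start == 0L, ]), 1L)
  expect_equal(w2$end[1], 4000L)
})

test_that("window counts equal the brute-force overlap oracle", {
  set.seed(51)
  for (i in 1:5) {
    len <- sample(30000:80000, 1)
    feats <- random_gene_table(200, len)
    phage <- sample(feats$feature_id, 80)
    w <- scan_windows(feats, phage, contig_lengths(len))
    g <- feats[feats$feature_id %in% phage, ]
    oracle <- brute_window_counts(g$start, g$end, len)
    expect_equal(w$start, oracle$start)
    expect_equal(w$end, oracle$end)
    expect_equal(w$n_phage_genes, oracle$n)
  }
})

test_that("counts never decrease when the phage gene set grows", {
  set.seed(52)
  feats <- random_gene_table(150, 40000)
  small <- sample(feats$feature_id, 40)
  big <- union(small, sample(feats$feature_id, 60))
  ws <- scan_windows(feats, small, contig_lengths(40000L))
  wb <- scan_windows(feats, big, contig_lengths(40000L))
  expect_true(all(wb$n_phage_genes >= ws$n_phage_genes))
})

test_that("window selection applies the gene-count and length thresholds strictly", {
  w <- tibble::tibble(
    contig_id = "c1",
    start = c(0L, 10000L, 20000L),
    end = c(10000L, 20000L, 24800L),     # last is a truncated 4.8 kb window
    n_phage_genes = c(8L, 7L, 9L),
    phage_gene_ids = list(paste0("a", 1:8), paste0("b", 1:7), paste0("c", 1:9))
  )
  sel <- select_windows(w)
  expect_equal(sel$start, 0L)   # 8 genes kept; 7 dropped; short window dropped
  # exactly 5000 bp does not pass the strict length bound
  w5 <- dplyr::mutate(w[3, ], end = start + 5000L)
  expect_equal(nrow(select_windows(w5)), 0L)
})

test_that("the genespan rule selects on the phage-gene span instead", {
  feats <- tibble::tibble(
    feature_id = paste0("g", 1:8), contig_id = "c1",
    start = seq(1000L, 4500L, by = 500L), end = seq(1300L, 4800L, by = 500L),
    strand = "+", ftype = "CDS", product = "", phase = 0L
  )
  w <- scan_windows(feats, feats$feature_id, contig_lengths(12000L))
  full <- w[w$start == 0L, ]
  # 8 genes spanning 1000..4800 = 3.8 kb: window rule keeps, genespan drops
  expect_equal(nrow(select_windows(full)), 1L)
  expect_equal(nrow(select_windows(full, features = feats,
                                   span_rule = "genespan")), 0L)
})

test_that("overlapping and book-ended windows merge into disjoint predictions", {
  w <- tibble::tibble(
    contig_id = "c1",
    start = c(0L, 1000L, 30000L),
    end = c(10000L, 11000L, 40000L),
    n_phage_genes = c(8L, 8L, 9L),
    phage_gene_ids = list(c("a", "b"), c("b", "c"), c("d"))
  )
  m <- merge_windows(w)
  expect_equal(m$start, c(0L, 30000L))
  expect_equal(m$end, c(11000L, 40000L))
  expect_equal(m$gene_ids[[1]], c("a", "b", "c"))
  expect_true(all(m$stage == "preliminary"))
  # idempotence under re-merge
  m2 <- merge_windows(dplyr::mutate(m, n_phage_genes = lengths(gene_ids),
                                    phage_gene_ids = gene_ids))
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)
})

test_that("merging matches a per-base paint-and-extract oracle", {
  set.seed(53)
  for (i in 1:15) {
    len <- 40000L
    n <- sample(2:30, 1)
    starts <- sample(seq(0L, len - 10000L, by = 1000L), n, replace = TRUE)
    w <- tibble::tibble(
      contig_id = "c1", start = starts, end = starts + 10000L,
      n_phage_genes = 8L,
      phage_gene_ids = replicate(n, paste0("g", sample.int(50, 8)),
                                 simplify = FALSE)
    )
    m <- merge_windows(w)
    oracle <- paint_union(w$start, w$end, len)
    expect_equal(m$start, oracle$start)
    expect_equal(m$end, oracle$end)
    # pairwise disjoint and sorted
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    # every selected window contained in exactly one merged prediction
    containing <- vapply(seq_len(nrow(w)), function(j) {
      sum(m$start <= w$start[j] & m$end >= w$end[j])
    }, integer(1))
    expect_true(all(containing == 1L))
  }
})

test_that("multi-contig input is scanned independently per contig", {
  f1 <- random_gene_table(40, 20000, contig_id = "c1")
  f2 <- random_gene_table(40, 15000, contig_id = "c2")
  feats <- dplyr::bind_rows(f1, f2)
  w <- scan_windows(feats, feats$feature_id,
                    c(c1 = 20000L, c2 = 15000L))
  expect_setequal(unique(w$contig_id), c("c1", "c2"))
  w1 <- scan_windows(f1, f1$feature_id, c(c1 = 20000L))
  expect_equal(w$n_phage_genes[w$contig_id == "c1"], w1$n_phage_genes)
})
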