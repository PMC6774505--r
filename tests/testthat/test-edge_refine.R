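mk_pred <- function(start, end, stage = "preliminary", contig = "c1",
                    gene_ids = list(character(0))) {
  tibble::tibble(contig_id = contig, start = as.integer(start),
                 end = as.integer(end), stage = stage, gene_ids = gene_ids,
                 anchored_trnas = list(character(0)))
}
mk_feats <- function(starts, ends, ftype = "CDS", ids = NULL, contig = "c1") {
  n <- length(starts)
  ph <- if (ftype == "CDS") 0L else NA_integer_
  tibble::tibble(
    feature_id = if (is.null(ids)) paste0(tolower(ftype), seq_len(n)) else ids,
    contig_id = contig, start = as.integer(starts), end = as.integer(ends),
    strand = "+", ftype = ftype, product = "",
    phase = ph
  )
}

test_that("trimming contracts to the outermost phage-like genes", {
  feats <- mk_feats(c(2000, 8000, 5000), c(2500, 9000, 5600),
                    ids = c("p1", "p2", "np"))
  tr <- trim_to_phage_genes(mk_pred(0, 11000), feats, c("p1", "p2"))
  expect_equal(tr$start, 2000L)
  expect_equal(tr$end, 9000L)
  expect_equal(tr$stage, "trimmed")
  expect_equal(tr$gene_ids[[1]], c("p1", "p2"))
  # fixed point: boundary genes already touch both edges
  tr2 <- trim_to_phage_genes(mk_pred(2000, 9000), feats, c("p1", "p2"))
  expect_equal(tr2$start, 2000L)
  expect_equal(tr2$end, 9000L)
})

test_that("a prediction with no overlapping phage-like gene is discarded with a warning", {
  feats <- mk_feats(20000, 20500, ids = "p1")
  expect_warning(tr <- trim_to_phage_genes(mk_pred(0, 11000), feats, "p1"),
                 "discarded")
  expect_equal(nrow(tr), 0L)
})

test_that("trimming equals the min-start/max-end oracle and never enlarges", {
  set.seed(61)
  for (i in 1:25) {
    len <- 30000L
    feats <- random_gene_table(40, len)
    phage <- sample(feats$feature_id, 15)
    s <- sample.int(len - 12000L, 1) - 1L
    pred <- mk_pred(s, s + 12000L)
    g <- feats[feats$feature_id %in% phage &
                 feats$start < pred$end & feats$end > pred$start, ]
    tr <- suppressWarnings(trim_to_phage_genes(pred, feats, phage))
    if (nrow(g) == 0) {
      expect_equal(nrow(tr), 0L)
    } else {
      expect_equal(tr$start, max(pred$start, min(g$start)))
      expect_equal(tr$end, min(pred$end, max(g$end)))
      expect_gte(tr$start, pred$start)
      expect_lte(tr$end, pred$end)
    }
  }
})

test_that("borders move to the outward coordinates of tRNAs within the flank", {
  # upstream tRNA 1.5 kb from the left border: extension
  trna <- mk_feats(500, 580, ftype = "tRNA", ids = "t1")
  adj <- adjust_to_trna(mk_pred(2000, 9000, stage = "trimmed"), trna)
  expect_equal(adj$start, 500L)
  expect_equal(adj$end, 9000L)
  expect_equal(adj$stage, "final")
  expect_equal(adj$anchored_trnas[[1]], "t1")

  # tRNA inside the prediction within 3 kb of the left border: contraction
  trna_in <- mk_feats(2600, 2680, ftype = "tRNA", ids = "t2")
  adj2 <- adjust_to_trna(mk_pred(2000, 9000, stage = "trimmed"), trna_in)
  expect_equal(adj2$start, 2600L)
  expect_equal(adj2$end, 9000L)

  # no tRNA within either flank: unchanged
  trna_far <- mk_feats(15000, 15080, ftype = "tRNA", ids = "t3")
  adj3 <- adjust_to_trna(mk_pred(2000, 9000, stage = "trimmed"), trna_far)
  expect_equal(adj3$start, 2000L)
  expect_equal(adj3$end, 9000L)
  expect_equal(adj3$anchored_trnas[[1]], character(0))
})

test_that("the outermost of several in-range tRNAs wins", {
  trnas <- mk_feats(c(400, 1200), c(480, 1280), ftype = "tRNA",
                    ids = c("t_out", "t_in"))
  adj <- adjust_to_trna(mk_pred(2000, 9000, stage = "trimmed"), trnas)
  expect_equal(adj$start, 400L)
  expect_equal(adj$anchored_trnas[[1]], "t_out")
})

test_that("border movement is bounded by flank plus tRNA length", {
  set.seed(62)
  for (i in 1:25) {
    len <- 40000L
    n_t <- sample(0:6, 1)
    ts <- sort(sample.int(len - 200L, n_t))
    trnas <- mk_feats(ts, ts + sample(60:120, max(1, n_t))[seq_len(n_t)],
                      ftype = "tRNA",
                      ids = if (n_t > 0) paste0("t", seq_len(n_t)) else character(0))[seq_len(n_t), ]
    s <- sample(5000:25000, 1)
    pred <- mk_pred(s, s + sample(3000:9000, 1), stage = "trimmed")
    adj <- suppressWarnings(adjust_to_trna(pred, trnas))
    max_trna_len <- if (n_t > 0) max(trnas$end - trnas$start) else 0L
    expect_lte(abs(adj$start - pred$start), 3000L + max_trna_len)
    expect_lte(abs(adj$end - pred$end), 3000L + max_trna_len)
    expect_lt(adj$start, adj$end)
  }
})

test_that("finalize merges overlaps created by extension, sorts and names", {
  preds <- dplyr::bind_rows(
    mk_pred(8800, 15000, stage = "final",
            gene_ids = list(c("g3", "g4"))),
    mk_pred(500, 9000, stage = "final", gene_ids = list(c("g1", "g2")))
  )
  fin <- finalize_predictions(preds)
  expect_equal(nrow(fin), 1L)
  expect_equal(fin$start, 500L)
  expect_equal(fin$end, 15000L)
  expect_equal(fin$gene_ids[[1]], c("g1", "g2", "g3", "g4"))
  expect_equal(fin$name, "prophage_1")

  disjoint <- dplyr::bind_rows(
    mk_pred(20000, 26000, stage = "final"),
    mk_pred(500, 9000, stage = "final")
  )
  fin2 <- finalize_predictions(disjoint)
  expect_equal(fin2$start, c(500L, 20000L))
  expect_equal(fin2$name, c("prophage_1", "prophage_2"))
})

test_that("finalized predictions are pairwise disjoint on random fixtures", {
  set.seed(63)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    starts <- sample.int(50000L, n)
    preds <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      mk_pred(starts[j], starts[j] + sample(2000:9000, 1), stage = "final")
    }))
    fin <- finalize_predictions(preds)
    if (nrow(fin) > 1) {
      expect_true(all(fin$start[-1] > fin$end[-nrow(fin)]))
    }
    expect_equal(fin$name, paste0("prophage_", seq_len(nrow(fin))))
  }
})
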