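test_that("an implanted island yields one truth interval and well-formed fixtures", {
  sc <- sim_scenario(seed = 91, contig_len = 40000, gene_density = 1,
                     islands = list(sim_island(position = 15000,
                                               n_genes = 12, gene_len = 600,
                                               spacing = 150)))
  fx <- simulate_fixtures(sc)
  expect_equal(nrow(fx$truth), 1L)
  expect_equal(fx$truth$start, 15000L)
  expect_equal(fx$truth$end, 15000L + 12L * 600L + 11L * 150L)
  expect_equal(fx$genome$length, 40000L)
  expect_equal(nchar(fx$genome$sequence), 40000L)
  # island genes all carry below-cutoff hits
  isl_ids <- fx$features$feature_id[grepl("^island", fx$features$feature_id) &
                                      fx$features$ftype == "CDS"]
  flagged <- flag_phage_genes(fx$hits)$gene_id
  expect_true(all(isl_ids %in% flagged))
  # background weak hits never flag
  expect_false(any(grepl("^bg", flagged)))
})

test_that("a zero phage fraction yields empty truth and no predictions", {
  sc <- sim_scenario(seed = 92, contig_len = 40000, gene_density = 1,
                     islands = list(sim_island(position = 15000,
                                               n_genes = 12,
                                               phage_fraction = 0)))
  fx <- simulate_fixtures(sc)
  expect_equal(nrow(fx$truth), 0L)
  pred <- predict_prophages(fx$genome, fx$features, fx$hits)
  expect_equal(nrow(pred), 0L)
})

test_that("the same seed produces byte-identical fixture files", {
  sc <- sim_scenario(seed = 93, contig_len = 30000, gene_density = 1,
                     background_hit_rate = 0.05,
                     islands = list(sim_island(position = 10000,
                                               left_trna = 1000)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_fixtures(sc, dir = d1)
  simulate_fixtures(sc, dir = d2)
  for (f in c("genome.fasta", "annotation.gff3", "hits.tsv", "truth.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("overlapping islands and out-of-contig islands are rejected", {
  expect_error(
    sim_scenario(islands = list(sim_island(position = 1000, n_genes = 12),
                                sim_island(position = 4000, n_genes = 12)),
                 contig_len = 50000),
    "overlap")
  expect_error(
    sim_scenario(islands = list(sim_island(position = 48000, n_genes = 12)),
                 contig_len = 50000),
    "outside the contig")
})

test_that("flanking tRNAs extend the truth to their outward coordinates", {
  sc <- sim_scenario(seed = 94, contig_len = 40000, gene_density = 0.5,
                     islands = list(sim_island(position = 15000,
                                               n_genes = 10,
                                               left_trna = 1200,
                                               right_trna = 2500,
                                               trna_len = 80)))
  fx <- simulate_fixtures(sc)
  hull_end <- 15000L + 10L * 600L + 9L * 150L
  expect_equal(fx$truth$start, 15000L - 1200L - 80L)
  expect_equal(fx$truth$end, hull_end + 2500L + 80L)
  # a tRNA farther than the flank does not extend the truth
  sc_far <- sim_scenario(seed = 94, contig_len = 40000, gene_density = 0.5,
                         islands = list(sim_island(position = 15000,
                                                   n_genes = 10,
                                                   left_trna = 3500)))
  fx_far <- simulate_fixtures(sc_far)
  expect_equal(fx_far$truth$start, 15000L)
})

test_that("scattered decoys stay below threshold; clustered decoys cross it", {
  sc <- decoy_inject(sim_scenario(seed = 95, contig_len = 80000,
                                  gene_density = 1),
                     n_decoys = 5, spacing = 12000L)
  fx <- simulate_fixtures(sc)
  expect_equal(sum(grepl("^decoy", fx$features$feature_id)), 5L)
  pred <- predict_prophages(fx$genome, fx$features, fx$hits)
  expect_equal(nrow(pred), 0L)
  expect_equal(nrow(fx$truth), 0L)

  clustered <- decoy_inject(sim_scenario(seed = 95, contig_len = 80000,
                                         gene_density = 1),
                            n_decoys = 8, spacing = 1100L)
  fxc <- simulate_fixtures(clustered)
  predc <- predict_prophages(fxc$genome, fxc$features, fxc$hits)
  expect_equal(nrow(predc), 1L)   # the designed false positive
  expect_equal(nrow(fxc$truth), 0L)
})

test_that("detectable islands are recovered with high sensitivity and perfect ppv", {
  sens <- numeric(10)
  for (i in 1:10) {
    sc <- sim_scenario(seed = 600 + i, contig_len = 50000, gene_density = 1,
                       islands = list(sim_island(position = 20000,
                                                 n_genes = 12)))
    fx <- simulate_fixtures(sc)
    pred <- predict_prophages(fx$genome, fx$features, fx$hits)
    res <- evaluate_predictions(pred, fx$truth)
    expect_equal(res$ppv, 1)
    sens[i] <- res$sensitivity
  }
  expect_gte(mean(sens), 0.95)
})
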